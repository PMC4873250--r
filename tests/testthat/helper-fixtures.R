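# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: counting by substring scan, AUC by exhaustive
# pair enumeration.

random_sequences <- function(n, min_len = 2L, max_len = 500L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1L)
    paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# letter-by-letter counting, independent of tabulate/factor machinery
naive_discrete <- function(s) {
  counts <- vapply(amino_acids(), function(a) {
    sum(gregexpr(a, s, fixed = TRUE)[[1]] > 0)
  }, numeric(1))
  100 * counts / nchar(s)
}

# sliding-window substring scan over every ordered pair
naive_coupled <- function(s) {
  L <- nchar(s)
  windows <- substring(s, 1:(L - 1), 2:L)
  counts <- vapply(dipeptides(), function(p) sum(windows == p), numeric(1))
  100 * counts / (L - 1)
}

# exhaustive Mann-Whitney pair counting (ties count one half)
paircount_auc <- function(scores, labels, positive = 1) {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  total <- 0
  for (p in ps) for (q in ns) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(ps) * length(ns))
}

# a small trained predictor over two synthetic families + background
toy_predictor <- function(seed = 11L, encoding = "coupled") {
  gA <- make_family_generator("HSP20", residue_bias = c(D = 4, E = 4),
                              length_range = c(30L, 60L))
  gB <- make_family_generator("HSP70", residue_bias = c(K = 4, R = 4),
                              length_range = c(30L, 60L))
  bg <- make_family_generator("bg", length_range = c(30L, 60L))
  recsA <- sample_records(gA, 25, seed = seed)
  recsB <- sample_records(gB, 25, seed = seed + 1L)
  recsBg <- sample_records(bg, 50, seed = seed + 2L)
  hsp <- rbind(recsA, recsB)
  class(hsp) <- c("protein_set", "data.frame")
  t1 <- build_tier1(hsp, recsBg, encoding, kernel_config("rbf", gamma = 0.01),
                    seed = seed)
  t2 <- build_tier2(list(HSP20 = recsA, HSP70 = recsB), encoding,
                    kernel_config("rbf", gamma = 0.01), seed = seed)
  tiered_predictor(t1, t2)
}

toy_probe_records <- function(n = 100L, seed = 99L) {
  gens <- list(
    make_family_generator("pA", residue_bias = c(D = 4, E = 4),
                          length_range = c(30L, 60L)),
    make_family_generator("pB", residue_bias = c(K = 4, R = 4),
                          length_range = c(30L, 60L)),
    make_family_generator("pBg", length_range = c(30L, 60L)))
  parts <- lapply(seq_along(gens), function(k) {
    sample_records(gens[[k]], ceiling(n / 3), seed = seed + k)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  out <- out[seq_len(n), ]
  rownames(out) <- NULL
  structure(out, class = c("protein_set", "data.frame"))
}

.rbind_sets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  structure(out, class = c("protein_set", "data.frame"))
}

write_temp_fasta <- function(records, dir = tempdir(), name = "seqs.fasta") {
  path <- file.path(dir, name)
  write_fasta(records, path)
  path
}
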