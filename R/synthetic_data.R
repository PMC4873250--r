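# Seeded synthetic sequence corpora with controlled residue and dipeptide
# structure. Sequences are drawn from first-order Markov chains (not i.i.d.
# residues) so the coupled encoder carries signal beyond the discrete one;
# the benchmark emulates the training-corpus shape of the original problem:
# six family classes of very unequal size plus a larger background class.

#' Construct a family sequence generator
#'
#' A first-order Markov chain over the 20-letter alphabet. The transition
#' matrix is built from a base of uniform weights: `residue_bias` multiplies
#' the weight of selected target residues everywhere (shifting the
#' stationary composition), `pair_bias` multiplies the weight of selected
#' ordered transitions (creating dipeptide structure invisible to the
#' 20-dim encoder). Explicit `transition`/`init` override the construction.
#'
#' @param name Generator name; prefixes record ids.
#' @param residue_bias Named positive multipliers, e.g. `c(A = 3)` makes A
#'   roughly 3x as frequent as the unbiased residues at stationarity.
#' @param pair_bias Optional data.frame/list with elements `from`, `to`,
#'   `strength`: positive multipliers on the ordered transitions
#'   `from[k] -> to[k]`.
#' @param length_range Integer `c(min, max)`, min >= 2; sampled lengths are
#'   uniform over the range.
#' @param transition Optional explicit 20 x 20 row-stochastic matrix.
#' @param init Optional explicit initial distribution (length 20, sums to 1).
#' @param seed Default seed stored with the generator.
#' @return Object of class `family_generator`.
#' @export
#' @examples
#' g <- make_family_generator("Arich", residue_bias = c(A = 3))
make_family_generator <- function(name, residue_bias = NULL, pair_bias = NULL,
                                  length_range = c(50L, 400L),
                                  transition = NULL, init = NULL, seed = 1L) {
  aa <- amino_acids()
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 2L ||
      length_range[1] > length_range[2]) {
    stop("'length_range' must be c(min >= 2, max >= min)")
  }
  if (is.null(transition)) {
    w <- setNames(rep(1, 20L), aa)
    if (!is.null(residue_bias)) {
      if (is.null(names(residue_bias)) || !all(names(residue_bias) %in% aa)) {
        stop("'residue_bias' must be named by canonical residues")
      }
      if (any(!is.finite(residue_bias)) || any(residue_bias <= 0)) {
        stop("'residue_bias' multipliers must be positive")
      }
      w[names(residue_bias)] <- residue_bias
    }
    B <- matrix(1, 20L, 20L, dimnames = list(aa, aa))
    if (!is.null(pair_bias)) {
      pb <- as.data.frame(pair_bias, stringsAsFactors = FALSE)
      if (!all(c("from", "to", "strength") %in% names(pb))) {
        stop("'pair_bias' needs elements from, to, strength")
      }
      if (!all(pb$from %in% aa) || !all(pb$to %in% aa)) {
        stop("'pair_bias' residues must be canonical")
      }
      if (any(!is.finite(pb$strength)) || any(pb$strength <= 0)) {
        stop("'pair_bias' strengths must be positive")
      }
      for (k in seq_len(nrow(pb))) {
        B[pb$from[k], pb$to[k]] <- B[pb$from[k], pb$to[k]] * pb$strength[k]
      }
    }
    transition <- sweep(B, 2L, w, `*`)
    transition <- transition / rowSums(transition)
    if (is.null(init)) init <- w / sum(w)
  } else {
    transition <- as.matrix(transition)
    if (!identical(dim(transition), c(20L, 20L))) {
      stop("'transition' must be 20 x 20")
    }
    if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
      stop("'transition' rows must be non-negative and sum to 1")
    }
    if (is.null(init)) init <- rep(1 / 20, 20L)
  }
  init <- as.numeric(init)
  if (length(init) != 20L || any(init < 0) || abs(sum(init) - 1) > 1e-12) {
    stop("'init' must be 20 non-negative probabilities summing to 1")
  }
  dimnames(transition) <- list(aa, aa)
  structure(list(name = name, init = setNames(init, aa),
                 transition = transition, length_range = length_range,
                 seed = as.integer(seed)),
            class = "family_generator")
}

#' Stationary distribution of a generator's chain
#'
#' Left eigenvector of the transition matrix (eigenvalue 1), normalized to
#' sum to 1; the long-run residue composition of sampled sequences.
#'
#' @param generator A [make_family_generator()].
#' @return Named numeric vector of 20 probabilities.
#' @export
stationary_distribution <- function(generator) {
  e <- eigen(t(generator$transition))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  setNames(v / sum(v), amino_acids())
}

#' Sample protein records from a generator
#'
#' Lengths uniform over the generator's range; residues by the first-order
#' chain. Identical (generator, n, seed) give identical records.
#'
#' @param generator A [make_family_generator()].
#' @param n Number of records (>= 1).
#' @param seed Integer seed (defaults to the generator's).
#' @return A [protein_set()] with ids `<name>_0001`, ...
#' @export
sample_records <- function(generator, n, seed = generator$seed) {
  stopifnot(inherits(generator, "family_generator"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  lr <- generator$length_range
  lengths <- if (lr[1] == lr[2]) rep(lr[1], n) else
    sample(seq(lr[1], lr[2]), n, replace = TRUE)
  seqs <- .sample_chains(cumsum(generator$init),
                         t(apply(generator$transition, 1L, cumsum)),
                         as.integer(lengths), amino_acids())
  protein_set(sprintf("%s_%04d", generator$name, seq_len(n)), seqs)
}

# Fixed family signatures: three residue triples, each shared by a pair of
# families that differ only in the orientation of the boosted transition
# cycle (r1->r2->r3->r1 vs the reverse). Paired families therefore share
# stationary residue composition and are separable only through dipeptide
# order, which is what makes the coupled encoder genuinely stronger than
# the discrete one on this benchmark.
.family_signatures <- function() {
  list(HSP20 = list(triple = c("D", "E", "S"), forward = TRUE),
       HSP40 = list(triple = c("D", "E", "S"), forward = FALSE),
       HSP60 = list(triple = c("K", "R", "G"), forward = TRUE),
       HSP70 = list(triple = c("K", "R", "G"), forward = FALSE),
       HSP90 = list(triple = c("F", "Y", "Q"), forward = TRUE),
       HSP100 = list(triple = c("F", "Y", "Q"), forward = FALSE))
}

.separation_strength <- function(level) {
  switch(level, strong = 5, moderate = 2.5, weak = 1.4,
         stop("unknown separation level: ", level))
}

.signature_generator <- function(family, level, length_range) {
  sig <- .family_signatures()[[family]]
  s <- .separation_strength(level)
  tr <- sig$triple
  cyc <- if (sig$forward) {
    data.frame(from = tr, to = tr[c(2, 3, 1)], strength = s * s)
  } else {
    data.frame(from = tr, to = tr[c(3, 1, 2)], strength = s * s)
  }
  make_family_generator(family,
                        residue_bias = setNames(rep(s, 3), tr),
                        pair_bias = cyc, length_range = length_range)
}

#' Benchmark specification
#'
#' The default class shape is the original training corpus scaled down by 5
#' (minimum 12 per class): 71/256/33/57/12/17 family records plus 2000
#' background records. `separation` controls how far the family chains
#' diverge from uniform (and from each other).
#'
#' @param counts Named integer vector over the six families plus
#'   `background`; all >= 2.
#' @param separation `"strong"`, `"moderate"` or `"weak"`.
#' @param length_range Sequence length range, default `c(50, 400)`.
#' @param seed Master seed.
#' @return Object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(counts = c(HSP20 = 71L, HSP40 = 256L, HSP60 = 33L,
                                      HSP70 = 57L, HSP90 = 12L, HSP100 = 17L,
                                      background = 2000L),
                           separation = c("strong", "moderate", "weak"),
                           length_range = c(50L, 400L), seed = 101L) {
  separation <- match.arg(separation)
  need <- c(hsp_families(), "background")
  if (!all(need %in% names(counts))) {
    stop("'counts' must name all of: ", paste(need, collapse = ", "))
  }
  counts <- vapply(counts[need], as.integer, integer(1))
  if (any(is.na(counts)) || any(counts < 2L)) stop("all counts must be >= 2")
  structure(list(counts = counts, separation = separation,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a labelled synthetic benchmark corpus
#'
#' Six family classes from signature Markov chains plus a background class
#' from the uniform chain, with per-class record counts exactly as
#' specified. Deterministic given the spec's master seed.
#'
#' @param spec A [benchmark_spec()].
#' @return List of class `benchmark_corpus`: `records` ([protein_set()]),
#'   `tier1` (`"HSP"`/`"non-HSP"` per record), `family` (family label or
#'   `NA` for background), `spec`.
#' @export
make_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  parts <- list(); tier1 <- character(0); family <- character(0)
  for (k in seq_along(hsp_families())) {
    fam <- hsp_families()[k]
    gen <- .signature_generator(fam, spec$separation, spec$length_range)
    recs <- sample_records(gen, spec$counts[[fam]],
                           seed = spec$seed + 7919L * k)
    parts[[length(parts) + 1L]] <- recs
    tier1 <- c(tier1, rep("HSP", nrow(recs)))
    family <- c(family, rep(fam, nrow(recs)))
  }
  bg_gen <- make_family_generator("background",
                                  length_range = spec$length_range)
  bg <- sample_records(bg_gen, spec$counts[["background"]],
                       seed = spec$seed + 7919L * 7L)
  parts[[length(parts) + 1L]] <- bg
  tier1 <- c(tier1, rep("non-HSP", nrow(bg)))
  family <- c(family, rep(NA_character_, nrow(bg)))
  records <- do.call(.bind_protein_sets, parts)
  structure(list(records = records, tier1 = tier1, family = family,
                 spec = spec),
            class = "benchmark_corpus")
}

#' Export a benchmark corpus as FASTA plus a label manifest
#'
#' The manifest is the same three-column TSV (`id`, `tier1_label`,
#' `family_label`) the training workflow consumes.
#'
#' @param corpus A [make_benchmark()] corpus.
#' @param fasta_path,manifest_path Output files.
#' @return Invisibly, `c(fasta_path, manifest_path)`.
#' @export
export_corpus <- function(corpus, fasta_path, manifest_path) {
  stopifnot(inherits(corpus, "benchmark_corpus"))
  write_fasta(corpus$records, fasta_path)
  write.table(
    data.frame(id = corpus$records$id, tier1_label = corpus$tier1,
               family_label = ifelse(is.na(corpus$family), "", corpus$family),
               stringsAsFactors = FALSE),
    manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, manifest_path))
}

#' Read a label manifest
#'
#' @param path TSV with columns `id`, `tier1_label` and optionally
#'   `family_label` (empty string = no family).
#' @return data.frame with `id`, `tier1_label`, `family_label` (NA when
#'   absent/empty).
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("id", "tier1_label") %in% names(m))) {
    stop("manifest needs columns id, tier1_label")
  }
  if (!"family_label" %in% names(m)) m$family_label <- NA_character_
  m$family_label[!nzchar(m$family_label) | is.na(m$family_label)] <- NA_character_
  m
}
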