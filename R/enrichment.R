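# Compositional enrichment/depletion profiling: the per-residue fractional
# difference (X_aa - Y_aa) / Y_aa between pooled residue fractions of a
# query and a background sample, with seeded bootstrap significance and
# biochemistry-group summaries.

#' Pooled residue fractions of a protein set
#'
#' Fraction of each canonical residue among all residues of the sample
#' (sequences pooled, not averaged per sequence); sums to 1.
#'
#' @param records A [protein_set()].
#' @return Named numeric vector of 20 fractions.
#' @export
pooled_fraction <- function(records) {
  records <- as_protein_set(records)
  counts <- colSums(.residue_count_matrix(records))
  total <- sum(counts)
  if (total < 1) stop("no residues in sample")
  counts / total
}

.residue_count_matrix <- function(records) {
  t(vapply(records$residues, function(s) {
    tabulate(.residue_factor(s), nbins = 20L)
  }, integer(20L), USE.NAMES = FALSE)) |>
    `colnames<-`(amino_acids())
}

#' Fractional difference between two residue fractions
#'
#' `(X - Y) / Y`: the relative enrichment (positive) or depletion
#' (negative) of a residue in the query sample X against the background
#' sample Y. A residue absent from the background (Y = 0) yields `NA` with
#' a warning.
#'
#' @param query_fraction,background_fraction Numeric (vectorized).
#' @return Numeric vector of fractional differences.
#' @export
#' @examples
#' fractional_difference(0.10, 0.05) # +1: doubled
#' fractional_difference(0.02, 0.08) # -0.75
fractional_difference <- function(query_fraction, background_fraction) {
  out <- (query_fraction - background_fraction) / background_fraction
  zero <- background_fraction == 0
  if (any(zero)) {
    warning("residue(s) absent from background: fractional difference undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Bootstrap enrichment/depletion test
#'
#' For each residue, the observed fractional difference between pooled
#' query and background fractions, with a two-sided p-value from a seeded
#' bootstrap: sequences are resampled with replacement within each sample,
#' the statistic recomputed, and the bootstrap distribution recentred at 0
#' serves as the null spread (p = fraction of recentred replicates at least
#' as extreme as the observation, with the +1 continuity correction). Calls
#' at level `alpha`: `enriched` (difference > 0, p <= alpha), `depleted`
#' (< 0, p <= alpha), else `not-significant`.
#'
#' @param query,background Non-empty [protein_set()]s.
#' @param iterations Bootstrap replicates (>= 100; default 10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; results are deterministic given it.
#' @param adjust `"none"` (default, per-residue significance) or `"BH"` for
#'   Benjamini-Hochberg correction across the 20 residues.
#' @return Object of class `enrichment_result`: data.frame with columns
#'   `residue`, `query_fraction`, `background_fraction`,
#'   `fractional_difference`, `p_value`, `call`; attributes `alpha`,
#'   `iterations`, `seed`.
#' @export
enrichment_test <- function(query, background, iterations = 10000L,
                            alpha = 0.05, seed = 1L,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 100L) {
    stop("'iterations' must be >= 100")
  }
  query <- as_protein_set(query)
  background <- as_protein_set(background)
  qc <- .residue_count_matrix(query)
  bc <- .residue_count_matrix(background)
  xf <- colSums(qc) / sum(qc)
  yf <- colSums(bc) / sum(bc)
  obs <- fractional_difference(xf, yf)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  nq <- nrow(qc); nb <- nrow(bc)
  boot <- matrix(NA_real_, iterations, 20L)
  for (b in seq_len(iterations)) {
    qs <- colSums(qc[sample.int(nq, nq, replace = TRUE), , drop = FALSE])
    bs <- colSums(bc[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
    boot[b, ] <- suppressWarnings((qs / sum(qs) - bs / sum(bs)) / (bs / sum(bs)))
  }
  # recentre the bootstrap distribution at 0 to form the null spread
  centred <- sweep(boot, 2L, obs, `-`)
  p <- vapply(seq_len(20L), function(k) {
    if (is.na(obs[k])) return(NA_real_)
    ex <- sum(abs(centred[, k]) >= abs(obs[k]), na.rm = TRUE)
    (ex + 1) / (iterations + 1)
  }, numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  call <- rep("not-significant", 20L)
  call[!is.na(p) & p <= alpha & obs > 0] <- "enriched"
  call[!is.na(p) & p <= alpha & obs < 0] <- "depleted"
  structure(
    data.frame(residue = amino_acids(), query_fraction = unname(xf),
               background_fraction = unname(yf),
               fractional_difference = unname(obs), p_value = p,
               call = call, stringsAsFactors = FALSE),
    alpha = alpha, iterations = iterations, seed = as.integer(seed),
    class = c("enrichment_result", "data.frame"))
}

#' Residue-group summary of an enrichment result
#'
#' Aggregates the 20 per-residue calls into conventional biochemistry
#' groups (overlapping membership — e.g. H, F, W, Y — is intentional and
#' documented): positively charged K/R/H, negatively charged D/E, polar
#' uncharged S/T/N/Q/C/Y, hydrophobic A/V/L/I/M/F/W/G/P, aromatic F/W/Y/H.
#' Each group is reported with its member calls and the majority direction
#' among significant members (`"no signal"` when none is significant,
#' `"mixed"` on an exact tie).
#'
#' @param result An [enrichment_test()] result.
#' @param groups Named list of residue character vectors (override to
#'   redefine group membership).
#' @return data.frame: `group`, `members`, `n_enriched`, `n_depleted`,
#'   `direction`.
#' @export
grouped_summary <- function(result, groups = residue_groups()) {
  stopifnot(inherits(result, "enrichment_result"))
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    sub <- result[result$residue %in% members, ]
    ne <- sum(sub$call == "enriched")
    nd <- sum(sub$call == "depleted")
    direction <- if (ne == 0 && nd == 0) "no signal"
      else if (ne > nd) "enriched"
      else if (nd > ne) "depleted"
      else "mixed"
    data.frame(group = g, members = paste(members, collapse = ","),
               n_enriched = ne, n_depleted = nd, direction = direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conventional residue groups
#' @return Named list of residue vectors used by [grouped_summary()].
#' @export
residue_groups <- function() {
  list(positively_charged = c("K", "R", "H"),
       negatively_charged = c("D", "E"),
       polar_uncharged = c("S", "T", "N", "Q", "C", "Y"),
       hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "G", "P"),
       aromatic = c("F", "W", "Y", "H"))
}

#' Write an enrichment result as TSV
#' @param result An [enrichment_test()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
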