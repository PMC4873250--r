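# Fixed-length percentage composition encoders. A variable-length protein
# becomes either a 20-dim residue composition vector,
#   comp(i) = 100 * count(residue i) / N,
# or a 400-dim coupled (dipeptide) composition vector,
#   coupled(j) = 100 * count(ordered adjacent pair j) / (L - 1),
# overlapping pairs counted. Both sum to 100 per sequence; values are kept in
# double precision with no further standardization.

.residue_factor <- function(residues) {
  factor(strsplit(residues, "", fixed = TRUE)[[1]], levels = amino_acids())
}

#' Discrete amino-acid composition
#'
#' Percentage frequency of each of the 20 canonical residues in one
#' sequence: a vector of 20 dimensions summing to 100.
#'
#' @param record A single-row [protein_set()] or a residue string.
#' @return Named numeric vector of length 20 (canonical residue order) with
#'   attribute `n`, the residue count N.
#' @export
#' @examples
#' discrete_composition("ACDA")
discrete_composition <- function(record) {
  residues <- .residue_string(record)
  n <- nchar(residues)
  if (n < 1L) stop("empty sequence: discrete composition undefined")
  counts <- tabulate(.residue_factor(residues), nbins = 20L)
  structure(setNames(100 * counts / n, amino_acids()), n = n)
}

#' Coupled (dipeptide) amino-acid composition
#'
#' Percentage frequency of each of the 400 ordered residue pairs among the
#' overlapping adjacent pairs of one sequence (L - 1 pairs for length L),
#' giving a fixed pattern length of 400. A coupling `gap` g counts pairs of
#' residues g + 1 positions apart (default 0 = adjacent dipeptides).
#'
#' @param record A single-row [protein_set()] or a residue string.
#' @param gap Non-negative integer coupling gap; the denominator becomes
#'   L - 1 - gap.
#' @return Named numeric vector of length 400 (first residue varying
#'   slowest) with attribute `n_pairs`.
#' @export
#' @examples
#' coupled_composition("ACAC")[c("AC", "CA")]
coupled_composition <- function(record, gap = 0L) {
  residues <- .residue_string(record)
  gap <- as.integer(gap)
  if (is.na(gap) || gap < 0L) stop("'gap' must be a non-negative integer")
  L <- nchar(residues)
  if (L < 2L + gap) {
    stop("sequence too short for coupled encoding (length ", L,
         ", need >= ", 2L + gap, ")")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  first <- chars[seq_len(L - 1L - gap)]
  second <- chars[seq_len(L - 1L - gap) + 1L + gap]
  pairs <- factor(paste0(first, second), levels = dipeptides())
  counts <- tabulate(pairs, nbins = 400L)
  n_pairs <- L - 1L - gap
  structure(setNames(100 * counts / n_pairs, dipeptides()), n_pairs = n_pairs)
}

.residue_string <- function(record) {
  if (is.character(record) && length(record) == 1L) {
    x <- toupper(record)
    if (grepl(.invalid_regex, x)) stop("non-canonical residues in input")
    return(x)
  }
  rec <- as_protein_set(record)
  if (nrow(rec) != 1L) stop("expected a single record")
  rec$residues
}

#' Encode a protein set as a feature matrix
#'
#' Batch form of the two encoders: one row per record, columns in canonical
#' residue / dipeptide order. Records ineligible for the chosen encoding
#' (shorter than 2 + gap residues under `coupled`) are reported in an
#' aggregated error rather than silently dropped.
#'
#' @param records A [protein_set()].
#' @param encoding `"coupled"` (default) or `"discrete"`.
#' @param labels Optional vector aligned 1:1 with `records`.
#' @param gap Coupling gap for `"coupled"` (default 0).
#' @return List with `features` (numeric matrix, rownames = record ids) and
#'   `labels` (as given, or `NULL`).
#' @export
encode_dataset <- function(records, encoding = c("coupled", "discrete"),
                           labels = NULL, gap = 0L) {
  records <- as_protein_set(records)
  encoding <- match.arg(encoding)
  if (!is.null(labels) && length(labels) != nrow(records)) {
    stop("'labels' must align 1:1 with 'records'")
  }
  min_len <- if (encoding == "coupled") 2L + as.integer(gap) else 1L
  short <- nchar(records$residues) < min_len
  if (any(short)) {
    stop("record(s) ineligible for ", encoding, " encoding (length < ",
         min_len, "): ", paste(records$id[short], collapse = ", "))
  }
  rows <- if (encoding == "discrete") {
    lapply(records$residues, discrete_composition)
  } else {
    lapply(records$residues, coupled_composition, gap = gap)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- records$id
  list(features = features, labels = labels, encoding = encoding)
}

#' Write a feature matrix as TSV
#'
#' Header row of residue/pair names preceded by an `id` column; one row per
#' record.
#'
#' @param features Matrix from [encode_dataset()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
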