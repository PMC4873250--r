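# Reading, sanitizing and writing protein sequences. All downstream modules
# rely on the contract enforced here: residues are uppercase letters drawn
# from the canonical 20-letter alphabet, ids are non-empty and unique.

#' Construct a sanitation policy
#'
#' Controls how non-canonical residues (B, J, O, U, X, Z, stop codons `*`,
#' gap characters, digits, whitespace) are handled when sequences enter the
#' package. Under `"skip-invalid"` (the default) offending characters are
#' dropped so that the 20- and 400-dimensional feature spaces stay exact;
#' under `"strict"` any non-canonical character rejects the record.
#'
#' @param mode `"skip-invalid"` or `"strict"`.
#' @return An object of class `sanitize_policy`.
#' @export
sanitize_policy <- function(mode = c("skip-invalid", "strict")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "sanitize_policy")
}

#' Build a protein sequence set
#'
#' The package's working container for sequence collections: a data.frame
#' with columns `id`, `description` and `residues`, one row per protein.
#' Sequences are uppercased and validated against the canonical alphabet;
#' duplicate ids are disambiguated with numeric suffixes (`id`, `id_2`, ...)
#' with a warning, preserving input order.
#'
#' @param id Character vector of non-empty identifiers.
#' @param residues Character vector of sequences (canonical residues only
#'   after uppercasing; use [read_fasta()] for raw external input).
#' @param description Optional character vector of free-text descriptions.
#' @return A `protein_set` data.frame.
#' @export
#' @examples
#' protein_set(c("a", "b"), c("ACDA", "MKV"))
protein_set <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (length(id) == 0L) stop("no records: a protein_set must be non-empty")
  if (any(!nzchar(id))) stop("protein ids must be non-empty")
  bad <- grepl(.invalid_regex, residues)
  if (any(bad)) {
    stop("non-canonical residues in record(s): ",
         paste(id[bad], collapse = ", "),
         " (sanitize via read_fasta or sanitize_residues first)")
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence in record(s): ", paste(id[!nzchar(residues)], collapse = ", "))
  }
  description <- rep_len(as.character(description), length(id))
  id <- .dedupe_ids(id)
  structure(
    data.frame(id = id, description = description, residues = residues,
               stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame"))
}

.invalid_regex <- "[^ACDEFGHIKLMNPQRSTVWY]"

.dedupe_ids <- function(id) {
  if (!anyDuplicated(id)) return(id)
  out <- id
  seen <- new.env(parent = emptyenv())
  for (k in seq_along(id)) {
    key <- id[[k]]
    count <- if (is.null(seen[[key]])) 0L else seen[[key]]
    if (count > 0L) out[[k]] <- paste0(key, "_", count + 1L)
    seen[[key]] <- count + 1L
  }
  warning("duplicate ids disambiguated: ",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  out
}

#' Sanitize a residue string
#'
#' Uppercases, then either drops every non-canonical character
#' (`skip-invalid`) or signals an error naming the record (`strict`).
#' Idempotent: sanitizing an already-clean sequence is the identity.
#'
#' @param x Character vector of raw sequences.
#' @param policy A [sanitize_policy()].
#' @param id Identifiers used in error messages.
#' @return Character vector of cleaned sequences (possibly empty strings
#'   under `skip-invalid`; callers must check).
#' @export
sanitize_residues <- function(x, policy = sanitize_policy(), id = NULL) {
  stopifnot(inherits(policy, "sanitize_policy"))
  x <- toupper(as.character(x))
  if (is.null(id)) id <- paste0("record ", seq_along(x))
  if (policy$mode == "strict") {
    bad <- grepl(.invalid_regex, x)
    if (any(bad)) {
      stop("strict sanitation rejected record(s) with non-canonical residues: ",
           paste(id[bad], collapse = ", "))
    }
    x
  } else {
    gsub(.invalid_regex, "", x)
  }
}

#' Read protein sequences from FASTA
#'
#' Parses a (possibly multi-record, arbitrarily wrapped) FASTA file, applies
#' the sanitation policy and returns a [protein_set()]. The first whitespace
#' separated token of each header is the id; the remainder the description.
#' Records emptied by `skip-invalid` sanitation are rejected with an error
#' naming them, as is any non-canonical character under `strict`.
#'
#' @param source Path to a FASTA file (or connection readable by
#'   `Biostrings::readBStringSet`).
#' @param policy A [sanitize_policy()].
#' @return A `protein_set` in input order.
#' @export
read_fasta <- function(source, policy = sanitize_policy()) {
  seqs <- Biostrings::readBStringSet(source, format = "fasta")
  if (length(seqs) == 0L) stop("no records in FASTA input: ", source)
  headers <- names(seqs)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  raw <- as.character(seqs)
  clean <- sanitize_residues(raw, policy, id = id)
  emptied <- !nzchar(clean)
  if (any(emptied)) {
    stop("record(s) emptied by sanitation: ", paste(id[emptied], collapse = ", "))
  }
  protein_set(id, clean, description)
}

#' Write a protein set to FASTA
#'
#' Round-trip safe: `read_fasta(write_fasta(x, f))` reproduces ids and
#' residues exactly.
#'
#' @param records A [protein_set()].
#' @param sink Output file path.
#' @param width Sequence line width (default 60).
#' @return Invisibly, `sink`.
#' @export
write_fasta <- function(records, sink, width = 60L) {
  records <- as_protein_set(records)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("'width' must be a positive integer")
  seqs <- Biostrings::AAStringSet(records$residues)
  names(seqs) <- ifelse(nzchar(records$description),
                        paste(records$id, records$description),
                        records$id)
  Biostrings::writeXStringSet(seqs, filepath = sink, width = width)
  invisible(sink)
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "record(s); residue lengths",
      min(nchar(x$residues)), "-", max(nchar(x$residues)), "\n")
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more\n")
  invisible(x)
}

#' Coerce to protein_set
#' @param x A `protein_set` or data.frame with `id` and `residues` columns.
#' @return A `protein_set`.
#' @export
as_protein_set <- function(x) {
  if (inherits(x, "protein_set")) return(x)
  if (is.data.frame(x) && all(c("id", "residues") %in% names(x))) {
    return(protein_set(x$id, x$residues,
                       if ("description" %in% names(x)) x$description else ""))
  }
  stop("cannot coerce to protein_set")
}

# rbind that keeps the class; base rbind.data.frame drops it
.bind_protein_sets <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  df <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(df) <- NULL
  structure(df, class = c("protein_set", "data.frame"))
}
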