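# The two-tier prediction schema: a tier-1 gate discriminating HSPs from
# non-HSPs, six tier-2 one-vs-rest family models, argmax family resolution
# with canonical-order tie-break, and text-based bundle persistence.

.bundle_format_version <- "1"

#' Train the tier-1 HSP / non-HSP gate
#'
#' One binary model with HSPs positive and non-HSPs negative, trained on the
#' chosen composition encoding.
#'
#' @param hsp_records,non_hsp_records Non-empty [protein_set()]s.
#' @param encoding `"coupled"` (default) or `"discrete"`.
#' @param config A [kernel_config()].
#' @param seed Integer.
#' @return A `binary_model` with positive semantics `"HSP"`.
#' @export
build_tier1 <- function(hsp_records, non_hsp_records,
                        encoding = c("coupled", "discrete"),
                        config = kernel_config(), seed = 1L) {
  encoding <- match.arg(encoding)
  hsp_records <- as_protein_set(hsp_records)
  non_hsp_records <- as_protein_set(non_hsp_records)
  all <- .bind_protein_sets(hsp_records, non_hsp_records)
  labels <- c(rep(1, nrow(hsp_records)), rep(-1, nrow(non_hsp_records)))
  enc <- encode_dataset(all, encoding)
  train_binary(enc$features, labels, config, seed = seed,
               encoding = encoding, positive = "HSP")
}

#' Train the tier-2 one-vs-rest family models
#'
#' For each family F, a binary model with F's proteins positive and the
#' union of all other families' proteins negative. Families are keyed by the
#' canonical labels of [hsp_families()] (other names are allowed but keep
#' their given order after the canonical ones).
#'
#' @param family_records Named list mapping family label to a
#'   [protein_set()]; at least two non-empty families.
#' @param encoding `"coupled"` or `"discrete"`.
#' @param config A single [kernel_config()] shared by all families, or a
#'   named list giving one per family (published winning parameters differ
#'   per family).
#' @param seed Integer.
#' @return Named list of `binary_model`s, one per input family.
#' @export
build_tier2 <- function(family_records, encoding = c("coupled", "discrete"),
                        config = kernel_config(), seed = 1L) {
  encoding <- match.arg(encoding)
  if (is.null(names(family_records)) || any(!nzchar(names(family_records)))) {
    stop("'family_records' must be a named list")
  }
  if (length(family_records) < 2L) {
    stop("one-vs-rest training needs at least 2 families")
  }
  fams <- names(family_records)
  canon <- intersect(hsp_families(), fams)
  fams <- c(canon, setdiff(fams, canon))
  sets <- lapply(family_records[fams], as_protein_set)
  sizes <- vapply(sets, nrow, integer(1))
  all <- do.call(.bind_protein_sets, unname(sets))
  fam_of_row <- rep(fams, sizes)
  enc <- encode_dataset(all, encoding)
  models <- lapply(fams, function(f) {
    cfg <- if (inherits(config, "kernel_config")) config else {
      if (is.null(config[[f]])) stop("no kernel_config for family ", f)
      config[[f]]
    }
    labels <- ifelse(fam_of_row == f, 1, -1)
    train_binary(enc$features, labels, cfg, seed = seed,
                 encoding = encoding, positive = f)
  })
  setNames(models, fams)
}

#' Assemble a tiered predictor
#'
#' @param tier1 Gate `binary_model` (positive = HSP).
#' @param tier2 Named list of family `binary_model`s.
#' @param threshold Tier-1 decision threshold (default 0).
#' @param metadata Optional list carried into the bundle manifest.
#' @return Object of class `tiered_predictor`.
#' @export
tiered_predictor <- function(tier1, tier2, threshold = 0, metadata = list()) {
  stopifnot(inherits(tier1, "binary_model"))
  if (length(tier2) < 2L || is.null(names(tier2))) {
    stop("'tier2' must be a named list of >= 2 binary models")
  }
  encs <- c(tier1$encoding, vapply(tier2, `[[`, "", "encoding"))
  if (length(unique(encs)) != 1L) {
    stop("all seven models must share one encoding, got: ",
         paste(unique(encs), collapse = ", "))
  }
  stamp <- list(built = format(Sys.time(), tz = "UTC"),
                version = as.character(packageVersion("hsptier")))
  metadata <- c(metadata, stamp[setdiff(names(stamp), names(metadata))])
  structure(list(tier1 = tier1, tier2 = tier2,
                 encoding = tier1$encoding, threshold = threshold,
                 metadata = metadata),
            class = "tiered_predictor")
}

#' @export
print.tiered_predictor <- function(x, ...) {
  cat(sprintf(
    "tiered_predictor (%s encoding): tier-1 gate + %d family models (%s); threshold %g\n",
    x$encoding, length(x$tier2), paste(names(x$tier2), collapse = ", "),
    x$threshold))
  invisible(x)
}

#' Predict HSP status and family for a set of proteins
#'
#' Each record passes the tier-1 gate (`is_hsp` iff tier-1 score >=
#' threshold). Gate-negative records are filtered out of tier 2: they get no
#' family and no family scores. Gate-positive records are scored by every
#' family model; the family is the argmax of the decision values, ties
#' broken by canonical family order, and the verdict is flagged low
#' confidence when even the winning score is negative. Records ineligible
#' for the predictor's encoding yield a per-record error entry; the run
#' continues.
#'
#' @param object A [tiered_predictor()].
#' @param records A [protein_set()].
#' @param ... Unused.
#' @return data.frame of verdicts in input order: `id`, `is_hsp`,
#'   `tier1_score`, `family` (NA for non-HSPs), per-family score columns
#'   (`score.HSP20`, ... — NA for non-HSPs), `confidence` (`"normal"`,
#'   `"low"`, or `"error"`), `error` message.
#' @export
predict.tiered_predictor <- function(object, records, ...) {
  records <- as_protein_set(records)
  fams <- names(object$tier2)
  min_len <- if (object$encoding == "coupled") 2L else 1L
  eligible <- nchar(records$residues) >= min_len
  n <- nrow(records)
  out <- data.frame(id = records$id, is_hsp = NA, tier1_score = NA_real_,
                    family = NA_character_, stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, n, length(fams),
                   dimnames = list(NULL, paste0("score.", fams)))
  confidence <- rep(NA_character_, n)
  errmsg <- rep(NA_character_, n)
  errmsg[!eligible] <- paste0("sequence too short for ", object$encoding,
                              " encoding")
  confidence[!eligible] <- "error"
  if (any(eligible)) {
    enc <- encode_dataset(records[eligible, , drop = FALSE], object$encoding)
    t1 <- decision_value(object$tier1, enc$features)
    out$tier1_score[eligible] <- t1
    out$is_hsp[eligible] <- t1 >= object$threshold
    hsp_rows <- which(eligible)[t1 >= object$threshold]
    if (length(hsp_rows)) {
      feat <- enc$features[t1 >= object$threshold, , drop = FALSE]
      fam_scores <- vapply(object$tier2,
                           function(m) decision_value(m, feat),
                           numeric(nrow(feat)))
      fam_scores <- matrix(fam_scores, nrow = nrow(feat),
                           dimnames = list(NULL, fams))
      scores[hsp_rows, ] <- fam_scores
      # argmax with canonical-order tie-break: canonical order is the
      # column order fixed by build_tier2, and max.col("first") honours it
      win <- max.col(fam_scores, ties.method = "first")
      out$family[hsp_rows] <- fams[win]
      best <- fam_scores[cbind(seq_len(nrow(fam_scores)), win)]
      confidence[hsp_rows] <- ifelse(best >= 0, "normal", "low")
    }
    confidence[setdiff(which(eligible), hsp_rows)] <- "normal"
  }
  cbind(out, as.data.frame(scores),
        data.frame(confidence = confidence, error = errmsg,
                   stringsAsFactors = FALSE))
}

#' Write a verdict table as TSV
#'
#' @param verdicts Output of [predict.tiered_predictor()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_verdicts_tsv <- function(verdicts, path) {
  write.table(verdicts, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# ---- persistence ----------------------------------------------------------

.model_to_list <- function(m) {
  list(positive = m$positive, encoding = m$encoding, dim = m$dim,
       config = m$config[c("kernel", "degree", "gamma", "cost_ratio", "C")],
       rho = m$rho, coef = m$coef, sv = m$sv,
       n_pos = m$n_pos, n_neg = m$n_neg, seed = m$seed)
}

.model_from_list <- function(l, what) {
  need <- c("positive", "encoding", "dim", "config", "rho", "coef", "sv")
  miss <- setdiff(need, names(l))
  if (length(miss)) {
    stop("corrupt bundle component '", what, "': missing ",
         paste(miss, collapse = ", "))
  }
  cfg <- l$config
  config <- kernel_config(cfg$kernel,
                          degree = if (is.null(cfg$degree) || is.na(cfg$degree)) 3L else cfg$degree,
                          gamma = if (is.null(cfg$gamma) || is.na(cfg$gamma)) 0.01 else cfg$gamma,
                          cost_ratio = cfg$cost_ratio, C = cfg$C)
  sv <- l$sv
  if (!is.matrix(sv)) sv <- matrix(unlist(sv), ncol = l$dim, byrow = TRUE)
  storage.mode(sv) <- "double"
  structure(list(sv = sv, coef = as.numeric(l$coef), rho = as.numeric(l$rho),
                 config = config, encoding = l$encoding,
                 dim = as.integer(l$dim), positive = l$positive,
                 n_pos = l$n_pos, n_neg = l$n_neg,
                 seed = l$seed, iterations = NA_integer_),
            class = "binary_model")
}

#' Save / load a tiered predictor bundle
#'
#' The bundle is a directory of human-readable JSON: `manifest.json`
#' (encoding, families, threshold, format version, metadata) plus one
#' parameter file per model (`tier1.json`, `tier2_<FAMILY>.json`). Numbers
#' are written at full double precision, so a round trip preserves decision
#' values to better than 1e-10.
#'
#' @param predictor A [tiered_predictor()].
#' @param path Bundle directory (created for save; must exist for load).
#' @return `save_bundle`: invisibly, `path`. `load_bundle`: the restored
#'   `tiered_predictor`.
#' @export
save_bundle <- function(predictor, path) {
  stopifnot(inherits(predictor, "tiered_predictor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = .bundle_format_version,
                   encoding = predictor$encoding,
                   threshold = predictor$threshold,
                   families = names(predictor$tier2),
                   metadata = predictor$metadata)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(.model_to_list(predictor$tier1),
                       file.path(path, "tier1.json"),
                       auto_unbox = TRUE, digits = NA)
  for (f in names(predictor$tier2)) {
    jsonlite::write_json(.model_to_list(predictor$tier2[[f]]),
                         file.path(path, paste0("tier2_", f, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a model bundle (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), .bundle_format_version)) {
    stop("bundle format version mismatch: bundle has ",
         manifest$format_version, ", this build reads ", .bundle_format_version)
  }
  t1f <- file.path(path, "tier1.json")
  if (!file.exists(t1f)) stop("bundle missing component: tier1")
  tier1 <- .model_from_list(
    jsonlite::read_json(t1f, simplifyVector = TRUE), "tier1")
  fams <- manifest$families
  tier2 <- setNames(vector("list", length(fams)), fams)
  for (f in fams) {
    ff <- file.path(path, paste0("tier2_", f, ".json"))
    if (!file.exists(ff)) stop("bundle missing component: tier2 model for ", f)
    tier2[[f]] <- .model_from_list(
      jsonlite::read_json(ff, simplifyVector = TRUE), paste0("tier2_", f))
  }
  tiered_predictor(tier1, tier2, threshold = manifest$threshold,
                   metadata = as.list(manifest$metadata))
}
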