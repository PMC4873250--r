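# Binary soft-margin kernel classifier: the contract both tiers are built
# on. Training solves the standard C-SVC dual by SMO (see src/smo.cpp); the
# cost ratio j multiplies the box constraint of positive examples, the
# SVM_light "-j" convention used to counter class imbalance.

#' Kernel configuration
#'
#' Hyper-parameters of one binary model, mirroring the SVM_light vocabulary:
#' kernel type (`-t`), polynomial degree (`-d`), rbf gamma (`-g`) and the
#' positive-class cost ratio (`-j`). Parameters irrelevant to the chosen
#' kernel are ignored. `C` is the soft-margin trade-off (unreported by most
#' published models; default 1).
#'
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param degree Integer >= 1 (polynomial only). Kernel is `(x.y + 1)^d`.
#' @param gamma Positive real (rbf only). Kernel is `exp(-g ||x - y||^2)`.
#' @param cost_ratio Positive real `j`: multiplier on the misclassification
#'   penalty of positive training examples.
#' @param C Positive real soft-margin trade-off.
#' @return Object of class `kernel_config`.
#' @export
#' @examples
#' kernel_config("rbf", gamma = 0.01, cost_ratio = 5)
kernel_config <- function(kernel = c("rbf", "linear", "polynomial"),
                          degree = 3L, gamma = 0.01, cost_ratio = 1,
                          C = 1) {
  kernel <- match.arg(kernel)
  if (kernel == "polynomial") {
    degree <- as.integer(degree)
    if (is.na(degree) || degree < 1L) stop("'degree' must be an integer >= 1")
  } else degree <- NA_integer_
  if (kernel == "rbf") {
    if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  } else gamma <- NA_real_
  if (!is.numeric(cost_ratio) || cost_ratio <= 0) stop("'cost_ratio' must be > 0")
  if (!is.numeric(C) || C <= 0) stop("'C' must be > 0")
  structure(list(kernel = kernel, degree = degree, gamma = gamma,
                 cost_ratio = as.numeric(cost_ratio), C = as.numeric(C)),
            class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  extra <- switch(x$kernel,
                  polynomial = paste0(", d = ", x$degree),
                  rbf = paste0(", g = ", format(x$gamma)),
                  "")
  cat(sprintf("kernel_config: %s%s, j = %s, C = %s\n",
              x$kernel, extra, format(x$cost_ratio), format(x$C)))
  invisible(x)
}

.kernel_code <- function(config) {
  match(config$kernel, c("linear", "polynomial", "rbf")) - 1L
}

#' Train a binary kernel classifier
#'
#' Fits a soft-margin SVM on a feature matrix with labels in {+1, -1}. The
#' optimizer is deterministic (maximal-violating-pair SMO), so identical
#' inputs, config and seed reproduce the decision function exactly; `seed`
#' is accepted for interface uniformity and forwarded to the model metadata.
#'
#' @param features Numeric matrix, one row per example; all values finite.
#' @param labels Numeric/integer vector of +1 / -1, one per row.
#' @param config A [kernel_config()].
#' @param seed Integer, recorded in the model.
#' @param encoding Optional encoding tag (`"discrete"`, `"coupled"`);
#'   inferred from the column count (20 / 400) when `NULL`.
#' @param positive Semantics of the positive label (e.g. `"HSP"`).
#' @param tol SMO stopping tolerance on the KKT violation gap (1e-3, the
#'   conventional working-set-selection default).
#' @param max_iter Iteration cap.
#' @return Object of class `binary_model`.
#' @export
train_binary <- function(features, labels, config = kernel_config(),
                         seed = 1L, encoding = NULL, positive = "+1",
                         tol = 1e-3, max_iter = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!all(is.finite(features))) stop("non-finite feature values")
  labels <- as.numeric(labels)
  if (length(labels) != nrow(features)) stop("labels must align with feature rows")
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(labels)) < 2L) {
    stop("training requires at least one example of each class")
  }
  stopifnot(inherits(config, "kernel_config"))
  if (is.null(encoding)) {
    encoding <- switch(as.character(ncol(features)),
                       "20" = "discrete", "400" = "coupled", "custom")
  }
  if (is.null(max_iter)) max_iter <- max(200000L, 100L * nrow(features))
  fit <- .smo_train(features, labels, config$C, config$cost_ratio,
                    .kernel_code(config),
                    ifelse(is.na(config$degree), 0, config$degree),
                    ifelse(is.na(config$gamma), 0, config$gamma),
                    tol, as.integer(max_iter))
  if (!fit$converged) {
    warning("SMO did not reach tolerance within ", max_iter, " iterations")
  }
  sv <- fit$sv_index + 1L
  structure(list(
    sv = features[sv, , drop = FALSE],
    coef = fit$alpha[sv] * labels[sv],
    rho = fit$rho,
    config = config,
    encoding = encoding,
    dim = ncol(features),
    positive = positive,
    n_pos = sum(labels > 0), n_neg = sum(labels < 0),
    seed = as.integer(seed),
    iterations = fit$iterations),
    class = "binary_model")
}

#' @export
print.binary_model <- function(x, ...) {
  cat(sprintf(
    "binary_model (positive = %s): %d support vectors, %s kernel, %d-dim %s features\n",
    x$positive, length(x$coef), x$config$kernel, x$dim, x$encoding))
  cat(sprintf("trained on %d positive / %d negative examples\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Decision value(s) of a binary model
#'
#' `f(x) = sum_t coef_t K(sv_t, x) - rho`; the sign of `f` gives the
#' predicted label at threshold 0, larger values are more positive-like.
#'
#' @param model A [train_binary()] model.
#' @param vector Numeric vector of length `model$dim`, or a matrix with that
#'   many columns (one decision value per row).
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, vector) {
  stopifnot(inherits(model, "binary_model"))
  x <- if (is.matrix(vector)) vector else matrix(vector, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != model$dim) {
    stop("dimension mismatch: model expects ", model$dim,
         " features, got ", ncol(x))
  }
  cfg <- model$config
  K <- .kernel_cross(x, model$sv, .kernel_code(cfg),
                     ifelse(is.na(cfg$degree), 0, cfg$degree),
                     ifelse(is.na(cfg$gamma), 0, cfg$gamma))
  drop(K %*% model$coef) - model$rho
}

#' Predict a binary label
#'
#' @inheritParams decision_value
#' @param threshold Decision threshold; a value exactly at the threshold is
#'   classified positive (documented convention).
#' @return Vector of +1 / -1.
#' @export
predict_label <- function(model, vector, threshold = 0) {
  ifelse(decision_value(model, vector) >= threshold, 1, -1)
}
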