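#' Fit the post hoc ancestry adjustment model
#'
#' Models the mean and variance of the raw PRS as linear functions of the top
#' `n_pcs` reference-panel PCs: an ordinary least squares regression of the
#' score on the PCs gives the mean model (coefficients alpha); the squared
#' residuals of that fit, regressed on the same PCs, give the variance model
#' (coefficients beta). Scores are fitted raw (no centering/scaling); the
#' convention is recorded in the saved model. Fitted variances are floored at
#' `variance_floor` (negative fitted variances can occur at extreme PCs,
#' which the linear variance model does not preclude).
#'
#' @param scores a `score_vector` (or data.frame with `sample_id`, `prs`)
#'   over the reference panel.
#' @param pcs an `ancestry_coords` over the same samples.
#' @param n_pcs number of PCs in both regressions (default 5).
#' @param variance_floor minimum admissible fitted variance; default
#'   `1e-6 * var(scores)`.
#' @return an object of class `adjustment_model`: `alpha` (intercept +
#'   `n_pcs` slopes), `beta` (same layout for the variance model), `n_pcs`,
#'   `variance_floor`, `n_floored_ref`, `fingerprint` (of the PC space),
#'   `centering` ("none").
#' @export
fit_adjustment <- function(scores, pcs, n_pcs = 5, variance_floor = NULL) {
  stopifnot(inherits(pcs, "ancestry_coords") || is.data.frame(pcs))
  pc_cols <- paste0("PC", seq_len(n_pcs))
  if (!all(pc_cols %in% names(pcs)))
    stop("pcs must contain columns ", paste(pc_cols, collapse = ", "))
  m <- merge(scores[, c("sample_id", "prs")],
             pcs[, c("sample_id", pc_cols)], by = "sample_id")
  n <- nrow(m)
  if (n < n_pcs + 2) stop("need at least n_pcs + 2 samples, got ", n)
  y <- m$prs
  if (sd(y) == 0) stop("constant scores: variance regression degenerate")
  x <- cbind(1, as.matrix(m[, pc_cols]))
  if (qr(x)$rank < ncol(x)) stop("rank-deficient PC matrix")
  fit1 <- lm.fit(x, y)
  alpha <- fit1$coefficients
  delta <- fit1$residuals^2
  fit2 <- lm.fit(x, delta)
  beta <- fit2$coefficients
  if (is.null(variance_floor)) variance_floor <- 1e-6 * var(y)
  fitted_var <- as.numeric(x %*% beta)
  n_floored <- sum(fitted_var < variance_floor)
  if (n_floored > 0)
    message("fit_adjustment: ", n_floored,
            " reference sample(s) had fitted variance below the floor")
  names(alpha) <- names(beta) <- c("intercept", pc_cols)
  structure(list(alpha = alpha, beta = beta, n_pcs = n_pcs,
                 variance_floor = variance_floor, n_floored_ref = n_floored,
                 fingerprint = attr(pcs, "fingerprint"), centering = "none"),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("adjustment_model on top", x$n_pcs, "PCs\n")
  cat("  alpha:", format(x$alpha, digits = 4), "\n")
  cat("  beta: ", format(x$beta, digits = 4), "\n")
  invisible(x)
}

#' Ancestry-adjust raw PRS values
#'
#' Applies `(raw - (a0 + sum a_k PC_k)) / sqrt(b0 + sum b_k PC_k)` per sample,
#' placing polygenic risk on one scale across ancestries. The PCs must come
#' from the same PC model used at fit time (checked via the stored
#' fingerprint). Samples whose fitted variance hit the floor are flagged.
#'
#' @param model an [fit_adjustment()] model.
#' @param raw a `score_vector` of raw scores.
#' @param pcs an `ancestry_coords` for the same samples.
#' @return data.frame of class `score_vector` with columns `sample_id`,
#'   `prs` (adjusted), `floored` (logical).
#' @export
adjust_prs <- function(model, raw, pcs) {
  stopifnot(inherits(model, "adjustment_model"))
  fp <- attr(pcs, "fingerprint")
  if (!is.null(model$fingerprint) && !is.null(fp) &&
      !identical(model$fingerprint, fp))
    stop("PC-space fingerprint mismatch: scores must be adjusted in the PC ",
         "space the model was fitted in")
  pc_cols <- paste0("PC", seq_len(model$n_pcs))
  m <- merge(raw[, c("sample_id", "prs")],
             pcs[, c("sample_id", pc_cols)], by = "sample_id", sort = FALSE)
  x <- cbind(1, as.matrix(m[, pc_cols]))
  if (any(!is.finite(x))) stop("non-finite PC coordinate")
  mu <- as.numeric(x %*% model$alpha)
  v <- as.numeric(x %*% model$beta)
  floored <- v < model$variance_floor
  v[floored] <- model$variance_floor
  out <- data.frame(sample_id = m$sample_id, prs = (m$prs - mu) / sqrt(v),
                    floored = floored, stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Save / load an adjustment model as JSON
#'
#' The file is a small human-readable JSON object holding alpha, beta,
#' `n_pcs`, the variance floor, the PC-space fingerprint and the centering
#' convention.
#'
#' @param model an `adjustment_model`.
#' @param path file path.
#' @return `path` (writer) or the restored `adjustment_model` (reader).
#' @export
save_adjustment <- function(model, path) {
  stopifnot(inherits(model, "adjustment_model"))
  obj <- unclass(model)
  obj$alpha <- as.list(obj$alpha)   # preserve coefficient names in JSON
  obj$beta <- as.list(obj$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_adjustment
#' @export
load_adjustment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$alpha <- unlist(obj$alpha)
  obj$beta <- unlist(obj$beta)
  structure(obj, class = "adjustment_model")
}
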