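#' Logistic regression fit with Wald summaries
#'
#' Thin wrapper around [stats::glm()] (binomial, logit link) returning
#' coefficients, Wald standard errors, fitted probabilities, a convergence
#' flag and a separation heuristic (diverging coefficients make Wald CIs
#' unreliable).
#'
#' @param status 0/1 outcome vector.
#' @param predictors data.frame or matrix of predictors (may be NULL for an
#'   intercept-only fit).
#' @return list with `coef`, `se`, `fitted`, `converged`, `separation`.
#' @export
logistic_fit <- function(status, predictors = NULL) {
  status <- as.integer(status)
  if (length(unique(status)) < 2) stop("both classes must be present")
  df <- if (is.null(predictors) || NCOL(predictors) == 0)
    data.frame(.y = status)
  else cbind(data.frame(.y = status), as.data.frame(predictors))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(sm[, "Std. Error"] > 100)
  list(coef = coef(fit), se = sm[, "Std. Error"],
       fitted = fitted(fit), converged = fit$converged,
       separation = separation)
}

drop_constant_cols <- function(x) {
  if (is.null(x)) return(NULL)
  x <- as.data.frame(x)
  x$sample_id <- NULL
  keep <- vapply(x, function(col) length(unique(col)) > 1, logical(1))
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) NULL else x
}

#' Odds ratio per standard deviation of the score
#'
#' Standardizes the score to unit SD within the evaluation sample and fits a
#' covariate-adjusted logistic regression; returns the exponentiated score
#' coefficient with a Wald 95% CI.
#'
#' @param status 0/1 outcome.
#' @param score numeric score.
#' @param covariates optional covariate data.frame.
#' @return list with `or`, `ci_low`, `ci_high`, `p`, `log_or`, `se`,
#'   `separation`.
#' @export
or_per_sd <- function(status, score, covariates = NULL) {
  if (sd(score) == 0) stop("constant score: zero SD")
  z <- as.numeric(scale(score))
  covariates <- drop_constant_cols(covariates)
  preds <- if (is.null(covariates)) data.frame(score_sd = z)
  else cbind(data.frame(score_sd = z), covariates)
  fit <- logistic_fit(status, preds)
  b <- fit$coef[["score_sd"]]
  se <- fit$se[["score_sd"]]
  list(or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       p = 2 * pnorm(-abs(b / se)), log_or = b, se = se,
       separation = fit$separation)
}

#' Area under the ROC curve
#'
#' Concordance probability computed from the rank statistic (Mann-Whitney),
#' with ties counted one half.
#'
#' @param status 0/1 outcome.
#' @param score numeric score.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(status, score) {
  status <- as.integer(status)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The four-AUC suite
#'
#' AUCs of (i) the covariates-only model (fitted probabilities of a logistic
#' fit on covariates alone), (ii) the raw score, (iii) the score residualized
#' on the covariates by least squares ("PRS adjusting for the covariates"),
#' and (iv) the joint score + covariates model.
#'
#' @inheritParams or_per_sd
#' @return named list `covariates_only`, `prs_only`, `prs_covariate_adjusted`,
#'   `combined`.
#' @export
auc_suite <- function(status, score, covariates = NULL) {
  covariates <- drop_constant_cols(covariates)
  if (is.null(covariates)) {
    cov_only <- 0.5                     # intercept-only: all ties
    resid_score <- score - mean(score)  # residualization is a no-op shift
    combined <- auc(status, logistic_fit(status,
                                         data.frame(prs = score))$fitted)
  } else {
    cov_fit <- logistic_fit(status, covariates)
    cov_only <- auc(status, cov_fit$fitted)
    mm_f <- stats::model.matrix(~ ., data = covariates)
    resid_score <- as.numeric(lm.fit(mm_f, score)$residuals)
    combined <- auc(status, logistic_fit(
      status, cbind(data.frame(prs = score), covariates))$fitted)
  }
  list(covariates_only = cov_only,
       prs_only = auc(status, score),
       prs_covariate_adjusted = auc(status, resid_score),
       combined = combined)
}

#' Liability-scale variance explained
#'
#' Incremental observed-scale R-squared of the score over the covariates
#' (linear model on 0/1 status), transformed to the liability scale with the
#' ascertainment-corrected factor
#' `C = K^2 (1-K)^2 / (z^2 P (1-P))`, where K is the population prevalence,
#' P the sample case fraction, and z the standard-normal density at the
#' liability threshold `qnorm(1 - K)`. The result is clipped to \[0, 1\].
#'
#' @inheritParams or_per_sd
#' @param K population disease prevalence in (0, 1).
#' @return liability-scale R-squared.
#' @export
liability_r2 <- function(status, score, covariates = NULL, K) {
  status <- as.integer(status)
  P <- mean(status)
  if (K <= 0 || K >= 1) stop("K must lie strictly in (0, 1)")
  if (P <= 0 || P >= 1) stop("sample case fraction must lie in (0, 1)")
  covariates <- drop_constant_cols(covariates)
  if (is.null(covariates)) {
    r2_cov <- 0
    r2_full <- summary(lm(status ~ score))$r.squared
  } else {
    r2_cov <- summary(lm(status ~ ., data = covariates))$r.squared
    r2_full <- summary(lm(status ~ score + .,
                          data = covariates))$r.squared
  }
  r2_obs <- r2_full - r2_cov
  z <- dnorm(qnorm(1 - K))
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  min(max(r2_obs * C, 0), 1)
}

#' Prevalence-adjusted predictive values
#'
#' Evaluates
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`
#' at an assumed population prevalence, so predictive values do not inherit
#' the (often ascertained) sample case fraction.
#'
#' @param sensitivity,specificity,prev values in \[0, 1\].
#' @return named list `ppv`, `npv`.
#' @export
ppv_npv <- function(sensitivity, specificity, prev) {
  for (v in c(sensitivity, specificity, prev))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("sensitivity, specificity and prev must lie in [0, 1]")
  den_p <- sensitivity * prev + (1 - specificity) * (1 - prev)
  den_n <- specificity * (1 - prev) + (1 - sensitivity) * prev
  if (den_p == 0) stop("PPV denominator is zero (no predicted positives)")
  if (den_n == 0) stop("NPV denominator is zero (no predicted negatives)")
  list(ppv = sensitivity * prev / den_p,
       npv = specificity * (1 - prev) / den_n)
}

#' Tail-discrimination metrics at one percentile cutoff
#'
#' Flags samples at or above the empirical `(100 - cutoff)` percentile of the
#' score (ties enter the top group; the realized group size is reported),
#' fits a covariate-adjusted logistic regression on the indicator for the OR,
#' and reports sensitivity, specificity and prevalence-adjusted PPV/NPV at
#' prevalence `prev`.
#'
#' @inheritParams or_per_sd
#' @param cutoff_percent percentile cutoff (percent in (0, 50)), e.g. 2, 5, 10.
#' @param prev assumed population prevalence for PPV/NPV.
#' @return one-row data.frame: `cutoff`, `n_top`, `or`, `ci_low`, `ci_high`,
#'   `p`, `sensitivity`, `specificity`, `ppv`, `npv`, `unstable`.
#' @export
tail_metrics <- function(status, score, covariates = NULL, cutoff_percent,
                         prev) {
  if (cutoff_percent <= 0 || cutoff_percent >= 50)
    stop("cutoff_percent must lie in (0, 50)")
  status <- as.integer(status)
  thr <- quantile(score, 1 - cutoff_percent / 100, names = FALSE)
  top <- as.integer(score >= thr)
  if (sum(top) == 0) stop("empty top group at cutoff ", cutoff_percent, "%")
  unstable <- all(status[top == 1] == 1) || all(status[top == 1] == 0)
  covariates <- drop_constant_cols(covariates)
  preds <- if (is.null(covariates)) data.frame(top_group = top)
  else cbind(data.frame(top_group = top), covariates)
  fit <- logistic_fit(status, preds)
  b <- fit$coef[["top_group"]]; se <- fit$se[["top_group"]]
  sens <- mean(top[status == 1] == 1)
  spec <- mean(top[status == 0] == 0)
  pv <- ppv_npv(sens, spec, prev)
  data.frame(cutoff = cutoff_percent, n_top = sum(top),
             or = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se), p = 2 * pnorm(-abs(b / se)),
             sensitivity = sens, specificity = spec,
             ppv = pv$ppv, npv = pv$npv,
             unstable = unstable || fit$separation)
}

#' Decile calibration table
#'
#' Ranks samples by the score (defaults to the predicted probabilities),
#' splits them into 10 near-equal groups (sizes differ by at most 1), and
#' reports the mean predicted probability and the observed case fraction per
#' decile.
#'
#' @param status 0/1 outcome.
#' @param predicted predicted case probabilities in \[0, 1\].
#' @param score optional ranking score (e.g. the PRS); defaults to
#'   `predicted`.
#' @return data.frame with `decile`, `n`, `predicted_risk`, `observed_risk`.
#' @export
calibration_by_decile <- function(status, predicted, score = NULL) {
  status <- as.integer(status)
  n <- length(status)
  if (n < 10) stop("need at least 10 samples for decile calibration")
  if (any(predicted < 0 | predicted > 1)) stop("probabilities outside [0, 1]")
  if (is.null(score)) score <- predicted
  ord <- order(score)
  bins <- rep(1:10, times = diff(round(seq(0, n, length.out = 11))))
  decile <- integer(n)
  decile[ord] <- bins
  out <- data.frame(decile = 1:10)
  out$n <- as.integer(table(decile))
  out$predicted_risk <- as.numeric(tapply(predicted, decile, mean))
  out$observed_risk <- as.numeric(tapply(status, decile, mean))
  rownames(out) <- NULL
  out
}

#' Full per-cohort performance report
#'
#' Computes the complete metrics suite on one evaluation sample: liability
#' R-squared, the four AUCs, OR/SD, tail metrics at each requested cutoff
#' (with prevalence-adjusted PPV/NPV), and the decile calibration table from
#' the joint score + covariates model.
#'
#' @inheritParams or_per_sd
#' @param prevalence assumed population prevalence K.
#' @param cutoffs percentile cutoffs for tail metrics (default 2, 5, 10).
#' @return object of class `metrics_report`: `liability_r2`, `auc` (list of
#'   four), `or_per_sd` (list), `tail` (data.frame), `calibration`
#'   (data.frame), `n`, `case_fraction`, `prevalence`.
#' @export
evaluate_prs <- function(status, score, covariates = NULL, prevalence,
                         cutoffs = c(2, 5, 10)) {
  status <- as.integer(status)
  stopifnot(length(status) == length(score))
  covariates <- drop_constant_cols(covariates)
  tail <- do.call(rbind, lapply(cutoffs, function(ct)
    tail_metrics(status, score, covariates, ct, prevalence)))
  joint <- if (is.null(covariates)) data.frame(prs = score)
  else cbind(data.frame(prs = score), covariates)
  fitted <- logistic_fit(status, joint)$fitted
  structure(list(
    liability_r2 = liability_r2(status, score, covariates, K = prevalence),
    auc = auc_suite(status, score, covariates),
    or_per_sd = or_per_sd(status, score, covariates),
    tail = tail,
    calibration = calibration_by_decile(status, fitted, score = score),
    n = length(status), case_fraction = mean(status),
    prevalence = prevalence), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: n = %d (case fraction %.3f, prevalence K = %.3f)\n",
              x$n, x$case_fraction, x$prevalence))
  cat(sprintf("  liability R2      : %.4f\n", x$liability_r2))
  cat(sprintf("  AUC cov-only      : %.3f\n", x$auc$covariates_only))
  cat(sprintf("  AUC PRS-only      : %.3f\n", x$auc$prs_only))
  cat(sprintf("  AUC PRS|cov       : %.3f\n", x$auc$prs_covariate_adjusted))
  cat(sprintf("  AUC combined      : %.3f\n", x$auc$combined))
  cat(sprintf("  OR/SD             : %.2f (%.2f-%.2f)\n", x$or_per_sd$or,
              x$or_per_sd$ci_low, x$or_per_sd$ci_high))
  for (i in seq_len(nrow(x$tail)))
    cat(sprintf("  top %g%%: OR %.2f (%.2f-%.2f), sens %.2f, spec %.2f, PPV %.2f, NPV %.2f\n",
                x$tail$cutoff[i], x$tail$or[i], x$tail$ci_low[i],
                x$tail$ci_high[i], x$tail$sensitivity[i],
                x$tail$specificity[i], x$tail$ppv[i], x$tail$npv[i]))
  invisible(x)
}

#' Default population prevalence registry
#'
#' Ships the literature-derived prevalence of diagnosed type 2 diabetes used
#' for prevalence-adjusted PPV/NPV: European 10.0%, African 12.5%, Hispanic
#' 13.1%, Asian 13.7%. Stored as a plain TSV under `extdata` and overridable
#' by passing your own file.
#'
#' @param path optional path to a two-column TSV (`population`, `prevalence`).
#' @return named numeric vector of prevalences.
#' @export
default_prevalence <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "prevalence.tsv", package = "transprs")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(tab$prevalence, tab$population)
}
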