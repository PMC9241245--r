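# 2x2 layout used by the worked odds-ratio examples:
# exposed 8 cases / 12 controls, unexposed 92 cases / 888 controls
layout_2x2 <- function() {
  status <- c(rep(1, 8), rep(0, 12), rep(1, 92), rep(0, 888))
  exposed <- c(rep(1, 20), rep(0, 980))
  list(status = status, exposed = exposed,
       or = (8 * 888) / (12 * 92))   # cross-product oracle = 6.434783
}

test_that("logistic OR matches the 2x2 cross-product", {
  l <- layout_2x2()
  fit <- logistic_fit(l$status, data.frame(exposed = l$exposed))
  expect_equal(exp(unname(fit$coef["exposed"])), l$or, tolerance = 1e-6)
})

test_that("null and generative OR/SD are recovered", {
  set.seed(201)
  n <- 10000
  x <- rnorm(n); y <- rbinom(n, 1, 0.3)
  o <- or_per_sd(y, x)
  expect_gt(o$or, 0.9); expect_lt(o$or, 1.1)

  set.seed(202)
  n <- 20000
  x <- rnorm(n)
  p <- plogis(qlogis(0.10) + log(2) * x)
  y <- rbinom(n, 1, p)
  o2 <- or_per_sd(y, x)
  expect_gt(o2$or, 1.85); expect_lt(o2$or, 2.15)

  # standardization invariance: rescaling the score changes nothing
  o3 <- or_per_sd(y, 37.5 * x)
  expect_equal(o3$or, o2$or, tolerance = 1e-8)
  expect_error(or_per_sd(y, rep(1, n)), "constant")
})

test_that("AUC is the exhaustive pair-concordance probability", {
  expect_equal(auc(c(1, 1, 0, 0), c(2, 3, 1, 2.5)), 3 / 4)
  expect_equal(auc(c(1, 1, 0), c(5, 6, 1)), 1.0)
  expect_equal(auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)
  expect_error(auc(c(1, 1), c(1, 2)), "classes")
  # cross-check the rank statistic against an independent ROC implementation
  set.seed(203)
  y <- rbinom(300, 1, 0.3); s <- rnorm(300) + y
  expect_equal(auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant to strictly increasing transforms", {
  set.seed(204)
  y <- rbinom(500, 1, 0.2); s <- rnorm(500) + 0.5 * y
  expect_equal(auc(y, s), auc(y, exp(s)))
  expect_equal(auc(y, s), auc(y, rank(s)))
})

test_that("the four-AUC suite behaves at the null and under nesting", {
  set.seed(205)
  n <- 10000
  cov <- data.frame(age = rnorm(n, 55, 10), sex = rbinom(n, 1, 0.5))
  p <- plogis(-2.2 + 0.03 * (cov$age - 55))
  y <- rbinom(n, 1, p)
  s <- rnorm(n)                       # independent of status and covariates
  a <- auc_suite(y, s, cov)
  expect_lt(abs(a$prs_only - 0.5), 0.02)
  expect_lt(abs(a$prs_covariate_adjusted - 0.5), 0.02)
  expect_lt(abs(a$combined - a$covariates_only), 0.02)
  expect_gt(a$combined, a$covariates_only - 0.01)

  # constant covariates: residualization is exactly a no-op
  cc <- data.frame(k = rep(1, n))
  a2 <- auc_suite(y, s, cc)
  expect_identical(a2$prs_covariate_adjusted, a2$prs_only)
})

test_that("liability transformation matches its closed forms", {
  set.seed(206)
  y <- rep(c(0, 1), each = 100)   # P exactly 0.5
  s <- rnorm(200) + 0.4 * y
  # K = P = 0.5: C = pi/2 (z^2 = 1/(2*pi)), so R2_liab = R2_obs * 1.5708
  r2_obs <- summary(lm(y ~ s))$r.squared
  expect_equal(liability_r2(y, s, K = 0.5), r2_obs * pi / 2,
               tolerance = 1e-10)
  # an uninformative score has zero observed-scale increment
  expect_equal(liability_r2(y, rep(0, 200), K = 0.5), 0, tolerance = 1e-6)
  expect_error(liability_r2(y, s, K = 0), "K")
})

test_that("liability R2 recovers the generative value under ascertainment", {
  # liability = g + e with var(g) = 0.09, K = 0.10; case-control sample at
  # P = 0.5 built by keeping all cases
  set.seed(207)
  n_pool <- 220000
  g <- rnorm(n_pool, 0, sqrt(0.09))
  liab <- g + rnorm(n_pool, 0, sqrt(0.91))
  y <- as.integer(liab > qnorm(0.90))
  cases <- which(y == 1); controls <- which(y == 0)
  keep <- c(sample(cases, 10000), sample(controls, 10000))
  r2 <- liability_r2(y[keep], g[keep], K = 0.10)
  expect_lt(abs(r2 - 0.09), 0.015)
})

test_that("prevalence-adjusted predictive values follow the formulas", {
  # printed row: sens 0.05, spec 0.99, prev 0.10 -> NPV 0.90 at 2 decimals
  pv <- ppv_npv(0.05, 0.99, 0.10)
  expect_equal(round(pv$npv, 2), 0.90)
  # direct arithmetic: sens 0.07, spec 0.98, prev 0.137 -> PPV 0.357
  expect_equal(round(ppv_npv(0.07, 0.98, 0.137)$ppv, 3), 0.357)
  pv1 <- ppv_npv(1, 1, 0.3)
  expect_equal(c(pv1$ppv, pv1$npv), c(1, 1))
  expect_error(ppv_npv(0, 1, 0.5), "denominator")
  expect_error(ppv_npv(0.5, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("PPV rises and NPV falls with prevalence", {
  grid <- seq(0.01, 0.99, by = 0.01)
  ppv <- vapply(grid, function(k) ppv_npv(0.6, 0.9, k)$ppv, numeric(1))
  npv <- vapply(grid, function(k) ppv_npv(0.6, 0.9, k)$npv, numeric(1))
  expect_true(all(diff(ppv) > 0))
  expect_true(all(diff(npv) < 0))
})

test_that("tail metrics reproduce the 2x2 worked layout", {
  l <- layout_2x2()
  # scores ranked so the exposed 20 are exactly the top 2%
  score <- ifelse(l$exposed == 1, 2, 1) + seq(0, 0.5, length.out = 1000)
  tm <- tail_metrics(l$status, score, NULL, cutoff_percent = 2, prev = 0.10)
  expect_equal(tm$n_top, 20)
  expect_equal(tm$or, l$or, tolerance = 1e-6)
  expect_equal(tm$sensitivity, 0.08)
  expect_equal(round(tm$specificity, 3), 0.987)
})

test_that("tail OR is null when the score is uninformative", {
  set.seed(208)
  n <- 50000
  y <- rbinom(n, 1, 0.1); s <- rnorm(n)
  tm <- tail_metrics(y, s, NULL, 10, prev = 0.1)
  expect_gt(tm$or, 0.85); expect_lt(tm$or, 1.15)
})

test_that("tail ORs steepen toward more extreme cutoffs on average", {
  set.seed(209)
  diffs25 <- diffs510 <- numeric(10)
  for (r in 1:10) {
    n <- 8000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(0.10) + log(2) * x))
    o <- vapply(c(2, 5, 10), function(ct)
      tail_metrics(y, x, NULL, ct, prev = 0.1)$or, numeric(1))
    diffs25[r] <- o[1] - o[2]
    diffs510[r] <- o[2] - o[3]
  }
  expect_gt(mean(diffs25), 0)
  expect_gt(mean(diffs510), 0)
})

test_that("decile calibration splits evenly and detects miscalibration", {
  set.seed(210)
  n <- 20000
  p <- plogis(rnorm(n, -2, 1))
  y <- rbinom(n, 1, p)
  cal <- calibration_by_decile(y, p)
  expect_equal(cal$n, rep(2000L, 10))
  expect_lt(max(abs(cal$predicted_risk - cal$observed_risk)), 0.03)

  cal100 <- calibration_by_decile(rbinom(100, 1, 0.5), runif(100))
  expect_equal(cal100$n, rep(10L, 10))

  # squared probabilities under-predict risk in the top decile
  cal_sq <- calibration_by_decile(y, p^2, score = p)
  expect_gt(cal_sq$observed_risk[10], cal_sq$predicted_risk[10])
  expect_error(calibration_by_decile(y[1:5], p[1:5]), "10")
})

test_that("the full report reproduces the qualitative tail ordering", {
  set.seed(211)
  n <- 20000
  x <- rnorm(n)
  cov <- data.frame(age = rnorm(n, 55, 10), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(qlogis(0.10) + log(2) * x))
  rep <- evaluate_prs(y, x, cov, prevalence = 0.10)
  expect_s3_class(rep, "metrics_report")
  ors <- rep$tail$or[match(c(2, 5, 10), rep$tail$cutoff)]
  expect_true(ors[1] > ors[2] && ors[2] > ors[3])
  expect_gt(ors[3], rep$or_per_sd$or)
  expect_true(all(rep$tail$ci_low <= rep$tail$or &
                    rep$tail$or <= rep$tail$ci_high))
  expect_gte(rep$auc$combined, rep$auc$covariates_only - 0.01)
})

test_that("the shipped prevalence registry carries the four populations", {
  prev <- default_prevalence()
  expect_equal(unname(prev[c("European", "African", "Hispanic", "Asian")]),
               c(0.100, 0.125, 0.131, 0.137))
})
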