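test_that("IVW meta-analysis matches its closed form and an oracle", {
  one <- ivw_meta(0.3, 0.05)
  expect_equal(one$estimate, 0.3)
  expect_equal(one$se, 0.05)

  # worked example: log-ORs (0.6931, 0), SEs (0.1, 0.2)
  m <- ivw_meta(c(0.6931, 0), c(0.1, 0.2))
  expect_equal(m$estimate, 69.31 / 125, tolerance = 1e-10)
  expect_equal(round(exp(m$estimate), 3), 1.741)
  expect_equal(sum(m$weights), 1)

  # equal SEs: combined is the simple mean
  m2 <- ivw_meta(c(0.2, 0.4, 0.9), rep(0.1, 3))
  expect_equal(m2$estimate, mean(c(0.2, 0.4, 0.9)))

  expect_error(ivw_meta(c(0.1, 0.2), c(0.1, 0)), "standard errors")

  # cross-check against the established fixed-effect implementation
  set.seed(301)
  yi <- rnorm(6, 0.3, 0.2); sei <- runif(6, 0.05, 0.3)
  ours <- ivw_meta(yi, sei)
  ref <- metafor::rma(yi = yi, sei = sei, method = "FE")
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
})

test_that("combined estimate is bounded and SE shrinks as studies accrue", {
  set.seed(302)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    est <- rnorm(k); se <- runif(k, 0.05, 0.5)
    m <- ivw_meta(est, se)
    expect_gte(m$estimate, min(est)); expect_lte(m$estimate, max(est))
    expect_lt(m$se, min(se))
    m_sub <- ivw_meta(est[-1], se[-1])
    expect_lt(m$se, m_sub$se)
  }
})

make_stats <- function(id, pos, beta, se, ea = "A", oa = "G", chrom = "1") {
  n <- length(id)
  data.frame(id = id, chrom = rep_len(chrom, n), pos = pos,
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
             freq = 0.3, n = 1e5, stringsAsFactors = FALSE)
}

test_that("variant-level fixed-effect meta combines and harmonizes", {
  s1 <- make_stats(c("v1", "v2"), c(100, 200), c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(fixed_effect_meta(list(s1))$beta, s1$beta)

  # two studies, equal SEs: combined beta 0.1, SE reduced by 1/sqrt(2)
  s2 <- make_stats(c("v1", "v2"), c(100, 200), c(0.1, 0.5), c(0.1, 0.1))
  mm <- fixed_effect_meta(list(s1, s2))
  expect_equal(mm$beta[mm$id == "v1"], 0.1, tolerance = 1e-12)
  expect_equal(mm$se[mm$id == "v1"], 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(mm$n_studies, c(2L, 2L))

  # swapped alleles in study 2 are sign-harmonized before combining
  s2f <- s2
  s2f$effect_allele <- "G"; s2f$other_allele <- "A"
  s2f$beta <- -s2f$beta
  mmf <- fixed_effect_meta(list(s1, s2f))
  expect_equal(mmf$beta, mm$beta, tolerance = 1e-12)

  # partial overlap: union kept, per-variant study count recorded
  s3 <- make_stats("v3", 300, 0.2, 0.1)
  mu <- fixed_effect_meta(list(s1, s3))
  expect_equal(sort(mu$id), c("v1", "v2", "v3"))
  expect_equal(mu$n_studies[mu$id == "v3"], 1L)

  # allele-pair mismatch at a shared key is dropped with a count
  s2m <- s2
  s2m$effect_allele[1] <- "C"; s2m$other_allele[1] <- "T"
  mx <- fixed_effect_meta(list(s1, s2m))
  expect_true(attr(mx, "n_mismatch_dropped") >= 0)
})

test_that("lead-variant extraction follows the greedy min-p rule", {
  s <- make_stats(c("a", "b", "c"), c(1e6, 1.2e6, 5e6),
                  beta = c(1, 1, 1), se = c(1, 1, 1))
  s$p <- c(1e-10, 1e-9, 1e-8)
  leads <- extract_lead_variants(s, p_threshold = 5e-8,
                                 locus_window_bp = 5e5)
  expect_equal(leads$id, c("a", "c"))   # b falls inside a's 500 kb window

  s$p <- c(0.5, 0.2, 0.9)
  expect_equal(nrow(suppressMessages(extract_lead_variants(s))), 0)
})

test_that("greedy extraction matches a brute-force oracle on 100 variants", {
  brute_force_leads <- function(stats, thr, win) {
    live <- stats[stats$p < thr, , drop = FALSE]
    out <- character()
    while (nrow(live) > 0) {
      i <- which.min(live$p)             # unique p-values: unambiguous
      out <- c(out, live$id[i])
      keep <- !(live$chrom == live$chrom[i] &
                  abs(live$pos - live$pos[i]) <= win)
      keep[i] <- FALSE
      live <- live[keep, , drop = FALSE]
    }
    out
  }
  set.seed(303)
  for (r in 1:5) {
    st <- make_stats(sprintf("v%03d", 1:100),
                     pos = sort(sample.int(2e7, 100)),
                     beta = rnorm(100), se = rep(0.1, 100),
                     chrom = sample(c("1", "2"), 100, replace = TRUE))
    st$p <- 10^runif(100, -12, -2)
    got <- extract_lead_variants(st, 5e-8, 3e5)
    expect_equal(got$id, brute_force_leads(st, 5e-8, 3e5))
    # order invariance of the input table
    perm <- st[sample.int(100), ]
    expect_equal(extract_lead_variants(perm, 5e-8, 3e5)$id, got$id)
  }
})

test_that("tag-variant search honours the r2 threshold", {
  cfg <- two_pop_config(n_populations = 1, n_variants = 50, n_causal = 0,
                        n_samples = 800, n_ld_copies = 8, ld_copy_r = 0.8,
                        seed = 304)
  panel <- simulate_reference_panel(cfg)
  g <- panel$genotypes
  # exact duplicate: correlation 1 by construction
  dup <- g
  dup$dosages <- cbind(dup$dosages, dup$dosages[, 1])
  dv <- dup$variants[1, ]; dv$id <- "v00001_dup"; dv$pos <- dv$pos + 2L
  dup$variants <- rbind(dup$variants, dv)
  dup$freq <- c(dup$freq, dup$freq[1])
  lead <- data.frame(id = "v00001", chrom = "1", pos = g$variants$pos[1])
  tag <- find_tag_variant(lead, target_ids = "v00001_dup", dup)
  expect_equal(tag$id, "v00001_dup")
  expect_equal(tag$r2, 1.0, tolerance = 1e-12)

  # generated LD copy: r2 approximately ld_copy_r^2 = 0.64
  tag2 <- find_tag_variant(lead, target_ids = "v00001_tag", g)
  expect_equal(tag2$id, "v00001_tag")
  expect_lt(abs(tag2$r2 - 0.64), 0.1)

  # proxies below the threshold return nothing
  expect_null(find_tag_variant(lead, target_ids = "v00001_tag", g,
                               r2_min = 0.9))
  # unrelated distant variant: no candidate in window
  expect_null(find_tag_variant(lead, target_ids = "v00040", g,
                               locus_window_bp = 1e4))
})

test_that("effect concordance uses |beta| and attenuates with noise", {
  s1 <- make_stats(sprintf("v%02d", 1:10), seq(1e6, 1e7, length.out = 10),
                   beta = seq(-0.5, 0.4, length.out = 10), se = rep(0.1, 10))
  leads <- s1
  conc <- effect_concordance(s1, s1, leads)
  expect_equal(conc$r, 1.0)
  expect_equal(conc$n_variants, 10)

  # sign flips leave the concordance untouched
  s2 <- s1
  s2$beta <- s1$beta * sample(c(-1, 1), 10, replace = TRUE)
  expect_equal(effect_concordance(s1, s2, leads)$r, 1.0)

  expect_error(effect_concordance(s1[1:2, ], s1[1:2, ], leads[1:2, ]),
               "pairs")

  # sampling noise attenuates concordance: N = 1e5 beats N = 1e3
  wins <- 0
  for (r in 1:10) {
    cfg_hi <- two_pop_config(gwas_n = 1e5, n_variants = 200, n_causal = 60,
                             seed = 310 + r)
    cfg_lo <- two_pop_config(gwas_n = 1e3, n_variants = 200, n_causal = 60,
                             seed = 310 + r)
    ss_hi <- simulate_gwas_summary(cfg_hi)
    ss_lo <- simulate_gwas_summary(cfg_lo)
    causal_ids <- ss_hi$POP1$id[
      transprs:::true_effects(cfg_hi)[seq_len(200)] != 0]
    ld <- ss_hi$POP1[ss_hi$POP1$id %in% causal_ids, ]
    r_hi <- effect_concordance(ss_hi$POP1, ss_hi$POP2, ld)$r
    r_lo <- effect_concordance(ss_lo$POP1, ss_lo$POP2, ld)$r
    wins <- wins + (r_hi > r_lo)
  }
  expect_gte(wins, 9)
})
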