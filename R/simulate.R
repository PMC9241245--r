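#' Simulation configuration for synthetic multi-ancestry cohorts
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' Populations diverge from a common ancestral allele-frequency pool under the
#' Balding-Nichols model (divergence set by `fst`), disease arises from a
#' liability-threshold model with population-specific prevalence, and
#' per-population GWAS summary statistics carry sampling noise set by `gwas_n`.
#'
#' @param n_populations number of discrete populations.
#' @param fst Balding-Nichols divergence parameter per population, each in
#'   (0, 1); recycled to `n_populations`.
#' @param n_variants number of biallelic variants (before optional LD copies).
#' @param n_causal number of variants with non-zero liability effects.
#' @param liability_h2 proportion of liability variance explained by the
#'   causal variants, in \[0, 1).
#' @param prevalence per-population disease prevalence K in (0, 1); recycled.
#' @param n_samples per-population cohort sample counts; recycled.
#' @param n_admixed number of two-way admixed samples appended to the cohort
#'   and reference panel.
#' @param admixture_proportions mixing weights of the first two populations
#'   for admixed samples; must sum to 1.
#' @param gwas_n per-population discovery GWAS sample sizes; recycled.
#' @param effect_correlation correlation of true per-variant effects between
#'   populations in \[0, 1\]; 1 means effects are shared exactly.
#' @param maf_range interval from which ancestral allele frequencies are drawn
#'   uniformly; default 0.05-0.5 so a 1% MAF filter rarely binds.
#' @param n_ld_copies number of variants duplicated with correlated genotypes
#'   (to exercise LD pruning and tag-variant search); 0 disables.
#' @param ld_copy_r allele-level copying probability for LD copies; dosage
#'   correlation between a variant and its copy is approximately this value.
#' @param confound_site when TRUE, study site is deterministically tied to
#'   population (to test covariate adjustment); default independent.
#' @param seed integer seed; fully determines every generator output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2, fst = 0.1, n_variants = 1000,
                       n_causal = 100, liability_h2 = 0.3, prevalence = 0.10,
                       n_samples = 500, n_admixed = 0,
                       admixture_proportions = c(0.5, 0.5), gwas_n = 1e5,
                       effect_correlation = 1, maf_range = c(0.05, 0.5),
                       n_ld_copies = 0, ld_copy_r = 0.9,
                       confound_site = FALSE, seed = 42) {
  stopifnot(n_populations >= 1, n_variants >= 1,
            n_causal >= 0, n_causal <= n_variants,
            liability_h2 >= 0, n_admixed >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            n_ld_copies >= 0, n_ld_copies <= n_variants,
            ld_copy_r >= 0, ld_copy_r <= 1,
            effect_correlation >= 0, effect_correlation <= 1)
  if (liability_h2 >= 1) stop("liability_h2 must be < 1")
  fst <- rep_len(fst, n_populations)
  if (any(fst <= 0) || any(fst >= 1))
    stop("fst must lie strictly in (0, 1): F = 0 or 1 degenerates the Beta")
  prevalence <- rep_len(prevalence, n_populations)
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  n_samples <- rep_len(as.integer(n_samples), n_populations)
  gwas_n <- rep_len(gwas_n, n_populations)
  if (n_admixed > 0) {
    if (n_populations < 2) stop("admixture requires >= 2 populations")
    if (abs(sum(admixture_proportions) - 1) > 1e-8)
      stop("admixture_proportions must sum to 1")
  }
  structure(list(n_populations = n_populations, fst = fst,
                 n_variants = n_variants, n_causal = n_causal,
                 liability_h2 = liability_h2, prevalence = prevalence,
                 n_samples = n_samples, n_admixed = n_admixed,
                 admixture_proportions = admixture_proportions,
                 gwas_n = gwas_n, effect_correlation = effect_correlation,
                 maf_range = maf_range, n_ld_copies = n_ld_copies,
                 ld_copy_r = ld_copy_r, confound_site = confound_site,
                 seed = as.integer(seed)),
            class = "sim_config")
}

pop_names <- function(config) sprintf("POP%d", seq_len(config$n_populations))

# Ancestral and population-specific allele frequencies under Balding-Nichols.
# Deterministic in config$seed. Returns list(p_anc, p_pop [pops x variants]).
bn_frequencies <- function(config) {
  set.seed(config$seed)
  m <- config$n_variants
  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
  p_pop <- matrix(NA_real_, config$n_populations, m,
                  dimnames = list(pop_names(config), NULL))
  for (k in seq_len(config$n_populations)) {
    f <- config$fst[k]
    p_pop[k, ] <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  # avoid exactly monomorphic frequencies (Beta mass near 0/1)
  p_pop <- pmin(pmax(p_pop, 1e-4), 1 - 1e-4)
  list(p_anc = p_anc, p_pop = p_pop)
}

variant_table <- function(config) {
  m <- config$n_variants
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)  # non-strand-ambiguous pairs only
  idx <- ((seq_len(m) - 1) %% 4) + 1
  data.frame(id = sprintf("v%05d", seq_len(m)), chrom = "1",
             pos = seq_len(m) * 5000L, a1 = pairs[idx, 1], a2 = pairs[idx, 2],
             stringsAsFactors = FALSE)
}

# Draw genotypes for one block of samples given per-variant frequencies p
# (vector) and optionally append LD copies of the first n_ld_copies variants.
draw_genotypes <- function(n, p, config) {
  m <- length(p)
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (config$n_ld_copies > 0) {
    r <- config$ld_copy_r
    src <- seq_len(config$n_ld_copies)
    cp <- matrix(NA_real_, n, length(src))
    for (ii in seq_along(src)) {
      j <- src[ii]
      # copy each of the two alleles with prob r, redraw otherwise: dosage
      # correlation with the source is r
      keep1 <- rbinom(n, 1L, r); keep2 <- rbinom(n, 1L, r)
      a1 <- pmin(g[, j], 1L); a2 <- g[, j] - a1
      new1 <- ifelse(keep1 == 1L, a1, rbinom(n, 1L, p[j]))
      new2 <- ifelse(keep2 == 1L, a2, rbinom(n, 1L, p[j]))
      cp[, ii] <- new1 + new2
    }
    g <- cbind(g, cp)
  }
  g
}

ld_copy_metadata <- function(variants, config) {
  if (config$n_ld_copies == 0) return(variants)
  src <- variants[seq_len(config$n_ld_copies), , drop = FALSE]
  src$id <- paste0(src$id, "_tag")
  src$pos <- src$pos + 1L
  rbind(variants, src)
}

#' Simulate a multi-ancestry reference panel
#'
#' Generates genotypes for `n_samples` individuals per population (plus
#' `n_admixed` two-way admixed individuals) under the Balding-Nichols model:
#' ancestral frequencies uniform on `maf_range`, population frequencies
#' Beta-distributed around them with divergence `fst`, genotypes binomial.
#' Admixed individuals draw each variant from the mixture of parental
#' population frequencies.
#'
#' @param config a [sim_config()].
#' @param n_per_pop optional override of the per-population panel size
#'   (defaults to `config$n_samples`).
#' @return a list of class `synthetic_panel` with elements `genotypes`
#'   (a [dosage_matrix()]), `population` (factor per sample), and
#'   `frequencies` (true per-population allele-frequency matrix).
#' @export
simulate_reference_panel <- function(config, n_per_pop = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fr <- bn_frequencies(config)
  if (is.null(n_per_pop)) n_per_pop <- config$n_samples
  n_per_pop <- rep_len(as.integer(n_per_pop), config$n_populations)
  set.seed(config$seed + 1L)
  blocks <- vector("list", config$n_populations)
  for (k in seq_len(config$n_populations))
    blocks[[k]] <- draw_genotypes(n_per_pop[k], fr$p_pop[k, ], config)
  labels <- rep(pop_names(config), n_per_pop)
  if (config$n_admixed > 0) {
    w <- config$admixture_proportions
    p_adm <- w[1] * fr$p_pop[1, ] + w[2] * fr$p_pop[2, ]
    blocks <- c(blocks, list(draw_genotypes(config$n_admixed, p_adm, config)))
    labels <- c(labels, rep("ADMIX", config$n_admixed))
  }
  g <- do.call(rbind, blocks)
  rownames(g) <- sprintf("REF%05d", seq_len(nrow(g)))
  vt <- ld_copy_metadata(variant_table(config), config)
  structure(list(genotypes = dosage_matrix(g, vt),
                 population = factor(labels),
                 frequencies = fr$p_pop, config = config),
            class = "synthetic_panel")
}

# True liability weights: N(0, 1) on n_causal variants chosen from the seed,
# zero elsewhere. LD-copy variants never carry their own effect.
true_effects <- function(config) {
  set.seed(config$seed + 2L)
  m <- config$n_variants
  w <- numeric(m + ifelse(config$n_ld_copies > 0, config$n_ld_copies, 0L))
  causal <- sample.int(m, config$n_causal)
  w[causal] <- rnorm(config$n_causal)
  w
}

#' Simulate a multi-ancestry case-control cohort
#'
#' Draws genotypes from the same per-population allele frequencies as the
#' reference panel (same `config`, same seed stream), builds a liability as
#' the within-population standardized genetic score scaled to variance
#' `liability_h2` plus Gaussian noise of variance `1 - liability_h2`, and
#' labels a sample a case iff its liability exceeds the population-specific
#' threshold `qnorm(1 - K)`. Admixed samples use mixture frequencies and the
#' mixture of parental prevalences.
#'
#' @param config a [sim_config()].
#' @param frequencies optional per-population frequency matrix (as returned in
#'   a `synthetic_panel`) so cohort and panel share the same variant pool;
#'   regenerated from `config` when `NULL` (identical either way).
#' @return a list of class `synthetic_cohort`: `genotypes` (dosage matrix),
#'   `status` (0/1), `covariates` (age, sex, site), `population`,
#'   `true_weights`, `liability`, `genetic_score` (raw, unstandardized),
#'   and the `config`.
#' @export
simulate_cohort <- function(config, frequencies = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(frequencies)) frequencies <- bn_frequencies(config)$p_pop
  set.seed(config$seed + 3L)
  blocks <- vector("list", config$n_populations)
  for (k in seq_len(config$n_populations))
    blocks[[k]] <- draw_genotypes(config$n_samples[k], frequencies[k, ], config)
  labels <- rep(pop_names(config), config$n_samples)
  kvec <- rep(config$prevalence, config$n_samples)
  if (config$n_admixed > 0) {
    w <- config$admixture_proportions
    p_adm <- w[1] * frequencies[1, ] + w[2] * frequencies[2, ]
    blocks <- c(blocks, list(draw_genotypes(config$n_admixed, p_adm, config)))
    labels <- c(labels, rep("ADMIX", config$n_admixed))
    k_adm <- w[1] * config$prevalence[1] + w[2] * config$prevalence[2]
    kvec <- c(kvec, rep(k_adm, config$n_admixed))
  }
  g <- do.call(rbind, blocks)
  n <- nrow(g)
  rownames(g) <- sprintf("S%05d", seq_len(n))
  wts <- true_effects(config)
  raw_score <- as.numeric(g %*% wts)
  h2 <- config$liability_h2
  gstd <- numeric(n)
  if (h2 > 0 && config$n_causal > 0) {
    for (lv in unique(labels)) {
      sel <- labels == lv
      s <- raw_score[sel]
      if (sd(s) > 0) gstd[sel] <- (s - mean(s)) / sd(s)
    }
  }
  liability <- sqrt(h2) * gstd + rnorm(n, 0, sqrt(1 - h2))
  status <- as.integer(liability > qnorm(1 - kvec))
  site <- if (config$confound_site) paste0("site_", labels) else
    sample(paste0("site_", 1:3), n, replace = TRUE)
  covariates <- data.frame(sample_id = rownames(g),
                           age = round(rnorm(n, 55, 10), 1),
                           sex = rbinom(n, 1L, 0.5),
                           site = site, stringsAsFactors = FALSE)
  vt <- ld_copy_metadata(variant_table(config), config)
  structure(list(genotypes = dosage_matrix(g, vt),
                 status = status, covariates = covariates,
                 population = factor(labels), true_weights = wts,
                 liability = liability, genetic_score = raw_score,
                 config = config),
            class = "synthetic_cohort")
}

#' Down-sample a cohort to a fixed case fraction
#'
#' Case-control ascertainment: keeps all (or a random subset of) cases and
#' controls so the retained sample has the requested case fraction, emulating
#' an over-sampled case-control study design.
#'
#' @param cohort a `synthetic_cohort`.
#' @param case_fraction target case fraction P in (0, 1); default 0.5.
#' @param seed seed for the subsampling draw.
#' @return the cohort restricted to the ascertained samples.
#' @export
ascertain_cases <- function(cohort, case_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            case_fraction > 0, case_fraction < 1)
  set.seed(seed)
  cases <- which(cohort$status == 1L)
  controls <- which(cohort$status == 0L)
  n_ctrl_want <- round(length(cases) * (1 - case_fraction) / case_fraction)
  if (n_ctrl_want <= length(controls)) {
    keep <- c(cases, sample(controls, n_ctrl_want))
  } else {
    n_case_want <- round(length(controls) * case_fraction / (1 - case_fraction))
    keep <- c(sample(cases, n_case_want), controls)
  }
  keep <- sort(keep)
  out <- cohort
  out$genotypes <- cohort$genotypes[keep, ]
  out$status <- cohort$status[keep]
  out$covariates <- cohort$covariates[keep, , drop = FALSE]
  out$population <- factor(as.character(cohort$population[keep]))
  out$liability <- cohort$liability[keep]
  out$genetic_score <- cohort$genetic_score[keep]
  out
}

#' Simulate per-population GWAS summary statistics
#'
#' For each population, per-variant effect estimates are the true liability
#' effects plus Gaussian noise with standard error `1 / sqrt(2 N p (1 - p))`
#' (the large-sample SE of a per-allele regression coefficient at allele
#' frequency p and discovery sample size N); p-values are two-sided Wald.
#' When `effect_correlation < 1`, each population receives its own correlated
#' draw of true effects around the shared architecture.
#'
#' @param config a [sim_config()] with `gwas_n` set per population.
#' @param frequencies optional per-population frequency matrix (shared with
#'   the panel/cohort); regenerated from `config` when `NULL`.
#' @return named list of data.frames (one per population) with columns
#'   `id, chrom, pos, effect_allele, other_allele, beta, se, p, freq, n`.
#'   Monomorphic variants (undefined SE) are dropped; the per-table attribute
#'   `n_dropped_monomorphic` records how many.
#' @export
simulate_gwas_summary <- function(config, frequencies = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(frequencies)) frequencies <- bn_frequencies(config)$p_pop
  wts <- true_effects(config)
  vt <- ld_copy_metadata(variant_table(config), config)
  set.seed(config$seed + 4L)
  rho <- config$effect_correlation
  out <- vector("list", config$n_populations)
  names(out) <- pop_names(config)
  for (k in seq_len(config$n_populations)) {
    b_true <- if (rho == 1) wts else {
      noise <- numeric(length(wts))
      causal <- wts != 0
      noise[causal] <- rnorm(sum(causal), 0, sd(wts[causal]))
      rho * wts + sqrt(1 - rho^2) * noise
    }
    p <- frequencies[k, ]
    if (config$n_ld_copies > 0)
      p <- c(p, p[seq_len(config$n_ld_copies)])
    mono <- p <= 0 | p >= 1
    n_drop <- sum(mono)
    if (n_drop > 0)
      message("population ", k, ": dropped ", n_drop,
              " monomorphic variant(s) with undefined SE")
    se <- 1 / sqrt(2 * config$gwas_n[k] * p * (1 - p))
    beta <- b_true + rnorm(length(p), 0, se)
    pval <- 2 * pnorm(-abs(beta / se))
    tab <- data.frame(id = vt$id, chrom = vt$chrom, pos = vt$pos,
                      effect_allele = vt$a1, other_allele = vt$a2,
                      beta = beta, se = se, p = pval, freq = p,
                      n = config$gwas_n[k], stringsAsFactors = FALSE)
    tab <- tab[!mono, , drop = FALSE]
    attr(tab, "n_dropped_monomorphic") <- n_drop
    out[[k]] <- tab
  }
  out
}

#' Weight table from generative effects
#'
#' Packages the generator's true liability effects (non-zero entries only) as
#' a scoring weight table, so synthetic cohorts can be scored through the same
#' I/O path as a published score.
#'
#' @param cohort a `synthetic_cohort` (or `synthetic_panel` plus explicit
#'   `weights`).
#' @param weights optional per-variant weights overriding `true_weights`.
#' @return a `weight_table` data.frame (see [load_weights()]).
#' @export
true_weight_table <- function(cohort, weights = NULL) {
  if (is.null(weights)) weights <- cohort$true_weights
  vt <- cohort$genotypes$variants
  keep <- weights != 0
  out <- data.frame(variant_id = vt$id[keep], chrom = vt$chrom[keep],
                    pos = vt$pos[keep], effect_allele = vt$a1[keep],
                    other_allele = vt$a2[keep], weight = weights[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_table", "data.frame")
  out
}
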