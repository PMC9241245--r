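#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines study estimates (log-ORs or betas) with weights `1 / se^2`:
#' the combined estimate is the weighted mean, its standard error
#' `1 / sqrt(sum of weights)`, and the p-value two-sided Wald. Cochran's Q
#' and I-squared are reported for heterogeneity inspection (not filtering).
#'
#' @param estimates numeric vector of study estimates (e.g. log-ORs).
#' @param ses matching standard errors, all > 0.
#' @return list of class `meta_result`: `estimate`, `se`, `p`, `weights`
#'   (normalized to sum 1), `Q`, `I2`, `n_studies`.
#' @export
ivw_meta <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses), length(estimates) >= 1)
  if (any(!is.finite(estimates)) || any(!is.finite(ses)))
    stop("non-finite estimate or SE")
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (estimates - est)^2)
  k <- length(estimates)
  I2 <- if (k > 1) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(estimate = est, se = se,
                 p = 2 * pnorm(-abs(est / se)),
                 weights = w / sum(w), Q = Q, I2 = I2, n_studies = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: estimate %.4f (se %.4f, p %.3g) over %d studies\n",
              x$estimate, x$se, x$p, x$n_studies))
  invisible(x)
}

# Harmonize a summary table to a reference orientation on the shared key
# (chrom, pos, unordered allele pair): swapped alleles flip the beta sign and
# frequency; mismatched pairs are dropped.
harmonize_to <- function(ref, tab) {
  rkey <- variant_key(ref$chrom, ref$pos, ref$effect_allele, ref$other_allele)
  tkey <- variant_key(tab$chrom, tab$pos, tab$effect_allele, tab$other_allele)
  hit <- match(tkey, rkey)
  keep <- !is.na(hit)
  tab <- tab[keep, , drop = FALSE]
  hit <- hit[keep]
  same <- tab$effect_allele == ref$effect_allele[hit]
  swap <- tab$effect_allele == ref$other_allele[hit] &
    tab$other_allele == ref$effect_allele[hit]
  tab$beta[swap] <- -tab$beta[swap]
  if ("freq" %in% names(tab)) tab$freq[swap] <- 1 - tab$freq[swap]
  tab$effect_allele[swap] <- ref$effect_allele[hit][swap]
  tab$other_allele[swap] <- ref$other_allele[hit][swap]
  ok <- same | swap
  attr(tab, "n_mismatch") <- sum(!ok)
  tab[ok, , drop = FALSE]
}

#' Per-variant fixed-effect meta-analysis of GWAS summary tables
#'
#' Matches variants across tables on (chrom, pos, unordered allele pair),
#' harmonizing swapped effect/other orientations by sign flip; allele-pair
#' mismatches at a shared position are dropped and counted. Each variant is
#' combined by inverse-variance weighting over the studies in which it
#' appears; `n_studies` records how many contributed.
#'
#' @param stats_list list of summary-statistic data.frames with columns
#'   `id, chrom, pos, effect_allele, other_allele, beta, se` (optionally
#'   `freq`, `n`).
#' @return data.frame with the union of variants, combined `beta`, `se`, `p`,
#'   and `n_studies`; attribute `n_mismatch_dropped` counts dropped rows.
#' @export
fixed_effect_meta <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1)
  if (length(stats_list) == 1) {
    out <- stats_list[[1]]
    out$n_studies <- 1L
    attr(out, "n_mismatch_dropped") <- 0L
    return(out)
  }
  # union reference frame: first occurrence of each key fixes the orientation
  all_tab <- do.call(rbind, lapply(stats_list, function(t)
    t[, c("id", "chrom", "pos", "effect_allele", "other_allele")]))
  key <- variant_key(all_tab$chrom, all_tab$pos, all_tab$effect_allele,
                     all_tab$other_allele)
  ref <- all_tab[!duplicated(key), , drop = FALSE]
  rkey <- key[!duplicated(key)]
  num <- den <- cnt <- setNames(numeric(nrow(ref)), rkey)
  n_mismatch <- 0L
  for (tab in stats_list) {
    h <- harmonize_to(ref, tab)
    n_mismatch <- n_mismatch + attr(h, "n_mismatch")
    hk <- variant_key(h$chrom, h$pos, h$effect_allele, h$other_allele)
    w <- 1 / h$se^2
    num[hk] <- num[hk] + w * h$beta
    den[hk] <- den[hk] + w
    cnt[hk] <- cnt[hk] + 1
  }
  beta <- num / den
  se <- 1 / sqrt(den)
  out <- data.frame(ref, beta = unname(beta), se = unname(se),
                    p = unname(2 * pnorm(-abs(beta / se))),
                    n_studies = unname(as.integer(cnt)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  attr(out, "n_mismatch_dropped") <- n_mismatch
  out
}

#' Extract lead variants of genome-wide significant loci
#'
#' Greedy clumping: repeatedly take the smallest-p variant below
#' `p_threshold`, emit it as a locus lead, and remove every variant within
#' `locus_window_bp` on each side on the same chromosome; repeat until no
#' significant variant remains.
#'
#' @param stats summary-statistics data.frame with `id, chrom, pos, p`.
#' @param p_threshold significance threshold (default 5e-8).
#' @param locus_window_bp window defining a locus, each side of the lead
#'   (default 500 kb).
#' @return the lead-variant rows of `stats`, in emission (ascending p) order.
#' @export
extract_lead_variants <- function(stats, p_threshold = 5e-8,
                                  locus_window_bp = 5e5) {
  live <- stats[stats$p < p_threshold, , drop = FALSE]
  if (nrow(live) == 0) {
    message("extract_lead_variants: no variant below p = ", p_threshold)
    return(stats[0, , drop = FALSE])
  }
  leads <- list()
  while (nrow(live) > 0) {
    i <- which.min(live$p)
    lead <- live[i, , drop = FALSE]
    leads[[length(leads) + 1]] <- lead
    live <- live[!(live$chrom == lead$chrom &
                     abs(live$pos - lead$pos) <= locus_window_bp), ,
                 drop = FALSE]
  }
  out <- do.call(rbind, leads)
  rownames(out) <- NULL
  out
}

#' Find an LD tag variant for a lead absent from a target dataset
#'
#' Among panel variants within `locus_window_bp` of the lead (same
#' chromosome) whose ids appear in `target_ids`, returns the one with the
#' highest squared dosage correlation with the lead, provided it reaches
#' `r2_min`; otherwise `NULL`.
#'
#' @param lead one-row data.frame with `id`, `chrom`, `pos`.
#' @param target_ids variant ids available in the target summary table.
#' @param genotypes a [dosage_matrix()] LD panel containing the lead.
#' @param r2_min minimum squared correlation (default 0.6).
#' @param locus_window_bp search window each side of the lead.
#' @return list(`id`, `r2`) or `NULL`.
#' @export
find_tag_variant <- function(lead, target_ids, genotypes, r2_min = 0.6,
                             locus_window_bp = 5e5) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  vt <- genotypes$variants
  li <- match(lead$id, vt$id)
  if (is.na(li)) stop("lead variant ", lead$id, " absent from LD panel")
  lead_d <- genotypes$dosages[, li]
  if (sd(lead_d, na.rm = TRUE) == 0) {
    message("find_tag_variant: lead ", lead$id, " monomorphic in panel")
    return(NULL)
  }
  cand <- which(vt$chrom == lead$chrom &
                  abs(vt$pos - lead$pos) <= locus_window_bp &
                  vt$id != lead$id & vt$id %in% target_ids)
  if (length(cand) == 0) return(NULL)
  r2 <- vapply(cand, function(j)
    suppressWarnings(cor(lead_d, genotypes$dosages[, j],
                         use = "pairwise.complete.obs"))^2, numeric(1))
  r2[is.na(r2)] <- 0
  best <- which.max(r2)
  if (r2[best] < r2_min) return(NULL)
  list(id = vt$id[cand[best]], r2 = unname(r2[best]))
}

#' Cross-population effect-size concordance
#'
#' Pearson correlation of absolute per-allele effect sizes at lead variants
#' present in two populations' summary tables. When a lead is missing from a
#' table and an LD panel is supplied, the best tag variant (r-squared at
#' least `r2_min`) substitutes for it; substitutions are listed. Tag
#' substitution tends to attenuate the correlation, so the reported value is
#' conservative.
#'
#' @param pop1,pop2 summary-statistic data.frames (`id`, `beta`, ...).
#' @param leads lead-variant data.frame from [extract_lead_variants()].
#' @param genotypes optional [dosage_matrix()] LD panel for tag search.
#' @param r2_min minimum tag r-squared.
#' @param locus_window_bp tag search window.
#' @return list: `r` (correlation of |beta|), `n_variants`, `substitutions`
#'   (data.frame lead/tag/population/r2).
#' @export
effect_concordance <- function(pop1, pop2, leads, genotypes = NULL,
                               r2_min = 0.6, locus_window_bp = 5e5) {
  subs <- list()
  pick_beta <- function(tab, lead, pop_label) {
    i <- match(lead$id, tab$id)
    if (!is.na(i)) return(tab$beta[i])
    if (is.null(genotypes)) return(NA_real_)
    tag <- find_tag_variant(lead, tab$id, genotypes, r2_min, locus_window_bp)
    if (is.null(tag)) return(NA_real_)
    subs[[length(subs) + 1]] <<- data.frame(lead = lead$id, tag = tag$id,
                                            population = pop_label,
                                            r2 = tag$r2)
    tab$beta[match(tag$id, tab$id)]
  }
  b1 <- b2 <- numeric(nrow(leads))
  for (i in seq_len(nrow(leads))) {
    b1[i] <- pick_beta(pop1, leads[i, ], "pop1")
    b2[i] <- pick_beta(pop2, leads[i, ], "pop2")
  }
  ok <- is.finite(b1) & is.finite(b2)
  if (sum(ok) < 3) stop("fewer than 3 lead/tag pairs present in both tables")
  list(r = cor(abs(b1[ok]), abs(b2[ok])), n_variants = sum(ok),
       substitutions = if (length(subs)) do.call(rbind, subs) else
         data.frame(lead = character(), tag = character(),
                    population = character(), r2 = numeric()))
}
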