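#' Load a PRS weight table
#'
#' Reads a scoring file in either PGS Catalog format (tab-separated, header
#' vocabulary `rsID / chr_name / chr_position / effect_allele / other_allele /
#' effect_weight`, optional `#`-prefixed metadata lines) or a generic TSV with
#' columns `variant_id / chrom / pos / effect_allele / other_allele / weight`.
#' Rows with non-ACGT alleles or non-finite weights are dropped and counted;
#' duplicate (chrom, pos, allele-pair) keys are an error.
#'
#' @param path path to the scoring file.
#' @param format `"auto"` (sniff the header), `"pgs_catalog"`, or `"tsv"`.
#' @return a `weight_table` data.frame with columns `variant_id, chrom, pos,
#'   effect_allele, other_allele, weight` and attribute `n_dropped`.
#' @export
load_weights <- function(path, format = c("auto", "pgs_catalog", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("scoring file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  pgs_cols <- c("rsID", "chr_name", "chr_position", "effect_allele",
                "other_allele", "effect_weight")
  tsv_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "weight")
  if (format == "auto")
    format <- if (all(pgs_cols[-1] %in% names(tab))) "pgs_catalog" else "tsv"
  want <- if (format == "pgs_catalog") pgs_cols else tsv_cols
  optional <- if (format == "pgs_catalog") "rsID" else character()
  miss <- setdiff(setdiff(want, optional), names(tab))
  if (length(miss))
    stop("scoring file missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (format == "pgs_catalog") {
    out <- data.frame(
      variant_id = if ("rsID" %in% names(tab)) as.character(tab$rsID) else
        paste0(tab$chr_name, ":", tab$chr_position),
      chrom = as.character(tab$chr_name), pos = as.integer(tab$chr_position),
      effect_allele = toupper(as.character(tab$effect_allele)),
      other_allele = toupper(as.character(tab$other_allele)),
      weight = suppressWarnings(as.numeric(tab$effect_weight)),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      variant_id = as.character(tab$variant_id),
      chrom = as.character(tab$chrom), pos = as.integer(tab$pos),
      effect_allele = toupper(as.character(tab$effect_allele)),
      other_allele = toupper(as.character(tab$other_allele)),
      weight = suppressWarnings(as.numeric(tab$weight)),
      stringsAsFactors = FALSE)
  }
  acgt <- c("A", "C", "G", "T")
  bad <- !(out$effect_allele %in% acgt) | !(out$other_allele %in% acgt) |
    !is.finite(out$weight) | out$effect_allele == out$other_allele
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  key <- paste(out$chrom, out$pos,
               pmin(out$effect_allele, out$other_allele),
               pmax(out$effect_allele, out$other_allele))
  if (anyDuplicated(key))
    stop("duplicate variant key(s) in weight table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("weight_table", "data.frame")
  out
}

variant_key <- function(chrom, pos, a, b)
  paste(chrom, pos, pmin(a, b), pmax(a, b))

is_ambiguous <- function(a, b)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")

#' Align weight-table alleles to genotype dosages
#'
#' Matches weight-table variants to dosage-matrix variants on
#' (chrom, pos, unordered allele pair). An exact effect/other orientation
#' keeps the weight as is; a swapped orientation flags the variant so scoring
#' uses dosage `2 - d` (the counted allele is the weight's effect allele
#' either way, so all scores are comparable); a mismatched allele pair is
#' dropped. Strand-ambiguous pairs (A/T, C/G) are dropped by default because
#' their orientation cannot be resolved without strand metadata.
#'
#' @param weights a `weight_table` from [load_weights()].
#' @param genotypes a [dosage_matrix()].
#' @param ambiguous `"drop"` (default) or `"keep"` for strand-ambiguous SNPs.
#' @return list of class `allele_match`: `index` (dosage column), `weight`,
#'   `flip` (logical: dosage must be reversed), and `report`, a named count
#'   vector (`matched`, `flipped`, `mismatch`, `ambiguous_dropped`, `absent`).
#' @export
align_alleles <- function(weights, genotypes, ambiguous = c("drop", "keep")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(weights, "weight_table"),
            inherits(genotypes, "dosage_matrix"))
  vt <- genotypes$variants
  gkey <- variant_key(vt$chrom, vt$pos, vt$a1, vt$a2)
  wkey <- variant_key(weights$chrom, weights$pos,
                      weights$effect_allele, weights$other_allele)
  hit <- match(wkey, gkey)
  # weights with no allele-pair match may still share a position: those are
  # allele mismatches, not absent variants
  pos_hit <- match(paste(weights$chrom, weights$pos),
                   paste(vt$chrom, vt$pos))
  hit[is.na(hit)] <- pos_hit[is.na(hit)]
  absent <- sum(is.na(hit))
  w <- weights[!is.na(hit), , drop = FALSE]
  j <- hit[!is.na(hit)]
  amb <- is_ambiguous(w$effect_allele, w$other_allele)
  n_amb <- 0L
  if (ambiguous == "drop" && any(amb)) {
    n_amb <- sum(amb)
    w <- w[!amb, , drop = FALSE]; j <- j[!amb]
  }
  same <- w$effect_allele == vt$a1[j] & w$other_allele == vt$a2[j]
  swap <- w$effect_allele == vt$a2[j] & w$other_allele == vt$a1[j]
  mismatch <- !(same | swap)  # same position, different allele pair
  keep <- same | swap
  report <- c(matched = sum(same), flipped = sum(swap),
              mismatch = sum(mismatch), ambiguous_dropped = n_amb,
              absent = absent)
  if (!any(keep)) stop("no weight-table variant matched the genotypes")
  structure(list(index = j[keep], weight = w$weight[keep],
                 flip = swap[keep], report = report),
            class = "allele_match")
}

#' Compute raw polygenic risk scores
#'
#' `score_i = sum_j w_j * d_ij` over the aligned variants, where `d_ij` is the
#' effect-allele dosage (reversed to `2 - d` for orientation-flipped
#' variants). Missing dosages are imputed as twice the effect-allele frequency
#' (the default of standard scoring tools) unless `impute_missing = FALSE`,
#' in which case they contribute zero.
#'
#' @param genotypes a [dosage_matrix()].
#' @param matched an `allele_match` from [align_alleles()].
#' @param impute_missing impute missing dosages from allele frequency?
#' @return data.frame of class `score_vector` with columns `sample_id`, `prs`;
#'   attributes `n_variants_used` and `n_missing_imputed`.
#' @export
compute_prs <- function(genotypes, matched, impute_missing = TRUE) {
  stopifnot(inherits(genotypes, "dosage_matrix"),
            inherits(matched, "allele_match"))
  d <- genotypes$dosages[, matched$index, drop = FALSE]
  f <- genotypes$freq[matched$index]
  n_missing <- sum(is.na(d))
  if (n_missing > 0) {
    if (impute_missing) {
      miss_by_var <- colSums(is.na(d)) > 0
      if (any(miss_by_var & !is.finite(f)))
        stop("variant(s) with missing dosages and no allele frequency: ",
             "cannot impute")
      fill <- matrix(rep(2 * f, each = nrow(d)), nrow(d))
      d[is.na(d)] <- fill[is.na(d)]
    } else {
      d[is.na(d)] <- 0
    }
  }
  flip <- matched$flip
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  prs <- as.numeric(d %*% matched$weight)
  out <- data.frame(sample_id = rownames(genotypes$dosages), prs = prs,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- length(matched$index)
  attr(out, "n_missing_imputed") <- if (impute_missing) n_missing else 0L
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Score a cohort in one call
#'
#' Convenience wrapper: align a weight table to a dosage matrix and compute
#' raw scores.
#'
#' @inheritParams align_alleles
#' @inheritParams compute_prs
#' @return a `score_vector` (see [compute_prs()]); the alignment report is
#'   attached as attribute `match_report`.
#' @export
score_samples <- function(weights, genotypes, ambiguous = c("drop", "keep"),
                          impute_missing = TRUE) {
  matched <- align_alleles(weights, genotypes, ambiguous = ambiguous)
  out <- compute_prs(genotypes, matched, impute_missing = impute_missing)
  attr(out, "match_report") <- matched$report
  out
}

#' Filter variants on minor allele frequency
#'
#' Removes variants whose minor allele frequency `min(f, 1 - f)` falls below
#' `threshold`. With a `groups` factor, the frequency is computed within each
#' group and a variant is removed when it fails the threshold in any group
#' (the within-population exclusion rule).
#'
#' @param genotypes a [dosage_matrix()].
#' @param threshold MAF threshold in \[0, 0.5); default 0.01.
#' @param groups optional factor of per-sample group labels.
#' @return the filtered `dosage_matrix`; attribute `n_removed` records the
#'   number of excluded variants.
#' @export
filter_maf <- function(genotypes, threshold = 0.01, groups = NULL) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  if (threshold < 0 || threshold >= 0.5)
    stop("MAF threshold must lie in [0, 0.5)")
  d <- genotypes$dosages
  maf_of <- function(f) pmin(f, 1 - f)
  if (is.null(groups)) {
    fails <- maf_of(colMeans(d, na.rm = TRUE) / 2) < threshold
  } else {
    stopifnot(length(groups) == nrow(d))
    fails <- rep(FALSE, ncol(d))
    for (g in unique(groups)) {
      f <- colMeans(d[groups == g, , drop = FALSE], na.rm = TRUE) / 2
      fails <- fails | maf_of(f) < threshold
    }
  }
  n_removed <- sum(fails)
  if (n_removed > 0)
    message("filter_maf: removed ", n_removed, " variant(s) below MAF ",
            threshold)
  out <- genotypes[, !fails]
  attr(out, "n_removed") <- n_removed
  out
}
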