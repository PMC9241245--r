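#' Greedy windowed LD pruning
#'
#' Within each window of `window` variants (advanced by `step` variants along
#' the position-sorted variant list, per chromosome), while any surviving pair
#' has squared Pearson dosage correlation above `r2_max`, the member of the
#' worst pair with the lower MAF is removed (tie: the later position). The
#' defaults mirror the common `--indep-pairwise 500 50 0.05` invocation.
#'
#' @param genotypes a [dosage_matrix()].
#' @param window window size in variant count.
#' @param step step size in variant count; must satisfy `window >= step >= 1`.
#' @param r2_max maximum allowed squared correlation, in (0, 1).
#' @return character vector of surviving variant ids, in position order.
#' @export
ld_prune <- function(genotypes, window = 500, step = 50, r2_max = 0.05) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must lie in (0, 1)")
  vt <- genotypes$variants
  if (nrow(vt) < 2) {
    warning("fewer than 2 variants: nothing to prune")
    return(vt$id)
  }
  d <- genotypes$dosages
  maf <- pmin(genotypes$freq, 1 - genotypes$freq)
  keep <- rep(TRUE, nrow(vt))
  for (chr in unique(vt$chrom)) {
    idx <- which(vt$chrom == chr)
    idx <- idx[order(vt$pos[idx])]
    start <- 1
    repeat {
      win <- idx[start:min(start + window - 1, length(idx))]
      live <- win[keep[win]]
      if (length(live) >= 2) {
        r2 <- suppressWarnings(cor(d[, live, drop = FALSE],
                                   use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (max(r2) > r2_max) {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          a <- live[worst[1]]; b <- live[worst[2]]
          drop_v <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else if (vt$pos[a] > vt$pos[b]) a else b
          keep[drop_v] <- FALSE
          di <- which(live == drop_v)
          live <- live[-di]
          r2 <- r2[-di, -di, drop = FALSE]
          if (length(live) < 2) break
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  vt$id[keep][order(vt$chrom[keep], vt$pos[keep])]
}

pc_fingerprint <- function(variants, loadings) {
  paste0("pcm:", nrow(loadings), "x", ncol(loadings), ":",
         variants$id[1], ":", variants$id[nrow(variants)], ":",
         format(sum(loadings * seq_along(loadings)) %% 1e6, digits = 12))
}

#' Fit a reference-panel PCA model
#'
#' Standardizes each variant by mean `2p` and scale `sqrt(2p(1-p))` (p =
#' counted-allele frequency in the reference), takes the top `K_pc` singular
#' vectors, and stores the variant loadings, standardization constants and
#' reference scores so new samples can be projected into the same space.
#' Zero-variance variants are excluded (with a count); missing dosages are
#' mean-imputed. Component signs are fixed so each component's
#' largest-magnitude loading is positive, making downstream regression
#' coefficients reproducible.
#'
#' @param reference a [dosage_matrix()] (LD-pruned, MAF-filtered).
#' @param K_pc number of components to retain; must be < min(n, m).
#' @param labels optional factor of reference population labels.
#' @return an object of class `pc_model`: `variants`, `freq`, `loadings`
#'   (m x K), `scores` (reference PC scores), `labels`, `sdev`,
#'   `n_zero_variance`, `fingerprint`.
#' @export
fit_pca <- function(reference, K_pc = 10, labels = NULL) {
  stopifnot(inherits(reference, "dosage_matrix"))
  d <- reference$dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  }
  p <- colMeans(d) / 2
  ok <- p > 0 & p < 1 & apply(d, 2, sd) > 0
  n_zero <- sum(!ok)
  if (n_zero > 0)
    message("fit_pca: excluded ", n_zero, " zero-variance variant(s)")
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  if (K_pc >= min(dim(d)))
    stop("K_pc (", K_pc, ") must be smaller than matrix rank bound ",
         min(dim(d)))
  x <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x, nu = K_pc, nv = K_pc)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(K_pc)], K_pc)
  for (k in seq_len(K_pc)) {     # deterministic sign convention
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(K_pc))
  rownames(scores) <- rownames(reference$dosages)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(scores))
    labels <- factor(labels)
  }
  vt <- reference$variants[ok, , drop = FALSE]
  structure(list(variants = vt, freq = p, loadings = loadings,
                 scores = scores, labels = labels,
                 sdev = sv$d[seq_len(K_pc)] / sqrt(nrow(d) - 1),
                 n_zero_variance = n_zero,
                 fingerprint = pc_fingerprint(vt, loadings)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", nrow(x$loadings), "variants,", ncol(x$loadings),
      "components,", nrow(x$scores), "reference samples\n")
  invisible(x)
}

#' Project samples into a reference PC space
#'
#' Target variants are matched to model variants on (chrom, pos, allele pair)
#' with orientation flips handled as in [align_alleles()]; each matched
#' variant is standardized with the reference constants, absent or missing
#' entries contribute the standardized mean (zero), and scores are the product
#' with the stored loadings. Requires at least `min_overlap` of model variants
#' present in the target.
#'
#' @param model a [fit_pca()] model.
#' @param genotypes target [dosage_matrix()].
#' @param min_overlap minimum fraction of model variants that must be matched.
#' @return data.frame of class `ancestry_coords`: `sample_id` plus PC columns;
#'   carries the model fingerprint as an attribute.
#' @export
project_samples <- function(model, genotypes, min_overlap = 0.5) {
  stopifnot(inherits(model, "pc_model"), inherits(genotypes, "dosage_matrix"))
  mv <- model$variants
  tv <- genotypes$variants
  mkey <- variant_key(mv$chrom, mv$pos, mv$a1, mv$a2)
  tkey <- variant_key(tv$chrom, tv$pos, tv$a1, tv$a2)
  hit <- match(mkey, tkey)
  overlap <- mean(!is.na(hit))
  if (overlap < min_overlap)
    stop(sprintf("only %.1f%% of model variants present in target (need %.0f%%)",
                 100 * overlap, 100 * min_overlap))
  n <- nrow(genotypes$dosages)
  x <- matrix(0, n, nrow(mv))
  present <- which(!is.na(hit))
  for (jj in present) {
    j <- hit[jj]
    d <- genotypes$dosages[, j]
    if (tv$a1[j] == mv$a1[jj]) {
      # same counted allele
    } else if (tv$a1[j] == mv$a2[jj]) {
      d <- 2 - d
    } else next                       # allele-pair mismatch: treat as absent
    z <- (d - 2 * model$freq[jj]) / sqrt(2 * model$freq[jj] *
                                           (1 - model$freq[jj]))
    z[is.na(z) | !is.finite(z)] <- 0  # missing dosage -> standardized mean
    x[, jj] <- z
  }
  scores <- x %*% model$loadings
  out <- data.frame(sample_id = rownames(genotypes$dosages), scores,
                    stringsAsFactors = FALSE)
  attr(out, "fingerprint") <- model$fingerprint
  attr(out, "overlap") <- overlap
  class(out) <- c("ancestry_coords", "data.frame")
  out
}

# Class-conditional classifier on top PCs: per-class mean and
# (ridge-regularized) covariance, priors proportional to class frequency.
# Densities are multivariate Student-t (df small) rather than Gaussian: with
# Gaussian tails a sample far from every class (e.g. admixed) is still given
# a near-1 posterior for whichever class is marginally closer, because the
# likelihood ratio is exponential in squared distance; heavy tails make the
# ratio polynomial, so such samples keep intermediate posteriors and abstain.
classifier_posteriors <- function(train, labels, test, df = 4) {
  classes <- levels(labels)
  k <- ncol(train)
  loglik <- matrix(NA_real_, nrow(test), length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    xs <- train[labels == cl, , drop = FALSE]
    mu <- colMeans(xs)
    sig <- cov(xs) + diag(1e-8 * mean(diag(cov(xs))) + 1e-12, k)
    ch <- chol(sig)
    z <- backsolve(ch, t(sweep(test, 2, mu)), transpose = TRUE)
    d2 <- colSums(z^2)
    loglik[, cl] <- -((df + k) / 2) * log1p(d2 / df) - sum(log(diag(ch))) +
      log(mean(labels == cl))
  }
  post <- exp(loglik - apply(loglik, 1, max))
  post / rowSums(post)
}

#' Assign samples to reference populations
#'
#' Trains a probabilistic classifier on the reference PC scores and labels,
#' then gives each sample its maximum-posterior population label when that
#' posterior exceeds `prob_threshold`, else `"unassigned"`. The default
#' classifier is a class-conditional model with per-class mean and
#' covariance and heavy-tailed (multivariate Student-t, `df = 4`) densities:
#' a deterministic fulfilment of the "probabilistic classifier over top PCs
#' with an abstention threshold" contract whose heavy tails keep posteriors
#' intermediate for samples (e.g. admixed) that sit far from every class,
#' so they abstain instead of being force-assigned.
#'
#' @param coords an `ancestry_coords` from [project_samples()].
#' @param model the [fit_pca()] model (must carry reference labels).
#' @param n_pcs number of leading PCs used by the classifier (default 6).
#' @param prob_threshold abstention threshold in \[0, 1\] (default 0.8).
#' @param df degrees of freedom of the class-conditional t densities.
#' @return `coords` with added columns `label` and `probability`.
#' @export
assign_population <- function(coords, model, n_pcs = 6, prob_threshold = 0.8,
                              df = 4) {
  stopifnot(inherits(coords, "ancestry_coords"), inherits(model, "pc_model"))
  if (is.null(model$labels)) stop("model carries no reference labels")
  if (n_pcs > ncol(model$loadings))
    stop("n_pcs (", n_pcs, ") exceeds model components (",
         ncol(model$loadings), ")")
  pcs <- paste0("PC", seq_len(n_pcs))
  post <- classifier_posteriors(model$scores[, pcs, drop = FALSE],
                                model$labels,
                                as.matrix(coords[, pcs, drop = FALSE]),
                                df = df)
  best <- max.col(post, ties.method = "first")
  prob <- post[cbind(seq_len(nrow(post)), best)]
  label <- colnames(post)[best]
  label[prob <= prob_threshold] <- "unassigned"
  coords$label <- label
  coords$probability <- prob
  coords
}
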