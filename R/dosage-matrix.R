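#' Construct a dosage matrix
#'
#' The central genotype container: a samples-by-variants matrix of
#' effect-allele dosages in \[0, 2\] (NA = missing), together with variant
#' metadata and per-variant counted-allele frequencies. Dosages count copies
#' of allele `a1`; `a2` is the other allele.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids (generated if absent).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per column of `dosages`.
#' @param freq optional numeric vector of counted-allele (`a1`) frequencies;
#'   computed from mean dosage / 2 on complete data when `NULL`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants, freq = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(is.numeric(dosages), is.data.frame(variants))
  req <- c("id", "chrom", "pos", "a1", "a2")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variants rows (", nrow(variants), ") != dosage columns (",
         ncol(dosages), ")")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  colnames(dosages) <- variants$id
  if (is.null(freq)) freq <- colMeans(dosages, na.rm = TRUE) / 2
  stopifnot(length(freq) == ncol(dosages))
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 freq = as.numeric(freq)),
            class = "dosage_matrix")
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants;", sum(is.na(x$dosages)), "missing entries\n")
  invisible(x)
}

#' Sample ids of a dosage matrix
#' @param x a `dosage_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) rownames(x$dosages)

#' Subset a dosage matrix
#'
#' @param x a `dosage_matrix`
#' @param i sample index (logical, integer or character)
#' @param j variant index (logical, integer or character variant ids)
#' @param ... unused
#' @return a `dosage_matrix` over the selected samples and variants
#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  d <- x$dosages[i, j, drop = FALSE]
  dosage_matrix(d, x$variants[j, , drop = FALSE], freq = x$freq[j])
}
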