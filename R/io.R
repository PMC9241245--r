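#' Write and read a dosage matrix as TSV
#'
#' The dosage file is samples-by-variants with a `sample_id` column and a
#' header row of variant ids; variant metadata (id, chrom, pos, counted
#' allele `a1`, other allele `a2`, frequency) travels in a sidecar file
#' `<path>.variants.tsv`.
#'
#' @param genotypes a [dosage_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  d <- as.data.frame(genotypes$dosages)
  d <- cbind(sample_id = rownames(genotypes$dosages), d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  vt <- genotypes$variants
  vt$freq <- genotypes$freq
  write.table(vt, paste0(path, ".variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param variants_path sidecar metadata path; defaults to
#'   `<path>.variants.tsv`.
#' @return for the reader, a [dosage_matrix()].
#' @export
read_dosage_tsv <- function(path, variants_path = paste0(path, ".variants.tsv")) {
  if (!file.exists(path)) stop("dosage file not found: ", path)
  if (!file.exists(variants_path))
    stop("variant metadata sidecar not found: ", variants_path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  vt <- read.table(variants_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$sample_id
  ord <- match(colnames(d), vt$id)
  if (anyNA(ord)) stop("variant metadata does not cover all dosage columns")
  vt <- vt[ord, , drop = FALSE]
  dosage_matrix(d, vt[, c("id", "chrom", "pos", "a1", "a2")],
                freq = if ("freq" %in% names(vt)) vt$freq else NULL)
}

#' Write a dosage matrix as a VCF with DS (and GT) fields
#'
#' The counted allele `a1` is written as ALT and `a2` as REF, so the DS field
#' carries the ALT-allele dosage (the standard imputation convention). GT is
#' the rounded dosage, for consumers without DS support.
#'
#' @param genotypes a [dosage_matrix()].
#' @param path output VCF path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  vt <- genotypes$variants
  d <- genotypes$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                      "Description=\"Dosage of the ALT allele\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    ds <- d[, j]
    gt <- ifelse(is.na(ds), "./.", gt_codes[pmin(pmax(round(ds), 0), 2) + 1])
    ds_txt <- ifelse(is.na(ds), ".", formatC(ds, digits = 4, format = "g"))
    writeLines(paste(c(vt$chrom[j], vt$pos[j], vt$id[j], vt$a2[j], vt$a1[j],
                       ".", "PASS", ".", "GT:DS",
                       paste(gt, ds_txt, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the DS (dosage) FORMAT field when present, otherwise converts GT calls
#' to allele counts. The ALT allele becomes the counted allele `a1`.
#' Multi-allelic records are dropped with a message.
#'
#' @param path VCF path (plain or gzipped).
#' @return a [dosage_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("read_vcf_dosages: dropping ", sum(multi),
            " multi-allelic record(s)")
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
               sum(a == "1"), numeric(1)))
    }
    ds <- apply(gt, 2, count_alt)
    rownames(ds) <- rownames(gt)
  }
  d <- t(ds)
  vt <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]), a1 = fix[, "ALT"],
                   a2 = fix[, "REF"], stringsAsFactors = FALSE)
  no_id <- is.na(vt$id) | vt$id == "."
  vt$id[no_id] <- paste0(vt$chrom[no_id], ":", vt$pos[no_id])
  dosage_matrix(d, vt)
}

#' Write a weight table in PGS Catalog scoring format
#'
#' @param weights a `weight_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgs_weights <- function(weights, path) {
  out <- data.frame(rsID = weights$variant_id, chr_name = weights$chrom,
                    chr_position = weights$pos,
                    effect_allele = weights$effect_allele,
                    other_allele = weights$other_allele,
                    effect_weight = weights$weight)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#format=PGS Catalog scoring file-like", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phenotype/covariate and GWAS summary tables
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(cohort, path) {
  out <- cbind(cohort$covariates,
               status = cohort$status,
               population = as.character(cohort$population))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @param stats a GWAS summary-statistics data.frame
#'   (see [simulate_gwas_summary()]).
#' @export
write_gwas_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_gwas_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}
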