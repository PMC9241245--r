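# Shared fixtures: all data is generated in code, seeded for determinism.

two_pop_config <- function(...) {
  args <- list(n_populations = 2, fst = 0.1, n_variants = 400, n_causal = 40,
               liability_h2 = 0.3, prevalence = 0.10, n_samples = 300,
               seed = 101)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# write a small weight table file and return its path
write_weight_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "weights.tsv")
  writeLines(lines, path)
  path
}

# dosage matrix from explicit values (variants default to A/G at 1-based kb
# spaced positions on chr 1)
toy_dosages <- function(d, a1 = NULL, a2 = NULL, freq = NULL, pos = NULL,
                        chrom = NULL) {
  d <- as.matrix(d)
  m <- ncol(d)
  vt <- data.frame(id = paste0("snp", seq_len(m)),
                   chrom = if (is.null(chrom)) rep("1", m) else chrom,
                   pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                   a1 = if (is.null(a1)) rep("A", m) else a1,
                   a2 = if (is.null(a2)) rep("G", m) else a2,
                   stringsAsFactors = FALSE)
  dosage_matrix(d, vt, freq = freq)
}

# Hudson-style FST estimator (ratio of averages) from two genotype blocks
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1); n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
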