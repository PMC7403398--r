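# Independent oracles and fixture builders used across the suite.

# Brute-force conditional exact HWE p-value by direct factorial arithmetic
# (no log-space, no recurrence): weights n! 2^h / (n_mm! h! n_MM!) over all
# heterozygote counts with the observed parity, normalised by their sum.
hwe_oracle_p <- function(n_mm, n_het, n_MM, mode = "two_sided") {
  n <- n_mm + n_het + n_MM
  m <- 2 * n_mm + n_het
  if (m == 0 || m == 2 * n) return(1)
  h <- seq.int(m %% 2L, min(m, 2 * n - m), by = 2L)
  n_mm_h <- (m - h) / 2
  n_MM_h <- n - h - n_mm_h
  w <- factorial(n) * 2^h /
    (factorial(n_mm_h) * factorial(h) * factorial(n_MM_h))
  probs <- w / sum(w)
  i_obs <- match(n_het, h)
  if (mode == "two_sided") {
    min(1, sum(probs[probs <= probs[i_obs] * (1 + 1e-9)]))
  } else {
    min(1, sum(probs[h >= n_het]))
  }
}

# all (minor hom, het, major hom) tables for a given sample size n:
# minor-allele count m from 0..n, het count with the parity of m
all_hwe_tables <- function(n) {
  out <- list()
  for (m in 0:n) {
    for (h in seq.int(m %% 2L, min(m, 2 * n - m), by = 2L)) {
      n_mm <- (m - h) / 2
      out[[length(out) + 1]] <- c(n_mm, h, n - h - n_mm)
    }
  }
  out
}

# Grid-search oracle for the two-locus haplotype-frequency MLE. The MLE fixes
# the marginal allele frequencies at their sample values, leaving p11 as the
# single free parameter; the grid scans its admissible range at `step`
# resolution and returns every p11 within `tie_tol` log-likelihood of the
# maximum (the likelihood can have tied modes).
ld_grid_oracle <- function(gA, gB, step = 1e-4, tie_tol = 1e-9) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  f1 <- mean(gA) / 2; f2 <- mean(gB) / 2
  tab <- matrix(0, 3, 3)
  for (k in seq_along(gA))
    tab[gA[k] + 1L, gB[k] + 1L] <- tab[gA[k] + 1L, gB[k] + 1L] + 1
  lo <- max(0, f1 + f2 - 1); hi <- min(f1, f2)
  p11 <- unique(c(seq(lo, hi, by = step), hi))
  p00 <- (1 - f1) - (f2 - p11); p01 <- f2 - p11; p10 <- f1 - p11
  clamp <- function(x) pmax(x, 1e-300)
  ll <- tab[1, 1] * log(clamp(p00^2)) +
    tab[1, 2] * log(clamp(2 * p00 * p01)) +
    tab[1, 3] * log(clamp(p01^2)) +
    tab[2, 1] * log(clamp(2 * p00 * p10)) +
    tab[2, 2] * log(clamp(2 * p00 * p11 + 2 * p01 * p10)) +
    tab[2, 3] * log(clamp(2 * p01 * p11)) +
    tab[3, 1] * log(clamp(p10^2)) +
    tab[3, 2] * log(clamp(2 * p10 * p11)) +
    tab[3, 3] * log(clamp(p11^2))
  best <- max(ll)
  list(p11 = p11[ll >= best - tie_tol], loglik = best)
}

# all 3x3 two-locus genotype tables with total n, both loci polymorphic
all_two_locus_tables <- function(n) {
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(k)
      cbind(k, compositions(total - k, parts - 1))))
  }
  tabs <- compositions(n, 9)
  keep <- apply(tabs, 1, function(x) {
    tab <- matrix(x, 3, 3, byrow = TRUE)
    f1 <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * n)
    f2 <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * n)
    f1 > 0 && f1 < 1 && f2 > 0 && f2 < 1
  })
  lapply(which(keep), function(i) matrix(tabs[i, ], 3, 3, byrow = TRUE))
}

# expand a 3x3 genotype table into per-sample code vectors
table_to_genotypes <- function(tab) {
  gA <- integer(); gB <- integer()
  for (i in 1:3) for (j in 1:3) {
    gA <- c(gA, rep(i - 1L, tab[i, j]))
    gB <- c(gB, rep(j - 1L, tab[i, j]))
  }
  list(gA = gA, gB = gB)
}

# quick genotype_matrix from a calls matrix (samples x variants)
make_matrix <- function(calls, chrom = "1", pos = NULL, population = NULL) {
  nv <- ncol(calls)
  if (is.null(pos)) pos <- 1000L * seq_len(nv)
  if (length(chrom) == 1) chrom <- rep(chrom, nv)
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, id = sprintf("v%d", seq_len(nv)),
               allele_A = "A", allele_B = "C", stringsAsFactors = FALSE),
    sprintf("s%d", seq_len(nrow(calls))), calls, population)
}

# minimal VCF text fixture writer
write_vcf_fixture <- function(path, records, samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# the bundled published genotype counts for the two candidate SNPs
ly49b_counts <- function() {
  utils::read.table(system.file("extdata", "ly49b_genotype_counts.tsv",
                                package = "lethscan"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
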