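#' Configuration for the homozygote-deficit scan
#'
#' @param alpha significance level applied to q-values (default 0.05).
#' @param fdr_method "storey" (default) or "bh".
#' @param test_mode exact-test mode passed to \code{\link{hwe_exact_test}};
#'   "two_sided" mirrors the standard genotype-QC tool, "deficit" is the
#'   one-sided heterozygote-excess tail.
#' @param max_observed_minor_hom largest observed minor-homozygote count still
#'   compatible with the lethal hypothesis (default 0: strict absence).
#' @param min_block_size minimum run of adjacent flagged variants to keep as a
#'   candidate block (default 2; singletons are treated as possible calling
#'   errors).
#' @param maf_floor minimum minor-allele frequency for a variant to be tested
#'   (default 0.01); monomorphic and sub-floor variants get p = 1 and are
#'   never candidates.
#' @param max_gap_bp maximum base-pair gap between consecutive members of a
#'   block (default Inf: panel adjacency only).
#' @export
scan_config <- function(alpha = 0.05, fdr_method = c("storey", "bh"),
                        test_mode = c("two_sided", "deficit"),
                        max_observed_minor_hom = 0L, min_block_size = 2L,
                        maf_floor = 0.01, max_gap_bp = Inf) {
  fdr_method <- match.arg(fdr_method)
  test_mode <- match.arg(test_mode)
  stopifnot(alpha > 0, alpha < 1, min_block_size >= 2,
            max_observed_minor_hom >= 0, maf_floor >= 0, max_gap_bp > 0)
  structure(list(alpha = alpha, fdr_method = fdr_method,
                 test_mode = test_mode,
                 max_observed_minor_hom = as.integer(max_observed_minor_hom),
                 min_block_size = as.integer(min_block_size),
                 maf_floor = maf_floor, max_gap_bp = max_gap_bp),
            class = "scan_config")
}

#' Scan every variant for a Hardy-Weinberg deficit of minor homozygotes
#'
#' Per variant: genotype class counts over non-missing calls, minor-allele
#' frequency, expected minor homozygotes n*q^2, the conditional exact HWE
#' p-value, and an FDR q-value computed across all tested variants. A variant
#' is flagged as a candidate when its q-value is below \code{alpha} and its
#' observed minor-homozygote count is at most
#' \code{max_observed_minor_hom}.
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param config a \code{\link{scan_config}}.
#' @return data.frame, one row per variant in matrix order: chrom, pos, id,
#'   n_AA, n_AB, n_BB, n_missing, maf, expected_minor_hom,
#'   expected_minor_hom_rounded, observed_minor_hom, p_hwe, q_value, tested,
#'   flagged. Untested variants carry p_hwe = 1 and q_value = NA.
#' @export
scan_deficit <- function(matrix, config = scan_config()) {
  calls <- matrix$calls
  if (ncol(calls) == 0) stop("empty genotype matrix")
  n_AA <- colSums(calls == 0L, na.rm = TRUE)
  n_AB <- colSums(calls == 1L, na.rm = TRUE)
  n_BB <- colSums(calls == 2L, na.rm = TRUE)
  n_missing <- colSums(is.na(calls))
  n <- n_AA + n_AB + n_BB
  if (any(n == 0)) stop("variant with all calls missing: ",
                        matrix$variants$id[which(n == 0)[1]])
  f_B <- (2 * n_BB + n_AB) / (2 * n)
  maf <- pmin(f_B, 1 - f_B)
  minor_is_B <- f_B <= 0.5
  obs_minor <- ifelse(minor_is_B, n_BB, n_AA)
  e_minor <- n * maf^2
  tested <- maf >= config$maf_floor

  p <- rep(1, length(n))
  min_hom <- ifelse(minor_is_B, n_BB, n_AA)
  maj_hom <- ifelse(minor_is_B, n_AA, n_BB)
  for (j in which(tested))
    p[j] <- hwe_exact_p(min_hom[j], n_AB[j], maj_hom[j], config$test_mode)

  q <- rep(NA_real_, length(n))
  if (any(tested)) q[tested] <- fdr_adjust(p[tested], config$fdr_method)
  flagged <- tested & !is.na(q) & q < config$alpha &
    obs_minor <= config$max_observed_minor_hom

  data.frame(chrom = matrix$variants$chrom, pos = matrix$variants$pos,
             id = matrix$variants$id, n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
             n_missing = n_missing, maf = maf, expected_minor_hom = e_minor,
             expected_minor_hom_rounded = as.integer(round_half_away(e_minor)),
             observed_minor_hom = obs_minor, p_hwe = p, q_value = q,
             tested = tested, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster flagged variants into candidate blocks of adjacent markers
#'
#' A candidate block is a maximal run of flagged variants that are consecutive
#' in the tested panel's map order on one chromosome (an isolated flagged
#' marker is discarded as a possible calling error). Runs shorter than
#' \code{min_block_size} are dropped; an optional \code{max_gap_bp} splits
#' runs at large physical gaps.
#'
#' @param results the data.frame from \code{\link{scan_deficit}}, in matrix
#'   variant order.
#' @param config a \code{\link{scan_config}}.
#' @return data.frame of blocks: block_id, chrom, start_pos, end_pos, n_snps,
#'   span_bp, min_q_value, member_ids (comma-separated), member_idx
#'   (comma-separated row indices into \code{results}).
#' @export
cluster_adjacent <- function(results, config = scan_config()) {
  flagged <- results$flagged
  grp <- cumsum(c(TRUE, results$chrom[-1] != results$chrom[-nrow(results)] |
                    !flagged[-1] | !flagged[-nrow(results)] |
                    diff(results$pos) > config$max_gap_bp))
  blocks <- list()
  for (g in unique(grp[flagged])) {
    idx <- which(grp == g & flagged)
    if (length(idx) < config$min_block_size) next
    blocks[[length(blocks) + 1]] <- data.frame(
      chrom = results$chrom[idx[1]],
      start_pos = results$pos[idx[1]],
      end_pos = results$pos[idx[length(idx)]],
      n_snps = length(idx),
      span_bp = results$pos[idx[length(idx)]] - results$pos[idx[1]],
      min_q_value = min(results$q_value[idx]),
      member_ids = paste(results$id[idx], collapse = ","),
      member_idx = paste(idx, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0)
    return(data.frame(block_id = integer(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), span_bp = integer(),
                      min_q_value = numeric(), member_ids = character(),
                      member_idx = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  out <- cbind(block_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Per-population genotype summary at selected variants
#'
#' Reproduces the published summary-table layout: per population and variant,
#' observed genotype class counts, the rounded expected minor-homozygote count
#' under Hardy-Weinberg equilibrium, the exact-test p-value (raw, per
#' population), the heterozygote fraction as a whole-number percentage, and a
#' significance star at p < 0.05. Samples without a label are grouped as
#' "unassigned"; a population with no non-missing calls at a variant yields a
#' row with n = 0 and no test.
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param variant_indices column indices of the variants to summarise.
#' @param by optional named character vector of population labels (defaults to
#'   the matrix's own labels).
#' @return data.frame: population, chrom, pos, id, n, n_minor_hom, n_het,
#'   n_major_hom, n_missing, expected_minor_hom_rounded, p_hwe, het_pct,
#'   significant.
#' @export
population_summary <- function(matrix, variant_indices, by = NULL) {
  labels <- by %||% matrix$population
  if (is.null(labels))
    labels <- structure(rep("unassigned", length(matrix$samples)),
                        names = matrix$samples)
  lab <- labels[matrix$samples]
  lab[is.na(lab)] <- "unassigned"
  pops <- unique(lab)

  rows <- list()
  for (j in variant_indices) {
    v <- matrix$variants[j, ]
    for (p in pops) {
      g <- matrix$calls[lab == p, j]
      n_AA <- sum(g == 0L, na.rm = TRUE)
      n_AB <- sum(g == 1L, na.rm = TRUE)
      n_BB <- sum(g == 2L, na.rm = TRUE)
      n <- n_AA + n_AB + n_BB
      if (n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          population = p, chrom = v$chrom, pos = v$pos, id = v$id, n = 0L,
          n_minor_hom = NA_integer_, n_het = NA_integer_,
          n_major_hom = NA_integer_, n_missing = sum(is.na(g)),
          expected_minor_hom_rounded = NA_integer_, p_hwe = NA_real_,
          het_pct = NA_integer_, significant = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      st <- count_stats(n_AA, n_AB, n_BB)
      e <- expected_minor_homozygotes(c(st$obs_minor_hom, n_AB,
                                        n - n_AB - st$obs_minor_hom))
      pval <- hwe_exact_p(st$obs_minor_hom, n_AB,
                          n - n_AB - st$obs_minor_hom)
      rows[[length(rows) + 1]] <- data.frame(
        population = p, chrom = v$chrom, pos = v$pos, id = v$id, n = n,
        n_minor_hom = st$obs_minor_hom, n_het = n_AB,
        n_major_hom = n - n_AB - st$obs_minor_hom,
        n_missing = sum(is.na(g)),
        expected_minor_hom_rounded = e$rounded, p_hwe = pval,
        het_pct = as.integer(round_half_away(100 * n_AB / n)),
        significant = pval < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
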