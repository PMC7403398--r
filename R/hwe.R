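#' Tabulate genotype class counts at one variant
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param variant_index column index of the variant.
#' @param subset optional character vector of sample ids to restrict to.
#' @return List of class \code{genotype_counts} with fields \code{n_AA},
#'   \code{n_AB}, \code{n_BB} (copies of \code{allele_B}: 0, 1, 2) and
#'   \code{n_missing}. Counts cover non-missing calls only.
#' @export
genotype_counts <- function(matrix, variant_index, subset = NULL) {
  stopifnot(variant_index >= 1, variant_index <= ncol(matrix$calls))
  g <- matrix$calls[, variant_index]
  if (!is.null(subset)) {
    if (!all(subset %in% matrix$samples))
      stop("subset contains unknown sample ids")
    g <- g[match(subset, matrix$samples)]
  }
  cnt <- list(n_AA = sum(g == 0L, na.rm = TRUE),
              n_AB = sum(g == 1L, na.rm = TRUE),
              n_BB = sum(g == 2L, na.rm = TRUE),
              n_missing = sum(is.na(g)))
  if (cnt$n_AA + cnt$n_AB + cnt$n_BB == 0)
    stop("degenerate variant: all calls missing")
  class(cnt) <- "genotype_counts"
  cnt
}

# minor-allele frequency from genotype class counts; ties (q = 0.5) resolve
# so that allele_B is treated as minor
count_stats <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  f_B <- (2 * n_BB + n_AB) / (2 * n)
  minor_is_B <- f_B <= 0.5
  list(n = n,
       q = min(f_B, 1 - f_B),
       minor_is_B = minor_is_B,
       obs_minor_hom = if (minor_is_B) n_BB else n_AA,
       n_het = n_AB)
}

#' Expected minor-allele homozygotes under Hardy-Weinberg equilibrium
#'
#' Computes E = n * q^2 where q is the observed minor-allele frequency, the
#' expectation used to judge an absence of minor homozygotes. The rounded
#' value uses round-half-away-from-zero.
#'
#' @param counts a \code{genotype_counts} object, or a length-3 numeric vector
#'   (n_minor_hom, n_het, n_major_hom).
#' @return List with \code{expected} (real), \code{rounded} (integer),
#'   \code{q}, \code{n} and \code{observed_minor_hom}.
#' @export
expected_minor_homozygotes <- function(counts) {
  cc <- as_count_triple(counts)
  st <- count_stats(cc[3], cc[2], cc[1])  # (major hom, het, minor hom) as A/B
  e <- st$n * st$q^2
  list(expected = e, rounded = as.integer(round_half_away(e)),
       q = st$q, n = st$n, observed_minor_hom = st$obs_minor_hom)
}

# accept genotype_counts (allele_B-coded) or (minor hom, het, major hom) triple
as_count_triple <- function(counts) {
  if (inherits(counts, "genotype_counts")) {
    st <- count_stats(counts$n_AA, counts$n_AB, counts$n_BB)
    c(st$obs_minor_hom, counts$n_AB,
      counts$n_AA + counts$n_BB - st$obs_minor_hom)
  } else {
    stopifnot(is.numeric(counts), length(counts) == 3, all(counts >= 0))
    as.numeric(counts)
  }
}

#' Conditional exact Hardy-Weinberg test
#'
#' Exact test conditioning on the observed allele counts: all heterozygote
#' counts h with the parity of the minor-allele count are enumerated, each
#' table weighted proportionally to n! 2^h / (n_AA(h)! h! n_BB(h)!), computed
#' in log space. The two-sided p-value sums P(h') over tables no more probable
#' than the observed one; the "deficit" mode sums the heterozygote-excess tail
#' h' >= h_obs, the direction a recessive lethal pushes genotype frequencies.
#' A monomorphic table returns p = 1 by convention.
#'
#' @param counts a \code{genotype_counts} object or length-3 vector
#'   (n_minor_hom, n_het, n_major_hom).
#' @param mode "two_sided" (default) or "deficit".
#' @return The p-value.
#' @export
hwe_exact_test <- function(counts, mode = c("two_sided", "deficit")) {
  mode <- match.arg(mode)
  cc <- as_count_triple(counts)
  hwe_exact_p(cc[1], cc[2], cc[3], mode)
}

# scalar worker on (minor hom, het, major hom) counts
hwe_exact_p <- function(n_mm, n_het, n_MM, mode = "two_sided") {
  n <- n_mm + n_het + n_MM
  if (n < 1) stop("empty genotype table")
  m <- 2 * n_mm + n_het                     # minor allele count
  if (m == 0 || m == 2 * n) return(1)       # monomorphic
  h <- seq.int(m %% 2L, min(m, 2 * n - m), by = 2L)
  n_mm_h <- (m - h) / 2
  n_MM_h <- n - h - n_mm_h
  logw <- lfactorial(n) - lfactorial(n_mm_h) - lfactorial(h) -
    lfactorial(n_MM_h) + h * log(2)
  logp <- logw - logsumexp(logw)
  i_obs <- match(n_het, h)
  if (mode == "two_sided") {
    p <- sum(exp(logp[logp <= logp[i_obs] + 1e-10]))
  } else {
    p <- sum(exp(logp[h >= n_het]))
  }
  min(1, p)
}

#' Probability of zero minor homozygotes under Hardy-Weinberg equilibrium
#'
#' The binomial companion to the deficit scan: with minor-allele frequency q,
#' each of n individuals is a minor homozygote with probability q^2, so the
#' chance of observing none is (1 - q^2)^n.
#'
#' @param n number of genotyped individuals.
#' @param q minor-allele frequency in [0, 0.5].
#' @export
zero_homozygote_null_prob <- function(n, q) {
  stopifnot(n >= 1, q >= 0, q <= 0.5)
  (1 - q^2)^n
}
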