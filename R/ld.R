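#' Configuration for LD-based shortlisting of linked variants
#'
#' @param window_bp one-sided physical window around the index variant
#'   (default 5 Mb).
#' @param r2_min,dprime_min strict lower thresholds on r-squared (default
#'   0.8) and D-prime (default 0.9): a partner is shortlisted only when both
#'   statistics strictly exceed their thresholds.
#' @param maf_floor minimum partner minor-allele frequency (default 0.01).
#' @export
ld_config <- function(window_bp = 5e6, r2_min = 0.8, dprime_min = 0.9,
                      maf_floor = 0.01) {
  stopifnot(window_bp > 0, r2_min > 0, r2_min < 1, dprime_min > 0,
            dprime_min < 1, maf_floor >= 0)
  structure(list(window_bp = window_bp, r2_min = r2_min,
                 dprime_min = dprime_min, maf_floor = maf_floor),
            class = "ld_config")
}

#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Every genotype pair determines its two haplotypes except the double
#' heterozygote, whose coupling/repulsion phase is latent. The EM iterates
#' expected phase counts given the current haplotype frequencies until the
#' log-likelihood improves by less than 1e-10 (at most 1000 iterations),
#' renormalising every step. Because the likelihood in the double-heterozygote
#' count can have one mode at positive and one at negative D, the EM is run
#' from the product-of-marginals initialisation and from both endpoints of the
#' admissible p11 range, keeping the best log-likelihood.
#'
#' @param genoA,genoB integer genotype codes (0/1/2/NA, copies of allele_B)
#'   at the two loci, same sample order.
#' @return List: \code{hap_freqs} (named p00, p01, p10, p11, where the digits
#'   give copies of allele_B at locus A then B), \code{loglik},
#'   \code{n_used}, \code{n_iter}.
#' @export
estimate_haplotype_freqs_em <- function(genoA, genoB) {
  ok <- !is.na(genoA) & !is.na(genoB)
  gA <- genoA[ok]; gB <- genoB[ok]
  n <- length(gA)
  if (n < 2) stop("need at least 2 samples with both calls non-missing")
  f1 <- mean(gA) / 2; f2 <- mean(gB) / 2
  if (f1 %in% c(0, 1) || f2 %in% c(0, 1))
    stop("undefined LD: monomorphic locus among the jointly called samples")

  # 3x3 genotype table, rows = gA + 1, cols = gB + 1
  tab <- matrix(0, 3, 3)
  for (k in seq_len(n)) tab[gA[k] + 1L, gB[k] + 1L] <-
      tab[gA[k] + 1L, gB[k] + 1L] + 1

  # starts: product of marginals plus the two p11 extremes (D bounds)
  p11_starts <- unique(c(f1 * f2,
                         max(0, f1 + f2 - 1) + 1e-6,
                         min(f1, f2) - 1e-6))
  p11_starts <- p11_starts[p11_starts > max(0, f1 + f2 - 1) - 1e-12 &
                             p11_starts < min(f1, f2) + 1e-12]
  best <- NULL
  for (p11_0 in p11_starts) {
    fit <- hap_em_run(tab, n, f1, f2, p11_0)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
  }
  best$n_used <- n
  best
}

# one EM run from haplotype frequencies implied by (f1, f2, p11)
hap_em_run <- function(tab, n, f1, f2, p11) {
  p <- c(p00 = (1 - f1) - (f2 - p11), p01 = f2 - p11,
         p10 = f1 - p11, p11 = p11)
  p <- pmax(p, 1e-12); p <- p / sum(p)
  ll_old <- -Inf
  for (iter in seq_len(1000)) {
    d_coup <- p["p00"] * p["p11"]
    d_rep <- p["p01"] * p["p10"]
    w <- if (d_coup + d_rep > 0) unname(d_coup / (d_coup + d_rep)) else 0.5
    n_dh <- tab[2, 2]
    c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + w * n_dh
    c01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - w) * n_dh
    c10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2] + (1 - w) * n_dh
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * n_dh
    p <- c(p00 = c00, p01 = c01, p10 = c10, p11 = c11) / (2 * n)
    ll <- hap_loglik(tab, p)
    if (ll - ll_old < 1e-10) break
    ll_old <- ll
  }
  list(hap_freqs = p, loglik = ll, n_iter = iter)
}

# multinomial log-likelihood of the 3x3 genotype table given haplotype freqs
hap_loglik <- function(tab, p) {
  gp <- matrix(0, 3, 3)
  gp[1, 1] <- p["p00"]^2
  gp[1, 2] <- 2 * p["p00"] * p["p01"]
  gp[1, 3] <- p["p01"]^2
  gp[2, 1] <- 2 * p["p00"] * p["p10"]
  gp[2, 2] <- 2 * p["p00"] * p["p11"] + 2 * p["p01"] * p["p10"]
  gp[2, 3] <- 2 * p["p01"] * p["p11"]
  gp[3, 1] <- p["p10"]^2
  gp[3, 2] <- 2 * p["p10"] * p["p11"]
  gp[3, 3] <- p["p11"]^2
  sum(tab[tab > 0] * log(pmax(gp[tab > 0], 1e-300)))
}

#' Linkage disequilibrium between two variants of a genotype matrix
#'
#' D, D-prime and r-squared from EM-estimated haplotype frequencies over
#' samples with both calls non-missing. D = p11*p00 - p01*p10; D_max is
#' min(pA*pb, pa*pB) for positive D and min(pA*pB, pa*pb) for negative D;
#' D-prime is reported unsigned, with the D = 0 case defined as D-prime = 0.
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param i,j distinct variant column indices.
#' @return List of class \code{ld_stat}: index_variant, partner_variant,
#'   hap_freqs, D, D_prime, r2, n_used.
#' @export
compute_ld <- function(matrix, i, j) {
  stopifnot(i != j)
  em <- estimate_haplotype_freqs_em(matrix$calls[, i], matrix$calls[, j])
  p <- em$hap_freqs
  f1 <- unname(p["p10"] + p["p11"])
  f2 <- unname(p["p01"] + p["p11"])
  D <- unname(p["p11"] * p["p00"] - p["p01"] * p["p10"])
  denom <- f1 * (1 - f1) * f2 * (1 - f2)
  r2 <- if (denom > 0) D^2 / denom else 0
  if (abs(D) < 1e-12) {
    dprime <- 0
  } else {
    d_max <- if (D > 0) min(f1 * (1 - f2), (1 - f1) * f2)
             else min(f1 * f2, (1 - f1) * (1 - f2))
    dprime <- abs(D) / d_max
  }
  structure(list(index_variant = matrix$variants[i, ],
                 partner_variant = matrix$variants[j, ],
                 hap_freqs = p, D = D, D_prime = min(dprime, 1),
                 r2 = min(r2, 1), n_used = em$n_used, loglik = em$loglik),
            class = "ld_stat")
}

#' Shortlist variants linked to an index variant
#'
#' Scans all same-chromosome variants within \code{window_bp} of the index
#' variant, computes EM-based LD, and keeps partners with r2 strictly above
#' \code{r2_min} and D-prime strictly above \code{dprime_min}, sorted by
#' descending r2 (ties by position). Monomorphic or sub-MAF partners are
#' treated as not linked.
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param index variant index (integer) or "chrom:pos" / id string.
#' @param config an \code{\link{ld_config}}.
#' @return data.frame: chrom, pos, id, r2, dprime, p00, p01, p10, p11,
#'   n_used; zero rows when nothing is linked.
#' @export
shortlist_linked <- function(matrix, index, config = ld_config()) {
  i <- if (is.character(index)) variant_index(matrix, index) else as.integer(index)
  v <- matrix$variants
  cand <- which(v$chrom == v$chrom[i] &
                  abs(v$pos - v$pos[i]) <= config$window_bp &
                  seq_len(nrow(v)) != i)
  rows <- list()
  for (j in cand) {
    g <- matrix$calls[, j]
    fB <- mean(g, na.rm = TRUE) / 2
    if (is.na(fB) || min(fB, 1 - fB) < config$maf_floor) next
    ld <- tryCatch(compute_ld(matrix, i, j), error = function(e) NULL)
    if (is.null(ld)) next
    if (ld$r2 > config$r2_min && ld$D_prime > config$dprime_min)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = v$chrom[j], pos = v$pos[j], id = v$id[j],
        r2 = ld$r2, dprime = ld$D_prime,
        p00 = unname(ld$hap_freqs["p00"]), p01 = unname(ld$hap_freqs["p01"]),
        p10 = unname(ld$hap_freqs["p10"]), p11 = unname(ld$hap_freqs["p11"]),
        n_used = ld$n_used, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      r2 = numeric(), dprime = numeric(), p00 = numeric(),
                      p01 = numeric(), p10 = numeric(), p11 = numeric(),
                      n_used = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2, out$pos), ]
  rownames(out) <- NULL
  out
}
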