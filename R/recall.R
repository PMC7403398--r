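#' Construct an intensity panel for one variant
#'
#' Raw two-channel array intensities (x = allele-A channel, y = allele-B
#' channel) for every sample at one variant, the input to mixture-model
#' genotype re-calling.
#'
#' @param variant one-row data.frame as in \code{genotype_matrix$variants}.
#' @param samples character sample ids.
#' @param x,y non-negative finite intensities, one per sample.
#' @export
intensity_panel <- function(variant, samples, x, y) {
  stopifnot(length(samples) == length(x), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)),
            all(x >= 0), all(y >= 0))
  structure(list(variant = variant, samples = as.character(samples),
                 x = as.numeric(x), y = as.numeric(y)),
            class = "intensity_panel")
}

#' Project two-channel intensities onto the genotype contrast coordinate
#'
#' theta = (2/pi) * atan2(y, x), mapping pure channel-A signal to 0, pure
#' channel-B signal to 1 and the balanced heterozygote direction to 0.5.
#' Samples with x = y = 0 have no direction and are flagged unprojectable.
#'
#' @param panel an \code{\link{intensity_panel}}.
#' @return List: \code{theta} (NA where unprojectable), \code{projectable}
#'   logical vector.
#' @export
project_intensities <- function(panel) {
  zero <- panel$x == 0 & panel$y == 0
  if (all(zero)) stop("no projectable samples: all intensities zero")
  theta <- (2 / pi) * atan2(panel$y, panel$x)
  theta[zero] <- NA_real_
  list(theta = theta, projectable = !zero)
}

#' Fit a Gaussian mixture to projected genotype intensities
#'
#' For K = 1, 2, 3 a one-dimensional Gaussian mixture is fitted to the
#' contrast coordinate theta by EM (means initialised at K evenly spaced
#' quantiles of theta, with a seeded 1e-6-scale jitter when quantiles
#' coincide; variances floored at 1e-6; convergence when the log-likelihood
#' improves by less than 1e-8, at most 500 iterations). The K minimising BIC
#' is kept. Components are ordered by mean and mapped to genotype codes:
#' for K = 3 directly to 0/1/2; for K < 3 each component takes the code of
#' its nearest canonical cluster position in {0, 0.5, 1} (distinct codes
#' enforced greedily by proximity). A sample whose maximum posterior falls
#' below \code{call_threshold} is NO_CALL (NA).
#'
#' @param panel an \code{\link{intensity_panel}} with at least 10
#'   projectable samples.
#' @param seed integer seed for the tie-breaking jitter.
#' @param call_threshold minimum posterior for a call (default 0.95).
#' @return Object of class \code{mixture_fit}: K, weights, means, vars,
#'   loglik, ll_trace, bic (all K), assignments (genotype codes, NA =
#'   NO_CALL), posterior (max posterior per sample), call_threshold,
#'   projectable.
#' @export
fit_genotype_mixture <- function(panel, seed = 1, call_threshold = 0.95) {
  proj <- project_intensities(panel)
  theta <- proj$theta[proj$projectable]
  if (length(theta) < 10)
    stop("insufficient data: need >= 10 projectable samples, have ",
         length(theta))

  fits <- lapply(1:3, function(K) gmm1d_em(theta, K, seed))
  bic <- vapply(fits, function(f)
    -2 * f$loglik + (3 * f$K - 1) * log(length(theta)), 0)
  best <- fits[[which.min(bic)]]

  codes <- component_codes(best$means)
  resp <- gmm1d_resp(theta, best)
  comp <- max.col(resp)
  post <- resp[cbind(seq_along(theta), comp)]
  call <- codes[comp]
  call[post < call_threshold] <- NA_integer_

  assignments <- rep(NA_integer_, length(panel$samples))
  posterior <- rep(NA_real_, length(panel$samples))
  assignments[proj$projectable] <- call
  posterior[proj$projectable] <- post

  structure(list(K = best$K, weights = best$weights, means = best$means,
                 vars = best$vars, loglik = best$loglik,
                 ll_trace = best$ll_trace, bic = bic,
                 assignments = assignments, posterior = posterior,
                 call_threshold = call_threshold,
                 projectable = proj$projectable, samples = panel$samples),
            class = "mixture_fit")
}

# map ordered component means to distinct genotype codes via the canonical
# cluster positions {0, 0.5, 1} (codes 0, 1, 2); greedy nearest-first so a
# component pair straddling one true cluster cannot hijack a wrong label
component_codes <- function(means) {
  K <- length(means)
  canon <- c(0, 0.5, 1)
  codes <- rep(NA_integer_, K)
  taken <- logical(3)
  # assign in order of confidence (smallest distance first)
  d <- abs(outer(means, canon, "-"))
  for (step in seq_len(K)) {
    pick <- which(d == min(d[!is.na(d)]), arr.ind = TRUE)[1, ]
    codes[pick[1]] <- pick[2] - 1L
    d[pick[1], ] <- NA
    d[, pick[2]] <- NA
  }
  codes
}

# 1-D Gaussian mixture EM with quantile initialisation
gmm1d_em <- function(theta, K, seed, max_iter = 500, tol = 1e-8,
                     var_floor = 1e-6) {
  n <- length(theta)
  mu <- as.numeric(stats::quantile(theta, probs = (2 * seq_len(K) - 1) / (2 * K)))
  if (K > 1 && any(diff(mu) <= 0))
    mu <- with_seed(seed, sort(mu + 1e-6 * stats::rnorm(K)))
  v <- rep(max(stats::var(theta), var_floor), K)
  w <- rep(1 / K, K)
  ll_trace <- numeric()
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(theta, mu[k], sqrt(v[k])), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot == 0] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * theta) / nk
    v <- pmax(colSums(resp * outer(theta, mu, "-")^2) / nk, var_floor)
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  o <- order(mu)
  list(K = K, weights = w[o], means = mu[o], vars = v[o], loglik = ll,
       ll_trace = ll_trace, n_iter = iter)
}

# posterior responsibilities under a fitted mixture
gmm1d_resp <- function(theta, fit) {
  n <- length(theta)
  dens <- vapply(seq_len(fit$K), function(k)
    fit$weights[k] * stats::dnorm(theta, fit$means[k], sqrt(fit$vars[k])),
    numeric(n))
  dens <- matrix(dens, nrow = n)
  dens / pmax(rowSums(dens), 1e-300)
}

#' Re-call one variant's genotypes from raw intensities
#'
#' Replaces the variant's calls in the matrix with mixture-model calls from
#' the intensity panel (NO_CALL becomes missing) and reports every sample
#' whose call changed.
#'
#' @param matrix a \code{\link{genotype_matrix}}.
#' @param panel an \code{\link{intensity_panel}} whose variant is present in
#'   the matrix and whose samples are a subset of the matrix's samples.
#' @param seed integer seed forwarded to \code{\link{fit_genotype_mixture}}.
#' @param call_threshold minimum posterior for a call.
#' @return List: \code{matrix} (updated), \code{fit} (the mixture fit),
#'   \code{changes} data.frame (sample_id, old_call, new_call, posterior).
#' @export
recall_variant <- function(matrix, panel, seed = 1, call_threshold = 0.95) {
  j <- variant_index(matrix, paste0(panel$variant$chrom, ":",
                                    panel$variant$pos))
  if (!all(panel$samples %in% matrix$samples))
    stop("intensity panel references unknown sample id(s): ",
         paste(setdiff(panel$samples, matrix$samples), collapse = ", "))
  fit <- fit_genotype_mixture(panel, seed = seed,
                              call_threshold = call_threshold)
  rows <- match(panel$samples, matrix$samples)
  old <- matrix$calls[rows, j]
  new <- fit$assignments
  changed <- which(!(is.na(old) & is.na(new)) &
                     (is.na(old) != is.na(new) | old != new))
  changes <- data.frame(sample_id = panel$samples[changed],
                        old_call = old[changed], new_call = new[changed],
                        posterior = fit$posterior[changed],
                        stringsAsFactors = FALSE)
  matrix$calls[rows, j] <- new
  list(matrix = matrix, fit = fit, changes = changes)
}

#' Read a per-variant intensity TSV (sample_id, x, y)
#'
#' @param path TSV with header columns sample_id, x, y.
#' @param variant one-row variant data.frame to attach.
#' @return An \code{\link{intensity_panel}}.
#' @export
read_intensity_panel <- function(path, variant) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "x", "y") %in% names(tab)))
  intensity_panel(variant, tab$sample_id, tab$x, tab$y)
}
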