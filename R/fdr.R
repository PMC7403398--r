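#' False discovery rate adjustment of p-values
#'
#' Two estimators: \code{"bh"} is the Benjamini-Hochberg step-up (via
#' \code{\link[stats]{p.adjust}}), which assumes the null proportion pi0 = 1;
#' \code{"storey"} estimates pi0 from the p-value distribution on the lambda
#' grid 0.05, 0.10, ..., 0.95 with a cubic smoothing-spline extrapolation at
#' lambda -> 1 (falling back to the most conservative grid estimate if the
#' smoother cannot be fitted), clamps pi0 to (0, 1], and returns
#' q_i = pi0 * m * p_(i) / i with monotonicity enforced. Storey q-values may
#' be smaller than the corresponding p-values when pi0 < 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param method "bh" or "storey".
#' @return q-values in the input order.
#' @export
fdr_adjust <- function(p_values, method = c("storey", "bh")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  m <- length(p)
  pi0 <- storey_pi0(p)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Storey pi0: fraction of p-values above each lambda, scaled by 1/(1-lambda),
# smoothed and read off at the largest lambda.
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) min(pi0_l[lambda >= 0.5]))
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- max(min(pi0_l), 1 / m)  # degenerate smoother overshoot
  min(pi0, 1)
}
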