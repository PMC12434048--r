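#' Quantile-integral linear model (QUAIL) dispersion test
#'
#' Tests whether genotype shifts the spread of the residual distribution by
#' aggregating quantile-regression effects over the lower and upper halves
#' of the distribution.  For quantile level \eqn{\tau \in (0, 0.5)} let
#' \eqn{\beta_\tau} be the slope of the \eqn{\tau}-th quantile regression
#' of the residuals on allele count.  The estimand is the
#' quantile-integrated effect
#' \deqn{\beta_{QI} = \int_0^{0.5} (\beta_{1-\tau} - \beta_\tau)\, d\tau,}
#' positive when larger allele counts widen the distribution.  The
#' integral is estimated by a midpoint (rectangle) rule on a grid of K
#' equal bins of (0, 0.5): \eqn{\tau_k = k/(2K) - 1/(4K)}, each rectangle
#' having width \eqn{1/(2K)}.
#'
#' Inference uses the integrated rank-score construction rather than 2K
#' full quantile regressions: each sample receives the integrated score
#' \deqn{\eta_j = \frac{1}{K} \sum_k
#'   [\psi_{1-\tau_k}(e_j) - \psi_{\tau_k}(e_j)], \qquad
#'   \psi_\tau(e) = \tau - 1\{e \le \hat Q_\tau\},}
#' with \eqn{\hat Q_\tau} the lower (type-1) marginal sample quantile, and
#' the slope of the OLS regression of \eqn{\eta} on allele count is tested
#' two-sided.  The point estimate of \eqn{\beta_{QI}} from per-quantile
#' regressions is computed when `estimate_effect = TRUE` (the default);
#' disable it in large scans or simulation loops, where only the p-value
#' is needed, since it costs 2K quantile-regression fits per variant.
#'
#' Covariates are assumed to have been removed by [residualize()]; no
#' covariate terms are re-fitted inside the quantile regressions.
#'
#' @inheritParams dglm_test
#' @param K number of quantile rectangles (default 100, the convention for
#'   this estimator); must satisfy `2 <= K <= N`, and a warning is issued
#'   when `N < 10 K`.
#' @param estimate_effect logical; also compute the rectangle-sum point
#'   estimate of \eqn{\beta_{QI}} via per-quantile regressions.
#' @return a [`vqtl_result`][new_vqtl_result] with method tag `"QUAIL"`;
#'   `statistic` is the t statistic of the integrated rank-score slope and
#'   `effect` is \eqn{\hat\beta_{QI}} (or `NA` when not estimated).
#' @export
quail_test <- function(residuals, group = NULL, allele_count = NULL,
                       K = 100L, estimate_effect = TRUE) {
  if (inherits(residuals, "vqtl_residuals")) {
    e <- residuals$values
    grp <- residuals$group
  } else {
    e <- as.numeric(residuals)
    if (is.null(group)) stop("group is required for plain numeric input")
    grp <- group
  }
  x <- if (is.null(allele_count)) as.numeric(grp) else as.numeric(allele_count)
  n <- length(e)
  if (length(x) != n) stop("allele_count must align with residuals")
  if (K < 2L) stop("K must be at least 2")
  if (K > n) stop("K may not exceed the sample size")
  if (n < 10L * K)
    warning("sample size below 10*K; quantile grid may be unstable")
  if (stats::sd(x) == 0) stop("allele count is constant; QUAIL undefined")

  tau <- (seq_len(K)) / (2 * K) - 1 / (4 * K)   # midpoints of K bins of (0,.5)

  # integrated rank scores from lower (type-1) marginal sample quantiles
  es <- sort(e)
  qlo <- es[ceiling(n * tau)]
  qhi <- es[ceiling(n * (1 - tau))]
  psi <- numeric(n)
  for (k in seq_len(K)) {
    psi <- psi + ((1 - tau[k]) - (e <= qhi[k])) - (tau[k] - (e <= qlo[k]))
  }
  eta <- psi / K

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * eta) / sxx
  res <- eta - mean(eta) - slope * xc
  se <- sqrt(sum(res^2) / (n - 2L) / sxx)
  counts <- count_groups(grp)
  if (se == 0)
    return(new_vqtl_result("QUAIL", 0, n - 2L, 1, counts, degenerate = TRUE))
  tstat <- slope / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2L, lower.tail = FALSE)

  beta_qi <- NA_real_
  if (estimate_effect) beta_qi <- quail_beta_qi(e, x, tau)
  new_vqtl_result("QUAIL", tstat, n - 2L, p, counts,
                  effect = beta_qi, se = se)
}

# rectangle-sum estimate of the quantile-integrated effect from 2K
# per-quantile regression slopes
quail_beta_qi <- function(e, x, tau) {
  K <- length(tau)
  taus <- c(tau, 1 - tau)
  method <- if (length(e) > 5000L) "fn" else "br"
  fit <- suppressWarnings(
    quantreg::rq(e ~ x, tau = taus, method = method))
  slopes <- coef(fit)["x", ]
  sum(slopes[K + seq_len(K)] - slopes[seq_len(K)]) / (2 * K)
}
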