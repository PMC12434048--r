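#' One full pipeline replicate under a simulation scenario
#'
#' Draws both loci and the trait, residualizes the trait on the tested
#' locus (SNP1), forms the median deviations, and returns each requested
#' method's p-value.  Uses the current RNG state; the benchmark drivers
#' seed each replicate deterministically.
#'
#' @param scenario a [sim_scenario()].
#' @param methods subset of `c("KW","BF","DRM","DGLM","DGLM_INT","QUAIL")`.
#' @param quail_K quantile-grid size passed to [quail_test()].
#' @return named numeric vector of p-values (`NA` for a method that errors
#'   on that replicate).
#' @export
vqtl_replicate <- function(scenario,
                           methods = c("KW", "BF", "DRM", "DGLM",
                                       "DGLM_INT"),
                           quail_K = 100L) {
  methods <- match.arg(methods, c("KW", "BF", "DRM", "DGLM", "DGLM_INT",
                                  "QUAIL"), several.ok = TRUE)
  g1 <- simulate_genotypes(scenario$n_samples, scenario$maf1)
  g2 <- simulate_genotypes(scenario$n_samples, scenario$maf2)
  y <- simulate_trait(g1, g2, scenario)
  res <- residualize(y, g1)
  dev <- group_median_deviations(res)
  p <- stats::setNames(rep(NA_real_, length(methods)), methods)
  for (m in methods) {
    p[m] <- tryCatch(switch(m,
      KW       = kw_test(dev)$p_value,
      BF       = bf_test(dev)$p_value,
      DRM      = drm_test(dev)$p_value,
      DGLM     = dglm_test(res)$p_value,
      DGLM_INT = dglm_test(res, apply_int = TRUE)$p_value,
      QUAIL    = quail_test(res, K = quail_K,
                            estimate_effect = FALSE)$p_value),
      error = function(e) NA_real_)
  }
  p
}

run_benchmark <- function(scenario, methods, alpha, n_replicates, quail_K) {
  withr_seed <- scenario$seed
  set.seed(withr_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  pmat <- matrix(NA_real_, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    pmat[i, ] <- vqtl_replicate(scenario, methods, quail_K = quail_K)
  }
  out <- lapply(methods, function(m) {
    p <- pmat[, m]
    n_failed <- sum(is.na(p))
    n_ok <- n_replicates - n_failed
    est <- if (n_ok > 0) mean(p[!is.na(p)] < alpha) else NA_real_
    data.frame(method = m, alpha = alpha, estimate = est,
               mc_se = sqrt(est * (1 - est) / n_ok),
               n_replicates = n_replicates, n_failed = n_failed,
               n_samples = scenario$n_samples, maf1 = scenario$maf1,
               maf2 = scenario$maf2, beta1 = scenario$beta1,
               beta2 = scenario$beta2, beta_int = scenario$beta_int,
               error_dist = scenario$error_dist, seed = scenario$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "p_values") <- pmat
  out
}

#' Estimate the false-positive rate of vQTL tests under a null scenario
#'
#' Runs the full simulate-residualize-test pipeline for `n_replicates`
#' independent replicates of a null scenario (`beta_int = 0`) and reports,
#' per method, the fraction of p-values below `alpha` with its binomial
#' Monte Carlo standard error.  Replicate seeds are derived
#' deterministically from the scenario seed, so results are bit-identical
#' on re-run and invariant to any replicate-level parallel scheduling.
#' Replicates on which a method fails are counted in `n_failed`, never
#' silently dropped.
#'
#' @inheritParams vqtl_replicate
#' @param alpha nominal significance level (default 0.05).
#' @param n_replicates number of Monte Carlo replicates (default: the
#'   scenario's `n_replicates`).
#' @return data frame, one row per method: `method, alpha, estimate,
#'   mc_se, n_replicates, n_failed` plus the scenario fields; the matrix
#'   of per-replicate p-values is attached as attribute `"p_values"` (for
#'   QQ diagnostics via [qq_points()]).
#' @export
estimate_fpr <- function(scenario,
                         methods = c("KW", "BF", "DRM", "DGLM",
                                     "DGLM_INT"),
                         alpha = 0.05, n_replicates = NULL,
                         quail_K = 100L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$beta_int != 0)
    stop("estimate_fpr requires a null scenario (beta_int = 0); ",
         "use estimate_power for beta_int != 0")
  if (is.null(n_replicates)) n_replicates <- scenario$n_replicates
  run_benchmark(scenario, methods, alpha, n_replicates, quail_K)
}

#' Estimate the power of vQTL tests under an interaction scenario
#'
#' Same Monte Carlo engine as [estimate_fpr()] but intended for scenarios
#' with `beta_int != 0`: the estimate is the fraction of replicates in
#' which the hidden interaction is detected at level `alpha`.  Passing a
#' null scenario is allowed (power then equals the size).  At desk scale,
#' use a larger `alpha` (e.g. 1e-3) and a smaller cohort than a
#' genome-wide study's 5e-8 threshold.
#'
#' @inheritParams estimate_fpr
#' @param alpha rejection threshold (default 1e-3, a desk-scale stand-in
#'   for genome-wide 5e-8).
#' @return as [estimate_fpr()].
#' @export
estimate_power <- function(scenario,
                           methods = c("KW", "BF", "DRM", "DGLM",
                                       "DGLM_INT"),
                           alpha = 1e-3, n_replicates = NULL,
                           quail_K = 100L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(n_replicates)) n_replicates <- scenario$n_replicates
  run_benchmark(scenario, methods, alpha, n_replicates, quail_K)
}

#' Expected-vs-observed points for a QQ plot of p-values
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return data frame with columns `expected` and `observed`
#'   (\eqn{-\log_{10}} scale, aligned by ascending p), with attribute
#'   `"lambda"`: the genomic-inflation-style slope, the ratio of the median
#'   observed chi-square (1 df) quantile to its null median.
#' @export
qq_points <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(p)
  ps <- sort(p)
  out <- data.frame(expected = -log10(seq_len(n) / (n + 1)),
                    observed = -log10(ps))
  attr(out, "lambda") <- stats::median(stats::qchisq(p, 1,
                                                     lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
  out
}
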