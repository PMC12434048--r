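#' Define a simulation scenario
#'
#' Bundles the parameters of one cell of the two-locus interaction design
#' used for calibration and power studies.  Traits are generated as
#' \deqn{Y_j = \beta_1 SNP_{1,j} + \beta_2 SNP_{2,j} +
#'       \beta_{INT} SNP_{1,j} \times SNP_{2,j} + \varepsilon_j,}
#' with both loci drawn under Hardy-Weinberg equilibrium at the given
#' minor-allele frequencies and the error z-scored per replicate (see
#' [simulate_trait()]).  With \eqn{\beta_{INT} \ne 0} and the interaction
#' partner unobserved, SNP1 is a variance QTL: its genotype groups differ
#' in trait variance.
#'
#' @param n_samples cohort size per replicate.
#' @param maf1,maf2 minor-allele frequencies of the tested locus (SNP1) and
#'   its hidden partner (SNP2), in (0, 0.5].
#' @param beta1,beta2 additive main effects (defaults 0; the paired study
#'   condition sets both to 0.3).
#' @param beta_int interaction coefficient; 0 for null (false-positive
#'   rate) scenarios, 0.3 in the reference power scenarios.
#' @param error_dist error law: `"normal"` (standard normal), `"t3"`
#'   (Student t, 3 df — kurtotic) or `"chisq6"` (chi-square, 6 df — skewed).
#' @param seed master RNG seed for the scenario.
#' @param n_replicates number of Monte Carlo replicates.
#' @return a `sim_scenario` object (validated list of the above).
#' @export
sim_scenario <- function(n_samples, maf1 = 0.3, maf2 = 0.3,
                         beta1 = 0, beta2 = 0, beta_int = 0,
                         error_dist = c("normal", "t3", "chisq6"),
                         seed = 1L, n_replicates = 1L) {
  error_dist <- match.arg(error_dist)
  stopifnot(n_samples >= 3, n_replicates >= 1,
            maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5)
  if (n_samples < 100)
    warning("n_samples < 100: distributional summaries will be unstable")
  structure(list(n_samples = as.integer(n_samples), maf1 = maf1,
                 maf2 = maf2, beta1 = beta1, beta2 = beta2,
                 beta_int = beta_int, error_dist = error_dist,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: N=%d, MAF=(%.2g, %.2g), beta=(%.2g, %.2g), betaINT=%.2g,\n  errors=%s, seed=%d, replicates=%d\n",
    x$n_samples, x$maf1, x$maf2, x$beta1, x$beta2, x$beta_int,
    x$error_dist, x$seed, x$n_replicates))
  invisible(x)
}

#' Simulate biallelic hard-call genotypes
#'
#' Draws independent minor-allele counts from Binomial(2, maf), i.e.
#' Hardy-Weinberg equilibrium under random mating.
#'
#' @param n number of samples.
#' @param maf minor-allele frequency in (0, 0.5].
#' @return integer vector of 0/1/2 calls with attribute `"maf"` holding the
#'   realised (sample) minor-allele frequency.
#' @export
simulate_genotypes <- function(n, maf) {
  stopifnot(n >= 1, maf > 0, maf <= 0.5)
  g <- stats::rbinom(n, 2L, maf)
  attr(g, "maf") <- mean(g) / 2
  g
}

#' Simulate a trait with a two-locus interaction
#'
#' Generates \eqn{Y_j = \beta_1 g_{1j} + \beta_2 g_{2j} + \beta_{INT}
#' g_{1j} g_{2j} + \varepsilon_j}.  The error is drawn from the scenario's
#' error law and then z-scored (sample mean 0, sample SD 1, n-1
#' denominator) per replicate, so the fraction of trait variance explained
#' by the genetic terms is comparable across error laws; shape features
#' (skewness, kurtosis) are unaffected by this affine standardisation.
#'
#' @param g1,g2 genotype vectors from [simulate_genotypes()].
#' @param scenario a [sim_scenario()] supplying the coefficients and error
#'   law (its `n_samples` must match `length(g1)`).
#' @return numeric phenotype vector.
#' @export
simulate_trait <- function(g1, g2, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"),
            length(g1) == length(g2),
            length(g1) == scenario$n_samples)
  n <- scenario$n_samples
  eps <- switch(scenario$error_dist,
                normal = stats::rnorm(n),
                t3     = stats::rt(n, df = 3),
                chisq6 = stats::rchisq(n, df = 6))
  eps <- (eps - mean(eps)) / stats::sd(eps)
  scenario$beta1 * g1 + scenario$beta2 * g2 +
    scenario$beta_int * g1 * g2 + eps
}
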