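#' Covariate- and main-effect-adjusted residuals
#'
#' Regresses a continuous trait on two genotype-group indicator variables
#' (heterozygote and minor-homozygote) plus any covariates, and returns the
#' ordinary-least-squares residuals together with the genotype group of each
#' retained sample.  Removing the variant's own mean (main) effect and the
#' covariate effects first ensures that downstream dispersion tests are not
#' confounded by mean differences between genotype groups.
#'
#' Samples with a missing phenotype, genotype or covariate value are dropped
#' listwise before fitting.  Genotypes must be hard calls in \{0, 1, 2\};
#' non-integer dosages are rejected because the group medians used by the
#' dispersion statistics are undefined for fractional allele counts.
#'
#' @param phenotype numeric vector, one trait value per sample.
#' @param genotype integer-valued vector of minor-allele counts (0, 1, 2 or
#'   `NA`), aligned with `phenotype`.
#' @param covariates optional numeric matrix or data frame of covariates
#'   (one row per sample).  An intercept is always added; do not include one.
#' @param sample_ids optional identifiers carried through to the result.
#'
#' @return An object of class `vqtl_residuals`: a list with elements
#'   `values` (residuals, mean zero), `group` (allele count 0/1/2 per
#'   retained sample), `sample_ids`, and `n_dropped` (samples removed by
#'   listwise deletion).
#'
#' @examples
#' g <- rep(0:2, each = 20)
#' y <- 0.5 * g + rnorm(60)
#' r <- residualize(y, g)
#' tapply(r$values, r$group, mean)   # all ~0: main effect removed
#' @export
residualize <- function(phenotype, genotype, covariates = NULL,
                        sample_ids = NULL) {
  phenotype <- as.numeric(phenotype)
  n <- length(phenotype)
  if (length(genotype) != n)
    stop("phenotype and genotype must have the same length")
  check_hard_calls(genotype)
  genotype <- as.integer(round(genotype))

  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("covariates must have one row per sample")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))

  keep <- is.finite(phenotype) & !is.na(genotype)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- phenotype[keep]
  g <- genotype[keep]
  if (length(y) < 3L)
    stop("fewer than 3 complete samples after listwise deletion")
  if (length(unique(g)) < 2L)
    stop("genotype is monomorphic after listwise deletion; no test can run")

  # Design: intercept + genotype-group indicators + covariates.  Indicators
  # for absent genotype groups simply never arise (treatment coding of the
  # groups actually present), so monomorphic-in-part variants still fit.
  X <- stats::model.matrix(~ factor(g))
  if (!is.null(covariates)) {
    Z <- covariates[keep, , drop = FALSE]
    check_covariate_rank(X, Z)
    X <- cbind(X, Z)
  }

  fit <- stats::lm.fit(X, y)
  structure(
    list(values = unname(fit$residuals), group = g,
         sample_ids = sample_ids[keep], n_dropped = sum(!keep)),
    class = "vqtl_residuals")
}

# Error with the offending column named when adding covariates breaks full
# column rank of the design.
check_covariate_rank <- function(X, Z) {
  qr0 <- qr(X)
  for (j in seq_len(ncol(Z))) {
    qr1 <- qr(cbind(X, Z[, seq_len(j), drop = FALSE]))
    if (qr1$rank < qr0$rank + j)
      stop("covariate '", colnames(Z)[j],
           "' is collinear with the design (constant or a linear ",
           "combination of earlier columns)")
  }
  invisible(TRUE)
}

check_hard_calls <- function(genotype) {
  ok <- is.na(genotype) | (genotype %in% c(0, 1, 2))
  if (!all(ok))
    stop("genotype must contain hard calls 0/1/2 (or NA); ",
         "dosage input is not supported")
  invisible(TRUE)
}

#' Absolute deviations from genotype-group medians
#'
#' Converts covariate-adjusted residuals into the dispersion measure used by
#' the Kruskal-Wallis, Brown-Forsythe and deviation-regression tests: the
#' absolute deviation of each residual from the median of its genotype
#' group, \eqn{D_{ij} = |e_{ij} - \tilde e_i|}.  Absolute (rather than
#' signed) deviations are used so that the downstream location tests respond
#' to spread, not to mean shifts.
#'
#' @param residuals a `vqtl_residuals` object from [residualize()], or a
#'   plain numeric vector if `group` is supplied.
#' @param group genotype group per sample (ignored when `residuals` is a
#'   `vqtl_residuals`).
#'
#' @return An object of class `vqtl_deviations`: list with `values`
#'   (absolute deviations) and `group`.
#' @export
group_median_deviations <- function(residuals, group = NULL) {
  if (inherits(residuals, "vqtl_residuals")) {
    e <- residuals$values
    group <- residuals$group
  } else {
    e <- as.numeric(residuals)
    if (is.null(group)) stop("group is required for plain numeric input")
  }
  if (length(e) == 0L) stop("empty input")
  if (length(group) != length(e)) stop("group must align with residuals")
  med <- stats::ave(e, group, FUN = stats::median)
  structure(list(values = abs(e - med), group = group),
            class = "vqtl_deviations")
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles through their ranks using the Blom
#' offset: \eqn{\Phi^{-1}((r - 3/8) / (N + 1/4))}, with average ranks for
#' ties.  Used by the `DGLM_INT` test variant to normalise heavy-tailed
#' residuals before the dispersion model is fitted.
#'
#' @param values numeric vector, length at least 2, not all equal.
#' @return numeric vector of normal scores, monotone in the input.
#' @export
inverse_normal_transform <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (length(unique(values)) == 1L)
    stop("all values equal: ranks are degenerate")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.375) / (n + 0.25))
}
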