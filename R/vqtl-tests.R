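#' @title vQTL test result container
#' @description Internal constructor for the per-variant test result shared
#'   by all five methods.
#' @keywords internal
new_vqtl_result <- function(method, statistic, df, p_value, group_counts,
                            effect = NA_real_, se = NA_real_,
                            degenerate = FALSE) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, group_counts = group_counts,
         effect = effect, se = se, degenerate = degenerate),
    class = "vqtl_result")
}

#' @export
print.vqtl_result <- function(x, ...) {
  cat(sprintf("vQTL test: %s\n", x$method))
  cat(sprintf("  statistic = %.6g on df = %s\n",
              x$statistic, paste(x$df, collapse = ", ")))
  if (!is.na(x$effect))
    cat(sprintf("  effect    = %.6g (se %.4g)\n", x$effect, x$se))
  cat(sprintf("  p-value   = %.4g\n", x$p_value))
  cat(sprintf("  group n   = %s\n",
              paste(names(x$group_counts), x$group_counts,
                    sep = "=", collapse = " ")))
  if (isTRUE(x$degenerate)) cat("  (degenerate input)\n")
  invisible(x)
}

# allele-count group table padded to 0/1/2
count_groups <- function(group) {
  tab <- table(factor(group, levels = 0:2))
  stats::setNames(as.integer(tab), c("n0", "n1", "n2"))
}

#' Kruskal-Wallis dispersion test
#'
#' Rank-based test of variance heterogeneity across genotype groups.  The
#' absolute median deviations are ranked jointly across all individuals
#' (average ranks for ties), and the statistic
#' \deqn{KW = (N-1)\,\frac{\sum_i n_i (\bar r_{i.} - \bar r)^2}
#'                       {\sum_i \sum_j (r_{ij} - \bar r)^2}}
#' is referred to a chi-square distribution with \eqn{M - 1} degrees of
#' freedom, where \eqn{M} is the number of genotype groups present.  Ties
#' need no separate correction factor: the denominator is computed from the
#' realised (average) ranks.
#'
#' @param deviations a `vqtl_deviations` object from
#'   [group_median_deviations()], or a numeric vector with `group`.
#' @param group genotype group per sample (for plain numeric input).
#' @return a [`vqtl_result`][new_vqtl_result] with method tag `"KW"`.
#' @export
kw_test <- function(deviations, group = NULL) {
  d <- unpack_deviations(deviations, group)
  grp <- d$group; D <- d$values
  groups <- sort(unique(grp))
  M <- length(groups)
  N <- length(D)
  if (M < 2L) stop("need at least 2 non-empty genotype groups")
  if (N < M + 1L) stop("need N >= M + 1 samples")
  counts <- count_groups(grp)
  if (length(unique(D)) == 1L)
    return(new_vqtl_result("KW", NA_real_, M - 1L, 1, counts,
                           degenerate = TRUE))
  r <- rank(D, ties.method = "average")
  rbar <- (N + 1) / 2
  ri <- tapply(r, grp, mean)
  ni <- tapply(r, grp, length)
  stat <- (N - 1) * sum(ni * (ri - rbar)^2) / sum((r - rbar)^2)
  p <- stats::pchisq(stat, df = M - 1L, lower.tail = FALSE)
  new_vqtl_result("KW", stat, M - 1L, p, counts)
}

#' Brown-Forsythe dispersion test
#'
#' One-way F test on the absolute median deviations:
#' \deqn{BF = \frac{\sum_i n_i (\bar D_{i.} - \bar D)^2 / (M-1)}
#'                 {\sum_i \sum_j (D_{ij} - \bar D_{i.})^2 / (N-M)}}
#' referred to an F distribution on \eqn{(M-1,\; N-M)} degrees of freedom.
#' Equivalent to the ANOVA F test of the deviations on genotype-group
#' indicator variables, i.e. genotype treated as categorical.  More robust
#' to outliers than the classical Levene test because deviations are taken
#' from group medians rather than means.
#'
#' @inheritParams kw_test
#' @return a [`vqtl_result`][new_vqtl_result] with method tag `"BF"` and a
#'   two-element `df` (numerator, denominator).
#' @export
bf_test <- function(deviations, group = NULL) {
  d <- unpack_deviations(deviations, group)
  grp <- d$group; D <- d$values
  groups <- sort(unique(grp))
  M <- length(groups)
  N <- length(D)
  if (M < 2L) stop("need at least 2 non-empty genotype groups")
  if (N <= M) stop("need N > M samples")
  counts <- count_groups(grp)
  Dbar <- mean(D)
  Di <- tapply(D, grp, mean)
  ni <- tapply(D, grp, length)
  ss_between <- sum(ni * (Di - Dbar)^2)
  ss_within <- sum((D - Di[as.character(grp)])^2)
  df <- c(M - 1L, N - M)
  if (ss_within <= 0) {
    if (ss_between <= 0)
      return(new_vqtl_result("BF", NA_real_, df, 1, counts,
                             degenerate = TRUE))
    return(new_vqtl_result("BF", Inf, df, 0, counts, degenerate = TRUE))
  }
  stat <- (ss_between / df[1L]) / (ss_within / df[2L])
  p <- stats::pf(stat, df[1L], df[2L], lower.tail = FALSE)
  new_vqtl_result("BF", stat, df, p, counts)
}

#' Deviation regression model (DRM) test
#'
#' Regresses the absolute median deviations on the minor-allele count
#' (0, 1, 2) treated as a continuous predictor, \eqn{D_{ij} = \alpha +
#' \beta (i-1) + \varepsilon_j}, and tests \eqn{H_0: \beta = 0} with a
#' two-sided t test on \eqn{N - 2} degrees of freedom.  Treating genotype
#' as continuous avoids the sparsity problems of per-group statistics at
#' low minor-allele frequency.
#'
#' @inheritParams kw_test
#' @param allele_count optional predictor overriding the group index
#'   carried by `deviations`.
#' @return a [`vqtl_result`][new_vqtl_result] with method tag `"DRM"`;
#'   `effect` is the slope \eqn{\hat\beta}.
#' @export
drm_test <- function(deviations, group = NULL, allele_count = NULL) {
  d <- unpack_deviations(deviations, group)
  D <- d$values
  x <- if (is.null(allele_count)) as.numeric(d$group) else
    as.numeric(allele_count)
  if (length(x) != length(D)) stop("allele_count must align with deviations")
  if (stats::sd(x) == 0) stop("allele count is constant; DRM undefined")
  N <- length(D)
  counts <- count_groups(d$group)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (D - mean(D))) / sxx
  alpha <- mean(D) - beta * mean(x)
  rss <- sum((D - alpha - beta * x)^2)
  if (rss <= 0) {
    degen_p <- if (beta == 0) 1 else 0
    return(new_vqtl_result("DRM", if (beta == 0) 0 else Inf,
                           N - 2L, degen_p, counts, effect = beta,
                           se = 0, degenerate = TRUE))
  }
  se <- sqrt(rss / (N - 2L) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = N - 2L, lower.tail = FALSE)
  new_vqtl_result("DRM", tstat, N - 2L, p, counts, effect = beta, se = se)
}

unpack_deviations <- function(deviations, group) {
  if (inherits(deviations, "vqtl_deviations")) return(deviations)
  if (is.null(group)) stop("group is required for plain numeric input")
  list(values = as.numeric(deviations), group = group)
}
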