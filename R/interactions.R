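#' Greedy linkage-disequilibrium clumping of scan hits
#'
#' Reduces a table of tested variants to approximately independent lead
#' variants: variants are visited in order of increasing p-value (ties
#' broken by variant id, lexicographically) and a variant is kept iff its
#' p-value is below `p_threshold` and its squared Pearson correlation of
#' allele counts with every already-kept variant is below `r2_threshold`.
#' A deliberately minimal re-statement of the usual clumping step: no
#' physical window, no secondary threshold — vQTL hit lists are short.
#'
#' @param results data frame with at least columns `id` and `p`.
#' @param genotypes numeric matrix of allele counts, samples x variants,
#'   with variant ids as column names (missing calls as `NA`).
#' @param p_threshold keep threshold on p (default genome-wide 5e-8).
#' @param r2_threshold pairwise r-squared ceiling (default 0.01).
#' @return character vector of lead-variant ids, in order of selection.
#' @export
clump <- function(results, genotypes, p_threshold = 5e-8,
                  r2_threshold = 0.01) {
  stopifnot(is.data.frame(results), all(c("id", "p") %in% names(results)))
  hits <- results[!is.na(results$p) & results$p < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  missing_g <- setdiff(hits$id, colnames(genotypes))
  if (length(missing_g))
    stop("no genotype column for variant(s): ",
         paste(missing_g, collapse = ", "))
  hits <- hits[order(hits$p, hits$id), , drop = FALSE]
  kept <- character(0)
  for (v in hits$id) {
    if (length(kept) == 0L) {
      kept <- v
      next
    }
    r2 <- suppressWarnings(
      stats::cor(genotypes[, v], genotypes[, kept, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    if (all(r2 < r2_threshold, na.rm = TRUE)) kept <- c(kept, v)
  }
  kept
}

#' Direct gene-environment interaction scan
#'
#' For every (vQTL, environment) pair, fits the ordinary least-squares
#' model: trait ~ allele count + all environmental factors + ancestry PCs
#' + allele count x the one environment under test, preserving the
#' hierarchy between main and interaction terms.  The raw trait (not the
#' pre-test residual) is the response, with adjustment inside the model.
#' The interaction coefficient gets a two-sided t test, and
#' `signed_log10p` = sign(beta_int * beta_g) * -log10(p): positive when
#' the environment exacerbates (pushes further from zero) the genetic
#' effect, negative when it attenuates it.
#'
#' @param phenotype numeric trait vector.
#' @param vqtls samples x vQTLs allele-count matrix with variant-id
#'   column names.
#' @param environments data frame / matrix of environmental factors (one
#'   column per E, named); all enter every model as main effects.
#' @param pcs optional matrix of ancestry principal components (adjusted
#'   as plain covariates).
#' @return data frame, one row per (vQTL, E) pair: `vqtl, partner, beta_g,
#'   beta_partner, beta_int, se_int, p_int, signed_log10p, n`.
#'   Constant-environment pairs are dropped with a warning.
#' @export
gxe_scan <- function(phenotype, vqtls, environments, pcs = NULL) {
  vqtls <- as.matrix(vqtls)
  environments <- as.data.frame(environments)
  if (is.null(colnames(vqtls)))
    colnames(vqtls) <- paste0("V", seq_len(ncol(vqtls)))
  e_names <- colnames(environments)
  const_e <- vapply(environments,
                    function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const_e)) {
    warning("dropping constant environment(s): ",
            paste(e_names[const_e], collapse = ", "))
    environments <- environments[, !const_e, drop = FALSE]
    e_names <- colnames(environments)
  }
  out <- list()
  for (v in colnames(vqtls)) {
    for (e in e_names) {
      out[[paste(v, e)]] <- interaction_fit(
        phenotype, g = vqtls[, v], partner = environments[[e]],
        mains = environments, pcs = pcs, vqtl = v, partner_name = e)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Direct gene-gene interaction scan
#'
#' For every unordered pair of vQTLs, fits trait ~ count(A) + count(B) +
#' environmental main effects + ancestry PCs + count(A) x count(B) and
#' tests the product coefficient (the product term takes values 0, 1, 2,
#' 4).  Sign convention for `signed_log10p` as in [gxe_scan()], using the
#' first variant's main effect.
#'
#' @inheritParams gxe_scan
#' @return data frame, one row per pair (C(V, 2) rows): columns as in
#'   [gxe_scan()] with `vqtl` and `partner` holding the two variant ids.
#' @export
gxg_scan <- function(phenotype, vqtls, environments = NULL, pcs = NULL) {
  vqtls <- as.matrix(vqtls)
  if (is.null(colnames(vqtls)))
    colnames(vqtls) <- paste0("V", seq_len(ncol(vqtls)))
  ids <- colnames(vqtls)
  if (length(ids) < 2L) stop("need at least two vQTLs")
  pairs <- utils::combn(ids, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    out[[k]] <- interaction_fit(
      phenotype, g = vqtls[, a], partner = vqtls[, b],
      mains = environments, pcs = pcs, vqtl = a, partner_name = b)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# shared OLS engine for one interaction fit
interaction_fit <- function(phenotype, g, partner, mains, pcs,
                            vqtl, partner_name) {
  X <- cbind(g = as.numeric(g))
  if (!is.null(mains)) {
    M <- as.matrix(as.data.frame(mains))
    storage.mode(M) <- "double"
    X <- cbind(X, M)
  }
  # the partner must be a main effect even when `mains` omits it (GxG)
  if (!partner_name %in% colnames(X))
    X <- cbind(X, stats::setNames(data.frame(as.numeric(partner)),
                                  partner_name))
  X <- as.matrix(X)
  X <- cbind(X, int = as.numeric(g) * as.numeric(partner))
  if (!is.null(pcs)) {
    P <- as.matrix(pcs)
    colnames(P) <- paste0("PC", seq_len(ncol(P)))
    X <- cbind(X, P)
  }
  y <- as.numeric(phenotype)
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  y <- y[keep]
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dfres <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                               drop = FALSE])
  se_all <- sqrt(diag(XtXinv) * rss / dfres)
  names(se_all) <- colnames(X)[fit$qr$pivot[seq_len(fit$rank)]]
  b_int <- cf[["int"]]; se_int <- se_all[["int"]]
  tstat <- b_int / se_int
  p <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
  b_g <- cf[["g"]]
  data.frame(vqtl = vqtl, partner = partner_name,
             beta_g = b_g,
             beta_partner = cf[[partner_name]],
             beta_int = b_int, se_int = se_int, p_int = p,
             signed_log10p = sign(b_int * b_g) * -log10(p),
             n = length(y), stringsAsFactors = FALSE)
}

#' Pivot interaction fits into a signed -log10(p) matrix
#'
#' Rows are vQTL ids, columns the interaction partners (environments or
#' vQTLs); cells hold `signed_log10p`.  For gene-gene fits the matrix is
#' made symmetric with zeros on the diagonal.  Suitable for external
#' heat-map rendering.
#'
#' @param fits output of [gxe_scan()] or [gxg_scan()].
#' @param file optional path: write the matrix as tab-delimited text with
#'   row names in a leading `id` column.
#' @return the signed matrix, invisibly when written to `file`.
#' @export
interaction_matrix <- function(fits, file = NULL) {
  rows <- unique(fits$vqtl)
  cols <- unique(fits$partner)
  if (any(fits$partner %in% fits$vqtl) || any(fits$vqtl %in% fits$partner)) {
    ids <- sort(unique(c(fits$vqtl, fits$partner)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_len(nrow(fits))) {
      m[fits$vqtl[i], fits$partner[i]] <- fits$signed_log10p[i]
      m[fits$partner[i], fits$vqtl[i]] <- fits$signed_log10p[i]
    }
  } else {
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    for (i in seq_len(nrow(fits)))
      m[fits$vqtl[i], fits$partner[i]] <- fits$signed_log10p[i]
  }
  if (!is.null(file)) {
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(m))
  }
  m
}
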