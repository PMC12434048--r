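#' Configuration for a genome-wide vQTL scan
#'
#' @param genotype path prefix of a PLINK `.bed/.bim/.fam` trio, or path to
#'   a delimited variants x samples matrix (see [read_genotype_matrix()]).
#' @param phenotype path to a delimited sample table; `trait` selects the
#'   column (default: the first).
#' @param format `"auto"` (PLINK when `<genotype>.bed` exists), `"plink"`
#'   or `"matrix"`.
#' @param trait phenotype column name.
#' @param covariates optional path to a covariate sample table.
#' @param covariate_cols optional subset of covariate columns.
#' @param method one of `"KW"`, `"BF"`, `"DRM"`, `"DGLM"`, `"DGLM_INT"`,
#'   `"QUAIL"`.
#' @param maf_min minor-allele-frequency filter computed on analyzed
#'   samples (default 0.05: rarer variants are hard to replicate in
#'   interaction follow-up).
#' @param alpha significance threshold carried into the output summary
#'   (default genome-wide 5e-8).
#' @param quail_K quantile-grid size for `method = "QUAIL"`.
#' @param seed RNG seed recorded for provenance (the scan itself is
#'   deterministic).
#' @param out_prefix optional output prefix; the scan table is written to
#'   `<out_prefix>.vqtl.tsv`.
#' @return a validated `scan_config` list.
#' @export
scan_config <- function(genotype, phenotype,
                        format = c("auto", "plink", "matrix"),
                        trait = NULL, covariates = NULL,
                        covariate_cols = NULL,
                        method = c("KW", "BF", "DRM", "DGLM", "DGLM_INT",
                                   "QUAIL"),
                        maf_min = 0.05, alpha = 5e-8, quail_K = 100L,
                        seed = 1L, out_prefix = NULL) {
  format <- match.arg(format)
  method <- match.arg(method)
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  if (format == "auto")
    format <- if (file.exists(paste0(genotype, ".bed"))) "plink" else
      "matrix"
  structure(list(genotype = genotype, format = format,
                 phenotype = phenotype, trait = trait,
                 covariates = covariates, covariate_cols = covariate_cols,
                 method = method, maf_min = maf_min, alpha = alpha,
                 quail_K = as.integer(quail_K), seed = as.integer(seed),
                 out_prefix = out_prefix),
            class = "scan_config")
}

#' Run a per-variant vQTL scan
#'
#' For every variant passing the MAF filter: orient to the minor allele
#' (recomputed on analyzed samples; frequency ties keep file orientation),
#' residualize the trait on the variant's genotype-group indicators and
#' the covariates, form absolute median deviations, and apply the
#' configured test.  Variants that pass the filter but fail a test
#' precondition (e.g. constant deviations) are emitted with `NA` p and a
#' reason code rather than aborting the scan.  Output is fully
#' deterministic for a fixed config.
#'
#' @param config a [scan_config()].
#' @return data frame, one row per analyzed variant: `chrom, pos, id, maf,
#'   n0, n1, n2, method, statistic, df, effect, p, reason`.  Written
#'   tab-delimited to `<out_prefix>.vqtl.tsv` when `out_prefix` is set.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  set.seed(config$seed)
  geno <- if (config$format == "plink") read_plink(config$genotype) else
    read_genotype_matrix(config$genotype)
  pheno_tab <- read_sample_table(config$phenotype)
  trait <- if (is.null(config$trait)) names(pheno_tab)[1L] else config$trait
  if (!trait %in% names(pheno_tab))
    stop("trait column '", trait, "' not found in phenotype file")

  covar_tab <- NULL
  if (!is.null(config$covariates)) {
    covar_tab <- read_sample_table(config$covariates)
    if (!is.null(config$covariate_cols))
      covar_tab <- covar_tab[, config$covariate_cols, drop = FALSE]
  }

  ids_g <- rownames(geno$genotypes)
  ids_p <- rownames(pheno_tab)
  unmatched <- c(setdiff(ids_g, ids_p), setdiff(ids_p, ids_g))
  if (!is.null(covar_tab))
    unmatched <- c(unmatched, setdiff(ids_p, rownames(covar_tab)),
                   setdiff(rownames(covar_tab), ids_p))
  if (length(unmatched))
    stop("sample ids do not match across input files: ",
         paste(unique(unmatched), collapse = ", "))
  ord <- ids_g
  y <- as.numeric(pheno_tab[ord, trait])
  Z <- if (is.null(covar_tab)) NULL else
    as.matrix(covar_tab[ord, , drop = FALSE])

  rows <- lapply(seq_len(ncol(geno$genotypes)), function(j) {
    scan_one_variant(geno$bim[j, ], geno$genotypes[, j], y, Z, config)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(config$out_prefix)) {
    path <- paste0(config$out_prefix, ".vqtl.tsv")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("scan: %d variants tested, %d NA, written to %s",
                    sum(!is.na(out$p)), sum(is.na(out$p)), path))
  }
  out
}

scan_one_variant <- function(bimrow, calls, y, Z, config) {
  ok <- !is.na(calls) & is.finite(y)
  if (!is.null(Z)) ok <- ok & stats::complete.cases(Z)
  maf <- if (any(ok)) mean(calls[ok]) / 2 else NA_real_
  flip <- !is.na(maf) && maf > 0.5
  if (flip) {
    calls <- 2L - calls
    maf <- 1 - maf
  }
  empty <- data.frame(chrom = bimrow$chrom, pos = bimrow$pos,
                      id = bimrow$id, maf = maf,
                      n0 = NA_integer_, n1 = NA_integer_,
                      n2 = NA_integer_, method = config$method,
                      statistic = NA_real_, df = NA_character_,
                      effect = NA_real_, p = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
  if (is.na(maf) || maf < config$maf_min || maf == 0) {
    if (config$maf_min > 0 && !is.na(maf) && maf > 0) {
      empty$id <- NA_character_        # filtered out entirely
      return(empty)
    }
    empty$reason <- if (!is.na(maf) && maf == 0) "monomorphic" else
      "low_maf"
    return(empty)
  }
  result <- tryCatch({
    res <- residualize(y, calls, covariates = Z)
    counts <- count_groups(res$group)
    fit <- switch(config$method,
      KW       = kw_test(group_median_deviations(res)),
      BF       = bf_test(group_median_deviations(res)),
      DRM      = drm_test(group_median_deviations(res)),
      DGLM     = dglm_test(res),
      DGLM_INT = dglm_test(res, apply_int = TRUE),
      QUAIL    = quail_test(res, K = config$quail_K,
                            estimate_effect = FALSE))
    data.frame(chrom = bimrow$chrom, pos = bimrow$pos, id = bimrow$id,
               maf = maf, n0 = counts[["n0"]], n1 = counts[["n1"]],
               n2 = counts[["n2"]], method = fit$method,
               statistic = fit$statistic,
               df = paste(fit$df, collapse = ","),
               effect = fit$effect, p = fit$p_value,
               reason = if (isTRUE(fit$degenerate)) "degenerate" else
                 NA_character_,
               stringsAsFactors = FALSE)
  }, error = function(e) {
    empty$reason <- conditionMessage(e)
    empty
  })
  result
}

#' Generate a synthetic cohort fixture on disk
#'
#' Writes a self-contained synthetic data set — genotypes in both dialects
#' (PLINK trio and delimited matrix), a phenotype table, a covariate table
#' and a ground-truth manifest — for pipeline testing and demonstrations.
#' Genotypes are independent Hardy-Weinberg draws with per-variant MAFs
#' uniform on `maf_range`.  The trait is built from the covariates (effect
#' 0.5 each) plus heteroscedastic noise: a planted dispersion effect
#' `theta` at variant v multiplies the error SD by `exp(theta * g_v / 2)`,
#' i.e. the log residual variance is linear in the allele count with slope
#' `theta` — the signature every dispersion test targets.
#'
#' @param dir output directory (created if needed).
#' @param n_samples,n_variants cohort dimensions.
#' @param planted optional data frame with columns `variant` (index) and
#'   `theta` (log-variance slope per allele).
#' @param n_covariates number of standard-normal covariates (default 2).
#' @param maf_range MAF range for the uniform per-variant draw.
#' @param seed RNG seed; fixed seed gives byte-identical files.
#' @return invisible list of file paths (`plink_prefix`, `matrix`,
#'   `phenotype`, `covariates`, `truth`) plus the in-memory `genotypes`,
#'   `phenotype` and `covariates` objects.
#' @export
generate_fixture <- function(dir, n_samples = 500L, n_variants = 50L,
                             planted = NULL, n_covariates = 2L,
                             maf_range = c(0.05, 0.5), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  mafs <- stats::runif(n_variants, maf_range[1L], maf_range[2L])
  g <- vapply(mafs, function(m) simulate_genotypes(n_samples, m),
              integer(n_samples))
  colnames(g) <- sprintf("var%03d", seq_len(n_variants))
  rownames(g) <- sprintf("S%04d", seq_len(n_samples))

  covar <- matrix(stats::rnorm(n_samples * n_covariates), n_samples,
                  dimnames = list(rownames(g),
                                  paste0("cov", seq_len(n_covariates))))
  log_sd <- rep(0, n_samples)
  if (!is.null(planted)) {
    stopifnot(all(c("variant", "theta") %in% names(planted)))
    for (k in seq_len(nrow(planted)))
      log_sd <- log_sd + planted$theta[k] * g[, planted$variant[k]] / 2
  }
  y <- drop(covar %*% rep(0.5, n_covariates)) +
    stats::rnorm(n_samples) * exp(log_sd)

  prefix <- file.path(dir, "cohort")
  bim <- data.frame(chrom = "1", id = colnames(g), cm = 0,
                    pos = seq_len(n_variants) * 1000L, a1 = "A", a2 = "B")
  write_plink(prefix, g, bim = bim)
  write_genotype_matrix(file.path(dir, "cohort.geno.tsv"), g)
  utils::write.table(
    data.frame(sample = rownames(g), trait = y),
    file.path(dir, "cohort.pheno.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(g), covar, check.names = FALSE),
    file.path(dir, "cohort.covar.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- if (is.null(planted))
    data.frame(variant = character(0), theta = numeric(0)) else
      data.frame(variant = colnames(g)[planted$variant],
                 theta = planted$theta)
  utils::write.table(truth, file.path(dir, "cohort.truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(plink_prefix = prefix,
                 matrix = file.path(dir, "cohort.geno.tsv"),
                 phenotype = file.path(dir, "cohort.pheno.tsv"),
                 covariates = file.path(dir, "cohort.covar.tsv"),
                 truth = file.path(dir, "cohort.truth.tsv"),
                 genotypes = g, phenotype_values = y, covariate_values = covar))
}
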