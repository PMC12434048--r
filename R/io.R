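# Readers and writers for the two genotype dialects (PLINK binary trio and
# a plain variants x samples text matrix) and for delimited sample tables.
# The PLINK .bed decoder handles the variant-major dialect: magic bytes
# 0x6c 0x1b 0x01, then ceiling(N/4) bytes per variant, two bits per sample
# (LSB first): 00 = two copies of allele A1, 01 = missing, 10 = het,
# 11 = zero copies of A1.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> A1 allele counts of the 4 packed samples
bed_lookup <- function() {
  codes <- matrix(NA_integer_, 256L, 4L)
  decode <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    v <- b
    for (s in 1:4) {
      codes[b + 1L, s] <- decode[[as.character(v %% 4L)]]
      v <- v %/% 4L
    }
  }
  codes
}

#' Read a PLINK .bed/.bim/.fam file set
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return list with `genotypes` (samples x variants integer matrix of A1
#'   allele counts, `NA` for missing; rownames = individual ids, colnames =
#'   variant ids), `bim` (chrom, id, cm, pos, a1, a2) and `fam` data frames.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "numeric"))
  n <- nrow(fam)
  v <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + as.numeric(bpv) * v)
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("not a PLINK .bed file (bad magic bytes): ", prefix, ".bed")
  if (length(raw) != 3L + bpv * v)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  lut <- bed_lookup()
  body <- as.integer(raw[-(1:3)]) + 1L
  # decode all variants at once: (bpv x v) bytes -> (4*bpv x v) calls
  calls <- matrix(t(lut[body, , drop = FALSE]), nrow = 4L * bpv, ncol = v)
  g <- calls[seq_len(n), , drop = FALSE]
  dimnames(g) <- list(fam$iid, bim$id)
  list(genotypes = g, bim = bim, fam = fam)
}

#' Write a PLINK .bed/.bim/.fam file set
#'
#' @param prefix output path prefix.
#' @param genotypes samples x variants matrix of A1 allele counts
#'   (0/1/2/NA).
#' @param bim,fam optional data frames as returned by [read_plink()];
#'   minimal stand-ins are synthesised from the dimnames when omitted.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(prefix, genotypes, bim = NULL, fam = NULL) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  v <- ncol(g)
  if (is.null(colnames(g))) colnames(g) <- paste0("var", seq_len(v))
  if (is.null(rownames(g))) rownames(g) <- paste0("S", seq_len(n))
  if (is.null(bim))
    bim <- data.frame(chrom = "1", id = colnames(g), cm = 0,
                      pos = seq_len(v), a1 = "A", a2 = "B")
  if (is.null(fam))
    fam <- data.frame(fid = rownames(g), iid = rownames(g), pat = "0",
                      mat = "0", sex = 0L, pheno = -9)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # encode: allele count -> 2-bit code
  code <- matrix(1L, nrow = n, ncol = v)     # 01 = missing
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  if (pad > 0L)
    code <- rbind(code, matrix(3L, pad, v))  # padding bits: hom A2 (code 11)
  mult <- c(1L, 4L, 16L, 64L)
  bytes <- vapply(seq_len(bpv), function(b) {
    rows <- (b - 1L) * 4L + 1:4
    as.integer(mult %*% code[rows, , drop = FALSE])
  }, integer(v))
  # bytes is v x bpv; transpose to variant-major byte stream
  stream <- as.raw(t(bytes))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(stream, con)
  invisible(prefix)
}

#' Read a delimited variants x samples genotype matrix
#'
#' Expects a header row of sample ids, a first column of variant ids, and
#' cell values in \{0, 1, 2, NA\}.  Tab or comma delimiters are sniffed
#' from the header line.
#'
#' @param path file path.
#' @return list with `genotypes` (samples x variants, as [read_plink()])
#'   and a minimal `bim` (variant ids only, chrom/pos `NA`).
#' @export
read_genotype_matrix <- function(path) {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  bad <- !is.na(m) & !(m %in% c(0L, 1L, 2L))
  if (any(bad)) stop("genotype matrix values must be 0/1/2/NA")
  g <- t(m)                               # samples x variants
  list(genotypes = g,
       bim = data.frame(chrom = NA_character_, id = colnames(g),
                        cm = NA_real_, pos = NA_integer_,
                        a1 = NA_character_, a2 = NA_character_))
}

#' Write a delimited variants x samples genotype matrix
#'
#' @param path output path.
#' @param genotypes samples x variants matrix (as held internally).
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(path, genotypes, sep = "\t") {
  m <- t(as.matrix(genotypes))            # variants x samples on disk
  out <- data.frame(variant = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a delimited sample table (phenotypes or covariates)
#'
#' Tab- or comma-delimited text with a header; the first column holds
#' sample ids and becomes the row names.
#'
#' @param path file path.
#' @return data frame with sample ids as row names.
#' @export
read_sample_table <- function(path) {
  sep <- sniff_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    row.names = 1L, colClasses = NA)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}
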