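# Read a labelled numeric block from delimited text, reporting the location
# of any non-numeric cell. Returns a numeric matrix (NAs preserved).
.read_numeric_block <- function(path, sep = "\t", row_label_col = 1L) {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop_input("malformed header in '", path,
               "': need a label column plus at least one data column")
  ids <- raw[[row_label_col]]
  dat <- raw[, -row_label_col, drop = FALSE]
  out <- matrix(NA_real_, nrow(dat), ncol(dat),
                dimnames = list(ids, colnames(dat)))
  for (j in seq_len(ncol(dat))) {
    x <- dat[[j]]
    miss <- is.na(x) | x %in% c("", "NA", "NaN", "nan", ".")
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & !miss)
    if (length(bad))
      stop_input("non-numeric value '", x[bad[1]], "' at row ", bad[1],
                 " (id '", ids[bad[1]], "'), column '", colnames(dat)[j],
                 "' of '", path, "'")
    out[, j] <- num
  }
  out
}

.is_plink_raw <- function(path, sep) {
  hdr <- strsplit(readLines(path, n = 1L), if (sep == "\t") "[\t ]+" else sep)[[1]]
  length(hdr) >= 6L &&
    identical(toupper(hdr[1:6]), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
}

.read_plink_raw <- function(path) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[["IID"]])
  dat <- as.matrix(raw[, -(1:6), drop = FALSE])
  storage.mode(dat) <- "double"
  rownames(dat) <- ids
  dat
}

#' Read phenotype, genotype or kinship tables
#'
#' The canonical interchange dialect is tab-separated text with marker /
#' trait / individual labels in the first row and individual labels in the
#' first column. Genotypes may instead be a PLINK `.raw` additive dosage
#' file (header `FID IID PAT MAT SEX PHENOTYPE` followed by marker
#' columns), detected automatically.
#'
#' Phenotypes are complete-case filtered: any individual with a missing
#' trait value is dropped (with a message stating how many). Missing
#' genotypes are mean-imputed per marker; markers that are monomorphic
#' (allele frequency 0 or 1) are removed with a warning.
#'
#' @param path file path.
#' @param kind `"traits"`, `"genotypes"` or `"kinship"`.
#' @param sep field separator (default tab).
#' @return a [trait_matrix()], [genotype_matrix()] or [kinship_matrix()].
#' @export
read_table <- function(path, kind = c("traits", "genotypes", "kinship"),
                       sep = "\t") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (kind == "genotypes" && .is_plink_raw(path, sep)) {
    vals <- .read_plink_raw(path)
  } else {
    vals <- .read_numeric_block(path, sep = sep)
  }
  switch(kind,
    traits = {
      complete <- stats::complete.cases(vals)
      if (any(!complete))
        message("read_table: dropped ", sum(!complete),
                " individual(s) with missing phenotypes")
      trait_matrix(vals[complete, , drop = FALSE])
    },
    genotypes = {
      bad <- vals[!is.na(vals)]
      if (any(!(bad %in% c(0, 1, 2))))
        stop_input("raw genotype values must be 0, 1 or 2 (missing allowed)")
      # per-marker mean imputation
      if (anyNA(vals)) {
        mu <- colMeans(vals, na.rm = TRUE)
        idx <- which(is.na(vals), arr.ind = TRUE)
        vals[idx] <- mu[idx[, 2]]
      }
      af <- colMeans(vals) / 2
      mono <- af <= 0 | af >= 1
      if (any(mono)) {
        warning("read_table: removed ", sum(mono), " monomorphic marker(s)")
        vals <- vals[, !mono, drop = FALSE]
        af <- af[!mono]
      }
      genotype_matrix(vals, coding = "raw012", allele_freqs = af)
    },
    kinship = kinship_matrix(vals)
  )
}

#' Write a container back to tab-separated text
#'
#' Inverse of [read_table()] for the canonical dialect: row labels in the
#' first column (header `id`), column labels in the first row.
#'
#' @param x a trait, genotype or kinship matrix (or plain labelled matrix).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = "\t") {
  m <- as.matrix(unclass(x))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Converts GT fields to additive dosages (count of ALT alleles).
#' Multi-allelic sites are skipped with a warning; missing calls are
#' mean-imputed per marker. Requires the `vcfR` package.
#'
#' @param path VCF (v4.x) file path.
#' @return a [genotype_matrix()] (individuals in rows).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("read_vcf_genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning("read_vcf_genotypes: skipped ", sum(multi), " multi-allelic site(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  vals <- t(dose)  # individuals x markers
  if (anyNA(vals)) {
    mu <- colMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- mu[idx[, 2]]
  }
  af <- colMeans(vals) / 2
  mono <- af <= 0 | af >= 1
  if (any(mono)) {
    warning("read_vcf_genotypes: removed ", sum(mono), " monomorphic marker(s)")
    vals <- vals[, !mono, drop = FALSE]
    af <- af[!mono]
  }
  genotype_matrix(vals, coding = "raw012", allele_freqs = af)
}
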