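#' Phenotype container
#'
#' An `n x q` matrix of trait observations with individual identifiers as
#' row names and trait names as column names. No missing values are allowed:
#' individuals with incomplete phenotypes are dropped at load time (see
#' [read_table()]).
#'
#' @param values numeric matrix (individuals in rows, traits in columns).
#' @param individual_ids,trait_names optional labels; default to the
#'   dimnames of `values`.
#' @return a `trait_matrix`: a numeric matrix with labelled dimensions.
#' @export
trait_matrix <- function(values, individual_ids = rownames(values),
                         trait_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); q <- ncol(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(q))
  if (n < 2L) stop_input("trait matrix needs at least 2 individuals")
  if (q < 1L) stop_input("trait matrix needs at least 1 trait")
  if (anyNA(values)) stop_input("trait matrix contains missing values")
  if (anyDuplicated(individual_ids)) stop_input("duplicate individual ids")
  if (anyDuplicated(trait_names)) stop_input("duplicate trait names")
  dimnames(values) <- list(as.character(individual_ids), as.character(trait_names))
  structure(values, class = c("trait_matrix", "matrix", "array"))
}

#' Genotype container
#'
#' An `n x p` matrix of marker scores. Raw genotypes are additive allele
#' counts in `{0, 1, 2}` (mean-imputed entries may be fractional);
#' standardized genotypes have column mean 0 and unit population standard
#' deviation so that a common penalty weight acts uniformly across markers.
#'
#' @param values numeric matrix (individuals in rows, markers in columns).
#' @param individual_ids,marker_ids optional labels.
#' @param coding `"raw012"` or `"standardized"`.
#' @param allele_freqs per-marker alternative-allele frequency; computed as
#'   `colMeans(values) / 2` for raw input when not supplied.
#' @return a `genotype_matrix` with `coding` and `allele_freqs` attributes.
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            marker_ids = colnames(values),
                            coding = c("raw012", "standardized"),
                            allele_freqs = NULL) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(p))
  if (anyDuplicated(individual_ids)) stop_input("duplicate individual ids")
  if (anyDuplicated(marker_ids)) stop_input("duplicate marker ids")
  if (anyNA(values)) stop_input("genotype matrix contains missing values; impute before construction")
  if (coding == "raw012") {
    if (min(values) < 0 || max(values) > 2)
      stop_input("raw genotypes must lie in [0, 2] (allele counts)")
    if (is.null(allele_freqs)) allele_freqs <- colMeans(values) / 2
  }
  dimnames(values) <- list(as.character(individual_ids), as.character(marker_ids))
  structure(values, coding = coding, allele_freqs = allele_freqs,
            class = c("genotype_matrix", "matrix", "array"))
}

geno_coding <- function(x) attr(x, "coding") %||% "raw012"

#' Kinship container
#'
#' A symmetric positive semi-definite `n x n` genomic relationship matrix.
#' Symmetry is enforced within `1e-10` (relative); eigenvalues slightly
#' below zero from rounding are tolerated and clamped downstream.
#'
#' @param values numeric square matrix.
#' @param individual_ids optional labels.
#' @return a `kinship_matrix`.
#' @export
kinship_matrix <- function(values, individual_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop_input("kinship matrix must be square (got ", nrow(values), " x ", ncol(values), ")")
  if (!is_symmetric_tol(values, 1e-10))
    stop_input("kinship matrix is not symmetric within tolerance")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (anyDuplicated(individual_ids)) stop_input("duplicate individual ids")
  values <- symmetrize(values)
  dimnames(values) <- list(as.character(individual_ids), as.character(individual_ids))
  structure(values, class = c("kinship_matrix", "matrix", "array"))
}

#' Align phenotypes, genotypes and kinship on shared individuals
#'
#' Restricts all three containers to the (sorted) intersection of their
#' individual ids, in one consistent order, and reports how many
#' individuals each input lost.
#'
#' @param traits a [trait_matrix()].
#' @param genotypes a [genotype_matrix()].
#' @param kinship a [kinship_matrix()].
#' @return an `aligned_dataset`: list with elements `traits`, `genotypes`,
#'   `kinship` sharing identical row ordering.
#' @export
align <- function(traits, genotypes, kinship) {
  ids <- sort(Reduce(intersect, list(rownames(traits), rownames(genotypes),
                                     rownames(kinship))))
  if (length(ids) == 0L)
    stop_input("alignment failed: no individuals shared by all three inputs")
  dropped <- c(traits = nrow(traits) - length(ids),
               genotypes = nrow(genotypes) - length(ids),
               kinship = nrow(kinship) - length(ids))
  if (any(dropped > 0))
    message("align: dropped ", paste(dropped, names(dropped), collapse = ", "),
            " individuals not shared by all inputs")
  tr <- trait_matrix(unclass(traits)[ids, , drop = FALSE])
  ge <- genotype_matrix(unclass(genotypes)[ids, , drop = FALSE],
                        coding = geno_coding(genotypes),
                        allele_freqs = attr(genotypes, "allele_freqs"))
  ki <- kinship_matrix(unclass(kinship)[ids, ids, drop = FALSE])
  structure(list(traits = tr, genotypes = ge, kinship = ki),
            class = "aligned_dataset")
}

#' Subset an aligned dataset by individual
#'
#' @param data an `aligned_dataset`.
#' @param idx integer or logical index, or character ids.
#' @return an `aligned_dataset` over the selected individuals (input order
#'   preserved).
#' @export
subset_dataset <- function(data, idx) {
  stopifnot(inherits(data, "aligned_dataset"))
  ids <- rownames(data$traits)
  if (is.character(idx)) idx <- match(idx, ids)
  tr <- trait_matrix(unclass(data$traits)[idx, , drop = FALSE])
  ge <- genotype_matrix(unclass(data$genotypes)[idx, , drop = FALSE],
                        coding = geno_coding(data$genotypes),
                        allele_freqs = attr(data$genotypes, "allele_freqs"))
  ki <- kinship_matrix(unclass(data$kinship)[idx, idx, drop = FALSE])
  structure(list(traits = tr, genotypes = ge, kinship = ki),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset:", nrow(x$traits), "individuals,",
      ncol(x$traits), "traits,", ncol(x$genotypes), "markers\n")
  invisible(x)
}

#' Genetic and residual trait covariances
#'
#' Holds the `q x q` genetic covariance `Cg` (positive semi-definite) and
#' residual/environment covariance `Ce` (positive definite) of the
#' multi-trait mixed model.
#'
#' @param Cg,Ce symmetric numeric matrices of equal dimension.
#' @return a `covariance_pair`.
#' @export
covariance_pair <- function(Cg, Ce) {
  Cg <- as.matrix(Cg); Ce <- as.matrix(Ce)
  if (!identical(dim(Cg), dim(Ce)))
    stop_input("Cg and Ce must have identical dimensions")
  if (!is_symmetric_tol(Cg, 1e-8) || !is_symmetric_tol(Ce, 1e-8))
    stop_input("covariance matrices must be symmetric")
  Cg <- symmetrize(Cg); Ce <- symmetrize(Ce)
  eg <- eigen(Cg, symmetric = TRUE, only.values = TRUE)$values
  ee <- eigen(Ce, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < -1e-8 * max(1, max(abs(eg))))
    stop_input("Cg must be positive semi-definite")
  if (min(ee) <= 0)
    stop_input("Ce must be positive definite")
  structure(list(Cg = Cg, Ce = Ce), class = "covariance_pair")
}
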