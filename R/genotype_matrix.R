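#' Diploid biallelic genotype matrix
#'
#' The central data container of the package: one population sample of `S`
#' diploid individuals genotyped at `L` biallelic SNP loci. Genotypes are
#' stored as the dosage of allele "1" (0, 1 or 2); `NA` marks a missing
#' genotype (both alleles missing together, the GENEPOP `"00"`/`"000"`
#' convention). Because genotypes are unordered, the dosage encoding is
#' lossless.
#'
#' @param dosage integer matrix, `S x L`, entries in `{0, 1, 2, NA}`: number
#'   of copies of allele "1".
#' @param individual_ids character vector of length `S`. Defaults to
#'   `ind_1 ... ind_S`.
#' @param locus_ids character vector of length `L`, unique. Defaults to
#'   `loc_1 ... loc_L`.
#' @param population_label single string naming the sample.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `individual_ids`, `locus_ids`, `population_label`.
#' @examples
#' g <- genotype_matrix(matrix(c(2L, 1L, 0L, 1L), 2, 2))
#' n_ind(g); n_loci(g)
#' @export
genotype_matrix <- function(dosage,
                            individual_ids = NULL,
                            locus_ids = NULL,
                            population_label = "pop_1") {
  if (!is.matrix(dosage)) {
    stop("`dosage` must be a matrix", call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) < 1L || ncol(dosage) < 1L) {
    stop("genotype matrix needs at least 1 individual and 1 locus",
         call. = FALSE)
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L))) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind_", seq_len(nrow(dosage)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- paste0("loc_", seq_len(ncol(dosage)))
  }
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != nrow(dosage)) {
    stop("length(individual_ids) must equal nrow(dosage)", call. = FALSE)
  }
  if (length(locus_ids) != ncol(dosage)) {
    stop("length(locus_ids) must equal ncol(dosage)", call. = FALSE)
  }
  if (anyDuplicated(locus_ids)) {
    stop("locus_ids must be unique", call. = FALSE)
  }
  dimnames(dosage) <- NULL
  structure(
    list(dosage = dosage,
         individual_ids = individual_ids,
         locus_ids = locus_ids,
         population_label = as.character(population_label)[1]),
    class = "genotype_matrix"
  )
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_ind <- function(x) nrow(x$dosage)

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) ncol(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci (pop \"%s\", %.1f%% missing)\n",
    n_ind(x), n_loci(x), x$population_label, 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i,j index vectors over individuals and loci.
#' @param ... unused.
#' @return a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  individual_ids = x$individual_ids[i],
                  locus_ids = x$locus_ids[j],
                  population_label = x$population_label)
}

#' Test equality of two genotype matrices
#'
#' Two matrices are equal when dosages (including the missingness pattern),
#' identifiers and the population label all agree.
#'
#' @param a,b `genotype_matrix` objects.
#' @return logical scalar.
#' @export
genotype_equal <- function(a, b) {
  identical(dim(a$dosage), dim(b$dosage)) &&
    identical(is.na(a$dosage), is.na(b$dosage)) &&
    all(a$dosage == b$dosage, na.rm = TRUE) &&
    identical(a$individual_ids, b$individual_ids) &&
    identical(a$locus_ids, b$locus_ids) &&
    identical(a$population_label, b$population_label)
}
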