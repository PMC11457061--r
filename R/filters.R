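#' Filtering configuration
#'
#' Bundles the data-quality thresholds applied to an observed sample before
#' estimation: the minor-allele-frequency cutoff and the maximum tolerated
#' missing-data fractions per locus and per individual. Defaults follow the
#' estimator's standard settings (MAF 0.05, 20% missing data for both
#' individuals and loci).
#'
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`; loci with
#'   MAF below this (strictly) are removed, so loci at exactly the cutoff
#'   are retained.
#' @param max_missing_individual maximum fraction of missing genotypes per
#'   individual, in `[0, 1]`.
#' @param max_missing_locus maximum fraction of missing genotypes per locus,
#'   in `[0, 1]`. Set to 0 to drop every locus with any missing call.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_maf = 0.05,
                          max_missing_individual = 0.20,
                          max_missing_locus = 0.20) {
  if (min_maf < 0 || min_maf > 0.5) {
    stop("min_maf must lie in [0, 0.5]", call. = FALSE)
  }
  if (max_missing_individual < 0 || max_missing_individual > 1 ||
      max_missing_locus < 0 || max_missing_locus > 1) {
    stop("missing-data thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(min_maf = min_maf,
                 max_missing_individual = max_missing_individual,
                 max_missing_locus = max_missing_locus),
            class = "filter_config")
}

#' Remove loci and individuals with excessive missing data
#'
#' Two fixed-order passes: first every locus whose missing fraction exceeds
#' `max_missing_locus` (strictly) is dropped, then every individual whose
#' missing fraction over the retained loci exceeds `max_missing_individual`.
#' Dropping bad loci first avoids discarding individuals for loci that would
#' have been removed anyway.
#'
#' @param matrix a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @param quiet suppress the removal-count message.
#' @return the filtered `genotype_matrix`.
#' @export
filter_missing <- function(matrix, cfg = filter_config(), quiet = FALSE) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  d <- matrix$dosage
  keep_loc <- colMeans(is.na(d)) <= cfg$max_missing_locus
  if (!any(keep_loc)) {
    stop("all loci exceed the missing-data threshold; nothing to analyse",
         call. = FALSE)
  }
  d2 <- d[, keep_loc, drop = FALSE]
  keep_ind <- rowMeans(is.na(d2)) <= cfg$max_missing_individual
  if (sum(keep_ind) < 2) {
    stop(paste("fewer than 2 individuals survive the missing-data filter;",
               "raise the thresholds or genotype more individuals"),
         call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("missing-data filter: removed %d/%d loci, %d/%d individuals",
                    sum(!keep_loc), ncol(d), sum(!keep_ind), nrow(d)))
  }
  matrix[keep_ind, keep_loc]
}

#' Remove loci below a minor-allele-frequency cutoff
#'
#' MAF is computed over non-missing allele calls at each locus. Loci with
#' MAF strictly below `min_maf` are removed; a locus at exactly the cutoff
#' is retained. Monomorphic loci (MAF 0) are always removed when
#' `min_maf > 0`.
#'
#' @inheritParams filter_missing
#' @param min_maf frequency cutoff in `[0, 0.5]`.
#' @return the filtered `genotype_matrix`.
#' @export
filter_maf <- function(matrix, min_maf = 0.05, quiet = FALSE) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  p <- allele1_freq(matrix)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf
  if (!any(keep)) {
    stop("no locus passes the minor-allele-frequency filter", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("MAF filter (>= %.3f): removed %d/%d loci",
                    min_maf, sum(!keep), n_loci(matrix)))
  }
  matrix[, keep]
}

# Frequency of allele "1" per locus over called genotypes; NA if a locus has
# no called genotype.
allele1_freq <- function(matrix) {
  colMeans(matrix$dosage, na.rm = TRUE) / 2
}
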