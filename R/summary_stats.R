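#' Mean expected heterozygosity
#'
#' Per locus, expected heterozygosity under Hardy-Weinberg proportions is
#' `2 p (1 - p)` with `p` the frequency of allele "1" over called alleles;
#' the statistic is the unweighted mean over all loci. Monomorphic loci
#' contribute 0. Missing genotypes are excluded per locus.
#'
#' @param matrix a [genotype_matrix()]; every locus must have at least one
#'   called genotype.
#' @return scalar in `[0, 1]`.
#' @export
expected_heterozygosity <- function(matrix) {
  he <- he_per_locus(matrix)
  mean(he)
}

he_per_locus <- function(matrix) {
  p <- allele1_freq(matrix)
  if (anyNA(p)) {
    stop("locus with no called genotype; apply filter_missing first",
         call. = FALSE)
  }
  2 * p * (1 - p)
}

ho_per_locus <- function(matrix) {
  colMeans(matrix$dosage == 1L, na.rm = TRUE)
}

#' Fixation index
#'
#' `1 - mean_i(Ho_i / He_i)`: one minus the average over loci of the ratio
#' of observed heterozygosity (fraction of heterozygous called genotypes)
#' to Hardy-Weinberg expected heterozygosity. Negative values indicate a
#' heterozygote excess, as produced by small two-sex populations.
#'
#' @inheritParams expected_heterozygosity
#' @param monomorphic how to treat loci with `He = 0`: `"error"` (default;
#'   such loci should have been removed by [filter_maf()]) or `"skip"`
#'   (average the ratio over polymorphic loci only, the behaviour used for
#'   simulated samples in which drift may have fixed loci).
#' @return scalar, at most 1.
#' @export
fixation_index <- function(matrix, monomorphic = c("error", "skip")) {
  monomorphic <- match.arg(monomorphic)
  he <- he_per_locus(matrix)
  ho <- ho_per_locus(matrix)
  poly <- he > 0
  if (!all(poly)) {
    if (monomorphic == "error") {
      stop("monomorphic locus (He = 0): apply filter_maf before fixation_index",
           call. = FALSE)
    }
    if (!any(poly)) {
      stop("no polymorphic locus; fixation index undefined", call. = FALSE)
    }
    he <- he[poly]
    ho <- ho[poly]
  }
  1 - mean(ho / he)
}

#' Moments of multi-locus homozygosity
#'
#' For each individual, `h_j` counts the called loci at which the individual
#' is homozygous. Returns the mean and the sample variance (denominator
#' `S - 1`) of `h` across individuals.
#'
#' @inheritParams expected_heterozygosity
#' @return named list with `h_mean` and `h_var`.
#' @export
multilocus_homozygosity <- function(matrix) {
  d <- matrix$dosage
  if (nrow(d) < 2) {
    stop("at least 2 individuals are needed (variance undefined)",
         call. = FALSE)
  }
  h <- rowSums(d != 1L, na.rm = TRUE)
  list(h_mean = mean(h), h_var = stats::var(h))
}

#' Burrows composite linkage disequilibrium for one locus pair
#'
#' Computes the phase-free Burrows composite disequilibrium between allele
#' "1" at locus `i` and allele "1" at locus `j` over the individuals called
#' at both loci (pairwise deletion). With dosages `X`, `Y` in `{0,1,2}` over
#' the `n` doubly-called individuals and `pA`, `pB` the corresponding allele
#' frequencies, the composite disequilibrium is
#' `delta = sum(X*Y)/(2n) - 2 pA pB`, the per-locus Hardy-Weinberg
#' departures are `D = freq(homozygote "1") - p^2`, and the correlation is
#' `r = delta / sqrt((pA(1-pA)+DA) (pB(1-pB)+DB))`, clamped to `[-1, 1]`.
#'
#' A pair is unusable (`usable = FALSE`, `r_hat = NA`) when fewer than 2
#' individuals are called at both loci, when either locus is monomorphic
#' within those individuals, or when a denominator term is not positive
#' (e.g. every individual heterozygous).
#'
#' @inheritParams expected_heterozygosity
#' @param i,j locus indices, `i != j`.
#' @return list with `locus_i`, `locus_j`, `delta`, `r_hat`, `n_used`,
#'   `usable`.
#' @export
burrows_pair <- function(matrix, i, j) {
  stopifnot(i != j)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  x <- matrix$dosage[, i]
  y <- matrix$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- list(locus_i = i, locus_j = j, delta = NA_real_, r_hat = NA_real_,
              n_used = n, usable = FALSE)
  if (n < 2) return(out)
  pa <- mean(x) / 2
  pb <- mean(y) / 2
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(out)
  delta <- sum(x * y) / (2 * n) - 2 * pa * pb
  da <- mean(x == 2L) - pa^2
  db <- mean(y == 2L) - pb^2
  den_a <- pa * (1 - pa) + da
  den_b <- pb * (1 - pb) + db
  out$delta <- delta
  if (den_a <= 0 || den_b <= 0) return(out)
  r <- delta / sqrt(den_a * den_b)
  out$r_hat <- max(-1, min(1, r))
  out$usable <- TRUE
  out
}

#' Mean squared Burrows disequilibrium correlation over locus pairs
#'
#' Computes the Burrows correlation `r` for every usable unordered locus
#' pair, squares each, and averages. All pairwise quantities are obtained
#' with cross-product matrix algebra (missingness handled by pairwise
#' deletion), so the cost is a handful of `L x L` matrix products rather
#' than an explicit loop over pairs.
#'
#' @inheritParams expected_heterozygosity
#' @param max_pairs optional cap on the number of pairs: when the number of
#'   usable pairs exceeds `max_pairs`, a simple random subset of that size
#'   is averaged (all-pairs LD dominates runtime for large `L`; the
#'   subsample uses the current RNG stream). Default `Inf` = all pairs.
#' @return mean of `r^2` over usable pairs, in `[0, 1]`.
#' @export
mean_r2 <- function(matrix, max_pairs = Inf) {
  r2 <- pairwise_r2(matrix)
  vals <- r2[upper.tri(r2)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("no usable locus pair for linkage disequilibrium", call. = FALSE)
  }
  if (is.finite(max_pairs) && length(vals) > max_pairs) {
    vals <- vals[sample.int(length(vals), max_pairs)]
  }
  mean(vals)
}

# L x L matrix of squared Burrows correlations (upper triangle meaningful);
# NA marks unusable pairs. Pairwise-deletion counts via crossproducts; a
# leaner path handles fully observed data (every simulated sample).
pairwise_r2 <- function(matrix) {
  d <- matrix$dosage
  if (!anyNA(d)) return(pairwise_r2_complete(d))
  M <- !is.na(d)
  storage.mode(M) <- "double"
  X <- d
  X[!M] <- 0L
  storage.mode(X) <- "double"
  H <- (d == 2L)
  H[is.na(d)] <- FALSE
  storage.mode(H) <- "double"

  n <- crossprod(M)                  # doubly-called counts
  sx <- crossprod(X, M)              # sum of dosage at row-locus over pairs
  sxy <- crossprod(X)                # sum of dosage products
  sh <- crossprod(H, M)              # homozygote-"1" counts at row-locus

  n_safe <- pmax(n, 1)
  pa <- sx / (2 * n_safe)            # freq at locus i within pair (i, j)
  pb <- t(pa)
  delta <- sxy / (2 * n_safe) - 2 * pa * pb
  da <- sh / n_safe - pa^2
  db <- t(da)
  den <- (pa * (1 - pa) + da) * (pb * (1 - pb) + db)

  usable <- n >= 2 & pa > 0 & pa < 1 & pb > 0 & pb < 1 & den > 0
  r <- delta / sqrt(ifelse(den > 0, den, 1))
  r <- pmin(pmax(r, -1), 1)
  r2 <- r^2
  r2[!usable] <- NA_real_
  diag(r2) <- NA_real_
  r2
}

pairwise_r2_complete <- function(d) {
  storage.mode(d) <- "double"
  n <- nrow(d)
  p <- colMeans(d) / 2
  delta <- crossprod(d) / (2 * n) - 2 * outer(p, p)
  den1 <- p * (1 - p) + colMeans(d == 2) - p^2
  den <- outer(den1, den1)
  usable <- outer(p > 0 & p < 1 & den1 > 0,
                  p > 0 & p < 1 & den1 > 0, "&") & den > 0
  r2 <- pmin(delta^2 / ifelse(den > 0, den, 1), 1)
  r2[!usable] <- NA_real_
  diag(r2) <- NA_real_
  r2
}

#' The five-statistic summary vector
#'
#' Bundles the five summary statistics used to compare an observed sample
#' with simulated samples: mean expected heterozygosity (`he`), fixation
#' index (`fis`), mean and sample variance of multi-locus homozygosity
#' (`h_mean`, `h_var`), and mean squared Burrows correlation (`r2`).
#' Deterministic given the matrix (when `max_pairs` leaves all pairs in),
#' and invariant to permuting individuals or loci.
#'
#' For simulated samples, loci that drift has made monomorphic are retained:
#' they contribute 0 to `he`, are skipped in `fis`, and are excluded from
#' LD pairs by the usability rules.
#'
#' @inheritParams mean_r2
#' @param monomorphic passed to [fixation_index()]; `stats_vector` defaults
#'   to `"skip"` so simulated samples containing drift-fixed loci remain
#'   summarisable.
#' @return named numeric vector `c(he, fis, h_mean, h_var, r2)`.
#' @export
stats_vector <- function(matrix, monomorphic = "skip", max_pairs = Inf) {
  ml <- multilocus_homozygosity(matrix)
  c(he = expected_heterozygosity(matrix),
    fis = fixation_index(matrix, monomorphic = monomorphic),
    h_mean = ml$h_mean,
    h_var = ml$h_var,
    r2 = mean_r2(matrix, max_pairs = max_pairs))
}
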