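#' Prior configuration for the simulation model
#'
#' Uniform priors for the parameters drawn anew for every simulated dataset:
#' the effective size `ne` (discrete uniform), the number of generations of
#' random mating `t` (discrete uniform), and the population mutation rate
#' `theta` (log-uniform over its bounds; the two default bounds span two
#' orders of magnitude, for which the log scale is the scale-neutral
#' reading). The model supports `ne` in `[4, 400]`; the default working
#' prior is `[50, 150]`.
#'
#' @param ne_low,ne_high integer bounds on Ne (default 50, 150; must lie in
#'   `[4, 400]`).
#' @param t_low,t_high integer bounds on the generation count (default 2, 8).
#' @param theta_low,theta_high bounds on the population mutation rate
#'   (defaults `4.8e-5`, `4.8e-3`).
#' @param mu per-locus per-generation mutation rate (default `1.2e-8`).
#' @param trials_J number of simulated datasets in the reference table
#'   (default `2e4`).
#' @param theta_scale `"log"` (default) or `"linear"` sampling of theta.
#' @return a `prior_config` list.
#' @export
prior_config <- function(ne_low = 50L, ne_high = 150L,
                         t_low = 2L, t_high = 8L,
                         theta_low = 4.8e-5, theta_high = 4.8e-3,
                         mu = 1.2e-8, trials_J = 20000L,
                         theta_scale = c("log", "linear")) {
  theta_scale <- match.arg(theta_scale)
  ne_low <- as.integer(ne_low); ne_high <- as.integer(ne_high)
  t_low <- as.integer(t_low); t_high <- as.integer(t_high)
  if (ne_low < 4L || ne_low > ne_high || ne_high > 400L) {
    stop("Ne prior bounds must satisfy 4 <= ne_low <= ne_high <= 400",
         call. = FALSE)
  }
  if (t_low < 2L || t_low > t_high) {
    stop("duration bounds must satisfy 2 <= t_low <= t_high", call. = FALSE)
  }
  if (theta_low <= 0 || theta_low > theta_high) {
    stop("theta bounds must satisfy 0 < theta_low <= theta_high",
         call. = FALSE)
  }
  if (trials_J < 1) stop("trials_J must be >= 1", call. = FALSE)
  structure(list(ne_low = ne_low, ne_high = ne_high,
                 t_low = t_low, t_high = t_high,
                 theta_low = theta_low, theta_high = theta_high,
                 mu = mu, trials_J = as.integer(trials_J),
                 theta_scale = theta_scale),
            class = "prior_config")
}

#' Draw one parameter triple from the prior
#'
#' Uses the current RNG stream. `ne` and `t` are discrete uniform over their
#' bounds; `theta` is log-uniform (or linear-uniform, per the config).
#'
#' @param cfg a [prior_config()].
#' @return named list `(ne, t, theta)`.
#' @export
draw_prior <- function(cfg) {
  ne <- if (cfg$ne_low == cfg$ne_high) cfg$ne_low else
    sample(cfg$ne_low:cfg$ne_high, 1L)
  t <- if (cfg$t_low == cfg$t_high) cfg$t_low else
    sample(cfg$t_low:cfg$t_high, 1L)
  theta <- if (cfg$theta_scale == "log") {
    exp(stats::runif(1, log(cfg$theta_low), log(cfg$theta_high)))
  } else {
    stats::runif(1, cfg$theta_low, cfg$theta_high)
  }
  list(ne = ne, t = t, theta = theta)
}

#' Initialize a two-sex population from the neutral frequency spectrum
#'
#' Creates `ne/2` males and `ne/2` females (an odd `ne` is rounded up to the
#' next even number with a warning). Each locus receives an initial allele-1
#' frequency drawn from the neutral-equilibrium folded frequency spectrum on
#' the grid `x in {1/(2 ne), ..., 1 - 1/(2 ne)}` with weight proportional to
#' `1/x + 1/(1-x)` (the symmetrized coalescent spectrum), conditioned on the
#' minor frequency being at least `maf_floor`, so every locus starts
#' polymorphic to match a MAF-filtered observed sample. Genotypes are then
#' assigned by independent Bernoulli draws of each allele at that frequency
#' (a Hardy-Weinberg draw). Because genotypes are unordered, the population
#' is stored as an allele-1 dosage matrix (0/1/2 per locus and individual;
#' loci-major, so one individual's genome is a contiguous column).
#' `theta` is recorded as the polymorphism-scale parameter but does not
#' alter the conditioned spectrum's shape.
#'
#' @param ne target population size (individuals); even, at least 4.
#' @param theta population mutation rate, recorded on the population.
#' @param L number of loci.
#' @param maf_floor minimum initial minor allele frequency in `[0, 0.5]`.
#' @return a `wf_population` list: dosage matrix `geno` (`L x ne`, columns
#'   1..`n_male` are males), `n_male`, `theta`.
#' @export
init_population <- function(ne, theta, L, maf_floor = 0.05) {
  if (ne %% 2L == 1L) {
    warning("odd ne rounded up to the next even number", call. = FALSE)
    ne <- ne + 1L
  }
  if (ne < 4L) stop("ne must be at least 4", call. = FALSE)
  p0 <- sample_init_freqs(ne, L, maf_floor)
  pm <- base::matrix(p0, L, ne)  # column-major recycling: column = p0
  # Hardy-Weinberg dosage drawn with a single uniform per cell via the
  # genotype-frequency partition ((1-p)^2, 2p(1-p), p^2)
  q2 <- (1 - pm)^2
  u <- stats::runif(ne * L)
  geno <- (u > q2) + (u > q2 + 2 * pm * (1 - pm))
  pop <- list(
    geno = base::matrix(as.integer(geno), L, ne),
    n_male = ne %/% 2L,
    theta = theta
  )
  class(pop) <- "wf_population"
  pop
}

# Grid and weights of the folded neutral spectrum conditioned on the MAF
# floor; shared by the sampler and the analytic expectation used in tests.
init_freq_grid <- function(ne, maf_floor) {
  x <- seq_len(2L * ne - 1L) / (2L * ne)
  w <- 1 / x + 1 / (1 - x)
  keep <- pmin(x, 1 - x) >= maf_floor
  if (!any(keep)) {
    # floor above the grid's reach (e.g. 0.5 exactly between grid points):
    # fall back to the grid point(s) closest to balanced frequency
    keep <- abs(x - 0.5) == min(abs(x - 0.5))
  }
  list(x = x[keep], w = w[keep] / sum(w[keep]))
}

sample_init_freqs <- function(ne, L, maf_floor) {
  g <- init_freq_grid(ne, maf_floor)
  if (length(g$x) == 1L) rep(g$x, L) else
    sample(g$x, L, replace = TRUE, prob = g$w)
}

#' Expected initial heterozygosity of the conditioned spectrum
#'
#' Direct summation of `2 x (1 - x)` over the conditioned frequency grid;
#' the analytic expectation matched by [init_population()].
#'
#' @inheritParams init_population
#' @return scalar expectation.
#' @export
init_expected_he <- function(ne, maf_floor = 0.05) {
  g <- init_freq_grid(ne, maf_floor)
  sum(2 * g$x * (1 - g$x) * g$w)
}

#' Advance the population one non-overlapping generation
#'
#' Random mating with two allogamous sexes: each of `n_out` offspring draws
#' a uniform-random father and a uniform-random mother and inherits one
#' uniformly chosen allele from each parent at every locus (free
#' recombination: transmissions are independent across loci, but all of an
#' offspring's paternal alleles come from the same father, which is what
#' generates linkage disequilibrium at finite size). Each transmitted
#' allele mutates (flips state) with probability `mu`. Offspring sexes are
#' assigned to keep male and female counts equal.
#'
#' In dosage form the transmitted paternal allele at a locus is Bernoulli
#' with success probability `dosage/2` of the father (0, 1/2 or 1): a
#' homozygote transmits its allele surely, a heterozygote a coin flip.
#' Transmission runs in a small compiled kernel on the current RNG stream;
#' for appreciable mutation rates (`mu >= 1e-3`) the two alleles are
#' instead sampled explicitly in R so that per-allele mutation flips stay
#' exact.
#'
#' @param pop a population from [init_population()].
#' @param mu per-allele per-generation mutation probability.
#' @param n_out size of the offspring cohort (default: same as parents).
#' @return the next-generation `wf_population`.
#' @export
advance_generation <- function(pop, mu = 0, n_out = NULL) {
  n_parent <- ncol(pop$geno)
  if (is.null(n_out)) n_out <- n_parent
  if (n_out %% 2L == 1L) n_out <- n_out + 1L
  L <- nrow(pop$geno)
  nm <- pop$n_male
  if (mu >= 1e-3) {
    # dense-mutation path: explicit alleles, exact iid Bernoulli(mu) flips
    fathers <- sample.int(nm, n_out, replace = TRUE)
    mothers <- nm + sample.int(n_parent - nm, n_out, replace = TRUE)
    n <- n_out * L
    half_pat <- pop$geno[, fathers, drop = FALSE] / 2
    half_mat <- pop$geno[, mothers, drop = FALSE] / 2
    pat <- flip_alleles(stats::runif(n) < half_pat, mu)
    mat <- flip_alleles(stats::runif(n) < half_mat, mu)
    geno <- base::matrix(as.integer(pat + mat), L, n_out)
  } else {
    geno <- advance_geno(pop$geno, nm, n_out)
    if (mu > 0) geno <- mutate_dosages(geno, mu)
  }
  structure(list(geno = geno, n_male = n_out %/% 2L, theta = pop$theta),
            class = "wf_population")
}

# Exact iid Bernoulli(mu) state flips: draw the Binomial(n, mu) number of
# flips, then flip that many distinct uniformly chosen positions (the
# exchangeable construction of iid flips; O(k) for the tiny mu regime).
flip_alleles <- function(a, mu) {
  n <- length(a)
  k <- stats::rbinom(1L, n, mu)
  if (k > 0) {
    idx <- sample.int(n, k)
    a[idx] <- !a[idx]
  }
  a
}

# Per-allele mutation applied at the dosage level: each of the 2n allele
# slots flips with probability mu; a flip event at a cell hits an allele
# "1" with probability dosage/2 (exact up to the O(mu^2) chance of two
# flips in one cell, negligible at the tiny rates this path serves).
mutate_dosages <- function(geno, mu) {
  n <- length(geno)
  k <- stats::rbinom(1L, 2L * n, mu)
  if (k > 0) {
    idx <- sample.int(n, min(k, n))
    d <- geno[idx]
    was_one <- stats::runif(length(idx)) < d / 2
    geno[idx] <- d + ifelse(was_one, -1, 1)
  }
  geno
}

#' Simulate one sampled dataset at known parameters
#'
#' Initializes a population of size `ne` from the conditioned neutral
#' spectrum, mates it at random for `t` generations, produces one further
#' progeny cohort from the generation-`t` adults, and samples `S` of those
#' progeny without replacement. When `S` exceeds `ne`, the progeny cohort
#' is enlarged to `S` offspring (the number of progeny a population
#' produces is not bounded by the number of breeders), so samples larger
#' than the effective size are supported. Uses the current RNG stream.
#'
#' @inheritParams init_population
#' @param t generations of random mating before sampling.
#' @param S number of individuals sampled from the final progeny cohort.
#' @param mu per-allele per-generation mutation probability.
#' @return a [genotype_matrix()] of dimension `S x L`.
#' @export
simulate_sample <- function(ne, t, theta, S, L, mu = 1.2e-8,
                            maf_floor = 0.05) {
  pop <- init_population(ne, theta, L, maf_floor)
  for (g in seq_len(t)) pop <- advance_generation(pop, mu)
  cohort <- advance_generation(pop, mu, n_out = max(ncol(pop$geno), S))
  pick <- sample.int(ncol(cohort$geno), S)
  genotype_matrix(t(cohort$geno[, pick, drop = FALSE]))
}

# Simulate a sample whose L loci are ascertained on sample-level MAF:
# a surplus of loci (1.6 L + 4) is simulated within one population (so all
# loci share the pedigree and its linkage disequilibrium), loci whose
# sampled minor allele frequency falls below `sample_maf` are discarded
# exactly as filter_maf() would discard them, and a random subset of L
# passing loci is kept. Returns NULL when fewer than L loci pass (callers
# redraw). With sample_maf = 0 this is plain simulate_sample().
ascertained_sample <- function(ne, t, theta, S, L, mu, maf_floor,
                               sample_maf) {
  if (sample_maf <= 0) {
    return(suppressWarnings(
      simulate_sample(ne, t, theta, S, L, mu = mu, maf_floor = maf_floor)))
  }
  L_sim <- as.integer(ceiling(1.6 * L)) + 4L
  m <- suppressWarnings(
    simulate_sample(ne, t, theta, S, L_sim, mu = mu, maf_floor = maf_floor))
  p <- colMeans(m$dosage) / 2
  pass <- which(pmin(p, 1 - p) >= sample_maf)
  if (length(pass) < L) return(NULL)
  keep <- if (length(pass) > L) sort(sample(pass, L)) else pass
  m[, keep]
}

#' Build the ABC reference table
#'
#' Draws `trials_J` parameter triples from the prior and simulates, for
#' each, a dataset with the same dimensions `S x L` as the (filtered)
#' observed sample, recording the five summary statistics. Each trial runs
#' on its own pre-derived L'Ecuyer-CMRG substream, so the table is
#' bit-identical for a given `seed` regardless of `workers`. A trial whose
#' sample has no usable LD pair (or no polymorphic locus) is redrawn within
#' its substream; a warning is raised if more than 1% of trials needed
#' redraws.
#'
#' Observed data reach the estimator only after the minor-allele-frequency
#' filter, so their loci are ascertained on sample MAF; each simulated
#' sample undergoes the same ascertainment (`sample_maf`): extra loci are
#' simulated within the same population (sharing its pedigree, hence its
#' linkage disequilibrium), loci whose sampled MAF falls below the cutoff
#' are discarded exactly as [filter_maf()] would, and a random subset of
#' `L` passing loci is kept. Without this the simulated samples carry
#' drift-depleted loci the observed data cannot contain, which biases the
#' match. Set `sample_maf = 0` to disable.
#'
#' @param cfg a [prior_config()].
#' @param S,L dimensions of the observed sample to match.
#' @param maf_floor minimum initial minor allele frequency.
#' @param sample_maf sample-level MAF ascertainment applied to each
#'   simulated sample (default: `maf_floor`, mirroring the filter applied
#'   to the observed data).
#' @param seed integer seed.
#' @param workers number of parallel processes (forked; 1 = serial).
#' @param max_pairs optional cap on LD pairs per sample (see [mean_r2()]).
#' @return a `reference_table`: data.frame with columns `ne`, `t`, `theta`,
#'   `he`, `fis`, `h_mean`, `h_var`, `r2`, plus attributes `S`, `L`, `seed`,
#'   `n_redrawn`.
#' @export
build_reference_table <- function(cfg, S, L, maf_floor = 0.05,
                                  sample_maf = maf_floor,
                                  seed = 1L, workers = 1L,
                                  max_pairs = Inf) {
  J <- cfg$trials_J
  streams <- derive_streams(seed, J)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  one_trial <- function(i) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    redraws <- 0L
    repeat {
      par <- draw_prior(cfg)
      # odd ne draws are legitimate; the size round-up inside
      # init_population is silent in ascertained_sample
      m <- ascertained_sample(par$ne, par$t, par$theta, S, L,
                              mu = cfg$mu, maf_floor = maf_floor,
                              sample_maf = sample_maf)
      st <- if (is.null(m)) NULL else
        tryCatch(stats_vector(m, max_pairs = max_pairs),
                 error = function(e) NULL)
      if (!is.null(st)) {
        return(c(ne = par$ne, t = par$t, theta = par$theta, st,
                 redraws = redraws))
      }
      redraws <- redraws + 1L
      if (redraws > 100L) {
        stop("trial produced no summarisable sample after 100 redraws",
             call. = FALSE)
      }
    }
  }
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(J), one_trial, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(J), one_trial)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  n_redrawn <- sum(tab$redraws > 0)
  if (n_redrawn > 0.01 * J) {
    warning(sprintf("%d of %d trials needed redraws (no usable LD pair)",
                    n_redrawn, J), call. = FALSE)
  }
  tab$redraws <- NULL
  structure(tab, S = S, L = L, seed = seed, n_redrawn = n_redrawn,
            class = c("reference_table", "data.frame"))
}

# One L'Ecuyer-CMRG substream per trial, derived sequentially from `seed`
# before any work is dispatched: results cannot depend on worker count.
# Restores the caller's RNG state on exit.
derive_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

#' Export a reference table as TSV
#'
#' @param table a `reference_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
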