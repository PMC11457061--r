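#' Specification of a synthetic GENEPOP dataset
#'
#' Describes one deterministic synthetic dataset: Wright-Fisher parameters
#' for the generating population, sample dimensions, optional uniform
#' missingness, and a seed. Used to produce test data at known true Ne
#' without any external files.
#'
#' @param ne true effective size of the generating population.
#' @param t generations of random mating before sampling (default 5).
#' @param S,L sample dimensions.
#' @param mu mutation rate.
#' @param maf_floor minimum initial minor allele frequency.
#' @param theta population mutation rate recorded in the simulation.
#' @param missing_rate_individuals,missing_rate_loci per-cell masking rates
#'   in `[0, 1]`; cells are masked independently with combined probability
#'   `1 - (1 - ri) (1 - rl)`.
#' @param seed integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(ne = 100L, t = 5L, S = 50L, L = 40L,
                         mu = 1.2e-8, maf_floor = 0.05, theta = 4.8e-4,
                         missing_rate_individuals = 0,
                         missing_rate_loci = 0,
                         seed = 1L) {
  if (missing_rate_individuals < 0 || missing_rate_individuals > 1 ||
      missing_rate_loci < 0 || missing_rate_loci > 1) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if (ne < 4 || S < 1 || L < 1 || t < 1) {
    stop("dimensions must be positive (ne >= 4)", call. = FALSE)
  }
  structure(list(ne = as.integer(ne), t = as.integer(t), S = as.integer(S),
                 L = as.integer(L), mu = mu, maf_floor = maf_floor,
                 theta = theta,
                 missing_rate_individuals = missing_rate_individuals,
                 missing_rate_loci = missing_rate_loci,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate one synthetic GENEPOP dataset
#'
#' Simulates a sample at the spec's parameters, injects uniform random
#' missingness at the combined cell rate, and serializes to GENEPOP text.
#' Deterministic: the same spec always yields the same file.
#'
#' When `maf_floor > 0` the emitted loci are conditioned to pass the
#' sample-level MAF floor (a surplus of loci is simulated in the same
#' population and a random subset of passing loci kept), so the nominal
#' `L` is the number of *analysable* loci -- a dataset advertised as 80
#' loci yields 80 loci after the estimator's MAF filter, matching how
#' locus panels are reported in practice. Set `maf_floor = 0` for raw,
#' unascertained panels.
#'
#' @param spec a [fixture_spec()].
#' @param path optional file to write.
#' @return GENEPOP text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
make_dataset <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  m <- with_preserved_rng({
    set.seed(spec$seed)
    m <- NULL
    for (attempt in 1:100) {
      m <- ascertained_sample(spec$ne, spec$t, spec$theta, spec$S, spec$L,
                              mu = spec$mu, maf_floor = spec$maf_floor,
                              sample_maf = spec$maf_floor)
      if (!is.null(m)) break
    }
    if (is.null(m)) {
      stop("could not assemble enough loci passing the MAF floor",
           call. = FALSE)
    }
    rate <- 1 - (1 - spec$missing_rate_individuals) *
      (1 - spec$missing_rate_loci)
    if (rate > 0) {
      mask <- stats::runif(length(m$dosage)) < rate
      d <- m$dosage
      d[mask] <- NA_integer_
      m <- genotype_matrix(d, m$individual_ids, m$locus_ids,
                           m$population_label)
    }
    m
  })
  m$population_label <- sprintf("synthetic WF sample (true Ne = %d, seed %d)",
                                spec$ne, spec$seed)
  out <- write_genepop(m, allele_width = 2L, path = path)
  if (is.null(path)) out else invisible(out)
}

#' Generate a grid of synthetic datasets with a manifest
#'
#' Cartesian grid over true Ne, sample size and locus count, with
#' `replicates` files per cell and a distinct derived seed per file. Writes
#' GENEPOP files to `dir` and a tab-separated manifest recording each
#' file's true parameters.
#'
#' @param ne_values,S_values,L_values grid values.
#' @param replicates files per grid cell.
#' @param seed base seed; file seeds are derived deterministically from it.
#' @param dir output directory (created if needed).
#' @param t generations of mating per dataset (single value recycled).
#' @return data.frame manifest (also written to `dir/manifest.tsv`) with
#'   columns `file`, `ne`, `S`, `L`, `replicate`, `t`, `seed`.
#' @export
make_grid <- function(ne_values, S_values, L_values, replicates = 1L,
                      seed = 1L, dir = tempfile("fixture_grid_"),
                      t = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      L = L_values, S = S_values, ne = ne_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    fseed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    file <- sprintf("ne%d_S%d_L%d_rep%d.gen", g$ne, g$S, g$L, g$replicate)
    spec <- fixture_spec(ne = g$ne, t = t, S = g$S, L = g$L, seed = fseed)
    make_dataset(spec, path = file.path(dir, file))
    data.frame(file = file, ne = g$ne, S = g$S, L = g$L,
               replicate = g$replicate, t = t, seed = fseed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

# Evaluate expr without disturbing the caller's RNG state.
with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}
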