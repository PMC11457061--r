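# Replicated parameter-recovery experiments shared by the acceptance tests.
# Each replicate simulates a dataset at known true Ne (with its own seed and
# a generation count cycling over the prior's support), then estimates Ne
# with a freshly built reference table matched to the replicate's filtered
# dimensions.

recovery_runs <- function(true_ne, prior, S_values, L_values, reps,
                          J, frac, base_seed) {
  grid <- expand.grid(rep = seq_len(reps), L = L_values, S = S_values)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    seed_k <- base_seed + 131L * k
    t_k <- 2L + (seed_k %% 7L)  # cycles over the prior's 2..8 support
    m <- read_genepop(make_dataset(
      fixture_spec(ne = true_ne, t = t_k, S = g$S, L = g$L,
                   seed = seed_k)))
    est <- suppressWarnings(suppressMessages(estimate_ne(
      m,
      priors = prior_config(ne_low = prior[1], ne_high = prior[2],
                            trials_J = J),
      abc = abc_config(acceptance_fraction = frac),
      seed = seed_k + 1L, quiet = TRUE)))
    data.frame(S = g$S, L = g$L, rep = g$rep,
               median = est$median, lo = est$ci_low, hi = est$ci_high,
               width = est$ci_high - est$ci_low)
  })
  do.call(rbind, out)
}

# lazily computed, cached across acceptance test blocks
experiment_cache <- new.env(parent = emptyenv())

cached_runs <- function(name, thunk) {
  if (!exists(name, experiment_cache)) {
    assign(name, thunk(), experiment_cache)
  }
  get(name, experiment_cache)
}

ne100_runs <- function() {
  cached_runs("ne100", function() {
    recovery_runs(true_ne = 100, prior = c(50, 150),
                  S_values = c(50, 100, 200), L_values = c(80, 160),
                  reps = 7, J = 800L, frac = 0.0625, base_seed = 41000L)
  })
}

# the Ne = 200, S = 50 cells feed a folded statistic (mean absolute
# percent deviation), which unlike the signed grand means does not average
# its Monte-Carlo noise away across replicates; these cells therefore run
# at the full desk-scale table size J = 2000 (100 accepted)
ne200_runs <- function() {
  cached_runs("ne200", function() {
    recovery_runs(true_ne = 200, prior = c(150, 250),
                  S_values = 50, L_values = c(80, 160),
                  reps = 5, J = 2000L, frac = 0.05, base_seed = 62000L)
  })
}
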