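#' Estimate effective population size from one genotype sample
#'
#' The full pipeline: missing-data filter, MAF filter, observed summary
#' statistics, reference table of Wright-Fisher simulations matched to the
#' filtered sample's dimensions, rejection on standardized Euclidean
#' distance, weighted local linear regression on Box-Cox transformed Ne,
#' and a weighted posterior summary. Fully reproducible given `seed`
#' (independent of `workers`).
#'
#' @param matrix a [genotype_matrix()] (e.g. from [read_genepop()]).
#' @param priors a [prior_config()].
#' @param filters a [filter_config()].
#' @param abc an [abc_config()].
#' @param seed integer seed for the reference table.
#' @param workers forked parallel workers for the simulations.
#' @param max_pairs optional LD pair cap (see [mean_r2()]).
#' @param table optional pre-built `reference_table` whose `S`/`L`
#'   attributes match the filtered sample; when supplied the simulation
#'   step is skipped (used to amortize tables over replicate analyses of
#'   samples with identical dimensions).
#' @param quiet suppress progress messages.
#' @return an `ne_estimate` (see [summarize_posterior()]) with extra fields
#'   `observed_stats`, `S`, `L`, `seed`, and the three configs.
#' @export
estimate_ne <- function(matrix,
                        priors = prior_config(),
                        filters = filter_config(),
                        abc = abc_config(),
                        seed = 1L, workers = 1L,
                        max_pairs = Inf,
                        table = NULL,
                        quiet = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  m <- stage("filter_missing", filter_missing(matrix, filters, quiet = quiet))
  m <- stage("filter_maf", filter_maf(m, filters$min_maf, quiet = quiet))
  S <- n_ind(m); L <- n_loci(m)
  if (L < 2) stop("[filter] fewer than 2 loci remain", call. = FALSE)
  obs <- stage("summary_stats",
               stats_vector(m, monomorphic = "error", max_pairs = max_pairs))
  if (is.null(table)) {
    if (!quiet) {
      message(sprintf("simulating reference table: J = %d at %d x %d",
                      priors$trials_J, S, L))
    }
    table <- stage("wf_simulator",
                   build_reference_table(priors, S, L,
                                         maf_floor = filters$min_maf,
                                         seed = seed, workers = workers,
                                         max_pairs = max_pairs))
  } else {
    if (attr(table, "S") != S || attr(table, "L") != L) {
      stop(sprintf(
        "[abc] supplied reference table is %d x %d but the filtered sample is %d x %d",
        attr(table, "S"), attr(table, "L"), S, L), call. = FALSE)
    }
  }
  sel <- stage("abc_select", select_accepted(table, obs, abc))
  adj <- stage("abc_regression",
               local_linear_adjust(sel, abc,
                                   ne_bounds = c(priors$ne_low,
                                                 priors$ne_high)))
  est <- summarize_posterior(adj$samples, adj$weights,
                             n_accepted = length(adj$samples),
                             delta = sel$delta)
  est$observed_stats <- obs
  est$S <- S
  est$L <- L
  est$seed <- seed
  est$adjusted <- adj$adjusted
  est$coefficients <- adj$coefficients
  est$priors <- priors
  est$filters <- filters
  est$abc <- abc
  est
}

#' Serialize an estimate as a JSON report
#'
#' Deterministic given the estimate: no timestamps or machine identifiers,
#' so identical seeds produce byte-identical reports.
#'
#' @param est an `ne_estimate` from [estimate_ne()].
#' @param path optional output file.
#' @param include_samples include the full posterior sample vector.
#' @return the JSON string, invisibly.
#' @export
report_json <- function(est, path = NULL, include_samples = FALSE) {
  payload <- list(
    median_ne = round(est$median, 4),
    ci_low = round(est$ci_low, 4),
    ci_high = round(est$ci_high, 4),
    n_accepted = est$n_accepted,
    delta = round(est$delta_used, 6),
    adjusted = isTRUE(est$adjusted),
    S = est$S,
    L = est$L,
    seed = est$seed,
    observed_stats = as.list(round(est$observed_stats, 6)),
    config = list(
      priors = unclass(est$priors),
      filters = unclass(est$filters),
      abc = unclass(est$abc)
    )
  )
  if (include_samples) {
    payload$posterior_samples <- round(est$posterior_samples, 4)
  }
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(as.character(txt))
}
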