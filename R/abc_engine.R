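#' ABC configuration
#'
#' Settings of the rejection + local-linear-regression step: the fraction of
#' reference-table records accepted (the distance threshold `delta` is set
#' to this quantile of the distances), the Box-Cox exponent applied to Ne
#' before regression, and how the five statistics are put on a common scale
#' before the Euclidean distance is taken.
#'
#' @param acceptance_fraction fraction in `(0, 1]` of trials accepted
#'   (default 0.02).
#' @param boxcox_lambda Box-Cox exponent for Ne (default -0.2).
#' @param standardization `"mad"` (default; centre by median, scale by
#'   median absolute deviation over the reference table) or `"none"` (raw
#'   Euclidean distance).
#' @return an `abc_config` list.
#' @export
abc_config <- function(acceptance_fraction = 0.02,
                       boxcox_lambda = -0.2,
                       standardization = c("mad", "none")) {
  standardization <- match.arg(standardization)
  if (acceptance_fraction <= 0 || acceptance_fraction > 1) {
    stop("acceptance_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(acceptance_fraction = acceptance_fraction,
                 boxcox_lambda = boxcox_lambda,
                 standardization = standardization),
            class = "abc_config")
}

stat_names <- c("he", "fis", "h_mean", "h_var", "r2")

#' Standardize reference-table statistics and the observed target
#'
#' Centres each of the five statistics by its reference-table median and
#' scales by its median absolute deviation (as computed by [stats::mad()],
#' so a standardized column has MAD 1), applying the identical transform to
#' the observed vector. A statistic whose scale is zero carries no distance
#' information and is dropped with a warning.
#'
#' @param table a `reference_table` from [build_reference_table()].
#' @param target named numeric vector from [stats_vector()].
#' @param method `"mad"` or `"none"`.
#' @return list with `table_stats` (matrix, J x kept-statistics), `target`
#'   (vector), `kept` (character names of retained statistics).
#' @export
standardize_stats <- function(table, target, method = "mad") {
  ts <- as.matrix(as.data.frame(table)[stat_names])
  tg <- target[stat_names]
  if (method == "none") {
    return(list(table_stats = ts, target = tg, kept = stat_names))
  }
  ctr <- apply(ts, 2, stats::median)
  scl <- apply(ts, 2, stats::mad)
  keep <- scl > 0
  if (!any(keep)) {
    stop("every summary statistic is constant over the reference table",
         call. = FALSE)
  }
  if (!all(keep)) {
    warning(sprintf("statistic(s) %s constant over the reference table; %s",
                    paste(stat_names[!keep], collapse = ", "),
                    "dropped from the distance"), call. = FALSE)
  }
  ts <- sweep(sweep(ts[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep],
              "/")
  tg <- (tg[keep] - ctr[keep]) / scl[keep]
  list(table_stats = ts, target = tg, kept = stat_names[keep])
}

#' Rejection step: accept the closest simulations
#'
#' Computes the Euclidean distance between every (standardized) simulated
#' statistic vector and the observed one, sets the threshold `delta` to the
#' `acceptance_fraction` quantile of the distances, and accepts every
#' record at distance `<= delta` (ties included).
#'
#' @param table a `reference_table`.
#' @param target observed statistic vector ([stats_vector()]).
#' @param cfg an [abc_config()].
#' @return list: `accepted` (data.frame of accepted records), `d` (their
#'   distances), `delta`, `std` (the standardization object), `dist_all`
#'   (all J distances).
#' @export
select_accepted <- function(table, target, cfg = abc_config()) {
  std <- standardize_stats(table, target, cfg$standardization)
  diff <- sweep(std$table_stats, 2, std$target)
  d <- sqrt(rowSums(diff^2))
  delta <- stats::quantile(d, cfg$acceptance_fraction, names = FALSE)
  idx <- which(d <= delta)
  if (length(idx) < 20) {
    stop(paste("fewer than 20 simulations accepted;",
               "increase trials_J or acceptance_fraction"), call. = FALSE)
  }
  if (length(idx) < 100) {
    warning(sprintf(
      "only %d simulations accepted; the regression may be unstable",
      length(idx)), call. = FALSE)
  }
  list(accepted = as.data.frame(table)[idx, , drop = FALSE],
       d = d[idx], delta = delta, std = std, dist_all = d)
}

#' Box-Cox transform and its inverse
#'
#' `boxcox(x, lambda) = (x^lambda - 1)/lambda` for `lambda != 0`, `log(x)`
#' for `lambda = 0`; strictly increasing in `x > 0` for every `lambda`.
#' `inv_boxcox` is the exact inverse on the range where `1 + lambda*y > 0`.
#'
#' @param x positive values.
#' @param y transformed values.
#' @param lambda exponent (the estimator uses -0.2 for Ne).
#' @return transformed (or back-transformed) numeric vector.
#' @export
boxcox <- function(x, lambda = -0.2) {
  if (any(x <= 0)) stop("boxcox requires x > 0", call. = FALSE)
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox
#' @export
inv_boxcox <- function(y, lambda = -0.2) {
  if (lambda == 0) return(exp(y))
  base <- 1 + lambda * y
  if (any(base <= 0)) {
    stop("inv_boxcox input outside the transform's range (1 + lambda*y <= 0)",
         call. = FALSE)
  }
  base^(1 / lambda)
}

#' Local linear regression adjustment of accepted Ne values
#'
#' The Beaumont-style correction: accepted records receive Epanechnikov
#' weights `w = 1 - (d/delta)^2`; Box-Cox transformed Ne is regressed by
#' weighted least squares on the standardized statistics (with intercept);
#' each accepted value is adjusted to `yhat(target) + residual` and mapped
#' back through the inverse Box-Cox, clamped into the prior support. If the
#' design is rank-deficient the function falls back to pure rejection
#' (unadjusted accepted Ne values) with a warning. Adjusted values whose
#' back-transform diverges (transformed value outside the inverse's range)
#' are clamped to the upper prior bound.
#'
#' @param sel result of [select_accepted()].
#' @param cfg an [abc_config()].
#' @param ne_bounds numeric length-2: prior support to clamp into.
#' @return list: `samples` (posterior Ne values), `weights`, `coefficients`
#'   (or `NULL` under the rejection fallback), `adjusted` (logical).
#' @export
local_linear_adjust <- function(sel, cfg = abc_config(),
                                ne_bounds = c(4, 400)) {
  acc <- sel$accepted
  d <- sel$d
  delta <- sel$delta
  w <- if (delta > 0) 1 - (d / delta)^2 else rep(1, length(d))
  # records exactly at the threshold get zero weight; keep them in the
  # posterior with a vanishing weight rather than dropping them
  w <- pmax(w, 1e-12)
  y <- boxcox(acc$ne, cfg$boxcox_lambda)
  # standardized accepted stats: reuse the table-wide transform
  Xs <- sel$std$table_stats[sel$dist_all <= sel$delta, , drop = FALSE]
  X <- cbind(intercept = 1, Xs)
  fit <- stats::lm.wfit(X, y, w)
  if (fit$rank < ncol(X) || any(is.na(fit$coefficients))) {
    warning("rank-deficient regression design; falling back to rejection",
            call. = FALSE)
    samples <- pmin(pmax(acc$ne, ne_bounds[1]), ne_bounds[2])
    return(list(samples = samples, weights = w, coefficients = NULL,
                adjusted = FALSE))
  }
  beta <- fit$coefficients
  yhat_target <- sum(beta * c(1, sel$std$target))
  y_adj <- yhat_target + fit$residuals
  lam <- cfg$boxcox_lambda
  base <- 1 + lam * y_adj
  samples <- numeric(length(y_adj))
  ok <- base > 0
  samples[ok] <- base[ok]^(1 / lam)
  # divergent back-transforms correspond to Ne beyond the upper bound
  samples[!ok] <- if (lam < 0) ne_bounds[2] else ne_bounds[1]
  samples <- pmin(pmax(samples, ne_bounds[1]), ne_bounds[2])
  list(samples = samples, weights = w, coefficients = beta, adjusted = TRUE)
}

#' Weighted posterior summary
#'
#' Weighted median and 2.5%/97.5% weighted quantiles of the posterior Ne
#' samples. Quantiles use the inverted-CDF rule on cumulative normalized
#' weights: `q(p)` is the smallest sample whose cumulative weight reaches
#' `p`.
#'
#' @param samples numeric posterior samples.
#' @param weights nonnegative weights (default: equal).
#' @param n_accepted,delta diagnostics recorded on the estimate.
#' @return an `ne_estimate` list: `median`, `ci_low`, `ci_high`,
#'   `posterior_samples`, `weights`, `n_accepted`, `delta_used`.
#' @export
summarize_posterior <- function(samples, weights = NULL,
                                n_accepted = length(samples),
                                delta = NA_real_) {
  if (length(samples) == 0) stop("no posterior samples", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(samples))
  qs <- weighted_quantile(samples, weights, c(0.025, 0.5, 0.975))
  structure(list(median = qs[2], ci_low = qs[1], ci_high = qs[3],
                 posterior_samples = samples, weights = weights,
                 n_accepted = n_accepted, delta_used = delta),
            class = "ne_estimate")
}

#' Weighted quantiles by the inverted-CDF rule
#'
#' @param x numeric values.
#' @param w nonnegative weights, at least one positive.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne estimate: median %.1f  (95%% interval %.1f - %.1f)\n",
              x$median, x$ci_low, x$ci_high))
  cat(sprintf("  accepted simulations: %d (delta = %.4g)\n",
              x$n_accepted, x$delta_used))
  invisible(x)
}
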