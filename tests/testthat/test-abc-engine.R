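# hand-built reference table with controllable statistics
synthetic_table <- function(J, f = NULL, sd_noise = 0, S = 50, L = 20,
                            ne_range = c(50, 150)) {
  vals <- seq(ne_range[1], ne_range[2])
  ne <- vals[sample.int(length(vals), J, replace = TRUE)]
  stats <- matrix(rnorm(J * 5), J, 5)
  colnames(stats) <- c("he", "fis", "h_mean", "h_var", "r2")
  if (!is.null(f)) {
    # make the statistics informative: stat1 is a linear image of
    # boxcox(ne) plus noise
    stats[, 1] <- f(ne) + rnorm(J, 0, sd_noise)
  }
  tab <- data.frame(ne = ne, t = 5L, theta = 1e-4, stats)
  structure(tab, S = S, L = L, seed = 0L,
            class = c("reference_table", "data.frame"))
}

test_that("box-cox transform: fixed point, round trip, monotonicity", {
  expect_equal(boxcox(1, -0.2), 0)
  for (x in c(4, 100, 400)) {
    expect_equal(inv_boxcox(boxcox(x, -0.2), -0.2), x)
  }
  expect_equal(inv_boxcox(boxcox(7, 0), 0), 7)
  xs <- boxcox(c(4, 50, 100, 400), -0.2)
  expect_true(all(diff(xs) > 0))
  expect_error(boxcox(0, -0.2), "x > 0")
  expect_error(inv_boxcox(10, -0.2), "range")
})

test_that("standardization gives MAD-1 columns and drops constant stats", {
  set.seed(12)
  tab <- synthetic_table(500)
  target <- stats_named(rnorm(5))
  std <- standardize_stats(tab, target)
  expect_equal(unname(apply(std$table_stats, 2, mad)), rep(1, 5))
  expect_equal(std$kept, c("he", "fis", "h_mean", "h_var", "r2"))
  # constant statistic -> dropped with a warning, distance uses the rest
  tab$r2 <- 1
  expect_warning(std2 <- standardize_stats(tab, target), "constant")
  expect_equal(std2$kept, c("he", "fis", "h_mean", "h_var"))
  # standardization changes which record is nearest when scales differ
  tab3 <- synthetic_table(200)
  tab3$h_var <- tab3$h_var * 1e3
  t3 <- stats_named(c(0, 0, 0, 0, 0))
  raw <- standardize_stats(tab3, t3, method = "none")
  d_raw <- sqrt(rowSums(sweep(raw$table_stats, 2, raw$target)^2))
  std3 <- standardize_stats(tab3, t3)
  d_std <- sqrt(rowSums(sweep(std3$table_stats, 2, std3$target)^2))
  expect_false(which.min(d_raw) == which.min(d_std) &&
                 isTRUE(all.equal(cor(d_raw, d_std), 1)))
})

test_that("rejection accepts the closest fraction, ties included", {
  set.seed(14)
  tab <- synthetic_table(1000)
  target <- stats_named(as.numeric(tab[17, 4:8]))
  sel <- suppressWarnings(   # < 100 accepted is fine at this toy size
    select_accepted(tab, target, abc_config(acceptance_fraction = 0.05)))
  expect_equal(min(sel$d), 0)            # the matching record has d = 0
  expect_gte(nrow(sel$accepted), 50)
  expect_equal(sel$delta, unname(quantile(sel$dist_all, 0.05)))
  # full acceptance keeps everything
  sel1 <- select_accepted(tab, target, abc_config(acceptance_fraction = 1))
  expect_equal(nrow(sel1$accepted), 1000)
  expect_equal(sel1$delta, max(sel1$dist_all))
  # too few accepted is an error
  expect_error(
    select_accepted(synthetic_table(100), target,
                    abc_config(acceptance_fraction = 0.05)),
    "fewer than 20")
})

test_that("weighted quantiles match the sort-and-accumulate oracle", {
  set.seed(15)
  x <- rnorm(1000)
  w <- rexp(1000)
  for (p in c(0.025, 0.1, 0.5, 0.9, 0.975)) {
    expect_equal(weighted_quantile(x, w, p),
                 oracle_weighted_quantile(x, w, p))
  }
})

test_that("posterior summaries behave on point masses and symmetry", {
  est <- summarize_posterior(rep(42, 30))
  expect_equal(est$median, 42)
  expect_equal(est$ci_low, 42)
  expect_equal(est$ci_high, 42)
  # symmetric samples with symmetric weights -> median at the centre
  x <- c(90, 95, 100, 105, 110)
  w <- c(1, 2, 3, 2, 1)
  expect_equal(summarize_posterior(x, w)$median, 100)
  expect_error(summarize_posterior(numeric(0)), "no posterior")
})

test_that("constant accepted Ne yields a constant posterior", {
  set.seed(16)
  tab <- synthetic_table(600, ne_range = c(100, 100))
  target <- stats_named(rnorm(5))
  sel <- suppressWarnings(
    select_accepted(tab, target, abc_config(acceptance_fraction = 0.1)))
  adj <- local_linear_adjust(sel, ne_bounds = c(50, 150))
  expect_true(all(abs(adj$samples - 100) < 1e-8))
})

test_that("an uninformative (constant) design falls back to rejection", {
  set.seed(17)
  tab <- synthetic_table(600)
  tab[, c("he", "fis", "h_mean", "h_var", "r2")] <- 1
  target <- stats_named(rep(1, 5))
  # all five statistics constant -> no distance information at all
  expect_error(suppressWarnings(select_accepted(tab, target)), "constant")
  # one varying statistic, constant within ties: rank-deficient design
  tab$he <- rep(c(1, 2), each = 300)
  target <- stats_named(c(1, 1, 1, 1, 1))
  sel <- suppressWarnings(
    select_accepted(tab, target, abc_config(acceptance_fraction = 0.3)))
  expect_warning(adj <- local_linear_adjust(sel, ne_bounds = c(50, 150)),
                 "rank-deficient")
  expect_false(adj$adjusted)
  expect_equal(sort(unique(adj$samples)), sort(unique(sel$accepted$ne)))
})

test_that("regression adjustment shrinks the posterior on a linear table", {
  set.seed(18)
  f <- function(ne) 2 * boxcox(ne, -0.2) + 1
  tab <- synthetic_table(4000, f = f, sd_noise = 0.02)
  true_ne <- 100
  target <- stats_named(c(f(true_ne), 0, 0, 0, 0))
  sel <- select_accepted(tab, target, abc_config(acceptance_fraction = 0.1))
  adj <- local_linear_adjust(sel, ne_bounds = c(50, 150))
  expect_true(adj$adjusted)
  rejection_spread <- var(sel$accepted$ne)
  adjusted_spread <- var(adj$samples)
  expect_lt(adjusted_spread, rejection_spread)
  # and the adjusted centre homes in on the true value
  expect_lt(abs(median(adj$samples) - true_ne),
            abs(median(sel$accepted$ne) - true_ne) + 5)
  # posterior support stays inside the prior bounds
  expect_gte(min(adj$samples), 50)
  expect_lte(max(adj$samples), 150)
})
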