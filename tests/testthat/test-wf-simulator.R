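# build a Hardy-Weinberg population at given allele frequency directly,
# bypassing the spectrum initialization, for drift-law checks
# (populations are loci-major: L rows, n individual columns)
hw_population <- function(n, L, p) {
  geno <- matrix(as.integer(rbinom(n * L, 2, p)), L, n)
  structure(list(geno = geno, n_male = n %/% 2L, theta = 0),
            class = "wf_population")
}

test_that("prior draws respect their bounds and distributions", {
  cfg <- prior_config()
  set.seed(1)
  draws <- replicate(5000, unlist(draw_prior(cfg)))
  expect_gte(min(draws["ne", ]), 50)
  expect_lte(max(draws["ne", ]), 150)
  expect_true(all(draws["t", ] %in% 2:8))
  expect_true(all(draws["theta", ] >= 4.8e-5 & draws["theta", ] <= 4.8e-3))
  # discrete-uniform ne: chi-square goodness of fit
  p_ne <- chisq.test(table(factor(draws["ne", ], levels = 50:150)))$p.value
  expect_gt(p_ne, 0.01)
  # log-uniform theta: KS against uniform on the log scale
  p_th <- suppressWarnings(
    ks.test(log(draws["theta", ]), "punif",
            log(4.8e-5), log(4.8e-3))$p.value)
  expect_gt(p_th, 0.01)
  # degenerate prior
  cfg1 <- prior_config(ne_low = 100, ne_high = 100)
  expect_true(all(replicate(20, draw_prior(cfg1)$ne) == 100))
})

test_that("prior_config rejects invalid bounds", {
  expect_error(prior_config(ne_low = 2), "4 <= ne_low")
  expect_error(prior_config(ne_low = 200, ne_high = 100), "ne_low")
  expect_error(prior_config(t_low = 1), "t_low")
  expect_error(prior_config(theta_low = 0), "theta")
})

test_that("initial frequencies follow the conditioned folded spectrum", {
  set.seed(3)
  # degenerate floor pins every locus at 1/2
  f05 <- neabc:::sample_init_freqs(100L, 500L, 0.5)
  expect_true(all(f05 == 0.5))
  # support: realized minor frequencies never fall under the floor
  f <- neabc:::sample_init_freqs(100L, 2000L, 0.05)
  expect_gte(min(pmin(f, 1 - f)), 0.05)
  # analytic oracle: mean heterozygosity of drawn frequencies matches the
  # explicit grid sum within 3 Monte-Carlo standard errors
  he <- 2 * f * (1 - f)
  expect_lt(abs(mean(he) - init_expected_he(100L, 0.05)),
            3 * sd(he) / sqrt(length(he)))
})

test_that("odd population sizes are rounded up with a warning", {
  set.seed(4)
  expect_warning(pop <- init_population(51, 1e-4, 5), "odd ne")
  expect_equal(ncol(pop$geno), 52L)
  expect_equal(nrow(pop$geno), 5L)
  expect_equal(pop$n_male, 26L)
})

test_that("generation advance conserves size and fixation is absorbing", {
  set.seed(5)
  pop <- hw_population(40, 6, 0.5)
  pop$geno[1, ] <- 2L  # locus 1 fixed for allele 1
  pop$geno[2, ] <- 0L  # locus 2 fixed for allele 2
  for (g in 1:5) pop <- advance_generation(pop, mu = 0)
  expect_equal(dim(pop$geno), c(6L, 40L))
  expect_true(all(pop$geno[1, ] == 2L))
  expect_true(all(pop$geno[2, ] == 0L))
  # mu = 0.5 scrambles transmission away from a fixed parent pool
  pop2 <- hw_population(200, 1, 1)
  off <- advance_generation(pop2, mu = 0.5)
  freq <- mean(off$geno) / 2
  expect_gt(freq, 0.35)
  expect_lt(freq, 0.65)
})

test_that("one-generation drift variance matches p(1-p)/(2Ne)", {
  set.seed(6)
  n <- 50
  reps <- 2000
  dp <- replicate(reps, {
    pop <- hw_population(n, 1, 0.5)
    p0 <- mean(pop$geno) / 2
    mean(advance_generation(pop, mu = 0)$geno) / 2 - p0
  })
  v <- var(dp)
  expected <- 0.5 * 0.5 / (2 * n)
  se <- v * sqrt(2 / (reps - 1))
  expect_lt(abs(v - expected), 3 * se + 0.1 * expected)
})

test_that("simulated samples have the requested shape, even when S > ne", {
  set.seed(7)
  m <- simulate_sample(100, 3, 1e-4, 50, 12)
  expect_equal(dim(m), c(50L, 12L))
  # the progeny cohort grows to cover samples larger than the census
  m2 <- simulate_sample(20, 2, 1e-4, 60, 8)
  expect_equal(dim(m2), c(60L, 8L))
})

test_that("reference tables are reproducible and worker-independent", {
  cfg <- prior_config(trials_J = 12L)
  t1 <- build_reference_table(cfg, 12, 6, seed = 9, workers = 1L)
  t2 <- build_reference_table(cfg, 12, 6, seed = 9, workers = 2L)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 12L)
  expect_named(as.data.frame(t1),
               c("ne", "t", "theta", "he", "fis", "h_mean", "h_var", "r2"))
  expect_true(all(t1$ne >= cfg$ne_low & t1$ne <= cfg$ne_high))
  t3 <- build_reference_table(cfg, 12, 6, seed = 10)
  expect_false(isTRUE(all.equal(as.data.frame(t1), as.data.frame(t3))))
})

test_that("LD in the reference table increases as Ne decreases", {
  cfg <- prior_config(ne_low = 10, ne_high = 300, trials_J = 150L)
  tab <- suppressWarnings(build_reference_table(cfg, 40, 20, seed = 11))
  # mean r2 rises with 1/ne under ascertainment and without
  expect_gt(cor(tab$r2, 1 / tab$ne, method = "spearman"), 0)
  # without the MAF ascertainment, drift also leaves its mark on sample
  # heterozygosity: He falls as 1/ne grows (ascertainment deliberately
  # removes most of this signal, so it is asserted on the raw table)
  tab0 <- suppressWarnings(
    build_reference_table(cfg, 40, 20, sample_maf = 0, seed = 11))
  expect_lt(cor(tab0$he, 1 / tab0$ne, method = "spearman"), 0)
  expect_gt(cor(tab0$r2, 1 / tab0$ne, method = "spearman"), 0)
})
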