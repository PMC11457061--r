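# Brute-force oracles: explicit loops over genotypes, no vectorization, no
# shared code with the package internals. Used to pin down the summary
# statistics on small matrices.

# random genotype matrix with optional missingness; loci guaranteed
# polymorphic when `polymorphic = TRUE`
random_matrix <- function(S, L, missing_rate = 0, polymorphic = TRUE) {
  repeat {
    p <- runif(L, 0.1, 0.9)
    d <- sapply(p, function(pp) rbinom(S, 2, pp))
    d <- matrix(as.integer(d), S, L)
    if (missing_rate > 0) {
      d[runif(S * L) < missing_rate] <- NA_integer_
    }
    called_ok <- all(colSums(!is.na(d)) >= 2)
    poly_ok <- !polymorphic || all(apply(d, 2, function(col) {
      v <- col[!is.na(col)]
      length(unique(v)) > 1 || any(v == 1)
    }))
    if (called_ok && poly_ok) return(genotype_matrix(d))
  }
}

oracle_he <- function(m) {
  d <- m$dosage
  tot <- 0
  for (l in seq_len(ncol(d))) {
    n1 <- 0; n_called <- 0
    for (s in seq_len(nrow(d))) {
      if (!is.na(d[s, l])) {
        n1 <- n1 + d[s, l]
        n_called <- n_called + 1
      }
    }
    p <- n1 / (2 * n_called)
    tot <- tot + 2 * p * (1 - p)
  }
  tot / ncol(d)
}

oracle_fis <- function(m, skip_monomorphic = FALSE) {
  d <- m$dosage
  ratios <- c()
  for (l in seq_len(ncol(d))) {
    col <- d[, l]
    col <- col[!is.na(col)]
    p <- sum(col) / (2 * length(col))
    he <- 2 * p * (1 - p)
    ho <- mean(col == 1)
    if (he > 0) {
      ratios <- c(ratios, ho / he)
    } else if (!skip_monomorphic) {
      stop("monomorphic locus in oracle_fis")
    }
  }
  1 - mean(ratios)
}

oracle_mlh <- function(m) {
  d <- m$dosage
  h <- numeric(nrow(d))
  for (s in seq_len(nrow(d))) {
    for (l in seq_len(ncol(d))) {
      if (!is.na(d[s, l]) && d[s, l] != 1) h[s] <- h[s] + 1
    }
  }
  list(h_mean = mean(h), h_var = var(h))
}

# Burrows composite LD for one pair, written directly from the genotype
# count definition over doubly-called individuals.
oracle_burrows_r <- function(m, i, j) {
  d <- m$dosage
  x <- c(); y <- c()
  for (s in seq_len(nrow(d))) {
    if (!is.na(d[s, i]) && !is.na(d[s, j])) {
      x <- c(x, d[s, i]); y <- c(y, d[s, j])
    }
  }
  n <- length(x)
  if (n < 2) return(NA_real_)
  pa <- sum(x) / (2 * n)
  pb <- sum(y) / (2 * n)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1) return(NA_real_)
  delta <- sum(x * y) / (2 * n) - 2 * pa * pb
  da <- sum(x == 2) / n - pa^2
  db <- sum(y == 2) / n - pb^2
  den <- (pa * (1 - pa) + da) * (pb * (1 - pb) + db)
  if (den <= 0) return(NA_real_)
  max(-1, min(1, delta / sqrt(den)))
}

oracle_mean_r2 <- function(m) {
  L <- ncol(m$dosage)
  vals <- c()
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      r <- oracle_burrows_r(m, i, j)
      if (!is.na(r)) vals <- c(vals, r^2)
    }
  }
  mean(vals)
}

# sort-and-accumulate weighted quantile oracle (inverted CDF)
oracle_weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  xs <- x[ord]; ws <- w[ord] / sum(w)
  acc <- 0
  for (k in seq_along(xs)) {
    acc <- acc + ws[k]
    if (acc >= p - 1e-12) return(xs[k])
  }
  xs[length(xs)]
}

# small GENEPOP text fixture used across io tests
genepop_lines <- function() {
  c("example dataset",
    "Loc1, Loc2",
    "Pop",
    "i1 , 0101 0102",
    "i2 , 0202 0000")
}

# name a bare length-5 vector as a summary-statistic vector
stats_named <- function(v) {
  stats::setNames(as.numeric(v), c("he", "fis", "h_mean", "h_var", "r2"))
}
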