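test_that("raw MAD matches hand values and a brute-force oracle", {
  expect_equal(mad_raw(c(1, 2, 3, 4, 5)), 1)
  expect_equal(mad_raw(rep(4.2, 10)), 0)
  expect_error(mad_raw(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:100) {
    x <- rnorm(sample(3:50, 1), sd = runif(1, 0.1, 10))
    # two-pass oracle: explicit sort-based medians
    med <- sort(x)[ceiling(length(x) / 2)]
    if (length(x) %% 2 == 0) {
      s <- sort(x); med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
    }
    dev <- sort(abs(x - med))
    om <- if (length(x) %% 2 == 0)
      (dev[length(x) / 2] + dev[length(x) / 2 + 1]) / 2 else
      dev[ceiling(length(x) / 2)]
    expect_equal(mad_raw(x), om)
  }
})

test_that("Z'-factor follows its formula, bounds and invariances", {
  # both dispersions zero: perfect separation
  expect_equal(z_prime(rep(10, 5), rep(0, 5)), 1)
  pos <- c(9, 10, 11); neg <- c(-1, 0, 1)
  expect_equal(z_prime(pos, neg), 1 - 3 * (sd(pos) + sd(neg)) / 10)
  expect_error(z_prime(c(1, 2), c(1, 2)), "undefined")

  set.seed(2)
  for (i in 1:50) {
    p <- rnorm(20, 5, 2); n <- rnorm(20, 0, 2)
    z <- z_prime(p, n)
    expect_lte(z, 1)
    # translation and positive-scale invariance
    a <- runif(1, 0.1, 7); b <- runif(1, -5, 5)
    expect_equal(z_prime(a * p + b, a * n + b), z, tolerance = 1e-12)
    expect_lte(z_prime(p, n, robust = TRUE), 1)
  }
})

test_that("robust Z' approaches consistency-rescaled classic Z' on normal data", {
  set.seed(3)
  pos <- rnorm(1e5, 10, 1); neg <- rnorm(1e5, 0, 1)
  robust <- z_prime(pos, neg, robust = TRUE)
  # classic Z' with sd replaced by 1.4826 * MAD
  rescaled <- 1 - 3 * 1.4826 * (mad_raw(pos) + mad_raw(neg)) /
    abs(median(pos) - median(neg))
  classic <- z_prime(pos, neg)
  expect_lt(abs(rescaled - classic), 0.05)
  # raw-MAD robust variant differs from the rescaled one by the factor alone
  expect_equal(1 - 1.4826 * (1 - robust), rescaled, tolerance = 1e-12)
})

test_that("SSMD* follows its formula, antisymmetry and affine invariance", {
  pos <- c(9, 10, 11); neg <- c(-1, 0, 1)   # medians 10 and 0, MADs 1 and 1
  expect_equal(ssmd_star(pos, neg), 10 / (1.4826 * sqrt(2)), tolerance = 1e-12)
  expect_equal(ssmd_star(pos, neg), 4.7695, tolerance = 1e-4)
  expect_equal(ssmd_star(neg, pos), -ssmd_star(pos, neg))
  set.seed(4)
  p <- rnorm(30, 3); n <- rnorm(30)
  a <- 2.7; b <- -4
  expect_equal(ssmd_star(a * p + b, a * n + b), ssmd_star(p, n),
               tolerance = 1e-12)
  expect_error(ssmd_star(rep(1, 5), rep(0, 5)), "denominator")
})

test_that("SSMD* converges to delta/sqrt(2) for unit-sd normal arms", {
  set.seed(5)
  delta <- 2
  s <- ssmd_star(rnorm(2e5, delta, 1), rnorm(2e5, 0, 1))
  expect_lt(abs(s - delta / sqrt(2)) / (delta / sqrt(2)), 0.03)
})

test_that("normal quantiles match the assay's power-analysis values", {
  expect_equal(normal_quantile(0.5), 0)
  expect_equal(round(normal_quantile(0.90), 2), 1.28)
  expect_equal(round(normal_quantile(1 - 0.005 / 2), 2), 2.81)
  expect_error(normal_quantile(0), "p > 0")
})

test_that("required sample size follows the two-arm normal formula", {
  expect_equal(required_sample_size(1, 1, z_alpha = 2.81, z_beta = 1.28), 34L)
  expect_equal(required_sample_size(1, 2, z_alpha = 2.81, z_beta = 1.28), 9L)
  expect_equal(required_sample_size(0, 1), 0L)
  expect_equal(required_sample_size(1, 1), 34L)  # exact quantiles round the same
  expect_error(required_sample_size(1, 0))
  expect_equal(normalized_effect(1.5, 25, 22), 0.5)
})

test_that("bootstrap group averaging is seeded, sane at g=1, and grows with g", {
  set.seed(6)
  pos <- rnorm(44, 3, 1); neg <- rnorm(44, 0, 1)
  t1 <- bootstrap_group_averaging(pos, neg, group_sizes = 1:5, B = 200, seed = 9)
  t2 <- bootstrap_group_averaging(pos, neg, group_sizes = 1:5, B = 200, seed = 9)
  expect_identical(t1, t2)
  expect_equal(t1$group_size, 1:5)
  expect_equal(t1$n_groups_pos, c(44L, 22L, 14L, 11L, 8L))
  # g=1 grouping is a no-op: close to the plain SSMD* up to bootstrap error
  expect_lt(abs(t1$ssmd_star[1] - ssmd_star(pos, neg)), 0.5)
  # averaging shrinks dispersion: SSMD* strictly increasing in g
  expect_true(all(diff(t1$ssmd_star) > 0))
  expect_error(bootstrap_group_averaging(pos, neg, group_sizes = 30, B = 10),
               "group size")
})

test_that("2x2 chi-squared matches the expected-counts oracle", {
  eq <- chi_squared_2x2(matrix(c(20, 20, 30, 30), 2, 2, byrow = TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(chi_squared_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    got <- chi_squared_2x2(m)
    # oracle: explicit expected counts
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches t^2 and the sum-of-squares oracle", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  r <- one_way_anova(g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(8)
  a <- rnorm(12, 1); b <- rnorm(15, 0)
  r2 <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-12)

  gs <- list(rnorm(10, 0), rnorm(8, 1), rnorm(12, 2))
  r3 <- one_way_anova(gs)
  # oracle: explicit between/within sums of squares
  all_v <- unlist(gs); gm <- mean(all_v)
  ssb <- sum(vapply(gs, function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(gs, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- length(gs) - 1; df2 <- length(all_v) - length(gs)
  f <- (ssb / df1) / (ssw / df2)
  expect_equal(r3$statistic, f, tolerance = 1e-12)
  expect_equal(r3$p_value, pf(f, df1, df2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("screen_metrics summarises a tidy score table", {
  set.seed(9)
  scores <- tibble::tibble(
    bhs = c(rnorm(10, 24, 0.3), rnorm(10, 22, 0.3)),
    condition = rep(c("DMSO", "Mtz"), each = 10))
  m <- screen_metrics(scores, positive = "DMSO", negative = "Mtz")
  expect_s3_class(m, "screen_metrics")
  expect_equal(m$ssmd_star, ssmd_star(scores$bhs[1:10], scores$bhs[11:20]))
  td <- tidy(m)
  expect_equal(td$metric, c("z_prime", "robust_z_prime", "ssmd_star"))
  gl <- glance(m)
  expect_equal(gl$n_pos, 10L)
  expect_equal(nrow(m$arms), 2L)
})
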