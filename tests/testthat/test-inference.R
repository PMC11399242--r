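test_that("paired t matches the closed form and a reference implementation", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3))
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-res$t, 2), tolerance = 1e-10)
  expect_equal(res$effect_size, 2, tolerance = 1e-10)

  same <- paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  set.seed(61)
  a <- rnorm(20)
  b <- rnorm(20)
  res2 <- paired_t(a, b)
  # independent closed-form oracle
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(res2$t, t_oracle, tolerance = 1e-10)
  expect_equal(res2$p, 2 * stats::pt(-abs(t_oracle), 19), tolerance = 1e-10)

  # antisymmetry
  flipped <- paired_t(b, a)
  expect_equal(flipped$t, -res2$t, tolerance = 1e-12)
  expect_equal(flipped$p, res2$p, tolerance = 1e-12)

  expect_error(paired_t(c(1, 2), c(0, 1)), "at least 3")
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "undefined")
})

test_that("BH step-up equals the brute-force cutoff search", {
  expect_identical(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.2), 0.05),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_bh(rep(1, 6), 0.05), rep(FALSE, 6))

  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    best <- 0
    for (i in seq_len(m)) {
      if (p[ord[i]] <= i / m * q) best <- i
    }
    rej <- rep(FALSE, m)
    if (best > 0) rej[ord[seq_len(best)]] <- TRUE
    rej
  }
  set.seed(62)
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    mask <- fdr_bh(p, q)
    expect_identical(mask, bh_oracle(p, q))
    # BH rejects a superset of Bonferroni
    expect_true(all(mask[p <= q / m]))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ci95 uses the t quantile and covers at the nominal rate", {
  expect_equal(ci95(c(1, 1, 1)), list(mean = 1, half_width = 0))
  res <- ci95(c(0, 2))
  expect_equal(res$mean, 1)
  expect_equal(res$half_width, stats::qt(0.975, 1) * sqrt(2) / sqrt(2),
               tolerance = 1e-4)
  set.seed(63)
  hits <- vapply(1:1000, function(i) {
    x <- rnorm(50)
    ci <- ci95(x)
    abs(ci$mean) <= ci$half_width
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("rich-club PCA loading test responds to curve offsets", {
  set.seed(64)
  base <- matrix(rep(seq(0.9, 0.3, length.out = 6), each = 12), 12, 6) +
    matrix(rnorm(72, sd = 0.02), 12, 6)
  a <- rich_club_curves(base + 0.1)
  b <- rich_club_curves(base)
  res <- rich_club_pca_test(a, b)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.01)

  same <- rich_club_pca_test(b, b)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # rank-1 construction: curves = subject scalar x fixed shape + noise
  shape <- seq(1, 0.2, length.out = 8)
  scal <- runif(24, 0.5, 1.5)
  curves <- outer(scal, shape) + matrix(rnorm(24 * 8, sd = 0.01), 24, 8)
  ca <- rich_club_curves(curves[1:12, ])
  cb <- rich_club_curves(curves[13:24, ])
  res2 <- rich_club_pca_test(ca, cb)
  expect_gte(res2$explained_variance, 0.9)
  expect_gt(abs(cor(c(res2$scores_a, res2$scores_b), scal)), 0.95)

  expect_error(rich_club_pca_test(a, rich_club_curves(base[, 1:5])), "k grid")
})

test_that("side-effect comparisons recover planted symptom effects", {
  n <- 30
  set.seed(65)
  detected <- 0
  false_pos <- 0
  n_seeds <- 5
  for (seed in seq_len(n_seeds)) {
    ratings <- array(0L, dim = c(n, 4, 2, 5))
    ratings[, , 1, ] <- rbinom(n * 4 * 5, 3, 0.1) # placebo: all symptoms
    ratings[, , 2, ] <- rbinom(n * 4 * 5, 3, 0.1) # drug: baseline...
    ratings[, 1, 2, ] <- rbinom(n * 5, 3, 0.6)    # ...but fatigue elevated
    tab <- side_effect_table(ratings,
                             symptoms = c("fatigue", "s2", "s3", "s4"),
                             conditions = c("placebo", "drug"))
    cmp <- side_effect_comparison(tab, q = 0.05)
    detected <- detected +
      cmp$significant_after_fdr[cmp$symptom == "fatigue"]
    false_pos <- false_pos +
      sum(cmp$significant_after_fdr[cmp$symptom != "fatigue"])
  }
  expect_equal(detected, n_seeds)
  expect_lte(false_pos / (3 * n_seeds), 0.05)

  zero <- side_effect_table(array(0L, dim = c(10, 3, 2, 5)))
  cmp0 <- side_effect_comparison(zero)
  expect_false(any(cmp0$significant_after_fdr))
  expect_true(all(cmp0$p == 1))

  # one symptom, two conditions: reduces to a single paired t
  one <- array(0L, dim = c(10, 1, 2, 1))
  set.seed(66)
  one[, 1, 1, 1] <- rbinom(10, 3, 0.5)
  tab1 <- side_effect_table(one)
  cmp1 <- side_effect_comparison(tab1)
  direct <- paired_t(one[, 1, 1, 1], one[, 1, 2, 1])
  expect_equal(cmp1$t, direct$t, tolerance = 1e-12)
  expect_equal(cmp1$significant_after_fdr, direct$p <= 0.05)
})

test_that("FC/side-effect association behaves under null and planted slopes", {
  expect_equal(fc_sideeffect_association(1:10, 2 * (1:10) + 5)$r, 1,
               tolerance = 1e-12)
  set.seed(67)
  type1 <- mean(vapply(1:1000, function(i) {
    fc_sideeffect_association(rnorm(30), rnorm(30))$p < 0.05
  }, logical(1)))
  expect_lt(abs(type1 - 0.05), 0.02)

  rs <- vapply(1:200, function(i) {
    x <- rnorm(34)
    y <- 0.5 * x + rnorm(34)
    fc_sideeffect_association(x, y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5 / sqrt(1.25)), 0.1)
})

test_that("pharmacokinetic elimination follows the closed form", {
  expect_equal(fraction_eliminated(15, 144), 1 - 2^(-144 / 15), tolerance = 1e-12)
  expect_equal(fraction_eliminated(20, 144), 1 - 2^(-144 / 20), tolerance = 1e-12)
  expect_equal(fraction_eliminated(10, 10), 0.5)
  # strictly increasing in time, decreasing in half-life
  expect_true(all(diff(fraction_eliminated(15, seq(1, 200, by = 1))) > 0))
  expect_true(all(diff(fraction_eliminated(seq(5, 50, by = 5), 144)) < 0))
  expect_error(fraction_eliminated(0, 10), "half-life")
  expect_error(fraction_eliminated(10, -1), "elapsed")
})

test_that("dose superposition matches geometric-series accumulation", {
  expect_equal(accumulate_doses(20, 0, 0), 1)
  expect_equal(accumulate_doses(10, c(0, 10), 10), 1.5)
  expect_equal(accumulate_doses(10, c(20), 10), 0)
  # 15 doses every 8 h, evaluated 1 h after the last dose
  hl <- 20
  times <- seq(0, by = 8, length.out = 15)
  eval_t <- times[15] + 1
  direct <- sum(2^(-(eval_t - times) / hl))
  ratio <- 2^(-8 / hl)
  geom <- 2^(-1 / hl) * (1 - ratio^15) / (1 - ratio)
  expect_equal(accumulate_doses(hl, times, eval_t), direct, tolerance = 1e-12)
  expect_equal(direct, geom, tolerance = 1e-12)
})
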