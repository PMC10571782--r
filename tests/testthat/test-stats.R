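test_that("Shapiro-Wilk wrapper validates input and matches the frozen reference", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(2.5, 10)), "constant")
  res <- shapiro_wilk(stats_fix$x)
  expect_equal(res$W, stats_fix$shapiro_W, tolerance = 1e-6)
  expect_equal(res$p, stats_fix$shapiro_p, tolerance = 1e-4)
})

test_that("normal samples pass normality at the expected rate", {
  set.seed(2024)
  ps <- replicate(200, shapiro_wilk(rnorm(50))$p)
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("polynomial trend fits recover exact curves and degenerate data", {
  t <- 7:18
  di <- 1 + 2 * t - t^2
  fit <- quadratic_fit(t, di)
  expect_equal(unname(fit$coefficients), c(1, 2, -1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  const <- quadratic_fit(t, rep(4.2, length(t)))
  expect_equal(unname(const$coefficients), c(4.2, 0, 0))
  expect_equal(const$r_squared, 0)

  # brute-force normal equations oracle on a noisy fixture
  set.seed(6)
  y <- 3 - 0.5 * t + 0.1 * t^2 + rnorm(length(t), 0, 0.3)
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit2 <- quadratic_fit(t, y)
  expect_equal(unname(fit2$coefficients), as.numeric(beta), tolerance = 1e-10)

  expect_error(quadratic_fit(c(1, 1, 2), c(1, 2, 3)), "distinct")
})

test_that("one-way ANOVA reproduces the hand-worked and reference fixtures", {
  # SS_between = 6, SS_within = 6 -> F = (6/2)/(6/6) = 3
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(v, g)
  expect_equal(an$F, 3, tolerance = 1e-12)
  expect_equal(c(an$df_between, an$df_within), c(2, 6))

  an2 <- one_way_anova(c(stats_fix$g1, stats_fix$g2, stats_fix$g3),
                       rep(c("g1", "g2", "g3"),
                           times = lengths(stats_fix[c("g1", "g2", "g3")])))
  expect_equal(an2$F, stats_fix$anova_F, tolerance = 1e-8)
  expect_equal(an2$p, stats_fix$anova_p, tolerance = 1e-8)

  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), ">= 2 observations")
  expect_error(one_way_anova(1:4, rep("a", 4)), "2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(sample(5:12, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(5:12, 1), mean = runif(1, -1, 1))
    an <- one_way_anova(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
    tt <- independent_t_test(a, b, equal_var = TRUE)
    expect_equal(an$F, tt$t^2, tolerance = 1e-10)
    expect_equal(an$p, tt$p, tolerance = 1e-10)
  }
})

test_that("t-test wrapper matches frozen Welch and Student references", {
  tw <- independent_t_test(stats_fix$a, stats_fix$b)
  expect_equal(tw$t, stats_fix$welch_t, tolerance = 1e-8)
  expect_equal(tw$p, stats_fix$welch_p, tolerance = 1e-8)
  ts <- independent_t_test(stats_fix$a, stats_fix$b, equal_var = TRUE)
  expect_equal(ts$t, stats_fix$student_t, tolerance = 1e-8)
  expect_equal(ts$p, stats_fix$student_p, tolerance = 1e-8)

  same <- independent_t_test(stats_fix$a, stats_fix$a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sep <- independent_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(sep$p, 1e-6)
  expect_error(independent_t_test(c(1, 1, 1), c(1, 1)), "degenerate")
})

test_that("Duncan range quantiles reproduce the published table values", {
  # published Duncan significant ranges, alpha = 0.05
  expect_equal(q_duncan(0.05, 2, 10), 3.151, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 3, 10), 3.293, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 4, 10), 3.376, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 5, 10), 3.430, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 6, 10), 3.465, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 2, 20), 2.950, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 3, 20), 3.097, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 4, 20), 3.190, tolerance = 1e-3)
  expect_equal(q_duncan(0.05, 5, 20), 3.255, tolerance = 1e-3)
})

test_that("Duncan letters reproduce a hand-worked 5-group example", {
  # 5 groups, n = 5, constructed so MSE = 8.06 (within-group pattern
  # (-2,-1,0,1,2)*d with d = sqrt(8.06/2.5)); means 9.8, 10.8, 15.4, 17.6,
  # 21.6. Hand-working with the published ranges at df = 20
  # (SE = sqrt(8.06/5) = 1.2696; R2..R5 = 3.745, 3.932, 4.050, 4.133):
  # 21.6 stands alone; 17.6 and 15.4 share a letter; 10.8 and 9.8 share one.
  d <- sqrt(8.06 / 2.5)
  means <- c(A = 9.8, B = 15.4, C = 17.6, D = 21.6, E = 10.8)
  v <- unlist(lapply(means, function(m) m + c(-2, -1, 0, 1, 2) * d))
  g <- rep(names(means), each = 5)
  res <- duncan_mrt(v, g, alpha = 0.05)
  expect_equal(res$ms_within, 8.06, tolerance = 1e-10)
  expect_equal(names(res$group_means), c("D", "C", "B", "E", "A"))
  expect_equal(unname(res$letters), c("a", "b", "b", "c", "c"))
})

test_that("Duncan handles the trivial extremes", {
  # identical groups (same values in every group): one shared letter
  v <- rep(c(1, 2, 3, 4, 5), times = 4)
  g <- rep(c("a", "b", "c", "d"), each = 5)
  res <- duncan_mrt(v, g)
  expect_true(all(res$letters == "a"))

  v2 <- c(rnorm(6, 0, 0.1), rnorm(6, 100, 0.1))
  res2 <- duncan_mrt(v2, rep(c("lo", "hi"), each = 6))
  expect_equal(unname(res2$letters), c("a", "b"))
})

test_that("Duncan never contradicts clearly equal means", {
  # groups whose unprotected pairwise t has p > 0.5 must share a letter
  set.seed(99)
  for (i in 1:5) {
    base <- rnorm(8)
    v <- c(base, base + rnorm(8, 0, 0.01), rnorm(8, 5))
    g <- rep(c("a", "b", "c"), each = 8)
    tt <- independent_t_test(v[g == "a"], v[g == "b"], equal_var = TRUE)
    res <- duncan_mrt(v, g)
    if (tt$p > 0.5)
      expect_true(grepl(substr(res$letters[["a"]], 1, 1), res$letters[["b"]]) ||
                  grepl(substr(res$letters[["b"]], 1, 1), res$letters[["a"]]))
  }
})
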