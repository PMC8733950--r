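test_that("student t matches closed form and the reference implementation", {
  r <- student_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$statistic, -1.0954451150, tolerance = 1e-9)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 0.3153335962, tolerance = 1e-9)

  r2 <- student_t_test(c(0.1, 0.2), c(0.4, 0.6))
  expect_equal(r2$statistic, -3.1304951685, tolerance = 1e-9)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, 0.0886776231, tolerance = 1e-9)

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(student_t_test(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(student_t_test(1, c(1, 2)), "at least 2")

  # live cross-check against stats::t.test on random samples
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), mean = runif(1))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    mine <- student_t_test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch t uses Welch-Satterthwaite df and reduces to student", {
  a <- student_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  w <- welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w$statistic, a$statistic, tolerance = 1e-12)
  expect_equal(w$df, a$df, tolerance = 1e-12)

  # unequal variances shrink the df below the pooled df
  x <- c(0, 0, 0, 10); y <- c(2, 2.1, 1.9, 2)
  expect_lt(welch_t_test(x, y)$df, student_t_test(x, y)$df)

  expect_error(welch_t_test(c(2, 2), c(3, 3)), "variances are zero")

  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 3))
    ref <- stats::t.test(x, y)
    mine <- welch_t_test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mann-whitney U: exact enumeration for small tie-free samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)

  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 2 / 20, tolerance = 1e-12)

  # identical tied samples go down the approximation path with p = 1
  r3 <- mann_whitney_u(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(r3$method, "normal_approx")
  expect_equal(r3$p_value, 1)

  # independent cross-check vs stats::wilcox.test exact p-values
  set.seed(9)
  for (i in 1:20) {
    x <- runif(sample(2:7, 1)); y <- runif(sample(2:7, 1))
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y)$statistic, unname(ref$statistic))
  }
})

test_that("large or tied samples use the tie-corrected normal approximation", {
  set.seed(13)
  x <- rexp(20); y <- rexp(25)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)

  xt <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 9)
  yt <- c(2, 3, 3, 4, 5, 6, 7, 7, 9)
  rt <- mann_whitney_u(xt, yt)
  reft <- stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(rt$p_value, reft$p.value, tolerance = 1e-10)
})

test_that("antisymmetry: swapping samples negates t and reflects U", {
  set.seed(17)
  for (i in 1:25) {
    x <- rexp(sample(3:10, 1)); y <- rexp(sample(3:10, 1), rate = runif(1, 0.3, 3))
    s1 <- student_t_test(x, y); s2 <- student_t_test(y, x)
    expect_equal(s1$statistic, -s2$statistic, tolerance = 1e-12)
    expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
    w1 <- welch_t_test(x, y); w2 <- welch_t_test(y, x)
    expect_equal(w1$statistic, -w2$statistic, tolerance = 1e-12)
    expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)
    u1 <- mann_whitney_u(x, y); u2 <- mann_whitney_u(y, x)
    expect_equal(u1$statistic, length(x) * length(y) - u2$statistic,
                 tolerance = 1e-12)
    expect_equal(u1$p_value, u2$p_value, tolerance = 1e-12)
    expect_gte(u1$statistic, 0)
    expect_lte(u1$statistic, length(x) * length(y))
  }
})

test_that("p-values fall as the location shift between samples grows", {
  set.seed(19)
  x <- rnorm(15)
  shifts <- c(0, 0.5, 1, 2, 4)
  ps <- sapply(shifts, function(s) {
    y <- x + s
    c(student = student_t_test(x, y)$p_value,
      welch = welch_t_test(x, y)$p_value,
      mw = mann_whitney_u(x, y)$p_value)
  })
  for (row in rownames(ps))
    expect_true(all(diff(ps[row, ]) <= 1e-12))
})

test_that("run_all_tests returns three slots in fixed order, tolerating partial failure", {
  out <- run_all_tests(c(1, 2, 3), c(2, 4, 6))
  expect_named(out, c("student_t", "welch_t", "mann_whitney_u"))
  expect_true(all(vapply(out, inherits, logical(1), "divergence_test")))

  partial <- run_all_tests(c(2, 2, 2), c(1, 3, 5))
  expect_s3_class(partial$student_t, "divergence_test")     # pooled var > 0
  expect_s3_class(partial$welch_t, "divergence_test")
  expect_s3_class(partial$mann_whitney_u, "divergence_test")

  both_const <- run_all_tests(c(2, 2, 2), c(2, 2, 2))
  expect_s3_class(both_const$student_t, "divergence_test_error")
  expect_s3_class(both_const$welch_t, "divergence_test_error")
  expect_s3_class(both_const$mann_whitney_u, "divergence_test")
  expect_equal(both_const$mann_whitney_u$p_value, 1)
})
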