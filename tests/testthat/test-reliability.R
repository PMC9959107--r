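test_that("consistency ICC is exact on identical and shifted columns", {
  set.seed(601)
  x <- rnorm(25)
  expect_equal(icc_consistency(cbind(x, x))$value, 1.0)
  # consistency ignores a uniform condition shift; agreement does not
  expect_equal(icc_consistency(cbind(x, x + 5))$value, 1.0)
  expect_lt(icc_consistency(cbind(x, x + 5), type = "agreement")$value, 1.0)
})

test_that("independent columns give a near-zero ICC", {
  set.seed(602)
  m <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_consistency(m)$value), 0.1)
})

test_that("ICC matches a from-scratch two-way ANOVA oracle on random tables", {
  set.seed(603)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    m <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 3)), n, 2)
    est <- icc_consistency(m)
    expect_lt(abs(est$value - oracle_icc_c1(m)), 1e-6)
    expect_lte(est$value, 1)
  }
})

test_that("ICC is invariant to a common affine transform and handles missingness", {
  set.seed(604)
  m <- matrix(rnorm(40), 20, 2)
  v1 <- icc_consistency(m)$value
  expect_equal(icc_consistency(3.2 * m + 7)$value, v1)
  m_na <- rbind(m, c(NA, 1), c(2, NA))
  est <- icc_consistency(m_na)
  expect_equal(est$value, v1)
  expect_identical(est$n_used, 20L)
  # degenerate inputs are undefined, not errors
  expect_message(und <- icc_consistency(m[1:2, ]), "complete pairs")
  expect_true(is.na(und$value))
  expect_message(und2 <- icc_consistency(matrix(1, 5, 2)), "zero total variance")
  expect_true(is.na(und2$value))
})

test_that("ICC bands assign the documented boundaries", {
  expect_identical(classify_icc(c(-0.416, 0.49)), c("poor", "poor"))
  expect_identical(classify_icc(c(0.5, 0.736, 0.75)),
                   c("moderate", "moderate", "moderate"))
  expect_identical(classify_icc(c(0.76, 0.894, 0.9)), c("good", "good", "good"))
  expect_identical(classify_icc(c(0.901, 0.958)), c("excellent", "excellent"))
  expect_error(classify_icc(NA), "finite")
})

test_that("correlation matrix recovers exact linear relations and nulls", {
  x <- seq(1, 10, length.out = 30)
  cm <- correlation_matrix(data.frame(x = x, y = 2 * x + 3, z = -x + 1))
  expect_equal(unname(cm$r["x", "y"]), 1.0)
  expect_equal(unname(cm$r["x", "z"]), -1.0)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_true(all(abs(cm$r[upper.tri(cm$r)]) <= 1))

  set.seed(605)
  mean_abs_r <- mean(replicate(30, {
    cm0 <- correlation_matrix(data.frame(a = rnorm(40), b = rnorm(40)))
    abs(cm0$r["a", "b"])
  }))
  expect_lt(mean_abs_r, 0.2)

  expect_message(cmz <- correlation_matrix(data.frame(a = rnorm(10), b = rep(1, 10))),
                 "zero variance")
  expect_true(is.na(cmz$r["a", "b"]))
})

test_that("group comparisons choose tests reproducibly and detect real shifts", {
  # identical tied groups: no evidence, p = 1 under the midrank convention
  res <- compare_groups(rep(4, 20), rep(c("a", "b"), each = 10))
  expect_identical(res$test_used, "mann_whitney")
  expect_equal(res$p_value, 1)

  set.seed(606)
  x <- c(rnorm(50), rnorm(50, 3))
  g <- rep(c("lo", "hi"), each = 50)
  res2 <- compare_groups(x, g)
  expect_identical(res2$test_used, "t")  # n = 50, normal draws pass the screen
  expect_lt(res2$p_value, 0.001)

  # small groups force the rank test
  res3 <- compare_groups(c(rnorm(8), rnorm(8, 3)), rep(c("a", "b"), each = 8))
  expect_identical(res3$test_used, "mann_whitney")
  expect_lt(res3$p_value, 0.05)

  expect_error(compare_groups(rnorm(5), rep("a", 5)), "two levels")
})

test_that("Cox fits agree with a grid-search partial-likelihood oracle", {
  set.seed(607)
  for (i in 1:8) {
    n <- 40
    x <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.4 * x))
    ev <- rbinom(n, 1, 0.85)
    if (sum(ev) < 2) ev[1:2] <- 1L
    fit <- cox_univariate(t, ev, x)
    expect_lt(abs(fit$beta - oracle_cox_beta(t, ev, x)), 1e-6)
  }
})

test_that("Cox recovers a known coefficient and respects reparametrization", {
  set.seed(608)
  n <- 500
  x <- rnorm(n)
  surv <- simulate_survival(0.5 * x, baseline_hazard = 0.03, censor_rate = 0.2)
  fit <- cox_univariate(surv$os_months, surv$os_event, x)
  expect_lt(abs(fit$beta - 0.5), 0.15)
  expect_gt(mean(surv$os_event == 0), 0.1)
  expect_lt(mean(surv$os_event == 0), 0.35)

  # rescaling the covariate rescales beta and leaves p unchanged
  fit10 <- cox_univariate(surv$os_months, surv$os_event, 10 * x)
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-6)
  expect_equal(fit10$p, fit$p, tolerance = 1e-8)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("monotone likelihood is flagged and tiny event counts are rejected", {
  t <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 1, 1, 1, 1, 1)
  x <- c(30, 20, 10, 3, 2, 1)  # each death has the largest x in its risk set
  expect_error(cox_univariate(c(1, 2), c(1, 0), c(0.5, 1)), "2 events")
  sep <- cox_univariate(t, ev, x)
  expect_s3_class(sep, "cox_result")
  expect_true(sep$flagged)
})
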