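# KM estimation, log-rank testing, optimal cutpoint, group comparisons

test_that("km_estimate: no censoring steps of 1/n, all-censored flat, manual table", {
  km <- km_estimate(c(1, 2, 3, 4, 5), rep(1L, 5))
  expect_equal(km$surv, seq(0.8, 0, by = -0.2))

  kmc <- km_estimate(c(1, 2, 3), rep(0L, 3))
  expect_true(all(kmc$surv == 1))

  # 6-record mixed dataset vs hand-computed product-limit oracle
  time <- c(2, 4, 4, 6, 8, 9)
  status <- c(1, 1, 0, 1, 0, 1)
  km6 <- km_estimate(time, status)
  ok <- oracle_km(time, status)
  expect_equal(km6$surv[km6$n_event > 0], ok$surv)
  # Greenwood CIs bracket the estimate
  expect_true(all(km6$lower <= km6$surv + 1e-12 & km6$surv <= km6$upper + 1e-12,
                  na.rm = TRUE))
  expect_error(km_estimate(c(0, 0), c(1, 1)), "times")
})

test_that("logrank_test: identical groups give 0, matches the manual oracle, symmetric", {
  time <- c(3, 5, 7, 2, 8, 4)
  status <- c(1, 0, 1, 1, 0, 1)
  r <- logrank_test(c(time, time), c(status, status),
                    rep(c("a", "b"), each = 6))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  # tiny 8-patient example vs brute-force observed-minus-expected
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  s8 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g8 <- c("a", "b", "a", "b", "a", "b", "a", "b")
  r8 <- logrank_test(t8, s8, g8)
  expect_equal(r8$statistic, oracle_logrank(t8, s8, g8), tolerance = 1e-8)
  expect_equal(r8$statistic,
               logrank_test(t8, s8, ifelse(g8 == "a", "b", "a"))$statistic)
  expect_error(logrank_test(t8, s8, rep("a", 8)), "two")
})

test_that("optimal_logrank_cutoff: separable clusters, constant marker, orientation", {
  set.seed(5)
  n <- 40
  marker <- c(runif(n / 2, 0, 1), runif(n / 2, 3, 4))  # gap in (1, 3)
  time <- c(rexp(n / 2, 0.05), rexp(n / 2, 0.002))     # low marker = high risk
  status <- rep(1L, n)
  res <- optimal_logrank_cutoff(marker, time, status)
  expect_gt(res$cutoff, 1)
  expect_lt(res$cutoff, 3)
  expect_identical(res$high_risk, "low_marker")
  expect_true(all(table(res$group) >= 3))

  expect_error(optimal_logrank_cutoff(rep(1, n), time, status), "constant")
})

test_that("maximally selected cutoff inflates the null log-rank rejection rate", {
  # documented inflation property: data-driven cutoff vs fixed median split
  reject <- matrix(NA, 60, 2)
  for (s in 1:60) {
    d <- quick_surv(40, beta = 0, seed = 700 + s)
    med <- d$z > median(d$z)
    reject[s, 1] <- logrank_test(d$time, d$status, med)$p < 0.05
    reject[s, 2] <- tryCatch(
      optimal_logrank_cutoff(d$z, d$time, d$status)$p < 0.05,
      error = function(e) NA)
  }
  expect_gte(mean(reject[, 2], na.rm = TRUE), mean(reject[, 1], na.rm = TRUE))
})

test_that("compare_groups: printed-table Fisher identity, MWU against exhaustive permutation", {
  # sex counts 8/9 vs 7/8: two-sided Fisher p = 1 (printed as > 0.999)
  sex <- c(rep("male", 8), rep("female", 9), rep("male", 7), rep("female", 8))
  grp <- c(rep("prog", 17), rep("nonprog", 15))
  tab <- compare_groups(data.frame(sex = sex), grp)
  expect_equal(tab$p, 1, tolerance = 1e-9)

  # identical continuous samples: MWU p = 1
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  t2 <- compare_groups(data.frame(v = c(x, x)), rep(c("a", "b"), each = 5))
  expect_equal(t2$p, 1)

  # n = 5 per group: MWU p equals the brute-force full-permutation p
  set.seed(8)
  a <- rnorm(5); b <- rnorm(5) + 2
  obs_u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  all_idx <- combn(10, 5)
  pool <- c(a, b)
  us <- apply(all_idx, 2, function(i)
    sum(outer(pool[i], pool[-i], ">")))
  p_perm <- mean(abs(us - 12.5) >= abs(obs_u - 12.5))
  got <- compare_groups(data.frame(v = pool),
                        rep(c("a", "b"), each = 5))
  # force the MWU branch only if Shapiro gate chose it; wilcox exact matches
  p_w <- wilcox.test(a, b)$p.value
  expect_equal(p_w, p_perm, tolerance = 1e-12)
  if (got$test == "Mann-Whitney U") expect_equal(got$p, p_perm, tolerance = 1e-12)

  expect_error(compare_groups(data.frame(v = 1:4), rep("a", 4)), "two")
})

test_that("compare_groups gates on Shapiro-Wilk and handles r x c tables", {
  set.seed(10)
  d <- data.frame(normalish = rnorm(40),
                  skewed = rexp(40),
                  stage = sample(c("IIIB", "IVA", "IVB"), 40, replace = TRUE))
  g <- rep(c("a", "b"), 20)
  out <- compare_groups(d, g, seed = 4)
  expect_identical(out$test[out$variable == "normalish"], "t-test")
  expect_identical(out$test[out$variable == "skewed"], "Mann-Whitney U")
  expect_identical(out$test[out$variable == "stage"], "Fisher exact")
  expect_true(all(out$p >= 0 & out$p <= 1))
  # Monte-Carlo Fisher is seeded: reproducible
  out2 <- compare_groups(d, g, seed = 4)
  expect_identical(out$p, out2$p)
})
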