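# Survival machinery against hand-computed and brute-force oracles.

test_that("endpoints derive from dates per the PFS/OS definitions", {
  start <- as.Date("2020-01-01")
  # progression at day 100, alive at day 400
  r <- compute_endpoints(start, progression_date = start + 100,
                         death_date = as.Date(NA),
                         last_followup = start + 400)
  expect_equal(unlist(r), c(pfs_time = 100, pfs_event = 1,
                            os_time = 400, os_event = 0))
  # no progression, no death
  r2 <- compute_endpoints(start, last_followup = start + 300)
  expect_equal(r2$pfs_time, 300)
  expect_false(r2$pfs_event)
  expect_equal(r2$os_time, 300)
  # death without recorded progression counts as a PFS event
  r3 <- compute_endpoints(start, death_date = start + 200,
                          last_followup = start + 200)
  expect_equal(unlist(r3), c(pfs_time = 200, pfs_event = 1,
                             os_time = 200, os_event = 1))
  expect_error(
    compute_endpoints(start, progression_date = start - 5,
                      last_followup = start + 10),
    class = "imscore_data_error")
})

test_that("KM equals the empirical survival function without censoring", {
  d <- tibble::tibble(t = c(1, 2, 3), e = TRUE)
  km <- km_estimate(d, t, e)
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 0))

  set.seed(41)
  d2 <- tibble::tibble(t = rexp(40), e = TRUE)
  km2 <- tidy(km_estimate(d2, t, e))
  emp <- vapply(km2$time, function(tt) mean(d2$t > tt), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("KM handles censoring by the product-limit formula", {
  d <- tibble::tibble(t = c(1, 2, 3), e = c(TRUE, FALSE, TRUE))
  km <- tidy(km_estimate(d, t, e))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  allc <- tibble::tibble(t = c(5, 6, 7), e = FALSE)
  kmc <- km_estimate(allc, t, e)
  expect_true(all(tidy(kmc)$survival == 1))
  expect_true(is.na(glance(kmc)$median))
  expect_error(km_estimate(tibble::tibble(t = c(-1, 2), e = TRUE), t, e),
               class = "imscore_validation_error")
})

test_that("log-rank matches hand hypergeometric tabulation on 4 events", {
  d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE,
                      g = c("A", "A", "B", "B"))
  # oracle: tabulate O - E and variance over the pooled event times
  oe <- 0; v <- 0
  for (tt in sort(d$t)) {
    at <- d$t >= tt
    n <- sum(at); n1 <- sum(at & d$g == "A")
    dth <- sum(d$t == tt & d$e)
    o1 <- sum(d$t == tt & d$e & d$g == "A")
    oe <- oe + o1 - dth * n1 / n
    if (n > 1) v <- v + dth * (n1 / n) * (1 - n1 / n) * (n - dth) / (n - 1)
  }
  oracle <- oe^2 / v
  res <- logrank_test(d, t, e, g)
  expect_equal(res$statistic, oracle, tolerance = 1e-10)
  expect_equal(res$df, 1)

  same <- tibble::tibble(t = rep(c(1, 2, 3), 2), e = TRUE,
                         g = rep(c("A", "B"), each = 3))
  r0 <- logrank_test(same, t, e, g)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p.value, 1)
  expect_error(logrank_test(dplyr::mutate(same, g = "A"), t, e, g),
               class = "imscore_validation_error")
})

test_that("null log-rank rejects at the nominal 5% rate", {
  set.seed(52)
  rej <- vapply(1:1000, function(i) {
    d <- tibble::tibble(t = rexp(60), e = TRUE,
                        g = rep(c("A", "B"), each = 30))
    logrank_test(d, t, e, g)$p.value < 0.05
  }, logical(1))
  # binomial envelope: 0.05 +/- 3 * sqrt(.05*.95/1000) ~ +/- 0.021
  expect_lt(abs(mean(rej) - 0.05), 0.021)
})

test_that("Cox matches grid maximisation of the partial likelihood", {
  d <- tibble::tibble(t = c(1, 2, 4, 3, 5, 6), e = TRUE,
                      x = c(1, 1, 1, 0, 0, 0))
  # brute-force partial log-likelihood (no ties)
  pll <- function(b) {
    ord <- order(d$t)
    sum(vapply(which(d$e[ord]), function(i) {
      risk <- ord[i:length(ord)]
      b * d$x[ord[i]] - log(sum(exp(b * d$x[risk])))
    }, numeric(1)))
  }
  oracle <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  fit <- tidy(cox_fit(d, t, e, "x"))
  expect_equal(fit$estimate, oracle, tolerance = 1e-4)
  expect_true(fit$conf.low < fit$hr & fit$hr < fit$conf.high)
  expect_equal(fit$hr, exp(fit$estimate))

  # duplicated covariate -> singular information matrix
  d$x2 <- d$x
  expect_error(cox_fit(d, t, e, c("x", "x2")),
               class = "imscore_validation_error")
  expect_error(cox_fit(dplyr::mutate(d, x = 1), t, e, "x"),
               class = "imscore_validation_error")
})

test_that("Breslow and Efron agree on tie-free data", {
  set.seed(61)
  d <- tibble::tibble(t = rexp(50) + (1:50) * 1e-6,
                      e = runif(50) < 0.7,
                      x = rnorm(50))
  b <- tidy(cox_fit(d, t, e, "x", ties = "breslow"))
  ef <- tidy(cox_fit(d, t, e, "x", ties = "efron"))
  expect_equal(b$estimate, ef$estimate, tolerance = 1e-8)
})

test_that("two-group log-rank equals the Cox score test", {
  set.seed(62)
  d <- tibble::tibble(t = rexp(60), e = runif(60) < 0.8,
                      g = rep(0:1, 30))
  lr <- logrank_test(d, t, e, g)
  sc <- survival::coxph(survival::Surv(t, e) ~ g, data = d,
                        ties = "breslow")$score
  expect_equal(lr$statistic, unname(sc), tolerance = 1e-8)
})

test_that("monotone likelihood is flagged, not reported as a finite HR", {
  # all events in one group: the partial likelihood is monotone in beta
  d <- tibble::tibble(t = c(1, 2, 3, 10, 11, 12),
                      e = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(d, t, e, "x")
  expect_false(fit$converged)
  expect_match(tidy(fit)$note[1], "monotone|limited events")
})

test_that("uncorrected chi-square reproduces the printed cohort tests", {
  ielsg <- chi_square_2x2(matrix(c(20, 14, 18, 31), 2))
  expect_equal(round(ielsg$p.value, 3), 0.047)
  gender <- chi_square_2x2(matrix(c(20, 24, 18, 21), 2))
  expect_equal(round(gender$p.value, 3), 0.949)

  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)),
               class = "imscore_validation_error")
  # the Yates-corrected variant is available but not the default
  expect_gt(chi_square_2x2(matrix(c(20, 14, 18, 31), 2),
                           correct = TRUE)$p.value, 0.047)
})
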