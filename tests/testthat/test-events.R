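test_that("koff is the reciprocal mean dwell time", {
  ev <- tibble::tibble(tau_off = rep(2, 20))
  expect_equal(koff(ev, conf = 0)$k_off, 0.5)
  # reordering invariance
  set.seed(1)
  tau <- rexp(500, 3)
  expect_equal(koff(tau, conf = 0)$k_off,
               koff(sample(tau), conf = 0)$k_off)
  # sampling: estimate within 3 SE of the true rate
  k_hat <- koff(tau, conf = 0)$k_off
  se <- 3 / sqrt(500)
  expect_lt(abs(k_hat - 3), 3 * se)
  expect_error(koff(numeric(0)), "empty")
})

test_that("exponential fit recovers the generating rate", {
  set.seed(2)
  tau <- rexp(5000, 77)
  fit <- fit_exponential(tau)
  expect_rel(fit$rate, 77, 0.05)
  expect_equal(fit$n, 5000)
  # left-censoring: memoryless shift keeps the estimate unbiased
  fit_c <- fit_exponential(tau, censor = 1e-2)
  expect_rel(fit_c$rate, 77, 0.1)
  expect_error(fit_exponential(tau[1:5]), "at least 10")
  td <- tidy(fit)
  expect_equal(td$estimate, fit$rate)
})

test_that("double-exponential fit separates the published rate pair", {
  set.seed(3)
  n <- 2e4
  pick <- runif(n) < 0.5
  tau <- ifelse(pick, rexp(n, 77), rexp(n, 6434))
  fit <- fit_double_exponential(tau, n_starts = 10, seed = 1)
  expect_rel(fit$rate_slow, 77, 0.15)
  expect_rel(fit$rate_fast, 6434, 0.15)
  expect_lt(abs(fit$weight_slow - 0.5), 0.1)
  # nesting: the mixture log-likelihood dominates the single exponential
  f1 <- fit_exponential(tau)
  expect_gte(fit$loglik, f1$loglik)
  # degenerate mixture collapses to a single rate
  set.seed(4)
  tau_1 <- rexp(5000, 100)
  fit_d <- fit_double_exponential(tau_1, n_starts = 6, seed = 2)
  f1_d <- fit_exponential(tau_1)
  expect_lt(fit_d$loglik - f1_d$loglik, stats::qchisq(0.999, df = 2) / 2)
})

test_that("censored double-exponential fitting renormalizes correctly", {
  set.seed(5)
  n <- 3e4
  pick <- runif(n) < 0.5
  tau <- ifelse(pick, rexp(n, 77), rexp(n, 6434))
  fit <- fit_double_exponential(tau, censor = 1e-4, n_starts = 10, seed = 3)
  expect_rel(fit$rate_slow, 77, 0.15)
})

test_that("koff versus voltage recovers a synthetic Bell slope", {
  set.seed(6)
  voltages <- c(100, 150, 200, 250)
  slope_true <- 0.004            # log10(k_off) per mV
  rows <- lapply(voltages, function(v) {
    k <- 10^(-1 + slope_true * v)
    tibble::tibble(tau_off = rexp(4000, k), voltage = v)
  })
  ev <- dplyr::bind_rows(rows)
  fit <- koff_vs_voltage(ev)
  expect_rel(fit$slope, slope_true, 0.05)
  # force-independent binding gives a flat line
  ev0 <- dplyr::bind_rows(lapply(voltages, function(v) {
    tibble::tibble(tau_off = rexp(4000, 5), voltage = v)
  }))
  fit0 <- koff_vs_voltage(ev0)
  expect_lt(abs(fit0$slope), 3 * tidy(fit0)$std.error[2] + 1e-4)
  expect_error(koff_vs_voltage(ev[ev$voltage == 100, ]), "two voltage")
})

test_that("histograms conserve counts under refinement", {
  set.seed(7)
  ev <- tibble::tibble(tau_off = rlnorm(2000, -12, 2),
                       amplitude = runif(2000),
                       outcome = sample(c("translocated", "escaped"), 2000, TRUE),
                       bound = FALSE)
  h1 <- event_histogram(ev, bins = 10)
  h2 <- event_histogram(ev, bins = 50)
  expect_equal(sum(h1$count), 2000)
  expect_equal(sum(h2$count), 2000)
  st <- scatter_table(ev)
  expect_equal(nrow(st), 2000)
  expect_true(all(c("tau_off", "amplitude", "outcome") %in% names(st)))
  expect_equal(nrow(event_histogram(ev[0, ])), 0)
})
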