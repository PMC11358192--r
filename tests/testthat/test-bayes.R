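test_that("slice_sample recovers the moments of simple targets", {
  # standard normal under the default eight-chain configuration
  ps <- slice_sample(function(x) -x^2 / 2, 0, sampler_config(seed = 1))
  draws <- as.vector(as.matrix(ps))
  expect_length(draws, 800)
  expect_lt(abs(mean(draws)), 3 / sqrt(800))
  expect_lt(abs(var(draws) - 1), 0.1)
  expect_true(all(ps$rhat < 1.05))

  # correlated bivariate normal, rho = 0.8
  rho <- 0.8
  logd <- function(x)
    -(x[1]^2 - 2 * rho * x[1] * x[2] + x[2]^2) / (2 * (1 - rho^2))
  ps2 <- slice_sample(logd, c(0, 0), sampler_config(seed = 2))
  m <- as.matrix(ps2)
  expect_lt(abs(cor(m[, 1], m[, 2]) - rho), 0.1)
})

test_that("slice_sample validates its inputs", {
  expect_error(slice_sample(function(x) if (x == 0) -Inf else -x^2, 0,
                            sampler_config()), "not finite")
  expect_error(sampler_config(n_chains = 0), "positive integer")
  expect_error(sampler_config(step_width = -1), "positive real")
  # improper target: interval expansion hits the cap
  expect_error(slice_sample(function(x) x * 1e-9, 0,
                            sampler_config(n_chains = 2, burn_in = 5,
                                           thin = 1, draws_per_chain = 5,
                                           max_steps = 20)),
               "expansion exceeded")
})

test_that("slice sampler leaves a discretized target invariant (chi-square)", {
  breaks <- c(-Inf, -1.5, -0.8, -0.3, 0.3, 0.8, 1.5, Inf)
  probs <- diff(pnorm(breaks))
  cfg <- function(s) sampler_config(n_chains = 2, burn_in = 200, thin = 5,
                                    draws_per_chain = 500, seed = s)
  reject <- 0
  for (s in 1:20) {
    draws <- as.vector(as.matrix(
      slice_sample(function(x) -x^2 / 2, 0, cfg(s))))
    counts <- table(cut(draws, breaks))
    p <- suppressWarnings(chisq.test(counts, p = probs)$p.value)
    if (p < 0.01) reject <- reject + 1
  }
  expect_lte(reject, 2)
})

test_that("check_convergence computes split-R-hat and flags disagreement", {
  # identical stationary chains
  set.seed(8)
  stream <- rnorm(400)
  d <- aperm(array(c(stream, stream), dim = c(400, 2, 1)), c(2, 1, 3))
  out <- check_convergence(d)
  expect_lt(abs(out$rhat - 1), 0.05)
  expect_true(out$pass)

  # chains centered far apart must fail
  d2 <- aperm(array(c(rnorm(200, -5), rnorm(200, 5)), dim = c(200, 2, 1)),
              c(2, 1, 3))
  out2 <- check_convergence(d2)
  expect_gt(out2$rhat, 1.05)
  expect_false(out2$pass)

  # hand-computed split-R-hat on a tiny 2 x 4 draw array
  d3 <- aperm(array(c(1, 2, 3, 4, 2, 2, 4, 8), dim = c(4, 2, 1)), c(2, 1, 3))
  segs <- list(c(1, 2), c(3, 4), c(2, 2), c(4, 8))
  W <- mean(sapply(segs, var))
  B <- 2 * var(sapply(segs, mean))
  expected <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(unname(check_convergence(d3)$rhat), expected,
               tolerance = 1e-10)

  expect_error(check_convergence(array(1:8, dim = c(1, 8, 1))),
               "at least 2 chains")
})

test_that("credible_interval uses interpolated percentiles", {
  expect_equal(credible_interval(1:1000), c(25.975, 975.025))
  expect_equal(credible_interval(rep(3.2, 500)), c(3.2, 3.2))
  set.seed(12)
  ci <- credible_interval(rnorm(5e5))
  expect_lt(max(abs(ci - c(-1.96, 1.96))), 0.05)
  expect_error(credible_interval(1:100, level = 1.2), "in \\(0, 1\\)")
  expect_error(credible_interval(1:100, level = 0), "in \\(0, 1\\)")
})

test_that("credible intervals cover at the nominal rate in conjugate runs", {
  set.seed(19)
  tau <- 1; sigma <- 1; n <- 20
  cover <- 0
  for (i in 1:500) {
    mu <- rnorm(1, 0, tau)
    ybar <- rnorm(1, mu, sigma / sqrt(n))
    post <- conjugate_posterior(ybar, n, sigma, tau)
    ci <- credible_interval(rnorm(2000, post$mean, post$sd))
    if (ci[1] <= mu && mu <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / 500, 0.93)
  expect_lte(cover / 500, 0.97)
})

test_that("savage_dickey_bf is near 1 when the posterior equals the prior", {
  set.seed(23)
  x <- rnorm(4000)
  bf <- savage_dickey_bf(x, prior_spec("normal", scale = 1))
  expect_lt(abs(log(bf$bf10)), log(1.2))
})

test_that("savage_dickey_bf matches analytic conjugate Bayes factors", {
  sigma <- 1; tau <- 1
  cfg <- sampler_config(n_chains = 8, burn_in = 200, thin = 1,
                        draws_per_chain = 3000, seed = 33)
  for (n in c(10, 30, 100)) {
    for (z in c(0, 1, 2)) {
      ybar <- z / sqrt(n)
      logpost <- function(mu)
        -n * (mu - ybar)^2 / (2 * sigma^2) + dnorm(mu, 0, tau, log = TRUE)
      ps <- slice_sample(logpost, ybar, cfg)
      bf <- savage_dickey_bf(as.vector(as.matrix(ps)),
                             prior_spec("normal", scale = tau))
      exact <- conjugate_bf_oracle(ybar, n, sigma, tau)
      expect_lt(abs(bf$bf10 / exact - 1), 0.1,
                label = sprintf("SD vs analytic at n=%d z=%g", n, z))
    }
  }
})

test_that("a posterior far from the null is displayed as >100", {
  set.seed(41)
  x <- rnorm(2000, mean = 5, sd = 0.1)
  bf <- suppressMessages(savage_dickey_bf(x, prior_spec("normal", scale = 1)))
  expect_identical(bf$display, ">100")
})

test_that("the display rule censors only above 100", {
  expect_identical(bf_display(100.0001), ">100")
  expect_identical(bf_display(99), "99")
  expect_identical(bf_result(100.2, "jzs_ttest")$display, ">100")
})

test_that("classify_bf follows the evidence bands", {
  expect_identical(classify_bf(5), "moderate against null")
  expect_identical(classify_bf(50), "strong against null")
  expect_identical(classify_bf(0.05), "strong for null")
  expect_identical(classify_bf(0.2), "moderate for null")
  expect_identical(classify_bf(1), "inconclusive")
  expect_identical(classify_bf(3), "inconclusive")
  expect_identical(classify_bf(1 / 3), "inconclusive")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("bf_robustness tracks the analytic conjugate curve", {
  sigma <- 1; n <- 50; ybar <- 0.25
  fit_at <- function(tau) {
    cfg <- sampler_config(n_chains = 4, burn_in = 200, thin = 1,
                          draws_per_chain = 3000, seed = 57)
    logpost <- function(mu)
      -n * (mu - ybar)^2 / (2 * sigma^2) + dnorm(mu, 0, tau, log = TRUE)
    ps <- slice_sample(logpost, ybar, cfg)
    savage_dickey_bf(as.vector(as.matrix(ps)),
                     prior_spec("normal", scale = tau))
  }
  curve <- bf_robustness(fit_at, c(0.5, 1, 2))
  for (i in seq_len(nrow(curve))) {
    exact <- conjugate_bf_oracle(ybar, n, sigma, curve$scale[i])
    expect_lt(abs(curve$bf10[i] / exact - 1), 0.1)
  }
  # determinism: same scale twice gives the same value
  curve2 <- bf_robustness(fit_at, c(1, 1))
  expect_identical(curve2$bf10[1], curve2$bf10[2])

  # zero observed effect favors the null at every scale >= 1
  fit_null <- function(tau) {
    logpost <- function(mu)
      -n * mu^2 / (2 * sigma^2) + dnorm(mu, 0, tau, log = TRUE)
    ps <- slice_sample(logpost, 0,
                       sampler_config(n_chains = 4, burn_in = 200, thin = 1,
                                      draws_per_chain = 2000, seed = 58))
    savage_dickey_bf(as.vector(as.matrix(ps)),
                     prior_spec("normal", scale = tau))
  }
  curve3 <- bf_robustness(fit_null, c(1, 2, 4))
  expect_true(all(curve3$bf10 < 1))

  # a failing fit is a missing point, not an error
  flaky <- function(s) if (s > 1) stop("boom") else 0.5
  expect_message(c4 <- bf_robustness(flaky, c(0.5, 2)), "failed")
  expect_equal(c4$bf10, c(0.5, NA))
})

test_that("prior_spec densities are proper and evaluable at the null", {
  for (fam in c("normal", "cauchy", "uniform")) {
    pr <- prior_spec(fam, scale = 1.5)
    expect_gt(pr$density_at(0), 0)
    mass <- integrate(function(x) pr$density_at(x), -Inf, Inf,
                      rel.tol = 1e-8)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  expect_error(prior_spec("normal", scale = 0), "positive")
})
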