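test_that("logistic is correct and stable", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(1), 0.73106, tolerance = 1e-5)
  x <- c(-3, -0.5, 0.2, 4)
  expect_equal(logistic(x) + logistic(-x), rep(1, 4))
  expect_equal(logistic(700), 1)
  expect_equal(logistic(-700), 0)
})

test_that("build_features sums counts over the shown descriptions only", {
  agg <- toy_aggregated()
  prof <- toy_profiles()
  # A: (n, m) = (2, 1) and (1, 0); B: (1, 1) and (0, 0) over two images
  f <- build_features(toy_trial(), agg, prof, model = "informant")
  expect_equal(f$dn, 2)
  expect_equal(f$dm, 0)
  expect_equal(f$outcome, 1)  # A is the more knowledgeable informant
  expect_true(is.na(f$theta))

  # only the first image shown
  f1 <- build_features(toy_trial(images = "img1", n_desc = 1L), agg, prof,
                       model = "informant")
  expect_equal(f1$dn, 1)
  expect_equal(f1$dm, 0)

  # evaluator model carries the evaluator's accuracy and the choice
  fe <- build_features(toy_trial(choice = "B"), agg, prof,
                       model = "evaluator")
  expect_equal(fe$theta, 0.6)
  expect_equal(fe$outcome, 0)

  # identical counts give zero differences
  agg2 <- agg
  agg2[agg2$informant_id == "B", c("n_specific_mode", "n_false_mode")] <-
    agg2[agg2$informant_id == "A", c("n_specific_mode", "n_false_mode")]
  f0 <- build_features(toy_trial(), agg2, prof, model = "evaluator")
  expect_equal(c(f0$dn, f0$dm), c(0, 0))
})

test_that("build_features rejects unusable trials by name", {
  agg <- toy_aggregated()
  expect_error(build_features(toy_trial(images = "img9;img2"), agg,
                              toy_profiles(), model = "informant"),
               "trial t1.*img9")
  expect_error(build_features(toy_trial(), agg,
                              toy_profiles(theta_A = 0.5, theta_B = 0.5),
                              model = "informant"),
               "equal accuracy")
  expect_error(build_features(toy_trial(), agg,
                              toy_profiles()[1:2, ], model = "evaluator"),
               "evaluator ev1")
})

test_that("choice_loglik matches hand computation and its analytic gradient", {
  f <- data.frame(trial_id = "t1", dn = 2, dm = 1, theta = 0.5,
                  n_descriptions = 1L, outcome = 1)
  expect_equal(choice_loglik(c(0, 0.32, -0.36), f, "evaluator"),
               log(plogis(0.32 * 2 - 0.36 * 0.5 * 1)))
  n <- 40
  f2 <- simulate_features(n, c(0.1, 0.3, -0.2), seed = 77)
  expect_equal(choice_loglik(c(0, 0, 0), f2, "evaluator"), n * log(0.5))

  # finite differences against the analytic gradient X'(y - p)
  X <- cbind(1, f2$dn, f2$theta * f2$dm)
  for (i in 1:5) {
    w <- rnorm(3, sd = 0.3)
    p <- plogis(as.vector(X %*% w))
    grad_analytic <- as.vector(crossprod(X, f2$outcome - p))
    eps <- 1e-6
    grad_fd <- sapply(1:3, function(j) {
      e <- rep(0, 3); e[j] <- eps
      (choice_loglik(w + e, f2, "evaluator") -
         choice_loglik(w - e, f2, "evaluator")) / (2 * eps)
    })
    expect_equal(grad_fd, grad_analytic, tolerance = 1e-4)
  }
  expect_error(choice_loglik(c(0, NA, 0), f2, "evaluator"), "finite")
})

test_that("fit_model recovers strong generating weights from many choices", {
  w_true <- c(0, 0.32, -0.36)
  feats <- simulate_features(20000, w_true, seed = 101)
  fit <- fit_model(feats, "evaluator", config = sampler_config(seed = 101))
  expect_lt(max(abs(fit$summary$mean - w_true)), 0.05)
  expect_true(all(fit$summary$rhat < 1.05))

  # Savage-Dickey term comparison: strong effects are censored at >100
  bfs <- suppressMessages(compare_models(fit))
  expect_identical(bfs$w1$display, ">100")
  expect_identical(bfs$w2$display, ">100")
})

test_that("cpp and r engines sample the same posterior", {
  feats <- simulate_features(400, c(0.1, 0.25, -0.3), seed = 55)
  cfg <- fast_sampler(seed = 55)
  fc <- fit_model(feats, "evaluator", config = cfg, engine = "cpp")
  fr <- fit_model(feats, "evaluator", config = cfg, engine = "r")
  # same target, independent randomness: means agree within joint MC error
  pooled_se <- sqrt(apply(as.matrix(fc$samples), 2, var) / 400 +
                    apply(as.matrix(fr$samples), 2, var) / 400)
  expect_true(all(abs(fc$summary$mean - fr$summary$mean) < 6 * pooled_se))
})

test_that("a null specificity weight is covered by its credible interval", {
  hits <- 0
  # enough retained draws that the CI endpoints carry negligible MC error
  cfg <- function(s) sampler_config(n_chains = 4, burn_in = 300, thin = 2,
                                    draws_per_chain = 1000, seed = s)
  for (s in 1:20) {
    feats <- simulate_features(500, c(0, 0, -0.3), seed = 200 + s)
    fit <- fit_model(feats, "evaluator", config = cfg(s))
    ci <- fit$summary[fit$summary$parameter == "w1", ]
    if (ci$ci_lower <= 0 && 0 <= ci$ci_upper) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("a null veracity weight yields null-favoring Bayes factors", {
  wins <- 0
  for (s in 1:20) {
    feats <- simulate_features(500, c(0, 0.3, 0), seed = 300 + s)
    fit <- fit_model(feats, "evaluator", config = fast_sampler(seed = s))
    bfs <- suppressMessages(compare_models(fit))
    if (bfs$w2$bf10 < 1) wins <- wins + 1
  }
  expect_gte(wins, 15)
})

test_that("the informant model recovers a positive specificity effect", {
  set.seed(404)
  dn <- sample(-8:8, 600, replace = TRUE)
  dm <- sample(-2:2, 600, replace = TRUE)
  p <- plogis(0.4 * dn - 0.2 * dm)
  feats <- data.frame(trial_id = seq_len(600), dn = dn, dm = dm,
                      theta = NA_real_, n_descriptions = 1L,
                      outcome = rbinom(600, 1, p))
  fit <- fit_model(feats, "informant", config = fast_sampler(seed = 404))
  expect_gt(fit$summary$mean[2], 0)
})

test_that("swapping the pair labels flips the weight signs", {
  feats <- simulate_features(2000, c(0.15, 0.3, -0.3), seed = 99)
  swapped <- feats
  swapped$dn <- -feats$dn
  swapped$dm <- -feats$dm
  swapped$outcome <- 1 - feats$outcome
  cfg <- fast_sampler(seed = 9)
  f1 <- fit_model(feats, "evaluator", config = cfg)
  f2 <- fit_model(swapped, "evaluator", config = cfg)
  expect_equal(f1$summary$mean[1], -f2$summary$mean[1], tolerance = 0.05)
  expect_equal(f1$summary$mean[2:3], f2$summary$mean[2:3], tolerance = 0.05)
})

test_that("the evaluator model with theta = 1 reduces to the informant model", {
  feats <- simulate_features(800, c(0, 0.3, -0.3), seed = 111)
  feats$theta <- 1
  cfg <- fast_sampler(seed = 11)
  fe <- fit_model(feats, "evaluator", config = cfg)
  fi <- fit_model(feats, "informant", config = cfg)
  # identical design matrices and seeds: draws coincide exactly
  expect_equal(as.matrix(fe$samples), as.matrix(fi$samples))
})

test_that("nonconvergence is reported with diagnostics", {
  feats <- simulate_features(200, c(0, 0.2, -0.2), seed = 13)
  # a one-iteration chain cannot converge
  cfg <- sampler_config(n_chains = 2, burn_in = 1, thin = 1,
                        draws_per_chain = 4, seed = 13)
  expect_error(fit_model(feats, "evaluator", config = cfg), "Rhat")
  expect_warning(fit_model(feats, "evaluator", config = cfg,
                           on_nonconvergence = "warn"), "Rhat")
  expect_error(fit_model(feats[1:10, ], "evaluator"), "at least 50")
})

test_that("Savage-Dickey term BFs agree with an importance-sampling oracle", {
  # a moderate veracity effect keeps the null inside the posterior's bulk,
  # where both the kernel ordinate and the IS marginal are reliable
  feats <- simulate_features(500, c(0, 0.35, -0.15), seed = 500,
                             theta_levels = c(0.4, 0.6, 0.8))
  prior_sd <- 1
  fit <- fit_model(feats, "evaluator",
                   config = sampler_config(seed = 500))
  bf_sd <- suppressMessages(compare_models(fit))$w2$bf10

  # marginal likelihood of a model by importance sampling from a Laplace
  # proposal around the posterior mode
  X_full <- cbind(1, feats$dn, feats$theta * feats$dm)
  marginal <- function(X) {
    p <- ncol(X)
    g <- suppressWarnings(glm.fit(X, feats$outcome, family = binomial()))
    cov <- 2 * chol2inv(chol(crossprod(X * sqrt(g$weights))))
    ch <- chol(cov)
    set.seed(1234)
    Z <- matrix(rnorm(8000 * p), ncol = p)
    W <- Z %*% ch + matrix(g$coefficients, 8000, p, byrow = TRUE)
    logq <- -rowSums(Z^2) / 2 - sum(log(diag(ch))) - p / 2 * log(2 * pi)
    logpost <- apply(W, 1, function(w) {
      eta <- as.vector(X %*% w)
      sum(ifelse(feats$outcome == 1, -log1p(exp(-eta)), -log1p(exp(eta)))) +
        sum(dnorm(w, 0, prior_sd, log = TRUE))
    })
    lw <- logpost - logq
    m <- max(lw)
    m + log(mean(exp(lw - m)))
  }
  bf_is <- exp(marginal(X_full) - marginal(X_full[, 1:2]))
  expect_lt(abs(bf_sd / bf_is - 1), 0.3)
})

test_that("predict_curves reflects the fitted effects", {
  # all-zero weights: flat chance curves
  flat <- predict_curves(c(0, 0, 0), model = "evaluator")
  expect_true(all(flat$p_mean == 0.5))

  w <- c(0, 0.32, -0.36)
  cv <- predict_curves(w, model = "evaluator", statement_range = 0:6)
  # more true statements by A always helps A (w1 > 0), for every theta
  for (th in unique(cv$theta)) {
    sub <- cv[cv$side == "A" & cv$type == "true" & cv$theta == th, ]
    expect_true(all(diff(sub$p_mean[order(sub$statements_added)]) > 0))
  }
  # at theta = 0.5 false statements still help A (0.32 - 0.36 * 0.5 > 0)
  sub <- cv[cv$side == "A" & cv$type == "false" & cv$theta == 0.5, ]
  expect_true(all(diff(sub$p_mean[order(sub$statements_added)]) > 0))
  # at theta = 0.9 the effect reverses
  sub <- cv[cv$side == "A" & cv$type == "false" & cv$theta == 0.9, ]
  expect_true(all(diff(sub$p_mean[order(sub$statements_added)]) < 0))
  # sides are mirror images
  a <- cv[cv$side == "A" & cv$type == "true" & cv$theta == 0.75, ]
  b <- cv[cv$side == "B" & cv$type == "true" & cv$theta == 0.75, ]
  expect_equal(a$p_mean + b$p_mean[order(b$statements_added)], rep(1, 7))
  expect_error(predict_curves(w, theta_grid = numeric(0)), "non-empty")
})

test_that("posterior curves carry bands from the draws", {
  feats <- simulate_features(1500, c(0, 0.3, -0.35), seed = 808)
  fit <- fit_model(feats, "evaluator", config = fast_sampler(seed = 8))
  cv <- predict_curves(fit, statement_range = c(0, 2, 4))
  expect_true(all(cv$p_lo <= cv$p_mean & cv$p_mean <= cv$p_hi))
  expect_true(any(cv$p_hi - cv$p_lo > 0))
})
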