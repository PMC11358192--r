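# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route than the package.

# JZS t-test BF via the classical g-integral (the package integrates the
# noncentral-t likelihood over the Cauchy effect prior instead).
jzs_bf_oracle <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  if (is.null(n2)) {
    N <- n1; df <- n1 - 1
  } else {
    N <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  integrand <- function(g)
    (1 + N * g)^-0.5 * (1 + t^2 / ((1 + N * g) * df))^(-(df + 1) / 2) *
      rscale / sqrt(2 * pi) * g^-1.5 * exp(-rscale^2 / (2 * g))
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-10,
                   subdivisions = 800L)$value
  num / (1 + t^2 / df)^(-(df + 1) / 2)
}

# Gauss hypergeometric 2F1 via the Euler integral representation (the
# package sums the power series instead).
hyp2f1_oracle <- function(a, b, c, z) {
  stopifnot(c > b, b > 0)
  lg <- lgamma(c) - lgamma(b) - lgamma(c - b)
  f <- function(t) t^(b - 1) * (1 - t)^(c - b - 1) * (1 - z * t)^(-a)
  exp(lg) * integrate(f, 0, 1, rel.tol = 1e-12)$value
}

# Stretched-beta correlation BF by fixed-grid trapezoid quadrature over the
# population correlation, with the Euler-integral 2F1.
pearson_bf_oracle <- function(r, n, kappa = 1, n_grid = 4001) {
  a <- 1 / kappa
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  loglr <- vapply(rho, function(p) {
    (n - 1) / 2 * log1p(-p^2) - (2 * n - 3) / 2 * log1p(-p * r) +
      log(hyp2f1_oracle(0.5, 0.5, (2 * n - 1) / 2, (p * r + 1) / 2)) -
      log(hyp2f1_oracle(0.5, 0.5, (2 * n - 1) / 2, 0.5))
  }, 0)
  w <- dbeta((rho + 1) / 2, a, a) / 2
  f <- exp(loglr) * w
  h <- diff(rho[1:2])
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

# ICC(2,1) from aov() mean squares (the package computes the sums of squares
# directly).
icc21_aov_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   item = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(aov(y ~ item + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exhaustive split-half ceiling for one pair: enumerate every half-subset of
# the question indices.
ceiling_enum_oracle <- function(a, b) {
  q <- length(a)
  splits <- utils::combn(q, q / 2)
  credit <- apply(splits, 2, function(idx) {
    seen_d <- sum(a[idx]) - sum(b[idx])
    unseen_d <- sum(a[-idx]) - sum(b[-idx])
    if (seen_d == 0) return(0.5)
    if (sign(unseen_d) == sign(seen_d)) return(1)
    if (unseen_d == 0) return(0.5)
    0
  })
  mean(credit)
}

# Analytic BF10 for a conjugate normal point-null problem: data mean ybar of
# n observations with known sigma; H1: mu ~ normal(0, tau).  Used to check
# the Savage-Dickey estimator.
conjugate_bf_oracle <- function(ybar, n, sigma, tau) {
  se2 <- sigma^2 / n
  m1 <- dnorm(ybar, 0, sqrt(se2 + tau^2))
  m0 <- dnorm(ybar, 0, sqrt(se2))
  m1 / m0
}

# Posterior of mu for the same conjugate problem.
conjugate_posterior <- function(ybar, n, sigma, tau) {
  se2 <- sigma^2 / n
  v <- 1 / (1 / tau^2 + 1 / se2)
  list(mean = v * ybar / se2, sd = sqrt(v))
}
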