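#' Prior specification for a single parameter
#'
#' A proper prior density with an evaluable ordinate, as required by the
#' Savage-Dickey density-ratio method.  The default for regression weights is
#' a zero-mean normal with scale 1.
#'
#' @param family one of `"normal"`, `"cauchy"`, `"uniform"`.
#' @param scale positive scale (sd for normal, scale for Cauchy, half-width
#'   for uniform).
#' @param location center of the prior.
#' @return an object of class `prior_spec` with a `density_at(x)` function.
#' @export
prior_spec <- function(family = c("normal", "cauchy", "uniform"), scale = 1,
                       location = 0) {
  family <- match.arg(family)
  if (!is.numeric(scale) || scale <= 0)
    stop("'scale' must be a positive real", call. = FALSE)
  density_at <- switch(family,
    normal  = function(x) dnorm(x, location, scale),
    cauchy  = function(x) dcauchy(x, location, scale),
    uniform = function(x) ifelse(abs(x - location) <= scale, 1 / (2 * scale), 0))
  structure(list(family = family, scale = scale, location = location,
                 density_at = density_at),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior: %s(location = %g, scale = %g)\n",
              x$family, x$location, x$scale))
  invisible(x)
}

#' Bayes-factor result container
#'
#' Holds a BF10 together with the method, prior, optional robustness curve,
#' and the display string: Bayes factors above 100 are shown as `">100"` for
#' readability.
#'
#' @param bf10 positive Bayes factor for the alternative over the null
#'   (`Inf` allowed when the posterior ordinate underflows; flagged).
#' @param method label, e.g. `"savage_dickey"`, `"jzs_ttest"`,
#'   `"stretched_beta_correlation"`.
#' @param prior the `prior_spec` (or a descriptive list) used.
#' @param robustness optional data.frame with columns `scale`, `bf10`.
#' @param censored logical; `TRUE` when the posterior ordinate was
#'   numerically zero and the BF is only known to exceed the display bound.
#' @return an object of class `bf_result`.
#' @export
bf_result <- function(bf10, method, prior = NULL, robustness = NULL,
                      censored = FALSE) {
  if (!is.numeric(bf10) || length(bf10) != 1 || is.na(bf10) || bf10 <= 0)
    stop("'bf10' must be a single positive number", call. = FALSE)
  structure(list(bf10 = bf10, method = method, prior = prior,
                 robustness = robustness, censored = censored,
                 display = bf_display(bf10)),
            class = "bf_result")
}

#' Display rule for Bayes factors
#'
#' @param bf10 positive Bayes factor.
#' @return `">100"` when `bf10 > 100`, otherwise the number formatted to three
#'   significant digits.
#' @export
bf_display <- function(bf10) {
  if (bf10 > 100) ">100" else format(signif(bf10, 3))
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %s (%s; %s)\n", x$display, x$method, classify_bf(x$bf10)))
  if (!is.null(x$robustness)) {
    cat("Robustness:\n")
    print(x$robustness, row.names = FALSE)
  }
  invisible(x)
}

#' Evidence category of a Bayes factor
#'
#' Classifies BF10 on the conventional evidence bands: values in (3, 10]
#' give moderate and values above 10 strong evidence against the null;
#' reciprocally for evidence in favour of the null; the closed band
#' \[1/3, 3\] is inconclusive.
#'
#' @param bf10 positive Bayes factor.
#' @return a label string.
#' @export
classify_bf <- function(bf10) {
  if (!is.numeric(bf10) || length(bf10) != 1 || is.na(bf10) || bf10 <= 0)
    stop("'bf10' must be a single positive number", call. = FALSE)
  if (bf10 > 10) "strong against null"
  else if (bf10 > 3) "moderate against null"
  else if (bf10 >= 1 / 3) "inconclusive"
  else if (bf10 >= 1 / 10) "moderate for null"
  else "strong for null"
}

#' Savage-Dickey Bayes factor for a point null
#'
#' Estimates BF10 for the nested point null `parameter = at` as the ratio of
#' prior to posterior density at the test value.  The posterior ordinate is
#' estimated from MCMC draws by a Gaussian kernel density with Silverman
#' bandwidth; a normal-approximation cross-check is logged (as a warning-level
#' message and a flag) when the two ordinates disagree by more than 25%.
#'
#' @param x numeric posterior draws for one parameter, or a
#'   `posterior_samples` object together with `parameter`.
#' @param prior a [prior_spec()]; must have positive density at `at`.
#' @param at the null value (default 0).
#' @param parameter name or index of the parameter when `x` is a
#'   `posterior_samples` object.
#' @return a [bf_result()] with method `"savage_dickey"`.  The
#'   `density_check` attribute carries the KDE and normal-approximation
#'   ordinates.
#' @export
savage_dickey_bf <- function(x, prior = prior_spec(), at = 0, parameter = 1) {
  if (inherits(x, "posterior_samples")) x <- as.matrix(x)[, parameter]
  x <- as.numeric(x)
  if (length(x) < 10) stop("need at least 10 posterior draws", call. = FALSE)
  p0 <- prior$density_at(at)
  if (!is.finite(p0) || p0 <= 0)
    stop("prior density at the test value must be finite and positive",
         call. = FALSE)
  bw <- bw.nrd0(x)
  post_kde <- mean(dnorm(at, mean = x, sd = bw))
  post_norm <- dnorm(at, mean(x), sd(x))
  mismatch <- is.finite(post_norm) && post_norm > 0 && post_kde > 0 &&
    abs(log(post_kde / post_norm)) > log(1.25)
  if (mismatch)
    message(sprintf(paste0("savage_dickey_bf: KDE ordinate %.3g and normal ",
                           "approximation %.3g disagree by more than 25%%; ",
                           "the posterior may be skewed or thin at the null"),
                    post_kde, post_norm))
  censored <- post_kde <= 0 || !is.finite(p0 / post_kde)
  bf10 <- if (censored) Inf else p0 / post_kde
  res <- bf_result(bf10, "savage_dickey", prior = prior, censored = censored)
  attr(res, "density_check") <- c(kde = post_kde, normal_approx = post_norm)
  res
}

#' Bayes-factor robustness curve
#'
#' Re-evaluates a Bayes factor across a set of prior scales.  `fit_fn` is
#' called once per scale and must return either a `bf_result` or a single
#' positive number; failures are recorded as missing points so a partial
#' curve is still returned.
#'
#' @param fit_fn function of one argument (the prior scale).
#' @param scales numeric vector of at least two positive prior scales.
#' @return data.frame with columns `scale` and `bf10` (NA where a fit failed).
#' @export
bf_robustness <- function(fit_fn, scales = c(0.5, 1, 2)) {
  if (length(scales) < 2) stop("need at least 2 prior scales", call. = FALSE)
  bf <- vapply(scales, function(s) {
    out <- tryCatch(fit_fn(s), error = function(e) {
      message(sprintf("bf_robustness: fit at scale %g failed: %s",
                      s, conditionMessage(e)))
      NA_real_
    })
    if (inherits(out, "bf_result")) out$bf10 else as.numeric(out)
  }, 0)
  data.frame(scale = as.numeric(scales), bf10 = bf)
}
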