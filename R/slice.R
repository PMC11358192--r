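#' Slice-sampler configuration
#'
#' Bundles the settings of the Markov chain Monte Carlo sampler used
#' throughout the package.  The defaults match the sampler configuration used
#' for all logistic-regression fits in this package: eight chains, a burn-in
#' of 1000 iterations, and 100 retained draws per chain taken every 20th
#' iteration after burn-in (800 pooled draws in total).
#'
#' @param n_chains number of independent chains.
#' @param burn_in iterations (full coordinate scans) discarded per chain.
#' @param thin keep every `thin`-th state after burn-in.
#' @param draws_per_chain retained draws per chain.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param step_width initial width of the slice stepping-out interval.
#' @param max_steps cap on stepping-out expansions per side.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 8, burn_in = 1000, thin = 20,
                           draws_per_chain = 100, seed = 1, step_width = 1,
                           max_steps = 100) {
  for (nm in c("n_chains", "burn_in", "thin", "draws_per_chain", "max_steps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  }
  if (!is.numeric(step_width) || step_width <= 0)
    stop("'step_width' must be a positive real", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 draws_per_chain = as.integer(draws_per_chain),
                 seed = as.integer(seed), step_width = step_width,
                 max_steps = as.integer(max_steps)),
            class = "sampler_config")
}

# Deterministic per-chain seed derived from the master seed; stays within
# 32-bit integer range.
chain_seed <- function(seed, chain) {
  as.integer((as.double(seed) * 48271 + chain * 30269) %% 2147483629)
}

#' Univariate stepping-out slice update (Neal 2003)
#'
#' Internal single-coordinate update.  `f` is the log density as a function of
#' the coordinate value; `x0` the current value; `f0 = f(x0)`.
#' @noRd
slice_update1 <- function(f, x0, f0, step_width, max_steps) {
  logy <- f0 - rexp(1)
  L <- x0 - step_width * runif(1)
  R <- L + step_width
  k <- 0
  while (f(L) > logy) {
    L <- L - step_width
    if ((k <- k + 1) > max_steps)
      stop(sprintf("slice interval expansion exceeded %d steps (left edge %.3g); the target may be improper", max_steps, L), call. = FALSE)
  }
  k <- 0
  while (f(R) > logy) {
    R <- R + step_width
    if ((k <- k + 1) > max_steps)
      stop(sprintf("slice interval expansion exceeded %d steps (right edge %.3g); the target may be improper", max_steps, R), call. = FALSE)
  }
  repeat {
    x1 <- L + (R - L) * runif(1)
    f1 <- f(x1)
    if (f1 >= logy) return(list(x = x1, f = f1))
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-300) return(list(x = x0, f = f0))
  }
}

#' Slice-sampling MCMC for an arbitrary log density
#'
#' Draws from a target distribution given only its unnormalised log density,
#' using univariate stepping-out/shrinkage slice updates cycled over
#' coordinates.  Chains are run independently from deterministically derived
#' per-chain seeds; after `burn_in` full scans every `thin`-th state is
#' retained until `draws_per_chain` draws are collected.
#'
#' @param log_density function taking a parameter vector, returning a finite
#'   log density (possibly `-Inf` outside the support).
#' @param init numeric parameter vector with finite `log_density(init)`.
#' @param config a [sampler_config()].
#' @param parameter_names optional character labels.
#' @return an object of class `posterior_samples`: a list with `draws`
#'   (chains x draws x parameters array), `parameter_names`, `config`, and
#'   `rhat` (split-R-hat per parameter, computed on the retained draws).
#' @examples
#' ps <- slice_sample(function(x) -x^2 / 2, 0,
#'                    sampler_config(n_chains = 4, burn_in = 100, thin = 2,
#'                                   draws_per_chain = 200, seed = 7))
#' mean(as.matrix(ps))
#' @export
slice_sample <- function(log_density, init, config = sampler_config(),
                         parameter_names = NULL) {
  stopifnot(inherits(config, "sampler_config"))
  init <- as.numeric(init)
  p <- length(init)
  f0 <- log_density(init)
  if (!is.finite(f0))
    stop("log_density is not finite at 'init'", call. = FALSE)
  if (is.null(parameter_names))
    parameter_names <- if (p == 1) "x" else paste0("x", seq_len(p))
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$draws_per_chain, p),
                 dimnames = list(NULL, NULL, parameter_names))
  total <- config$burn_in + config$thin * config$draws_per_chain
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seed(config$seed, ch))
    x <- init
    fx <- f0
    kept <- 0L
    for (it in seq_len(total)) {
      for (j in seq_len(p)) {
        fj <- function(v) { x2 <- x; x2[j] <- v; log_density(x2) }
        up <- slice_update1(fj, x[j], fx, config$step_width, config$max_steps)
        x[j] <- up$x
        fx <- up$f
      }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        kept <- kept + 1L
        draws[ch, kept, ] <- x
      }
    }
  }
  out <- structure(list(draws = draws, parameter_names = parameter_names,
                        config = config, rhat = NULL),
                   class = "posterior_samples")
  out$rhat <- check_convergence(out)$rhat
  out
}

#' Pool posterior draws into a matrix
#'
#' @param x a `posterior_samples` object.
#' @param ... unused.
#' @return a (chains * draws) x parameters matrix.
#' @export
as.matrix.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- x$parameter_names
  m
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior samples: %d chains x %d draws x %d parameter(s)\n",
              d[1], d[2], d[3]))
  m <- as.matrix(x)
  for (j in seq_len(ncol(m))) {
    ci <- credible_interval(m[, j])
    cat(sprintf("  %-10s mean %8.4f  95%% CI [%.4f, %.4f]  Rhat %.3f\n",
                x$parameter_names[j], mean(m[, j]), ci[1], ci[2], x$rhat[j]))
  }
  invisible(x)
}

#' Split-R-hat convergence diagnostic
#'
#' Computes the split-chain potential scale reduction factor per parameter and
#' compares it against a threshold.  Each chain is split in half so that
#' within-chain trends register as between-chain disagreement.
#'
#' @param samples a `posterior_samples` object (or a chains x draws x
#'   parameters array) with at least two chains.
#' @param threshold pass if every R-hat is below this (default 1.05).
#' @return list with `rhat` (named numeric) and `pass` (logical).
#' @export
check_convergence <- function(samples, threshold = 1.05) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  stopifnot(length(dim(draws)) == 3)
  nch <- dim(draws)[1]
  if (nch < 2) stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  nd <- dim(draws)[2]
  if (nd %% 2 == 1) { draws <- draws[, -1, , drop = FALSE]; nd <- nd - 1 }
  half <- nd / 2
  p <- dim(draws)[3]
  rhat <- numeric(p)
  for (j in seq_len(p)) {
    segs <- vector("list", 2 * nch)
    for (ch in seq_len(nch)) {
      segs[[2 * ch - 1]] <- draws[ch, seq_len(half), j]
      segs[[2 * ch]] <- draws[ch, half + seq_len(half), j]
    }
    mns <- vapply(segs, mean, 0)
    vrs <- vapply(segs, var, 0)
    W <- mean(vrs)
    B <- half * var(mns)
    vplus <- (half - 1) / half * W + B / half
    rhat[j] <- if (W == 0) 1 else sqrt(vplus / W)
  }
  names(rhat) <- if (inherits(samples, "posterior_samples"))
    samples$parameter_names else paste0("x", seq_len(p))
  list(rhat = rhat, pass = all(rhat < threshold))
}

#' Equal-tailed credible interval
#'
#' Percentile interval from posterior draws, using linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param x numeric draws for a single parameter.
#' @param level interval mass in (0, 1); default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(x, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("'level' must be a single number in (0, 1)", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 draws", call. = FALSE)
  a <- (1 - level) / 2
  quantile(x, c(a, 1 - a), type = 7, names = FALSE)
}
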