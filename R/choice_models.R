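#' Logistic function
#'
#' `1 / (1 + exp(-x))`, numerically stable over the full double range.
#'
#' @param x numeric vector.
#' @return probabilities in (0, 1).
#' @export
logistic <- function(x) plogis(x)

# log logistic(z), stable for large |z|
log_logistic <- function(z) ifelse(z < 0, z - log1p(exp(z)), -log1p(exp(-z)))

trial_cols <- c("trial_id", "evaluator_id", "category_id", "informant_A",
                "informant_B", "image_ids", "n_descriptions", "choice")

#' Read a discrimination-trials table
#'
#' One row per evaluator trial: the informant pair compared, the semicolon
#' separated list of image ids whose descriptions were shown, and the
#' evaluator's choice (`"A"` or `"B"`).
#'
#' @param path CSV file with header columns `trial_id`, `evaluator_id`,
#'   `category_id`, `informant_A`, `informant_B`, `image_ids`,
#'   `n_descriptions`, `choice`.
#' @return a validated data.frame.
#' @export
read_trials <- function(path) {
  validate_trials(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(image_ids = "character")))
}

#' @rdname read_trials
#' @param df trials data.frame to validate.
#' @export
validate_trials <- function(df) {
  missing <- setdiff(trial_cols, names(df))
  if (length(missing))
    stop(sprintf("trials table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!all(df$choice %in% c("A", "B")))
    stop("'choice' must be 'A' or 'B'", call. = FALSE)
  n_img <- lengths(strsplit(as.character(df$image_ids), ";", fixed = TRUE))
  bad <- n_img != df$n_descriptions
  if (any(bad))
    stop(sprintf("trial %s: image_ids lists %d image(s) but n_descriptions is %d",
                 df$trial_id[bad][1], n_img[bad][1],
                 df$n_descriptions[bad][1]), call. = FALSE)
  df
}

#' Write a trials table
#' @param df trials data.frame.
#' @param path output CSV path.
#' @export
write_trials <- function(df, path) {
  write.csv(validate_trials(df)[trial_cols], path, row.names = FALSE)
  invisible(path)
}

#' Build model covariates for discrimination trials
#'
#' For every trial, sums the mode-aggregated statement counts over exactly
#' the descriptions shown and forms the covariates of the two logistic
#' models: `dn` (difference in total specific statements, A minus B), `dm`
#' (difference in total false statements), and for the evaluator model the
#' evaluator's accuracy `theta` in the trial's category.  The outcome is the
#' ground truth (informant model: whether A scored higher than B on the
#' category's knowledge questions) or the evaluator's observed choice
#' (evaluator model).
#'
#' @param trials validated trials data.frame.
#' @param aggregated output of [aggregate_annotations()].
#' @param profiles output of [score_knowledge()] covering all informants (and
#'   for the evaluator model, all evaluators).
#' @param model `"informant"` or `"evaluator"`.
#' @return data.frame of features: `trial_id`, `dn`, `dm`, `theta`,
#'   `n_descriptions`, `outcome`.
#' @export
build_features <- function(trials, aggregated, profiles,
                           model = c("informant", "evaluator")) {
  model <- match.arg(model)
  trials <- validate_trials(trials)
  agg_key <- paste(aggregated$informant_id, aggregated$category_id,
                   aggregated$image_id, sep = "\r")
  lookup_counts <- function(informant, category, images, trial_id) {
    idx <- match(paste(informant, category, images, sep = "\r"), agg_key)
    if (anyNA(idx))
      stop(sprintf("trial %s: no aggregated annotation for informant %s, category %s, image %s",
                   trial_id, informant, category, images[is.na(idx)][1]),
           call. = FALSE)
    c(n = sum(aggregated$n_specific_mode[idx]),
      m = sum(aggregated$n_false_mode[idx]))
  }
  prof_key <- paste(profiles$participant_id, profiles$category_id, sep = "\r")
  lookup_theta <- function(participant, category, trial_id, who) {
    idx <- match(paste(participant, category, sep = "\r"), prof_key)
    if (is.na(idx))
      stop(sprintf("trial %s: no knowledge profile for %s %s in category %s",
                   trial_id, who, participant, category), call. = FALSE)
    profiles$theta[idx]
  }
  images <- strsplit(as.character(trials$image_ids), ";", fixed = TRUE)
  out <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    ca <- lookup_counts(tr$informant_A, tr$category_id, images[[i]], tr$trial_id)
    cb <- lookup_counts(tr$informant_B, tr$category_id, images[[i]], tr$trial_id)
    if (model == "informant") {
      ta <- lookup_theta(tr$informant_A, tr$category_id, tr$trial_id, "informant")
      tb <- lookup_theta(tr$informant_B, tr$category_id, tr$trial_id, "informant")
      if (ta == tb)
        stop(sprintf("trial %s: informants %s and %s have equal accuracy; ground truth undefined",
                     tr$trial_id, tr$informant_A, tr$informant_B),
             call. = FALSE)
      outcome <- as.integer(ta > tb)
      theta <- NA_real_
    } else {
      theta <- lookup_theta(tr$evaluator_id, tr$category_id, tr$trial_id,
                            "evaluator")
      outcome <- as.integer(tr$choice == "A")
    }
    data.frame(trial_id = tr$trial_id, dn = ca["n"] - cb["n"],
               dm = ca["m"] - cb["m"], theta = theta,
               n_descriptions = tr$n_descriptions, outcome = outcome,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

# Design matrix for a model: informant uses dm directly, evaluator scales dm
# by the evaluator's accuracy theta (the knowledgeability x veracity
# interaction).
model_design <- function(features, model, center_theta = FALSE) {
  if (model == "evaluator") {
    if (anyNA(features$theta))
      stop("evaluator model requires 'theta' for every trial", call. = FALSE)
    th <- features$theta
    if (center_theta) th <- th - mean(th)
    cbind(w0 = 1, w1 = features$dn, w2 = th * features$dm)
  } else {
    cbind(w0 = 1, w1 = features$dn, w2 = features$dm)
  }
}

#' Log likelihood of a choice model
#'
#' Sum over trials of the Bernoulli log likelihood with success probability
#' `logistic(w0 + w1*dn + w2*dm)` (informant model) or
#' `logistic(w0 + w1*dn + w2*theta*dm)` (evaluator model).
#'
#' @param weights numeric vector `(w0, w1, w2)`.
#' @param features output of [build_features()].
#' @param model `"informant"` or `"evaluator"`.
#' @param center_theta center theta before forming the interaction.
#' @return the log likelihood (a single real).
#' @export
choice_loglik <- function(weights, features,
                          model = c("informant", "evaluator"),
                          center_theta = FALSE) {
  model <- match.arg(model)
  if (length(weights) != 3 || any(!is.finite(weights)))
    stop("'weights' must be 3 finite numbers", call. = FALSE)
  X <- model_design(features, model, center_theta)
  s <- ifelse(features$outcome == 1, 1, -1)
  sum(log_logistic(s * as.vector(X %*% weights)))
}

#' Fit a Bayesian logistic choice model by slice sampling
#'
#' Posterior over the weights `(w0, w1, w2)` under independent zero-mean
#' normal priors, sampled with the stepping-out/shrinkage slice sampler (the
#' default configuration runs eight chains of 1000 burn-in iterations and
#' retains 100 draws per chain at every 20th iteration).  The default engine
#' is a compiled implementation of the identical algorithm; `engine = "r"`
#' runs the generic [slice_sample()] on the same posterior.
#'
#' @param features output of [build_features()] (>= 50 trials).
#' @param model `"informant"` or `"evaluator"`.
#' @param prior a [prior_spec()] with family `"normal"`; its scale is the
#'   common prior sd of the weights (a length-3 `scale` is allowed).
#' @param config a [sampler_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @param center_theta center theta before forming the interaction.
#' @param on_nonconvergence `"error"` (default) or `"warn"` when any
#'   split-R-hat exceeds 1.05.
#' @return object of class `choice_fit`: list with `samples`
#'   (`posterior_samples`), `summary` (posterior means and 95% CIs), `model`,
#'   `prior`, `n_trials`.
#' @export
fit_model <- function(features, model = c("informant", "evaluator"),
                      prior = prior_spec("normal", scale = 1),
                      config = sampler_config(), engine = c("cpp", "r"),
                      center_theta = FALSE,
                      on_nonconvergence = c("error", "warn")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (nrow(features) < 50)
    stop("need at least 50 trials to fit a choice model", call. = FALSE)
  if (!inherits(prior, "prior_spec") || prior$family != "normal")
    stop("'prior' must be a normal prior_spec", call. = FALSE)
  X <- model_design(features, model, center_theta)
  y <- as.integer(features$outcome)
  prior_sd <- rep_len(prior$scale, 3)
  samples <- fit_logistic_bayes(X, y, prior_sd, config, engine,
                                parameter_names = c("w0", "w1", "w2"))
  conv <- check_convergence(samples)
  if (!conv$pass) {
    msg <- sprintf("sampler did not converge: Rhat = %s",
                   paste(sprintf("%s %.3f", names(conv$rhat), conv$rhat),
                         collapse = ", "))
    if (on_nonconvergence == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  m <- as.matrix(samples)
  summ <- data.frame(parameter = colnames(m), mean = colMeans(m),
                     ci_lower = apply(m, 2, function(v) credible_interval(v)[1]),
                     ci_upper = apply(m, 2, function(v) credible_interval(v)[2]),
                     rhat = conv$rhat, row.names = NULL)
  structure(list(samples = samples, summary = summ, model = model,
                 prior = prior, center_theta = center_theta,
                 n_trials = nrow(features), features = features),
            class = "choice_fit")
}

# Shared fitting core for an arbitrary logistic design matrix.
fit_logistic_bayes <- function(X, y, prior_sd, config, engine = "cpp",
                               parameter_names = colnames(X)) {
  p <- ncol(X)
  prior_sd <- rep_len(prior_sd, p)
  if (engine == "cpp") {
    # collapse duplicate (x, y) rows into weighted rows: the likelihood is
    # unchanged and evaluations get cheaper
    key <- do.call(paste, c(as.data.frame(X), list(y)))
    first <- !duplicated(key)
    wt <- as.numeric(table(key)[key[first]])
    Xc <- X[first, , drop = FALSE]
    yc <- as.integer(y[first])
    # per-coordinate stepping-out widths from a preliminary IWLS fit
    # (slice sampling is exact for any fixed width; this only sizes the
    # initial bracket), capped at the configured width
    widths <- rep(config$step_width, p)
    se <- tryCatch({
      g <- suppressWarnings(stats::glm.fit(Xc, yc, weights = wt,
                                           family = stats::binomial()))
      # g$weights are the IWLS working weights (already including wt)
      cov <- chol2inv(chol(crossprod(Xc * sqrt(g$weights))))
      sqrt(diag(cov))
    }, error = function(e) NULL)
    if (!is.null(se) && all(is.finite(se)) && all(se > 0))
      widths <- pmin(widths, 4 * se)
    draws <- array(NA_real_, dim = c(config$n_chains, config$draws_per_chain, p),
                   dimnames = list(NULL, NULL, parameter_names))
    for (ch in seq_len(config$n_chains)) {
      set.seed(chain_seed(config$seed, ch))
      draws[ch, , ] <- .slice_logistic_chain(
        Xc, yc, wt, prior_sd, rep(0, p), config$burn_in, config$thin,
        config$draws_per_chain, widths, config$max_steps)
    }
    out <- structure(list(draws = draws, parameter_names = parameter_names,
                          config = config, rhat = NULL),
                     class = "posterior_samples")
    out$rhat <- check_convergence(out)$rhat
    out
  } else {
    s <- ifelse(y == 1, 1, -1)
    logpost <- function(w)
      sum(log_logistic(s * as.vector(X %*% w))) +
        sum(dnorm(w, 0, prior_sd, log = TRUE))
    slice_sample(logpost, rep(0, p), config, parameter_names)
  }
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("Bayesian logistic %s model (%d trials, prior sd %s)\n",
              x$model, x$n_trials,
              paste(format(x$prior$scale), collapse = "/")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Savage-Dickey model comparison for the choice-model terms
#'
#' For the specificity weight `w1` and the veracity weight `w2` (the
#' interaction weight in the evaluator model), computes the Savage-Dickey
#' Bayes factor comparing the full model against the nested model with that
#' weight fixed at zero.  Optionally refits across prior scales for a
#' robustness curve on each term.
#'
#' @param fit a `choice_fit`, or `features` plus fitting arguments as in
#'   [fit_model()].
#' @param robustness_scales prior scales for robustness curves, or `NULL` to
#'   skip refitting.
#' @param ... passed to [fit_model()] when `fit` is a features data.frame.
#' @return named list of [bf_result()] for `w1` and `w2`.
#' @export
compare_models <- function(fit, robustness_scales = NULL, ...) {
  if (!inherits(fit, "choice_fit")) fit <- fit_model(fit, ...)
  m <- as.matrix(fit$samples)
  prior_sd <- rep_len(fit$prior$scale, 3)
  out <- list()
  for (j in 2:3) {
    nm <- c("w0", "w1", "w2")[j]
    res <- savage_dickey_bf(m[, j], prior_spec("normal", scale = prior_sd[j]))
    if (!is.null(robustness_scales)) {
      res$robustness <- bf_robustness(function(s) {
        refit <- fit_model(fit$features, model = fit$model,
                           prior = prior_spec("normal", scale = s),
                           config = fit$samples$config,
                           center_theta = fit$center_theta)
        savage_dickey_bf(as.matrix(refit$samples)[, j],
                         prior_spec("normal", scale = s))$bf10
      }, robustness_scales)
    }
    out[[nm]] <- res
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model-implied choice-probability curves
#'
#' Predicted probability of choosing (or correctly identifying) informant A
#' as a function of statements added to one informant, holding the other
#' fixed: adding a true statement to A raises the linear predictor by `w1`
#' per statement; adding a false statement raises it by `w1 + w2*theta`
#' (evaluator model; `w1 + w2` for the informant model), since a false
#' statement increments both the specific and the false count.  Statements
#' added to B act with opposite sign.  With a fitted posterior the curves
#' carry 95% bands from per-draw predicted probabilities.
#'
#' @param fit a `choice_fit`, or a numeric weight vector `(w0, w1, w2)`.
#' @param theta_grid evaluator accuracies at which to evaluate the evaluator
#'   model (default `c(0.5, 0.75, 0.9)`); ignored for the informant model.
#' @param statement_range integer counts of statements added (default 0:5).
#' @param model required when `fit` is a bare weight vector.
#' @param baseline linear-predictor offset added to every curve (default 0,
#'   i.e. curves start from evenly matched informants).
#' @return tidy data.frame: `theta`, `statements_added`, `side` (A/B),
#'   `type` (true/false), `p_mean`, `p_lo`, `p_hi`.
#' @export
predict_curves <- function(fit, theta_grid = c(0.5, 0.75, 0.9),
                           statement_range = 0:5,
                           model = c("informant", "evaluator"),
                           baseline = 0) {
  if (length(theta_grid) == 0 || length(statement_range) == 0)
    stop("'theta_grid' and 'statement_range' must be non-empty", call. = FALSE)
  if (inherits(fit, "choice_fit")) {
    model <- fit$model
    W <- as.matrix(fit$samples)
  } else {
    model <- match.arg(model)
    W <- matrix(as.numeric(fit), nrow = 1)
  }
  if (model == "informant") theta_grid <- NA_real_
  grid <- expand.grid(theta = theta_grid, statements_added = statement_range,
                      side = c("A", "B"), type = c("true", "false"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    slope <- if (g$type == "true") W[, 2]
             else W[, 2] + W[, 3] * (if (model == "evaluator") g$theta else 1)
    sgn <- if (g$side == "A") 1 else -1
    eta <- W[, 1] + baseline + sgn * slope * g$statements_added
    p <- logistic(eta)
    data.frame(g, p_mean = mean(p),
               p_lo = if (length(p) > 1) credible_interval(p)[1] else p,
               p_hi = if (length(p) > 1) credible_interval(p)[2] else p,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Knowledgeability at which false statements stop helping
#'
#' In the evaluator model the net effect of one additional false statement by
#' A on the linear predictor is `w1 + w2*theta`; it is positive (false
#' statements make choosing A more likely) below `theta* = w1 / (-w2)` and
#' negative above.
#'
#' @param fit a `choice_fit` for the evaluator model, or a numeric weight
#'   vector `(w0, w1, w2)` (posterior means are used for a fit).
#' @return the crossover accuracy `w1 / (-w2)`.
#' @export
false_statement_crossover <- function(fit) {
  w <- if (inherits(fit, "choice_fit")) fit$summary$mean else as.numeric(fit)
  if (w[3] >= 0)
    stop("crossover requires a negative veracity weight w2", call. = FALSE)
  w[2] / (-w[3])
}
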