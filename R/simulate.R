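#' Configuration of a synthetic study
#'
#' All generative parameters of the simulated study.  The defaults reproduce
#' the design of the study the package analyses: 100 informants and 160
#' evaluators, 30 categories with 30 multiple-choice questions each, four
#' categories per participant (two self-selected, two randomly assigned), 12
#' image descriptions per informant-category scored by 7 raters (in three
#' rater groups), and 32 discrimination trials per evaluator balanced over
#' 1/3/6/12 shown descriptions.  The calibration targets are the study's
#' reported summary values: mean accuracy 0.730 for self-selected versus
#' 0.573 for assigned categories; mean specific-statement counts 1.68 among
#' informant-categories scoring above 90% accuracy versus 0.55 below 50%; a
#' 0.14 probability that a statement is false (independent of
#' knowledgeability); and evaluator choice weights (0, 0.32, -0.36).
#'
#' @param n_informants,n_evaluators participant counts.
#' @param n_categories number of knowledge categories.
#' @param categories_per_participant categories completed per participant
#'   (half self-selected, half assigned).
#' @param questions_per_category multiple-choice questions per category.
#' @param descriptions_per_informant_category image descriptions per
#'   informant and category.
#' @param n_raters raters scoring each description.
#' @param n_rater_groups disjoint rater groups the descriptions are split
#'   over.
#' @param theta_selected_mean,theta_assigned_mean mean latent accuracy by
#'   selection condition.
#' @param theta_concentration beta concentration of latent accuracy; the
#'   default 80 yields a worst-to-best within-category accuracy spread near
#'   0.51, matching the observed individual differences.
#' @param statement_rate_high,statement_rate_low target mean statement counts
#'   per description among informant-categories with realized accuracy above
#'   0.9 and below 0.5.
#' @param false_rate probability that any statement is false.
#' @param rater_noise rater perturbation rate: each statement is missed with
#'   this probability, a spurious statement added with half of it, and a
#'   veracity label flipped with a quarter of it.
#' @param evaluator_weights `(w0, w1, w2)` generating the evaluator choices.
#' @param trials_per_evaluator discrimination trials per evaluator.
#' @param descriptions_shown_levels descriptions shown per trial (balanced).
#' @param seed master seed of the study.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_informants = 100, n_evaluators = 160,
                       n_categories = 30, categories_per_participant = 4,
                       questions_per_category = 30,
                       descriptions_per_informant_category = 12,
                       n_raters = 7, n_rater_groups = 3,
                       theta_selected_mean = 0.730,
                       theta_assigned_mean = 0.573,
                       theta_concentration = 80,
                       statement_rate_high = 1.68,
                       statement_rate_low = 0.55,
                       false_rate = 0.14, rater_noise = 0.14,
                       evaluator_weights = c(0, 0.32, -0.36),
                       trials_per_evaluator = 32,
                       descriptions_shown_levels = c(1, 3, 6, 12),
                       seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("theta_selected_mean", "theta_assigned_mean", "false_rate",
               "rater_noise")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
  }
  if (statement_rate_high <= 0 || statement_rate_low <= 0)
    stop("statement rates must be positive", call. = FALSE)
  if (statement_rate_high <= statement_rate_low)
    stop("'statement_rate_high' must exceed 'statement_rate_low'",
         call. = FALSE)
  if (categories_per_participant %% 2 != 0)
    stop("'categories_per_participant' must be even (half selected, half assigned)",
         call. = FALSE)
  if (categories_per_participant > n_categories)
    stop("more categories per participant than categories", call. = FALSE)
  if (trials_per_evaluator %% (categories_per_participant) != 0)
    stop("'trials_per_evaluator' must divide evenly over the participant's categories",
         call. = FALSE)
  if (length(evaluator_weights) != 3 || any(!is.finite(evaluator_weights)))
    stop("'evaluator_weights' must be 3 finite numbers", call. = FALSE)
  if (max(descriptions_shown_levels) > descriptions_per_informant_category)
    stop("cannot show more descriptions than exist per informant-category",
         call. = FALSE)
  for (nm in c("n_informants", "n_evaluators", "n_categories",
               "categories_per_participant", "questions_per_category",
               "descriptions_per_informant_category", "n_raters",
               "n_rater_groups", "trials_per_evaluator",
               "descriptions_shown_levels", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study config: %d informants, %d evaluators, ",
                     "%d categories, seed %d\n"),
              x$n_informants, x$n_evaluators, x$n_categories, x$seed))
  invisible(x)
}

# Latent accuracy density: equal mixture of the selected- and assigned-
# condition beta distributions.
theta_mixture_density <- function(theta, config) {
  k <- config$theta_concentration
  0.5 * dbeta(theta, config$theta_selected_mean * k,
              (1 - config$theta_selected_mean) * k) +
  0.5 * dbeta(theta, config$theta_assigned_mean * k,
              (1 - config$theta_assigned_mean) * k)
}

#' Calibrate the statement-count rate curve
#'
#' Solves for the coefficients of the log-linear Poisson rate
#' `lambda(theta) = exp(a + b * theta)` such that the expected statement
#' count per description equals `statement_rate_high` among
#' informant-categories whose *realized* accuracy (correct answers out of
#' `questions_per_category`) exceeds 0.9, and `statement_rate_low` below 0.5,
#' under the configured latent-accuracy distribution.  The conditional means
#' are computed by numerical integration over the beta mixture and the
#' binomial realized-accuracy distribution.
#'
#' @param config a [sim_config()].
#' @return named vector `c(a, b)`.
#' @export
calibrate_statement_rates <- function(config) {
  q <- config$questions_per_category
  grid <- seq(1e-4, 1 - 1e-4, length.out = 4000)
  dens <- theta_mixture_density(grid, config)
  w_hi <- (1 - pbinom(floor(0.9 * q + 1e-9), q, grid)) * dens
  w_lo <- pbinom(ceiling(0.5 * q - 1e-9) - 1, q, grid) * dens
  cond_mean <- function(b, w) sum(exp(b * grid) * w) / sum(w)
  target_ratio <- config$statement_rate_high / config$statement_rate_low
  ratio <- function(b) cond_mean(b, w_hi) / cond_mean(b, w_lo) - target_ratio
  if (ratio(50) < 0)
    stop("statement-rate calibration infeasible: target ratio too extreme",
         call. = FALSE)
  b <- uniroot(ratio, c(1e-6, 50), tol = 1e-12)$root
  a <- log(config$statement_rate_high) - log(cond_mean(b, w_hi))
  c(a = a, b = b)
}

# ids
.inf_id <- function(i) sprintf("inf%03d", i)
.eva_id <- function(i) sprintf("eva%03d", i)
.cat_id <- function(i) sprintf("cat%02d", i)
.img_id <- function(cat, i) sprintf("%s_img%02d", cat, i)

# Draw the category assignment and latent accuracy for a set of
# participants; returns one row per participant x category.
draw_participants <- function(ids, config) {
  k <- config$theta_concentration
  cpp <- config$categories_per_participant
  half <- cpp / 2
  cats <- lapply(ids, function(i) sample.int(config$n_categories, cpp))
  df <- data.frame(
    participant_id = rep(ids, each = cpp),
    category_id = .cat_id(unlist(cats)),
    selection = rep(c(rep("selected", half), rep("assigned", half)),
                    length(ids)),
    stringsAsFactors = FALSE)
  mu <- ifelse(df$selection == "selected", config$theta_selected_mean,
               config$theta_assigned_mean)
  df$theta_latent <- rbeta(nrow(df), mu * k, (1 - mu) * k)
  df
}

# Bernoulli answers for each participant x category row.
draw_answers <- function(part, config) {
  q <- config$questions_per_category
  n <- nrow(part)
  data.frame(
    participant_id = rep(part$participant_id, each = q),
    category_id = rep(part$category_id, each = q),
    question_index = rep(seq_len(q), n),
    correct = rbinom(n * q, 1, rep(part$theta_latent, each = q)),
    selection = rep(part$selection, each = q),
    stringsAsFactors = FALSE)
}

#' Simulate informants: knowledge profiles and latent description counts
#'
#' Draws each informant's latent accuracy per category from the condition
#' beta distributions, their multiple-choice answers as Bernoulli trials, and
#' for every image description a latent count of specific statements
#' (Poisson with a log-linear rate in latent accuracy, calibrated by
#' [calibrate_statement_rates()]) of which each statement is independently
#' false with probability `false_rate`.
#'
#' Uses the current RNG state; seed via [generate_study()] or `set.seed()`.
#'
#' @param config a [sim_config()].
#' @return list with `answers` (answers table), `participants` (latent
#'   accuracy per informant x category), `latent` (per-description true
#'   counts: `informant_id`, `category_id`, `image_id`, `n_specific`,
#'   `n_true`, `n_false`), and `rate_coef`.
#' @export
simulate_informants <- function(config) {
  coef <- calibrate_statement_rates(config)
  part <- draw_participants(.inf_id(seq_len(config$n_informants)), config)
  answers <- draw_answers(part, config)
  nd <- config$descriptions_per_informant_category
  lambda <- exp(coef["a"] + coef["b"] * part$theta_latent)
  latent <- data.frame(
    informant_id = rep(part$participant_id, each = nd),
    category_id = rep(part$category_id, each = nd),
    image_id = .img_id(rep(part$category_id, each = nd),
                       rep(seq_len(nd), nrow(part))),
    n_specific = rpois(nrow(part) * nd, rep(lambda, each = nd)),
    stringsAsFactors = FALSE)
  latent$n_false <- rbinom(nrow(latent), latent$n_specific, config$false_rate)
  latent$n_true <- latent$n_specific - latent$n_false
  names(part)[names(part) == "participant_id"] <- "informant_id"
  list(answers = answers, participants = part,
       latent = latent[c("informant_id", "category_id", "image_id",
                         "n_specific", "n_true", "n_false")],
       rate_coef = coef)
}

#' Simulate rater annotations of the latent description counts
#'
#' Descriptions are split at random into `n_rater_groups` sets, each scored
#' by its own `n_raters` raters.  Each rater independently perturbs the true
#' counts: every statement is missed with probability `rater_noise`, one
#' spurious statement is added with probability `rater_noise / 2` (false with
#' probability `false_rate`), and each kept statement's veracity label is
#' flipped with probability `rater_noise / 4` (extraction of statements is
#' harder to agree on than their truth value, which keeps the reliability
#' ordering true > any > false counts seen in practice).  The per-rater
#' identity `n_true + n_false == n_specific` holds by construction.
#'
#' @param latent latent description counts from [simulate_informants()].
#' @param config a [sim_config()].
#' @return per-rater annotations data.frame (see [read_annotations()]).
#' @export
simulate_raters <- function(latent, config) {
  rho <- config$rater_noise
  ndesc <- nrow(latent)
  group <- sample(rep_len(seq_len(config$n_rater_groups), ndesc))
  k <- config$n_raters
  idx <- rep(seq_len(ndesc), each = k)
  ann <- data.frame(
    informant_id = latent$informant_id[idx],
    category_id = latent$category_id[idx],
    image_id = latent$image_id[idx],
    rater_id = sprintf("g%d_r%d", group[idx], rep(seq_len(k), ndesc)),
    stringsAsFactors = FALSE)
  n <- nrow(ann)
  kept_true <- rbinom(n, latent$n_true[idx], 1 - rho)
  kept_false <- rbinom(n, latent$n_false[idx], 1 - rho)
  t2f <- rbinom(n, kept_true, rho / 4)
  f2t <- rbinom(n, kept_false, rho / 4)
  added <- rbinom(n, 1, rho / 2)
  added_false <- rbinom(n, added, config$false_rate)
  ann$n_true <- kept_true - t2f + f2t + (added - added_false)
  ann$n_false <- kept_false - f2t + t2f + added_false
  ann$n_specific <- ann$n_true + ann$n_false
  validate_annotations(ann[c("informant_id", "category_id", "image_id",
                             "rater_id", "n_specific", "n_true", "n_false")])
}

#' Simulate evaluators and their discrimination trials
#'
#' Evaluators receive their own category assignment, latent accuracy, and
#' multiple-choice answers exactly as informants do.  Each evaluator then
#' completes `trials_per_evaluator` trials split evenly over their
#' categories, with the shown-description counts balanced over
#' `descriptions_shown_levels`.  Each trial pairs two informants of the
#' trial's category with different realized accuracy; the shown images are
#' sampled without replacement; and the evaluator's choice is drawn from the
#' evaluator choice model `p(choose A) = logistic(w0 + w1*dn + w2*theta*dm)`
#' at `evaluator_weights`, with `dn`/`dm` summed over the shown descriptions'
#' latent counts and `theta` the evaluator's realized accuracy in the
#' category.
#'
#' @param informants output of [simulate_informants()].
#' @param config a [sim_config()].
#' @return list with `answers` (evaluator answers table), `trials` (trials
#'   table, see [read_trials()]), and `trial_truth` (per-trial generative
#'   record: `dn`, `dm`, `theta`, `p_choose_A`, informant accuracies).
#' @export
simulate_evaluators <- function(informants, config) {
  part <- draw_participants(.eva_id(seq_len(config$n_evaluators)), config)
  answers <- draw_answers(part, config)
  eva_prof <- score_knowledge(answers)

  inf_prof <- score_knowledge(informants$answers)
  inf_by_cat <- split(inf_prof, inf_prof$category_id)
  lat <- informants$latent
  lat_key <- paste(lat$informant_id, lat$image_id, sep = "\r")

  w <- config$evaluator_weights
  per_cat <- config$trials_per_evaluator / config$categories_per_participant
  levels_seq <- rep_len(config$descriptions_shown_levels, per_cat)
  eva_key <- paste(eva_prof$participant_id, eva_prof$category_id, sep = "\r")

  n_trials <- config$n_evaluators * config$trials_per_evaluator
  col <- list(evaluator_id = character(n_trials),
              category_id = character(n_trials),
              informant_A = character(n_trials),
              informant_B = character(n_trials),
              image_ids = character(n_trials),
              n_descriptions = integer(n_trials),
              choice = character(n_trials), dn = integer(n_trials),
              dm = integer(n_trials), theta = numeric(n_trials),
              p_choose_A = numeric(n_trials), acc_A = numeric(n_trials),
              acc_B = numeric(n_trials))
  tid <- 0L
  for (ev in unique(part$participant_id)) {
    ev_cats <- part$category_id[part$participant_id == ev]
    for (cat in ev_cats) {
      pool <- inf_by_cat[[cat]]
      if (is.null(pool) || nrow(pool) < 2 ||
          length(unique(pool$theta)) < 2)
        stop(sprintf("category %s lacks two informants with distinct accuracy",
                     cat), call. = FALSE)
      theta_ev <- eva_prof$theta[match(paste(ev, cat, sep = "\r"), eva_key)]
      for (nshow in levels_seq) {
        repeat {
          pick <- sample.int(nrow(pool), 2)
          if (pool$theta[pick[1]] != pool$theta[pick[2]]) break
        }
        a_id <- pool$participant_id[pick[1]]
        b_id <- pool$participant_id[pick[2]]
        imgs <- .img_id(cat, sample.int(
          config$descriptions_per_informant_category, nshow))
        ia <- match(paste(a_id, imgs, sep = "\r"), lat_key)
        ib <- match(paste(b_id, imgs, sep = "\r"), lat_key)
        dn <- sum(lat$n_specific[ia]) - sum(lat$n_specific[ib])
        dm <- sum(lat$n_false[ia]) - sum(lat$n_false[ib])
        p <- logistic(w[1] + w[2] * dn + w[3] * theta_ev * dm)
        tid <- tid + 1L
        col$evaluator_id[tid] <- ev
        col$category_id[tid] <- cat
        col$informant_A[tid] <- a_id
        col$informant_B[tid] <- b_id
        col$image_ids[tid] <- paste(imgs, collapse = ";")
        col$n_descriptions[tid] <- nshow
        col$choice[tid] <- if (runif(1) < p) "A" else "B"
        col$dn[tid] <- dn
        col$dm[tid] <- dm
        col$theta[tid] <- theta_ev
        col$p_choose_A[tid] <- p
        col$acc_A[tid] <- pool$theta[pick[1]]
        col$acc_B[tid] <- pool$theta[pick[2]]
      }
    }
  }
  all <- data.frame(trial_id = sprintf("t%05d", seq_len(n_trials)), col,
                    stringsAsFactors = FALSE)
  list(answers = answers,
       trials = validate_trials(all[trial_cols]),
       trial_truth = all[c("trial_id", "dn", "dm", "theta", "p_choose_A",
                           "acc_A", "acc_B")])
}

#' Generate a complete synthetic study
#'
#' Runs the full generative model under the master seed: informants (latent
#' accuracy, answers, latent description counts), rater annotations, and
#' evaluator trials with model-generated choices.  Optionally writes the
#' three analysis tables as CSV plus a `truth.json` record of all latent
#' quantities.
#'
#' @param config a [sim_config()].
#' @param dir output directory, or `NULL` to skip writing.
#' @return list of class `synthetic_study`: `answers` (informants and
#'   evaluators combined), `annotations`, `trials`, `truth` (latent record),
#'   `config`.
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  inf <- simulate_informants(config)
  ann <- simulate_raters(inf$latent, config)
  eva <- simulate_evaluators(inf, config)
  answers <- rbind(inf$answers, eva$answers)
  truth <- list(
    informants = inf$participants, latent_counts = inf$latent,
    rate_coef = as.list(inf$rate_coef),
    evaluator_weights = config$evaluator_weights,
    trial_truth = eva$trial_truth, seed = config$seed)
  study <- structure(list(answers = answers, annotations = ann,
                          trials = eva$trials, truth = truth,
                          config = config),
                     class = "synthetic_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_answers(answers, file.path(dir, "answers.csv"))
    write_annotations(ann, file.path(dir, "annotations.csv"))
    write_trials(eva$trials, file.path(dir, "trials.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d answer rows, %d annotation rows, ",
                     "%d trials (seed %d)\n"),
              nrow(x$answers), nrow(x$annotations), nrow(x$trials),
              x$config$seed))
  invisible(x)
}
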