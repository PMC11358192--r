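# Reduced-scale study and sampler settings for fast unit tests; the
# full-scale defaults are exercised in the acceptance suite.

small_config <- function(seed = 1, ...) {
  args <- list(n_informants = 40, n_evaluators = 16, n_categories = 8,
               trials_per_evaluator = 16, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

fast_sampler <- function(seed = 1, ...) {
  sampler_config(n_chains = 4, burn_in = 300, thin = 5,
                 draws_per_chain = 200, seed = seed, ...)
}

# Simulate trial features directly from the evaluator choice model on a
# discrete covariate grid (bypassing the full study machinery).
simulate_features <- function(n, weights, seed = 1,
                              theta_levels = seq(0.3, 0.95, by = 0.05)) {
  set.seed(seed)
  dn <- sample(-8:8, n, replace = TRUE)
  dm <- sample(-3:3, n, replace = TRUE)
  theta <- sample(theta_levels, n, replace = TRUE)
  p <- plogis(weights[1] + weights[2] * dn + weights[3] * theta * dm)
  data.frame(trial_id = sprintf("t%06d", seq_len(n)), dn = dn, dm = dm,
             theta = theta, n_descriptions = 1L,
             outcome = rbinom(n, 1, p))
}

# Minimal aggregated-annotation and profile tables for feature-building
# tests.
toy_aggregated <- function() {
  data.frame(
    informant_id = rep(c("A", "B"), each = 2),
    category_id = "cat1",
    image_id = rep(c("img1", "img2"), 2),
    n_specific_mode = c(2L, 1L, 1L, 0L),
    n_true_mode = c(1L, 1L, 0L, 0L),
    n_false_mode = c(1L, 0L, 1L, 0L),
    n_raters = 7L, consistent_flag = TRUE,
    stringsAsFactors = FALSE)
}

toy_profiles <- function(theta_A = 0.8, theta_B = 0.5, theta_ev = 0.6) {
  data.frame(
    participant_id = c("A", "B", "ev1"),
    category_id = "cat1",
    selection = "selected",
    n_questions = 30L,
    n_correct = as.integer(30 * c(theta_A, theta_B, theta_ev)),
    theta = c(theta_A, theta_B, theta_ev),
    stringsAsFactors = FALSE)
}

toy_trial <- function(choice = "A", images = "img1;img2", n_desc = 2L) {
  data.frame(trial_id = "t1", evaluator_id = "ev1", category_id = "cat1",
             informant_A = "A", informant_B = "B", image_ids = images,
             n_descriptions = n_desc, choice = choice,
             stringsAsFactors = FALSE)
}
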