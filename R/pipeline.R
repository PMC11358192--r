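#' Score trials against ground truth
#'
#' Joins evaluator choices to the ground truth (which informant scored higher
#' on the category's knowledge questions) and marks each trial correct or
#' not.
#'
#' @param trials validated trials data.frame.
#' @param profiles output of [score_knowledge()] covering all informants.
#' @return trials with added columns `correct` (0/1) and `acc_diff`
#'   (absolute accuracy difference of the pair).
#' @export
score_trials <- function(trials, profiles) {
  trials <- validate_trials(trials)
  key <- paste(profiles$participant_id, profiles$category_id, sep = "\r")
  ia <- match(paste(trials$informant_A, trials$category_id, sep = "\r"), key)
  ib <- match(paste(trials$informant_B, trials$category_id, sep = "\r"), key)
  if (anyNA(ia) || anyNA(ib))
    stop("some trial informants have no knowledge profile", call. = FALSE)
  ta <- profiles$theta[ia]
  tb <- profiles$theta[ib]
  if (any(ta == tb))
    stop("trials include informant pairs with equal accuracy", call. = FALSE)
  trials$correct <- as.integer((trials$choice == "A") == (ta > tb))
  trials$acc_diff <- abs(ta - tb)
  trials
}

#' Evaluator accuracy by number of shown descriptions
#'
#' Per-evaluator, per-level accuracy; level means; and a default-prior paired
#' t-test Bayes factor contrasting the fewest- versus most-description
#' levels.  Evaluators missing either contrast level are excluded from the
#' paired test with a logged message.
#'
#' @param scored_trials output of [score_trials()] (columns `evaluator_id`,
#'   `n_descriptions`, `correct`).
#' @param contrast_levels the two levels entering the paired test (default
#'   the minimum and maximum observed level).
#' @return list with `by_level` (level means), `per_evaluator` (wide
#'   accuracy table), `bf` (paired [bf_result()]), `contrast_levels`,
#'   `n_paired`.
#' @export
accuracy_by_condition <- function(scored_trials, contrast_levels = NULL) {
  if (!"correct" %in% names(scored_trials))
    stop("trials must be scored against ground truth first", call. = FALSE)
  lv <- sort(unique(scored_trials$n_descriptions))
  if (is.null(contrast_levels)) contrast_levels <- range(lv)
  agg <- aggregate(correct ~ evaluator_id + n_descriptions,
                   data = scored_trials, FUN = mean)
  by_level <- aggregate(correct ~ n_descriptions, data = agg, FUN = mean)
  names(by_level)[2] <- "accuracy"
  evs <- sort(unique(agg$evaluator_id))
  wide <- matrix(NA_real_, length(evs), length(lv),
                 dimnames = list(evs, paste0("n", lv)))
  wide[cbind(match(agg$evaluator_id, evs),
             match(agg$n_descriptions, lv))] <- agg$correct
  lo <- wide[, paste0("n", contrast_levels[1])]
  hi <- wide[, paste0("n", contrast_levels[2])]
  keep <- is.finite(lo) & is.finite(hi)
  if (any(!keep))
    message(sprintf("accuracy_by_condition: excluding %d evaluator(s) missing a contrast level",
                    sum(!keep)))
  bf <- if (sum(keep) >= 3) paired_bf10(hi[keep], lo[keep]) else {
    message("accuracy_by_condition: fewer than 3 paired evaluators; skipping the Bayes factor")
    NULL
  }
  list(by_level = by_level,
       per_evaluator = data.frame(evaluator_id = evs, wide,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE),
       bf = bf, contrast_levels = contrast_levels, n_paired = sum(keep))
}

#' Distinct informant pairs used in the trials
#'
#' Builds the answer-vector pairs for [split_half_ceiling()] from the
#' distinct (category, informant A, informant B) combinations in the trials
#' table, each weighted once regardless of how many trials used it
#' (set `weight_by = "trial"` to weight by trial count instead).
#'
#' @param trials validated trials data.frame.
#' @param answers answers table covering the informants.
#' @param weight_by `"pair"` (default) or `"trial"`.
#' @return list of pairs, each with 0/1 vectors `a` and `b`.
#' @export
trial_pairs <- function(trials, answers, weight_by = c("pair", "trial")) {
  weight_by <- match.arg(weight_by)
  key <- data.frame(category_id = trials$category_id,
                    a = pmin(trials$informant_A, trials$informant_B),
                    b = pmax(trials$informant_A, trials$informant_B),
                    stringsAsFactors = FALSE)
  if (weight_by == "pair") key <- unique(key)
  lapply(seq_len(nrow(key)), function(i)
    list(a = answer_vector(answers, key$a[i], key$category_id[i]),
         b = answer_vector(answers, key$b[i], key$category_id[i])))
}

# ---- configuration ------------------------------------------------------

#' Default pipeline configuration
#'
#' @return nested list of every pipeline setting with its default:
#'   `simulation` ([sim_config()] fields), `sampler` ([sampler_config()]
#'   fields), `prior_scale`, `robustness_scales`, `icc_form`, `ceiling`
#'   (`n_splits`, `weight_by`), `inputs` (paths to `answers`, `annotations`,
#'   `trials`), `simulate_first`, `seed`.
#' @export
default_pipeline_config <- function() {
  list(simulation = unclass(sim_config()),
       sampler = unclass(sampler_config()),
       prior_scale = 1,
       robustness_scales = c(0.5, 1, 2),
       icc_form = "ICC2_1",
       ceiling = list(n_splits = 10000, weight_by = "pair"),
       inputs = list(answers = NULL, annotations = NULL, trials = NULL),
       simulate_first = TRUE,
       seed = 1)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON configuration and merges it over the defaults;
#' unknown keys are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for pure defaults.
#' @return full configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_into <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop(sprintf("unknown config key: %s%s", prefix, nm), call. = FALSE)
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]],
                                 paste0(prefix, nm, "."))
      else base[nm] <- upd[nm]
    }
    base
  }
  merge_into(cfg, user)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# ---- the pipeline -------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes all stages in order: ingest (or simulate) the three tables;
#' aggregate annotations across raters and compute the reliability report;
#' score knowledgeability, the self-selected versus assigned contrast, and
#' the per-category accuracy spread; compute evaluator accuracy by number of
#' descriptions and the split-half ceiling; fit the informant and evaluator
#' logistic models with Savage-Dickey term comparisons (and robustness
#' curves unless skipped); and assemble a report.  Any stage failure aborts
#' with a stage-named error.
#'
#' @param config path to a YAML/JSON configuration, or a configuration list
#'   as from [load_pipeline_config()].
#' @param out_dir directory for `report.json`, `report.md`, and intermediate
#'   CSV tables, or `NULL` to return the report only.
#' @param model `"informant"`, `"evaluator"`, or `"both"`.
#' @param skip_robustness skip the robustness refits.
#' @param seed overrides the configured master seed.
#' @return the report (nested list), invisibly written to `out_dir` if given.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL,
                         model = c("both", "informant", "evaluator"),
                         skip_robustness = FALSE, seed = NULL) {
  model <- match.arg(model)
  cfg <- if (is.character(config)) load_pipeline_config(config)
         else if (is.null(config)) load_pipeline_config()
         else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$simulation$seed <- cfg$seed
  cfg$sampler$seed <- cfg$seed

  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- ingest -------------------------------------------------------------
  t0 <- Sys.time()
  tables <- wrap("ingest", {
    if (isTRUE(cfg$simulate_first)) {
      stage_log("ingest", "simulating study (seed %d)", cfg$simulation$seed)
      st <- generate_study(do.call(sim_config, cfg$simulation))
      list(answers = st$answers, annotations = st$annotations,
           trials = st$trials)
    } else {
      for (nm in c("answers", "annotations", "trials"))
        if (is.null(cfg$inputs[[nm]]) || !file.exists(cfg$inputs[[nm]]))
          stop(sprintf("input table '%s' not found at %s", nm,
                       if (is.null(cfg$inputs[[nm]])) "(unset)"
                       else cfg$inputs[[nm]]), call. = FALSE)
      stage_log("ingest", "reading tables from configured paths")
      list(answers = read_answers(cfg$inputs$answers),
           annotations = read_annotations(cfg$inputs$annotations),
           trials = read_trials(cfg$inputs$trials))
    }
  })
  stage_log("ingest", "done in %.1fs", as.numeric(Sys.time() - t0, "secs"))

  # -- aggregate ----------------------------------------------------------
  t0 <- Sys.time()
  agg <- wrap("aggregate", aggregate_annotations(tables$annotations))
  reliability <- wrap("aggregate",
                      reliability_report(tables$annotations,
                                         form = cfg$icc_form))
  stage_log("aggregate", "%d descriptions, ICC range [%.2f, %.2f] (%.1fs)",
            nrow(agg), min(reliability$icc), max(reliability$icc),
            as.numeric(Sys.time() - t0, "secs"))

  # -- score --------------------------------------------------------------
  profiles <- wrap("score", score_knowledge(tables$answers))
  contrast <- wrap("score", selection_contrast(profiles))
  spread <- wrap("score", {
    by_cat <- split(profiles$theta, profiles$category_id)
    mean(vapply(by_cat, function(v) max(v) - min(v), 0))
  })
  stage_log("score", "selected %.3f vs assigned %.3f (BF %s); mean spread %.2f",
            contrast$mean_selected, contrast$mean_assigned,
            contrast$bf$display, spread)

  # -- evaluator ----------------------------------------------------------
  t0 <- Sys.time()
  scored <- wrap("evaluator", score_trials(tables$trials, profiles))
  acc <- wrap("evaluator", accuracy_by_condition(scored))
  ceiling_est <- wrap("evaluator", {
    pairs <- trial_pairs(tables$trials, tables$answers,
                         weight_by = cfg$ceiling$weight_by)
    split_half_ceiling(pairs, n_splits = cfg$ceiling$n_splits,
                       seed = cfg$seed)
  })
  stage_log("evaluator", "accuracy %.3f -> %.3f; ceiling %.3f (%.1fs)",
            acc$by_level$accuracy[1],
            acc$by_level$accuracy[nrow(acc$by_level)],
            ceiling_est$probability, as.numeric(Sys.time() - t0, "secs"))

  # -- models -------------------------------------------------------------
  fit_one <- function(which) {
    t0 <- Sys.time()
    feats <- wrap(which, build_features(tables$trials, agg, profiles,
                                        model = which))
    fit <- wrap(which, fit_model(feats, model = which,
                                 prior = prior_spec("normal",
                                                    scale = cfg$prior_scale),
                                 config = do.call(sampler_config,
                                                  cfg$sampler)))
    bfs <- wrap(which, compare_models(
      fit, robustness_scales = if (skip_robustness) NULL
                               else cfg$robustness_scales))
    curves <- wrap(which, predict_curves(fit))
    stage_log(which, "w1 %.3f, w2 %.3f; BF(w1) %s, BF(w2) %s (%.1fs)",
              fit$summary$mean[2], fit$summary$mean[3],
              bfs$w1$display, bfs$w2$display,
              as.numeric(Sys.time() - t0, "secs"))
    list(summary = fit$summary,
         bf = lapply(bfs, function(b)
           list(bf10 = b$bf10, display = b$display,
                evidence = classify_bf(b$bf10),
                robustness = b$robustness)),
         curves = curves)
  }
  models <- list()
  if (model %in% c("both", "informant")) models$informant <- fit_one("informant")
  if (model %in% c("both", "evaluator")) models$evaluator <- fit_one("evaluator")

  report <- list(
    reliability = reliability,
    knowledge = list(
      mean_selected = contrast$mean_selected,
      mean_assigned = contrast$mean_assigned,
      difference = contrast$difference,
      bf10 = contrast$bf$bf10, bf_display = contrast$bf$display,
      n = contrast$n,
      mean_category_spread = spread),
    evaluator = list(
      accuracy_by_level = acc$by_level,
      contrast_levels = acc$contrast_levels,
      contrast_bf10 = acc$bf$bf10, contrast_bf_display = acc$bf$display,
      ceiling = list(probability = ceiling_est$probability,
                     n_splits = ceiling_est$n_splits,
                     n_pairs = ceiling_est$n_pairs,
                     seed = ceiling_est$seed)),
    models = models,
    provenance = list(seed = cfg$seed,
                      config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("knowjudge"))))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_answers(tables$answers, file.path(out_dir, "answers.csv"))
    write_annotations(tables$annotations,
                      file.path(out_dir, "annotations.csv"))
    write_trials(tables$trials, file.path(out_dir, "trials.csv"))
    write.csv(agg, file.path(out_dir, "aggregated_annotations.csv"),
              row.names = FALSE)
    for (nm in names(models))
      write.csv(models[[nm]]$curves,
                file.path(out_dir, sprintf("curves_%s.csv", nm)),
                row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

render_report_md <- function(report) {
  lines <- c("# Analysis report", "",
             "## Inter-rater reliability (ICC)", "")
  r <- report$reliability
  lines <- c(lines, sprintf("- %s / %s: %.3f", r$statement_type, r$group,
                            r$icc), "")
  k <- report$knowledge
  lines <- c(lines, "## Knowledgeability", "",
             sprintf("- selected %.3f vs assigned %.3f (diff %.3f, BF10 %s, n = %d)",
                     k$mean_selected, k$mean_assigned, k$difference,
                     k$bf_display, k$n),
             sprintf("- mean within-category accuracy spread: %.3f",
                     k$mean_category_spread), "")
  e <- report$evaluator
  lines <- c(lines, "## Evaluator accuracy", "",
             sprintf("- %d descriptions: %.3f", e$accuracy_by_level$n_descriptions,
                     e$accuracy_by_level$accuracy),
             sprintf("- paired BF10 (%d vs %d descriptions): %s",
                     e$contrast_levels[1], e$contrast_levels[2],
                     e$contrast_bf_display),
             sprintf("- split-half ceiling: %.3f (%d pairs, %d splits)",
                     e$ceiling$probability, e$ceiling$n_pairs,
                     e$ceiling$n_splits), "")
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    lines <- c(lines, sprintf("## %s model", nm), "",
               sprintf("- %s: mean %.3f, 95%% CI [%.3f, %.3f]",
                       m$summary$parameter, m$summary$mean,
                       m$summary$ci_lower, m$summary$ci_upper),
               sprintf("- BF10(%s) = %s (%s)", names(m$bf),
                       vapply(m$bf, function(b) b$display, ""),
                       vapply(m$bf, function(b) b$evidence, "")), "")
  }
  lines
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the report structure against the JSON schema in
#' `inst/schema/report_schema.json` (required keys and types; a lightweight
#' structural check).
#'
#' @param report a report list or path to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "knowjudge"),
                                simplifyVector = FALSE)
  check <- function(obj, sch, path) {
    for (key in sch$required %||% list())
      if (is.null(obj[[key]]))
        stop(sprintf("report is missing required field %s%s", path, key),
             call. = FALSE)
    for (key in names(sch$properties %||% list())) {
      sub <- sch$properties[[key]]
      if (!is.null(obj[[key]]) && identical(sub$type, "object"))
        check(obj[[key]], sub, paste0(path, key, "."))
    }
  }
  check(report, schema, "")
  invisible(TRUE)
}
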