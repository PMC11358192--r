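ans_cols <- c("participant_id", "category_id", "question_index", "correct",
              "selection")

#' Read a multiple-choice answers table
#'
#' One row per (participant, category, question).  `correct` is 0/1 (timed-out
#' questions are recorded as incorrect); `selection` is `"selected"` for
#' self-selected categories and `"assigned"` for randomly assigned ones.
#'
#' @param path CSV file with header columns `participant_id`, `category_id`,
#'   `question_index`, `correct`, `selection`.
#' @return a validated data.frame.
#' @export
read_answers <- function(path) {
  validate_answers(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_answers
#' @param df answers data.frame to validate.
#' @export
validate_answers <- function(df) {
  missing <- setdiff(ans_cols, names(df))
  if (length(missing))
    stop(sprintf("answers table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!all(df$correct %in% c(0, 1)))
    stop("'correct' must be 0/1", call. = FALSE)
  if (!all(df$selection %in% c("selected", "assigned")))
    stop("'selection' must be 'selected' or 'assigned'", call. = FALSE)
  key <- paste(df$participant_id, df$category_id, df$question_index)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (participant, category, question) rows, e.g. %s",
                 key[duplicated(key)][1]), call. = FALSE)
  df
}

#' Write an answers table
#' @param df answers data.frame.
#' @param path output CSV path.
#' @export
write_answers <- function(df, path) {
  write.csv(validate_answers(df)[ans_cols], path, row.names = FALSE)
  invisible(path)
}

#' Score knowledgeability from multiple-choice answers
#'
#' Computes, per participant and category, the accuracy theta = proportion of
#' the category's questions answered correctly (the ground-truth
#' knowledgeability measure).  Every participant x category must have a
#' complete answer vector of the same length.
#'
#' @param answers validated answers data.frame.
#' @return data.frame of profiles: `participant_id`, `category_id`,
#'   `selection`, `n_questions`, `n_correct`, `theta`.
#' @export
score_knowledge <- function(answers) {
  answers <- validate_answers(answers)
  key <- interaction(answers$participant_id, answers$category_id,
                     drop = TRUE, sep = "\r")
  parts <- split(seq_len(nrow(answers)), key)
  nq <- lengths(parts)
  if (length(unique(nq)) > 1)
    stop("participants have unequal numbers of questions per category",
         call. = FALSE)
  out <- do.call(rbind, lapply(parts, function(idx) {
    a <- answers[idx, ]
    data.frame(participant_id = a$participant_id[1],
               category_id = a$category_id[1],
               selection = a$selection[1],
               n_questions = nrow(a),
               n_correct = sum(a$correct),
               stringsAsFactors = FALSE)
  }))
  out$theta <- out$n_correct / out$n_questions
  rownames(out) <- NULL
  out[order(out$participant_id, out$category_id), ]
}

#' Answer matrix for one participant x category
#'
#' @param answers answers data.frame.
#' @param participant_id,category_id keys.
#' @return 0/1 vector ordered by `question_index`.
#' @export
answer_vector <- function(answers, participant_id, category_id) {
  a <- answers[answers$participant_id == participant_id &
               answers$category_id == category_id, ]
  if (nrow(a) == 0)
    stop(sprintf("no answers for participant %s in category %s",
                 participant_id, category_id), call. = FALSE)
  a$correct[order(a$question_index)]
}

#' Self-selected versus assigned category accuracy
#'
#' Per participant, the mean accuracy over self-selected and over assigned
#' categories, their paired difference, and a default-prior paired t-test
#' Bayes factor for the contrast.  Participants missing one selection type
#' are excluded with a logged warning.
#'
#' @param profiles output of [score_knowledge()].
#' @param rscale Cauchy prior scale for the paired Bayes factor.
#' @return list with `per_participant` (data.frame), `mean_selected`,
#'   `mean_assigned`, `difference`, `bf` (a [bf_result()]), `n`, `n_excluded`.
#' @export
selection_contrast <- function(profiles, rscale = sqrt(2) / 2) {
  parts <- split(profiles, profiles$participant_id)
  rows <- lapply(parts, function(p) {
    sel <- p$theta[p$selection == "selected"]
    asg <- p$theta[p$selection == "assigned"]
    if (length(sel) == 0 || length(asg) == 0) return(NULL)
    data.frame(participant_id = p$participant_id[1],
               theta_selected = mean(sel), theta_assigned = mean(asg),
               stringsAsFactors = FALSE)
  })
  dropped <- names(parts)[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning(sprintf("excluding %d participant(s) missing a selection type: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(per) <- NULL
  bf <- if (nrow(per) >= 3)
    paired_bf10(per$theta_selected, per$theta_assigned, rscale = rscale)
  else {
    warning("fewer than 3 complete participants; skipping the paired Bayes factor",
            call. = FALSE)
    NULL
  }
  list(per_participant = per,
       mean_selected = mean(per$theta_selected),
       mean_assigned = mean(per$theta_assigned),
       difference = mean(per$theta_selected - per$theta_assigned),
       bf = bf, n = nrow(per), n_excluded = length(dropped))
}

#' Split-half ceiling on pairwise discrimination accuracy
#'
#' Estimates the accuracy achievable by an observer who, for each informant
#' pair, sees each informant's correctness on a random half of the
#' knowledge questions and predicts which informant scores higher on the
#' unseen half.  Because a limited question set measures knowledge noisily,
#' this ceiling bounds how well any evaluator could do.
#'
#' For each of `n_splits` random half-partitions per pair: the member with
#' more correct answers on the sampled half is predicted (a seen-half tie
#' scores 0.5 directly); the split scores 1 if the predicted member has
#' strictly more correct answers on the unseen half, 0.5 on an unseen-half
#' tie, and 0 otherwise.  The estimate is the mean over splits, then over
#' pairs (each pair weighted once).
#'
#' @param pairs list of pairs; each element a list/df with 0/1 vectors `a`
#'   and `b` of equal even length.  Pair members must differ in overall
#'   accuracy.
#' @param n_splits random half-partitions per pair (default 10000).
#' @param seed integer seed.
#' @return object of class `ceiling_estimate`: list with `probability`,
#'   `per_pair`, `n_splits`, `n_pairs`, `seed`.
#' @export
split_half_ceiling <- function(pairs, n_splits = 10000, seed = 1) {
  if (length(pairs) == 0) stop("'pairs' must be non-empty", call. = FALSE)
  set.seed(as.integer(seed))
  per_pair <- vapply(seq_along(pairs), function(i) {
    a <- as.integer(pairs[[i]]$a)
    b <- as.integer(pairs[[i]]$b)
    q <- length(a)
    if (length(b) != q || q %% 2 != 0)
      stop(sprintf("pair %d: answer vectors must have equal even length", i),
           call. = FALSE)
    if (sum(a) == sum(b))
      stop(sprintf("pair %d: members have identical accuracy", i),
           call. = FALSE)
    half <- q %/% 2
    H <- matrix(0L, n_splits, q)
    for (s in seq_len(n_splits)) H[s, sample.int(q, half)] <- 1L
    seen_a <- as.vector(H %*% a)
    seen_b <- as.vector(H %*% b)
    unseen_d <- (sum(a) - seen_a) - (sum(b) - seen_b)
    seen_d <- seen_a - seen_b
    credit <- ifelse(seen_d == 0, 0.5,
              ifelse(sign(unseen_d) == sign(seen_d), 1,
              ifelse(unseen_d == 0, 0.5, 0)))
    mean(credit)
  }, 0)
  structure(list(probability = mean(per_pair), per_pair = per_pair,
                 n_splits = as.integer(n_splits), n_pairs = length(pairs),
                 seed = as.integer(seed)),
            class = "ceiling_estimate")
}

#' @export
print.ceiling_estimate <- function(x, ...) {
  cat(sprintf("Split-half discrimination ceiling: %.3f (%d pairs, %d splits, seed %d)\n",
              x$probability, x$n_pairs, x$n_splits, x$seed))
  invisible(x)
}
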