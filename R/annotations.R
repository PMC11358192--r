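#' Mode of a vector of counts
#'
#' Most frequent value among non-negative integer counts; on ties the
#' smallest tied value is returned (a deterministic rule that is conservative
#' toward fewer claimed statements).
#'
#' @param counts non-empty vector of non-negative integers.
#' @return the modal count (integer).
#' @examples
#' mode_aggregate(c(0, 1, 1, 2, 1, 0, 1))  # 1
#' mode_aggregate(c(1, 1, 2, 2, 0, 3, 4))  # tie between 1 and 2 -> 1
#' @export
mode_aggregate <- function(counts) {
  if (length(counts) == 0)
    stop("'counts' must be non-empty", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  tab <- table(counts)
  vals <- as.integer(names(tab))
  # ties broken toward the smallest value: vals is sorted ascending
  vals[which.max(tab)]
}

ann_cols <- c("informant_id", "category_id", "image_id", "rater_id",
              "n_specific", "n_true", "n_false")

#' Read a per-rater annotation table
#'
#' One row per (description, rater) with counts of specific, true, and false
#' statements.  Validates column names, non-negative integer counts, and the
#' per-rater identity `n_true + n_false == n_specific`.
#'
#' @param path CSV file with header columns `informant_id`, `category_id`,
#'   `image_id`, `rater_id`, `n_specific`, `n_true`, `n_false`.
#' @return a validated data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param df annotation data.frame to validate in place.
#' @export
validate_annotations <- function(df) {
  missing <- setdiff(ann_cols, names(df))
  if (length(missing))
    stop(sprintf("annotation table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cnt <- df[c("n_specific", "n_true", "n_false")]
  if (any(!vapply(cnt, is.numeric, TRUE)) ||
      any(unlist(cnt) < 0) || any(unlist(cnt) != round(unlist(cnt))))
    stop("annotation counts must be non-negative integers", call. = FALSE)
  bad <- df$n_true + df$n_false != df$n_specific
  if (any(bad))
    stop(sprintf("%d row(s) violate n_true + n_false == n_specific (first at row %d)",
                 sum(bad), which(bad)[1]), call. = FALSE)
  df
}

#' Write an annotation table
#' @param df annotation data.frame.
#' @param path output CSV path.
#' @export
write_annotations <- function(df, path) {
  write.csv(validate_annotations(df)[ann_cols], path, row.names = FALSE)
  invisible(path)
}

#' Aggregate one description's rater annotations by mode
#'
#' Collapses all raters' counts for a single description to per-field modes
#' (computed independently for specific, true, and false counts).  The
#' independent modes need not be arithmetically consistent; inconsistency is
#' flagged, never reconciled, because downstream models use only the specific
#' and false counts.
#'
#' @param annotations data.frame of rater rows sharing one
#'   (informant_id, category_id, image_id).
#' @return one-row data.frame with `n_specific_mode`, `n_true_mode`,
#'   `n_false_mode`, `n_raters`, and `consistent_flag`.
#' @export
aggregate_description <- function(annotations) {
  annotations <- validate_annotations(annotations)
  key <- unique(annotations[c("informant_id", "category_id", "image_id")])
  if (nrow(key) != 1)
    stop("all rows must describe the same (informant, category, image)",
         call. = FALSE)
  ns <- mode_aggregate(annotations$n_specific)
  nt <- mode_aggregate(annotations$n_true)
  nf <- mode_aggregate(annotations$n_false)
  data.frame(key,
             n_specific_mode = ns, n_true_mode = nt, n_false_mode = nf,
             n_raters = nrow(annotations),
             consistent_flag = nt + nf == ns,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate a full annotation table across raters
#'
#' Applies [aggregate_description()] to every description in the table.
#'
#' @param annotations validated per-rater annotation data.frame.
#' @return data.frame with one row per description.
#' @export
aggregate_annotations <- function(annotations) {
  annotations <- validate_annotations(annotations)
  key <- interaction(annotations$informant_id, annotations$category_id,
                     annotations$image_id, drop = TRUE, sep = "\r")
  parts <- split(seq_len(nrow(annotations)), key)
  out <- do.call(rbind, lapply(parts, function(idx) {
    a <- annotations[idx, ]
    data.frame(informant_id = a$informant_id[1],
               category_id = a$category_id[1],
               image_id = a$image_id[1],
               n_specific_mode = mode_aggregate(a$n_specific),
               n_true_mode = mode_aggregate(a$n_true),
               n_false_mode = mode_aggregate(a$n_false),
               n_raters = nrow(a), stringsAsFactors = FALSE)
  }))
  out$consistent_flag <- out$n_true_mode + out$n_false_mode == out$n_specific_mode
  rownames(out) <- NULL
  out[order(out$informant_id, out$category_id, out$image_id), ]
}

#' Intraclass correlation from a ratings matrix
#'
#' Inter-rater reliability of counts, computed from two-way ANOVA mean
#' squares.  The default form is ICC(2,1): two-way random effects, absolute
#' agreement, single rater.  ICC(3,1) (two-way mixed, consistency) is also
#' available.
#'
#' @param ratings items x raters numeric matrix with no missing cells.
#' @param form `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return the ICC (a value <= 1).
#' @export
icc_agreement <- function(ratings, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings)))
    stop("ratings matrix must have no missing cells", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2)
    stop("need at least 2 items and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  resid <- ratings - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  msr <- ss_rows / (n - 1)          # between-items (rows)
  msc <- ss_cols / (k - 1)          # between-raters (columns)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (form == "ICC2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

# Union-find over rater ids based on co-occurrence on descriptions: raters
# that ever scored the same description belong to the same group.
infer_rater_groups <- function(annotations) {
  raters <- sort(unique(annotations$rater_id))
  parent <- seq_along(raters)
  names(parent) <- raters
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- interaction(annotations$informant_id, annotations$category_id,
                     annotations$image_id, drop = TRUE, sep = "\r")
  for (idx in split(match(annotations$rater_id, raters), key)) {
    roots <- unique(vapply(idx, find, 0L))
    parent[roots[-1]] <- roots[1]
  }
  root <- vapply(seq_along(raters), find, 0L)
  grp <- match(root, sort(unique(root)))
  stats::setNames(paste0("group", grp), raters)
}

#' Inter-rater reliability report
#'
#' Computes the ICC per rater group and statement type (true, false, any),
#' mirroring the layout of a reliability table: one row per statement type,
#' one column per group of raters.  Groups are inferred from which raters
#' co-occur on descriptions unless supplied.
#'
#' @param annotations per-rater annotation data.frame.
#' @param rater_groups optional named character vector mapping `rater_id` to a
#'   group label.
#' @param form ICC form, see [icc_agreement()].
#' @return data.frame with columns `statement_type`, `group`, `icc`,
#'   `n_descriptions`, `n_raters`.
#' @export
reliability_report <- function(annotations, rater_groups = NULL,
                               form = "ICC2_1") {
  annotations <- validate_annotations(annotations)
  if (is.null(rater_groups)) rater_groups <- infer_rater_groups(annotations)
  annotations$.group <- unname(rater_groups[as.character(annotations$rater_id)])
  if (any(is.na(annotations$.group)))
    stop("rater_groups is missing some rater ids", call. = FALSE)
  types <- c(True = "n_true", False = "n_false", Any = "n_specific")
  out <- list()
  for (g in sort(unique(annotations$.group))) {
    a <- annotations[annotations$.group == g, ]
    desc <- interaction(a$informant_id, a$category_id, a$image_id,
                        drop = TRUE, sep = "\r")
    raters <- sort(unique(a$rater_id))
    for (ty in names(types)) {
      m <- matrix(NA_real_, nrow = length(levels(desc)), ncol = length(raters))
      m[cbind(as.integer(desc), match(a$rater_id, raters))] <- a[[types[ty]]]
      if (any(is.na(m)))
        stop(sprintf("group %s has incomplete rater coverage", g),
             call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        statement_type = ty, group = g,
        icc = icc_agreement(m, form = form),
        n_descriptions = nrow(m), n_raters = ncol(m),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
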