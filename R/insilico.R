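#' Tally a model's binary hazard calls against truth labels
#'
#' Builds the confusion counts for one in-silico model from per-chemical
#' binary DART hazard calls. Chemicals whose truth label is `"unknown"` are
#' dropped before tallying (they are not part of the labelled benchmark).
#' Calls of `"not_predicted"` count towards the labelled total (they reduce
#' coverage) but contribute to none of TP/FN/TN/FP.
#'
#' @param records data.frame with columns `chemical_id`, `model_id`, `call`
#'   (one of `"toxic"`, `"nontoxic"`, `"not_predicted"`) and `truth`
#'   (one of `"toxic"`, `"nontoxic"`, `"unknown"`).
#' @param model_id model to tally; must be present in `records`.
#' @return object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fn`, `tn`, `fp` and `total_labelled`.
#' @examples
#' rec <- data.frame(
#'   chemical_id = c("a", "b", "c"), model_id = "m",
#'   call = c("toxic", "nontoxic", "toxic"),
#'   truth = c("toxic", "toxic", "nontoxic"))
#' tally_confusion(rec, "m")
#' @export
tally_confusion <- function(records, model_id) {
  stopifnot(is.data.frame(records),
            all(c("chemical_id", "model_id", "call", "truth") %in%
                  names(records)))
  rec <- records[records$model_id == model_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no records for model '", model_id, "'")
  if (anyDuplicated(rec$chemical_id))
    stop("duplicate (chemical_id, model_id) pairs for model '", model_id, "'")
  if (any(!nzchar(rec$chemical_id)) || anyNA(rec$chemical_id))
    stop("chemical_id must be nonempty")
  ok_call  <- c("toxic", "nontoxic", "not_predicted")
  ok_truth <- c("toxic", "nontoxic", "unknown")
  if (!all(rec$call %in% ok_call))
    stop("call values must be one of: ", paste(ok_call, collapse = ", "))
  if (!all(rec$truth %in% ok_truth))
    stop("truth values must be one of: ", paste(ok_truth, collapse = ", "))

  rec <- rec[rec$truth != "unknown", , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no labelled chemicals for model '", model_id, "'")

  out <- list(
    tp = sum(rec$call == "toxic"    & rec$truth == "toxic"),
    fn = sum(rec$call == "nontoxic" & rec$truth == "toxic"),
    tn = sum(rec$call == "nontoxic" & rec$truth == "nontoxic"),
    fp = sum(rec$call == "toxic"    & rec$truth == "nontoxic"),
    total_labelled = nrow(rec))
  structure(out, class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' Convenience constructor used when counts (rather than per-chemical calls)
#' are the starting point, e.g. when working from a published performance
#' table.
#'
#' @param tp,fn,tn,fp nonnegative integer counts.
#' @param total_labelled number of chemicals with a known truth label;
#'   must be at least `tp + fn + tn + fp` (the excess is chemicals the model
#'   could not predict).
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, tn, fp, total_labelled) {
  vals <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("tp, fn, tn, fp must be nonnegative integers")
  if (total_labelled < 1 || sum(vals) > total_labelled)
    stop("total_labelled must be >= tp + fn + tn + fp and positive")
  out <- stats::setNames(as.list(as.integer(vals)), names(vals))
  out$total_labelled <- as.integer(total_labelled)
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FN=%d TN=%d FP=%d (labelled n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$total_labelled))
  invisible(x)
}

#' Performance metrics for a binary hazard classifier
#'
#' Sensitivity, specificity, accuracy, balanced accuracy and coverage, all
#' as percentages. Balanced accuracy is computed from the unrounded
#' sensitivity and specificity; rounding happens only at presentation.
#' Accuracy is taken over evaluable calls (TP+TN+FP+FN), not over all
#' labelled chemicals; coverage is the evaluable fraction of the labelled
#' set. Undefined metrics (empty denominator) are returned as `NA` rather
#' than coerced to zero.
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `performance_metrics`: list with unrounded
#'   numeric fields `se`, `sp`, `acc`, `ba`, `cov` (percent scale).
#' @examples
#' performance(confusion_counts(18, 2, 10, 3, 33))
#' @export
performance <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  evaluable <- tp + tn + fp + fn
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- if (evaluable > 0) 100 * (tp + tn) / evaluable else NA_real_
  ba <- if (!is.na(se) && !is.na(sp)) (se + sp) / 2 else NA_real_
  cov <- 100 * evaluable / counts$total_labelled
  structure(list(se = se, sp = sp, acc = acc, ba = ba, cov = cov),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, digits = 2, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.*f", digits, v))
  cat(sprintf("SE %s  SP %s  ACC %s  BA %s  COV %s (%%)\n",
              fmt(x$se), fmt(x$sp), fmt(x$acc), fmt(x$ba), fmt(x$cov)))
  invisible(x)
}

#' Evaluate every model in a calls table
#'
#' Runs [tally_confusion()] and [performance()] for each distinct model in a
#' calls data.frame and returns one row per model with counts and metrics
#' (metrics rounded to `digits` decimals for presentation).
#'
#' @param records calls data.frame (see [tally_confusion()]).
#' @param digits decimals for the metric columns.
#' @return data.frame with one row per model.
#' @export
evaluate_insilico <- function(records, digits = 2) {
  models <- unique(records$model_id)
  rows <- lapply(models, function(m) {
    cc <- tally_confusion(records, m)
    pm <- performance(cc)
    data.frame(model_id = m, tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
               total_labelled = cc$total_labelled,
               se = round(pm$se, digits), sp = round(pm$sp, digits),
               acc = round(pm$acc, digits), ba = round(pm$ba, digits),
               cov = round(pm$cov, digits))
  })
  do.call(rbind, rows)
}
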