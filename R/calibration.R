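#' Speed-stratum thresholds from self-selected walking speeds
#'
#' The two boundaries defining the walking-speed strata: the 75th
#' percentile of the self-selected slow-bout speeds (`t_low_ms`) and the
#' 25th percentile of the self-selected brisk-bout speeds (`t_high_ms`),
#' both weighted-average percentiles (see [percentile()]). Bouts at or
#' below `t_low_ms` are LOW, at or above `t_high_ms` HIGH, otherwise MID.
#'
#' @param bouts Bout tibble with `condition` and `speed_ms` columns.
#' @return A one-row tibble with `t_low_ms` and `t_high_ms`.
#' @export
speed_thresholds <- function(bouts) {
  cond <- as_condition(bouts$condition)
  slow <- bouts$speed_ms[cond == "SLOW"]
  brisk <- bouts$speed_ms[cond == "BRISK"]
  if (length(slow) == 0L) abort("no SLOW bouts present")
  if (length(brisk) == 0L) abort("no BRISK bouts present")
  t_low <- percentile(slow, 75)
  t_high <- percentile(brisk, 25)
  if (t_low >= t_high) {
    abort(sprintf("strata collapse: t_low (%.3f) >= t_high (%.3f)",
                  t_low, t_high))
  }
  tibble::tibble(t_low_ms = t_low, t_high_ms = t_high)
}

#' Restructure bouts into speed strata
#'
#' Labels every bout by its *measured* speed, not its instructed
#' condition: a normal-condition bout walked below the slow threshold is
#' LOW. The thresholds come from [speed_thresholds()] (or can be supplied,
#' e.g. to hold them fixed across cross-validation folds).
#'
#' @param bouts Bout tibble with `condition` and `speed_ms`.
#' @param thresholds Optional one-row tibble with `t_low_ms`, `t_high_ms`;
#'   computed from `bouts` when `NULL`.
#' @return `bouts` with a `stratum` factor column (LOW/MID/HIGH); the
#'   thresholds are attached as attribute `"speed_thresholds"`.
#' @export
restructure <- function(bouts, thresholds = NULL) {
  thresholds <- thresholds %||% speed_thresholds(bouts)
  if (thresholds$t_low_ms >= thresholds$t_high_ms) {
    abort("strata collapse: t_low >= t_high")
  }
  out <- bouts |>
    dplyr::mutate(stratum = dplyr::case_when(
      .data$speed_ms <= thresholds$t_low_ms ~ "LOW",
      .data$speed_ms >= thresholds$t_high_ms ~ "HIGH",
      .default = "MID"
    ) |> as_stratum())
  attr(out, "speed_thresholds") <- thresholds
  out
}

#' Empirical ROC coordinates
#'
#' One coordinate per candidate threshold: every distinct observed score
#' plus -Inf and +Inf sentinels. For `direction = "le"` a score is
#' predicted positive iff it is at or below the threshold (the slow-walking
#' convention: low counts indicate the positive, slow class); for `"ge"`
#' iff at or above (brisk walking).
#'
#' @param scores Numeric scores (counts).
#' @param positive Logical vector, `TRUE` for the positive class.
#' @param direction `"le"` or `"ge"`.
#' @return A tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, positive, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(positive), is.logical(positive))
  if (!any(positive) || all(positive)) {
    abort("both classes must be non-empty")
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[positive]
  neg <- scores[!positive]
  if (direction == "le") {
    sens <- vapply(thr, function(t) mean(pos <= t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg > t), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  }
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Mann-Whitney AUC with Hanley-McNeil confidence interval
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' probability that a positive score beats a negative score in the
#' direction of the test, ties counted one half. The 95% CI uses the
#' Hanley-McNeil closed-form standard error, clamped to `[0, 1]`; it is
#' adequate at calibration-study sample sizes and keeps the pipeline
#' dependency-light.
#'
#' @inheritParams roc_points
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `roc_summary`: list with `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `points` (the [roc_points()] tibble), `direction`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, positive, direction = c("le", "ge"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  if (!any(positive) || all(positive)) {
    abort("both classes must be non-empty")
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  # midranks give wins + half-ties in one pass
  r <- rank(scores)
  auc_ge <- (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auc <- if (direction == "ge") auc_ge else 1 - auc_ge

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(auc = auc,
         auc_ci_low = max(0, auc - zc * se),
         auc_ci_high = min(1, auc + zc * se),
         points = roc_points(scores, positive, direction),
         direction = direction, n_pos = n_pos, n_neg = n_neg),
    class = "roc_summary"
  )
}

#' Verbal grade of an AUC value
#'
#' Conventional discrimination bands: excellent at or above 0.90, good in
#' 0.80-0.89, fair in 0.70-0.79, poor below 0.70 (band edges inclusive on
#' the lower edge).
#'
#' @param auc AUC in `[0, 1]`.
#' @return One of `"EXCELLENT"`, `"GOOD"`, `"FAIR"`, `"POOR"`.
#' @examples
#' grade_auc(0.94) # EXCELLENT
#' @export
grade_auc <- function(auc) {
  stopifnot(length(auc) == 1L)
  if (is.na(auc) || auc < 0 || auc > 1) abort("`auc` must be in [0, 1]")
  if (auc >= 0.90) "EXCELLENT"
  else if (auc >= 0.80) "GOOD"
  else if (auc >= 0.70) "FAIR"
  else "POOR"
}

#' Select a cut point from ROC coordinates under a priority rule
#'
#' Deterministic replacement for visual inspection of ROC coordinates:
#' among coordinates whose *non*-priority metric is at least `floor_other`,
#' pick the one maximising the priority metric; break ties by the larger
#' non-priority metric; break remaining ties by the threshold closest to
#' `midpoint` (typically the midpoint of the two class medians); any final
#' tie goes to the smaller threshold. For slow walking the priority is
#' sensitivity (catching every truly slow bout); for brisk walking it is
#' specificity (false negatives preferred over false positives).
#'
#' @param points A [roc_points()] tibble.
#' @param priority `"sensitivity"` or `"specificity"`.
#' @param floor_other Minimum admissible value of the other metric
#'   (default 0.60).
#' @param midpoint Optional reference threshold for the final tie-break.
#' @return The selected row of `points` (one-row tibble).
#' @export
select_cut_point <- function(points,
                             priority = c("sensitivity", "specificity"),
                             floor_other = 0.60, midpoint = NA_real_) {
  priority <- match.arg(priority)
  if (nrow(points) == 0L) abort("no ROC points supplied")
  other <- setdiff(c("sensitivity", "specificity"), priority)
  adm <- points[points[[other]] >= floor_other, , drop = FALSE]
  if (nrow(adm) == 0L) {
    best <- points[which.max(points[[priority]] + points[[other]]), ]
    abort(sprintf(
      "no admissible threshold: no point has %s >= %.2f (best pair: sensitivity %.3f, specificity %.3f at threshold %g)",
      other, floor_other, best$sensitivity, best$specificity, best$threshold))
  }
  adm <- adm[adm[[priority]] == max(adm[[priority]]), , drop = FALSE]
  adm <- adm[adm[[other]] == max(adm[[other]]), , drop = FALSE]
  if (nrow(adm) > 1L && !is.na(midpoint)) {
    d <- abs(adm$threshold - midpoint)
    adm <- adm[d == min(d), , drop = FALSE]
  }
  adm[order(adm$threshold)[1L], ]
}

#' Derive count cut points for the speed strata
#'
#' Calibrates the two count thresholds on stratified bouts, scored by
#' their mean counts/15 s on the chosen signal (the bout is the unit of
#' analysis). The low cut comes from the ROC of LOW versus MID+HIGH with
#' predicted-positive at-or-below the threshold and sensitivity priority;
#' the high cut from HIGH versus LOW+MID, at-or-above, specificity
#' priority. Cuts are reported as integers — floor of the selected
#' threshold for the low cut, ceiling for the high cut — so the
#' intermediate interval is `[low_cut + 1, high_cut - 1]`. The selected
#' real-valued thresholds are kept alongside (`low_threshold`,
#' `high_threshold`): on integer counts the integer rule reproduces the
#' exact rule (`s <= floor(t)` iff `s <= t` for integer `s`), and on
#' real-valued bout means [classify_counts()] uses the exact thresholds so
#' that a bout scoring exactly at the selected threshold stays in its
#' calibrated class.
#'
#' @param bouts Stratified bout tibble (see [restructure()]) with
#'   `mean_counts_v` / `mean_counts_vm` columns (see [add_bout_counts()]).
#' @param signal `"v"` or `"vm"`.
#' @param floor_other Admissibility floor for the non-priority metric
#'   passed to [select_cut_point()].
#' @return An object of class `cutpoint_set`: list with `signal`,
#'   `low_cut`, `high_cut`, `low_roc`, `high_roc` (both `roc_summary`),
#'   `low_point`, `high_point` (selected coordinates), `floor_other`.
#' @export
derive_cut_points <- function(bouts, signal = c("v", "vm"),
                              floor_other = 0.60) {
  signal <- match.arg(signal)
  if (!"stratum" %in% names(bouts)) {
    abort("bouts are not stratified; call restructure() first")
  }
  if (!all(STRATA %in% as.character(bouts$stratum))) {
    abort("all three strata must be non-empty")
  }
  scores <- bouts[[paste0("mean_counts_", signal)]]
  if (anyNA(scores)) abort("bouts carry missing mean counts")
  stratum <- as_stratum(bouts$stratum)

  pick <- function(positive, direction, priority) {
    midpoint <- (median(scores[positive]) + median(scores[!positive])) / 2
    summ <- roc_auc(scores, positive, direction)
    sel <- select_cut_point(summ$points, priority,
                            floor_other = floor_other, midpoint = midpoint)
    list(roc = summ, point = sel)
  }
  low <- pick(stratum == "LOW", "le", "sensitivity")
  high <- pick(stratum == "HIGH", "ge", "specificity")
  if (!is.finite(low$point$threshold) || !is.finite(high$point$threshold)) {
    abort("degenerate calibration: selected threshold is not finite")
  }
  low_cut <- floor(low$point$threshold)
  high_cut <- ceiling(high$point$threshold)
  if (low_cut >= high_cut) {
    abort(sprintf("degenerate calibration: low cut (%d) >= high cut (%d)",
                  low_cut, high_cut))
  }
  structure(
    list(signal = signal, low_cut = low_cut, high_cut = high_cut,
         low_threshold = low$point$threshold,
         high_threshold = high$point$threshold,
         low_roc = low$roc, high_roc = high$roc,
         low_point = low$point, high_point = high$point,
         floor_other = floor_other),
    class = "cutpoint_set"
  )
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat(sprintf("Cut points (%s counts/15 s):\n", toupper(x$signal)))
  cat(sprintf("  LOW  : <= %d  (sensitivity %.2f, specificity %.2f, AUC %.3f [%.3f-%.3f], %s)\n",
              x$low_cut, x$low_point$sensitivity, x$low_point$specificity,
              x$low_roc$auc, x$low_roc$auc_ci_low, x$low_roc$auc_ci_high,
              grade_auc(x$low_roc$auc)))
  cat(sprintf("  MID  : %d-%d\n", x$low_cut + 1, x$high_cut - 1))
  cat(sprintf("  HIGH : >= %d  (sensitivity %.2f, specificity %.2f, AUC %.3f [%.3f-%.3f], %s)\n",
              x$high_cut, x$high_point$sensitivity, x$high_point$specificity,
              x$high_roc$auc, x$high_roc$auc_ci_low, x$high_roc$auc_ci_high,
              grade_auc(x$high_roc$auc)))
  invisible(x)
}

#' @export
tidy.cutpoint_set <- function(x, ...) {
  tibble::tibble(
    signal = x$signal,
    boundary = c("low", "high"),
    cut = c(x$low_cut, x$high_cut),
    rule = c("<=", ">="),
    sensitivity = c(x$low_point$sensitivity, x$high_point$sensitivity),
    specificity = c(x$low_point$specificity, x$high_point$specificity),
    auc = c(x$low_roc$auc, x$high_roc$auc),
    auc_ci_low = c(x$low_roc$auc_ci_low, x$high_roc$auc_ci_low),
    auc_ci_high = c(x$low_roc$auc_ci_high, x$high_roc$auc_ci_high),
    auc_grade = c(grade_auc(x$low_roc$auc), grade_auc(x$high_roc$auc))
  )
}

#' @export
glance.cutpoint_set <- function(x, ...) {
  tibble::tibble(signal = x$signal, low_cut = x$low_cut,
                 high_cut = x$high_cut,
                 mid_from = x$low_cut + 1, mid_to = x$high_cut - 1)
}

#' @export
autoplot.roc_summary <- function(object, ...) {
  pts <- object$points[order(1 - object$points$specificity,
                             object$points$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.3f (%.3f-%.3f)", object$auc,
                                  object$auc_ci_low, object$auc_ci_high)) +
    ggplot2::theme_minimal()
}
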