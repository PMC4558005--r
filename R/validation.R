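#' Classify counts into speed strata by cut points
#'
#' LOW at or below the low cut, HIGH at or above the high cut, MID in
#' between — the complementary intermediate interval
#' `[low_cut + 1, high_cut - 1]` for integer counts. A `cutpoint_set`
#' carries the exact selected ROC thresholds alongside the reported
#' integer cuts; classification then uses the exact thresholds, which
#' coincide with the integer rule on integer counts and keep a bout
#' scoring exactly at a selected threshold in its calibrated class when
#' scores are real-valued bout means.
#'
#' @param mean_counts Non-negative counts/15 s (vectorised).
#' @param cuts A `cutpoint_set` (see [derive_cut_points()]), or a list
#'   with `low_cut` and `high_cut`.
#' @return Factor with levels LOW/MID/HIGH.
#' @examples
#' classify_counts(c(200, 328, 329, 729, 730), list(low_cut = 328, high_cut = 730))
#' @export
classify_counts <- function(mean_counts, cuts) {
  if (any(mean_counts < 0)) abort("counts must be non-negative")
  low <- cuts$low_threshold %||% cuts$low_cut
  high <- cuts$high_threshold %||% cuts$high_cut
  if (low >= high) abort("crossed cuts: low_cut >= high_cut")
  as_stratum(ifelse(mean_counts <= low, "LOW",
                    ifelse(mean_counts >= high, "HIGH", "MID")))
}

#' Leave-one-out cross-validation of the calibration
#'
#' For each participant in turn, cut points are derived on all other
#' participants' bouts and used to classify the held-out participant's
#' bouts by their mean counts; the (true stratum, predicted stratum) pairs
#' are pooled over folds into a 3x3 confusion matrix. The speed-stratum
#' thresholds are computed once on the full sample and held fixed across
#' folds — the stratification is part of the study design, the cut points
#' are what is being validated. `strict = TRUE` instead recomputes the
#' percentile thresholds on each fold's training sample (relabelling the
#' training bouts; the held-out truth labels stay at the full-sample
#' strata, which remain the reference).
#'
#' Folds whose calibration degenerates (crossed or non-finite cuts, empty
#' training stratum) are skipped with a warning and recorded.
#'
#' @param bouts Bout tibble with `speed_ms` and mean-count columns (see
#'   [add_bout_counts()]); at least 3 participants.
#' @param signal `"v"` or `"vm"`.
#' @param floor_other Admissibility floor for [select_cut_point()].
#' @param strict Recompute speed thresholds per fold? Default `FALSE`.
#' @return An object of class `accel_loocv`: list with `folds` (tibble:
#'   participant_id, low_cut, high_cut, ok), `pairs` (tibble:
#'   participant_id, truth, predicted), `matrix` (3x3 table, rows = truth),
#'   `n_folds`, `n_skipped`, `signal`, `thresholds`.
#' @export
loocv <- function(bouts, signal = c("v", "vm"), floor_other = 0.60,
                  strict = FALSE) {
  signal <- match.arg(signal)
  ids <- unique(bouts$participant_id)
  if (length(ids) < 3L) abort("leave-one-out needs at least 3 participants")

  thresholds <- speed_thresholds(bouts)
  labeled <- restructure(bouts, thresholds)
  score_col <- paste0("mean_counts_", signal)

  folds <- purrr::map(ids, function(pid) {
    train <- labeled[labeled$participant_id != pid, , drop = FALSE]
    test <- labeled[labeled$participant_id == pid, , drop = FALSE]
    if (strict) {
      train <- restructure(dplyr::select(train, -"stratum"))
    }
    cuts <- tryCatch(derive_cut_points(train, signal, floor_other),
                     error = function(e) e)
    if (inherits(cuts, "error")) {
      warn(sprintf("fold %s skipped: %s", pid, conditionMessage(cuts)))
      return(list(fold = tibble::tibble(participant_id = pid,
                                        low_cut = NA_real_,
                                        high_cut = NA_real_, ok = FALSE),
                  pairs = NULL))
    }
    list(fold = tibble::tibble(participant_id = pid,
                               low_cut = cuts$low_cut,
                               high_cut = cuts$high_cut, ok = TRUE),
         pairs = tibble::tibble(participant_id = pid,
                                truth = test$stratum,
                                predicted = classify_counts(test[[score_col]],
                                                            cuts)))
  })

  fold_tbl <- purrr::map_dfr(folds, "fold")
  pairs <- purrr::map_dfr(folds, "pairs")
  if (nrow(pairs) == 0L) abort("all folds degenerated; nothing to validate")
  structure(
    list(folds = fold_tbl, pairs = pairs,
         matrix = confusion_matrix(pairs$truth, pairs$predicted),
         n_folds = length(ids), n_skipped = sum(!fold_tbl$ok),
         signal = signal, thresholds = thresholds),
    class = "accel_loocv"
  )
}

#' Pooled 3x3 confusion matrix
#'
#' @param truth,predicted Stratum factors or strings (LOW/MID/HIGH).
#' @return A 3x3 table, rows = true stratum, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  table(truth = as_stratum(truth), predicted = as_stratum(predicted))
}

#' Absolute agreement of a confusion matrix
#'
#' @param matrix Square confusion matrix (rows = truth).
#' @return Proportion of agreeing classifications, `trace / total`.
#' @examples
#' absolute_agreement(diag(c(10, 10, 10))) # 1
#' @export
absolute_agreement <- function(matrix) {
  m <- as.matrix(matrix)
  total <- sum(m)
  if (total <= 0) abort("empty confusion matrix")
  sum(diag(m)) / total
}

#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordered categories with quadratic
#' weights `w_ij = 1 - (i - j)^2 / (k - 1)^2`: disagreement is penalised
#' in proportion to the squared category distance, so a slow bout called
#' intermediate costs less than one called brisk. The observed weighted
#' proportion is compared with the one expected from the marginals:
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param matrix Square confusion matrix with ordered categories (rows =
#'   truth).
#' @return The kappa point estimate in `[-1, 1]`.
#' @examples
#' qw_kappa(diag(c(5, 5, 5))) # 1
#' @export
qw_kappa <- function(matrix) {
  m <- as.matrix(matrix)
  k <- nrow(m)
  stopifnot(k == ncol(m), k >= 2)
  total <- sum(m)
  if (total <= 0) abort("empty confusion matrix")
  p <- m / total
  idx <- seq_len(k)
  w <- 1 - (outer(idx, idx, "-"))^2 / (k - 1)^2
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (1 - pe < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    abort("degenerate marginals: expected agreement is 1")
  }
  (po - pe) / (1 - pe)
}

#' Verbal interpretation of a kappa value
#'
#' Landis-Koch bands: below 0 poor, 0-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect.
#'
#' @param kappa Kappa in `[-1, 1]`.
#' @return One of `"POOR"`, `"SLIGHT"`, `"FAIR"`, `"MODERATE"`,
#'   `"SUBSTANTIAL"`, `"ALMOST_PERFECT"`.
#' @examples
#' interpret_kappa(0.79) # SUBSTANTIAL
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(length(kappa) == 1L)
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    abort("`kappa` must be in [-1, 1]")
  }
  if (kappa < 0) "POOR"
  else if (kappa <= 0.20) "SLIGHT"
  else if (kappa <= 0.40) "FAIR"
  else if (kappa <= 0.60) "MODERATE"
  else if (kappa <= 0.80) "SUBSTANTIAL"
  else "ALMOST_PERFECT"
}

#' Agreement summary with bootstrap kappa confidence interval
#'
#' Pools the classification records into a confusion matrix and reports
#' absolute agreement and quadratic weighted kappa. The kappa CI is a
#' percentile bootstrap resampling *participants* (not bouts): bouts of
#' one participant share a random intercept and a fold, so resampling the
#' independent sampling units respects the clustering.
#'
#' @param x An `accel_loocv` object, or a tibble with columns
#'   `participant_id`, `truth`, `predicted`.
#' @param boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap (default 1).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `accel_agreement`: list with `matrix`,
#'   `absolute_agreement`, `kappa`, `kappa_ci_low`, `kappa_ci_high`,
#'   `interpretation`, `boot`, `seed`, `n_participants`, `n_bouts`.
#' @export
agreement <- function(x, boot = 2000L, seed = 1L, conf_level = 0.95) {
  pairs <- if (inherits(x, "accel_loocv")) x$pairs else tibble::as_tibble(x)
  stopifnot(all(c("participant_id", "truth", "predicted") %in% names(pairs)))
  m <- confusion_matrix(pairs$truth, pairs$predicted)
  kap <- qw_kappa(m)

  ids <- unique(pairs$participant_id)
  by_id <- split(pairs, pairs$participant_id)[ids]
  boot_kappas <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      res <- dplyr::bind_rows(by_id[take])
      mb <- confusion_matrix(res$truth, res$predicted)
      tryCatch(qw_kappa(mb), error = function(e) NA_real_)
    }, numeric(1))
  })
  boot_kappas <- boot_kappas[!is.na(boot_kappas)]
  alpha <- 1 - conf_level
  ci <- if (length(boot_kappas) > 0) {
    unname(stats::quantile(boot_kappas, c(alpha / 2, 1 - alpha / 2),
                           type = 6))
  } else c(NA_real_, NA_real_)

  structure(
    list(matrix = m,
         absolute_agreement = absolute_agreement(m),
         kappa = kap,
         kappa_ci_low = min(ci[1], kap, na.rm = TRUE),
         kappa_ci_high = max(ci[2], kap, na.rm = TRUE),
         interpretation = interpret_kappa(kap),
         boot = as.integer(boot), seed = as.integer(seed),
         n_participants = length(ids), n_bouts = nrow(pairs)),
    class = "accel_agreement"
  )
}

#' @export
print.accel_agreement <- function(x, ...) {
  cat("Pooled confusion matrix (rows = true stratum):\n")
  print(x$matrix)
  cat(sprintf("Absolute agreement: %.1f%% (%d bouts, %d participants)\n",
              100 * x$absolute_agreement, x$n_bouts, x$n_participants))
  cat(sprintf("Quadratic weighted kappa: %.2f (95%% CI %.2f-%.2f), %s\n",
              x$kappa, x$kappa_ci_low, x$kappa_ci_high, x$interpretation))
  invisible(x)
}

#' @export
tidy.accel_agreement <- function(x, ...) {
  as.data.frame(x$matrix) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @export
glance.accel_agreement <- function(x, ...) {
  tibble::tibble(absolute_agreement = x$absolute_agreement,
                 kappa = x$kappa,
                 kappa_ci_low = x$kappa_ci_low,
                 kappa_ci_high = x$kappa_ci_high,
                 interpretation = x$interpretation,
                 n_participants = x$n_participants,
                 n_bouts = x$n_bouts)
}

#' @export
autoplot.accel_agreement <- function(object, ...) {
  df <- as.data.frame(object$matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted stratum", y = "True stratum",
                  fill = "Bouts") +
    ggplot2::theme_minimal()
}
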