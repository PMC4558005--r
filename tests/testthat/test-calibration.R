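test_that("weighted-average percentile follows the (n+1) definition", {
  expect_equal(percentile(c(1, 2, 3, 4), 50), 2.5)
  expect_equal(percentile(c(1, 2, 3, 4), 75), 3.75) # h = 3.75
  expect_equal(percentile(5, 25), 5)                # clamped single value
  expect_equal(percentile(c(4, 1, 3, 2), 75), 3.75) # order-free
  expect_equal(percentile(c(1, 2, 3, 4), 99), 4)    # clamped to max
  expect_error(percentile(numeric(), 50), "empty")
  # agrees with the type-6 quantile definition on random draws
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1))
    p <- runif(1, 5, 95)
    expect_equal(percentile(x, p),
                 unname(stats::quantile(x, p / 100, type = 6)),
                 tolerance = 1e-12)
  }
})

test_that("restructuring labels bouts by measured speed, not condition", {
  bouts <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B", "B"),
    condition = rep(c("SLOW", "NORMAL", "BRISK"), 2),
    speed_ms = c(0.8, 1.2, 1.6, 1.0, 0.9, 1.5)
  )
  thr <- tibble::tibble(t_low_ms = 1.0, t_high_ms = 1.3)
  lab <- restructure(bouts, thr)
  expect_equal(as.character(lab$stratum),
               c("LOW", "MID", "HIGH", "LOW", "LOW", "HIGH"))
  # the 0.9 m/s NORMAL bout is LOW despite its condition
  expect_equal(as.character(lab$stratum[5]), "LOW")

  # thresholds come from slow/brisk percentiles of the sample itself
  auto <- restructure(bouts)
  thr_auto <- attr(auto, "speed_thresholds")
  expect_equal(thr_auto$t_low_ms, percentile(c(0.8, 1.0), 75))
  expect_equal(thr_auto$t_high_ms, percentile(c(1.6, 1.5), 25))

  # labeling is invariant to row order
  perm <- sample(nrow(bouts))
  relab <- restructure(bouts[perm, ], thr)
  expect_equal(as.character(relab$stratum),
               as.character(lab$stratum[perm]))

  expect_error(restructure(bouts, tibble::tibble(t_low_ms = 1.4,
                                                 t_high_ms = 1.3)),
               "strata collapse")
  expect_error(speed_thresholds(dplyr::filter(bouts, condition != "BRISK")),
               "BRISK")
})

test_that("ROC coordinates match a brute-force confusion count", {
  pts <- roc_points(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE), "le")
  at2 <- pts[pts$threshold == 2, ]
  expect_equal(at2$sensitivity, 1)
  expect_equal(at2$specificity, 1)

  pts2 <- roc_points(c(1, 5, 2, 6), c(TRUE, TRUE, FALSE, FALSE), "le")
  at1 <- pts2[pts2$threshold == 1, ]
  expect_equal(at1$sensitivity, 0.5)
  expect_equal(at1$specificity, 1)

  set.seed(8)
  for (dir in c("le", "ge")) {
    scores <- sample(0:50, 30, replace = TRUE)
    positive <- c(rep(TRUE, 12), rep(FALSE, 18))
    pts <- roc_points(scores, positive, dir)
    for (i in sample(nrow(pts), 10)) {
      t <- pts$threshold[i]
      pred <- if (dir == "le") scores <= t else scores >= t
      expect_equal(pts$sensitivity[i],
                   sum(pred & positive) / sum(positive))
      expect_equal(pts$specificity[i],
                   sum(!pred & !positive) / sum(!positive))
    }
    # monotone in the threshold by construction
    s <- if (dir == "le") 1 else -1
    expect_true(all(s * diff(pts$sensitivity) >= 0))
    expect_true(all(s * diff(pts$specificity) <= 0))
  }
  expect_error(roc_points(1:4, rep(TRUE, 4), "le"), "both classes")
})

test_that("AUC equals the exhaustive pair-count probability", {
  sep <- roc_auc(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE), "le")
  expect_equal(sep$auc, 1)
  same <- roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE), "le")
  expect_equal(same$auc, 0.5)

  pair_oracle <- function(pos, neg, dir) {
    wins <- 0
    for (p in pos) for (n in neg) {
      beat <- if (dir == "le") p < n else p > n
      wins <- wins + beat + 0.5 * (p == n)
    }
    wins / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(1, 2, 4, 3, 5), c(T, T, T, F, F), "le")$auc,
               pair_oracle(c(1, 2, 4), c(3, 5), "le"))

  set.seed(13)
  for (i in 1:25) {
    npos <- sample(3:10, 1); nneg <- sample(3:10, 1)
    scores <- sample(0:12, npos + nneg, replace = TRUE) # ties likely
    positive <- c(rep(TRUE, npos), rep(FALSE, nneg))
    dir <- sample(c("le", "ge"), 1)
    r <- roc_auc(scores, positive, dir)
    expect_equal(r$auc, pair_oracle(scores[positive], scores[!positive], dir),
                 tolerance = 1e-12)
    expect_lte(r$auc_ci_low, r$auc)
    expect_gte(r$auc_ci_high, r$auc)
    expect_gte(r$auc_ci_low, 0)
    expect_lte(r$auc_ci_high, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    scores <- c(rnorm(15, 3), rnorm(20, 5))
    positive <- c(rep(TRUE, 15), rep(FALSE, 20))
    # positives score lower: predicted positive at or below the threshold
    ours <- roc_auc(scores, positive, "le")
    ref <- pROC::roc(response = positive, predictor = scores,
                     direction = ">", levels = c(FALSE, TRUE),
                     quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("AUC grading bands have inclusive lower edges", {
  expect_equal(grade_auc(0.940), "EXCELLENT")
  expect_equal(grade_auc(0.90), "EXCELLENT")
  expect_equal(grade_auc(0.899), "GOOD")
  expect_equal(grade_auc(0.80), "GOOD")
  expect_equal(grade_auc(0.784), "FAIR")
  expect_equal(grade_auc(0.70), "FAIR")
  expect_equal(grade_auc(0.5), "POOR")
  expect_error(grade_auc(1.2), "\\[0, 1\\]")
})

test_that("cut-point selection follows the floor-constrained priority rule", {
  pts <- tibble::tibble(threshold = c(10, 8),
                        sensitivity = c(1.0, 0.9),
                        specificity = c(0.75, 0.9))
  expect_equal(select_cut_point(pts, "sensitivity")$threshold, 10)
  expect_equal(select_cut_point(pts, "specificity")$threshold, 8)
  expect_error(select_cut_point(pts, "sensitivity", floor_other = 0.95),
               "no admissible threshold")

  # invariant to duplicating every data point behind the curve: the
  # coordinates are proportions, so replication cannot change them
  scores <- c(1, 3, 4, 7, 9, 12)
  positive <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  a <- select_cut_point(roc_points(scores, positive, "le"), "sensitivity")
  b <- select_cut_point(roc_points(rep(scores, 3), rep(positive, 3), "le"),
                        "sensitivity")
  expect_equal(a, b)
})

test_that("cut-point selection matches an exhaustive-search oracle", {
  oracle <- function(points, priority, floor_other, midpoint) {
    other <- setdiff(c("sensitivity", "specificity"), priority)
    best <- NULL
    for (i in seq_len(nrow(points))) {
      row <- points[i, ]
      if (row[[other]] < floor_other) next
      key <- c(row[[priority]], row[[other]],
               -abs(row$threshold - midpoint), -row$threshold)
      if (is.null(best) || lex_gt(key, best$key)) {
        best <- list(row = row, key = key)
      }
    }
    best$row
  }
  lex_gt <- function(a, b) {
    for (j in seq_along(a)) {
      if (a[j] > b[j]) return(TRUE)
      if (a[j] < b[j]) return(FALSE)
    }
    FALSE
  }
  set.seed(17)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    pts <- tibble::tibble(
      threshold = sort(sample(0:100, n)),
      sensitivity = round(runif(n), 1), # coarse grid to force ties
      specificity = round(runif(n), 1)
    )
    priority <- sample(c("sensitivity", "specificity"), 1)
    midpoint <- runif(1, 0, 100)
    other <- setdiff(c("sensitivity", "specificity"), priority)
    if (all(pts[[other]] < 0.6)) {
      expect_error(select_cut_point(pts, priority, midpoint = midpoint),
                   "no admissible")
    } else {
      got <- select_cut_point(pts, priority, midpoint = midpoint)
      want <- oracle(pts, priority, 0.6, midpoint)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("derived cut points separate a noiseless cohort perfectly", {
  bouts <- separable_bouts()
  for (sig in c("v", "vm")) {
    cuts <- derive_cut_points(bouts, sig)
    td <- tidy(cuts)
    expect_equal(td$sensitivity, c(1, 1))
    expect_equal(td$specificity, c(1, 1))
    expect_equal(td$auc, c(1, 1))
    offset <- if (sig == "v") 0 else 120
    expect_gte(cuts$low_cut, 180 + offset) # above the LOW count band
    expect_lt(cuts$low_cut, 500 + offset)  # below the MID band
    expect_gt(cuts$high_cut, 530 + offset)
    expect_lte(cuts$high_cut, 900 + offset)
    pred <- classify_counts(bouts[[paste0("mean_counts_", sig)]], cuts)
    expect_equal(as.character(pred), as.character(bouts$stratum))
  }
})

test_that("cut points partition all counts into exactly one stratum", {
  cuts <- derive_cut_points(separable_bouts(), "v")
  strata <- classify_counts(0:2000, cuts)
  expect_false(anyNA(strata))
  expect_equal(sum(strata == "LOW") + sum(strata == "MID") +
                 sum(strata == "HIGH"), 2001L)
  # the intermediate interval is the integer complement of the cuts
  expect_equal(as.character(strata[cuts$low_cut + 1]), "LOW")  # 0-based
  expect_equal(as.character(strata[cuts$low_cut + 2]), "MID")
  expect_equal(as.character(strata[cuts$high_cut]), "MID")
  expect_equal(as.character(strata[cuts$high_cut + 1]), "HIGH")
})

test_that("degenerate calibrations are rejected", {
  bouts <- separable_bouts()
  expect_error(derive_cut_points(dplyr::select(bouts, -"stratum"), "v"),
               "not stratified")
  expect_error(derive_cut_points(dplyr::filter(bouts, stratum != "MID"),
                                 "v"),
               "three strata")
})
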