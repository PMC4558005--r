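# Fixtures built in code: small cohorts with known structure.

# Labeled bouts with widely separated count levels per stratum and one
# bout per participant/condition; speeds placed so stratification is
# unambiguous.
separable_bouts <- function(n_per_stratum = 8) {
  strata <- rep(c("LOW", "MID", "HIGH"), each = n_per_stratum)
  speeds <- rep(c(0.8, 1.15, 1.5), each = n_per_stratum) +
    rep(seq(0, 0.05, length.out = n_per_stratum), times = 3)
  counts_v <- rep(c(150, 500, 900), each = n_per_stratum) +
    rep(seq(0, 30, length.out = n_per_stratum), times = 3)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_along(strata)),
    condition = factor(rep(c("SLOW", "NORMAL", "BRISK"),
                           each = n_per_stratum),
                       levels = c("SLOW", "NORMAL", "BRISK")),
    speed_ms = speeds,
    speed_kmh = speeds * 3.6,
    mean_counts_v = counts_v,
    mean_counts_vm = counts_v + 120,
    stratum = factor(strata, levels = c("LOW", "MID", "HIGH"))
  )
}

# Fully degenerate noiseless cohort: no count noise and no speed spread,
# so every participant is identical and leave-one-out cannot move any
# training extreme. Built by hand (the generator requires positive SDs).
degenerate_bouts <- function(n = 6) {
  pv <- default_count_params("v")
  pvm <- default_count_params("vm")
  tidyr::expand_grid(
    participant_id = sprintf("P%02d", seq_len(n)),
    condition = factor(c("SLOW", "NORMAL", "BRISK"),
                       levels = c("SLOW", "NORMAL", "BRISK"))
  ) |>
    dplyr::mutate(
      speed_ms = c(0.89, 1.17, 1.47)[as.integer(condition)],
      speed_kmh = speed_ms * 3.6,
      mean_counts_v = pmax(0, pv$intercept + pv$slope * speed_ms),
      mean_counts_vm = pmax(0, pvm$intercept + pvm$slope * speed_ms)
    )
}

# Per-second triaxial frame for aggregation tests
per_second_frame <- function(v, ap = 0, ml = 0) {
  tibble::tibble(axis_v = v, axis_ap = rep_len(ap, length(v)),
                 axis_ml = rep_len(ml, length(v)))
}
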