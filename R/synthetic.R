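# Stratum targets the generator emulates: per-stratum mean +/- SD of
# vertical-axis and VM counts/15 s and walking speed (m/s) for slow /
# intermediate / brisk hallway walking in older adults with parkinsonian
# gait, at the strata boundaries 1.04 and 1.31 m/s.
stratum_targets <- tibble::tibble(
  stratum = factor(STRATA, levels = STRATA),
  speed_mean_ms = c(0.89, 1.17, 1.47),
  speed_sd_ms = c(0.11, 0.08, 0.14),
  counts_v_mean = c(256, 574, 819),
  counts_v_sd = c(150, 144, 217),
  counts_vm_mean = c(427, 679, 911),
  counts_vm_sd = c(230, 176, 232)
)

#' Default count-model parameters for a signal
#'
#' The generator's mean model is linear in speed:
#' `E[counts | speed] = intercept + slope * speed`, with a Gaussian
#' between-participant random intercept (`participant_sd`) and independent
#' within-bout epoch noise (`epoch_sd`), rectified at zero. The intercept
#' and slope are the least-squares line through the three published
#' (stratum mean speed, stratum mean counts) points; the three points are
#' near-collinear, so a line is the minimal structure that makes the
#' calibration recoverable.
#'
#' The residual stratum variance (published stratum count variance minus
#' the component mediated by within-stratum speed spread through the slope,
#' averaged over strata) is split 50/50 between `participant_sd^2` and
#' `epoch_sd^2`; the split between the two sources is not identifiable from
#' stratum tables and is configurable.
#'
#' @param signal `"v"` (vertical axis) or `"vm"` (vector magnitude).
#' @return A list with `intercept`, `slope`, `participant_sd`, `epoch_sd`
#'   (all in counts/15 s, slope in counts/15 s per m/s), class
#'   `count_model_params`.
#' @examples
#' default_count_params("v")$slope # ~969 counts per m/s
#' @export
default_count_params <- function(signal = c("v", "vm")) {
  signal <- match.arg(signal)
  # frozen least-squares fits through (0.89, 1.17, 1.47) m/s versus
  # (256, 574, 819) [v] and (427, 679, 911) [vm] counts/15 s
  p <- switch(signal,
    v  = list(intercept = -590.357369255, slope = 968.858954041),
    vm = list(intercept = -308.719492868, slope = 833.755942948)
  )
  sds <- switch(signal,
    v  = list(counts = c(150, 144, 217)),
    vm = list(counts = c(230, 176, 232))
  )
  speed_sd <- c(0.11, 0.08, 0.14)
  resid_var <- mean(pmax(sds$counts^2 - (p$slope * speed_sd)^2, 0))
  structure(
    list(intercept = p$intercept, slope = p$slope,
         participant_sd = sqrt(resid_var / 2),
         epoch_sd = sqrt(resid_var / 2)),
    class = "count_model_params"
  )
}

#' Configuration for a synthetic walking cohort
#'
#' Defines the study conditions the generator emulates: each participant
#' walks one bout per instructed condition (slow, normal, brisk) in a
#' 210-m circular hallway for at least three minutes, wearing a waist-worn
#' triaxial monitor summarised into 15-s epochs.
#'
#' @param n_participants Number of participants (default 30).
#' @param speed_means_ms Mean self-selected speed (m/s) per condition
#'   SLOW/NORMAL/BRISK.
#' @param speed_sds_ms Between-participant SD of speed per condition.
#' @param pace_sd_ms SD of the shared participant "pace" shift (m/s),
#'   common to all three conditions of one participant, so slow < normal <
#'   brisk is violated only rarely (violations are kept; stratification is
#'   by measured speed, not condition).
#' @param count_params Named list with elements `v` and `vm`, each a
#'   `count_model_params` list (see [default_count_params()]).
#' @param missing_bout_prob Probability that a bout is missing (a
#'   participant failing to complete it), default 0.02.
#' @param noise_scale Multiplier applied to both count noise SDs
#'   (`participant_sd`, `epoch_sd`) of both signals; 1 keeps the
#'   published-variance defaults, 0 gives noiseless counts.
#' @param hallway_m Lap length in metres (default 210).
#' @param min_duration_s Minimum bout duration in seconds (default 180).
#' @param seed Integer seed; the generated cohort is a pure function of
#'   the configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 30,
                          speed_means_ms = c(0.89, 1.17, 1.47),
                          speed_sds_ms = c(0.11, 0.08, 0.14),
                          pace_sd_ms = 0.06,
                          count_params = list(v = default_count_params("v"),
                                              vm = default_count_params("vm")),
                          missing_bout_prob = 0.02,
                          noise_scale = 1,
                          hallway_m = 210,
                          min_duration_s = 180,
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              speed_means_ms = speed_means_ms,
              speed_sds_ms = speed_sds_ms,
              pace_sd_ms = pace_sd_ms,
              count_params = count_params,
              missing_bout_prob = missing_bout_prob,
              noise_scale = noise_scale,
              hallway_m = hallway_m,
              min_duration_s = min_duration_s,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  ok <- is.list(cfg) &&
    length(cfg$n_participants) == 1L && cfg$n_participants >= 1 &&
    length(cfg$speed_means_ms) == 3L && all(cfg$speed_means_ms > 0) &&
    length(cfg$speed_sds_ms) == 3L && all(cfg$speed_sds_ms > 0) &&
    cfg$pace_sd_ms >= 0 &&
    all(c("v", "vm") %in% names(cfg$count_params)) &&
    cfg$missing_bout_prob >= 0 && cfg$missing_bout_prob <= 1 &&
    cfg$noise_scale >= 0 && cfg$hallway_m > 0 && cfg$min_duration_s > 0
  if (!ok) abort("invalid cohort configuration")
  for (s in c("v", "vm")) {
    p <- cfg$count_params[[s]]
    if (!(p$slope > 0 && p$participant_sd >= 0 && p$epoch_sd >= 0)) {
      abort("invalid count-model parameters")
    }
  }
  invisible(cfg)
}

#' Read a cohort configuration from JSON
#'
#' @param path Path to a JSON file with (a subset of) the fields of
#'   [cohort_config()].
#' @return A `cohort_config` list.
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(cohort_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$count_params)) {
    raw$count_params <- purrr::map(raw$count_params, ~ do.call(list, as.list(.x)))
  }
  do.call(cohort_config, raw)
}

#' Generate a synthetic walking cohort
#'
#' Draws one self-selected speed per participant and condition
#' (`N(mean_c + pace_i, resid_sd_c)`, truncated below at 0.3 m/s, where
#' `pace_i` is the participant's shared pace shift), walks each bout over
#' the smallest whole number of hallway laps lasting at least the minimum
#' duration, and fills the bout with 15-s epochs whose counts follow the
#' linear count model: `max(0, intercept + slope*speed + b_i + e)` with
#' participant effect `b_i` (shared standard-normal draw scaled by each
#' signal's `participant_sd`) and epoch noise `e`. The vector-magnitude
#' signal is generated from its own model, floored at the vertical count
#' (a vector magnitude cannot be smaller than one of its components), and
#' the residual magnitude is split equally between the two horizontal
#' axes so `vm = sqrt(axis_v^2 + axis_ap^2 + axis_ml^2)` holds exactly.
#' Each bout is independently missing with `missing_bout_prob`.
#'
#' The output is a pure function of the configuration (including its
#' seed); the global RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A list with `bouts` (tibble: participant_id, condition,
#'   distance_m, duration_s, speed_ms, speed_kmh, mean_counts_v,
#'   mean_counts_vm, n_epochs) and `epochs` (tibble of epoch records).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  pace <- rnorm(n, 0, cfg$pace_sd_ms)
  resid_sd <- sqrt(pmax(cfg$speed_sds_ms^2 - cfg$pace_sd_ms^2, 1e-12))

  grid <- tidyr::expand_grid(
    participant_id = ids,
    condition = factor(CONDITIONS, levels = CONDITIONS)
  )
  ci <- as.integer(grid$condition)
  pi <- match(grid$participant_id, ids)
  speed <- cfg$speed_means_ms[ci] + pace[pi] +
    rnorm(nrow(grid), 0, resid_sd[ci])
  speed <- pmax(speed, 0.3)

  laps <- pmax(1, ceiling(cfg$min_duration_s * speed / cfg$hallway_m))
  distance <- laps * cfg$hallway_m
  duration <- distance / speed

  # shared participant movement-intensity effect, scaled per signal
  z <- rnorm(n)
  pv <- cfg$count_params$v
  pvm <- cfg$count_params$vm
  b_v <- z * pv$participant_sd * cfg$noise_scale
  b_vm <- z * pvm$participant_sd * cfg$noise_scale

  keep <- runif(nrow(grid)) >= cfg$missing_bout_prob

  bouts <- grid |>
    dplyr::mutate(distance_m = distance, duration_s = duration,
                  speed_ms = speed, speed_kmh = speed * 3.6) |>
    dplyr::filter(keep)
  pi <- pi[keep]

  n_ep <- floor(bouts$duration_s / 15)
  epochs <- purrr::map_dfr(seq_len(nrow(bouts)), function(i) {
    k <- n_ep[i]
    mu_v <- pv$intercept + pv$slope * bouts$speed_ms[i] + b_v[pi[i]]
    mu_vm <- pvm$intercept + pvm$slope * bouts$speed_ms[i] + b_vm[pi[i]]
    v <- pmax(0, mu_v + rnorm(k, 0, pv$epoch_sd * cfg$noise_scale))
    vm <- pmax(0, mu_vm + rnorm(k, 0, pvm$epoch_sd * cfg$noise_scale))
    vm <- pmax(vm, v)
    horiz <- sqrt(pmax(vm^2 - v^2, 0) / 2)
    tibble::tibble(participant_id = bouts$participant_id[i],
                   condition = bouts$condition[i],
                   epoch_index = seq_len(k) - 1L,
                   axis_v = v, axis_ap = horiz, axis_ml = horiz,
                   vm = vm)
  })

  means <- epochs |>
    dplyr::summarise(mean_counts_v = mean(.data$axis_v),
                     mean_counts_vm = mean(.data$vm),
                     n_epochs = dplyr::n(),
                     .by = c("participant_id", "condition"))
  bouts <- dplyr::left_join(bouts, means,
                            by = c("participant_id", "condition"))
  list(bouts = bouts, epochs = epochs)
}
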