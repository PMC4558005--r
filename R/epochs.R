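#' Vector magnitude of triaxial counts
#'
#' Euclidean norm of the three axis counts, the composite signal most
#' triaxial activity monitors report alongside the per-axis counts.
#'
#' @param axis_v,axis_ap,axis_ml Non-negative count vectors (vertical,
#'   anteroposterior, mediolateral).
#' @return Numeric vector of vector-magnitude counts.
#' @examples
#' vector_magnitude(3, 4, 0) # 5
#' @export
vector_magnitude <- function(axis_v, axis_ap, axis_ml) {
  if (any(c(axis_v, axis_ap, axis_ml) < 0, na.rm = TRUE)) {
    abort("invalid counts: negative values are not allowed")
  }
  sqrt(axis_v^2 + axis_ap^2 + axis_ml^2)
}

#' Aggregate per-second counts into fixed-length epochs
#'
#' Sums consecutive per-second triaxial counts into epochs of
#' `epoch_length_s` seconds (15 s by default, the resolution at which the
#' calibration operates). Epoch `k` (0-based) holds the sum of seconds
#' `[k*L, (k+1)*L)`. A trailing partial epoch is dropped unless
#' `keep_partial = TRUE`: instructed bouts span whole epochs, and a padded
#' short epoch would bias bout count means downward. The vector magnitude
#' is computed from the epoch-summed axis values, matching how monitor
#' software reports epoch VM.
#'
#' Grouping columns (`participant_id`, `condition`), if present, are
#' carried through and aggregation is done within each group in row order.
#'
#' @param per_second Data frame with numeric columns `axis_v`, `axis_ap`,
#'   `axis_ml`, one row per second in chronological order, optionally with
#'   `participant_id` and `condition` columns.
#' @param epoch_length_s Positive integer epoch length in seconds.
#' @param keep_partial Keep a trailing partial epoch? Default `FALSE`.
#' @return A tibble of epoch records: any grouping columns, `epoch_index`
#'   (0-based), `axis_v`, `axis_ap`, `axis_ml`, `vm`.
#' @examples
#' sec <- tibble::tibble(axis_v = rep(1, 20), axis_ap = 0, axis_ml = 0)
#' aggregate_epochs(sec) # one epoch of 15 counts; trailing 5 s dropped
#' @export
aggregate_epochs <- function(per_second, epoch_length_s = 15L,
                             keep_partial = FALSE) {
  stopifnot(is.data.frame(per_second),
            length(epoch_length_s) == 1L, epoch_length_s >= 1)
  if (nrow(per_second) == 0L) abort("no samples")
  axes <- c("axis_v", "axis_ap", "axis_ml")
  missing_cols <- setdiff(axes, names(per_second))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(as.matrix(per_second[axes]) < 0, na.rm = TRUE)) {
    abort("invalid counts: negative values are not allowed")
  }
  L <- as.integer(epoch_length_s)

  keys <- intersect(c("participant_id", "condition"), names(per_second))
  one_group <- function(df) {
    n <- nrow(df)
    idx <- (seq_len(n) - 1L) %/% L
    if (!keep_partial) {
      complete <- idx < (n %/% L)
      if (!any(complete)) {
        return(tibble::tibble(epoch_index = integer(),
                              axis_v = double(), axis_ap = double(),
                              axis_ml = double(), vm = double()))
      }
      df <- df[complete, , drop = FALSE]
      idx <- idx[complete]
    }
    out <- df |>
      dplyr::mutate(epoch_index = idx[seq_len(nrow(df))]) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(axes), sum),
                       .by = "epoch_index")
    out$vm <- vector_magnitude(out$axis_v, out$axis_ap, out$axis_ml)
    out
  }

  if (length(keys) == 0L) {
    one_group(per_second)
  } else {
    per_second |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::group_modify(~ one_group(.x)) |>
      dplyr::ungroup()
  }
}

#' Walking speed from distance and duration
#'
#' @param distance_m Distance walked in metres (>= 0).
#' @param duration_s Duration in seconds (> 0).
#' @return A tibble with columns `speed_ms` and `speed_kmh`.
#' @examples
#' compute_speed(210, 180) # 1.1667 m/s, 4.2 km/h: one 210-m hallway lap
#' @export
compute_speed <- function(distance_m, duration_s) {
  if (any(duration_s <= 0)) abort("`duration_s` must be positive")
  if (any(distance_m < 0)) abort("`distance_m` must be non-negative")
  speed_ms <- distance_m / duration_s
  tibble::tibble(speed_ms = speed_ms, speed_kmh = speed_ms * 3.6)
}

#' Convert km/h to m/s
#'
#' @param v_kmh Speed in km/h (>= 0).
#' @param decimals Optional number of decimals for half-up rounding of the
#'   result; `NULL` (default) returns the unrounded value.
#' @return Speed in m/s.
#' @examples
#' kmh_to_ms(3.74, 2) # 1.04
#' kmh_to_ms(4.73, 2) # 1.31
#' @export
kmh_to_ms <- function(v_kmh, decimals = NULL) {
  stopifnot(all(v_kmh >= 0))
  v <- v_kmh / 3.6
  if (is.null(decimals)) v else round_half_up(v, decimals)
}

# ---- CSV dialects ----------------------------------------------------------

epoch_cols <- readr::cols(
  participant_id = readr::col_character(),
  condition = readr::col_character(),
  epoch_index = readr::col_integer(),
  axis_v = readr::col_double(),
  axis_ap = readr::col_double(),
  axis_ml = readr::col_double(),
  vm = readr::col_double()
)

#' Read and write epoch-count CSV files
#'
#' The epoch CSV dialect is a plain comma-separated UTF-8 file with header
#' `participant_id,condition,epoch_index,axis_v,axis_ap,axis_ml[,vm]`, one
#' row per 15-s epoch, in the style of activity-monitor software exports.
#' The `vm` column is recomputed from the axes when absent.
#'
#' @param path File path.
#' @return `read_epochs()` returns a tibble of epoch records.
#' @export
read_epochs <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  spec <- epoch_cols
  spec$cols <- spec$cols[intersect(names(spec$cols), hdr)]
  df <- readr::read_csv(path, col_types = spec)
  required <- c("participant_id", "condition", "epoch_index",
                "axis_v", "axis_ap", "axis_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("epoch file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(as.matrix(df[c("axis_v", "axis_ap", "axis_ml")]) < 0)) {
    abort("invalid counts: negative values are not allowed")
  }
  df$condition <- as_condition(df$condition)
  if (!"vm" %in% names(df) || all(is.na(df$vm))) {
    df$vm <- vector_magnitude(df$axis_v, df$axis_ap, df$axis_ml)
  }
  tibble::as_tibble(df)
}

#' @rdname read_epochs
#' @param epochs A tibble of epoch records.
#' @export
write_epochs <- function(epochs, path) {
  out <- epochs
  out$condition <- as.character(out$condition)
  readr::write_csv(out, path)
  invisible(path)
}

bout_cols <- readr::cols(
  participant_id = readr::col_character(),
  condition = readr::col_character(),
  distance_m = readr::col_double(),
  duration_s = readr::col_double()
)

#' Read and write bout metadata CSV files
#'
#' The bout CSV dialect has header
#' `participant_id,condition,distance_m,duration_s`, one row per instructed
#' walking bout. Walking speeds (m/s and km/h) are derived on read.
#'
#' @param path File path.
#' @return `read_bouts()` returns a tibble of bouts with derived
#'   `speed_ms` and `speed_kmh`.
#' @export
read_bouts <- function(path) {
  df <- readr::read_csv(path, col_types = bout_cols)
  required <- c("participant_id", "condition", "distance_m", "duration_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("bout file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$distance_m <= 0) || any(df$duration_s <= 0)) {
    abort("bout distances and durations must be positive")
  }
  df$condition <- as_condition(df$condition)
  dplyr::bind_cols(tibble::as_tibble(df),
                   compute_speed(df$distance_m, df$duration_s))
}

#' @rdname read_bouts
#' @param bouts A tibble of bouts.
#' @export
write_bouts <- function(bouts, path) {
  out <- bouts[c("participant_id", "condition", "distance_m", "duration_s")]
  out$condition <- as.character(out$condition)
  readr::write_csv(out, path)
  invisible(path)
}

#' Attach per-bout mean counts from epoch records
#'
#' Joins epochs onto bouts by participant and condition and adds
#' `mean_counts_v` and `mean_counts_vm`, the bout means of the vertical
#' axis and vector-magnitude counts per 15-s epoch. The bout mean is the
#' calibration's unit of analysis. `trim_epochs` optionally discards that
#' many epochs from each end of every bout before averaging (gait
#' initiation/termination); the default 0 keeps all epochs.
#'
#' @param bouts Bout tibble (see [read_bouts()]).
#' @param epochs Epoch tibble (see [read_epochs()]).
#' @param trim_epochs Non-negative integer, epochs trimmed from each end.
#' @return `bouts` with `mean_counts_v` and `mean_counts_vm` columns; bouts
#'   with no remaining epochs are dropped with a warning.
#' @export
add_bout_counts <- function(bouts, epochs, trim_epochs = 0L) {
  stopifnot(trim_epochs >= 0)
  ep <- epochs
  if (trim_epochs > 0) {
    ep <- ep |>
      dplyr::group_by(.data$participant_id, .data$condition) |>
      dplyr::filter(dplyr::row_number() > trim_epochs,
                    dplyr::row_number() <= dplyr::n() - trim_epochs) |>
      dplyr::ungroup()
  }
  means <- ep |>
    dplyr::summarise(mean_counts_v = mean(.data$axis_v),
                     mean_counts_vm = mean(.data$vm),
                     n_epochs = dplyr::n(),
                     .by = c("participant_id", "condition"))
  out <- dplyr::inner_join(bouts, means,
                           by = c("participant_id", "condition"))
  if (nrow(out) < nrow(bouts)) {
    warn(sprintf("%d bout(s) had no epochs and were dropped",
                 nrow(bouts) - nrow(out)))
  }
  out
}
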