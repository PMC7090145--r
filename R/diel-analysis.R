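#' Assemble a diel trace from raw columns
#'
#' Validates a gas-exchange time series against the declared photoperiod
#' schedule: time strictly increasing, no gaps beyond
#' \code{gap_tolerance} times the median sampling interval, and a
#' light/dark flag consistent with lights-on at the start of each day.
#'
#' @param time_s Seconds since experiment start (strictly increasing).
#' @param assimilation Net CO2 assimilation (umol m-2 s-1) per sample.
#' @param light_hours,dark_hours Photoperiod split (default 12/12).
#' @param gap_tolerance Maximum allowed gap as a multiple of the median
#'   sampling interval (default 2).
#' @return A data frame of class \code{diel_trace} with columns
#'   \code{time_s}, \code{assimilation}, \code{light_on},
#'   \code{day_index}.
#' @export
diel_trace <- function(time_s, assimilation, light_hours = 12,
                       dark_hours = 12, gap_tolerance = 2) {
  stopifnot(length(time_s) == length(assimilation),
            light_hours + dark_hours == 24)
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  dt <- stats::median(diff(time_s))
  gaps <- which(diff(time_s) > gap_tolerance * dt)
  if (length(gaps)) {
    stop("trace has gaps beyond tolerance at t = ",
         paste(sprintf("[%g, %g]", time_s[gaps], time_s[gaps + 1]), collapse = ", "),
         call. = FALSE)
  }
  day_index <- as.integer(time_s %/% 86400) + 1L
  light_on <- (time_s %% 86400) < light_hours * 3600
  out <- data.frame(time_s = time_s, assimilation = assimilation,
                    light_on = light_on, day_index = day_index)
  class(out) <- c("diel_trace", "data.frame")
  attr(out, "schedule") <- c(light = light_hours, dark = dark_hours)
  out
}

#' Per-day day/night phase summaries of a diel trace
#'
#' Partitions every sample into exactly one (day, phase) cell — the
#' night following a day's light period carries that day's index — and
#' summarises each phase. The per-phase sample counts therefore sum to
#' the trace length.
#'
#' @param trace A \code{diel_trace} (from [diel_trace()] or
#'   [simulate_diel_trace()]).
#' @return Data frame with one row per day: \code{day_index},
#'   \code{day_mean}, \code{day_max}, \code{day_min}, \code{night_mean},
#'   \code{night_max}, \code{night_min}, \code{n_day}, \code{n_night}.
#' @export
phase_summaries <- function(trace) {
  stopifnot(inherits(trace, "diel_trace"))
  agg <- dplyr::summarise(
    dplyr::group_by(as.data.frame(trace), .data$day_index, .data$light_on),
    mean = mean(.data$assimilation), max = max(.data$assimilation),
    min = min(.data$assimilation), n = dplyr::n(), .groups = "drop")
  days <- sort(unique(agg$day_index))
  out <- data.frame(day_index = days, day_mean = NA_real_, day_max = NA_real_,
                    day_min = NA_real_, night_mean = NA_real_,
                    night_max = NA_real_, night_min = NA_real_,
                    n_day = 0L, n_night = 0L)
  for (i in seq_along(days)) {
    dl <- agg[agg$day_index == days[i] & agg$light_on, ]
    dn <- agg[agg$day_index == days[i] & !agg$light_on, ]
    if (nrow(dl)) {
      out[i, c("day_mean", "day_max", "day_min")] <- dl[1, c("mean", "max", "min")]
      out$n_day[i] <- dl$n[1]
    }
    if (nrow(dn)) {
      out[i, c("night_mean", "night_max", "night_min")] <- dn[1, c("mean", "max", "min")]
      out$n_night[i] <- dn$n[1]
    }
  }
  out
}

#' Detect the onset of CAM from nocturnal assimilation
#'
#' CAM photosynthesis fixes CO2 at night, so its onset is read from the
#' nightly mean net assimilation rising from the C3 respiratory baseline
#' (about -1 umol m-2 s-1 here) towards zero. The onset day is the
#' first day whose nightly mean reaches \code{threshold}; the default
#' -0.1 umol m-2 s-1 operationalises "almost zero" while rejecting the
#' baseline.
#'
#' @param summaries Output of [phase_summaries()] (>= 2 days).
#' @param threshold Nightly-mean threshold in umol m-2 s-1 (default -0.1).
#' @return A \code{cam_onset} list: \code{onset_day} (integer or NA),
#'   \code{threshold}, \code{nightly_means} (named by day), and
#'   \code{criterion} (a human-readable descriptor).
#' @export
detect_cam_onset <- function(summaries, threshold = -0.1) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2,
            all(c("day_index", "night_mean") %in% names(summaries)))
  s <- summaries[order(summaries$day_index), ]
  ok <- !is.na(s$night_mean) & s$night_mean >= threshold
  onset <- if (any(ok)) s$day_index[which(ok)[1]] else NA_integer_
  structure(list(onset_day = onset, threshold = threshold,
                 nightly_means = stats::setNames(s$night_mean, s$day_index),
                 criterion = sprintf("first day with nightly mean assimilation >= %g umol m-2 s-1",
                                     threshold)),
            class = "cam_onset")
}

#' @export
print.cam_onset <- function(x, ...) {
  cat("<cam_onset>", x$criterion, "\n  onset day:",
      if (is.na(x$onset_day)) "none" else x$onset_day, "\n")
  invisible(x)
}

#' Dawn/dusk anticipation transients of the CAM circadian clock
#'
#' In established CAM, stomata close in anticipation of lights-on and
#' open before lights-off, producing a sharp rise in net assimilation
#' across the light-on edge (from strongly negative to positive) and a
#' drop across the light-off edge. This compares the mean assimilation
#' in the last \code{window_min} minutes of dark against the first
#' \code{window_min} minutes of light for the given day (and the same
#' around light-off), flagging a "CAM-like" morning edge when the
#' light-on jump spans from below -2 to above +2 umol m-2 s-1.
#'
#' @param trace A \code{diel_trace}.
#' @param day Day index; its light-on edge uses the tail of the previous
#'   night, so \code{day} must be > the first day in the trace.
#' @param window_min Edge window in minutes (default 15).
#' @return List: \code{light_on_pre}, \code{light_on_post},
#'   \code{light_on_delta}, \code{light_off_pre}, \code{light_off_post},
#'   \code{light_off_delta}, \code{cam_like} (logical).
#' @export
detect_anticipation <- function(trace, day, window_min = 15) {
  stopifnot(inherits(trace, "diel_trace"))
  if (!day %in% trace$day_index) stop("day ", day, " not in trace", call. = FALSE)
  dt <- stats::median(diff(trace$time_s))
  w <- max(1L, as.integer(round(window_min * 60 / dt)))

  prev_night <- which(trace$day_index == day - 1 & !trace$light_on)
  this_day <- which(trace$day_index == day & trace$light_on)
  this_night <- which(trace$day_index == day & !trace$light_on)
  if (length(prev_night) < w) {
    stop("no full ", window_min, "-min dark window before day ", day, call. = FALSE)
  }
  if (length(this_day) < 2 * w || length(this_night) < w) {
    stop("day ", day, " shorter than two edge windows", call. = FALSE)
  }
  a <- trace$assimilation
  pre_on <- mean(a[utils::tail(prev_night, w)])
  post_on <- mean(a[utils::head(this_day, w)])
  pre_off <- mean(a[utils::tail(this_day, w)])
  post_off <- mean(a[utils::head(this_night, w)])
  list(light_on_pre = pre_on, light_on_post = post_on,
       light_on_delta = post_on - pre_on,
       light_off_pre = pre_off, light_off_post = post_off,
       light_off_delta = post_off - pre_off,
       cam_like = pre_on < -2 && post_on > 2)
}

#' Aperture statistics and open proportions per day and timepoint
#'
#' For each (day, timepoint) cell: mean aperture, standard error
#' (sample SD / sqrt(n)), and the proportion of open stomata — the
#' count of apertures at or above \code{open_threshold} divided by the
#' total count. The default threshold, 1.4 um, is the midpoint between
#' the observed closed ceiling (1.1 um) and open floor (1.7 um).
#'
#' @param table Stomata table with columns \code{day}, \code{timepoint},
#'   \code{aperture_um} (positive).
#' @param open_threshold Aperture (um) at which a stoma counts as open.
#' @return Data frame: \code{day}, \code{timepoint}, \code{mean_um},
#'   \code{se_um}, \code{open_proportion}, \code{n}. Cells with no
#'   observations are simply absent.
#' @export
aperture_stats <- function(table, open_threshold = 1.4) {
  stopifnot(is.data.frame(table),
            all(c("day", "timepoint", "aperture_um") %in% names(table)))
  if (any(table$aperture_um <= 0)) stop("apertures must be positive", call. = FALSE)
  if (!all(table$timepoint %in% c("4pm", "4am"))) {
    stop("timepoint labels must be '4pm' or '4am'", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$day, .data$timepoint),
    mean_um = mean(.data$aperture_um),
    se_um = stats::sd(.data$aperture_um) / sqrt(dplyr::n()),
    open_proportion = sum(.data$aperture_um >= open_threshold) / dplyr::n(),
    n = dplyr::n(), .groups = "drop")
  as.data.frame(out)
}

#' Detect stomatal inversion
#'
#' Returns the first day whose mean 4 am (nocturnal) aperture exceeds
#' the mean 4 pm (diurnal) aperture — the signature of CAM stomatal
#' behaviour — or NA when no scanned day inverts.
#'
#' @param stats Output of [aperture_stats()]; every scanned day must
#'   carry both timepoints.
#' @return Integer day or \code{NA_integer_}.
#' @export
detect_inversion <- function(stats) {
  stopifnot(is.data.frame(stats),
            all(c("day", "timepoint", "mean_um") %in% names(stats)))
  days <- sort(unique(stats$day))
  for (d in days) {
    am <- stats$mean_um[stats$day == d & stats$timepoint == "4am"]
    pm <- stats$mean_um[stats$day == d & stats$timepoint == "4pm"]
    if (!length(am) || !length(pm)) {
      stop("day ", d, " is missing a timepoint; cannot scan for inversion",
           call. = FALSE)
    }
    if (am[1] > pm[1]) return(as.integer(d))
  }
  NA_integer_
}
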