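#' Simulation configuration
#'
#' Shared configuration for the synthetic-data generators: experiment
#' length, gas-exchange sampling density (one sample per 30 s by
#' default, matching the instrument logging interval), the 12/12 h
#' photoperiod, and the treatment group.
#'
#' @param seed Integer RNG seed; fixed seed implies bit-identical output.
#' @param n_days Number of treatment days simulated (default 14).
#' @param samples_per_day Gas-exchange samples per 24 h (default 2880).
#' @param light_hours,dark_hours Photoperiod split; must sum to 24.
#' @param group \code{"control"} or \code{"salt"}.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1, n_days = 14, samples_per_day = 2880,
                       light_hours = 12, dark_hours = 12,
                       group = c("control", "salt")) {
  group <- match.arg(group)
  stopifnot(n_days >= 1, samples_per_day >= 2,
            light_hours > 0, dark_hours > 0,
            light_hours + dark_hours == 24)
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 samples_per_day = as.integer(samples_per_day),
                 light_hours = light_hours, dark_hours = dark_hours,
                 group = group),
            class = "sim_config")
}

#' Diel gas-exchange simulation parameters
#'
#' Parameters of the synthetic net-assimilation waveform. Control days
#' follow a half-sine hump from \code{day_floor} to \code{day_peak};
#' control nights sit at \code{night_level}. For the salt group the
#' nightly mean ramps linearly from \code{night_level} (at
#' \code{onset_ramp_start_day - 1}) to -0.05 umol m-2 s-1 at
#' \code{night_zero_day} and to +0.3 thereafter, while the daytime hump
#' decays towards zero over the same window. From
#' \code{inversion_spikes_from_day} the trace carries the CAM circadian
#' anticipation pattern: a light-on transient rising from below -2 to
#' above +2 and a light-off drop from above +1 to below -2.
#'
#' @param day_peak,day_floor Daytime assimilation extremes
#'   (umol m-2 s-1); defaults 10.5 / 6.5 keep the waveform inside the
#'   6.0-12.0 range observed for well-watered plants.
#' @param night_level Nocturnal level for the C3 state (default -1.0).
#' @param noise_sd Per-sample Gaussian noise SD (default 0.3).
#' @param onset_ramp_start_day First day of the nocturnal ramp (default 6).
#' @param night_zero_day Day the nightly mean reaches -0.05 (default 8).
#' @param inversion_spikes_from_day First day carrying the anticipation
#'   spikes (default 9).
#' @param spike_amplitude Magnitude of the dawn/dusk transients (default 2.5).
#' @return A \code{diel_sim_params} list.
#' @export
diel_sim_params <- function(day_peak = 10.5, day_floor = 6.5,
                            night_level = -1.0, noise_sd = 0.3,
                            onset_ramp_start_day = 6, night_zero_day = 8,
                            inversion_spikes_from_day = 9,
                            spike_amplitude = 2.5) {
  stopifnot(day_floor < day_peak, noise_sd >= 0,
            onset_ramp_start_day < night_zero_day)
  structure(list(day_peak = day_peak, day_floor = day_floor,
                 night_level = night_level, noise_sd = noise_sd,
                 onset_ramp_start_day = onset_ramp_start_day,
                 night_zero_day = night_zero_day,
                 inversion_spikes_from_day = inversion_spikes_from_day,
                 spike_amplitude = spike_amplitude),
            class = "diel_sim_params")
}

#' Stomatal-aperture simulation parameters
#'
#' Apertures are drawn uniformly within the observed open (1.7-3.0 um)
#' and closed (0.7-1.1 um) ranges. At an open-phase timepoint a fraction
#' \code{open_fraction_when_open_phase} of stomata is open; at a
#' closed-phase timepoint that fraction is closed. For the salt group
#' the phase pattern (day-open / night-closed) swaps from
#' \code{inversion_day} onward.
#'
#' @param open_range,closed_range Aperture ranges in um.
#' @param n_stomata_per_timepoint Stomata measured per timepoint
#'   (default 150).
#' @param inversion_day First day with inverted behaviour in the salt
#'   group (default 7).
#' @param open_fraction_when_open_phase Proportion of open stomata during
#'   the open phase (default 0.8).
#' @return A \code{stomata_sim_params} list.
#' @export
stomata_sim_params <- function(open_range = c(1.7, 3.0),
                               closed_range = c(0.7, 1.1),
                               n_stomata_per_timepoint = 150,
                               inversion_day = 7,
                               open_fraction_when_open_phase = 0.8) {
  stopifnot(length(open_range) == 2, length(closed_range) == 2,
            all(open_range > 0), all(closed_range > 0),
            closed_range[2] <= open_range[1],
            open_fraction_when_open_phase >= 0,
            open_fraction_when_open_phase <= 1,
            n_stomata_per_timepoint >= 1)
  structure(list(open_range = open_range, closed_range = closed_range,
                 n_stomata_per_timepoint = as.integer(n_stomata_per_timepoint),
                 inversion_day = as.integer(inversion_day),
                 open_fraction_when_open_phase = open_fraction_when_open_phase),
            class = "stomata_sim_params")
}

# ---------------------------------------------------------------------------
# Leaf-scene renderer

# Pixel-exact elliptical blob: take exactly n px with the smallest
# normalised elliptical distance from (cx, cy). Ties broken by row-major
# order so the raster is fully deterministic.
.ellipse_pixels <- function(cx, cy, rx, ry, n) {
  if (n == 0L) return(cbind(x = integer(0), y = integer(0)))
  pad <- 2
  xs <- seq.int(floor(cx - rx - pad), ceiling(cx + rx + pad))
  ys <- seq.int(floor(cy - ry - pad), ceiling(cy + ry + pad))
  g <- expand.grid(x = xs, y = ys)
  d <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2
  ord <- order(d, g$y, g$x)
  idx <- ord[seq_len(n)]
  cbind(x = g$x[idx], y = g$y[idx])
}

#' Render a synthetic leaf scene with known ground truth
#'
#' Draws green elliptical leaf blobs and one 1 cm^2 black reference
#' square on a white canvas, returning the image together with its
#' latent ground truth (exact green and reference pixel masks), so the
#' image-analysis pipeline can be scored against a known area. Each
#' requested area is rasterised to an exact pixel count; per-blob counts
#' are apportioned by largest remainder so the total green count equals
#' \code{round(sum(areas_cm2) * px_per_cm^2)} exactly. Blob colour is
#' (0, 180, 0) with per-pixel channel jitter of at most 20, the
#' reference square (0, 0, 0) with jitter at most 10, so default
#' segmentation thresholds succeed while still being exercised.
#'
#' @param areas_cm2 Numeric vector of leaf areas (cm^2, >= 0); may be
#'   empty for a scene with only the reference square.
#' @param px_per_cm Resolution (>= 10 px per cm).
#' @param seed Integer seed for the colour jitter.
#' @param canvas_px Optional c(width, height); by default sized to fit.
#'   A canvas too small for non-overlapping placement is an error.
#' @return A \code{leaf_scene} list: \code{image} (H x W x 3 integer
#'   array, 0-255), \code{green_mask}, \code{reference_mask} (logical
#'   H x W), and \code{truth} (true total area, per-blob pixel counts,
#'   reference pixel count).
#' @export
render_leaf_scene <- function(areas_cm2, px_per_cm, seed = 1,
                              canvas_px = NULL) {
  stopifnot(is.numeric(areas_cm2), all(areas_cm2 >= 0), px_per_cm >= 10)
  areas_cm2 <- areas_cm2[areas_cm2 > 0]
  sq <- as.integer(round(px_per_cm))        # reference square side in px
  total_px <- as.integer(round(sum(areas_cm2) * px_per_cm^2))

  # largest-remainder apportionment of the exact total across blobs
  n_blob <- length(areas_cm2)
  if (n_blob > 0) {
    raw <- areas_cm2 * px_per_cm^2
    base <- floor(raw)
    short <- total_px - sum(base)
    frac_ord <- order(raw - base, decreasing = TRUE)
    counts <- as.integer(base)
    if (short > 0) counts[frac_ord[seq_len(short)]] <- counts[frac_ord[seq_len(short)]] + 1L
    if (short < 0) counts[frac_ord[seq(n_blob, by = -1, length.out = -short)]] <-
        counts[frac_ord[seq(n_blob, by = -1, length.out = -short)]] - 1L
  } else counts <- integer(0)

  # blob geometry: ellipses with 3:2 aspect, laid out in a row
  rxs <- sqrt(counts / pi * 1.5); rys <- sqrt(counts / pi / 1.5)
  margin <- max(6L, sq %/% 4L)
  widths <- ceiling(2 * rxs) + margin
  need_w <- margin + sq + margin + sum(widths) + margin
  need_h <- margin + max(sq, if (n_blob) ceiling(2 * max(rys)) else 0L) + margin
  if (is.null(canvas_px)) canvas_px <- c(need_w, need_h)
  W <- as.integer(canvas_px[1]); H <- as.integer(canvas_px[2])
  if (W < need_w || H < need_h) {
    stop(sprintf("canvas %dx%d too small: need at least %dx%d to place shapes without overlap",
                 W, H, need_w, need_h), call. = FALSE)
  }

  green <- matrix(FALSE, H, W); ref <- matrix(FALSE, H, W)
  ref[seq.int(margin + 1L, margin + sq), seq.int(margin + 1L, margin + sq)] <- TRUE

  x0 <- margin + sq + margin
  cy <- H / 2
  for (i in seq_len(n_blob)) {
    cx <- x0 + widths[i] / 2
    px <- .ellipse_pixels(cx, cy, max(rxs[i], 1), max(rys[i], 1), counts[i])
    green[cbind(px[, "y"], px[, "x"])] <- TRUE
    x0 <- x0 + widths[i]
  }
  stopifnot(sum(green) == total_px, !any(green & ref))

  img <- array(255L, dim = c(H, W, 3L))
  old <- .Random.seed_exists()
  set.seed(seed)
  ng <- sum(green)
  img[, , 1][green] <- sample.int(21L, ng, replace = TRUE) - 1L          # R in 0..20
  img[, , 2][green] <- 160L + sample.int(41L, ng, replace = TRUE) - 1L   # G in 160..200
  img[, , 3][green] <- sample.int(21L, ng, replace = TRUE) - 1L          # B in 0..20
  nr <- sum(ref)
  for (ch in 1:3) img[, , ch][ref] <- sample.int(11L, nr, replace = TRUE) - 1L
  .restore_seed(old)

  structure(list(image = img, green_mask = green, reference_mask = ref,
                 truth = list(total_area_cm2 = total_px / px_per_cm^2,
                              green_px = total_px, blob_px = counts,
                              ref_px = sum(ref), px_per_cm = px_per_cm)),
            class = "leaf_scene")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write a leaf scene to a PNG file
#' @param scene A [render_leaf_scene()] result.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_leaf_scene <- function(scene, path) {
  stopifnot(inherits(scene, "leaf_scene"))
  png::writePNG(scene$image / 255, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Growth, diel, stomata, physio generators

#' Simulate daily leaf-area observations from a growth model
#'
#' @param model A [growth_model()].
#' @param days Integer vector of days after treatment.
#' @param noise_sd Additive Gaussian noise SD in cm^2 (0 reproduces the
#'   model exactly).
#' @param seed Integer seed.
#' @return Data frame with columns \code{day}, \code{area_cm2}.
#' @export
simulate_growth <- function(model, days, noise_sd = 0, seed = 1) {
  stopifnot(inherits(model, "growth_model"), noise_sd >= 0)
  A <- growth_area(model, days)   # errors on negative predicted area
  if (noise_sd > 0) {
    old <- .Random.seed_exists(); set.seed(seed)
    A <- A + stats::rnorm(length(A), 0, noise_sd)
    .restore_seed(old)
    A <- pmax(A, 0)
  }
  data.frame(day = days, area_cm2 = A)
}

# Nightly-mean target of the salt trace on day d (before noise).
.salt_night_target <- function(d, p) {
  d0 <- p$onset_ramp_start_day - 1
  if (d <= d0) return(p$night_level)
  if (d < p$night_zero_day)
    return(p$night_level + (d - d0) * (-0.05 - p$night_level) / (p$night_zero_day - d0))
  if (d == p$night_zero_day) return(-0.05)
  0.3
}

# Daytime amplitude scale on day d: 1 until the ramp starts, linear decay
# to 0 at inversion_spikes_from_day.
.salt_day_scale <- function(d, p) {
  d0 <- p$onset_ramp_start_day - 1
  if (d <= d0) return(1)
  max(0, (p$inversion_spikes_from_day - d) / (p$inversion_spikes_from_day - d0))
}

#' Simulate a diel net-assimilation trace
#'
#' Builds the noiseless diel template for the configured group (see
#' [diel_sim_params()] for the waveform description), adds Gaussian
#' noise, and returns the trace with its latent ground truth attached.
#' Lights come on at the start of each simulated day; the night that
#' follows a day's light period carries that day's index.
#'
#' For salt traces the nightly base level of each night is solved so
#' that the night's mean (including any injected dawn/dusk excursion
#' windows) equals the ramp target exactly in expectation.
#'
#' @param cfg A [sim_config()].
#' @param params A [diel_sim_params()].
#' @return A data frame of class \code{diel_trace} with columns
#'   \code{time_s}, \code{assimilation}, \code{light_on},
#'   \code{day_index}; attribute \code{truth} holds the generator's
#'   latent transition days.
#' @export
simulate_diel_trace <- function(cfg, params = diel_sim_params()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(params, "diel_sim_params"))
  spd <- cfg$samples_per_day
  n <- spd * cfg$n_days
  dt <- 86400 / spd
  time_s <- (seq_len(n) - 1) * dt
  day_index <- (seq_len(n) - 1L) %/% spd + 1L
  frac24 <- ((seq_len(n) - 1) %% spd) / spd * 24
  light_on <- frac24 < cfg$light_hours

  n_light <- sum(light_on[seq_len(spd)])
  n_dark <- spd - n_light
  win <- max(1L, as.integer(round(15 * 60 / dt)))   # 15-min edge window

  template <- numeric(n)
  p <- params
  for (d in seq_len(cfg$n_days)) {
    i_day <- which(day_index == d & light_on)
    i_night <- which(day_index == d & !light_on)
    fr_day <- (seq_along(i_day) - 0.5) / n_light

    if (cfg$group == "control") {
      template[i_day] <- p$day_floor + (p$day_peak - p$day_floor) * sin(pi * fr_day)
      template[i_night] <- p$night_level
      next
    }

    s <- .salt_day_scale(d, p)
    spikes <- d >= p$inversion_spikes_from_day
    if (s > 0) {
      # decaying C3 hump
      template[i_day] <- s * (p$day_floor + (p$day_peak - p$day_floor) * sin(pi * fr_day))
    } else {
      # CAM state: shallow parabola dipping below zero at 2/3 of the
      # photoperiod (mid-afternoon minimum)
      template[i_day] <- 0.4 - 1.4 * pmax(0, 1 - ((fr_day - 2 / 3) / (2 / 3))^2)
    }
    if (spikes) {
      template[i_day[seq_len(win)]] <- p$spike_amplitude            # light-on burst
      template[i_day[seq.int(n_light - win + 1, n_light)]] <- 1.5   # pre-dusk rise
    }

    # night: flat base solved so the realised mean hits the ramp target
    tgt <- .salt_night_target(d, p)
    w_head <- if (spikes) win else 0L                                 # light-off drop
    w_tail <- if ((d + 1) >= p$inversion_spikes_from_day && d < cfg$n_days) win else 0L
    n_exc <- w_head + w_tail
    base <- (tgt * n_dark + p$spike_amplitude * n_exc) / (n_dark - n_exc)
    template[i_night] <- base
    if (w_head > 0) template[i_night[seq_len(w_head)]] <- -p$spike_amplitude
    if (w_tail > 0) template[i_night[seq.int(n_dark - w_tail + 1, n_dark)]] <- -p$spike_amplitude
  }

  assim <- template
  if (p$noise_sd > 0) {
    old <- .Random.seed_exists(); set.seed(cfg$seed)
    assim <- assim + stats::rnorm(n, 0, p$noise_sd)
    .restore_seed(old)
  }

  out <- data.frame(time_s = time_s, assimilation = assim,
                    light_on = light_on, day_index = day_index)
  class(out) <- c("diel_trace", "data.frame")
  attr(out, "schedule") <- c(light = cfg$light_hours, dark = cfg$dark_hours)
  attr(out, "truth") <- list(
    group = cfg$group,
    night_zero_day = if (cfg$group == "salt") as.integer(p$night_zero_day) else NA_integer_,
    spikes_from_day = if (cfg$group == "salt") as.integer(p$inversion_spikes_from_day) else NA_integer_,
    nightly_targets = if (cfg$group == "salt")
      vapply(seq_len(cfg$n_days), .salt_night_target, numeric(1), p = p)
    else rep(p$night_level, cfg$n_days))
  out
}

#' Simulate a stomatal-aperture table
#'
#' Draws apertures for the 4 pm and 4 am observation timepoints of each
#' day. Control plants keep the day-open / night-closed pattern
#' throughout; salt-treated plants swap it from
#' \code{params$inversion_day} onward.
#'
#' @param cfg A [sim_config()].
#' @param params A [stomata_sim_params()].
#' @return Data frame with columns \code{day}, \code{timepoint}
#'   (\code{"4pm"}/\code{"4am"}), \code{plant}, \code{image},
#'   \code{aperture_um}; attribute \code{truth} carries the latent
#'   inversion day.
#' @export
simulate_stomata <- function(cfg, params = stomata_sim_params()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(params, "stomata_sim_params"))
  p <- params
  if (cfg$group == "salt") {
    stopifnot(p$inversion_day >= 1, p$inversion_day <= cfg$n_days)
  }
  old <- .Random.seed_exists(); set.seed(cfg$seed)
  n <- p$n_stomata_per_timepoint
  rows <- vector("list", 2L * cfg$n_days)
  k <- 0L
  for (d in seq_len(cfg$n_days)) {
    inverted <- cfg$group == "salt" && d >= p$inversion_day
    for (tp in c("4pm", "4am")) {
      phase_open <- if (tp == "4pm") !inverted else inverted
      f_open <- if (phase_open) p$open_fraction_when_open_phase
                else 1 - p$open_fraction_when_open_phase
      n_open <- round(n * f_open)
      ap <- c(stats::runif(n_open, p$open_range[1], p$open_range[2]),
              stats::runif(n - n_open, p$closed_range[1], p$closed_range[2]))
      k <- k + 1L
      rows[[k]] <- data.frame(
        day = d, timepoint = tp,
        plant = rep_len(sprintf("p%d", 1:3), n),
        image = rep_len(sprintf("img%02d", 1:15), n),
        aperture_um = ap)
    }
  }
  .restore_seed(old)
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    group = cfg$group,
    inversion_day = if (cfg$group == "salt") p$inversion_day else NA_integer_)
  out
}

# Target trajectories for the physiology generator (units: g cm-2, %, nmol/g).
.succulence_target <- function(d, group) {
  base <- ifelse(d <= 5, 0.12 + (0.16 - 0.12) * d / 5, 0.16)
  if (group == "salt") {
    bump <- ifelse(d <= 5, 0, pmin((d - 5) / 6, 1) * 0.02)   # to 0.18 by day 11
    base + bump
  } else base
}
.rwc_target <- function(d, group, n_days) {
  base <- 62.5 + (80 - 62.5) * d / n_days
  if (group == "salt") base + ifelse(d >= 4 & d <= 11, 3, 0) else base
}
.mda_target <- function(d, group) {
  base <- 1.15 + 0.1 * sin(d / 4)           # stays well inside 0.8-1.5
  if (group == "salt") {
    base + ifelse(d < 7, 0, ifelse(d == 7, 0.35, pmin(0.55 + 0.05 * (d - 8), 0.8)))
  } else base
}

#' Simulate daily physiology samples
#'
#' Generates per-replicate raw measurements (fresh, turgid and dry
#' weights, leaf area, absorbances at 532 and 450 nm, tissue mass) whose
#' derived indices follow the study trajectories: succulence rising from
#' 0.12 to 0.16 g cm-2 over days 0-5 in both groups and on to
#' 0.18 g cm-2 by day 11 under salt; relative water content drifting
#' from 62.5% to 80%; malondialdehyde near 1.15 nmol g-1 fresh weight in
#' controls with a salt increase from day 7. Weights are constructed so
#' that dry < fresh < turgid always holds; absorbances are back-computed
#' from the MDA target through the assay's volume bookkeeping.
#'
#' @param cfg A [sim_config()] (its \code{group} selects the trajectory
#'   set; days run 0..n_days).
#' @param n_replicates Biological replicates per day (default 4).
#' @param noise_cv Relative noise applied to the index targets
#'   (default 0.05; MDA uses an absolute SD of 0.12 nmol/g).
#' @return Data frame with columns \code{day}, \code{group},
#'   \code{plant}, \code{fw_g}, \code{tw_g}, \code{dw_g},
#'   \code{area_cm2}, \code{od532}, \code{od450}, \code{tissue_g};
#'   attribute \code{truth} carries the noiseless index trajectories.
#' @export
simulate_physio <- function(cfg, n_replicates = 4, noise_cv = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  old <- .Random.seed_exists(); set.seed(cfg$seed)
  days <- 0:cfg$n_days
  g <- cfg$group
  rows <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    S <- .succulence_target(d, g) * (1 + stats::rnorm(n_replicates, 0, noise_cv))
    R <- .rwc_target(d, g, cfg$n_days) * (1 + stats::rnorm(n_replicates, 0, noise_cv / 2))
    M <- pmax(.mda_target(d, g) + stats::rnorm(n_replicates, 0, 0.12), 0.2)
    area <- (4 + 0.4 * d) * (1 + stats::rnorm(n_replicates, 0, noise_cv))
    fw <- S * area
    dw <- 0.10 * fw
    tw <- fw + (fw - dw) * 100 / R              # printed RWC formula inverted
    tissue <- 0.2
    conc <- M * tissue / (0.004 * (3 / 2) * 1000)  # umol/L giving M nmol/g
    od450 <- 0.05 * (1 + stats::rnorm(n_replicates, 0, noise_cv))
    od532 <- (conc + 0.56 * od450) / 6.45
    rows[[i]] <- data.frame(day = d, group = g,
                            plant = sprintf("p%d", seq_len(n_replicates)),
                            fw_g = fw, tw_g = tw, dw_g = dw,
                            area_cm2 = area, od532 = od532, od450 = od450,
                            tissue_g = tissue)
  }
  .restore_seed(old)
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(
    group = g,
    succulence = .succulence_target(days, g),
    rwc = .rwc_target(days, g, cfg$n_days),
    mda = vapply(days, .mda_target, numeric(1), group = g))
  out
}
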