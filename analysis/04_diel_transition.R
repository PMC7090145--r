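#!/usr/bin/env Rscript
# Summarise the diel gas-exchange traces per day/night phase, detect the
# nocturnal-assimilation onset of CAM, and flag the dawn/dusk anticipation
# transients of the CAM circadian clock.
suppressMessages(library(camphen))
dir.create("results", showWarnings = FALSE)

for (g in c("control", "salt")) {
  raw <- read.csv(sprintf("results/data/diel_%s.csv", g))
  tr <- diel_trace(raw$time_s, raw$assimilation)
  ps <- phase_summaries(tr)
  write.csv(ps, sprintf("results/diel_summaries_%s.csv", g), row.names = FALSE)
  onset <- detect_cam_onset(ps, threshold = -0.1)
  message(g, ": day means ", sprintf("%.1f-%.1f", min(ps$day_mean), max(ps$day_mean)),
          ", night means ", sprintf("%.2f-%.2f", min(ps$night_mean), max(ps$night_mean)),
          " umol m-2 s-1; CAM onset ",
          ifelse(is.na(onset$onset_day), "none", onset$onset_day))
  if (g == "salt" && !is.na(onset$onset_day)) {
    for (d in c(onset$onset_day - 4, onset$onset_day + 1, onset$onset_day + 2)) {
      a <- detect_anticipation(tr, d)
      message(sprintf(
        "  day %d light-on edge: %.2f -> %.2f umol m-2 s-1 (CAM-like: %s)",
        d, a$light_on_pre, a$light_on_post, a$cam_like))
    }
  }
}
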