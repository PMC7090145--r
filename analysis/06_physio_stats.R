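#!/usr/bin/env Rscript
# Physiological indices (RWC, succulence, MDA) from raw samples, with
# per-day control-vs-salt Student's t-tests and star annotation.
suppressMessages(library(camphen))
dir.create("results", showWarnings = FALSE)

samples <- rbind(read.csv("results/data/physio_control.csv"),
                 read.csv("results/data/physio_salt.csv"))
idx <- index_series(samples)
write.csv(idx, "results/physio_indices.csv", row.names = FALSE)

for (ix in unique(idx$index)) {
  val <- switch(ix,
    rwc = rwc(samples$fw_g, samples$dw_g, samples$tw_g),
    succulence = succulence(samples$fw_g, samples$area_cm2),
    mda = mda_per_gram(mda_concentration(samples$od532, samples$od450),
                       tissue_mass = samples$tissue_g))
  cmp <- daily_comparison(data.frame(day = samples$day, group = samples$group,
                                     value = val))
  write.csv(cmp, sprintf("results/comparison_%s.csv", ix), row.names = FALSE)
  starred <- cmp$day[cmp$stars != ""]
  message(ix, ": significant days ",
          if (length(starred)) paste(starred, collapse = ",") else "none")
}
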