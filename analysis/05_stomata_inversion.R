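#!/usr/bin/env Rscript
# Aperture statistics per day and timepoint (4 pm / 4 am) and detection of
# the day/night inversion of stomatal movement under salt.
suppressMessages(library(camphen))
dir.create("results", showWarnings = FALSE)

for (g in c("control", "salt")) {
  tab <- read.csv(sprintf("results/data/stomata_%s.csv", g))
  s <- aperture_stats(tab, open_threshold = 1.4)
  write.csv(s, sprintf("results/stomata_stats_%s.csv", g), row.names = FALSE)
  inv <- detect_inversion(s)
  message(g, ": mean 4pm aperture ",
          sprintf("%.2f", mean(s$mean_um[s$timepoint == "4pm"])),
          " um, mean 4am ", sprintf("%.2f", mean(s$mean_um[s$timepoint == "4am"])),
          " um; inversion ", ifelse(is.na(inv), "none", paste("day", inv)))
}
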