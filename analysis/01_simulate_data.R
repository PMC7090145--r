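#!/usr/bin/env Rscript
# Generate the synthetic study datasets: leaf scenes with known area,
# growth trajectories from the study equations, diel gas-exchange traces,
# stomatal aperture tables, and daily physiology samples for both groups.
suppressMessages(library(camphen))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scene <- render_leaf_scene(c(2.5, 0.7), px_per_cm = 50, seed = 42)
write_leaf_scene(scene, file.path(out, "p1_control_day01.png"))
message("scene: ", scene$truth$green_px, " green px, true area ",
        scene$truth$total_area_cm2, " cm2")

for (g in c("control", "salt")) {
  model <- if (g == "control") study_control_model() else study_salt_model()
  write.csv(simulate_growth(model, -21:14, noise_sd = 1, seed = 42),
            file.path(out, sprintf("growth_%s.csv", g)), row.names = FALSE)

  tr <- simulate_diel_trace(sim_config(seed = 42, group = g))
  write.csv(tr[, c("time_s", "assimilation")],
            file.path(out, sprintf("diel_%s.csv", g)), row.names = FALSE)

  write.csv(simulate_stomata(sim_config(seed = 7, group = g)),
            file.path(out, sprintf("stomata_%s.csv", g)), row.names = FALSE)

  write.csv(simulate_physio(sim_config(seed = match(g, c("control", "salt")),
                                       group = g)),
            file.path(out, sprintf("physio_%s.csv", g)), row.names = FALSE)
}
message("wrote synthetic datasets under ", out)
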