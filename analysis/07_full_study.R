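#!/usr/bin/env Rscript
# End-to-end orchestration: simulate -> measure -> fit -> detect ->
# indices -> compare, emitting a machine-readable study report.
suppressMessages(library(camphen))

report <- run_study(list(seed = 42L), out_dir = "results/study")
print(report)
message("report and stage artifacts under results/study/")
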