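#!/usr/bin/env Rscript
## Stage 1: generate the synthetic study cohort.
##
## 14 subjects, 300 s of quiet standing at 100 Hz, minimal-intervention
## dynamics structured on the CoM-position manifold: slow accumulation
## (tau = 30 s, SD 1.0 deg/dim) within the task-equivalent subspace, fast
## correction (tau = 0.5 s, SD 0.3 deg) along the task-relevant direction.
## Writes one joint-angle CSV per subject, plus a marker TRC file for
## subject 1 as a demonstration of the marker-level pipeline.

suppressPackageStartupMessages(library(swayucm))

seed <- 42L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()   # shipped study conditions
cohort <- simulate_cohort(14, cfg, seed = seed)

for (s in seq_along(cohort)) {
  write_angles_csv(cohort[[s]], file.path(data_dir, sprintf("subject_%02d.csv", s)))
}
write_trc(synthesize_markers(cohort[[1]], cfg$chain),
          file.path(data_dir, "subject_01_markers.trc"))

sds <- t(vapply(cohort, function(s) apply(s$values, 2, sd), numeric(6)))
cat(sprintf("Simulated %d subjects x %d frames (seed %d).\n",
            length(cohort), nrow(cohort[[1]]$values), seed))
cat("Per-joint angle SD across subjects (deg):\n")
print(round(rbind(mean = colMeans(sds), min = apply(sds, 2, min),
                  max = apply(sds, 2, max)), 3))
cat("All joint SDs fall in the 0.1-2 deg range typical of quiet standing:",
    all(sds > 0.1 & sds < 2), "\n")
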