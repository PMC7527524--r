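#!/usr/bin/env Rscript
# Step 2 — measure eyeball translation on the simulated cohort.
#
# Runs the full pipeline per subject: static-tissue co-registration of
# each secondary gaze onto central gaze, globe segmentation by seeded
# region growing, centroid displacement in the gaze plane (axial for
# right/left, sagittal for up/down). One eye per subject is analysed,
# selected by a seeded right/left alternation. Writes displacements.csv,
# cohort tables, QC overlays and the run log under results/run.

suppressPackageStartupMessages(library(oculotrans))

subject_seeds <- c(A = 101, B = 102, C = 103)
axial <- c(A = 14.2, B = 14.8, C = 15.3)
subjects <- lapply(names(subject_seeds), function(id)
  phantom_config(grid_shape = c(96, 96, 48), axial_length = axial[[id]],
                 interpupillary_offset = 13, seed = subject_seeds[[id]]))
names(subjects) <- names(subject_seeds)

cfg <- run_config(subjects, out_dir = "results/run",
                  eye_selection_seed = 20260928, qc = TRUE)
res <- run_all(cfg)

cat("measured", nrow(res$displacements), "gaze displacements;",
    length(res$exclusions), "subjects excluded\n")
cat("\nper-gaze displacement (mm) and direction (deg, signed):\n")
print(res$displacements[, c("subject", "gaze", "side", "movement", "d_mm",
                            "theta_signed_deg", "rotation_deg",
                            "alignment_residual")],
      digits = 3, row.names = FALSE)
cat("\ntruth for every subject: horizontal translation 0.7 mm along the",
    "gaze,\nvertical 0.43 mm opposite; all alignment residuals should pass",
    "the 0.02 gate.\n")
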