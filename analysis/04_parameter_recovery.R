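#!/usr/bin/env Rscript
# Step 4 — parameter-recovery sweep.
#
# How well does the end-to-end pipeline recover a known globe-centre
# translation? Sweeps the true translation magnitude at bench scale
# (noiseless, no head motion, lateral direction) and reports recovered
# distance and direction; also measures the rotation-null floor (pure
# 30 deg rotation, zero translation).

suppressPackageStartupMessages(library(oculotrans))
out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- function(...) phantom_config(
  grid_shape = c(96, 96, 48), axial_length = 15.2,
  interpupillary_offset = 13, noise_sd = 0,
  head_motion = c(rotation = 0, translation = 0), seed = 17, ...)

central <- generate_phantom(base(), gazes = "central")$volumes$central
seed <- seed_spec()
masks <- lapply(c(left = "left", right = "right"),
                function(s) segment_globe(central, seed, side = s))
static <- build_static_mask(central, masks, 3)

rows <- list()
for (m in c(0, 0.3, 0.5, 0.7, 1.0)) {
  cfg <- base(true_translation = list(right = c(-m, 0, 0), left = c(m, 0, 0),
                                      up = c(0, 0, -0.43), down = c(0, 0, 0.43)))
  sec <- generate_phantom(cfg, gazes = "right")$volumes$right
  disp <- end_to_end_displacement(central, sec, side = "left", seed = seed,
                                  primary_masks = masks, static_mask = static)
  rows[[length(rows) + 1]] <- data.frame(
    true_mm = m, recovered_mm = disp$d,
    error_mm = disp$d - m,
    theta_deg = ifelse(disp$theta_undefined, NA, disp$theta))
  cat(sprintf("true %.1f mm -> recovered %.3f mm (theta %s)\n", m, disp$d,
              ifelse(disp$theta_undefined, "undefined",
                     sprintf("%.1f deg", disp$theta))))
}
sweep <- do.call(rbind, rows)
write.csv(sweep, file.path(out, "translation_recovery.csv"), row.names = FALSE)
cat(sprintf("\nmax |error| over the sweep: %.3f mm (m = 0 row is the",
            max(abs(sweep$error_mm))), "\n")
cat("discretisation + registration noise floor; truth direction is 0 deg\n")
cat("(medial movement of the left eye) for every nonzero magnitude.\n")
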