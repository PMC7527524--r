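# Shared phantom configurations and a per-session cache so slow phantom
# renders are reused across tests in one run.

# bench-scale grid: full voxel spacing, reduced extent; the globe is scaled
# down (axial length 15.2 mm) so it fits with the required 5 mm margin
desk_config <- function(...) {
  defaults <- list(grid_shape = c(96, 96, 48), axial_length = 15.2,
                   interpupillary_offset = 13)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# smallest workable grid for orchestration tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(72, 72, 44), axial_length = 13,
                   interpupillary_offset = 11,
                   true_translation = list(right = c(-0.7, 0, 0),
                                           left = c(0.7, 0, 0),
                                           up = c(0, 0, -0.3),
                                           down = c(0, 0, 0.3)))
  do.call(phantom_config, utils::modifyList(defaults, args))
}

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, maker) {
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- maker()
  .phantom_cache[[key]]
}

# noiseless, no head motion, default gaze geometry; central + right
clean_phantom_cr <- function() {
  cached_phantom("clean_cr", function() {
    cfg <- desk_config(noise_sd = 0, head_motion = c(rotation = 0, translation = 0),
                       seed = 3)
    generate_phantom(cfg, gazes = c("central", "right"))
  })
}

expect_angle_equal <- function(a, b, tol) {
  diff <- abs(wrap_angle(a - b, "signed"))
  expect_lte(diff, tol)
}
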