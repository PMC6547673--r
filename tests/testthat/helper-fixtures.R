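# Small fixture builders shared across test files.

# track with prescribed per-interval downstream speeds (um/s) at 1 fps
track_from_speeds <- function(speeds, diameter_um = 85, track_id = 1L,
                              y = 0) {
  data.frame(frame = seq_len(length(speeds) + 1) - 1L,
             track_id = track_id,
             x_um = cumsum(c(0, speeds)),
             y_um = y, diameter_um = diameter_um)
}

default_flow_005 <- function() flow_context(shear_dyn_cm2 = 0.05)

# tiny field for fast rendering tests
small_field_flow <- function(shear = 0.05) {
  flow_context(channel_geometry(fov_x_um = 900, fov_y_um = 700),
               fluid_properties(), shear_dyn_cm2 = shear)
}
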