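# Fixtures built in code: tiny traces, configs and CSV files.

# A short bout config so pipeline-level tests stay fast.
short_bout_config <- function(...) {
  bout_model_config(duration_range_min = c(3, 10), ...)
}

# Write a small accelerometer CSV and return its path.
write_tiny_accel <- function(x, y, z, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny_accel.csv")
  utils::write.csv(data.frame(t_s = seq_along(x) - 1, x_g = x, y_g = y, z_g = z),
                   path, row.names = FALSE)
  path
}

# One well-formed deployment row as a data frame.
tiny_deployment <- function(event_id = "ev001", duration = 60, sst = 27,
                            tl = 200, lactate = 1.2) {
  data.frame(event_id = event_id, species = "nurse", tl_cm = tl, sst_c = sst,
             capture_duration_min = duration, ph37 = 7.4, lactate = lactate,
             glucose = 15, haematocrit = 18, sodium = 250, potassium = 5.5,
             chloride = 240, calcium = 4.8)
}

# Build a vs_trace directly from a numeric signal.
as_vs_trace <- function(vs) {
  out <- data.frame(event_id = "sig", t_s = seq_along(vs) - 1, vs_g = vs)
  class(out) <- c("vs_trace", "data.frame")
  out
}
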