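# Shared in-code fixtures; everything is generated, nothing read from disk.

# straight track along +x at constant speed (um/s), dt seconds per frame
make_ballistic_ensemble <- function(v = 1, dt = 1, n = 10,
                                    cal = calibration(frame_interval = dt)) {
  tr <- trajectory("b1", frame = 0:(n - 1), x = v * dt * (0:(n - 1)),
                   y = rep(0, n), frame_interval = dt)
  trajectory_ensemble(list(tr), cal)
}

make_stationary_ensemble <- function(n = 10, dt = 1) {
  tr <- trajectory("s1", frame = 0:(n - 1), x = rep(2, n), y = rep(3, n),
                   frame_interval = dt)
  trajectory_ensemble(list(tr), calibration(frame_interval = dt))
}

# msd_curve built directly from a known law msd(tau)
make_msd_curve <- function(lags, msd) {
  out <- data.frame(lag = lags, msd = msd, n_pairs = rep(1L, length(lags)))
  class(out) <- c("msd_curve", "data.frame")
  out
}

# tracker-XML text fixture: list of matrices with columns t, x, y
write_xml_fixture <- function(particles, path) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<Tracks nTracks=\"%d\">", length(particles)))
  for (p in particles) {
    lines <- c(lines, sprintf("  <particle nSpots=\"%d\">", nrow(p)))
    for (i in seq_len(nrow(p)))
      lines <- c(lines, sprintf(
        "    <detection t=\"%d\" x=\"%g\" y=\"%g\"/>", p[i, 1], p[i, 2], p[i, 3]))
    lines <- c(lines, "  </particle>")
  }
  writeLines(c(lines, "</Tracks>"), path)
  path
}
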