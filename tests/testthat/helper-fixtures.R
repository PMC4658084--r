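# Small in-code fixtures shared across test files.

scale8 <- colour_scale(8)

# frame with uniform scales: mpr = mpc = cell metres (depth range forces mpr)
toy_frame <- function(px, cell_m = 1, n_colours = 8L, mpc = cell_m) {
  echogram_frame(px, 0, nrow(px) * cell_m, colour_scale(n_colours),
                 metres_per_col = mpc)
}

# single-pixel-set candidate helper on a toy frame
toy_candidate <- function(rows, cols, frame) {
  echofish:::candidate_geometry(rows, cols, frame)
}

# a small deterministic survey used by several files (kept modest for speed)
small_survey <- function(seed = 11, ...) {
  spec <- survey_spec(seed = seed, n_frames = 5L, n_schools = 4L, ...)
  list(spec = spec, sv = generate_survey(spec))
}
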