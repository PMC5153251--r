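# Shared fixtures, built in code.

# Reference RI table mimicking a hydrocarbon RI database: methyl branches
# depress the index of a same-carbon-count alkane by roughly 60 units each
# on an apolar phase. Used where tests need curves consistent with the
# packaged compound table (e.g. C30 monomethyl ~ 2940).
make_ri_reference <- function(carbons = 20:40, branches = 0:5,
                              per_branch = -60) {
  ref <- expand.grid(carbons = carbons, branches = branches)
  ref$ri <- 100 * ref$carbons + per_branch * ref$branches
  ref
}

# Evenly spaced synthetic ladder covering the packaged table's span.
make_uniform_ladder <- function(carbons = 8:40, rt_start = 5, spacing = 1.2) {
  alkane_ladder(carbons, rt_start + spacing * (carbons - carbons[1]))
}

# A clean multi-Gaussian trace with known apex positions/heights.
make_gaussian_trace <- function(apex_rt, height, window = c(36, 51),
                                peak_sd = 0.02, dt = 0.01) {
  rt <- seq(window[1], window[2], by = dt)
  y <- numeric(length(rt))
  for (i in seq_along(apex_rt)) {
    y <- y + height[i] * exp(-(rt - apex_rt[i])^2 / (2 * peak_sd^2))
  }
  chromatogram(rt, y, sample_id = "synthetic")
}
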