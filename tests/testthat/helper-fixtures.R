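# Shared fixtures: the reference design at 488 nm and small helpers used
# across the suite. Everything is built in code; no files are read.

ref_setup <- function() optical_setup(488e-9)

# printed reference optimum of the two-Bessel design
ref_spec <- function() {
  superposition_spec(0.525, 2.95e4, 0.475, 5.17e4, ref_setup())
}

# brute-force local-maximum search on a sampled profile: independent oracle
# for sidelobe detection (no derivative logic shared with the implementation)
brute_force_maxima <- function(r, v) {
  idx <- which(v > c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf))
  idx <- idx[idx > 1 & idx < length(v)]
  list(radius = r[idx], value = v[idx])
}

# circular phase distance (radians)
phase_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
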