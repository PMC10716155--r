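# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# Mid-size LNP recording: enough spikes (~30k) for parameter-recovery checks.
lnp_fixture <- function() {
  fixture("lnp", function() {
    clip <- generate_checkerboard(80000, 8, 8, square_size_um = 75,
                                  refresh_ms = 33, seed = 42)
    params <- rgc_cell_params(center_um = c(290, 310), angle_rad = 0.6)
    spikes <- simulate_spike_train(params, clip, seed = 7)
    sta <- factorize_rank_one(compute_sta(spikes, clip, depth_frames = 12))
    list(clip = clip, params = params, spikes = spikes, sta = sta)
  })
}

# Repeat-protocol recording: 10-s clip (20-ms refresh -> exactly 2000 5-ms
# bins) repeated 100x, for one Poisson and one overdispersed cell.
repeat_fixture <- function() {
  fixture("repeat", function() {
    base <- generate_checkerboard(520, 12, 12, square_size_um = 75,
                                  refresh_ms = 20, seed = 11)
    rep_clip <- make_repeat_clip(base, 10, 100)
    p1 <- rgc_cell_params(center_um = c(450, 450), dispersion_phi = 1)
    p25 <- rgc_cell_params(center_um = c(450, 450), dispersion_phi = 2.5)
    list(rep_clip = rep_clip,
         p1 = p1, p25 = p25,
         st1 = simulate_spike_train(p1, rep_clip, seed = 3),
         st25 = simulate_spike_train(p25, rep_clip, seed = 3))
  })
}

# A clean biphasic temporal filter sampled at frame-bin centers.
sampled_kernel <- function(params, refresh_ms, depth) {
  t_ms <- (seq_len(depth) - 0.5) * refresh_ms
  temporal_kernel(t_ms, params)
}

# Noise-free elliptical Gaussian map sampled at checker centers.
gaussian_map <- function(n_rows, n_cols, square_um, center_um, sigma_um,
                        angle_rad = 0, amplitude = 1) {
  xs <- (seq_len(n_cols) - 0.5) * square_um
  ys <- (seq_len(n_rows) - 0.5) * square_um
  m <- matrix(0, n_rows, n_cols)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    dx <- xs[c] - center_um[1]; dy <- ys[r] - center_um[2]
    u <- cos(angle_rad) * dx + sin(angle_rad) * dy
    v <- -sin(angle_rad) * dx + cos(angle_rad) * dy
    m[r, c] <- amplitude *
      exp(-0.5 * ((u / sigma_um[1])^2 + (v / sigma_um[2])^2))
  }
  m
}
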