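test_that("STA of a single spike equals the preceding stimulus window", {
  clip <- generate_checkerboard(60, 3, 3, 75, 33, seed = 4)
  depth <- 10
  spike_frame <- 40
  t_spike <- (spike_frame - 0.5) * 0.033
  st <- spike_train(t_spike, duration_s = clip_duration_s(clip))
  sta <- compute_sta(st, clip, depth)
  for (lag in 0:(depth - 1))
    expect_equal(sta$kernel[lag + 1, , ], clip$frames[spike_frame - lag, , ])
})

test_that("stimulus-independent spikes give a vanishing STA", {
  clip <- generate_checkerboard(20000, 4, 4, 75, 33, seed = 4)
  n_spk <- 4000
  set.seed(6)
  times <- sort(runif(n_spk, 15 * 0.033, clip_duration_s(clip)))
  st <- spike_train(times, duration_s = clip_duration_s(clip))
  sta <- compute_sta(st, clip, 10)
  expect_true(all(abs(sta$kernel_mat) < 4 / sqrt(sta$n_spikes)))
})

test_that("spikes in the first depth_frames are excluded", {
  clip <- generate_checkerboard(50, 2, 2, 75, 33, seed = 1)
  early <- spike_train(c(0.01, 0.05), duration_s = clip_duration_s(clip))
  expect_error(compute_sta(early, clip, 10), "no usable spikes")
})

test_that("rank-one factorization is exact for separable kernels", {
  p <- rgc_cell_params()
  tf <- sampled_kernel(p, 33, 12)
  sp <- as.vector(gaussian_map(4, 4, 75, c(150, 150), c(60, 45)))
  sta <- structure(list(kernel_mat = outer(tf, sp), depth_frames = 12,
                        n_rows = 4, n_cols = 4, refresh_ms = 33,
                        square_size_um = 75, n_spikes = 1000),
                   class = "sta_fit")
  out <- factorize_rank_one(sta)
  expect_equal(out$variance_fraction_rank1, 1, tolerance = 1e-12)
  expect_true(out$is_separable)
  expect_equal(sum(out$temporal_filter^2), 1, tolerance = 1e-12)
  # reconstruction identity: residual energy equals discarded singular values
  sv <- svd(out$kernel_mat)
  recon <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
  expect_equal(sum((out$kernel_mat - recon)^2), sum(sv$d[-1]^2),
               tolerance = 1e-12)
  expect_error(factorize_rank_one(structure(
    list(kernel_mat = matrix(0, 3, 4)), class = "sta_fit")), "all-zero")
})

test_that("two-component kernels report their exact energy split", {
  p <- rgc_cell_params()
  t1 <- sampled_kernel(p, 33, 12); t1 <- t1 / sqrt(sum(t1^2))
  t2raw <- exp(-(1:12) / 4)
  t2 <- t2raw - t1 * sum(t1 * t2raw); t2 <- t2 / sqrt(sum(t2^2))
  s1 <- rep(0, 16); s1[6] <- 1
  s2 <- rep(0, 16); s2[11] <- 1
  for (eps in c(0.55, 0.599, 0.60, 0.601, 0.8)) {
    k <- sqrt(eps) * outer(t1, s1) + sqrt(1 - eps) * outer(t2, s2)
    sta <- structure(list(kernel_mat = k, depth_frames = 12, n_rows = 4,
                          n_cols = 4, refresh_ms = 33, square_size_um = 75,
                          n_spikes = 1000), class = "sta_fit")
    out <- factorize_rank_one(sta)
    expect_equal(out$variance_fraction_rank1, eps, tolerance = 1e-9)
    expect_identical(out$is_separable, eps >= 0.60)
  }
})

test_that("biphasic screen accepts opposite-sign lobes and rejects decays", {
  p <- rgc_cell_params()
  tf <- sampled_kernel(p, 33, 12)
  expect_true(is_biphasic(tf))
  expect_true(is_biphasic(-tf))            # polarity invariance
  expect_false(is_biphasic(exp(-(1:12) / 3)))  # monophasic decay
  weak <- c(1, 0.5, 0.2, -0.01, -0.02, -0.01)  # secondary lobe below 5%
  expect_false(is_biphasic(weak))
  expect_false(is_biphasic(rep(0, 10)))
})

test_that("time-to-zero interpolates the crossing and is scale invariant", {
  p <- rgc_cell_params()
  t0 <- true_time_to_zero_ms(p)
  for (refresh in c(33, 16.5, 8)) {
    tf <- sampled_kernel(p, refresh, ceiling(400 / refresh))
    tm <- time_to_zero(tf, refresh)
    expect_lt(abs(tm$time_to_zero_ms - t0), refresh)
  }
  tf <- sampled_kernel(p, 33, 12)
  expect_equal(time_to_zero(5 * tf, 33)$time_to_zero_ms,
               time_to_zero(tf, 33)$time_to_zero_ms)
  # a sampled exact zero between the lobes returns that sample's lag time
  tfz <- c(0.2, 1, 0.5, 0, -0.4, -0.2)
  expect_equal(time_to_zero(tfz, 33)$time_to_zero_ms, (4 - 0.5) * 33)
  expect_error(time_to_zero(exp(-(1:10)), 33), "zero crossing")
})

test_that("simulated LNP cells are recovered by the STA chain", {
  fx <- lnp_fixture()
  expect_gt(fx$sta$n_spikes, 20000)
  ktrue <- rgcfidelity:::temporal_weights(fx$params, 33, 12)
  cosine <- abs(sum(fx$sta$temporal_filter * ktrue))
  expect_gt(cosine, 0.95)
  expect_true(fx$sta$is_separable)
  expect_identical(fx$sta$polarity, "ON")
  rf <- fit_spatial_gaussian(fx$sta$spatial_map, 75)
  expect_true(rf$ok)
  err <- sqrt(sum((rf$center_um - fx$params$center_um)^2))
  expect_lt(err, 75 / 2)
})
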