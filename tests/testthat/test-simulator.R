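test_that("temporal kernel zero crossing matches the closed form", {
  p <- rgc_cell_params()
  t0 <- true_time_to_zero_ms(p)
  # independent oracle: root-find the sign change of the kernel itself
  root <- uniroot(function(t) temporal_kernel(t, p),
                  lower = p$tau_fast_ms * p$cascade_shape, upper = 400,
                  tol = 1e-10)$root
  expect_equal(t0, root, tolerance = 1e-6)
  # biphasic by construction: opposite-sign lobes around t0
  expect_gt(temporal_kernel(t0 - 20, p), 0)
  expect_lt(temporal_kernel(t0 + 40, p), 0)
})

test_that("constant-rate cell is homogeneous Poisson", {
  clip <- generate_checkerboard(3000, 4, 4, 75, 33, seed = 1)
  p <- rgc_cell_params(center_um = c(150, 150), slope_spk_s = 0,
                       baseline_rate_spk_s = 20)
  st <- simulate_spike_train(p, clip, seed = 2)
  cT <- 20 * clip_duration_s(clip)
  expect_lt(abs(length(st$spike_times_s) - cT), 4 * sqrt(cT))
  expect_true(all(diff(st$spike_times_s) >= 0))
  expect_true(all(st$spike_times_s >= 0 &
                    st$spike_times_s <= st$duration_s))
})

test_that("simulation is seed-deterministic and clip-length guarded", {
  clip <- generate_checkerboard(500, 4, 4, 75, 33, seed = 1)
  p <- rgc_cell_params(center_um = c(150, 150))
  a <- simulate_spike_train(p, clip, seed = 5)
  b <- simulate_spike_train(p, clip, seed = 5)
  expect_identical(a$spike_times_s, b$spike_times_s)
  short <- generate_checkerboard(5, 4, 4, 75, 33, seed = 1)
  expect_error(simulate_spike_train(p, short, seed = 1), "shorter")
})

test_that("dispersion control delivers the configured variance/mean ratio", {
  fx <- repeat_fixture()
  r1 <- variance_mean(count_matrix(fx$st1, fx$rep_clip, 5), 5)$ratio
  r25 <- variance_mean(count_matrix(fx$st25, fx$rep_clip, 5), 5)$ratio
  expect_gt(r1, 0.9); expect_lt(r1, 1.1)
  expect_lt(abs(r25 - 2.5) / 2.5, 0.10)
  # law-of-total-variance oracle: with multiplier variance v the expected
  # ratio at the reference bin is 1 + v * sum(mu_b^2) / sum(mu_b)
  tr <- rgcfidelity:::cell_rate_trace(fx$p25, fx$rep_clip)
  mu <- tr$rate_spk_s * fx$rep_clip$refresh_ms / 1000
  n_sub <- fx$rep_clip$refresh_ms / 5
  v <- (2.5 - 1) * n_sub * sum(mu) / sum(mu^2)
  mu_b <- rep(mu / n_sub, each = n_sub)
  expect_equal(1 + v * sum(mu_b^2) / sum(mu_b), 2.5, tolerance = 1e-12)
})

test_that("refractory period suppresses short interspike intervals", {
  clip <- generate_checkerboard(2000, 4, 4, 75, 33, seed = 1)
  p <- rgc_cell_params(center_um = c(150, 150), baseline_rate_spk_s = 40,
                       slope_spk_s = 0, refractory_ms = 3)
  st <- simulate_spike_train(p, clip, seed = 9)
  expect_true(all(diff(st$spike_times_s) >= 0.003 - 1e-12))
})

test_that("population presets impose matched deterministic scalings", {
  clip <- generate_checkerboard(600, 12, 12, 75, 33, seed = 3)
  pr <- condition_presets(c("WT", "late"))
  pop <- simulate_population(pr, 4, clip, seed = 21, n_retinas = 2)
  tr <- pop$truth
  expect_identical(nrow(tr), 8L)
  wt <- tr[tr$condition == "WT", ]
  expect_true(all(wt$phi == 1))
  expect_identical(length(unique(wt$retina_id)), 2L)
  late <- tr[tr$condition == "late", ]
  # matched archetype draws: every late cell's max rate below its WT partner
  expect_true(all(late$max_rate_spk_s < wt$max_rate_spk_s))
  expect_true(all(c("sex", "cell_type", "age_months") %in% names(tr)))
  expect_error(simulate_population(pr[0, ], 4, clip), "empty")
})

test_that("spike-table export and import round-trip a population", {
  clip <- generate_checkerboard(600, 8, 8, 75, 33, seed = 3)
  pop <- simulate_population(condition_presets("WT"), 2, clip, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_spike_table(pop, path)
  back <- read_spike_table(path)
  expect_identical(sort(names(back)), sort(names(pop$spike_trains)))
  id <- names(back)[1]
  expect_equal(back[[id]]$spike_times_s, pop$spike_trains[[id]]$spike_times_s)
  expect_equal(back[[id]]$metadata$condition, "WT")
  unlink(path)
})
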