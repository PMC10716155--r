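test_that("count matrices conserve spikes and have the protocol shape", {
  fx <- repeat_fixture()
  cm <- count_matrix(fx$st1, fx$rep_clip, 5)
  # 10-s clip, 100 repeats, 5-ms bins
  expect_identical(dim(cm), c(100L, 2000L))
  expect_identical(sum(cm), length(fx$st1$spike_times_s))
  empty <- spike_train(numeric(0), duration_s = 1000)
  expect_true(all(count_matrix(empty, fx$rep_clip, 5) == 0))
  expect_error(count_matrix(fx$st1, fx$rep_clip, 0), "bin_ms")
})

test_that("variance/mean statistics follow Poisson and overdispersed truth", {
  fx <- repeat_fixture()
  cm <- count_matrix(fx$st1, fx$rep_clip, 5)
  ns <- variance_mean(cm, 5)
  expect_gt(ns$ratio, 0.9); expect_lt(ns$ratio, 1.1)
  ns25 <- variance_mean(count_matrix(fx$st25, fx$rep_clip, 5), 5)
  expect_lt(abs(ns25$ratio - 2.5) / 2.5, 0.10)
  # deterministic repeats have zero variance
  det <- matrix(rep(c(0L, 2L, 1L, 0L), each = 10), nrow = 10)
  nd <- variance_mean(det, 5)
  expect_equal(nd$variance_count, 0)
  expect_equal(nd$ratio, 0)
  expect_error(variance_mean(det[1, , drop = FALSE]), "repeats")
  # an empty train has an undefined ratio
  ne <- variance_mean(matrix(0L, 5, 20), 5)
  expect_false(ne$defined)
  expect_true(is.na(ne$ratio))
})

test_that("the Ma bound obeys its exact identities and never exceeds H", {
  expect_equal(ma_bound(rep(1 / 8, 8)), 3)           # uniform: equals H
  expect_equal(ma_bound(1), 0)                       # degenerate
  expect_equal(ma_bound(c(0.5, 0.25, 0.25)), -log2(0.375), tolerance = 1e-12)
  expect_error(ma_bound(numeric(0)), "empty")
  set.seed(3)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    expect_lte(ma_bound(p), rgcfidelity:::entropy_bits(p) + 1e-12)
  }
})

test_that("direct information reproduces hand-enumerated word entropies", {
  # two word-aligned slices over binary 2-bin words, 4 repeats:
  # slice 1 deterministic {1.0}; slice 2 split {0.5, 0.5}
  counts <- rbind(c(0L, 0L, 0L, 1L),
                  c(0L, 0L, 0L, 1L),
                  c(0L, 0L, 1L, 0L),
                  c(0L, 0L, 1L, 0L))
  ir <- direct_info(counts, bin_ms = 5, word_bins = 2)
  expect_equal(ir$noise_entropy_bits_per_word, 0.5, tolerance = 1e-12)
  expect_equal(ir$total_entropy_bits_per_word,
               -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(ir$info_bits_per_s, (1.5 - 0.5) / 0.010, tolerance = 1e-9)
  # Ma bound of the pooled words {1/2, 1/4, 1/4}
  expect_equal(ir$ma_bound_bits_per_word, -log2(0.375), tolerance = 1e-12)
})

test_that("deterministic responses have zero noise entropy", {
  fx <- repeat_fixture()
  one <- count_matrix(fx$st1, fx$rep_clip, 5)[1, ]
  det <- matrix(rep(one, each = 50), nrow = 50)
  ir <- direct_info(det, 5, 4)
  expect_equal(ir$noise_entropy_bits_per_word, 0)
  expect_equal(ir$info_bits_per_s,
               ir$total_entropy_bits_per_word / (4 * 5 / 1000))
})

test_that("shuffled responses carry no information beyond plug-in bias", {
  fx <- repeat_fixture()
  cm <- count_matrix(fx$st1, fx$rep_clip, 5)
  set.seed(8)
  shuf <- matrix(sample(as.vector(cm)), nrow(cm), ncol(cm))
  ir <- direct_info(shuf, 5, 4)
  bias_bound <- (ir$n_words - 1) / (2 * ir$n_repeats * log(2))
  expect_lte(ir$info_bits_per_word, bias_bound)
  expect_gte(ir$info_bits_per_word, 0)
})

test_that("coarser bins never increase entropy rate on the same train", {
  fx <- repeat_fixture()
  h_rate <- sapply(c(4, 6), function(b) {
    ir <- direct_info(count_matrix(fx$st1, fx$rep_clip, b), b, 4)
    ir$total_entropy_bits_per_word / (4 * b / 1000)
  })
  expect_gte(h_rate[1], h_rate[2])
})

test_that("word-parameter selection follows the Ma-proximity rule", {
  fx <- repeat_fixture()
  single <- select_word_params(fx$st1, fx$rep_clip, bin_grid_ms = 5,
                               word_grid = 4)
  expect_equal(single$bin_ms, 5)
  expect_equal(single$word_bins, 4)
  full <- select_word_params(fx$st1, fx$rep_clip)
  expect_identical(nrow(full$diagnostics), 12L)
  gap <- abs(full$diagnostics$ma_gap)
  chosen <- full$diagnostics$bin_ms == full$bin_ms &
    full$diagnostics$word_bins == full$word_bins
  expect_equal(min(gap), gap[chosen], tolerance = 1e-12)
  expect_error(select_word_params(fx$st1, fx$rep_clip, numeric(0)), "grid")
})

test_that("top-informative selection is deterministic under ties", {
  rates <- c(rep(5, 50), rep(7, 50))
  ids <- sprintf("c%03d", 1:100)
  sel <- top_informative(rates, ids, 0.10)
  expect_identical(length(sel), 10L)
  expect_true(all(sel > 50))          # the 10 largest come from the 7s
  expect_identical(sel, 51:60)        # ties broken by id
  expect_identical(length(top_informative(rates, ids, 1)), 100L)
  expect_error(top_informative(rates, ids, 0), "fraction")
})

test_that("autocorrelograms are flat for Poisson and gapped when refractory", {
  set.seed(5)
  lambda <- 30; T_s <- 400
  pois <- spike_train(sort(runif(rpois(1, lambda * T_s), 0, T_s)), T_s)
  ac <- autocorrelogram(pois, window_ms = 40, bin_ms = 2)
  expect_equal(mean(ac$rate_spk_s), lambda, tolerance = 0.1 * lambda)
  expect_lt(diff(range(ac$rate_spk_s)) / lambda, 0.5)
  # symmetry and time-reversal invariance
  expect_identical(ac$rate_spk_s, rev(ac$rate_spk_s))
  revd <- spike_train(T_s - rev(pois$spike_times_s), T_s)
  expect_equal(autocorrelogram(revd, 40, 2)$rate_spk_s, ac$rate_spk_s)
  # absolute refractory period empties the short-lag bins
  clip <- generate_checkerboard(4000, 4, 4, 75, 33, seed = 2)
  p <- rgc_cell_params(center_um = c(150, 150), baseline_rate_spk_s = 50,
                       slope_spk_s = 0, refractory_ms = 4)
  stref <- simulate_spike_train(p, clip, seed = 3)
  acr <- autocorrelogram(stref, 20, 1)
  expect_true(all(acr$rate_spk_s[abs(acr$lags_ms) < 4] == 0))
  expect_error(autocorrelogram(spike_train(1, 10), 50, 1), "2 spikes")
})

test_that("cell-type clustering separates archetypes order-invariantly", {
  set.seed(9)
  f1 <- cbind(rnorm(20, 0), rnorm(20, 0))
  f2 <- cbind(rnorm(20, 8), rnorm(20, 8))
  feats <- rbind(f1, f2)
  ids <- sprintf("c%02d", 1:40)
  cl <- cluster_cell_types(feats, 2, ids, seed = 4)
  truth <- rep(1:2, each = 20)
  agreement <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agreement, 1)
  expect_gt(cl$silhouette, 0.5)
  perm <- sample(40)
  cl2 <- cluster_cell_types(feats[perm, ], 2, ids[perm], seed = 4)
  expect_identical(cl2$labels, cl$labels[perm])
  expect_identical(unique(cluster_cell_types(feats, 1, ids)$labels), 1L)
  expect_error(cluster_cell_types(feats, 0, ids), "k must")
})
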