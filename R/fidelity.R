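#' Spike-count matrix over stimulus repeats
#'
#' Bins a spike train recorded during a repeated clip into a repeat x bin
#' count matrix: repeat r covers [(r-1) * T, r * T) where T is the duration
#' of one presentation; bins tile each presentation at \code{bin_ms},
#' dropping a trailing partial bin.
#'
#' @param spikes a \code{spike_train} covering n_repeats presentations.
#' @param repeat_clip the \code{stimulus_clip} with \code{n_repeats > 1}
#'   (or any clip; \code{n_repeats} is taken from it).
#' @param bin_ms temporal bin, milliseconds (> 0); 5 ms is the convention
#'   for variance/mean analysis.
#' @return integer matrix, n_repeats x n_bins.
#' @export
count_matrix <- function(spikes, repeat_clip, bin_ms = 5) {
  if (bin_ms <= 0) stop("bin_ms must be > 0")
  T_s <- clip_duration_s(repeat_clip)
  n_rep <- repeat_clip$n_repeats
  n_bins <- floor(T_s * 1000 / bin_ms)
  t <- spikes$spike_times_s
  t <- t[t >= 0 & t < n_rep * T_s]
  rep_idx <- floor(t / T_s) + 1L
  within <- t - (rep_idx - 1L) * T_s
  bin_idx <- floor(within * 1000 / bin_ms) + 1L
  keep <- bin_idx <= n_bins
  m <- matrix(0L, n_rep, n_bins)
  if (any(keep)) {
    tab <- table(factor(rep_idx[keep], levels = seq_len(n_rep)),
                 factor(bin_idx[keep], levels = seq_len(n_bins)))
    m <- matrix(as.integer(tab), n_rep, n_bins)
  }
  m
}

#' Across-repeat spike-count variance vs mean (signal-dependent noise)
#'
#' For each time bin, computes the across-repeat mean count and unbiased
#' variance; summarizes a cell by the ratio of the bin-averaged variance to
#' the bin-averaged mean.  For a conditionally Poisson cell the ratio is 1;
#' values above 1 indicate signal-dependent noise in excess of Poisson.
#'
#' @param counts repeat x bin matrix from \code{\link{count_matrix}}.
#' @param bin_ms bin size used (metadata).
#' @return A \code{noise_stats}: list with \code{mean_count},
#'   \code{variance_count} (bin averages), \code{ratio}, per-bin vectors
#'   \code{bin_means} and \code{bin_vars} (for variance-vs-mean scatters),
#'   \code{mean_rate_spk_s}, \code{n_repeats}, \code{bin_ms} and
#'   \code{defined} (FALSE for an empty train).
#' @export
variance_mean <- function(counts, bin_ms = 5) {
  if (nrow(counts) < 2) stop("need at least 2 repeats")
  bin_means <- colMeans(counts)
  bin_vars <- apply(counts, 2, stats::var)
  mean_count <- mean(bin_means)
  variance_count <- mean(bin_vars)
  defined <- mean_count > 0
  structure(list(mean_count = mean_count,
                 variance_count = variance_count,
                 ratio = if (defined) variance_count / mean_count else NA_real_,
                 bin_means = bin_means, bin_vars = bin_vars,
                 mean_rate_spk_s = mean_count / (bin_ms / 1000),
                 n_repeats = nrow(counts), bin_ms = bin_ms,
                 defined = defined),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf(
    "Noise stats (%g-ms bins, %d repeats): mean rate %.2f spk/s, variance/mean %.3f\n",
    x$bin_ms, x$n_repeats, x$mean_rate_spk_s,
    if (x$defined) x$ratio else NA))
  invisible(x)
}

# Tokenize a count matrix into word ids: words are word_bins consecutive
# non-overlapping bins, counts clipped at clip_level, base-(clip+1) encoded.
# Returns a repeat x slice integer matrix of word ids.
word_matrix <- function(counts, word_bins, clip_level = 1) {
  n_slices <- floor(ncol(counts) / word_bins)
  if (n_slices < 1) stop("fewer bins than one word")
  cl <- pmin(counts, clip_level)
  base <- clip_level + 1
  w <- matrix(0L, nrow(counts), n_slices)
  for (j in seq_len(word_bins)) {
    cols <- (seq_len(n_slices) - 1) * word_bins + j
    w <- w * base + cl[, cols, drop = FALSE]
  }
  w
}

#' Coincidence-based (Ma) entropy bound
#'
#' Returns -log2(sum(p^2)), the Renyi-2 (collision) entropy of a word
#' distribution.  It never exceeds the Shannon entropy, with equality for
#' uniform distributions; in the direct-method workflow it vets whether a
#' word-parameter choice is adequately sampled.  (The neural-coding
#' literature calls this quantity the "Ma Upper Bound" — an upper bound on
#' the entropy consistent with the observed coincidence rate — though as an
#' estimator it lower-bounds the Shannon entropy of the true distribution.)
#'
#' @param p probability vector (sums to 1) or a table of word counts.
#' @return bound in bits.
#' @export
ma_bound <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty distribution")
  if (any(p < 0)) stop("negative probabilities")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) p <- p / s      # accept raw counts
  -log2(sum(p^2))
}

#' Direct-method mutual information from repeated responses
#'
#' Estimates the information a spike train carries about a repeated
#' stimulus as I = H(R) - H(R|S): spike counts are clipped to a small
#' alphabet (binary by default) and grouped into words of
#' \code{word_bins} consecutive bins; H(R) is the plug-in entropy of the
#' word distribution pooled over all word-aligned slices and repeats, and
#' H(R|S) is the mean over slices of the plug-in entropy of words across
#' repeats at that slice (the repeated stimulus plays the role of S).  The
#' rate is (H(R) - H(R|S)) / word duration.
#'
#' @param counts repeat x bin matrix from \code{\link{count_matrix}}.
#' @param bin_ms bin size in ms.
#' @param word_bins bins per word (patterns of 3-6 bins are conventional).
#' @param clip_level per-bin count ceiling defining the word alphabet
#'   (default 1: binary words).
#' @return An \code{info_result}: list with \code{total_entropy_bits_per_word},
#'   \code{noise_entropy_bits_per_word}, \code{info_bits_per_s},
#'   \code{info_bits_per_word}, \code{ma_bound_bits_per_word} (pooled
#'   distribution), \code{noise_ma_bound_bits_per_word} (slice average),
#'   \code{bin_ms}, \code{word_bins}, \code{clip_level}, \code{n_words},
#'   \code{n_repeats}, \code{n_slices}.
#' @export
direct_info <- function(counts, bin_ms, word_bins, clip_level = 1) {
  if (nrow(counts) < 2) stop("need at least 2 repeats")
  w <- word_matrix(counts, word_bins, clip_level)
  n_rep <- nrow(w); n_slices <- ncol(w)
  pooled <- table(as.vector(w))
  p_pool <- as.numeric(pooled) / length(w)
  H_total <- entropy_bits(p_pool)
  H_noise_slices <- numeric(n_slices)
  ma_noise_slices <- numeric(n_slices)
  for (s in seq_len(n_slices)) {
    ps <- as.numeric(table(w[, s])) / n_rep
    H_noise_slices[s] <- entropy_bits(ps)
    ma_noise_slices[s] <- ma_bound(ps)
  }
  H_noise <- mean(H_noise_slices)
  word_dur_s <- word_bins * bin_ms / 1000
  I_word <- H_total - H_noise
  structure(list(total_entropy_bits_per_word = H_total,
                 noise_entropy_bits_per_word = H_noise,
                 info_bits_per_word = I_word,
                 info_bits_per_s = I_word / word_dur_s,
                 ma_bound_bits_per_word = ma_bound(p_pool),
                 noise_ma_bound_bits_per_word = mean(ma_noise_slices),
                 bin_ms = bin_ms, word_bins = word_bins,
                 clip_level = clip_level,
                 n_words = length(p_pool),
                 n_repeats = n_rep, n_slices = n_slices),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf(
    "Direct-method information (%g-ms bins, %d-bin words): H = %.3f, H_noise = %.3f bits/word -> %.2f bits/s\n",
    x$bin_ms, x$word_bins, x$total_entropy_bits_per_word,
    x$noise_entropy_bits_per_word, x$info_bits_per_s))
  invisible(x)
}

#' Word-parameter selection by Ma-bound proximity
#'
#' Runs \code{\link{direct_info}} over a grid of bin sizes and word lengths
#' and selects the setting whose noise-entropy plug-in estimate is closest
#' to its Ma bound — the setting whose word statistics are best sampled.
#' Ties break toward the smallest bin, then the smallest word.  The spike
#' train is re-binned for every bin size.
#'
#' @param spikes a \code{spike_train} over the repeated stimulus.
#' @param repeat_clip the repeat \code{stimulus_clip}.
#' @param bin_grid_ms candidate bin sizes, ms (default 4, 5, 6).
#' @param word_grid candidate word lengths in bins (default 3:6).
#' @param clip_level word alphabet ceiling.
#' @return the selected \code{info_result} with a \code{diagnostics}
#'   data.frame (one row per grid setting) attached.
#' @export
select_word_params <- function(spikes, repeat_clip, bin_grid_ms = c(4, 5, 6),
                               word_grid = 3:6, clip_level = 1) {
  if (!length(bin_grid_ms) || !length(word_grid)) stop("empty parameter grid")
  grid <- expand.grid(bin_ms = sort(bin_grid_ms),
                      word_bins = sort(word_grid))
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cm <- count_matrix(spikes, repeat_clip, grid$bin_ms[i])
    results[[i]] <- direct_info(cm, grid$bin_ms[i], grid$word_bins[i],
                                clip_level)
  }
  diag <- do.call(rbind, lapply(results, function(r) data.frame(
    bin_ms = r$bin_ms, word_bins = r$word_bins,
    H_total = r$total_entropy_bits_per_word,
    H_noise = r$noise_entropy_bits_per_word,
    noise_ma_bound = r$noise_ma_bound_bits_per_word,
    info_bits_per_s = r$info_bits_per_s,
    ma_gap = r$noise_entropy_bits_per_word - r$noise_ma_bound_bits_per_word)))
  # proximity of plug-in noise entropy to its Ma bound; ties -> smaller bin,
  # then smaller word (grid is ordered that way)
  ord <- order(abs(diag$ma_gap), diag$bin_ms, diag$word_bins)
  best <- results[[ord[1]]]
  best$diagnostics <- diag
  best
}

#' Select the most informative cells
#'
#' Returns the indices of the cells whose information rate lies in the top
#' \code{fraction} (ceiling of fraction * n cells), mirroring population
#' read-outs restricted to the top 10 percent most informative RGCs.  Ties
#' on the information rate break by cell id for determinism.
#'
#' @param info_rates numeric vector of information rates (bits/s).
#' @param cell_ids identifiers, same length; default seq_along.
#' @param fraction fraction to keep, in (0, 1].
#' @return integer indices of the selected cells, ordered by decreasing rate.
#' @export
top_informative <- function(info_rates, cell_ids = seq_along(info_rates),
                            fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * length(info_rates))
  ord <- order(-info_rates, cell_ids)
  sort(ord[seq_len(n_keep)])
}

#' Spike-train autocorrelogram
#'
#' Histogram of pairwise spike-time differences within a +/- window,
#' excluding zero-lag self pairs, normalized to the conditional firing rate
#' (spikes per second observed at lag t given a spike at 0).  Symmetric by
#' construction; for a stationary train it converges to the mean rate at
#' large lags.
#'
#' @param spikes a \code{spike_train} with >= 2 spikes.
#' @param window_ms half-width of the lag window, ms.
#' @param bin_ms lag bin, ms.
#' @return An \code{autocorrelogram}: list with \code{lags_ms} (bin centers),
#'   \code{rate_spk_s}, \code{window_ms}, \code{bin_ms}, \code{n_spikes}.
#' @export
autocorrelogram <- function(spikes, window_ms = 50, bin_ms = 1) {
  t <- spikes$spike_times_s
  n <- length(t)
  if (n < 2) stop("need at least 2 spikes")
  w_s <- window_ms / 1000
  # forward differences within the window via a sliding pointer
  diffs <- vector("list", n)
  j_hi <- 1L
  for (i in seq_len(n - 1L)) {
    if (j_hi < i + 1L) j_hi <- i + 1L
    while (j_hi <= n && t[j_hi] - t[i] <= w_s) j_hi <- j_hi + 1L
    if (j_hi > i + 1L) diffs[[i]] <- t[(i + 1L):(j_hi - 1L)] - t[i]
  }
  d <- unlist(diffs)
  edges <- seq(0, w_s, by = bin_ms / 1000)
  n_bins <- length(edges) - 1L
  h <- if (length(d)) tabulate(pmin(floor(d / (bin_ms / 1000)) + 1L, n_bins),
                               nbins = n_bins) else integer(n_bins)
  # mirror: rate at lag +t equals rate at -t by the pair definition
  rate <- h / (n * bin_ms / 1000)
  lags <- c(-rev(edges[-1] - bin_ms / 2000), edges[-1] - bin_ms / 2000) * 1000
  structure(list(lags_ms = lags,
                 rate_spk_s = c(rev(rate), rate),
                 window_ms = window_ms, bin_ms = bin_ms, n_spikes = n),
            class = "autocorrelogram")
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  graphics::plot(x$lags_ms, x$rate_spk_s, type = "h",
                 xlab = "lag (ms)", ylab = "conditional rate (spk/s)", ...)
  invisible(x)
}

#' Cluster cells into functional types
#'
#' Groups cells by their receptive-field properties and spike-train
#' autocorrelation shape: the feature matrix is standardized column-wise and
#' partitioned with k-means (many restarts under a fixed seed).  Rows are
#' internally sorted by cell id before clustering so the partition is
#' invariant to input order.
#'
#' @param features numeric matrix or data.frame, one row per cell (e.g.
#'   t0_ms, area, gain, autocorrelogram principal components).
#' @param k number of clusters (>= 1).
#' @param cell_ids row identifiers; default rownames or seq.
#' @param seed RNG seed for the k-means restarts.
#' @return list with \code{labels} (integer per cell, input order),
#'   \code{centers} (on the standardized scale), and \code{silhouette}
#'   (mean silhouette width; NA when k = 1).
#' @export
cluster_cell_types <- function(features, k, cell_ids = NULL, seed = 1) {
  x <- as.matrix(features)
  if (k < 1) stop("k must be >= 1")
  if (nrow(x) < k) stop("need at least k cells")
  if (is.null(cell_ids))
    cell_ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  ord <- order(cell_ids)
  xs <- scale(x[ord, , drop = FALSE])
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  if (k == 1) {
    labels <- rep(1L, nrow(x))
    return(list(labels = labels, centers = colMeans(xs), silhouette = NA_real_))
  }
  km <- with_seed(seed, stats::kmeans(xs, centers = k, nstart = 25,
                                      iter.max = 100))
  labels_sorted <- km$cluster
  labels <- integer(nrow(x))
  labels[ord] <- labels_sorted
  sil <- cluster::silhouette(labels_sorted, stats::dist(xs))
  list(labels = labels, centers = km$centers,
       silhouette = mean(sil[, "sil_width"]))
}
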