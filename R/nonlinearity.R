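#' Static nonlinearity (contrast-response function) and response gain
#'
#' Maps the generator signal — the convolution of the unit-norm rank-one
#' receptive field with the stimulus — onto the observed spike rate.  The
#' generator axis is partitioned into equal-count (quantile) bins and the
#' mean rate in each bin estimates the contrast-response function.  Response
#' gain is the linearly interpolated rate at 50 percent of the peak
#' generator value (the x-axis convention; the rate-axis alternative can be
#' derived from the returned curve).
#'
#' @param spikes the \code{spike_train} recorded during \code{clip}.
#' @param clip the driving (non-repeat) \code{stimulus_clip}.
#' @param sta an \code{sta_fit} processed by \code{\link{factorize_rank_one}};
#'   the cell should have passed the separability screen.
#' @param n_bins number of equal-count generator bins (>= 4, default 20).
#' @return A \code{contrast_response}: list with \code{generator_bin_centers},
#'   \code{mean_rate_spk_s}, \code{gain_spk_s}, \code{peak_rate_spk_s},
#'   \code{g_max} and \code{n_bins}.
#' @export
estimate_nonlinearity <- function(spikes, clip, sta, n_bins = 20) {
  stopifnot(inherits(sta, "sta_fit"))
  if (is.null(sta$temporal_filter))
    stop("run factorize_rank_one() on the STA first")
  if (n_bins < 4) stop("n_bins must be >= 4")
  if (clip$n_repeats > 1)
    stop("estimate_nonlinearity expects non-repeated noise")
  g <- generator_signal(clip, sta)
  dt_s <- clip$refresh_ms / 1000
  n_frames <- dim(clip$frames)[1]
  sf <- floor(spikes$spike_times_s / dt_s) + 1L
  sf <- sf[sf >= 1 & sf <= n_frames]
  cnt <- tabulate(sf, nbins = n_frames)
  usable <- (sta$depth_frames + 1L):n_frames
  g <- g[usable]; cnt <- cnt[usable]
  qs <- stats::quantile(g, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin <- cut(g, breaks = unique(qs), labels = FALSE, include.lowest = TRUE)
  centers <- tapply(g, bin, mean)
  rates <- tapply(cnt, bin, mean) / dt_s
  ord <- order(centers)
  centers <- as.numeric(centers[ord]); rates <- as.numeric(rates[ord])
  g_max <- max(g)
  x0 <- 0.5 * g_max
  gain <- if (x0 > max(centers)) {
    # the top equal-count bin's center sits below 0.5 * g_max; extend the
    # line through the last two bin means rather than clamping
    n <- length(centers)
    rates[n] + (rates[n] - rates[n - 1]) / (centers[n] - centers[n - 1]) *
      (x0 - centers[n])
  } else {
    stats::approx(centers, rates, xout = x0, rule = 2)$y
  }
  structure(list(generator_bin_centers = centers,
                 mean_rate_spk_s = rates,
                 gain_spk_s = gain,
                 peak_rate_spk_s = max(rates),
                 g_max = g_max,
                 n_bins = length(centers)),
            class = "contrast_response")
}

#' Generator signal of a separable receptive field on a stimulus
#'
#' Projects each frame onto the unit-norm spatial factor and convolves with
#' the unit-norm temporal factor; with both factors unit-norm the overall
#' space-time filter has unit Frobenius norm, so the generator scale is
#' stimulus-contrast units and all response scale lives in the nonlinearity.
#' Frames with incomplete history get g = 0.
#'
#' @param clip a \code{stimulus_clip}.
#' @param sta a factorized \code{sta_fit}.
#' @return numeric vector, one generator value per frame.
#' @export
generator_signal <- function(clip, sta) {
  sp <- sta$spatial_vec
  sp <- sp / sqrt(sum(sp^2))
  tf <- sta$temporal_filter / sqrt(sum(sta$temporal_filter^2))
  sproj <- as.numeric(clip_matrix(clip) %*% sp)
  g <- as.numeric(stats::filter(sproj, tf, method = "convolution", sides = 1))
  g[is.na(g)] <- 0
  g
}

#' @export
print.contrast_response <- function(x, ...) {
  cat(sprintf(
    "Contrast-response function (%d quantile bins): peak %.1f spk/s, gain %.1f spk/s at g = %.2f\n",
    x$n_bins, x$peak_rate_spk_s, x$gain_spk_s, 0.5 * x$g_max))
  invisible(x)
}

#' @export
plot.contrast_response <- function(x, ...) {
  graphics::plot(x$generator_bin_centers, x$mean_rate_spk_s, type = "b",
                 pch = 16, xlab = "generator signal (contrast units)",
                 ylab = "spike rate (spk/s)", ...)
  graphics::abline(v = 0.5 * x$g_max, lty = 2)
  graphics::points(0.5 * x$g_max, x$gain_spk_s, col = 2, pch = 17)
  invisible(x)
}

#' Full single-cell receptive-field analysis
#'
#' Convenience wrapper running the whole reverse-correlation chain for one
#' cell: STA, rank-one factorization and separability screen, temporal
#' metrics, spatial Gaussian fit, and the contrast-response function, with
#' per-stage exclusion bookkeeping.
#'
#' @inheritParams compute_sta
#' @param n_bins generator bins for the nonlinearity.
#' @return list with elements \code{sta}, \code{temporal} (or NULL),
#'   \code{spatial} (or NULL), \code{cr} (or NULL) and a one-row
#'   \code{summary} data.frame (cell_id, condition, n_spikes,
#'   variance_fraction, t0_ms, area_um2, gain_spk_s, flags).
#' @export
analyze_cell <- function(spikes, clip,
                         depth_frames = default_depth_frames(clip$refresh_ms),
                         n_bins = 20) {
  sta <- factorize_rank_one(compute_sta(spikes, clip, depth_frames))
  temporal <- NULL; spatial <- NULL; cr <- NULL
  flags <- character()
  if (sta$is_separable) {
    temporal <- time_to_zero(sta$temporal_filter, sta$refresh_ms)
    spatial <- fit_spatial_gaussian(sta$spatial_map, sta$square_size_um)
    if (!spatial$ok) flags <- c(flags, spatial$exclusion_reason)
    cr <- estimate_nonlinearity(spikes, clip, sta, n_bins = n_bins)
  } else {
    flags <- c(flags, sta$exclusion_reason)
  }
  md <- spikes$metadata
  summary <- data.frame(
    cell_id = spikes$cell_id,
    condition = md$condition %||% NA_character_,
    retina_id = md$retina_id %||% NA_character_,
    sex = md$sex %||% NA_character_,
    cell_type = md$cell_type %||% NA_character_,
    n_spikes = sta$n_spikes,
    variance_fraction = sta$variance_fraction_rank1,
    is_separable = sta$is_separable,
    t0_ms = if (!is.null(temporal)) temporal$time_to_zero_ms else NA_real_,
    area_um2 = if (!is.null(spatial) && spatial$ok) spatial$area_um2 else NA_real_,
    gain_spk_s = if (!is.null(cr)) cr$gain_spk_s else NA_real_,
    flags = if (length(flags)) paste(flags, collapse = ";") else "",
    stringsAsFactors = FALSE)
  list(sta = sta, temporal = temporal, spatial = spatial, cr = cr,
       summary = summary)
}
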