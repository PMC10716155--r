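#' Spike-triggered average receptive field
#'
#' Estimates the linear component of a cell's spatiotemporal receptive field
#' by reverse correlation: the kernel at lag l is the mean stimulus frame
#' displayed l frames before each spike.  A spike belongs to the frame being
#' displayed at its time (half-open frame intervals); spikes during the
#' first \code{depth_frames} frames are excluded so every averaged window is
#' complete.
#'
#' @param spikes a \code{spike_train}.
#' @param clip the (non-repeat) \code{stimulus_clip} that drove the cell.
#' @param depth_frames lags to average; default covers ~500 ms of history.
#' @return An \code{sta_fit}: list with \code{kernel} (lag x row x col,
#'   entries in [-1, 1]), \code{n_spikes}, \code{depth_frames}, timing and
#'   geometry metadata.  \code{\link{factorize_rank_one}} fills the rank-one
#'   factors.
#' @export
compute_sta <- function(spikes, clip,
                        depth_frames = default_depth_frames(clip$refresh_ms)) {
  stopifnot(inherits(spikes, "spike_train"), inherits(clip, "stimulus_clip"))
  if (clip$n_repeats > 1)
    stop("compute_sta expects non-repeated noise, not a repeat clip")
  d <- dim(clip$frames)
  n_frames <- d[1]
  dt_s <- clip$refresh_ms / 1000
  sf <- floor(spikes$spike_times_s / dt_s) + 1L   # frame of each spike
  sf <- sf[sf > depth_frames & sf <= n_frames]
  n_spk <- length(sf)
  if (n_spk < 1) stop("no usable spikes after the first depth_frames frames")
  cnt <- tabulate(sf, nbins = n_frames)
  sm <- clip_matrix(clip)
  usable <- (depth_frames + 1L):n_frames
  kern <- matrix(0, depth_frames, ncol(sm))
  for (lag in 0:(depth_frames - 1L))
    kern[lag + 1L, ] <-
      crossprod(sm[usable - lag, , drop = FALSE], cnt[usable]) / n_spk
  out <- structure(list(kernel_mat = kern,
                 n_spikes = n_spk,
                 depth_frames = depth_frames,
                 refresh_ms = clip$refresh_ms,
                 square_size_um = clip$square_size_um,
                 n_rows = d[2], n_cols = d[3],
                 cell_id = spikes$cell_id,
                 metadata = spikes$metadata),
            class = "sta_fit")
  out$kernel <- sta_kernel_array(out)
  out
}

# kernel_mat columns are row-major checkers; rebuild (lag, row, col) array.
sta_kernel_array <- function(sta) {
  arr <- array(0, dim = c(sta$depth_frames, sta$n_rows, sta$n_cols))
  for (r in seq_len(sta$n_rows))
    arr[, r, ] <- sta$kernel_mat[, (r - 1) * sta$n_cols + seq_len(sta$n_cols)]
  arr
}

#' Rank-one (space-time separable) factorization of an STA
#'
#' Unfolds the kernel to a (lag x checker) matrix and takes its singular
#' value decomposition.  The separability variance fraction is
#' \code{sigma1^2 / sum(sigma_i^2)}; a cell is screened in
#' (\code{is_separable}) when at least 60 percent of the STA variance is
#' captured by the rank-one term AND the temporal factor is biphasic (a
#' well-defined zero crossing is required downstream).  The sign is fixed so
#' the spatial map's dominant checker is positive; the temporal factor (unit
#' Euclidean norm) then carries the cell's polarity: dominant lobe positive
#' for ON cells, negative for OFF.
#'
#' @param sta an \code{sta_fit} from \code{\link{compute_sta}}.
#' @param variance_threshold inclusion threshold on the variance fraction
#'   (default 0.60, inclusive).
#' @return the \code{sta_fit} with \code{temporal_filter} (unit norm),
#'   \code{spatial_map} (row x col matrix carrying the scale),
#'   \code{variance_fraction_rank1}, \code{polarity} and \code{is_separable}
#'   filled in.
#' @export
factorize_rank_one <- function(sta, variance_threshold = 0.60) {
  stopifnot(inherits(sta, "sta_fit"))
  k <- sta$kernel_mat
  if (all(k == 0)) stop("all-zero kernel cannot be factorized")
  sv <- svd(k)
  vf <- sv$d[1]^2 / sum(sv$d^2)
  tf <- sv$u[, 1]
  sp <- sv$v[, 1] * sv$d[1]
  # sign convention: dominant spatial checker positive
  if (sp[which.max(abs(sp))] < 0) { sp <- -sp; tf <- -tf }
  sta$temporal_filter <- tf
  sta$spatial_map <- matrix(sp, sta$n_rows, sta$n_cols, byrow = TRUE)
  sta$spatial_vec <- sp
  sta$variance_fraction_rank1 <- vf
  sta$polarity <- if (tf[which.max(abs(tf))] >= 0) "ON" else "OFF"
  sta$biphasic <- is_biphasic(tf)
  sta$is_separable <- (vf >= variance_threshold) && sta$biphasic
  sta$exclusion_reason <- if (vf < variance_threshold) "non-separable"
    else if (!sta$biphasic) "non-biphasic" else NA_character_
  sta
}

#' Is a temporal filter biphasic?
#'
#' TRUE when the filter has a dominant lobe plus an opposite-sign lobe whose
#' peak magnitude is at least \code{min_lobe_fraction} of the dominant
#' lobe's, with a zero crossing between them.  Polarity-invariant.  The 5
#' percent secondary-lobe criterion is this package's operational choice for
#' "well-defined zero crossing".
#'
#' @param temporal_filter numeric vector (lag 0 first).
#' @param min_lobe_fraction minimum secondary-lobe magnitude, as a fraction
#'   of the dominant lobe.
#' @export
is_biphasic <- function(temporal_filter, min_lobe_fraction = 0.05) {
  tf <- temporal_filter
  if (all(tf == 0) || any(!is.finite(tf))) return(FALSE)
  i0 <- which.max(abs(tf))
  s <- sign(tf[i0])
  opp <- which(sign(tf) == -s)
  if (!length(opp)) return(FALSE)
  j <- opp[which.max(abs(tf[opp]))]
  if (abs(tf[j]) < min_lobe_fraction * abs(tf[i0])) return(FALSE)
  # a sign change necessarily exists between i0 and j
  TRUE
}

#' Time-to-zero and temporal metrics of a biphasic filter
#'
#' The time-to-zero is the lag, counted back from the spike, at which the
#' temporal filter crosses zero between its dominant lobe and the
#' opposite-sign lobe — a standard proxy for the cell's integration time.
#' Lag l is assigned time (l + 0.5) * refresh_ms (frame-bin centers); the
#' crossing is located by linear interpolation between samples.  If a sample
#' between the lobes is exactly zero its own lag time is returned.
#'
#' @param temporal_filter numeric vector (lag 0 first); must be biphasic.
#' @param refresh_ms stimulus frame duration, ms.
#' @return list with \code{time_to_zero_ms}, \code{peak_time_ms},
#'   \code{biphasic_index} (|secondary| / |dominant|).
#' @export
time_to_zero <- function(temporal_filter, refresh_ms) {
  tf <- temporal_filter
  if (!is_biphasic(tf)) stop("temporal filter has no well-defined zero crossing")
  t_ms <- (seq_along(tf) - 0.5) * refresh_ms
  i0 <- which.max(abs(tf))
  s <- sign(tf[i0])
  opp <- which(sign(tf) == -s)
  j <- opp[which.max(abs(tf[opp]))]
  lo <- min(i0, j); hi <- max(i0, j)
  tz <- NA_real_
  for (i in lo:(hi - 1)) {
    if (tf[i] == 0) { tz <- t_ms[i]; break }
    if (sign(tf[i]) != sign(tf[i + 1])) {
      if (tf[i + 1] == 0) { tz <- t_ms[i + 1]; break }
      tz <- t_ms[i] + (t_ms[i + 1] - t_ms[i]) * tf[i] / (tf[i] - tf[i + 1])
      break
    }
  }
  if (is.na(tz)) stop("no zero crossing found between lobes")
  list(time_to_zero_ms = tz,
       peak_time_ms = t_ms[i0],
       biphasic_index = abs(tf[j]) / abs(tf[i0]))
}

#' @export
print.sta_fit <- function(x, ...) {
  cat(sprintf("STA for '%s': %d lags x %d x %d checkers, %d spikes\n",
              x$cell_id, x$depth_frames, x$n_rows, x$n_cols, x$n_spikes))
  if (!is.null(x$variance_fraction_rank1)) {
    cat(sprintf("  rank-one variance fraction %.3f; %s; polarity %s%s\n",
                x$variance_fraction_rank1,
                if (x$is_separable) "space-time separable"
                else paste0("screened out (", x$exclusion_reason, ")"),
                x$polarity,
                if (isTRUE(x$biphasic)) ", biphasic" else ""))
  }
  invisible(x)
}

#' @export
plot.sta_fit <- function(x, ...) {
  if (is.null(x$temporal_filter)) x <- factorize_rank_one(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t_ms <- (seq_len(x$depth_frames) - 0.5) * x$refresh_ms
  graphics::plot(t_ms, x$temporal_filter, type = "b", pch = 16,
                 xlab = "time before spike (ms)", ylab = "filter (a.u.)",
                 main = "temporal factor", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::image(
    seq_len(x$n_cols) * x$square_size_um,
    seq_len(x$n_rows) * x$square_size_um,
    t(x$spatial_map)[, rev(seq_len(x$n_rows)), drop = FALSE],
    xlab = "x (um)", ylab = "y (um)", main = "spatial map",
    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  invisible(x)
}
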