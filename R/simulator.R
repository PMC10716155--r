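#' Parameterize a synthetic RGC for the LNP simulator
#'
#' Defines one model cell for the linear-nonlinear-Poisson (LNP) simulator.
#' The linear stage is space-time separable by construction: an elliptical
#' Gaussian spatial profile times a biphasic temporal kernel (difference of
#' two gamma-shaped cascades, which has a closed-form zero crossing).  The
#' static nonlinearity is a saturating rectifier.  Spiking is conditionally
#' Poisson (\code{dispersion_phi = 1}) or gamma-mixed Poisson with
#' variance/mean ratio \code{dispersion_phi} at the 5-ms reference bin.
#'
#' @param center_um receptive-field center (x, y) in micrometers.
#' @param sigma_um Gaussian SDs (major, minor) in micrometers.
#' @param angle_rad orientation of the major axis, radians.
#' @param polarity "ON" or "OFF".
#' @param tau_fast_ms,tau_slow_ms,cascade_shape,undershoot_weight temporal
#'   kernel parameters, see \code{\link{temporal_kernel}}.
#' @param threshold,slope_spk_s,max_rate_spk_s saturating-rectifier
#'   nonlinearity: rate = min(max_rate, slope * max(g - threshold, 0)) where
#'   g is the generator signal (unit-norm filter, so g has SD ~ 1 under
#'   binary white noise).
#' @param dispersion_phi target spike-count variance/mean ratio (>= 1).
#' @param baseline_rate_spk_s stimulus-independent rate added to the
#'   nonlinearity output.
#' @param refractory_ms absolute refractory period enforced on spike times.
#' @return An object of class \code{rgc_cell_params}.
#' @export
rgc_cell_params <- function(center_um = c(300, 300),
                            sigma_um = c(55, 40),
                            angle_rad = 0,
                            polarity = c("ON", "OFF"),
                            tau_fast_ms = 15,
                            tau_slow_ms = 22.5,
                            cascade_shape = 5,
                            undershoot_weight = 0.75,
                            threshold = 0.5,
                            slope_spk_s = 60,
                            max_rate_spk_s = 180,
                            dispersion_phi = 1,
                            baseline_rate_spk_s = 1,
                            refractory_ms = 0) {
  polarity <- match.arg(polarity)
  stopifnot(sigma_um[1] >= sigma_um[2], sigma_um[2] > 0,
            dispersion_phi >= 1, tau_slow_ms > tau_fast_ms,
            undershoot_weight > 0, undershoot_weight < 1)
  structure(list(center_um = center_um, sigma_um = sigma_um,
                 angle_rad = angle_rad, polarity = polarity,
                 tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
                 cascade_shape = cascade_shape,
                 undershoot_weight = undershoot_weight,
                 threshold = threshold, slope_spk_s = slope_spk_s,
                 max_rate_spk_s = max_rate_spk_s,
                 dispersion_phi = dispersion_phi,
                 baseline_rate_spk_s = baseline_rate_spk_s,
                 refractory_ms = refractory_ms),
            class = "rgc_cell_params")
}

#' Biphasic temporal kernel and its zero crossing
#'
#' The temporal filter is a difference of two gamma-shaped cascades with a
#' common shape parameter p:
#'   k(t) = (t/tau_f)^p exp(-t/tau_f) - w (t/tau_s)^p exp(-t/tau_s),
#' t in ms before the spike.  With tau_s > tau_f and 0 < w < 1 this is
#' biphasic (positive early lobe, delayed negative undershoot) with a unique
#' zero crossing at
#'   t0 = (log w + p log(tau_f / tau_s)) / (1/tau_s - 1/tau_f),
#' which serves as the ground-truth time-to-zero for parameter-recovery tests.
#'
#' @param t_ms times (ms) at which to evaluate the kernel.
#' @param params an \code{rgc_cell_params}.
#' @return kernel values (arbitrary scale; consumers normalize).
#' @export
temporal_kernel <- function(t_ms, params) {
  p <- params$cascade_shape
  k <- (t_ms / params$tau_fast_ms)^p * exp(-t_ms / params$tau_fast_ms) -
    params$undershoot_weight *
      (t_ms / params$tau_slow_ms)^p * exp(-t_ms / params$tau_slow_ms)
  if (params$polarity == "OFF") -k else k
}

#' @rdname temporal_kernel
#' @export
true_time_to_zero_ms <- function(params) {
  (log(params$undershoot_weight) +
     params$cascade_shape * log(params$tau_fast_ms / params$tau_slow_ms)) /
    (1 / params$tau_slow_ms - 1 / params$tau_fast_ms)
}

# Unit-L2 spatial weights of the cell on a clip's checker grid.
spatial_weights <- function(params, clip) {
  cc <- checker_centers_um(clip)
  dx <- cc$x_um - params$center_um[1]
  dy <- cc$y_um - params$center_um[2]
  ca <- cos(params$angle_rad); sa <- sin(params$angle_rad)
  u <- ca * dx + sa * dy      # along major axis
  v <- -sa * dx + ca * dy
  w <- exp(-0.5 * ((u / params$sigma_um[1])^2 + (v / params$sigma_um[2])^2))
  w / sqrt(sum(w^2))
}

# Unit-L2 temporal weights sampled at frame-bin centers, lag 0 = spike frame.
temporal_weights <- function(params, refresh_ms, depth_frames) {
  t_ms <- (seq_len(depth_frames) - 0.5) * refresh_ms
  k <- temporal_kernel(t_ms, params)
  k / sqrt(sum(k^2))
}

#' Default STA depth covering ~500 ms of stimulus history
#' @param refresh_ms frame duration in ms.
#' @export
default_depth_frames <- function(refresh_ms) max(2L, round(500 / refresh_ms))

# Per-frame deterministic firing rate (spk/s) of a cell driven by a clip;
# also returns the generator trace.  Frames with incomplete stimulus history
# are driven at baseline (g = 0).
cell_rate_trace <- function(params, clip,
                            depth_frames = default_depth_frames(clip$refresh_ms)) {
  sm <- clip_matrix(clip)
  w <- spatial_weights(params, clip)
  kt <- temporal_weights(params, clip$refresh_ms, depth_frames)
  sproj <- as.numeric(sm %*% w)
  g <- as.numeric(stats::filter(sproj, kt, method = "convolution", sides = 1))
  g[is.na(g)] <- 0
  rate <- params$baseline_rate_spk_s +
    pmin(params$max_rate_spk_s,
         params$slope_spk_s * pmax(g - params$threshold, 0))
  list(g = g, rate_spk_s = rate)
}

#' Construct a spike train object
#'
#' @param spike_times_s numeric vector of spike times, seconds; must lie in
#'   [0, duration_s] and is sorted on construction.
#' @param duration_s recording duration.
#' @param cell_id identifier string.
#' @param metadata named list (retina_id, condition, age_months, sex,
#'   cell_type, ...).
#' @export
spike_train <- function(spike_times_s, duration_s, cell_id = "cell",
                        metadata = list()) {
  spike_times_s <- sort(as.numeric(spike_times_s))
  if (length(spike_times_s) &&
      (spike_times_s[1] < 0 || spike_times_s[length(spike_times_s)] > duration_s))
    stop("spike times must lie within [0, duration_s]")
  structure(list(spike_times_s = spike_times_s,
                 duration_s = duration_s,
                 cell_id = cell_id,
                 metadata = metadata),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d spikes over %.1f s (%.2f spk/s)\n",
              x$cell_id, length(x$spike_times_s), x$duration_s,
              length(x$spike_times_s) / x$duration_s))
  invisible(x)
}

#' Simulate an RGC spike train with the LNP model
#'
#' Runs the cell's space-time filter over the stimulus, applies the
#' saturating rectifier, and draws per-frame spike counts.  For
#' \code{dispersion_phi = 1} counts are conditionally Poisson.  For
#' \code{dispersion_phi > 1} each frame's rate is multiplied by an
#' independent gamma variate with mean 1 whose variance is calibrated from
#' the deterministic rate trace so that the expected across-repeat
#' variance/mean spike-count ratio at the 5-ms reference bin equals
#' \code{dispersion_phi} (law of total variance; see the methods vignette).
#' Spike times are placed uniformly within their frame.  Repeat clips
#' (\code{n_repeats > 1}) are presented back-to-back with fresh noise each
#' repeat.
#'
#' @param params an \code{rgc_cell_params}.
#' @param clip a \code{stimulus_clip} (plain or repeat clip); must be at
#'   least as long as the filter's temporal support.
#' @param seed integer seed.
#' @param cell_id,metadata passed to \code{\link{spike_train}}.
#' @param ref_bin_ms reference bin at which \code{dispersion_phi} is defined.
#' @return a \code{spike_train}.
#' @export
simulate_spike_train <- function(params, clip, seed = 1, cell_id = "sim",
                                 metadata = list(), ref_bin_ms = 5) {
  depth <- default_depth_frames(clip$refresh_ms)
  if (dim(clip$frames)[1] < depth)
    stop("clip shorter than the temporal filter support")
  tr <- cell_rate_trace(params, clip, depth)
  dt_s <- clip$refresh_ms / 1000
  mu1 <- tr$rate_spk_s * dt_s                # expected counts, one presentation
  mu <- rep(mu1, clip$n_repeats)
  phi <- params$dispersion_phi
  with_seed(seed, {
    if (phi > 1) {
      # gamma multiplier variance v chosen so the expected variance/mean
      # ratio of counts in ref_bin_ms bins is phi:
      #   ratio = 1 + v * sum(mu_b^2)/sum(mu_b), mu_b = mu_f / n_sub
      n_sub <- clip$refresh_ms / ref_bin_ms
      v <- (phi - 1) * n_sub * sum(mu) / sum(mu^2)
      gmult <- stats::rgamma(length(mu), shape = 1 / v, rate = 1 / v)
      counts <- stats::rpois(length(mu), mu * gmult)
    } else {
      counts <- stats::rpois(length(mu), mu)
    }
    frame_start <- (seq_along(mu) - 1) * dt_s
    times <- rep(frame_start, counts) + stats::runif(sum(counts)) * dt_s
    times <- sort(times)
    if (params$refractory_ms > 0 && length(times) > 1)
      times <- enforce_refractory(times, params$refractory_ms / 1000)
    spike_train(times, duration_s = length(mu) * dt_s, cell_id = cell_id,
                metadata = metadata)
  })
}

# Sequentially drop spikes closer than tau_s to the last kept spike.
enforce_refractory <- function(times, tau_s) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= tau_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}
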