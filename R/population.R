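#' Condition presets for the population simulator
#'
#' Qualitative emulations of the experimental cohorts: wild type (WT),
#' untreated degeneration, and early / mid / late genetic-rescue timepoints.
#' They are NOT fits to any recorded dataset; the scales encode the
#' qualitative population trends — response gain recovers with early and mid
#' treatment but not late treatment, and the spike-count variance/mean ratio
#' stays near 1 (Poisson) for WT/early/mid but is elevated for untreated and
#' late-treated cells.  \code{gain_scale} multiplies the nonlinearity slope
#' and maximum rate, \code{phi} is the target count variance/mean ratio,
#' \code{t0_scale} multiplies the temporal-kernel time constants (shorter
#' integration in degenerated retina), \code{density_scale} scales RGC
#' sampling density (bookkeeping only).
#'
#' @param labels subset of c("WT", "untreated", "early", "mid", "late").
#' @param age_months age tag attached to every preset.
#' @return data.frame, one row per preset.
#' @export
condition_presets <- function(labels = c("WT", "untreated", "early", "mid",
                                         "late"),
                              age_months = 7) {
  all <- data.frame(
    label = c("WT", "untreated", "early", "mid", "late"),
    gain_scale = c(1, 0.55, 0.91, 0.98, 0.67),
    phi = c(1, 1.9, 1, 1, 1.8),
    t0_scale = c(1, 0.9, 1, 1, 0.9),
    density_scale = c(1, 0.7, 0.9, 0.9, 0.8),
    stringsAsFactors = FALSE)
  labels <- match.arg(labels, all$label, several.ok = TRUE)
  out <- all[match(labels, all$label), ]
  out$age_months <- age_months
  rownames(out) <- NULL
  out
}

# Archetype draw for cell k: identical across conditions given the same
# population seed, so preset scales act on matched cells.
archetype_params <- function(k, seed, stim_extent_um, cell_type) {
  with_seed(child_seed(seed, k), {
    margin <- 120
    center <- stats::runif(2, margin, stim_extent_um - margin)
    sig_major <- 55 * exp(stats::rnorm(1, 0, 0.10))
    sig_minor <- 40 * exp(stats::rnorm(1, 0, 0.10))
    if (sig_minor > sig_major) { tmp <- sig_major; sig_major <- sig_minor; sig_minor <- tmp }
    list(center_um = center,
         sigma_um = c(sig_major, sig_minor),
         angle_rad = stats::runif(1, 0, pi),
         polarity = if (stats::runif(1) < 0.5) "ON" else "OFF",
         # two physiological archetypes: brisk (fast kernel) vs sluggish
         # (slow kernel); no dead time, so the measured variance/mean ratio
         # tracks the preset's phi (dead-time thinning would deflate it)
         tau_fast_ms = if (cell_type == "brisk") 12 else 18,
         refractory_ms = 0,
         slope = 60 * exp(stats::rnorm(1, 0, 0.08)),
         max_rate = 180 * exp(stats::rnorm(1, 0, 0.08)))
  })
}

#' Simulate an RGC population across condition presets
#'
#' Draws per-cell parameters around each preset (matched archetype draws
#' across conditions, so preset scales act deterministically on comparable
#' cells), simulates every cell's spike train on \code{base_clip}, and
#' attaches the grouping structure needed downstream: retina, sex, and cell
#' type.  Cells are split evenly over \code{n_retinas} retinas per condition;
#' each retina is assigned a sex (alternating F/M); cell types alternate
#' between the "brisk" and "sluggish" archetypes.
#'
#' @param presets data.frame from \code{\link{condition_presets}} (or a
#'   subset of its rows).
#' @param n_cells_per_condition cells per condition (>= 1).
#' @param base_clip the \code{stimulus_clip} all cells respond to.
#' @param seed integer seed.
#' @param n_retinas retinas per condition (>= 2 keeps the mixed-model
#'   random effect identifiable).
#' @return An \code{rgc_population}: list with \code{spike_trains} (list of
#'   \code{spike_train}) and \code{truth} (data.frame of ground-truth
#'   parameters per cell, including the realized \code{rgc_cell_params}).
#' @export
simulate_population <- function(presets, n_cells_per_condition, base_clip,
                                seed = 1, n_retinas = 2) {
  if (is.null(nrow(presets)) || nrow(presets) < 1) stop("empty preset list")
  if (n_cells_per_condition < 1) stop("n_cells_per_condition must be >= 1")
  extent <- min(dim(base_clip$frames)[2], dim(base_clip$frames)[3]) *
    base_clip$square_size_um
  trains <- list()
  truth <- list()
  param_list <- list()
  for (ci in seq_len(nrow(presets))) {
    pr <- presets[ci, ]
    for (k in seq_len(n_cells_per_condition)) {
      cell_type <- if (k %% 2 == 1) "brisk" else "sluggish"
      arch <- archetype_params(k, seed, extent, cell_type)
      params <- rgc_cell_params(
        center_um = arch$center_um, sigma_um = arch$sigma_um,
        angle_rad = arch$angle_rad, polarity = arch$polarity,
        tau_fast_ms = arch$tau_fast_ms * pr$t0_scale,
        tau_slow_ms = 1.5 * arch$tau_fast_ms * pr$t0_scale,
        threshold = 0.5,
        slope_spk_s = arch$slope * pr$gain_scale,
        max_rate_spk_s = arch$max_rate * pr$gain_scale,
        dispersion_phi = pr$phi,
        refractory_ms = arch$refractory_ms)
      retina_idx <- ((k - 1) %% n_retinas) + 1
      retina_id <- sprintf("%s_r%d", pr$label, retina_idx)
      meta <- list(retina_id = retina_id, condition = pr$label,
                   age_months = pr$age_months,
                   sex = if (retina_idx %% 2 == 1) "F" else "M",
                   cell_type = cell_type)
      cell_id <- sprintf("%s_c%03d", pr$label, k)
      st <- simulate_spike_train(params, base_clip,
                                 seed = child_seed(seed, ci * 100000 + k),
                                 cell_id = cell_id, metadata = meta)
      trains[[cell_id]] <- st
      param_list[[cell_id]] <- params
      truth[[cell_id]] <- data.frame(
        cell_id = cell_id, condition = pr$label, retina_id = retina_id,
        age_months = pr$age_months, sex = meta$sex, cell_type = cell_type,
        polarity = params$polarity,
        center_x_um = params$center_um[1], center_y_um = params$center_um[2],
        sigma_major_um = params$sigma_um[1],
        sigma_minor_um = params$sigma_um[2],
        t0_ms = true_time_to_zero_ms(params),
        slope_spk_s = params$slope_spk_s,
        max_rate_spk_s = params$max_rate_spk_s,
        phi = params$dispersion_phi,
        n_spikes = length(st$spike_times_s),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(spike_trains = trains,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 cell_params = param_list,
                 clip_seed = base_clip$seed, seed = seed),
            class = "rgc_population")
}

#' @export
print.rgc_population <- function(x, ...) {
  tab <- table(x$truth$condition)
  cat(sprintf("Simulated RGC population: %d cells over %d conditions\n",
              nrow(x$truth), length(tab)))
  print(tab)
  invisible(x)
}

#' Write / read a population's spike trains as a long-format table
#'
#' The exchange format is one CSV with columns cell_id, retina_id,
#' condition, age_months, sex, cell_type, spike_time_s — one row per spike.
#' Cells and times are written in sorted order so the file is reproducible.
#'
#' @param pop an \code{rgc_population} (or any list of \code{spike_train}).
#' @param path CSV path.
#' @export
write_spike_table <- function(pop, path) {
  trains <- if (inherits(pop, "rgc_population")) pop$spike_trains else pop
  rows <- lapply(trains, function(st) {
    m <- st$metadata
    data.frame(cell_id = st$cell_id,
               retina_id = m$retina_id %||% NA_character_,
               condition = m$condition %||% NA_character_,
               age_months = m$age_months %||% NA_real_,
               sex = m$sex %||% NA_character_,
               cell_type = m$cell_type %||% NA_character_,
               spike_time_s = st$spike_times_s,
               duration_s = st$duration_s,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "spike_time_s", "duration_s")
  if (!all(needed %in% names(tab)))
    stop("spike table must have columns: ", paste(needed, collapse = ", "))
  split_tab <- split(tab, tab$cell_id)
  trains <- lapply(split_tab, function(d) {
    spike_train(d$spike_time_s, duration_s = d$duration_s[1],
                cell_id = d$cell_id[1],
                metadata = list(retina_id = d$retina_id[1],
                                condition = d$condition[1],
                                age_months = d$age_months[1],
                                sex = d$sex[1], cell_type = d$cell_type[1]))
  })
  trains[order(names(trains))]
}
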