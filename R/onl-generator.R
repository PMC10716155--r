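#' Generate a synthetic outer-nuclear-layer image with planted nuclei
#'
#' Renders bright elliptical nuclei with 2-D Gaussian intensity profiles on
#' a dark background, plus i.i.d. Gaussian pixel noise, and returns the
#' ground truth needed to score a nuclei counter.  A nucleus's bookkeeping
#' "width" is the full width at half maximum (FWHM) of its minor axis.  The
#' peak amplitude is calibrated so the standard 8-bit detection threshold
#' (pixel value 104) sits at the blob's half-maximum above background, hence
#' a raw thresholded component reproduces the planted half-max ellipse.
#'
#' Truth labels follow the detection constraints: a nucleus passes on width
#' when FWHM >= 2.1 um, and on separation when its nearest-edge distance to
#' every neighbor is >= 1.05 um.  \code{n_invalid_nuclei} plants
#' width-violators (FWHM ~ 1.2-1.7 um); \code{n_separation_pairs} plants
#' pairs of normal-width nuclei with an edge gap of ~0.85 um, so both
#' members fail separation.
#'
#' @param n_valid_nuclei number of constraint-satisfying nuclei.
#' @param n_invalid_nuclei number of width-violating nuclei.
#' @param scale_um_per_px pixel size, micrometers (default 0.2).
#' @param noise_sd Gaussian pixel-noise SD in 8-bit units (default 6).
#' @param seed integer seed.
#' @param n_separation_pairs pairs violating the separation rule.
#' @param width_px,height_px image size in pixels.
#' @param background background gray level (8-bit).
#' @return A \code{synthetic_onl_image}: list with \code{pixels} (integer
#'   matrix, 0-255, \code{height_px} x \code{width_px}),
#'   \code{scale_um_per_px}, and \code{truth}: data.frame of planted nuclei
#'   (x_um, y_um from the top-left corner, width_um = minor FWHM, major_um,
#'   angle_rad, passes_width, passes_separation, valid).
#' @export
generate_onl_image <- function(n_valid_nuclei, n_invalid_nuclei = 0,
                               scale_um_per_px = 0.2, noise_sd = 6,
                               seed = 1, n_separation_pairs = 0,
                               width_px = 512, height_px = 200,
                               background = 25) {
  stopifnot(n_valid_nuclei >= 0, n_invalid_nuclei >= 0,
            n_separation_pairs >= 0, scale_um_per_px > 0)
  amp <- 2 * (104 - background)   # threshold 104 lands at blob half-max
  W_um <- width_px * scale_um_per_px
  H_um <- height_px * scale_um_per_px
  with_seed(seed, {
    placed <- data.frame()  # x_um, y_um, fwhm_minor, fwhm_major, angle, kind
    add_nucleus <- function(fwhm_minor, fwhm_major, min_gap_um,
                            kind, near = NULL, gap_um = NA) {
      margin <- fwhm_major + 1.5
      for (try in 1:400) {
        if (is.null(near)) {
          x <- stats::runif(1, margin, W_um - margin)
          y <- stats::runif(1, margin, H_um - margin)
        } else {
          # place at a controlled edge gap from an existing nucleus
          th <- stats::runif(1, 0, 2 * pi)
          d <- gap_um + (near$fwhm_major + fwhm_major) / 2
          x <- near$x_um + d * cos(th)
          y <- near$y_um + d * sin(th)
          if (x < margin || x > W_um - margin ||
              y < margin || y > H_um - margin) next
        }
        ok <- TRUE
        if (nrow(placed)) {
          cd <- sqrt((placed$x_um - x)^2 + (placed$y_um - y)^2)
          gaps <- cd - (placed$fwhm_major + fwhm_major) / 2
          others <- if (is.null(near)) gaps else
            gaps[!(placed$x_um == near$x_um & placed$y_um == near$y_um)]
          if (length(others) && min(others) < min_gap_um) ok <- FALSE
        }
        if (ok) {
          placed <<- rbind(placed, data.frame(
            x_um = x, y_um = y, fwhm_minor = fwhm_minor,
            fwhm_major = fwhm_major, angle_rad = stats::runif(1, 0, pi),
            kind = kind, stringsAsFactors = FALSE))
          return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(n_valid_nuclei)) {
      f <- stats::runif(1, 2.8, 4.2)
      if (!add_nucleus(f, f * stats::runif(1, 1, 1.25), 3.0, "valid"))
        stop("infeasible packing: could not place all valid nuclei")
    }
    for (i in seq_len(n_invalid_nuclei)) {
      f <- stats::runif(1, 1.2, 1.7)
      if (!add_nucleus(f, f * stats::runif(1, 1, 1.2), 3.0, "narrow"))
        stop("infeasible packing: could not place width violators")
    }
    for (i in seq_len(n_separation_pairs)) {
      # circular, so the truth edge-gap computation is exact
      f1 <- stats::runif(1, 2.8, 3.6)
      if (!add_nucleus(f1, f1, 3.5, "close_pair"))
        stop("infeasible packing: could not place separation pair")
      anchor <- placed[nrow(placed), ]
      f2 <- stats::runif(1, 2.8, 3.6)
      ok <- add_nucleus(f2, f2, 3.0, "close_pair", near = anchor,
                        gap_um = stats::runif(1, 0.6, 0.8))
      if (!ok) stop("infeasible packing: could not place pair partner")
    }

    img <- matrix(background, height_px, width_px)
    if (nrow(placed)) {
      xs <- (seq_len(width_px) - 0.5) * scale_um_per_px
      ys <- (seq_len(height_px) - 0.5) * scale_um_per_px
      for (i in seq_len(nrow(placed))) {
        p <- placed[i, ]
        s_min <- p$fwhm_minor / 2.355
        s_maj <- p$fwhm_major / 2.355
        rx <- which(abs(xs - p$x_um) < 4 * s_maj)
        ry <- which(abs(ys - p$y_um) < 4 * s_maj)
        if (!length(rx) || !length(ry)) next
        dx <- outer(ys[ry] - p$y_um, xs[rx] - p$x_um,
                    function(yy, xx) cos(p$angle_rad) * xx + sin(p$angle_rad) * yy)
        dy <- outer(ys[ry] - p$y_um, xs[rx] - p$x_um,
                    function(yy, xx) -sin(p$angle_rad) * xx + cos(p$angle_rad) * yy)
        # max-compositing: nuclei are opaque bodies, so the half-max contour
        # of each blob survives even for near-touching neighbors
        img[ry, rx] <- pmax(img[ry, rx],
                            background +
                              amp * exp(-0.5 * ((dx / s_maj)^2 + (dy / s_min)^2)))
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                  nrow(img), ncol(img))

    truth <- if (nrow(placed)) {
      passes_width <- placed$fwhm_minor >= 2.1
      passes_sep <- rep(TRUE, nrow(placed))
      if (nrow(placed) > 1) {
        for (i in seq_len(nrow(placed))) {
          cd <- sqrt((placed$x_um - placed$x_um[i])^2 +
                       (placed$y_um - placed$y_um[i])^2)
          gaps <- cd - (placed$fwhm_major + placed$fwhm_major[i]) / 2
          gaps[i] <- Inf
          if (min(gaps) < 1.05) passes_sep[i] <- FALSE
        }
      }
      data.frame(x_um = placed$x_um, y_um = placed$y_um,
                 width_um = placed$fwhm_minor, major_um = placed$fwhm_major,
                 angle_rad = placed$angle_rad, kind = placed$kind,
                 passes_width = passes_width,
                 passes_separation = passes_sep,
                 valid = passes_width & passes_sep,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(x_um = numeric(), y_um = numeric(), width_um = numeric(),
                 major_um = numeric(), angle_rad = numeric(),
                 kind = character(), passes_width = logical(),
                 passes_separation = logical(), valid = logical(),
                 stringsAsFactors = FALSE)
    }
    structure(list(pixels = img, scale_um_per_px = scale_um_per_px,
                   truth = truth, seed = seed, noise_sd = noise_sd),
              class = "synthetic_onl_image")
  })
}

#' @export
print.synthetic_onl_image <- function(x, ...) {
  cat(sprintf(
    "Synthetic ONL image: %d x %d px at %.3g um/px, %d planted nuclei (%d valid)\n",
    ncol(x$pixels), nrow(x$pixels), x$scale_um_per_px,
    nrow(x$truth), sum(x$truth$valid)))
  invisible(x)
}

#' Write / read an ONL image with its JSON truth sidecar
#'
#' Images are written as 8-bit grayscale TIFF (or PNG by extension); the
#' planted-truth table, scale and seed go to a JSON sidecar at
#' \code{paste0(path, ".json")}.
#' @param img a \code{synthetic_onl_image}.
#' @param path output path ending in .tif/.tiff or .png.
#' @export
write_onl_image <- function(img, path) {
  m <- img$pixels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  jsonlite::write_json(list(scale_um_per_px = img$scale_um_per_px,
                            seed = img$seed, noise_sd = img$noise_sd,
                            truth = img$truth),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
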