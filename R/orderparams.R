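#' Nematic order parameter
#'
#' Maximum eigenvalue of the 2x2 orientation tensor
#' \deqn{N = \frac{1}{n}\sum_i \begin{pmatrix} 2\cos^2\theta_i - 1 &
#'   2\sin\theta_i\cos\theta_i \\ 2\sin\theta_i\cos\theta_i &
#'   2\sin^2\theta_i - 1 \end{pmatrix}}
#' which is 0 for an isotropic orientation distribution and 1 for perfect
#' alignment.  Angles are head-tail symmetric: adding 180 degrees to any
#' angle leaves the result unchanged.
#'
#' @param theta rod orientations in radians (at least one).
#' @return the maximum eigenvalue, in `[0, 1]` up to arithmetic noise.
#' @export
nematic_order <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) < 1L)
    stop("nematic order is undefined for an empty orientation sample")
  n <- length(theta)
  c2 <- sum(2 * cos(theta)^2 - 1) / n
  s2 <- sum(2 * sin(theta) * cos(theta)) / n
  N <- matrix(c(c2, s2, s2, -c2), 2, 2)
  max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
}

#' Orientation occupancy fractions
#'
#' @param k orientation indices in 0:2.
#' @param n total rod count (defaults to `length(k)`); returns zeros when 0.
#' @return numeric triple summing to 1 (or zeros when empty).
#' @export
orientation_fractions <- function(k, n = length(k)) {
  if (n == 0L) return(c(0, 0, 0))
  tabulate(as.integer(k) + 1L, nbins = 3L) / n
}

#' Rasterize rod centers onto a pixel grid
#'
#' Each rod center marks the pixel `floor(coordinate * grid_side /
#' box_side)` and is then padded to a `pad x pad` block centered on that
#' pixel, wrapping periodically at the image edges.  Accumulation is binary:
#' a pixel is 1 if covered by any block.  Rows index y, columns index x
#' (both 1-based; pixel (0,0) in image coordinates is `img[1, 1]`).
#'
#' @param x,y rod center coordinates in box units.
#' @param box_side box side length.
#' @param grid_side image side in pixels.
#' @param pad odd block side in pixels.
#' @return `grid_side x grid_side` binary matrix of class `center_image`
#'   with attribute `pixels_per_unit`.
#' @export
rasterize_centers <- function(x, y, box_side, grid_side = 500, pad = 5) {
  if (pad %% 2 == 0) stop("pad must be odd so blocks have a center pixel")
  ppu <- grid_side / box_side
  img <- matrix(0, grid_side, grid_side)
  if (length(x) > 0) {
    px <- floor(x * ppu) %% grid_side
    py <- floor(y * ppu) %% grid_side
    h <- (pad - 1) / 2
    off <- -h:h
    dd <- expand.grid(dx = off, dy = off)
    for (d in seq_len(nrow(dd))) {
      cc <- (px + dd$dx[d]) %% grid_side + 1L
      rr <- (py + dd$dy[d]) %% grid_side + 1L
      img[cbind(rr, cc)] <- 1
    }
  }
  structure(img, class = c("center_image", "matrix"),
            pixels_per_unit = ppu)
}

#' Normalized Fourier magnitude spectrum of a center image
#'
#' Two-dimensional discrete Fourier transform magnitude, shifted so the zero
#' frequency sits at the center pixel, and scaled so the maximum intensity is
#' one.  Before normalization the zero-frequency magnitude equals the total
#' lit-pixel mass (the rod count times the block area for non-colliding
#' blocks), and is the global maximum, so the normalized center pixel is 1.
#'
#' @param image matrix from [rasterize_centers()] (any nonnegative matrix).
#' @return square matrix of class `rod_spectrum` with values in `[0, 1]`,
#'   attributes `center` (row, col of zero frequency) and `dc_mass` (the
#'   pre-normalization zero-frequency magnitude).
#' @export
center_spectrum <- function(image) {
  m <- unclass(image)
  if (all(m == 0)) stop("cannot normalize the spectrum of an all-zero image")
  n <- nrow(m)
  mag <- Mod(stats::fft(m))
  shift <- c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
  mag <- mag[shift, shift, drop = FALSE]
  center <- rep(floor(n / 2) + 1L, 2L)
  dc <- mag[center[1], center[2]]
  structure(mag / max(mag), class = c("rod_spectrum", "matrix"),
            center = center, dc_mass = dc)
}

strip_cache <- new.env(parent = emptyenv())

# Pixel membership and along-strip bins for the three search strips
# (0, 60, 120 degrees through the spectrum center).  Cached per geometry.
strip_geometry <- function(n, center, strip_width) {
  key <- paste(n, center[1], center[2], strip_width, sep = "_")
  if (!is.null(strip_cache[[key]])) return(strip_cache[[key]])
  jj <- matrix(rep(seq_len(n) - center[2], each = n), n, n)   # kx (columns)
  ii <- matrix(rep(seq_len(n) - center[1], times = n), n, n)  # ky (rows)
  angles <- c(0, pi / 3, 2 * pi / 3)
  geom <- lapply(angles, function(a) {
    tt <- jj * cos(a) + ii * sin(a)
    dd <- -jj * sin(a) + ii * cos(a)
    keep <- abs(dd) <= strip_width / 2
    list(idx = which(keep), bin = as.integer(round(tt[keep])))
  })
  strip_cache[[key]] <- geom
  geom
}

# Local maxima (strictly above at least one neighbor, not below either) of
# the per-bin maximum profile of one strip, excluding bins within
# `dc_exclusion_radius` of the center.  The strict comparison uses a 1e-9
# margin so the float noise of an exactly flat spectrum creates no peaks.
strip_local_maxima <- function(spectrum, geom1, dc_exclusion_radius) {
  vals <- spectrum[geom1$idx]
  prof <- tapply(vals, geom1$bin, max)
  bins <- as.integer(names(prof))
  o <- order(bins)
  bins <- bins[o]
  prof <- as.numeric(prof[o])
  m <- length(prof)
  if (m < 3L) return(numeric(0))
  inner <- 2:(m - 1)
  eps <- 1e-9
  is_max <- prof[inner] >= prof[inner - 1] & prof[inner] >= prof[inner + 1] &
    (prof[inner] > prof[inner - 1] + eps | prof[inner] > prof[inner + 1] + eps)
  sel <- inner[is_max]
  sel <- sel[abs(bins[sel]) > dc_exclusion_radius]
  prof[sel]
}

#' Smectic order parameter by strip peak search
#'
#' Searches for the Fourier peak produced by the periodic end-to-end row
#' spacing of a smectic arrangement.  Three strips of width `strip_width`
#' pixels run through the spectrum center at 0, 60 and 120 degrees (the
#' three allowed rod directions).  Along each strip a 1-d profile of
#' per-position maxima is built; positions within `dc_exclusion_radius` of
#' the center are excluded, and the largest remaining local maximum over the
#' three strips is returned (0 when no local maximum exists, e.g. flat
#' spectra of fewer than two rods).  Since the spectrum is normalized to a
#' maximum of one at the zero frequency, this equals the ratio of the
#' row-spacing peak to the center peak.
#'
#' @param spectrum a [center_spectrum()].
#' @param strip_width strip width in pixels.
#' @param dc_exclusion_radius bins around the center excluded from the
#'   search.
#' @return value in `[0, 1]`.
#' @export
smectic_order_strips <- function(spectrum, strip_width = 10,
                                 dc_exclusion_radius = 3) {
  geom <- strip_geometry(nrow(spectrum), attr(spectrum, "center"), strip_width)
  peaks <- unlist(lapply(geom, strip_local_maxima, spectrum = spectrum,
                         dc_exclusion_radius = dc_exclusion_radius))
  if (length(peaks) == 0L) return(0)
  max(peaks)
}

#' Locate the strongest row-spacing peak in a spectrum
#'
#' Runs the same strip search as [smectic_order_strips()] and returns the
#' pixel location (row, col) of the best local maximum, for use as the fixed
#' window center of [smectic_order_window()] across a frame series.
#'
#' @inheritParams smectic_order_strips
#' @return integer `c(row, col)`, or `NULL` when no peak exists.
#' @export
find_row_spacing_peak <- function(spectrum, strip_width = 10,
                                  dc_exclusion_radius = 3) {
  geom <- strip_geometry(nrow(spectrum), attr(spectrum, "center"), strip_width)
  best <- NULL
  best_val <- -Inf
  for (g in geom) {
    vals <- spectrum[g$idx]
    prof <- tapply(vals, g$bin, max)
    bins <- as.integer(names(prof))
    o <- order(bins)
    bins <- bins[o]
    prof <- as.numeric(prof[o])
    m <- length(prof)
    if (m < 3L) next
    inner <- 2:(m - 1)
    eps <- 1e-9
    is_max <- prof[inner] >= prof[inner - 1] & prof[inner] >= prof[inner + 1] &
      (prof[inner] > prof[inner - 1] + eps | prof[inner] > prof[inner + 1] + eps)
    sel <- inner[is_max]
    sel <- sel[abs(bins[sel]) > dc_exclusion_radius]
    for (s in sel) {
      if (prof[s] > best_val) {
        in_bin <- g$idx[as.integer(round(g$bin)) == bins[s]]
        px <- in_bin[which.max(spectrum[in_bin])]
        best_val <- prof[s]
        best <- c((px - 1L) %% nrow(spectrum) + 1L,
                  (px - 1L) %/% nrow(spectrum) + 1L)
      }
    }
  }
  best
}

#' Smectic order parameter from a fixed peak window
#'
#' For frame series in which the row-spacing peak position is known and
#' stable (up to a few pixels of jitter), returns the maximum spectrum value
#' within a `window x window` pixel region centered at `peak_location`.
#' Windows extending beyond the spectrum edge are clipped.
#'
#' @param spectrum a [center_spectrum()].
#' @param peak_location integer `c(row, col)` inside the spectrum.
#' @param window window side in pixels.
#' @return value in `[0, 1]`.
#' @export
smectic_order_window <- function(spectrum, peak_location, window = 20) {
  n <- nrow(spectrum)
  stopifnot(length(peak_location) == 2L,
            all(peak_location >= 1), all(peak_location <= n))
  h <- window / 2
  rr <- max(1, floor(peak_location[1] - h)):min(n, ceiling(peak_location[1] + h))
  cc <- max(1, floor(peak_location[2] - h)):min(n, ceiling(peak_location[2] + h))
  max(spectrum[rr, cc])
}

#' Smectic order of a rod configuration
#'
#' Convenience chain: rasterize centers, take the normalized Fourier
#' spectrum, and search the three orientation strips for the row-spacing
#' peak.  Configurations with fewer than two rods have order 0 by
#' convention.
#'
#' @param x,y rod centers.
#' @param box_side box side length.
#' @inheritParams rasterize_centers
#' @inheritParams smectic_order_strips
#' @return value in `[0, 1]`.
#' @export
smectic_order <- function(x, y, box_side, grid_side = 500, pad = 5,
                          strip_width = 10, dc_exclusion_radius = 3) {
  if (length(x) < 2L) return(0)
  img <- rasterize_centers(x, y, box_side, grid_side = grid_side, pad = pad)
  smectic_order_strips(center_spectrum(img), strip_width = strip_width,
                       dc_exclusion_radius = dc_exclusion_radius)
}

#' Snap continuous angles to the nearest lattice direction
#'
#' Maps angles (degrees) to the nearest of 0, 60 or 120 degrees under
#' head-tail symmetry (distances taken modulo 180).  Ties break toward the
#' lower index.
#'
#' @param theta_deg angles in degrees.
#' @return integer orientation indices in 0:2.
#' @export
snap_orientation <- function(theta_deg) {
  ref <- c(0, 60, 120)
  d <- vapply(ref, function(a) {
    abs(((theta_deg - a + 90) %% 180) - 90)
  }, numeric(length(theta_deg)))
  d <- matrix(d, ncol = 3L)
  as.integer(apply(d, 1L, which.min) - 1L)
}

#' Order-parameter time series of frame-indexed rod detections
#'
#' For each frame: rod count, orientation fractions (angles snapped to the
#' nearest lattice direction for counting only), nematic order from the raw
#' angles, and smectic order from the fixed-window peak intensity of the
#' frame's center-image spectrum.  The window center is `peak_location` if
#' supplied, otherwise auto-detected by a strip search on the average
#' spectrum of all frames with at least two detections (the row-spacing peak
#' position is assumed stable across a movie).  Pixels within
#' `dc_exclusion_radius` of the spectrum center are masked before the window
#' maximum is taken, so the zero-frequency peak never masquerades as the
#' row-spacing peak when the two are closer than half a window.  Empty
#' frames record missing order parameters.
#'
#' @param detections data frame with columns `frame`, `x`, `y`, `theta_deg`.
#' @param box_side side length of the imaged region, same units as `x`, `y`.
#' @param frames frame identifiers to report (defaults to those present).
#' @param peak_location optional `c(row, col)` window center.
#' @inheritParams smectic_order
#' @param window window side in pixels for the per-frame peak search.
#' @return tibble with columns `frame`, `n_rods`, `frac0`, `frac1`, `frac2`,
#'   `nematic`, `smectic`.
#' @export
analyze_frames <- function(detections, box_side,
                           frames = sort(unique(detections$frame)),
                           peak_location = NULL, grid_side = 500, pad = 5,
                           strip_width = 10, dc_exclusion_radius = 3,
                           window = 20) {
  stopifnot(all(c("frame", "x", "y", "theta_deg") %in% names(detections)))
  per_frame <- lapply(frames, function(f)
    detections[detections$frame == f, , drop = FALSE])
  spectra <- lapply(per_frame, function(d) {
    if (nrow(d) < 2L) return(NULL)
    center_spectrum(rasterize_centers(d$x, d$y, box_side,
                                      grid_side = grid_side, pad = pad))
  })
  if (is.null(peak_location)) {
    have <- !vapply(spectra, is.null, logical(1))
    if (any(have)) {
      avg <- Reduce(`+`, lapply(spectra[have], unclass)) / sum(have)
      avg <- structure(avg, class = c("rod_spectrum", "matrix"),
                       center = attr(spectra[which(have)[1]][[1]], "center"))
      peak_location <- find_row_spacing_peak(avg, strip_width = strip_width,
                                             dc_exclusion_radius = dc_exclusion_radius)
    }
  }
  mask_dc <- function(sp) {
    ctr <- attr(sp, "center")
    r <- dc_exclusion_radius
    sp[(ctr[1] - r):(ctr[1] + r), (ctr[2] - r):(ctr[2] + r)] <- 0
    sp
  }
  rows <- mapply(function(f, d, sp) {
    n <- nrow(d)
    if (n == 0L)
      return(tibble::tibble(frame = f, n_rods = 0L, frac0 = 0, frac1 = 0,
                            frac2 = 0, nematic = NA_real_,
                            smectic = NA_real_))
    fr <- orientation_fractions(snap_orientation(d$theta_deg))
    nem <- nematic_order(d$theta_deg * pi / 180)
    sme <- if (is.null(sp) || is.null(peak_location)) 0
           else smectic_order_window(mask_dc(sp), peak_location,
                                     window = window)
    tibble::tibble(frame = f, n_rods = n, frac0 = fr[1], frac1 = fr[2],
                   frac2 = fr[3], nematic = nem, smectic = sme)
  }, frames, per_frame, spectra, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
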