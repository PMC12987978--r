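#' Perfect smectic lattice configuration
#'
#' Co-aligned rods on a rectangular lattice: `per_row` rods side by side in
#' each row (spaced `lateral_spacing` along the short axis) and `rows` rows
#' spaced `row_spacing` apart along the rod axis (the end-to-end direction).
#' This is the fully ordered reference state: nematic order 1 and a sharp
#' Fourier peak at the row-spacing frequency.
#'
#' @param rows,per_row lattice dimensions.
#' @param row_spacing center spacing along the rod axis; must be at least
#'   the rod length.
#' @param lateral_spacing center spacing perpendicular to the rod axis; must
#'   be at least the rod width.
#' @param orientation shared orientation index in 0:2.
#' @param box a [rod_box()].
#' @param dims a [rod_dims()].
#' @param origin lattice offset `c(x, y)` in box units.
#' @return a [surface_state()].
#' @export
perfect_smectic <- function(rows, per_row, row_spacing, lateral_spacing,
                            orientation = 0L, box = rod_box(100),
                            dims = rod_dims(7), origin = c(0.5, 0.5)) {
  if (row_spacing < dims$length || lateral_spacing < dims$width)
    stop("spacings admit no non-overlapping lattice (need row_spacing >= ",
         "length and lateral_spacing >= width)")
  a <- orientation_angle(orientation)
  u <- c(cos(a), sin(a))   # along the rod axis: rows repeat this way
  v <- c(-sin(a), cos(a))  # lateral: rods sit side by side this way
  g <- expand.grid(i = seq_len(rows) - 1L, j = seq_len(per_row) - 1L)
  pos <- cbind(origin[1] + g$i * row_spacing * u[1] + g$j * lateral_spacing * v[1],
               origin[2] + g$i * row_spacing * u[2] + g$j * lateral_spacing * v[2])
  w <- wrap_point(pos[, 1], pos[, 2], box)
  surface_state(box, dims, cbind(w$x, w$y, orientation))
}

# Random sequential adsorption with a bounded attempt budget.
rsa_fill <- function(n, box, dims, orient_fun, max_attempts = 100 * n) {
  rods <- empty_rods()
  L <- box$side_length
  attempts <- 0L
  while (nrow(rods) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- c(stats::runif(1) * L, stats::runif(1) * L, orient_fun())
    if (nrow(rods) == 0L ||
        !cpp_any_overlap(rods, cand[1], cand[2], as.integer(cand[3]),
                         L, dims$length, dims$width)) {
      rods <- rbind(rods, cand)
    }
  }
  if (nrow(rods) < n)
    stop("random sequential adsorption placed only ", nrow(rods), " of ", n,
         " rods within the attempt budget")
  rownames(rods) <- NULL
  surface_state(box, dims, rods, check = FALSE)
}

#' Nematic configuration without row structure
#'
#' Random sequential adsorption of `n` co-aligned rods: perfect orientational
#' order but no positional (row) order, so the smectic signal stays at noise
#' level.
#'
#' @param n rod count.
#' @param orientation shared orientation index.
#' @param box a [rod_box()].
#' @param dims a [rod_dims()].
#' @param max_attempts insertion attempt budget before failing.
#' @return a [surface_state()].
#' @export
nematic_no_rows <- function(n, orientation = 0L, box = rod_box(100),
                            dims = rod_dims(7), max_attempts = 100 * n) {
  rsa_fill(n, box, dims, function() orientation, max_attempts)
}

#' High-density disordered configuration
#'
#' Random sequential adsorption with orientations drawn uniformly from the
#' three lattice directions: near-equal occupancy of the three orientations
#' and neither nematic nor smectic order.
#'
#' @inheritParams nematic_no_rows
#' @return a [surface_state()].
#' @export
hdd_config <- function(n, box = rod_box(100), dims = rod_dims(7),
                       max_attempts = 100 * n) {
  rsa_fill(n, box, dims, function() sample(0:2, 1L), max_attempts)
}

#' Uniform random centers (no hard core)
#'
#' Point-process control used for the noise floor of the smectic statistic:
#' centers uniform over the box, orientations uniform over the lattice
#' directions, overlaps allowed.
#'
#' @inheritParams nematic_no_rows
#' @return matrix with columns `x`, `y`, `k`.
#' @export
random_centers <- function(n, box = rod_box(100)) {
  L <- box$side_length
  cbind(x = stats::runif(n) * L, y = stats::runif(n) * L,
        k = sample(0:2, n, replace = TRUE))
}

#' Emulate noisy rod detections of a configuration
#'
#' Produces one detection frame the way a particle-tracking pipeline on AFM
#' movies would: each rod is reported with probability `1 - dropout`, its
#' center jittered by isotropic Gaussian noise of scale `pos_jitter` (box
#' units) and its angle (60 degrees times the orientation index) jittered by
#' Gaussian noise of scale `angle_jitter` degrees; emission order is
#' shuffled.  This is test scaffolding, not a model of real AFM error
#' structure.
#'
#' @param state a [surface_state()].
#' @param pos_jitter positional noise scale, box units.
#' @param angle_jitter angular noise scale, degrees.
#' @param dropout per-rod missed-detection probability in `[0, 1)`.
#' @param frame frame identifier stored in the output.
#' @return tibble with columns `frame`, `x`, `y`, `theta_deg`.
#' @export
detection_noise <- function(state, pos_jitter = 0, angle_jitter = 0,
                            dropout = 0, frame = 1L) {
  stopifnot(pos_jitter >= 0, angle_jitter >= 0, dropout >= 0, dropout < 1)
  rods <- state$rods
  keep <- stats::runif(nrow(rods)) >= dropout
  rods <- rods[keep, , drop = FALSE]
  n <- nrow(rods)
  if (n > 0) {
    w <- wrap_point(rods[, 1] + stats::rnorm(n, sd = pos_jitter),
                    rods[, 2] + stats::rnorm(n, sd = pos_jitter), state$box)
    theta <- rods[, 3] * 60 + stats::rnorm(n, sd = angle_jitter)
    ord <- sample.int(n)
    return(tibble::tibble(frame = frame, x = w$x[ord], y = w$y[ord],
                          theta_deg = theta[ord]))
  }
  tibble::tibble(frame = frame, x = numeric(0), y = numeric(0),
                 theta_deg = numeric(0))
}

#' Surface-filling detection series toward a target configuration
#'
#' Emulates the time course of an assembling surface: frame `t` contains a
#' random subset of the target rods of size `round(fill_curve[t] * n)`, with
#' subsets nested over time (rods arrive and never leave), passed through
#' [detection_noise()].
#'
#' @param target a [surface_state()] (the final configuration).
#' @param n_frames number of frames (at least 2).
#' @param fill_curve nondecreasing vector of length `n_frames` in `[0, 1]`;
#'   the default is a sigmoid rescaled to run from exactly 0 (empty first
#'   frame) to exactly 1 (full target in the last frame).
#' @inheritParams detection_noise
#' @return tibble of detections with columns `frame`, `x`, `y`, `theta_deg`
#'   and attribute `frames = seq_len(n_frames)` (frames may be empty).
#' @export
#' @rdname filling_series
#' @export
sigmoid_fill <- function(n_frames) {
  s <- stats::plogis(seq(-4, 4, length.out = n_frames))
  (s - s[1]) / (s[n_frames] - s[1])
}

filling_series <- function(target, n_frames,
                           fill_curve = sigmoid_fill(n_frames),
                           pos_jitter = 0, angle_jitter = 0, dropout = 0) {
  stopifnot(n_frames >= 2, length(fill_curve) == n_frames,
            !is.unsorted(fill_curve), all(fill_curve >= 0), all(fill_curve <= 1))
  n <- nrow(target$rods)
  arrival <- sample.int(n)  # nested subsets: first round(f*n) arrivals
  frames <- lapply(seq_len(n_frames), function(t) {
    m <- round(fill_curve[t] * n)
    sub <- target
    sub$rods <- target$rods[arrival[seq_len(m)], , drop = FALSE]
    detection_noise(sub, pos_jitter = pos_jitter,
                    angle_jitter = angle_jitter, dropout = dropout,
                    frame = t)
  })
  out <- do.call(rbind, frames)
  attr(out, "frames") <- seq_len(n_frames)
  out
}
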