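#' @useDynLib rodphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

#' Allowed rod orientations
#'
#' Rods may point along 0, 60 or 120 degrees (orientation index k = 0, 1, 2),
#' the three equivalent binding directions of a hexagonal surface sublattice.
#'
#' @param k integer orientation index in 0:2.
#' @return angle in radians.
#' @export
orientation_angle <- function(k) {
  stopifnot(all(k %in% 0:2))
  k * pi / 3
}

#' Periodic square box
#'
#' @param side_length box side, in units of the rod width; must be positive.
#' @return a `rod_box` object.
#' @export
rod_box <- function(side_length) {
  stopifnot(is.numeric(side_length), length(side_length) == 1L,
            is.finite(side_length), side_length > 0)
  structure(list(side_length = side_length), class = "rod_box")
}

#' Rod dimensions
#'
#' `length` is the aspect ratio (the width is the unit of length, fixed at 1
#' by default).
#'
#' @param length rod length, must satisfy `length >= width`.
#' @param width rod width, default 1.
#' @return a `rod_dims` object.
#' @export
rod_dims <- function(length, width = 1) {
  stopifnot(is.numeric(length), is.numeric(width),
            width > 0, length >= width)
  structure(list(length = length, width = width), class = "rod_dims")
}

#' Wrap coordinates into the periodic box
#'
#' @param x,y coordinates (vectorized).
#' @param box a [rod_box()].
#' @return list with wrapped `x` and `y` in `[0, side_length)`.
#' @export
wrap_point <- function(x, y, box) {
  L <- box$side_length
  list(x = ((x %% L) + L) %% L, y = ((y %% L) + L) %% L)
}

#' Corners of a rod's rectangle
#'
#' Returns the four corners of the `length x width` rectangle centered at the
#' rod position with long axis along its orientation, in counter-clockwise
#' order (unwrapped: corners may fall outside the periodic box).
#'
#' @param x,y rod center.
#' @param k orientation index in 0:2.
#' @param dims a [rod_dims()].
#' @return a 4x2 matrix of (x, y) corner coordinates.
#' @export
rod_corners <- function(x, y, k, dims) {
  stopifnot(k %in% 0:2)
  a <- orientation_angle(k)
  u <- c(cos(a), sin(a))          # long axis
  v <- c(-sin(a), cos(a))         # short axis
  hl <- dims$length / 2
  hw <- dims$width / 2
  signs <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  co <- t(apply(signs, 1L, function(s) c(x, y) + s[1] * hl * u + s[2] * hw * v))
  dimnames(co) <- NULL
  co
}

#' Exact hard-core overlap of two rods
#'
#' Separating-axis test of the two rectangles' open interiors under the
#' minimum-image convention (all nine periodic images are considered when the
#' box is smaller than twice the overlap cutoff).  Exact contact does not
#' count as overlap.
#'
#' @param a,b rods given as `c(x, y, k)` numeric vectors.
#' @param box a [rod_box()].
#' @param dims a [rod_dims()].
#' @return logical.
#' @export
rods_overlap <- function(a, b, box, dims) {
  cpp_rods_overlap(a[1], a[2], as.integer(a[3]), b[1], b[2], as.integer(b[3]),
                   box$side_length, dims$length, dims$width)
}

#' Surface state: a collection of non-overlapping rods in a periodic box
#'
#' @param box a [rod_box()].
#' @param dims a [rod_dims()].
#' @param rods numeric matrix with columns `x`, `y`, `k` (may have 0 rows).
#' @param check assert the hard-core invariant on construction.
#' @return a `surface_state` object.
#' @export
surface_state <- function(box, dims, rods = empty_rods(), check = TRUE) {
  rods <- as_rod_matrix(rods)
  w <- wrap_point(rods[, 1], rods[, 2], box)
  rods[, 1] <- w$x
  rods[, 2] <- w$y
  st <- structure(list(box = box, dims = dims, rods = rods),
                  class = "surface_state")
  if (check && nrow(rods) > 1L) {
    pr <- cpp_first_overlap_pair(rods, box$side_length, dims$length, dims$width)
    if (pr[1] > 0L)
      stop("hard-core violation between rods ", pr[1], " and ", pr[2])
  }
  st
}

#' @export
print.surface_state <- function(x, ...) {
  cat(sprintf("surface_state: %d rods (l = %g, w = %g) in %g x %g box\n",
              nrow(x$rods), x$dims$length, x$dims$width,
              x$box$side_length, x$box$side_length))
  invisible(x)
}

#' @rdname surface_state
#' @export
empty_rods <- function() {
  matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "k")))
}

as_rod_matrix <- function(rods) {
  rods <- as.matrix(rods)
  if (ncol(rods) != 3L) stop("rods must have columns x, y, k")
  colnames(rods) <- c("x", "y", "k")
  storage.mode(rods) <- "double"
  rods
}

#' Does a candidate rod overlap any rod of a state?
#'
#' @param state a [surface_state()].
#' @param candidate rod as `c(x, y, k)`.
#' @param skip optional 1-based row index to exclude (the candidate's own
#'   slot when testing a translation proposal).
#' @return logical.
#' @export
candidate_overlaps <- function(state, candidate, skip = 0L) {
  cpp_any_overlap(state$rods, candidate[1], candidate[2],
                  as.integer(candidate[3]), state$box$side_length,
                  state$dims$length, state$dims$width,
                  skip = as.integer(skip) - 1L)
}

#' Assert the hard-core invariant of a configuration
#'
#' @param state a [surface_state()].
#' @return `TRUE` invisibly; errors if any pair of rods overlaps.
#' @export
assert_hard_core <- function(state) {
  pr <- cpp_first_overlap_pair(state$rods, state$box$side_length,
                               state$dims$length, state$dims$width)
  if (pr[1] > 0L)
    stop("hard-core violation between rods ", pr[1], " and ", pr[2])
  invisible(TRUE)
}
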