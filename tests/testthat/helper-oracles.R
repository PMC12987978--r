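# Independent oracles used across test files.  These deliberately avoid the
# package's separating-axis code path: the rasterization oracle samples a
# dense point grid of one rectangle and asks whether any point falls inside
# the other; the image-shift oracle re-derives periodic wrapping by rolling.

rod_frame <- function(k) {
  a <- k * pi / 3
  list(u = c(cos(a), sin(a)), v = c(-sin(a), cos(a)))
}

# Maximum over the four edge-normal axes of |d.axis| - (half_a + half_b).
# Negative values mean penetration; used only to exclude near-contact pairs.
sat_gap <- function(dx, dy, ka, kb, len, wid) {
  fa <- rod_frame(ka)
  fb <- rod_frame(kb)
  axes <- rbind(fa$u, fa$v, fb$u, fb$v)
  gaps <- apply(axes, 1L, function(ax) {
    ra <- len / 2 * abs(sum(ax * fa$u)) + wid / 2 * abs(sum(ax * fa$v))
    rb <- len / 2 * abs(sum(ax * fb$u)) + wid / 2 * abs(sum(ax * fb$v))
    abs(dx * ax[1] + dy * ax[2]) - (ra + rb)
  })
  max(gaps)
}

min_image <- function(d, L) d - L * round(d / L)

.oracle_grid <- local({
  cache <- new.env(parent = emptyenv())
  function(len, wid, step) {
    key <- paste(len, wid, step)
    if (is.null(cache[[key]])) {
      us <- seq(-len / 2 + step / 2, len / 2 - step / 2, by = step)
      vs <- seq(-wid / 2 + step / 2, wid / 2 - step / 2, by = step)
      cache[[key]] <- list(u = rep(us, times = length(vs)),
                           v = rep(vs, each = length(us)))
    }
    cache[[key]]
  }
})

# TRUE iff some interior grid point of rectangle b lies strictly inside
# rectangle a, for a given (already image-resolved) displacement of b.
raster_overlap_disp <- function(dx, dy, ka, kb, len, wid, step = 0.005) {
  if (dx * dx + dy * dy >= len^2 + wid^2) return(FALSE)
  g <- .oracle_grid(len, wid, step)
  fb <- rod_frame(kb)
  px <- dx + g$u * fb$u[1] + g$v * fb$v[1]
  py <- dy + g$u * fb$u[2] + g$v * fb$v[2]
  fa <- rod_frame(ka)
  pu <- px * fa$u[1] + py * fa$u[2]
  inside <- abs(pu) < len / 2
  if (!any(inside)) return(FALSE)
  pv <- px[inside] * fa$v[1] + py[inside] * fa$v[2]
  any(abs(pv) < wid / 2)
}

# Periodic rasterization oracle: all nine images when the box is small,
# otherwise the minimum image.
raster_overlap_oracle <- function(a, b, L, len, wid, step = 0.005) {
  dx <- min_image(b[1] - a[1], L)
  dy <- min_image(b[2] - a[2], L)
  shifts <- if (L >= 2 * sqrt(len^2 + wid^2)) {
    cbind(0, 0)
  } else {
    as.matrix(expand.grid(sx = -1:1, sy = -1:1)) * L
  }
  for (i in seq_len(nrow(shifts))) {
    if (raster_overlap_disp(dx + shifts[i, 1], dy + shifts[i, 2],
                            a[3], b[3], len, wid, step))
      return(TRUE)
  }
  FALSE
}

# Near-contact SAT gap across the images actually considered.
pbc_gap <- function(a, b, L, len, wid) {
  dx <- min_image(b[1] - a[1], L)
  dy <- min_image(b[2] - a[2], L)
  if (L >= 2 * sqrt(len^2 + wid^2)) return(sat_gap(dx, dy, a[3], b[3], len, wid))
  sh <- as.matrix(expand.grid(sx = -1:1, sy = -1:1)) * L
  min(vapply(seq_len(nrow(sh)), function(i)
    sat_gap(dx + sh[i, 1], dy + sh[i, 2], a[3], b[3], len, wid), numeric(1)))
}

# Analytic first-order Bragg value of a commensurate row lattice rasterized
# with an odd pad block: the block form factor at one period in pixels.
bragg_block_value <- function(period_px, grid_side = 500, pad = 5) {
  k <- grid_side / period_px
  dirichlet <- function(k) {
    if (k %% grid_side == 0) return(pad)
    sin(pad * pi * k / grid_side) / sin(pi * k / grid_side)
  }
  dirichlet(k) * dirichlet(0) / pad^2
}

# Small deterministic hard-core state for move-level tests.
two_rod_state <- function(gap = 0.4, L = 100, len = 7) {
  surface_state(rod_box(L), rod_dims(len),
                rbind(c(10, 10, 0), c(10 + len + gap, 10, 0)))
}
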