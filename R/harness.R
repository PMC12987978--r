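#' Parameter sweep over chemical potential, mobility, bias and aspect ratio
#'
#' Runs one seeded simulation per cell of the Cartesian grid and summarizes
#' each run by the mean nematic/smectic order, orientation fractions and
#' packing fraction over the last 10 percent of trajectory records (a
#' terminal window robust to fluctuations), plus the same quantities on the
#' final configuration.  Cells run independently with per-cell derived
#' seeds, so results do not depend on execution order; per-cell failures are
#' recorded in the `error` column and do not stop the sweep.
#'
#' @param mu_values,mobility_values numeric grids.
#' @param bias_values list of length-3 bias triples.
#' @param aspect_ratios numeric grid of rod lengths.
#' @param seeds integer replicate seeds.
#' @param ... overrides passed to [sim_params()] (e.g. `box_side`,
#'   `n_steps`, `exchange_attempts_per_step`).
#' @param keep_snapshots retain per-run snapshots (memory-heavy; off by
#'   default).
#' @return tibble with one row per (cell, seed).
#' @export
run_sweep <- function(mu_values, mobility_values, bias_values = list(c(1, 1, 1)),
                      aspect_ratios = 7, seeds = 1L, ...,
                      keep_snapshots = FALSE) {
  stopifnot(length(mu_values) > 0, length(mobility_values) > 0,
            length(bias_values) > 0, length(aspect_ratios) > 0,
            length(seeds) > 0)
  grid <- expand.grid(mu = mu_values, mobility = mobility_values,
                      bias_id = seq_along(bias_values),
                      aspect_ratio = aspect_ratios, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    bias <- bias_values[[g$bias_id]]
    cell_seed <- as.integer((as.double(g$seed) * 7919 + i * 104729) %%
                              2147483647)
    base <- tibble::tibble(mu = g$mu, mobility = g$mobility,
                           bias = paste(bias, collapse = ","),
                           aspect_ratio = g$aspect_ratio, seed = g$seed,
                           cell_seed = cell_seed)
    res <- tryCatch({
      params <- sim_params(mu = g$mu, mobility = g$mobility, bias = bias,
                           aspect_ratio = g$aspect_ratio, seed = cell_seed,
                           ...)
      sim <- run_simulation(params, keep_snapshots = keep_snapshots)
      rec <- sim$records
      tail_n <- max(1L, ceiling(0.1 * nrow(rec)))
      w <- rec[seq(nrow(rec) - tail_n + 1L, nrow(rec)), ]
      fs <- sim$final_state
      area <- params$box_side^2
      nf <- nrow(fs$rods)
      cbind(base, tibble::tibble(
        n_rods = nf,
        packing = mean(w$n_rods) * params$aspect_ratio / area,
        nematic = mean(w$nematic, na.rm = TRUE),
        smectic = mean(w$smectic, na.rm = TRUE),
        frac0 = mean(w$frac0), frac1 = mean(w$frac1), frac2 = mean(w$frac2),
        nematic_final = if (nf >= 1)
          nematic_order(orientation_angle(fs$rods[, 3])) else NA_real_,
        smectic_final = smectic_order(fs$rods[, 1], fs$rods[, 2],
                                      params$box_side),
        error = NA_character_))
    }, error = function(e) {
      cbind(base, tibble::tibble(
        n_rods = NA_integer_, packing = NA_real_, nematic = NA_real_,
        smectic = NA_real_, frac0 = NA_real_, frac1 = NA_real_,
        frac2 = NA_real_, nematic_final = NA_real_, smectic_final = NA_real_,
        error = conditionMessage(e)))
    })
    res
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Draw a rod configuration
#'
#' Rods are drawn as rectangles to scale in box coordinates, colored by
#' orientation with a fixed three-color map (rods of the same orientation
#' share the same color).
#'
#' @param state a [surface_state()].
#' @param file optional PNG path; when given the plot is also written there.
#' @param px image side in pixels when writing to file.
#' @return a ggplot object, invisibly when writing to file.
#' @export
render_snapshot <- function(state, file = NULL, px = 800) {
  pal <- c(`0` = "#D55E00", `1` = "#0072B2", `2` = "#009E73")
  L <- state$box$side_length
  n <- nrow(state$rods)
  if (n > 0) {
    polys <- lapply(seq_len(n), function(i) {
      co <- rod_corners(state$rods[i, 1], state$rods[i, 2],
                        state$rods[i, 3], state$dims)
      data.frame(x = co[, 1], y = co[, 2], id = i,
                 k = factor(unname(state$rods[i, 3]), levels = 0:2))
    })
    df <- do.call(rbind, polys)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$id,
                                          fill = .data$k)) +
      ggplot2::geom_polygon(color = NA) +
      ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                                 name = "orientation")
  } else {
    p <- ggplot2::ggplot()
  }
  p <- p + ggplot2::coord_fixed(xlim = c(0, L), ylim = c(0, L),
                                expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(file)) {
    grDevices::png(file, width = px, height = px)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
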