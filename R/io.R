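#' Write a trajectory table as CSV
#'
#' Columns: `step,n_rods,frac0,frac1,frac2,nematic,smectic,acc_trans,`
#' `acc_dep,acc_evap`.
#'
#' @param records tibble from [run_simulation()].
#' @param path output file.
#' @export
write_trajectory_csv <- function(records, path) {
  cols <- c("step", "n_rods", "frac0", "frac1", "frac2", "nematic",
            "smectic", "acc_trans", "acc_dep", "acc_evap")
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a configuration snapshot as JSON
#'
#' @param state a [surface_state()].
#' @param path output file.
#' @param step Monte Carlo step of the snapshot.
#' @export
write_snapshot_json <- function(state, path, step = NA) {
  obj <- list(box = state$box$side_length,
              dims = list(length = state$dims$length,
                          width = state$dims$width),
              step = step,
              rods = unname(apply(state$rods, 1L, function(r)
                list(r[[1]], r[[2]], as.integer(r[[3]])), simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a configuration snapshot written by [write_snapshot_json()]
#'
#' @param path JSON file.
#' @return a [surface_state()].
#' @export
read_snapshot_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rods <- if (length(obj$rods)) {
    m <- matrix(unlist(obj$rods), ncol = 3, byrow = is.list(obj$rods))
    if (!is.list(obj$rods)) m <- obj$rods
    m
  } else empty_rods()
  surface_state(rod_box(obj$box), rod_dims(obj$dims$length, obj$dims$width),
                rods)
}

#' Write run metadata (parameters, seed, package version) as JSON
#'
#' @param params a [sim_params()] or plain list.
#' @param path output file.
#' @param extra optional named list merged into the record.
#' @export
write_run_metadata <- function(params, path, extra = list()) {
  obj <- c(unclass(params), list(package_version =
             as.character(utils::packageVersion("rodphase"))), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write frame-indexed rod detections as CSV
#'
#' Header: `frame,x,y,theta_deg`.
#'
#' @param path CSV file.
#' @return tibble of detections.
#' @export
read_detections_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame", "x", "y", "theta_deg") %in% names(d)))
  tibble::as_tibble(d)
}

#' @rdname read_detections_csv
#' @param detections data frame with columns `frame`, `x`, `y`, `theta_deg`.
#' @export
write_detections_csv <- function(detections, path) {
  cols <- c("frame", "x", "y", "theta_deg")
  utils::write.csv(as.data.frame(detections)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an order-parameter time series as CSV
#'
#' Header: `frame,n_rods,frac0,frac1,frac2,nematic,smectic`.
#'
#' @param series tibble from [analyze_frames()].
#' @param path output file.
#' @export
write_timeseries_csv <- function(series, path) {
  cols <- c("frame", "n_rods", "frac0", "frac1", "frac2", "nematic",
            "smectic")
  utils::write.csv(as.data.frame(series)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
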