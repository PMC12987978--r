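#' Simulation parameters for the grand-canonical hard-rod model
#'
#' The model deposits, evaporates and translates hard rectangular rods on a
#' periodic square surface.  Rods take one of three orientations (0, 60,
#' 120 degrees); each orientation `k` carries an adsorption energy
#' `bias[k+1] * baseline_energy` (so a bias factor of 2 on a baseline of -2
#' kT gives -4 kT, i.e. twice as favorable).
#'
#' @param mu chemical potential, in kT.  Higher values favor deposition.
#' @param mobility in `[0, 1]`: each translation proposal draws each
#'   displacement component uniformly from `[-mobility * box_side,
#'   mobility * box_side]`, so 1 proposes anywhere in the box and 0 freezes
#'   all rods in place.
#' @param bias length-3 positive multipliers on the baseline energy, one per
#'   orientation.  `c(2, 1, 1)` makes orientation 0 twice as favorable.
#' @param baseline_energy adsorption energy of an unbiased rod, kT.
#' @param beta inverse temperature (energies are already in kT, so 1).
#' @param aspect_ratio rod length in units of the rod width.
#' @param box_side box side length, in rod widths.
#' @param n_steps number of Monte Carlo steps.
#' @param exchange_attempts_per_step deposition/evaporation attempts made
#'   after the translation phase of each step.
#' @param record_every steps between trajectory records.
#' @param snapshot_every steps between stored full configurations.
#' @param seed integer seed for the engine's random stream.
#' @param hard_core disable to simulate non-interacting (ideal-gas) rods,
#'   whose occupancy has a closed form useful for validating the exchange
#'   moves.
#' @param translation_mode `"displacement"` (bounded jump, the default) or
#'   `"relocation"` (with probability `mobility`, propose a uniform random
#'   position anywhere in the box).
#' @return a `sim_params` object (validated list).
#' @export
sim_params <- function(mu,
                       mobility = 1,
                       bias = c(1, 1, 1),
                       baseline_energy = -2,
                       beta = 1,
                       aspect_ratio = 7,
                       box_side = 100,
                       n_steps = 1e7,
                       exchange_attempts_per_step = 2000,
                       record_every = 1e3,
                       snapshot_every = 1e5,
                       seed = 1L,
                       hard_core = TRUE,
                       translation_mode = c("displacement", "relocation")) {
  translation_mode <- match.arg(translation_mode)
  stopifnot(is.numeric(mu), length(mu) == 1L,
            mobility >= 0, mobility <= 1,
            length(bias) == 3L, all(bias > 0),
            beta > 0, aspect_ratio >= 1, box_side > 0,
            n_steps >= 0, exchange_attempts_per_step > 0,
            record_every >= 1, snapshot_every >= 1)
  structure(list(
    mu = mu, mobility = mobility, bias = as.numeric(bias),
    baseline_energy = baseline_energy, beta = beta,
    aspect_ratio = aspect_ratio, box_side = box_side,
    n_steps = as.double(n_steps),
    exchange_attempts_per_step = as.integer(exchange_attempts_per_step),
    record_every = as.double(record_every),
    snapshot_every = as.double(snapshot_every),
    seed = as.integer(seed), hard_core = isTRUE(hard_core),
    translation_mode = translation_mode), class = "sim_params")
}

#' Adsorption energy of an orientation
#'
#' Multiplicative bias rule: orientation `k` has energy
#' `bias[k+1] * baseline_energy` (kT), so a 1.5-fold more favorable
#' orientation on the default baseline of -2 kT sits at -3 kT.
#'
#' @param k orientation index in 0:2 (vectorized).
#' @param params a [sim_params()].
#' @return energy in kT.
#' @export
orientation_energy <- function(k, params) {
  stopifnot(all(k %in% 0:2))
  params$bias[k + 1] * params$baseline_energy
}

#' Boltzmann acceptance thresholds for particle exchange
#'
#' A deposition taking the rod count from `n` to `n + 1` is accepted when a
#' uniform draw does not exceed `A * exp(beta * (mu - E)) / (n + 1)`;
#' removing one of `n` rods is accepted below `n / (A * exp(beta *
#' (mu - E)))`.  The product of the two thresholds across an `n -> n + 1 ->
#' n` round trip is identically 1 (detailed balance of the symmetric
#' proposal).
#'
#' @param n rod count before the move.
#' @param area box area `A`.
#' @param mu chemical potential, kT.
#' @param energy rod adsorption energy `E`, kT.
#' @param beta inverse temperature.
#' @return the acceptance threshold (may exceed 1, meaning always accept).
#' @export
deposit_threshold <- function(n, area, mu, energy, beta = 1) {
  area * exp(beta * (mu - energy)) / (n + 1)
}

#' @rdname deposit_threshold
#' @export
evaporation_threshold <- function(n, area, mu, energy, beta = 1) {
  n / (area * exp(beta * (mu - energy)))
}

#' Single translation attempt (reference implementation)
#'
#' Draws a proposed displacement for one rod (orientation unchanged), wraps
#' it into the box and accepts if and only if the moved rod overlaps no other
#' rod.  Uses R's RNG; the compiled engine used by [run_simulation()]
#' implements the same move with its own seeded stream.
#'
#' @param state a [surface_state()].
#' @param rod_id 1-based row index of the rod to move.
#' @param params a [sim_params()].
#' @return list with `state` (updated on acceptance) and `accepted`.
#' @export
attempt_translation <- function(state, rod_id, params) {
  stopifnot(rod_id >= 1, rod_id <= nrow(state$rods))
  L <- state$box$side_length
  rod <- state$rods[rod_id, ]
  if (params$translation_mode == "relocation") {
    if (stats::runif(1) >= params$mobility)
      return(list(state = state, accepted = TRUE))  # identity proposal
    p <- c(stats::runif(1) * L, stats::runif(1) * L)
  } else {
    d <- (2 * stats::runif(2) - 1) * params$mobility * L
    w <- wrap_point(rod[1] + d[1], rod[2] + d[2], state$box)
    p <- c(w$x, w$y)
  }
  cand <- c(p, rod[3])
  if (params$hard_core && candidate_overlaps(state, cand, skip = rod_id))
    return(list(state = state, accepted = FALSE))
  state$rods[rod_id, 1:2] <- p
  list(state = state, accepted = TRUE)
}

#' Single deposition/evaporation attempt (reference implementation)
#'
#' Picks deposition or evaporation with probability 1/2 each.  Deposition
#' draws a uniform position and orientation, rejects on hard-core overlap,
#' then applies the Boltzmann criterion of [deposit_threshold()].
#' Evaporation picks a rod uniformly (rejecting outright when the surface is
#' empty) and applies [evaporation_threshold()].
#'
#' @inheritParams attempt_translation
#' @return list with `state`, `kind` (`"deposit"` or `"evaporate"`) and
#'   `accepted`.
#' @export
attempt_exchange <- function(state, params) {
  L <- state$box$side_length
  A <- L^2
  n <- nrow(state$rods)
  if (stats::runif(1) < 0.5) {
    pos <- stats::runif(2) * L
    k <- min(floor(stats::runif(1) * 3), 2)
    cand <- c(pos, k)
    if (params$hard_core && candidate_overlaps(state, cand))
      return(list(state = state, kind = "deposit", accepted = FALSE))
    thr <- deposit_threshold(n, A, params$mu,
                             orientation_energy(k, params), params$beta)
    if (stats::runif(1) <= thr) {
      state$rods <- rbind(state$rods, cand)
      rownames(state$rods) <- NULL
      return(list(state = state, kind = "deposit", accepted = TRUE))
    }
    return(list(state = state, kind = "deposit", accepted = FALSE))
  }
  if (n == 0)
    return(list(state = state, kind = "evaporate", accepted = FALSE))
  idx <- min(floor(stats::runif(1) * n) + 1, n)
  thr <- evaporation_threshold(n, A, params$mu,
                               orientation_energy(state$rods[idx, 3], params),
                               params$beta)
  if (stats::runif(1) <= thr) {
    state$rods <- state$rods[-idx, , drop = FALSE]
    return(list(state = state, kind = "evaporate", accepted = TRUE))
  }
  list(state = state, kind = "evaporate", accepted = FALSE)
}

#' One Monte Carlo step (reference implementation)
#'
#' A step is one translation attempt per rod existing at the start of the
#' step, followed by `exchange_attempts_per_step` deposition/evaporation
#' attempts.
#'
#' @inheritParams attempt_translation
#' @return list with `state` and counters `acc_trans`, `acc_dep`, `acc_evap`.
#' @export
mc_step <- function(state, params) {
  acc_trans <- acc_dep <- acc_evap <- 0L
  n0 <- nrow(state$rods)  # rods deposited mid-step are not translated
  for (i in seq_len(n0)) {
    r <- attempt_translation(state, i, params)
    state <- r$state
    acc_trans <- acc_trans + r$accepted
  }
  for (e in seq_len(params$exchange_attempts_per_step)) {
    r <- attempt_exchange(state, params)
    state <- r$state
    if (r$accepted) {
      if (r$kind == "deposit") acc_dep <- acc_dep + 1L
      else acc_evap <- acc_evap + 1L
    }
  }
  list(state = state, acc_trans = acc_trans, acc_dep = acc_dep,
       acc_evap = acc_evap)
}

engine_from_params <- function(params) {
  cpp_engine_create(params$box_side, params$aspect_ratio, 1.0,
                    params$beta, params$mu, params$baseline_energy,
                    params$bias, params$mobility,
                    params$exchange_attempts_per_step,
                    params$hard_core,
                    if (params$translation_mode == "relocation") 1L else 0L,
                    params$seed)
}

engine_state_to_surface <- function(es, params) {
  rods <- cbind(x = es$x, y = es$y, k = as.numeric(es$k))
  surface_state(rod_box(params$box_side), rod_dims(params$aspect_ratio),
                rods, check = FALSE)
}

record_from_state <- function(state, es, smectic_setup, order = TRUE) {
  n <- nrow(state$rods)
  fr <- orientation_fractions(state$rods[, 3], n)
  nem <- if (order && n >= 1)
    nematic_order(orientation_angle(state$rods[, 3])) else NA_real_
  sme <- if (order && n >= 2) {
    img <- rasterize_centers(state$rods[, 1], state$rods[, 2],
                             state$box$side_length,
                             grid_side = smectic_setup$grid_side,
                             pad = smectic_setup$pad)
    smectic_order_strips(center_spectrum(img),
                         strip_width = smectic_setup$strip_width,
                         dc_exclusion_radius = smectic_setup$dc_exclusion_radius)
  } else if (order) 0 else NA_real_
  tibble::tibble(step = es$step, n_rods = n,
                 frac0 = fr[1], frac1 = fr[2], frac2 = fr[3],
                 nematic = nem, smectic = sme,
                 acc_trans = es$acc_trans, acc_dep = es$acc_dep,
                 acc_evap = es$acc_evap)
}

#' Run a grand-canonical Monte Carlo simulation
#'
#' Starts from an empty box and executes `n_steps` Monte Carlo steps with
#' the compiled engine, emitting a trajectory record (rod count, orientation
#' fractions, nematic and smectic order, cumulative acceptance counters)
#' every `record_every` steps and a full configuration snapshot every
#' `snapshot_every` steps.  An initial record (and snapshot) at step 0 is
#' always included.  Runs with identical parameters and seed reproduce
#' identical trajectories.
#'
#' @param params a [sim_params()].
#' @param keep_snapshots store configurations at snapshot times (the final
#'   state is always returned).
#' @param order compute nematic/smectic order per record (disable for runs
#'   where only counts are needed; order columns are then `NA`).
#' @param smectic_setup list of rasterization/peak-search settings passed to
#'   the smectic order computation.
#' @return list with `records` (tibble), `snapshots` (list of
#'   `list(step, state)`), `final_state` and `params`.
#' @export
run_simulation <- function(params, keep_snapshots = TRUE, order = TRUE,
                           smectic_setup = list(grid_side = 500, pad = 5,
                                                strip_width = 10,
                                                dc_exclusion_radius = 3)) {
  eng <- engine_from_params(params)
  n_steps <- params$n_steps
  rec_times <- unique(c(seq(0, n_steps, by = params$record_every), n_steps))
  snap_times <- if (n_steps >= params$snapshot_every)
    seq(params$snapshot_every, n_steps, by = params$snapshot_every) else numeric(0)
  events <- sort(unique(c(0, rec_times, snap_times)))
  records <- vector("list", length(rec_times))
  snapshots <- list()
  ri <- 0L
  now <- 0
  state <- NULL
  for (tm in events) {
    if (tm > now) {
      cpp_engine_run(eng, as.integer(tm - now))
      now <- tm
    }
    es <- cpp_engine_state(eng)
    state <- engine_state_to_surface(es, params)
    if (tm %in% rec_times) {
      ri <- ri + 1L
      records[[ri]] <- record_from_state(state, es, smectic_setup, order)
    }
    if (keep_snapshots && (tm == 0 || tm %in% snap_times))
      snapshots[[length(snapshots) + 1L]] <- list(step = tm, state = state)
  }
  list(records = do.call(rbind, records[seq_len(ri)]),
       snapshots = snapshots, final_state = state, params = params)
}
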