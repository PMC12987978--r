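test_that("orientation energy applies the multiplicative bias rule", {
  p <- sim_params(mu = 1, bias = c(1.5, 1, 2))
  expect_identical(orientation_energy(0, p), -3)
  expect_identical(orientation_energy(1, p), -2)
  expect_identical(orientation_energy(2, p), -4)
  expect_identical(orientation_energy(c(0, 1, 2), p), c(-3, -2, -4))
  expect_error(orientation_energy(3, p))
})

test_that("deposit and evaporation thresholds satisfy detailed balance", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(0:500, 1)
    A <- runif(1, 1, 1e4)
    mu <- runif(1, -5, 9)
    E <- runif(1, -5, 0)
    beta <- runif(1, 0.5, 2)
    expect_equal(deposit_threshold(n, A, mu, E, beta) *
                   evaporation_threshold(n + 1, A, mu, E, beta), 1)
  }
})

test_that("translation attempts respect mobility and the hard core", {
  st <- two_rod_state(gap = 2)
  p0 <- sim_params(mu = 1, mobility = 0)
  set.seed(1)
  r <- attempt_translation(st, 1, p0)
  expect_true(r$accepted)  # identity proposal cannot overlap
  expect_identical(r$state$rods, st$rods)

  single <- surface_state(rod_box(100), rod_dims(7), rbind(c(50, 50, 1)))
  p5 <- sim_params(mu = 1, mobility = 0.5)
  set.seed(2)
  for (i in 1:50) {
    r <- attempt_translation(single, 1, p5)
    expect_true(r$accepted)
    single <- r$state
  }

  # near-contact pair, tiny mobility: rejections occur exactly when the
  # proposal overlaps, and rejected attempts leave the state untouched
  near <- two_rod_state(gap = 0.1)
  ptiny <- sim_params(mu = 1, mobility = 0.002)
  seen <- c(acc = 0L, rej = 0L)
  set.seed(3)
  for (i in 1:200) {
    r <- attempt_translation(near, 1, ptiny)
    if (r$accepted) {
      seen["acc"] <- seen["acc"] + 1L
      expect_false(rods_overlap(r$state$rods[1, ], r$state$rods[2, ],
                                near$box, near$dims))
      near <- r$state
    } else {
      seen["rej"] <- seen["rej"] + 1L
      expect_identical(r$state$rods, near$rods)
    }
  }
  expect_true(all(seen > 0L))
})

test_that("deposition follows the Boltzmann criterion in an empty unit box", {
  # A = 1, beta = 1, mu = -3, E = -2: threshold exp(-1)
  p <- sim_params(mu = -3, box_side = 1, aspect_ratio = 1, hard_core = FALSE)
  empty <- surface_state(rod_box(1), rod_dims(1))
  dep <- acc <- 0L
  set.seed(11)
  for (i in 1:100000) {
    r <- attempt_exchange(empty, p)
    if (r$kind == "deposit") {
      dep <- dep + 1L
      acc <- acc + r$accepted
    }
  }
  expect_equal(acc / dep, exp(-1), tolerance = 0.005 / exp(-1))
})

test_that("evaporation: rejected on empty surfaces, certain for a lone cheap rod", {
  p <- sim_params(mu = -3, box_side = 1, aspect_ratio = 1, hard_core = FALSE)
  empty <- surface_state(rod_box(1), rod_dims(1))
  one <- surface_state(rod_box(1), rod_dims(1), rbind(c(0.5, 0.5, 0)),
                       check = FALSE)
  # threshold n / (A exp(beta (mu - E))) = e > 1: always accepted
  expect_gt(evaporation_threshold(1, 1, -3, -2), 1)
  set.seed(4)
  evap_seen <- 0L
  for (i in 1:200) {
    r0 <- attempt_exchange(empty, p)
    if (r0$kind == "evaporate") expect_false(r0$accepted)
    r1 <- attempt_exchange(one, p)
    if (r1$kind == "evaporate") {
      evap_seen <- evap_seen + 1L
      expect_true(r1$accepted)
      expect_identical(nrow(r1$state$rods), 0L)
    }
  }
  expect_gt(evap_seen, 0L)
})

test_that("a step translates rods existing at step start, then exchanges", {
  # engine counters from one step of an empty box
  p <- sim_params(mu = -3, box_side = 20, aspect_ratio = 7,
                  exchange_attempts_per_step = 2000, seed = 9)
  eng <- rodphase:::engine_from_params(p)
  rodphase:::cpp_engine_run(eng, 1L)
  es <- rodphase:::cpp_engine_state(eng)
  expect_identical(es$att_trans, 0)
  expect_identical(es$att_dep + es$att_evap, 2000)

  # zero mobility: translation phase is a no-op on positions (R reference)
  st <- two_rod_state(gap = 3, L = 30)
  pz <- sim_params(mu = 8, mobility = 0, box_side = 30,
                   exchange_attempts_per_step = 50)
  set.seed(6)
  r <- mc_step(st, pz)
  expect_identical(r$state$rods[1:2, ], st$rods)
  expect_identical(r$acc_trans, 2L)  # identity proposals always accepted
})

test_that("zero mobility freezes engine rod positions", {
  # at mu = 8 evaporation is effectively never accepted, so every initial
  # rod must keep its exact position and orientation through the run
  init <- perfect_smectic(3, 3, 10, 3, box = rod_box(30), dims = rod_dims(7))
  p <- sim_params(mu = 8, mobility = 0, box_side = 30, aspect_ratio = 7,
                  n_steps = 0, exchange_attempts_per_step = 100, seed = 21)
  eng <- rodphase:::engine_from_params(p)
  rodphase:::cpp_engine_insert(eng, init$rods)
  rodphase:::cpp_engine_run(eng, 50L)
  es <- rodphase:::cpp_engine_state(eng)
  key <- function(x, y, k) paste(round(x, 9), round(y, 9), k)
  expect_true(all(key(init$rods[, 1], init$rods[, 2], init$rods[, 3]) %in%
                    key(es$x, es$y, es$k)))
  expect_gte(es$n_rods, nrow(init$rods))
})

test_that("snapshots never contain overlapping pairs", {
  p <- sim_params(mu = 6, mobility = 0.5, box_side = 30, aspect_ratio = 7,
                  n_steps = 2000, exchange_attempts_per_step = 100,
                  record_every = 500, snapshot_every = 500, seed = 17)
  sim <- run_simulation(p, order = FALSE)
  expect_gt(length(sim$snapshots), 2)
  for (sn in sim$snapshots) expect_true(assert_hard_core(sn$state))
  expect_true(assert_hard_core(sim$final_state))
})

test_that("adsorption from an empty box rises to a plateau", {
  p <- sim_params(mu = 6, mobility = 0.5, box_side = 50, aspect_ratio = 7,
                  n_steps = 2e4, exchange_attempts_per_step = 500,
                  record_every = 200, snapshot_every = 1e9, seed = 23)
  sim <- run_simulation(p, keep_snapshots = FALSE, order = FALSE)
  n <- sim$records$n_rods
  sm <- stats::filter(n, rep(1 / 11, 11), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_gt(stats::cor(sm, seq_along(sm), method = "spearman"), 0.8)
  expect_gt(mean(tail(n, 10)), 0.8 * max(n))
  expect_identical(n[1], 0L)  # starts from an empty box
})

test_that("ideal-gas limit recovers the grand-canonical Poisson mean", {
  p <- sim_params(mu = -3, box_side = 5, aspect_ratio = 1, hard_core = FALSE,
                  n_steps = 1500, exchange_attempts_per_step = 20,
                  record_every = 5, snapshot_every = 1e9, seed = 5)
  sim <- run_simulation(p, keep_snapshots = FALSE, order = FALSE)
  n <- sim$records$n_rods[sim$records$step > 250]
  target <- 25 * exp(-1)
  se <- stats::sd(n) / sqrt(length(n) / 4)  # conservative for autocorrelation
  expect_lt(abs(mean(n) - target), 3 * se)
})

test_that("n_steps = 0 yields only the initial record", {
  p <- sim_params(mu = 2, box_side = 20, n_steps = 0, seed = 1)
  sim <- run_simulation(p)
  expect_identical(nrow(sim$records), 1L)
  expect_identical(sim$records$step, 0)
  expect_identical(sim$records$n_rods, 0L)
  expect_identical(nrow(sim$final_state$rods), 0L)
})

test_that("identical seeds reproduce identical trajectories", {
  p <- sim_params(mu = 4, mobility = 0.5, box_side = 30, aspect_ratio = 7,
                  n_steps = 1000, exchange_attempts_per_step = 100,
                  record_every = 200, snapshot_every = 500, seed = 33)
  s1 <- run_simulation(p)
  s2 <- run_simulation(p)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$final_state$rods, s2$final_state$rods)
  p2 <- p
  p2$seed <- 34L
  s3 <- run_simulation(p2)
  expect_false(identical(s1$records, s3$records))
})

test_that("an orientation bias enriches that orientation when turnover is fast", {
  # at mu = 3 the evaporation rate allows many orientation-changing
  # exchanges within the run, so the 2x bias visibly enriches orientation 0
  frac0 <- function(bias, seed) {
    p <- sim_params(mu = 3, mobility = 1, bias = bias, aspect_ratio = 7,
                    box_side = 50, n_steps = 2e4,
                    exchange_attempts_per_step = 500, record_every = 2e3,
                    snapshot_every = 1e9, seed = seed)
    sim <- run_simulation(p, keep_snapshots = FALSE, order = FALSE)
    mean(tail(sim$records$frac0, 3))
  }
  for (s in 1:3) {
    expect_gt(frac0(c(2, 1, 1), s), frac0(c(1, 1, 1), s))
  }
})
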