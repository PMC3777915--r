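test_that("noise statistics recover known inputs", {
  tr <- data.frame(time = seq(0, 100, 0.1), a_mean = 0.4)
  ns <- noise_stats(tr, burn_in = 10)
  expect_equal(ns$a0, 0.4)
  expect_equal(ns$sigma_aa, 0)
  # white noise of known variance
  set.seed(1)
  s <- 0.03
  tr2 <- data.frame(time = seq(0, 500, 0.1),
                    a_mean = 0.4 + rnorm(5001, 0, s))
  ns2 <- noise_stats(tr2, burn_in = 0)
  expect_equal(sqrt(ns2$sigma_aa), s, tolerance = 0.05)
  expect_equal(ns2$rel_noise, s / 0.4, tolerance = 0.05)
  expect_error(noise_stats(tr, burn_in = 1000), "burn_in")
})

test_that("adaptation precision is one for a perfect return to baseline", {
  prot <- ligand_protocol("step", L0 = 0, L1 = 1000, t_step = 100)
  tt <- seq(0, 500, 0.5)
  a <- ifelse(tt < 100, 0.4, 0.4 - 0.3 * exp(-(tt - 100) / 40))
  ap <- adaptation_precision(data.frame(time = tt, a_mean = a), prot)
  expect_equal(ap$precision, 1, tolerance = 0.01)
  # an imprecise trace scores the documented deficit
  a2 <- ifelse(tt < 100, 0.4, 0.3)
  ap2 <- adaptation_precision(data.frame(time = tt, a_mean = a2), prot)
  expect_equal(ap2$precision, 1 - 0.1 / 0.4, tolerance = 1e-9)
  expect_error(adaptation_precision(data.frame(time = tt, a_mean = a),
                                    ligand_protocol("constant", 5)),
               "step")
})

test_that("the mean-field model adapts precisely to steps of either size", {
  # integrate the localized mean-field model through a step and score it
  p <- meanfield_params()
  st <- mf_steady_state(0, p)
  prot <- ligand_protocol("step", L0 = 0, L1 = 1000, t_step = 100)
  f <- function(t, y, parms) list(mf_rhs(y, protocol_ligand(prot, t), p))
  tt <- seq(0, 3000, 1)
  out <- deSolve::lsoda(c(m = st$m0, Rstar = st$Rstar, Bstar = st$Bstar),
                        tt, f, NULL, rtol = 1e-10, atol = 1e-10)
  a <- mwc_activity(pmin(pmax(out[, "m"], 0), 48),
                    protocol_ligand(prot, tt), p$mwc)
  ap <- adaptation_precision(data.frame(time = tt, a_mean = a), prot)
  expect_equal(ap$precision, 1, tolerance = 0.01)
})

test_that("ramp plateaus fall monotonically with the up-ramp rate", {
  rr <- ramp_response(c(0, 0.005, 0.02), engine = "meanfield",
                      params = meanfield_params(), duration = 500)
  expect_equal(rr$plateau[1], mf_steady_state(84, meanfield_params())$a0,
               tolerance = 0.02)
  expect_true(all(diff(rr$plateau) < 0))
})

test_that("protocol evaluation matches its definition", {
  pr <- ligand_protocol("ramp", rate = 0.01)
  expect_equal(protocol_ligand(pr, 0), 84)
  expect_equal(protocol_ligand(pr, 50), 84 * exp(0.5))
  expect_equal(protocol_ligand(pr, 1e4), 620)  # clipped at the bound
  ps <- ligand_protocol("step", L0 = 2, L1 = 7, t_step = 10)
  expect_equal(protocol_ligand(ps, c(9.9, 10.1)), c(2, 7))
  expect_error(ligand_protocol("step", L0 = 0), "L1")
})

test_that("analytic scans are deterministic and carry steady-state columns", {
  s1 <- param_scan(range = c(0.5, 1, 2), engine = "meanfield")
  s2 <- param_scan(range = c(0.5, 1, 2), engine = "meanfield")
  expect_identical(s1, s2)
  expect_true(all(diff(s1$a0) > 0))  # more CheR, more activity
  s3 <- param_scan(range = c(0.5, 1), engine = "lna")
  expect_true(all(is.finite(s3$rel_noise)))
})

test_that("population sampling is stratified, ratio-preserving, reproducible", {
  sp <- population_spec(n_cells = 8)
  expect_length(sp$multipliers, 8)
  expect_true(all(sp$multipliers > 0.45 & sp$multipliers < 2.2))
  expect_identical(sp$multipliers, population_spec(n_cells = 8)$multipliers)
  # ratio preservation: cheR/cheB constant across realized cells
  lat <- tiny_lattice()
  pop <- population_run(population_spec(n_cells = 3, sigma_ln = 0.2), lat,
                        rate_set(), seed = 2, burn_in = 60, duration = 60)
  expect_equal(nrow(pop), 3)
  dens_R <- pop$cheR / pop$dimers
  expect_lt(max(dens_R) - min(dens_R), 0.3 * mean(dens_R) + 1 / min(pop$dimers))
})

test_that("processivity from a synthetic contact log is exact", {
  # enzyme 0: one residence [1, 11] s visiting dimers 4, 5, 4, 6 -> 3 unique
  # enzyme 1: two residences of 5 s each, one dimer per residence
  log <- data.frame(
    time = c(1, 2, 3.5, 4, 9, 11,   2, 3, 7,  10, 12, 15),
    enzyme = c(0, 0, 0, 0, 0, 0,    1, 1, 1,  1, 1, 1),
    dimer = c(-1, 4, 5, 4, 6, -1,  -1, 2, -1, -1, 9, -1),
    kind = c(1, 0, 0, 0, 0, 2,      1, 0, 2,  1, 0, 2))
  # note: dimer 4 recontacted at t = 4 is not a new unique visit
  pr <- processivity_rate(log)
  expect_equal(unname(pr$visits[["all"]]), 5)
  expect_equal(unname(pr$loc_time[["all"]]), 10 + 5 + 5)
  expect_equal(unname(pr$rate[["all"]]), 5 / 20)
  # windowing restricts both visits and localized time (contacts at
  # t = 2, 3.5 for enzyme 0 and t = 3 for enzyme 1 fall inside [0, 8])
  prw <- processivity_rate(log, window = c(0, 8))
  expect_equal(unname(prw$visits[["all"]]), 3)
  # species split
  prs <- processivity_rate(log, enzyme_species = c(0L, 1L))
  expect_equal(unname(prs$visits[["cheR"]]), 3)
  expect_equal(unname(prs$visits[["cheB"]]), 2)
})

test_that("log-based and online processivity agree on a simulated run", {
  lat <- small_lattice()
  cp <- list(cheR = 3L, cheB = 5L, dimers = lat$n_dimers)
  tr <- simulate_lattice(lat, rate_set(), cp, duration = 300, seed = 77,
                         log_contacts = TRUE)
  fin <- attr(tr, "final_state")
  on <- processivity_rate(tr)
  off <- processivity_rate(attr(tr, "contacts"), window = c(0, 300),
                           enzyme_species = fin$species)
  expect_equal(unname(on$visits[["cheR"]]), unname(off$visits[["cheR"]]))
  expect_equal(unname(on$visits[["cheB"]]), unname(off$visits[["cheB"]]))
  expect_equal(unname(on$loc_time[["cheR"]]), unname(off$loc_time[["cheR"]]),
               tolerance = 1e-6)
  expect_equal(unname(on$loc_time[["cheB"]]), unname(off$loc_time[["cheB"]]),
               tolerance = 1e-6)
})

test_that("activity tracks the localized enzyme ratio in the adapted state", {
  lat <- build_lattice(8, 8)
  # the ratio fluctuations are slow; pool the correlation over two
  # independent stationary windows to beat the small number of effective
  # samples per trace
  cors <- vapply(c(23, 24), function(s) {
    eq <- equilibrate_lattice(lat, rate_set(), copy_numbers(lat),
                              burn_in = 500, duration = 1000, seed = s)
    tr <- eq$trace
    sm_a <- smooth_trace(tr, 30)
    ratio <- tr$loc_cheR / pmax(tr$loc_cheBp_active, 1)
    sm_r <- as.numeric(stats::filter(ratio, rep(1 / 301, 301), sides = 2))
    keep <- !is.na(sm_r)
    stats::cor(sm_a[keep], sm_r[keep])
  }, numeric(1))
  expect_gt(mean(cors), 0)
})

test_that("smoothing is display-only and windowed correctly", {
  tr <- data.frame(time = seq(0, 100, 0.1), a_mean = rep(c(0.2, 0.6), 501)[1:1001])
  sm <- smooth_trace(tr, 10)
  expect_equal(length(sm), nrow(tr))
  expect_lt(max(abs(sm[100:900] - 0.4)), 0.01)
})
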