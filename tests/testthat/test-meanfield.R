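# a symmetric parameterization: with d_p = 0 the bulk CheB-P pool saturates
# (phi = 1) and the CheB side becomes the mirror image of the CheR side, so
# the steady state must sit exactly at a0 = 1/2
symmetric_params <- function(K = 0.05) {
  meanfield_params(K_r = K, K_b = K, d_p = 0, a_p = 5,
                   k_t_minus_r = 1, k_t_minus_b = 1,
                   k_t_plus_r = 0.1, k_t_plus_b = 0.1,
                   k_r = 2, k_b = 2, B_Tot = 140)
}

test_that("modification-site occupancy follows the local binding equilibrium", {
  p <- meanfield_params()
  st <- list(Rstar = 70, Bstar = 120)
  # vanishing affinity removes the doubly bound pool
  p_inf <- p; p_inf$K_r <- 1e9
  expect_lt(mf_bound_enzymes(st, 0.5, p_inf)$Rdouble, 1e-6)
  # symmetry at a = 1/2 with equal constants and pools
  p_eq <- p; p_eq$K_b <- p_eq$K_r
  be <- mf_bound_enzymes(list(Rstar = 50, Bstar = 50), 0.5, p_eq)
  expect_equal(be$Rdouble, be$Bdouble)
  # direct evaluation: K_r = 0.01, a = 0.3 -> fraction 0.7/0.71
  p2 <- p; p2$K_r <- 0.01
  be2 <- mf_bound_enzymes(list(Rstar = 100, Bstar = 0), 0.3, p2)
  expect_equal(be2$Rdouble / 100, 0.7 / 0.71, tolerance = 1e-12)
  # occupancy fraction matches a two-state bind/unbind micro-simulation:
  # bind at rate kon * (1 - a), unbind at koff, K = koff/kon
  kon <- 50; koff <- 1; a <- 0.3
  set.seed(4)
  tb <- 0; tf <- 0; bound <- FALSE; t <- 0
  while (t < 4000) {
    dt <- rexp(1, if (bound) koff else kon * (1 - a))
    if (bound) tb <- tb + dt else tf <- tf + dt
    bound <- !bound; t <- t + dt
  }
  p3 <- p; p3$K_r <- koff / kon
  frac <- mf_bound_enzymes(list(Rstar = 1, Bstar = 0), a, p3)$Rdouble
  expect_equal(tb / (tb + tf), frac, tolerance = 0.03)
})

test_that("derivatives vanish at the steady state and respect one-sided limits", {
  p <- meanfield_params()
  st <- mf_steady_state(0, p)
  d <- mf_rhs(c(m = st$m0, Rstar = st$Rstar, Bstar = st$Bstar), 0, p)
  expect_lt(max(abs(d)), 1e-10)
  # no CheB-P localization possible: methylation can only increase
  p0 <- p; p0$k_t_plus_b <- 0
  for (m in c(1, 10, 30)) {
    d0 <- mf_rhs(c(m = m, Rstar = 50, Bstar = 0), 0, p0)
    expect_gte(d0[["m"]], 0)
  }
})

test_that("root solver and ODE relaxation find the same steady state", {
  for (p in list(meanfield_params(), symmetric_params(),
                 meanfield_params(R_Tot = 60, K_r = 0.1))) {
    st <- mf_steady_state(0, p)
    relaxed <- mf_relax(p, L = 0)
    expect_equal(unname(relaxed["m"]), st$m0, tolerance = 1e-6)
    expect_equal(unname(relaxed["Rstar"]), st$Rstar, tolerance = 1e-6)
    expect_equal(unname(relaxed["Bstar"]), st$Bstar, tolerance = 1e-6)
  }
})

test_that("the localized model adapts precisely: a0 independent of ligand", {
  for (p in list(meanfield_params(), symmetric_params(),
                 meanfield_params(R_Tot = 300, B_Tot = 150))) {
    a_ref <- mf_steady_state(0, p)$a0
    for (L in c(1, 10, 100, 1000))
      expect_equal(mf_steady_state(L, p)$a0, a_ref, tolerance = 1e-10)
  }
  # relaxation from a perturbed state reaches the same activity at 0 and
  # 100 uM ligand
  p <- meanfield_params()
  for (L in c(0, 100)) {
    st <- mf_relax(p, L = L, state0 = c(m = 20, Rstar = 10, Bstar = 10))
    a <- mwc_activity(st[["m"]], L, p$mwc)
    expect_equal(a, mf_steady_state(0, p)$a0, tolerance = 1e-6)
  }
})

test_that("symmetric kinetics put the adapted activity at one half", {
  expect_equal(mf_steady_state(0, symmetric_params())$a0, 0.5,
               tolerance = 1e-10)
})

test_that("one enzyme absent gives the flagged nonfunctional regimes", {
  p <- meanfield_params(B_Tot = 0)
  st <- mf_steady_state(0, p)
  expect_false(st$interior)
  expect_gt(st$a0, 1 - 1e-6)   # fully active: methylation unopposed
})

test_that("effective constants reduce the model to Goldbeter-Koshland form", {
  p <- meanfield_params()
  # tether release -> 0 removes the localization penalty
  p0 <- p; p0$k_t_minus_r <- 0; p0$k_t_minus_b <- 0
  kt <- mf_effective_constants(p0, 0.4)
  expect_equal(kt$K_tilde_r, p$K_r)
  expect_equal(kt$K_tilde_b, p$K_b)
  # effective constants never fall below the bare ones
  for (a in c(0.1, 0.3, 0.5, 0.9)) {
    kt <- mf_effective_constants(p, a)
    expect_gte(kt$K_tilde_r, p$K_r)
    expect_gte(kt$K_tilde_b, p$K_b)
  }
  # closed GK form reproduces the full steady state across a K grid
  for (K in 10^seq(-3, 0, length.out = 7)) {
    pk <- meanfield_params(K_r = K, K_b = K)
    expect_equal(mf_gk_steady(pk), mf_steady_state(0, pk)$a0,
                 tolerance = 1e-8)
  }
})

test_that("gk_root solves the covalent-modification balance", {
  expect_equal(gk_root(1, 0.3, 0.3), 0.5)
  expect_equal(gk_root(1, 0.2, 0.6), 0.6 / 0.8)
  # residual check over a grid, against direct root finding
  for (u in c(0.3, 0.9, 1.5, 4)) for (K in c(1e-3, 0.1, 10)) {
    a <- gk_root(u, K, K)
    expect_equal(u * (1 - a) / ((1 - a) + K), a / (a + K), tolerance = 1e-9)
  }
  # monotone in the velocity ratio
  roots <- vapply(seq(0.5, 2, by = 0.1), gk_root, numeric(1),
                  K1 = 0.05, K2 = 0.05)
  expect_true(all(diff(roots) > 0))
  # zero-order ultrasensitivity: K = 1e-3 switches within a few percent
  expect_lt(gk_root(0.97, 1e-3, 1e-3), 0.1)
  expect_gt(gk_root(1.03, 1e-3, 1e-3), 0.9)
  # K = 10: quasi-linear response; first-order expansion gives
  # a ~ u/(1+u) for K >> 1, so da/du = 1/4 at u = 1
  d1 <- gk_root(1.05, 10, 10) - gk_root(0.95, 10, 10)
  expect_equal(d1 / 0.1, 0.25, tolerance = 0.1)
})

test_that("robustness criterion: K_tilde near one flattens the enzyme-ratio curve", {
  # same bare saturation K = 0.005; tether exchange sets K_tilde = K(1+q/p)
  mk <- function(Ktilde) {
    K <- 0.005; qp <- Ktilde / K - 1
    meanfield_params(K_r = K, K_b = K, d_p = 0, a_p = 100,
                     k_t_minus_r = qp / 15, k_t_minus_b = qp / 15,
                     k_b = 2.0, B_Tot = 140)
  }
  slope <- function(p) {
    h <- 0.02
    p1 <- p; p2 <- p
    p1$R_Tot <- p$R_Tot * (1 - h); p2$R_Tot <- p$R_Tot * (1 + h)
    abs(log(mf_steady_state(0, p2)$a0) - log(mf_steady_state(0, p1)$a0)) /
      (2 * h)
  }
  expect_equal(mf_steady_state(0, mk(1))$a0, 0.5, tolerance = 1e-8)
  expect_gt(slope(mk(0.01)) / slope(mk(1)), 10)
})

test_that("B1 baseline: shallow response, B2 markedly steeper", {
  pb <- b1_params()
  st <- b1_steady_state(0, pb)
  expect_true(st$interior)
  expect_equal(st$a0, 1 / 3, tolerance = 0.02)
  # precise adaptation holds for B1 as well (same activity-only structure)
  expect_equal(b1_steady_state(500, pb)$a0, st$a0, tolerance = 1e-10)
  # symmetric construction reaches one half
  psym <- b1_params(K_r = 0.3, K_b = 0.3, d_p = 0, a_p = 10,
                    k_r = 2, k_b = 2, B_Tot = 140)
  expect_equal(b1_steady_state(0, psym)$a0, 0.5, tolerance = 1e-10)
  slope_b <- function(pp) {
    h <- 0.02
    p1 <- pp; p2 <- pp
    p1$R_Tot <- pp$R_Tot * (1 - h); p2$R_Tot <- pp$R_Tot * (1 + h)
    abs(log(b1_steady_state(0, p2)$a0) - log(b1_steady_state(0, p1)$a0)) /
      (2 * h)
  }
  pb2 <- b1_params(b2_scale = 10)
  expect_gt(slope_b(pb2) / slope_b(pb), 1.5)  # tenfold affinity steepens
  # B1 total-count sensitivity is comparable to the localized model's
  sl_loc <- {
    h <- 0.02; p <- meanfield_params()
    p1 <- p; p2 <- p
    p1$R_Tot <- p$R_Tot * (1 - h); p2$R_Tot <- p$R_Tot * (1 + h)
    abs(log(mf_steady_state(0, p2)$a0) - log(mf_steady_state(0, p1)$a0)) /
      (2 * h)
  }
  expect_lt(max(sl_loc, slope_b(pb)) / min(sl_loc, slope_b(pb)), 4)
})
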