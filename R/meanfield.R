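#' Parameters of the mean-field model with enzyme localization
#'
#' The analytical counterpart of the lattice simulation: all receptors share
#' the mean activity `a` (the limit of a single, maximally large assistance
#' neighborhood, or infinitely fast brachiation), and the enzymes cycle
#' between the cytoplasmic bulk, a tether-localized pool, and a
#' modification-site-bound pool.  States are molecule numbers, not
#' concentrations; volume factors are folded into the binding rates.
#'
#' Dynamics (state `m` = mean methylation per 2N-receptor MWC complex,
#' `Rstar` = tether-localized CheR, `Bstar` = tether-localized CheB-P, with
#' the bulk CheB-P pool `Bp` at quasi-steady state):
#' \deqn{dm/dt = (2N/T_{Tot}) [k_r R^{**} - k_b B^{**}]}
#' \deqn{dR^*/dt = k^{t+}_r (R_{Tot} - R^*) - k^{t-}_r R^* K_r/((1-a)+K_r)}
#' \deqn{dB^*/dt = k^{t+}_b B_p - k^{t-}_b B^* K_b/(a+K_b)}
#' with the doubly bound (modification-site-engaged) enzymes
#' `R** = Rstar (1-a)/((1-a)+K_r)`, `B** = Bstar a/(a+K_b)` from the fast
#' local binding equilibrium, and
#' `Bp = [a_p a/(d_p + a_p a)] (B_Tot - Bstar)` from the bulk
#' phosphorylation balance (localized CheB-P is excluded from the
#' phosphorylation reactions).  Unbinding from the lattice is a two-step
#' process: only the tether-only fraction `K/((1-a)+K)` of the localized
#' pool can release its tether, which makes the overall unbinding rate
#' activity-dependent.
#'
#' By default the parameters are derived from the simulator's M1 [rate_set()]
#' and the nominal [copy_numbers()] through the documented mapping in
#' [mf_from_rates()], so both models describe the same cell.
#'
#' @param ... named overrides of any field: `k_t_plus_r`, `k_t_minus_r`,
#'   `k_t_plus_b`, `k_t_minus_b` (tether exchange, 1/s), `K_r`, `K_b`
#'   (dimensionless local saturation constants), `k_r`, `k_b` (catalytic
#'   rates, 1/s), `a_p`, `d_p` (CheB (de)phosphorylation, 1/s), `R_Tot`,
#'   `B_Tot` (enzyme copies), `T_Tot` (total receptors = 2 x dimers), `N`
#'   (dimers per complex), `mwc` ([mwc_params()]).
#' @return Object of class `meanfield_params`.
#' @export
meanfield_params <- function(...) {
  p <- mf_from_rates(rate_set(), copy_numbers(7200))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown mean-field fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  p <- modifyList(p, dots)
  .validate_mf(p)
}

#' Derive mean-field parameters from a simulator rate set
#'
#' The mapping from per-site lattice rates to aggregate mean-field
#' constants: tether binding/unbinding rates carry over directly
#' (`tether_unbind_scale` applied); the local saturation constant is
#' `K = (k_m_unbind + k_cat) / (7 k_m_bind_local)`, the ratio of the
#' leaving rate of a modification-site-bound enzyme to its aggregate
#' rebinding rate over a 7-dimer assistance neighborhood at unit activity
#' weight; catalytic and phosphorylation rates carry over; `T_Tot` is twice
#' the dimer count (receptor monomers).
#'
#' @param rates a [rate_set()].
#' @param copies [copy_numbers()].
#' @param mwc [mwc_params()].
#' @return `meanfield_params`.
#' @export
mf_from_rates <- function(rates, copies, mwc = mwc_params()) {
  stopifnot(inherits(rates, "rate_set"))
  an <- if (rates$neighbor_binding) 7 else 1
  p <- list(
    k_t_plus_r = rates$k_t_bind_r,
    k_t_minus_r = rates$k_t_unbind_r * rates$tether_unbind_scale,
    k_t_plus_b = rates$k_t_bind_b,
    k_t_minus_b = rates$k_t_unbind_b * rates$tether_unbind_scale,
    K_r = (rates$k_m_unbind_r + rates$k_cat_r) /
      (an * rates$k_m_bind_local_r),
    K_b = (rates$k_m_unbind_b + rates$k_cat_b) /
      (an * rates$k_m_bind_local_b),
    k_r = rates$k_cat_r, k_b = rates$k_cat_b,
    a_p = rates$a_p, d_p = rates$d_p,
    R_Tot = copies$cheR, B_Tot = copies$cheB,
    T_Tot = 2 * copies$dimers, N = mwc$N, mwc = mwc)
  .validate_mf(p)
}

.validate_mf <- function(p) {
  num <- c("k_t_plus_r", "k_t_minus_r", "k_t_plus_b", "k_t_minus_b",
           "K_r", "K_b", "k_r", "k_b", "a_p", "d_p", "R_Tot", "B_Tot",
           "T_Tot")
  v <- vapply(p[num], as.numeric, numeric(1))
  if (any(!is.finite(v)) || any(v < 0))
    stop("mean-field parameters must be finite and non-negative",
         call. = FALSE)
  if (p$K_r <= 0 || p$K_b <= 0)
    stop("K_r and K_b must be positive", call. = FALSE)
  structure(p, class = "meanfield_params")
}

#' @export
print.meanfield_params <- function(x, ...) {
  cat("Mean-field model with enzyme localization\n")
  cat(sprintf("  tether exchange CheR: + %.4g / - %.4g 1/s;  CheB-P: + %.4g / - %.4g 1/s\n",
              x$k_t_plus_r, x$k_t_minus_r, x$k_t_plus_b, x$k_t_minus_b))
  cat(sprintf("  saturation K_r = %.4g, K_b = %.4g;  catalysis k_r = %.4g, k_b = %.4g 1/s\n",
              x$K_r, x$K_b, x$k_r, x$k_b))
  cat(sprintf("  CheB phosphorylation a_p = %.3g, d_p = %.3g 1/s\n",
              x$a_p, x$d_p))
  cat(sprintf("  copies: R_Tot = %g, B_Tot = %g, T_Tot = %g receptors (N = %d)\n",
              x$R_Tot, x$B_Tot, x$T_Tot, x$N))
  invisible(x)
}

.clamp_a <- function(a, eps = 1e-12) pmin(pmax(a, eps), 1 - eps)

# bulk CheB-P pool at its phosphorylation steady state, given mean activity
# and the localized CheB-P count (localized CheB-P does not dephosphorylate)
.mf_bp <- function(a, Bstar, p) {
  phi <- p$a_p * a / (p$d_p + p$a_p * a)
  phi * max(p$B_Tot - Bstar, 0)
}

#' Modification-site-bound enzyme numbers
#'
#' The fast local binding equilibrium within the tether radius gives the
#' number of localized enzymes engaged with a modification site:
#' `Rdouble = Rstar (1-a)/((1-a)+K_r)` and
#' `Bdouble = Bstar a/(a+K_b)`.
#'
#' @param state list or vector with `Rstar` and `Bstar` (localized pools).
#' @param a mean receptor activity in (0, 1).
#' @param params [meanfield_params()].
#' @return List with `Rdouble` and `Bdouble`.
#' @export
mf_bound_enzymes <- function(state, a, params) {
  a <- .clamp_a(a)
  Rstar <- if (is.list(state)) state$Rstar else state[["Rstar"]]
  Bstar <- if (is.list(state)) state$Bstar else state[["Bstar"]]
  list(Rdouble = Rstar * (1 - a) / ((1 - a) + params$K_r),
       Bdouble = Bstar * a / (a + params$K_b))
}

#' Time derivatives of the localized mean-field model
#'
#' @param state named vector or list `(m, Rstar, Bstar)`.
#' @param L ligand concentration (uM).
#' @param params [meanfield_params()].
#' @return Named vector `(m, Rstar, Bstar)` of time derivatives.
#' @export
mf_rhs <- function(state, L, params) {
  p <- params
  m <- if (is.list(state)) state$m else state[["m"]]
  Rstar <- if (is.list(state)) state$Rstar else state[["Rstar"]]
  Bstar <- if (is.list(state)) state$Bstar else state[["Bstar"]]
  a <- .clamp_a(mwc_activity(min(max(m, 0), 8 * p$N), L, p$mwc))
  be <- mf_bound_enzymes(list(Rstar = Rstar, Bstar = Bstar), a, p)
  cc <- 2 * p$N / p$T_Tot
  Bp <- .mf_bp(a, Bstar, p)
  c(m = cc * (p$k_r * be$Rdouble - p$k_b * be$Bdouble),
    Rstar = p$k_t_plus_r * (p$R_Tot - Rstar) -
      p$k_t_minus_r * Rstar * p$K_r / ((1 - a) + p$K_r),
    Bstar = p$k_t_plus_b * Bp -
      p$k_t_minus_b * Bstar * p$K_b / (a + p$K_b))
}

# localized pools at steady state, as functions of activity
.mf_pools_at <- function(a, p) {
  Rstar <- p$R_Tot / (1 + (p$k_t_minus_r / p$k_t_plus_r) *
                        p$K_r / ((1 - a) + p$K_r))
  phi <- p$a_p * a / (p$d_p + p$a_p * a)
  cc <- if (phi > 0 && p$k_t_minus_b > 0)
    p$k_t_plus_b * phi * (a + p$K_b) / (p$k_t_minus_b * p$K_b)
  else if (p$k_t_minus_b == 0) Inf else 0
  Bstar <- if (is.infinite(cc)) p$B_Tot else p$B_Tot * cc / (1 + cc)
  list(Rstar = Rstar, Bstar = Bstar)
}

#' Steady state of the localized mean-field model
#'
#' Solves the coupled steady state of methylation and the localized enzyme
#' pools.  Because the tether and local-binding equations can be solved
#' exactly for the localized pools as functions of activity, the problem
#' reduces to a single monotone scalar equation in `a`, bracketed on
#' (0, 1); the returned root satisfies all three balance equations to
#' machine precision (verified internally).  Since the methylation balance
#' depends on ligand only through `a`, the adapted activity `a0` is
#' independent of `L` -- precise adaptation -- while the methylation level
#' `m0` shifts to absorb the stimulus.
#'
#' If no interior balance exists (e.g. one enzyme absent), the system is in
#' a fully active or fully inactive state; this "nonfunctional cell" case is
#' flagged via `interior = FALSE`, as is an `m0` outside the physical range
#' `[0, 8N]`.
#'
#' @param L ligand concentration (uM).
#' @param params [meanfield_params()].
#' @return Object of class `mf_steady`: list with `a0`, `m0`, `Rstar`,
#'   `Bstar`, `Bp`, `Rdouble`, `Bdouble`, `interior`, `L`, `params`.
#' @export
mf_steady_state <- function(L = 0, params = meanfield_params()) {
  p <- params
  G <- function(a) {
    pools <- .mf_pools_at(a, p)
    be <- mf_bound_enzymes(pools, a, p)
    p$k_r * be$Rdouble - p$k_b * be$Bdouble
  }
  eps <- 1e-12
  glo <- G(eps); ghi <- G(1 - eps)
  interior <- is.finite(glo) && is.finite(ghi) && glo > 0 && ghi < 0
  if (!interior) {
    a0 <- if (glo <= 0) eps else 1 - eps
  } else {
    a0 <- uniroot(G, c(eps, 1 - eps), tol = 1e-14)$root
  }
  pools <- .mf_pools_at(a0, p)
  be <- mf_bound_enzymes(pools, a0, p)
  # invert the MWC relation for the methylation level at this (a0, L)
  F0 <- log(1 / a0 - 1)
  m0 <- p$mwc$m_half +
    (p$N * log((1 + L / p$mwc$K_off) / (1 + L / p$mwc$K_on)) - F0) /
    p$mwc$eps_m
  if (m0 < 0 || m0 > 8 * p$N) interior <- FALSE
  res <- mf_rhs(c(m = min(max(m0, 0), 8 * p$N),
                  Rstar = pools$Rstar, Bstar = pools$Bstar), L, p)
  if (interior && max(abs(res)) > 1e-6)
    stop("steady-state residual check failed: ", max(abs(res)),
         call. = FALSE)
  structure(list(a0 = a0, m0 = m0, Rstar = pools$Rstar,
                 Bstar = pools$Bstar, Bp = .mf_bp(a0, pools$Bstar, p),
                 Rdouble = be$Rdouble, Bdouble = be$Bdouble,
                 interior = interior, L = L, params = p),
            class = "mf_steady")
}

#' @export
print.mf_steady <- function(x, ...) {
  cat(sprintf("Mean-field steady state at L = %g uM%s\n", x$L,
              if (x$interior) "" else "  [NON-INTERIOR: fully (in)active regime]"))
  cat(sprintf("  a0 = %.6f, m0 = %.4f per complex\n", x$a0, x$m0))
  cat(sprintf("  localized CheR %.2f (on modsites %.2f); localized CheB-P %.2f (on modsites %.2f); bulk CheB-P %.2f\n",
              x$Rstar, x$Rdouble, x$Bstar, x$Bdouble, x$Bp))
  invisible(x)
}

#' Effective inverse affinities of the reduced Goldbeter-Koshland form
#'
#' Eliminating the localized enzyme pools at steady state turns the
#' methylation balance into a Goldbeter-Koshland equation in the *total*
#' enzyme counts,
#' \deqn{k_r R_{Tot} \frac{1-a}{(1-a)+\tilde K_r} =
#'       k_b B_{Tot} \frac{a}{a+\tilde K_b},}
#' with effective saturation constants
#' \deqn{\tilde K_r = K_r (1 + k^{t-}_r / k^{t+}_r)}
#' \deqn{\tilde K_b = K_b [1 + (k^{t-}_b / k^{t+}_b)(1 + d_p/(a_p a))].}
#' Slow tether binding relative to unbinding inflates the effective
#' constants, so the steady state can be robust (`K_tilde >~ 1`) even when
#' the localized enzymes themselves are fully saturated (`K << 1`); the
#' `1 + d_p/(a_p a)` factor is the additional desensitization contributed by
#' the CheB phosphorylation feedback.
#'
#' @param params [meanfield_params()].
#' @param a activity at which to evaluate (only `K_tilde_b` depends on it).
#' @return List with `K_tilde_r` and `K_tilde_b`.
#' @export
mf_effective_constants <- function(params, a = 0.5) {
  a <- .clamp_a(a)
  p <- params
  list(K_tilde_r = p$K_r * (1 + p$k_t_minus_r / p$k_t_plus_r),
       K_tilde_b = p$K_b * (1 + (p$k_t_minus_b / p$k_t_plus_b) *
                              (1 + p$d_p / (p$a_p * a))))
}

#' Steady state from the reduced Goldbeter-Koshland form
#'
#' Solves the activity balance written with the effective constants of
#' [mf_effective_constants()] (self-consistently, since `K_tilde_b` depends
#' on `a` through the phosphorylation feedback).  Algebraically equivalent
#' to [mf_steady_state()]; kept as an independent route for cross-checks and
#' for reasoning in Goldbeter-Koshland terms.
#'
#' @param params [meanfield_params()].
#' @return The activity root `a0` in (0, 1).
#' @export
mf_gk_steady <- function(params) {
  p <- params
  h <- function(a) {
    kt <- mf_effective_constants(p, a)
    p$k_r * p$R_Tot * (1 - a) / ((1 - a) + kt$K_tilde_r) -
      p$k_b * p$B_Tot * a / (a + kt$K_tilde_b)
  }
  uniroot(h, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

#' Root of the Goldbeter-Koshland balance
#'
#' Admissible root in (0, 1) of
#' `ratio (1-a)/((1-a)+K1) = a/(a+K2)`, the steady state of a covalent
#' modification cycle with forward/backward velocity ratio `ratio` and
#' saturation constants `K1`, `K2`.  For `K1, K2 << 1` the root switches
#' from near 0 to near 1 over a few-percent change of `ratio` around 1
#' (zero-order ultrasensitivity); for `K1, K2 >> 1` it responds
#' quasi-linearly.
#'
#' @param ratio forward/backward velocity ratio (> 0).
#' @param K1,K2 saturation constants (> 0).
#' @return The root `a0` in (0, 1); monotone increasing in `ratio`.
#' @export
gk_root <- function(ratio, K1, K2) {
  stopifnot(ratio > 0, K1 > 0, K2 > 0)
  u <- ratio
  # (u-1) a^2 - (u - 1 - u K2 - K1) a - u K2 = 0
  A <- u - 1; B <- -(u - 1 - u * K2 - K1); C <- -u * K2
  if (abs(A) < 1e-12) {
    a <- K2 / (K1 + K2)
  } else {
    disc <- sqrt(max(B^2 - 4 * A * C, 0))
    roots <- c((-B - disc) / (2 * A), (-B + disc) / (2 * A))
    a <- roots[roots > 0 & roots < 1][1]
    if (is.na(a))
      a <- uniroot(function(x) u * (1 - x) / ((1 - x) + K1) - x / (x + K2),
                   c(1e-15, 1 - 1e-15), tol = 1e-15)$root
  }
  a
}

#' Parameters and steady state of the no-localization baseline B1
#'
#' In the analytical B1 model all of CheR and all bulk CheB-P act directly
#' on the receptor pool with activity-dependent Michaelis-Menten kinetics;
#' there is no tether localization step:
#' \deqn{dm/dt = (2N/T_{Tot})[k_r R_{Tot} \frac{1-a}{(1-a)+K_r} -
#'       k_b B_p \frac{a}{a+K_b}]}
#' with `B_p` following the bulk phosphorylation balance.  `b2_scale`
#' divides the saturation constants, giving the high-affinity variant B2
#' (`b2_scale = 10`), whose steady state is ultrasensitive to enzyme
#' counts.
#'
#' @param ... named overrides (fields as in [meanfield_params()], minus the
#'   tether rates).
#' @param b2_scale saturation-constant divisor (1 = B1, 10 = B2).
#' @return Object of class `b1_params`.
#' @export
b1_params <- function(..., b2_scale = 1) {
  r <- b1_rate_set()
  cp <- copy_numbers(7200)
  p <- list(K_r = (r$k_m_unbind_r + r$k_cat_r) / r$k_m_bind_bulk_r / b2_scale,
            K_b = (r$k_m_unbind_b + r$k_cat_b) / r$k_m_bind_bulk_b / b2_scale,
            k_r = r$k_cat_r, k_b = r$k_cat_b, a_p = r$a_p, d_p = r$d_p,
            R_Tot = cp$cheR, B_Tot = cp$cheB, T_Tot = 2 * cp$dimers,
            N = 6L, mwc = mwc_params())
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown B1 fields: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(modifyList(p, dots), class = "b1_params")
}

#' @rdname b1_params
#' @param state named vector or list `(m, Bp)`.
#' @param L ligand concentration (uM).
#' @param params `b1_params`.
#' @return `b1_rhs`: named derivative vector `(m, Bp)`.
#' @export
b1_rhs <- function(state, L, params) {
  p <- params
  m <- if (is.list(state)) state$m else state[["m"]]
  Bp <- if (is.list(state)) state$Bp else state[["Bp"]]
  a <- .clamp_a(mwc_activity(min(max(m, 0), 8 * p$N), L, p$mwc))
  cc <- 2 * p$N / p$T_Tot
  c(m = cc * (p$k_r * p$R_Tot * (1 - a) / ((1 - a) + p$K_r) -
                p$k_b * Bp * a / (a + p$K_b)),
    Bp = p$a_p * a * (p$B_Tot - Bp) - p$d_p * Bp)
}

#' @rdname b1_params
#' @return `b1_steady_state`: object of class `mf_steady` (with
#'   `Rstar`/`Bstar` fields absent), carrying `a0`, `m0`, `Bp`, `interior`.
#' @export
b1_steady_state <- function(L = 0, params = b1_params()) {
  p <- params
  G <- function(a) {
    Bp <- p$a_p * a * p$B_Tot / (p$d_p + p$a_p * a)
    p$k_r * p$R_Tot * (1 - a) / ((1 - a) + p$K_r) -
      p$k_b * Bp * a / (a + p$K_b)
  }
  eps <- 1e-12
  interior <- G(eps) > 0 && G(1 - eps) < 0
  a0 <- if (!interior) { if (G(eps) <= 0) eps else 1 - eps }
        else uniroot(G, c(eps, 1 - eps), tol = 1e-14)$root
  F0 <- log(1 / a0 - 1)
  m0 <- p$mwc$m_half +
    (p$N * log((1 + L / p$mwc$K_off) / (1 + L / p$mwc$K_on)) - F0) /
    p$mwc$eps_m
  if (m0 < 0 || m0 > 8 * p$N) interior <- FALSE
  structure(list(a0 = a0, m0 = m0,
                 Bp = p$a_p * a0 * p$B_Tot / (p$d_p + p$a_p * a0),
                 interior = interior, L = L, params = p),
            class = "mf_steady")
}

#' Relax the mean-field model to steady state by ODE integration
#'
#' Independent route to the steady state: integrates [mf_rhs()] (or
#' [b1_rhs()]) with `deSolve::lsoda` from a perturbed initial condition
#' until the derivatives vanish.  Used as a built-in cross-check of the
#' root-finding solver.
#'
#' @param params `meanfield_params` or `b1_params`.
#' @param L ligand (uM).
#' @param state0 optional initial state (defaults to a mildly perturbed
#'   interior state).
#' @param t_end integration horizon (s).
#' @return Named state vector at `t_end`.
#' @export
mf_relax <- function(params, L = 0, state0 = NULL, t_end = 20000) {
  b1 <- inherits(params, "b1_params")
  if (is.null(state0)) {
    state0 <- if (b1) c(m = 8, Bp = params$B_Tot / 4)
              else c(m = 8, Rstar = params$R_Tot / 3,
                     Bstar = params$B_Tot / 3)
  }
  f <- function(t, y, parms) {
    d <- if (b1) b1_rhs(y, L, params) else mf_rhs(y, L, params)
    list(d)
  }
  out <- deSolve::lsoda(state0, c(0, t_end / 2, t_end), f, NULL,
                        rtol = 1e-12, atol = 1e-12)
  st <- out[nrow(out), -1]
  names(st) <- names(state0)
  st
}
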