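#' Stationary noise statistics of an activity trace
#'
#' Mean, variance and relative noise of the raw (unsmoothed) activity
#' series over the retained window `time > burn_in`.  Display smoothing
#' (see [smooth_trace()]) is never applied before computing statistics.
#'
#' @param trace a `lattice_trace`, a data frame with `time` and `a_mean`
#'   columns, or (for the Langevin simulator output) `time` and `a`.
#' @param burn_in initial time span to discard (s).
#' @return List with `a0` (mean), `sigma_aa` (variance), `rel_noise`
#'   (`sqrt(sigma_aa)/a0`) and `n` (samples retained).
#' @export
noise_stats <- function(trace, burn_in = 0) {
  a <- if (!is.null(trace$a_mean)) trace$a_mean else trace$a
  if (is.null(a)) stop("trace has no activity column", call. = FALSE)
  keep <- trace$time > burn_in
  if (!any(keep)) stop("trace shorter than burn_in", call. = FALSE)
  a <- a[keep]
  a0 <- mean(a); s2 <- if (length(a) > 1) var(a) else 0
  list(a0 = a0, sigma_aa = s2,
       rel_noise = if (a0 > 0) sqrt(s2) / a0 else NA_real_,
       n = length(a))
}

#' Precision of adaptation to a step stimulus
#'
#' Compares the adapted activity after a step with the pre-stimulus level:
#' `precision = 1 - |a_adapted - a_pre| / a_pre`, with `a_pre` the mean
#' activity over the window `[pre_from, t_step]` and `a_adapted` the mean
#' over the final `adapted_frac` fraction of the post-step window.  A
#' perfectly adapting system returns 1.  The windowing is a package
#' convention (reported alongside the value) since adaptation curves, not
#' scalars, are what step experiments show directly.
#'
#' @param trace a `lattice_trace` (or any data frame with `time`, `a_mean`).
#' @param protocol the step [ligand_protocol()] used for the run.
#' @param pre_from start of the pre-stimulus averaging window (s); defaults
#'   to half the pre-step span.
#' @param adapted_frac final fraction of the post-step window averaged as
#'   the adapted level.
#' @return List with `precision`, `a_pre`, `a_adapted`, and the windows.
#' @export
adaptation_precision <- function(trace, protocol, pre_from = NULL,
                                 adapted_frac = 0.2) {
  stopifnot(inherits(protocol, "ligand_protocol"))
  if (protocol$kind != "step")
    stop("adaptation precision is defined for step protocols", call. = FALSE)
  ts <- protocol$t_step
  t_end <- max(trace$time)
  if (ts <= 0 || ts >= t_end)
    stop("step time outside the trace", call. = FALSE)
  if (is.null(pre_from)) pre_from <- ts / 2
  a <- if (!is.null(trace$a_mean)) trace$a_mean else trace$a
  pre <- a[trace$time >= pre_from & trace$time < ts]
  post_start <- t_end - adapted_frac * (t_end - ts)
  post <- a[trace$time >= post_start]
  a_pre <- mean(pre); a_ad <- mean(post)
  list(precision = 1 - abs(a_ad - a_pre) / a_pre,
       a_pre = a_pre, a_adapted = a_ad,
       windows = list(pre = c(pre_from, ts), adapted = c(post_start, t_end)))
}

#' Steady ramp activity versus ramp rate
#'
#' Exposes the model to exponential ligand ramps `L(t) = L0 exp(r t)`
#' (clipped to the protocol bounds) and records, for each rate, the steady
#' activity reached while the ramp runs, obtained from an exponential fit
#' `a(t) = plateau + A exp(-t/tau)` over the ramp window.  With the
#' mean-field engine a single deterministic integration is used; with the
#' SSA engine the response is averaged over an ensemble of seeds before
#' fitting.
#'
#' @param ramp_rates numeric vector of ramp rates (1/s, either sign).
#' @param engine `"meanfield"` or `"ssa"`.
#' @param params [meanfield_params()] (mean-field engine).
#' @param geometry,rates,copies,mwc lattice run ingredients (SSA engine).
#' @param n_seeds ensemble size (SSA engine).
#' @param seed base seed (SSA engine).
#' @param duration ramp duration to simulate (s).
#' @param L_min,L_max ramp bounds (uM).
#' @return Data frame with one row per rate: `rate`, `plateau`, `tau`, `a0`
#'   (the unstimulated adapted activity, for reference).
#' @export
ramp_response <- function(ramp_rates, engine = c("meanfield", "ssa"),
                          params = meanfield_params(),
                          geometry = NULL, rates = rate_set(),
                          copies = NULL, mwc = mwc_params(),
                          n_seeds = 10, seed = 1, duration = 400,
                          L_min = 84, L_max = 620) {
  engine <- match.arg(engine)
  rows <- lapply(ramp_rates, function(r) {
    # the ramp is informative only until it hits its clipping bound; fit
    # the approach to the steady ramp activity over that window
    t_active <- if (r == 0) duration
                else min(duration, log(L_max / L_min) / abs(r))
    if (engine == "meanfield") {
      a0 <- mf_steady_state(L_min, params)$a0
      st <- mf_steady_state(if (r >= 0) L_min else L_max, params)
      y0 <- c(m = st$m0, Rstar = st$Rstar, Bstar = st$Bstar)
      Lfun <- function(t) min(max((if (r >= 0) L_min else L_max) * exp(r * t),
                                  L_min), L_max)
      f <- function(t, y, parms) list(mf_rhs(y, Lfun(t), params))
      tt <- seq(0, t_active, length.out = 401)
      out <- deSolve::lsoda(y0, tt, f, NULL, rtol = 1e-10, atol = 1e-10)
      aa <- mwc_activity(pmin(pmax(out[, "m"], 0), 8 * params$N),
                         vapply(tt, Lfun, numeric(1)), params$mwc)
      df <- data.frame(time = tt, a = aa)
    } else {
      stopifnot(inherits(geometry, "receptor_lattice"))
      if (is.null(copies)) copies <- copy_numbers(geometry)
      a0 <- NA_real_
      prot <- ligand_protocol("ramp", L0 = if (r >= 0) L_min else L_max,
                              rate = r, L_min = L_min, L_max = L_max)
      ens <- vapply(seq_len(n_seeds), function(k) {
        eq <- equilibrate_lattice(geometry, rates, copies,
                                  protocol = prot, burn_in = 300,
                                  duration = duration, seed = seed + 100 * k,
                                  record_dt = 0.5, mwc = mwc)
        eq$trace$a_mean
      }, numeric(duration / 0.5 + 1))
      df <- data.frame(time = seq(0, duration, by = 0.5),
                       a = rowMeans(ens))
      df <- df[df$time <= t_active, , drop = FALSE]
    }
    if (r == 0) {
      data.frame(rate = r, plateau = mean(tail(df$a, 20)), tau = NA_real_,
                 a0 = if (is.na(a0)) mean(tail(df$a, 20)) else a0)
    } else {
      fit <- .fit_exponential_approach(df$time, df$a)
      data.frame(rate = r, plateau = fit["plateau"], tau = fit["tau"],
                 a0 = a0)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.fit_exponential_approach <- function(t, a) {
  p0 <- list(plateau = tail(a, 1), A = a[1] - tail(a, 1), tau = max(t) / 3)
  # near-exponential traces can stall the optimizer with a singular
  # gradient at the optimum; warnOnly keeps the best fit, which is checked
  # by the caller against its fallback
  fit <- try(suppressWarnings(
    nls(a ~ plateau + A * exp(-t / tau), start = p0,
        algorithm = "port",
        lower = c(plateau = 0, A = -1, tau = 1e-2),
        upper = c(plateau = 1, A = 1, tau = 1e5),
        control = list(maxiter = 500, warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(c(plateau = mean(tail(a, ceiling(length(a) / 5))), tau = NA_real_))
  cf <- coef(fit)
  c(plateau = unname(cf["plateau"]), tau = unname(cf["tau"]))
}

#' Scan steady-state output against an enzyme-count parameter
#'
#' Sweeps total CheR (`param = "R_Tot"`, as a multiple of its nominal
#' value) or the CheR/CheB ratio and reports, per point, the adapted
#' activity, activity variance and relative noise, computed by the engine
#' requested: the deterministic mean-field steady state (`"meanfield"`),
#' the linear noise approximation (`"lna"`), or the stochastic lattice
#' simulation (`"ssa"`, which also reports the mean localized enzyme
#' counts; rows carry the seed and window metadata).
#'
#' @param param `"R_Tot"` (CheR count multiplier) is currently the scanned
#'   quantity; CheB and receptors stay at nominal.
#' @param range multipliers to scan (numeric vector).
#' @param engine `"meanfield"`, `"lna"` or `"ssa"`.
#' @param params [meanfield_params()] or [b1_params()] (analytic engines).
#' @param geometry,rates,mwc,seed,burn_in,duration,record_dt SSA engine
#'   ingredients.
#' @param n_seeds seeds averaged per SSA point.
#' @return Data frame, one row per scan point.
#' @export
param_scan <- function(param = "R_Tot", range = 2^seq(-2, 2, length.out = 25),
                       engine = c("lna", "meanfield", "ssa"),
                       params = meanfield_params(),
                       geometry = NULL, rates = rate_set(),
                       mwc = mwc_params(), seed = 1, n_seeds = 3,
                       burn_in = 500, duration = 600, record_dt = 0.1) {
  engine <- match.arg(engine)
  if (param != "R_Tot")
    stop("only the total CheR count is scanned in this release",
         call. = FALSE)
  if (engine %in% c("meanfield", "lna")) {
    b1 <- inherits(params, "b1_params")
    base_R <- params$R_Tot
    rows <- lapply(range, function(mult) {
      p <- params; p$R_Tot <- base_R * mult
      st <- if (b1) b1_steady_state(0, p) else mf_steady_state(0, p)
      row <- data.frame(R_mult = mult, R_Tot = p$R_Tot, a0 = st$a0,
                        m0 = st$m0, interior = st$interior,
                        sigma_aa = NA_real_, rel_noise = NA_real_)
      if (!b1) { row$Rstar <- st$Rstar; row$Bstar <- st$Bstar }
      if (engine == "lna" && st$interior) {
        nv <- activity_variance(mf_linearize(p, st))
        row$sigma_aa <- nv$sigma_aa
        row$rel_noise <- nv$rel_noise
      }
      row
    })
    out <- do.call(rbind, rows)
  } else {
    stopifnot(inherits(geometry, "receptor_lattice"))
    rows <- lapply(seq_along(range), function(i) {
      mult <- range[i]
      cp <- copy_numbers(geometry, cheR_factor = mult)
      per_seed <- lapply(seq_len(n_seeds), function(k) {
        sd_k <- seed + 1000 * i + k
        eq <- equilibrate_lattice(geometry, rates, cp,
                                  burn_in = burn_in, duration = duration,
                                  seed = sd_k, record_dt = record_dt,
                                  mwc = mwc)
        ns <- noise_stats(eq$trace)
        c(a0 = ns$a0, sigma_aa = ns$sigma_aa, rel_noise = ns$rel_noise,
          locR = mean(eq$trace$loc_cheR),
          locB = mean(eq$trace$loc_cheBp),
          locB_active = mean(eq$trace$loc_cheBp_active))
      })
      m <- colMeans(do.call(rbind, per_seed))
      data.frame(R_mult = mult, cheR = cp$cheR, cheB = cp$cheB,
                 a0 = m[["a0"]], sigma_aa = m[["sigma_aa"]],
                 rel_noise = m[["rel_noise"]], mean_loc_cheR = m[["locR"]],
                 mean_loc_cheBp = m[["locB"]],
                 mean_loc_cheBp_active = m[["locB_active"]],
                 n_seeds = n_seeds, seed0 = seed + 1000 * i,
                 burn_in = burn_in, duration = duration)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Specification of a cell population with conserved expression ratios
#'
#' Cell-to-cell variability in chemotaxis protein levels is modeled by a
#' log-normal distribution of an overall expression multiplier applied
#' jointly to CheR, CheB and the receptor-associated enzyme densities,
#' preserving the CheR/CheB/receptor ratio (the cotranscription
#' constraint); intrinsic (uncorrelated) expression noise is ignored.  The
#' default shape `sigma_ln = 0.35` (median 1) spans roughly 0.5x-2x of the
#' modal level, matching reporter-based estimates of chemotaxis operon
#' variability.  Multipliers are placed at evenly spaced quantiles of the
#' distribution (a deterministic stratified sample given `n_cells`), which
#' covers the tails reproducibly with few cells; `stratified = FALSE`
#' draws them randomly instead.
#'
#' @param n_cells number of sampled cells.
#' @param sigma_ln log-normal shape parameter.
#' @param seed RNG seed (random sampling only).
#' @param stratified quantile-stratified (default) or random multipliers.
#' @param p_range quantile range covered by the stratified sample.
#' @return Object of class `population_spec` with the `multipliers`.
#' @export
population_spec <- function(n_cells = 8, sigma_ln = 0.35, seed = 1,
                            stratified = TRUE, p_range = c(0.025, 0.975)) {
  stopifnot(n_cells >= 1, sigma_ln > 0)
  mult <- if (stratified) {
    qlnorm(seq(p_range[1], p_range[2], length.out = n_cells),
           meanlog = 0, sdlog = sigma_ln)
  } else {
    set.seed(seed)
    stats::rlnorm(n_cells, 0, sigma_ln)
  }
  structure(list(n_cells = n_cells, sigma_ln = sigma_ln, seed = seed,
                 stratified = stratified, multipliers = mult,
                 ratio_preserved = TRUE),
            class = "population_spec")
}

#' Per-cell noise statistics across a population
#'
#' Runs the stochastic model once per sampled cell.  Ratio preservation
#' means CheR, CheB *and* the receptor cluster all scale together with the
#' cell's expression multiplier, so each cell gets its own lattice: the
#' number of hexagonal units of the reference geometry is scaled by the
#' multiplier (rounded to a near-square tiling) and enzyme counts follow
#' the lattice through [copy_numbers()], keeping the CheR/CheB/receptor
#' ratio fixed across the population.  The realized multiplier (dimer count
#' relative to the reference lattice) is reported per cell; it differs from
#' the sampled one only by the unit rounding.
#'
#' @param spec a [population_spec()].
#' @param geometry the reference `receptor_lattice` (the multiplier-1 cell).
#' @param rates a [rate_set()] (use `rate_set(variant = "B1")` for the
#'   well-mixed baseline).
#' @param mwc [mwc_params()].
#' @param seed base seed; each cell uses an offset of it.
#' @param burn_in,duration,record_dt run windows (s).
#' @return Data frame with one row per cell: `multiplier` (realized),
#'   `multiplier_sampled`, `dimers`, `cheR`, `cheB`, `a0`, `sigma_aa`,
#'   `rel_noise`, `seed`.
#' @export
population_run <- function(spec, geometry, rates = rate_set(),
                           mwc = mwc_params(), seed = 1,
                           burn_in = 500, duration = 600, record_dt = 0.1) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(geometry, "receptor_lattice"))
  base_units <- prod(geometry$units)
  base_dimers <- geometry$n_dimers
  rows <- lapply(seq_along(spec$multipliers), function(i) {
    mult <- spec$multipliers[i]
    u <- max(1L, as.integer(round(base_units * mult)))
    w <- max(1L, as.integer(round(sqrt(u))))
    h <- max(1L, as.integer(round(u / w)))
    lat_i <- build_lattice(w, h)
    cp <- copy_numbers(lat_i)
    sd_i <- seed + 17 * i
    eq <- equilibrate_lattice(lat_i, rates, cp, burn_in = burn_in,
                              duration = duration, seed = sd_i,
                              record_dt = record_dt, mwc = mwc)
    ns <- noise_stats(eq$trace)
    data.frame(multiplier = lat_i$n_dimers / base_dimers,
               multiplier_sampled = mult, dimers = lat_i$n_dimers,
               cheR = cp$cheR, cheB = cp$cheB,
               a0 = ns$a0, sigma_aa = ns$sigma_aa, rel_noise = ns$rel_noise,
               seed = sd_i)
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  rownames(out) <- NULL
  out
}

#' Rate of unique receptor dimers visited by localized enzymes
#'
#' The processivity metric: the number of distinct receptor dimers whose
#' tether or modification site an enzyme occupies, counted per residence
#' on the lattice (revisits within one residence do not count) and divided
#' by the total localized time, averaged per species.  High rates indicate
#' distributive modification (the enzyme samples many receptors between
#' catalytic events); in the no-neighbor-binding variant M2 every residence
#' visits exactly one dimer.
#'
#' Operates either on the per-species summary every [simulate_lattice()]
#' run collects (`x` a `lattice_trace`), or from scratch on a dimer-contact
#' event log (`x` a data frame with columns `time`, `enzyme`, `dimer`,
#' `kind`, where kind 0 = contact with a new dimer, 1 = localization,
#' 2 = return to bulk, as produced with `log_contacts = TRUE`), optionally
#' restricted to a time window.
#'
#' @param x a `lattice_trace` or a contact-log data frame.
#' @param window optional `c(t0, t1)` window (log path only).
#' @param enzyme_species for the log path, optional vector mapping enzyme
#'   id to species (`0` CheR, `1` CheB); if missing a single pooled rate is
#'   returned.
#' @return Object of class `processivity_stats`: list with per-species
#'   `rate` (unique dimers per localized enzyme-second), `visits`,
#'   `loc_time`.
#' @export
processivity_rate <- function(x, window = NULL, enzyme_species = NULL) {
  if (inherits(x, "lattice_trace")) {
    pr <- attr(x, "processivity")
    out <- list(
      rate = c(cheR = if (pr$loc_time_cheR > 0)
                 pr$visits_cheR / pr$loc_time_cheR else NA_real_,
               cheB = if (pr$loc_time_cheB > 0)
                 pr$visits_cheB / pr$loc_time_cheB else NA_real_),
      visits = c(cheR = pr$visits_cheR, cheB = pr$visits_cheB),
      loc_time = c(cheR = pr$loc_time_cheR, cheB = pr$loc_time_cheB))
    return(structure(out, class = "processivity_stats"))
  }
  log <- as.data.frame(x)
  need <- c("time", "enzyme", "dimer", "kind")
  if (!all(need %in% names(log)))
    stop("contact log must have columns time, enzyme, dimer, kind",
         call. = FALSE)
  t0 <- if (is.null(window)) min(log$time) else window[1]
  t1 <- if (is.null(window)) max(log$time) else window[2]
  ids <- sort(unique(log$enzyme))
  visits <- setNames(numeric(length(ids)), ids)
  loct <- setNames(numeric(length(ids)), ids)
  for (e in ids) {
    le <- log[log$enzyme == e, , drop = FALSE]
    le <- le[order(le$time), , drop = FALSE]
    res_start <- NA_real_
    seen <- integer(0)
    localized_at_t0 <- FALSE
    for (i in seq_len(nrow(le))) {
      k <- le$kind[i]; tm <- le$time[i]
      if (k == 1) { res_start <- tm; seen <- integer(0) }
      else if (k == 2) {
        if (!is.na(res_start)) {
          lo <- max(res_start, t0); hi <- min(tm, t1)
          if (hi > lo) loct[as.character(e)] <- loct[as.character(e)] + hi - lo
        }
        res_start <- NA_real_; seen <- integer(0)
      } else if (k == 0) {
        if (is.na(res_start)) { res_start <- tm; localized_at_t0 <- TRUE }
        if (!(le$dimer[i] %in% seen) && tm >= t0 && tm <= t1) {
          seen <- c(seen, le$dimer[i])
          visits[as.character(e)] <- visits[as.character(e)] + 1
        } else if (!(le$dimer[i] %in% seen)) {
          seen <- c(seen, le$dimer[i])
        }
      }
    }
    if (!is.na(res_start)) {  # still localized at the end of the log
      lo <- max(res_start, t0); hi <- t1
      if (hi > lo) loct[as.character(e)] <- loct[as.character(e)] + hi - lo
    }
  }
  if (is.null(enzyme_species)) {
    out <- list(rate = c(all = sum(visits) / max(sum(loct), 1e-300)),
                visits = c(all = sum(visits)), loc_time = c(all = sum(loct)))
  } else {
    sp <- enzyme_species[ids + 1]
    agg <- function(v) c(cheR = sum(v[sp == 0]), cheB = sum(v[sp == 1]))
    vs <- agg(visits); lt <- agg(loct)
    out <- list(rate = vs / pmax(lt, 1e-300), visits = vs, loc_time = lt)
  }
  structure(out, class = "processivity_stats")
}

#' @export
print.processivity_stats <- function(x, ...) {
  cat("Unique dimers visited per localized enzyme-second:\n")
  for (nm in names(x$rate))
    cat(sprintf("  %-5s %.4g  (%g visits over %.4g s localized)\n",
                nm, x$rate[[nm]], x$visits[[nm]], x$loc_time[[nm]]))
  invisible(x)
}
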