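# 0-based, padded representation of a lattice for the C++ engine
.geom_for_engine <- function(geometry) {
  stopifnot(inherits(geometry, "receptor_lattice"))
  n <- geometry$n_dimers
  nbm <- matrix(-1L, n, 6L)
  for (d in seq_len(n)) {
    nbd <- geometry$neighbors[[d]] - 1L
    if (length(nbd)) nbm[d, seq_along(nbd)] <- nbd
  }
  list(n_dimers = n, n_complexes = geometry$n_complexes,
       neighbors0 = nbm,
       complex_of0 = geometry$complex_of - 1L,
       complexes0 = geometry$complexes - 1L)
}

.default_init <- function(geometry, copies, rates, init_methyl = 1L) {
  n <- geometry$n_dimers
  methyl <- if (length(init_methyl) == 1L) rep(as.integer(init_methyl), n)
            else as.integer(init_methyl)
  if (length(methyl) != n || any(methyl < 0) || any(methyl > rates$methyl_max))
    stop("invalid initial methylation", call. = FALSE)
  nR <- copies$cheR; nB <- copies$cheB
  # start bulk CheB partly phosphorylated at the rate balance for a = 0.5,
  # shortening the phosphorylation transient
  phi <- rates$a_p * 0.5 / (rates$d_p + rates$a_p * 0.5)
  nBp <- as.integer(round(phi * nB))
  list(methyl = methyl,
       species = c(rep(0L, nR), rep(1L, nB)),
       phos = c(rep(1L, nR), rep(1L, nBp), rep(0L, nB - nBp)),
       teth0 = rep(-1L, nR + nB),
       mod0 = rep(-1L, nR + nB))
}

#' Exact stochastic simulation of adaptation on the receptor lattice
#'
#' Runs the Gillespie-type simulation of CheR/CheB-P binding, brachiation
#' and receptor (de)methylation defined by a [rate_set()] on a
#' [build_lattice()] geometry, under a [ligand_protocol()].  The trajectory
#' is exact: propensities of activity-dependent channels are refreshed after
#' every event that touches the affected complexes, and time-varying ligand
#' is handled as a piecewise-constant profile on the recording grid.
#' Identical `(geometry, rates, copies, protocol, seed)` give bit-identical
#' traces.
#'
#' @param geometry a `receptor_lattice`.
#' @param rates a [rate_set()] (selects the model variant).
#' @param copies [copy_numbers()] for this lattice.
#' @param protocol a [ligand_protocol()].
#' @param duration simulated time (s).
#' @param seed integer RNG seed (required: the trace is a pure function of
#'   the arguments).
#' @param record_dt recording interval (s).
#' @param mwc [mwc_params()].
#' @param init_state `NULL` for a fresh start (all enzymes in bulk, bulk
#'   CheB partly phosphorylated, methylation from `init_methyl`), or the
#'   `final_state` of a previous run (see [equilibrate_lattice()]).
#' @param init_methyl initial per-dimer methylation (scalar or vector);
#'   the default, 1 methyl group per dimer, puts every complex at the
#'   half-activity anchor `m_total = 6`.
#' @param log_contacts record the per-enzyme dimer-contact log needed by
#'   [processivity_rate()]'s from-scratch path (memory-heavy on long runs;
#'   the per-species summary is always collected).
#' @return An object of class `lattice_trace`: the recorded time series as a
#'   data frame (`time`, `a_mean`, `m_mean`, `loc_cheR`, `loc_cheBp`,
#'   `loc_cheBp_active`, `bulk_cheBp`, `bulk_cheB`) with the processivity
#'   summary, event counts, final state and run metadata attached as
#'   attributes.
#' @examples
#' lat <- build_lattice(2, 2)
#' tr <- simulate_lattice(lat, rate_set(), copy_numbers(lat),
#'                        duration = 50, seed = 1)
#' summary(tr)
#' @export
simulate_lattice <- function(geometry, rates = rate_set(),
                             copies = copy_numbers(geometry),
                             protocol = ligand_protocol("constant", 0),
                             duration = 600, seed, record_dt = 0.1,
                             mwc = mwc_params(), init_state = NULL,
                             init_methyl = 1L, log_contacts = FALSE) {
  stopifnot(inherits(geometry, "receptor_lattice"),
            inherits(rates, "rate_set"),
            inherits(protocol, "ligand_protocol"))
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  if (duration <= 0 || record_dt <= 0)
    stop("duration and record_dt must be positive", call. = FALSE)
  if (copies$dimers != geometry$n_dimers)
    stop("copy numbers were derived for a different lattice", call. = FALSE)
  init <- if (is.null(init_state))
    .default_init(geometry, copies, rates, init_methyl)
  else init_state
  grid <- .protocol_grid(protocol, duration, record_dt)
  set.seed(seed)
  res <- .ssa_run(.geom_for_engine(geometry), unclass(rates), unclass(mwc),
                  init, grid, duration, record_dt, log_contacts)
  tr <- res$trace
  attr(tr, "processivity") <- res$processivity
  attr(tr, "final_state") <- res$final_state
  attr(tr, "event_counts") <- res$event_counts
  attr(tr, "n_events") <- res$n_events
  if (log_contacts) attr(tr, "contacts") <- res$contacts
  attr(tr, "meta") <- list(variant = rates$variant, seed = seed,
                           duration = duration, record_dt = record_dt,
                           copies = copies, units = geometry$units,
                           n_dimers = geometry$n_dimers,
                           protocol = protocol)
  class(tr) <- c("lattice_trace", "data.frame")
  tr
}

#' Equilibrate, then record
#'
#' Runs a burn-in of `burn_in` seconds at the protocol baseline, discards
#' it, and continues for `duration` seconds under the full protocol starting
#' from the equilibrated state.  The burn-in must span several tether
#' exchange times (>> 15 s) for the localized enzyme pools to reach their
#' stationary levels; a burn-in of 0 is flagged with a warning.
#'
#' @inheritParams simulate_lattice
#' @param burn_in burn-in time (s), discarded.
#' @return List with `state` (the post-burn-in engine state) and `trace`
#'   (the post-burn-in `lattice_trace`, time starting at 0).
#' @export
equilibrate_lattice <- function(geometry, rates = rate_set(),
                                copies = copy_numbers(geometry),
                                protocol = ligand_protocol("constant", 0),
                                burn_in = 500, duration = 600, seed,
                                record_dt = 0.1, mwc = mwc_params(),
                                init_methyl = 1L, log_contacts = FALSE) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  if (burn_in <= 0) {
    warning("burn_in = 0: the recorded trace includes the relaxation transient")
    st <- NULL
  } else {
    base <- ligand_protocol("constant", protocol$L0)
    pre <- simulate_lattice(geometry, rates, copies, base, burn_in,
                            seed = seed, record_dt = record_dt, mwc = mwc,
                            init_methyl = init_methyl)
    st <- attr(pre, "final_state")
  }
  tr <- simulate_lattice(geometry, rates, copies, protocol, duration,
                         seed = seed + 1L, record_dt = record_dt, mwc = mwc,
                         init_state = st, init_methyl = init_methyl,
                         log_contacts = log_contacts)
  list(state = st, trace = tr)
}

#' @export
print.lattice_trace <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Lattice trace: variant %s, %d dimers, %.6g s at dt = %g s (seed %d)\n",
              m$variant, m$n_dimers, m$duration, m$record_dt, m$seed))
  cat(sprintf("  %d rows, %.3g reaction events\n", nrow(x),
              attr(x, "n_events")))
  cat(sprintf("  final mean activity %.4f, mean methylation per complex %.3f\n",
              x$a_mean[nrow(x)], x$m_mean[nrow(x)]))
  invisible(x)
}

#' @export
summary.lattice_trace <- function(object, burn_in = 0, ...) {
  ns <- noise_stats(object, burn_in = burn_in)
  m <- attr(object, "meta")
  out <- list(variant = m$variant, n_dimers = m$n_dimers,
              duration = m$duration, a0 = ns$a0, sigma_aa = ns$sigma_aa,
              rel_noise = ns$rel_noise,
              mean_loc_cheR = mean(object$loc_cheR),
              mean_loc_cheBp = mean(object$loc_cheBp),
              event_counts = attr(object, "event_counts"))
  class(out) <- "summary.lattice_trace"
  out
}

#' @export
print.summary.lattice_trace <- function(x, ...) {
  cat(sprintf("Variant %s on %d dimers, %.6g s\n", x$variant, x$n_dimers,
              x$duration))
  cat(sprintf("  a0 = %.4f, sigma_aa = %.3g, sigma_a/a0 = %.2f%%\n",
              x$a0, x$sigma_aa, 100 * x$rel_noise))
  cat(sprintf("  mean localized CheR %.1f, CheB-P %.1f\n",
              x$mean_loc_cheR, x$mean_loc_cheBp))
  invisible(x)
}

#' @export
plot.lattice_trace <- function(x, smooth_window = 0, ...) {
  a <- if (smooth_window > 0) smooth_trace(x, smooth_window) else x$a_mean
  plot(x$time, x$a_mean, type = "l", col = "grey70",
       xlab = "time (s)", ylab = "mean receptor activity a(t)", ...)
  if (smooth_window > 0) lines(x$time, a, col = "black", lwd = 2)
  invisible(x)
}

#' Sliding-window average of the activity trace
#'
#' Produces the display-smoothed activity series (default 30 s window, the
#' convention used for plotted traces); statistics such as [noise_stats()]
#' are always computed on the raw series.
#'
#' @param trace a `lattice_trace` (or data frame with `time` and `a_mean`).
#' @param window window length in seconds.
#' @return Numeric vector, same length as the trace.
#' @export
smooth_trace <- function(trace, window = 30) {
  dt <- diff(trace$time[1:2])
  k <- max(1L, as.integer(round(window / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  as.numeric(stats::filter(trace$a_mean, rep(1 / k, k), sides = 2)) -> sm
  # shrink the window at the edges instead of dropping to NA
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1L, i - (k %/% 2L)); hi <- min(length(sm), i + (k %/% 2L))
    sm[i] <- mean(trace$a_mean[lo:hi])
  }
  sm
}
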