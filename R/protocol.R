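#' Ligand stimulation protocol
#'
#' Describes the methyl-aspartate input `L(t)` presented to the simulated
#' cell: a constant background, a step applied at `t_step`, or an
#' exponential ramp `L(t) = L0 * exp(rate * t)` clipped to
#' `[L_min, L_max]`.  The default ramp bounds, 84-620 uM, reproduce the
#' range used in ramp-response calibration experiments.
#'
#' During simulation a ramp is discretized to a piecewise-constant profile
#' on the recording grid; ramp time scales (tens of seconds) are far slower
#' than reaction events (milliseconds), so the discretization bias is
#' negligible.
#'
#' @param kind `"constant"`, `"step"` or `"ramp"`.
#' @param L0 baseline concentration (uM).
#' @param L1 post-step concentration (uM; step only).
#' @param t_step step time (s; step only).
#' @param rate exponential ramp rate (1/s; ramp only, may be negative).
#' @param L_min,L_max ramp clipping bounds (uM).
#' @return An object of class `ligand_protocol`.
#' @examples
#' ligand_protocol("step", L0 = 0, L1 = 1000, t_step = 200)
#' ligand_protocol("ramp", L0 = 84, rate = 0.01)
#' @export
ligand_protocol <- function(kind = c("constant", "step", "ramp"),
                            L0 = 0, L1 = NULL, t_step = NULL,
                            rate = NULL, L_min = 84, L_max = 620) {
  kind <- match.arg(kind)
  if (L0 < 0) stop("ligand concentrations must be >= 0", call. = FALSE)
  if (kind == "step") {
    if (is.null(L1) || is.null(t_step) || L1 < 0 || t_step < 0)
      stop("a step protocol needs L1 >= 0 and t_step >= 0", call. = FALSE)
  }
  if (kind == "ramp") {
    if (is.null(rate)) stop("a ramp protocol needs a rate (1/s)", call. = FALSE)
    if (L_min < 0 || L_max <= L_min)
      stop("ramp bounds must satisfy 0 <= L_min < L_max", call. = FALSE)
    if (L0 == 0) L0 <- if (rate >= 0) L_min else L_max
  }
  structure(list(kind = kind, L0 = L0, L1 = L1, t_step = t_step,
                 rate = rate, L_min = L_min, L_max = L_max),
            class = "ligand_protocol")
}

#' @export
print.ligand_protocol <- function(x, ...) {
  switch(x$kind,
    constant = cat(sprintf("Ligand protocol: constant %g uM\n", x$L0)),
    step = cat(sprintf("Ligand protocol: step %g -> %g uM at t = %g s\n",
                       x$L0, x$L1, x$t_step)),
    ramp = cat(sprintf(
      "Ligand protocol: exponential ramp from %g uM, rate %g /s, bounds [%g, %g] uM\n",
      x$L0, x$rate, x$L_min, x$L_max)))
  invisible(x)
}

#' Evaluate a ligand protocol
#'
#' @param protocol a [ligand_protocol()].
#' @param t time(s) in seconds.
#' @return `L(t)` in uM (vectorized).
#' @export
protocol_ligand <- function(protocol, t) {
  stopifnot(inherits(protocol, "ligand_protocol"))
  switch(protocol$kind,
    constant = rep(protocol$L0, length(t)),
    step = ifelse(t < protocol$t_step, protocol$L0, protocol$L1),
    ramp = pmin(pmax(protocol$L0 * exp(protocol$rate * t),
                     protocol$L_min), protocol$L_max))
}

# piecewise-constant (time, L) grid handed to the SSA engine
.protocol_grid <- function(protocol, duration, dt) {
  switch(protocol$kind,
    constant = cbind(0, protocol$L0),
    step = {
      if (protocol$t_step >= duration) cbind(0, protocol$L0)
      else if (protocol$t_step <= 0) cbind(0, protocol$L1)
      else rbind(c(0, protocol$L0), c(protocol$t_step, protocol$L1))
    },
    ramp = {
      tt <- seq(0, duration, by = dt)
      cbind(tt, protocol_ligand(protocol, tt))
    })
}
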