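#' MWC parameters for a receptor signaling complex
#'
#' Parameters of the equilibrium Monod-Wyman-Changeux (MWC) two-state model
#' of a signaling complex of `N` receptor dimers.  The free-energy difference
#' between the active and the inactive state of a complex decreases by
#' `eps_m` (in units of kT) per methyl group and increases with ligand
#' through the standard log-occupancy term with dissociation constants
#' `K_off` (inactive state) and `K_on` (active state).  The attractant
#' convention `K_off < K_on` makes ligand inactivating, so that adaptation
#' proceeds by re-methylation.
#'
#' `m_half` is the total complex methylation (summed over the `N` dimers,
#' each carrying 0-8 methyl groups) at which the free energy vanishes in the
#' absence of ligand, i.e. at which activity is exactly 1/2.  When `m_half`
#' is `NULL` it is set by [mwc_calibrate()] so that a complex with total
#' methylation 6 is half active at zero ligand, the anchor used throughout
#' the package (a Shimizu-style Tar/MeAsp calibration).
#'
#' @param N dimers per complex (integer, >= 1).
#' @param eps_m free-energy decrement per methyl group (kT, > 0).
#' @param K_off ligand dissociation constant of the inactive state (uM).
#' @param K_on ligand dissociation constant of the active state (uM);
#'   must exceed `K_off`.
#' @param m_half methylation offset in `[0, 8N]`, or `NULL` to calibrate.
#' @return An object of class `mwc_params`.
#' @seealso [mwc_activity()], [mwc_free_energy()], [mwc_calibrate()]
#' @examples
#' p <- mwc_params()
#' mwc_activity(6, 0, p)      # 0.5 by calibration
#' mwc_activity(6, 100, p)    # attractant lowers activity
#' @export
mwc_params <- function(N = 6L, eps_m = 1.0, K_off = 18.2, K_on = 3000,
                       m_half = NULL) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("'N' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(eps_m) || length(eps_m) != 1L || eps_m <= 0)
    stop("'eps_m' must be a single positive number (kT)", call. = FALSE)
  if (!is.numeric(K_off) || !is.numeric(K_on) || K_off <= 0 || K_on <= K_off)
    stop("need 0 < K_off < K_on (attractant convention)", call. = FALSE)
  p <- structure(list(N = N, eps_m = eps_m, K_off = K_off, K_on = K_on,
                      m_half = NA_real_),
                 class = "mwc_params")
  if (is.null(m_half)) return(mwc_calibrate(p))
  if (!is.numeric(m_half) || m_half < 0 || m_half > 8 * N)
    stop("'m_half' must lie in [0, 8N]", call. = FALSE)
  p$m_half <- m_half
  p
}

#' Calibrate the MWC free-energy offset
#'
#' Fixes the free-energy intercept `m_half` of an [mwc_params()] set so that
#' the activity of a complex with total methylation 6 equals exactly 1/2 at
#' zero ligand.  Because the free energy is linear in methylation with slope
#' `-eps_m`, this amounts to `m_half = 6`, independent of the remaining
#' parameters; the constraint is still solved numerically as a guard on the
#' parameterization.
#'
#' @param params an `mwc_params` object (its `m_half` is ignored), or a list
#'   of arguments forwarded to [mwc_params()].
#' @return The calibrated `mwc_params` object.
#' @export
mwc_calibrate <- function(params = mwc_params(m_half = 6)) {
  if (!inherits(params, "mwc_params"))
    params <- do.call(mwc_params, c(params, list(m_half = 0)))
  if (params$eps_m <= 0) stop("calibration infeasible: eps_m <= 0", call. = FALSE)
  anchor <- 6
  if (anchor > 8 * params$N)
    stop("calibration infeasible: anchor methylation exceeds 8N", call. = FALSE)
  # a(m_half, 0) = 1/2 by construction and F is linear in m, so m_half = anchor;
  # solve anyway so any future reparameterization cannot silently break this.
  f <- function(mh) {
    q <- params; q$m_half <- mh
    mwc_free_energy(anchor, 0, q)
  }
  params$m_half <- uniroot(f, c(0, 8 * params$N), tol = 1e-12)$root
  params
}

#' @export
print.mwc_params <- function(x, ...) {
  cat("MWC complex parameters\n")
  cat(sprintf("  N      : %d dimers per complex\n", x$N))
  cat(sprintf("  eps_m  : %.4g kT per methyl group\n", x$eps_m))
  cat(sprintf("  K_off  : %.4g uM (inactive state)\n", x$K_off))
  cat(sprintf("  K_on   : %.4g uM (active state)\n", x$K_on))
  cat(sprintf("  m_half : %.4g (complex methylation with a = 0.5 at L = 0)\n",
              x$m_half))
  invisible(x)
}

.check_mL <- function(m_total, L, params) {
  if (!inherits(params, "mwc_params")) stop("'params' must be mwc_params", call. = FALSE)
  if (any(!is.finite(m_total)) || any(m_total < 0) || any(m_total > 8 * params$N))
    stop("'m_total' must lie in [0, 8N]", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0))
    stop("'L' must be a non-negative ligand concentration (uM)", call. = FALSE)
}

#' Free energy of the active state of a signaling complex
#'
#' \deqn{F(m, L) = \epsilon_m (m_{1/2} - m) +
#'   N \log\frac{1 + L/K_{off}}{1 + L/K_{on}}}
#' in units of kT.  `F` is strictly decreasing in total methylation `m_total`
#' and strictly increasing in the attractant concentration `L`.
#'
#' @param m_total total methylation of the complex, in `[0, 8N]` (vectorized).
#' @param L ligand (methyl-aspartate) concentration, uM (vectorized).
#' @inheritParams mwc_calibrate
#' @return Free energy in kT.
#' @export
mwc_free_energy <- function(m_total, L, params = mwc_params()) {
  .check_mL(m_total, L, params)
  params$eps_m * (params$m_half - m_total) +
    params$N * log((1 + L / params$K_off) / (1 + L / params$K_on))
}

#' Activity (open probability) of a signaling complex
#'
#' The fraction of time an MWC complex spends in the active state,
#' `a = 1 / (1 + exp(F))` with `F` from [mwc_free_energy()].  `a` is
#' monotone increasing in methylation, decreasing in attractant, and equals
#' exactly 1/2 where the free energy vanishes.
#'
#' @inheritParams mwc_free_energy
#' @return Activity in (0, 1).
#' @export
mwc_activity <- function(m_total, L, params = mwc_params()) {
  1 / (1 + exp(mwc_free_energy(m_total, L, params)))
}
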