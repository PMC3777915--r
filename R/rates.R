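#' Kinetic rate set for the lattice simulation
#'
#' All first-order rate constants of the enzyme-receptor reaction scheme,
#' per species (suffix `_r` for CheR, `_b` for CheB-P), plus the bulk CheB
#' phosphorylation cycle.  The shipped defaults satisfy the calibration
#' constraints the model is built on (supplementary parameter tables for the
#' original study are not available, so the constraints themselves are the
#' specification):
#'
#' * localization of a cytoplasmic enzyme through tether binding takes
#'   about 15 s (`k_t_bind = 1/15` per second), as measured by FRAP;
#' * direct bulk binding to the modification site is slower still
#'   (`k_m_bind_bulk = 1/60`), reflecting the lower affinity of that site;
#' * reactions within the ~5 nm tether radius are fast, on 1-10 ms time
#'   scales (`k_m_bind_local`, `k_t_bind_local` = 100 per second per target
#'   dimer, ~1.4 ms aggregated over a 7-dimer assistance neighborhood), so
#'   brachiation moves are fast relative to catalysis and enzymes randomize
#'   their position between modification events (the distributive regime);
#' * the local saturation constants `K = (k_m_unbind + k_cat) /
#'   (7 k_m_bind_local)` equal 0.02 for both enzymes, placing the localized
#'   enzymes deep in the saturated (zero-order) regime `K << 1`;
#' * tether unbinding rates are set so that, at an operating activity of
#'   `1/3`, localized and cytoplasmic enzyme numbers are comparable
#'   (the balanced-tether-exchange regime), which also puts the effective
#'   inverse affinities near 1 (robust steady state);
#' * `k_cat_r` gives recovery from a 1 mM methyl-aspartate step within a
#'   few hundred seconds; `k_cat_b` is calibrated against the lattice
#'   simulation itself so that the simulated adapted activity sits in the
#'   typical range 0.3-0.5 at nominal expression (lattice correlations make
#'   localized CheB-P less effective than the mean-field balance assumes,
#'   so this calibration is done on the stochastic model, not its
#'   mean-field reduction).
#'
#' The derivation of each default from these constraints is worked through
#' in the package vignette.
#'
#' @param ... named overrides of any rate (see Details for names).
#' @param variant model variant, `"M1"` (reference: assistance neighborhoods
#'   and brachiation), `"M2"` (no neighbor binding, hence no assistance
#'   neighborhoods or brachiation), `"M3"` (tether unbinding slowed tenfold,
#'   hence inefficient brachiation), or `"B1"` (no tethering or lattice
#'   localization at all; see [b1_rate_set()]).
#' @return An object of class `rate_set`: a named list of rates and variant
#'   flags understood by [simulate_lattice()].
#' @examples
#' rate_set()                       # M1 defaults
#' rate_set(variant = "M3")         # slow tether release
#' rate_set(k_cat_r = 1)            # override one rate
#' @export
rate_set <- function(..., variant = c("M1", "M2", "M3", "B1")) {
  variant <- match.arg(variant)
  if (variant == "B1") return(b1_rate_set(...))
  r <- list(
    k_t_bind_r = 1 / 15, k_t_bind_b = 1 / 15,
    k_t_unbind_r = 2.29, k_t_unbind_b = 1.024,
    k_m_bind_bulk_r = 1 / 60, k_m_bind_bulk_b = 1 / 60,
    k_m_bind_local_r = 100, k_m_bind_local_b = 100,
    k_t_bind_local_r = 100, k_t_bind_local_b = 100,
    k_m_unbind_r = 12.0, k_m_unbind_b = 12.2,
    k_cat_r = 2.0, k_cat_b = 1.8,
    a_p = 20, d_p = 1.0,
    neighbor_binding = TRUE, tethering = TRUE,
    release_on_catalysis = TRUE,
    tether_unbind_scale = 1.0, methyl_max = 8L,
    variant = variant)
  if (variant == "M2") r$neighbor_binding <- FALSE
  if (variant == "M3") r$tether_unbind_scale <- 0.1
  r <- .apply_overrides(r, list(...))
  .validate_rate_set(r)
}

#' Rate set for the well-mixed baseline model B1
#'
#' In B1 there is no enzyme tethering and no lattice localization: enzymes
#' in the bulk bind receptor modification sites directly, with the same
#' activity-dependent weighting as the full model (CheR proportional to
#' `1 - a`, CheB-P to `a`), unbind or catalyze, and return to the bulk.
#' Receptor cooperativity (MWC complexes) is retained.  The defaults put
#' the enzyme-substrate interaction well away from saturation
#' (`K_B1 = (k_m_unbind + k_cat) / k_m_bind_bulk = 0.5` for both enzymes),
#' the regime in which a ramp-calibrated methylation model reproduces mean
#' adaptation kinetics with low noise.  `b2_scale` divides that constant
#' (by increasing the binding rate), producing the high-affinity variant B2;
#' `b2_scale = 10` gives the tenfold-affinity model whose steady state is
#' ultrasensitive to enzyme counts.
#'
#' @param ... named overrides.
#' @param b2_scale affinity multiplier (1 = B1, 10 = B2).
#' @return A `rate_set` with tethering disabled.
#' @export
b1_rate_set <- function(..., b2_scale = 1) {
  r <- list(
    k_t_bind_r = 0, k_t_bind_b = 0,
    k_t_unbind_r = 0, k_t_unbind_b = 0,
    k_m_bind_bulk_r = 16 * b2_scale, k_m_bind_bulk_b = 16 * b2_scale,
    k_m_bind_local_r = 0, k_m_bind_local_b = 0,
    k_t_bind_local_r = 0, k_t_bind_local_b = 0,
    k_m_unbind_r = 6.0, k_m_unbind_b = 6.08,
    k_cat_r = 2.0, k_cat_b = 1.92,
    a_p = 20, d_p = 1.0,
    neighbor_binding = FALSE, tethering = FALSE,
    release_on_catalysis = TRUE,
    tether_unbind_scale = 1.0, methyl_max = 8L,
    variant = if (b2_scale == 1) "B1" else "B2")
  r <- .apply_overrides(r, list(...))
  .validate_rate_set(r)
}

.apply_overrides <- function(r, dots) {
  if (!length(dots)) return(r)
  bad <- setdiff(names(dots), names(r))
  if (length(bad))
    stop("unknown rate-set fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  modifyList(r, dots)
}

.validate_rate_set <- function(r) {
  num <- vapply(r[!(names(r) %in% c("neighbor_binding", "tethering",
                                    "release_on_catalysis", "variant"))],
                as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num < 0))
    stop("all rates must be finite and non-negative", call. = FALSE)
  if (r$methyl_max < 1) stop("methyl_max must be >= 1", call. = FALSE)
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("Rate set (variant %s)\n", x$variant))
  flags <- c("neighbor_binding", "tethering", "release_on_catalysis")
  for (nm in setdiff(names(x), "variant")) {
    if (nm %in% flags) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
    else cat(sprintf("  %-22s %.5g\n", nm, as.numeric(x[[nm]])))
  }
  invisible(x)
}

#' Enzyme and receptor copy numbers
#'
#' Default copy numbers follow published immunoblotting estimates for cells
#' expressing the chemotaxis proteins from the native loci: about 140 CheR
#' and 240 CheB per cell for a receptor cluster of 7200 dimers.  When the
#' simulation lattice is smaller than the production-scale 7200-dimer
#' cluster, enzyme counts are scaled down proportionally to the dimer count
#' so that the enzyme-to-receptor density is preserved (the scaled-down
#' mode).  An overall `expression` multiplier co-scales CheR and CheB
#' (receptors are the lattice itself), preserving the CheR/CheB/receptor
#' ratio as enforced by cotranscription, which is how population variability
#' is modeled.
#'
#' @param geometry a `receptor_lattice`, or a dimer count.
#' @param cheR,cheB copy numbers at the 7200-dimer reference scale.
#' @param expression overall expression multiplier (ratio-preserving).
#' @param cheR_factor extra multiplier applied to CheR only (enzyme scans).
#' @return List with integer `cheR`, `cheB` and the `dimers` they refer to.
#' @export
copy_numbers <- function(geometry, cheR = 140, cheB = 240, expression = 1,
                         cheR_factor = 1) {
  n <- if (inherits(geometry, "receptor_lattice")) geometry$n_dimers
       else as.integer(geometry)
  s <- n / 7200
  list(cheR = max(1L, as.integer(round(cheR * s * expression * cheR_factor))),
       cheB = max(1L, as.integer(round(cheB * s * expression))),
       dimers = n)
}
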