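#' Read a run configuration file
#'
#' A run is fully described by a structured YAML file with named blocks,
#' all optional (package defaults fill the gaps):
#'
#' ```yaml
#' variant: M1            # M1 | M2 | M3 | B1
#' lattice: {width: 8, height: 8}
#' mwc:     {N: 6, eps_m: 1.0, K_off: 18.2, K_on: 3000}
#' rates:   {k_cat_r: 2.0}          # overrides of rate_set(variant)
#' copies:  {cheR: 140, cheB: 240, expression: 1, cheR_factor: 1}
#' protocol: {kind: step, L0: 0, L1: 1000, t_step: 200}
#' run:     {duration: 600, burn_in: 500, record_dt: 0.1, seed: 1}
#' ```
#'
#' `copies` values refer to the 7200-dimer reference scale and are scaled
#' to the configured lattice by [copy_numbers()].  The MWC offset `m_half`
#' is calibrated via [mwc_calibrate()] unless given explicitly.
#'
#' @param path YAML file path.
#' @return Object of class `run_config`: list with `geometry`, `rates`,
#'   `mwc`, `copies`, `protocol`, `run`, ready for [run_simulation()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a nested list with the blocks described above (an already
#'   parsed configuration).
#' @export
as_run_config <- function(cfg) {
  variant <- cfg$variant %||% "M1"
  lat_cfg <- cfg$lattice %||% list(width = 8, height = 8)
  geometry <- build_lattice(lat_cfg$width %||% 8,
                            lat_cfg$height %||% lat_cfg$width %||% 8)
  mwc_cfg <- cfg$mwc %||% list()
  mwc <- do.call(mwc_params, mwc_cfg)
  rates <- do.call(rate_set, c(cfg$rates %||% list(),
                               list(variant = variant)))
  cp_cfg <- cfg$copies %||% list()
  copies <- copy_numbers(geometry,
                         cheR = cp_cfg$cheR %||% 140,
                         cheB = cp_cfg$cheB %||% 240,
                         expression = cp_cfg$expression %||% 1,
                         cheR_factor = cp_cfg$cheR_factor %||% 1)
  pr_cfg <- cfg$protocol %||% list(kind = "constant", L0 = 0)
  protocol <- do.call(ligand_protocol, pr_cfg)
  run <- modifyList(list(duration = 600, burn_in = 500, record_dt = 0.1,
                         seed = 1), cfg$run %||% list())
  structure(list(geometry = geometry, rates = rates, mwc = mwc,
                 copies = copies, protocol = protocol, run = run),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured run
#'
#' Equilibrates and records a stochastic lattice simulation as described by
#' a [read_run_config()] object, returning the post-burn-in trace.
#'
#' @param config a `run_config`.
#' @param seed optional override of the configured seed.
#' @return A `lattice_trace` (see [simulate_lattice()]).
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  r <- config$run
  eq <- equilibrate_lattice(config$geometry, config$rates, config$copies,
                            protocol = config$protocol,
                            burn_in = r$burn_in, duration = r$duration,
                            seed = seed %||% r$seed,
                            record_dt = r$record_dt, mwc = config$mwc)
  eq$trace
}
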