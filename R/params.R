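#' Model parameters
#'
#' Creates the full ecological-economic parameter set. Thirteen slots are
#' calibratable (see [default_priors()]); the rest are fixed constants of the
#' model configuration. Defaults are the package's reference ("truth")
#' conditions, chosen so the synthetic-Earth model reproduces the observed
#' global magnitudes of the 20th-century fishery (see the methods vignette).
#'
#' @param ... Named overrides of any parameter below.
#' @section Calibrated slots:
#' \describe{
#'   \item{eps_trophic}{Trophic transfer efficiency per trophic level (-).}
#'   \item{ppmr}{Predator-prey mass ratio (-), sets the number of trophic
#'     steps from phytoplankton to 10-g fish.}
#'   \item{growth_A}{Allometric growth coefficient, g^(1-b) yr^-1.}
#'   \item{growth_b}{Growth exponent (-).}
#'   \item{mort_zeta}{Mortality coefficient, g^(1-h) yr^-1.}
#'   \item{mort_h}{Mortality exponent (-).}
#'   \item{Ea}{Activation energy, eV; one Arrhenius factor shared by growth,
#'     mortality and trophic transfer.}
#'   \item{s_egg}{Egg/larval survival to the smallest resolved size (-).}
#'   \item{recruit_K}{Half-saturation of the egg-production flux,
#'     g m^-2 yr^-1 (density-dependent recruitment).}
#'   \item{repro_frac}{Asymptotic fraction of acquired energy allocated to
#'     reproduction at maturity (-).}
#'   \item{q0}{Baseline (1950) catchability, m^2 W^-1 yr^-1.}
#'   \item{k_e}{Fleet responsiveness, W $^-1: effort change per unit profit.}
#'   \item{sel_ratio}{Position of the 50% selectivity point relative to each
#'     group's asymptotic mass (-).}
#' }
#' @section Fixed slots:
#' `T_ref` (degC), `m_phyto` (g, effective phytoplankton mass), `price0`
#' ($ kg^-1), `cost0` ($ W^-1 yr^-1), `E_floor` (W m^-2 exploratory effort
#' floor), `E_init` (W m^-2 seed effort at the start of a coupled run),
#' `sel_width` (selectivity logistic width, ln-mass units),
#' `psi_center` (maturity midpoint as a fraction of asymptotic mass),
#' `psi_width` (maturity logistic width, log10-mass units).
#' @return Named list of class `fc_params`.
#' @export
fc_params <- function(...) {
  p <- list(
    # calibrated (13)
    eps_trophic = 0.15,
    ppmr        = 1500,
    growth_A    = 4.5,
    growth_b    = 0.7,
    mort_zeta   = 1.0,
    mort_h      = 0.55,
    Ea          = 0.35,
    s_egg       = 0.10,
    recruit_K   = 0.003,
    repro_frac  = 0.8,
    q0          = 11000,
    k_e         = 0.011,
    sel_ratio   = 0.20,
    # fixed
    T_ref      = 10,
    m_phyto    = 1e-9,
    price0     = 1,
    cost0      = 14,
    E_floor    = 1e-12,
    E_init     = 1e-8,
    sel_width  = log(10) / 4,
    psi_center = 0.25,
    psi_width  = 0.25
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "fc_params")
}

validate_params <- function(p) {
  stopifnot(p$eps_trophic > 0, p$eps_trophic < 1,
            p$growth_b > 0, p$growth_b < 1,
            p$mort_h > 0, p$mort_h < 1,
            p$ppmr > 1, p$growth_A > 0, p$mort_zeta > 0,
            p$s_egg > 0, p$recruit_K > 0,
            p$repro_frac > 0, p$repro_frac <= 1,
            p$q0 > 0, p$k_e > 0, p$sel_ratio > 0, p$E_floor > 0)
  invisible(p)
}

#' @export
print.fc_params <- function(x, ...) {
  cat("<fc_params>\n")
  print(params_table(x), n = Inf)
  invisible(x)
}

#' Parameter set as a tibble
#'
#' @param params An `fc_params`.
#' @return Tibble with `name`, `value`, `calibrated`.
#' @export
params_table <- function(params = fc_params()) {
  pr <- default_priors()
  tibble::tibble(name = names(params),
                 value = unlist(params, use.names = FALSE),
                 calibrated = names(params) %in% pr$name)
}

#' Update a parameter set from a named vector or tibble row
#' @param params An `fc_params` to start from.
#' @param values Named numeric vector (or one-row data frame) of overrides.
#' @export
set_params <- function(params, values) {
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  values <- values[names(values) %in% names(params)]
  params[names(values)] <- as.numeric(values)
  validate_params(params)
  structure(params, class = "fc_params")
}

#' Priors for the 13 calibrated parameters
#'
#' Independent uniform priors, on log scale for scale-type parameters. Bounds
#' bracket literature ranges for metabolic, life-history and fleet-dynamics
#' constants; the reference values of [fc_params()] sit near the centres.
#'
#' @return Tibble of class `fc_priors`: `name`, `lower`, `upper`, `scale`
#'   ("linear" or "log"), `calibrated`.
#' @export
default_priors <- function() {
  pr <- tibble::tribble(
    ~name,          ~lower, ~upper, ~scale,
    "eps_trophic",   0.08,   0.28,  "log",
    "ppmr",          500,    4500,  "log",
    "growth_A",      1.5,    12,    "log",
    "growth_b",      0.6,    0.8,   "linear",
    "mort_zeta",     0.35,   3,     "log",
    "mort_h",        0.4,    0.7,   "linear",
    "Ea",            0.2,    0.55,  "linear",
    "s_egg",         0.02,   0.5,   "log",
    "recruit_K",     3e-4,   3e-2,  "log",
    "repro_frac",    0.5,    0.95,  "linear",
    "q0",            3000,   40000, "log",
    "k_e",           0.002,  0.05,  "log",
    "sel_ratio",     0.07,   0.6,   "log"
  )
  pr$calibrated <- TRUE
  structure(pr, class = c("fc_priors", class(pr)))
}
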