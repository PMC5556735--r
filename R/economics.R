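#' Harvest selectivity
#'
#' Logistic in log mass, reaching 0.5 at `sel_ratio` times the group's
#' asymptotic mass: small individuals escape the gear, large ones are fully
#' selected.
#'
#' @param m Body mass, g.
#' @param m_asym Asymptotic mass of the group, g.
#' @param params [fc_params()].
#' @return Dimensionless selectivity in `[0, 1]`.
#' @export
selectivity <- function(m, m_asym, params) {
  1 / (1 + exp(-(log(m) - log(params$sel_ratio * m_asym)) / params$sel_width))
}

#' Harvest rate from biomass and effort
#'
#' Fishing mortality `F(group, bin) = q * effort * selectivity(m)` and total
#' harvest rate `h = sum(F * B)` for one cell.
#'
#' @param B Biomass matrix (group x bin), g m^-2.
#' @param effort Nominal effort, W m^-2.
#' @param q Catchability, m^2 W^-1 yr^-1.
#' @param params,axis Model configuration.
#' @return List: `h` (g m^-2 yr^-1), `F_mort` (group x bin, yr^-1).
#' @export
harvest_rate <- function(B, effort, q, params, axis = mass_axis()) {
  F_mort <- q * effort * fc_sel(axis, params) * fc_mask(axis)
  list(h = sum(F_mort * B), F_mort = F_mort)
}

#' Open-access effort update
#'
#' Forward-Euler step of `dE/dt = k_e * (price * h / 1000 - cost * E)`:
#' effort grows where revenue (price $ kg^-1 times harvest, the 1/1000
#' converting g to kg) exceeds cost, shrinks where it does not, and never
#' falls below the exploratory floor `E_floor`.
#'
#' @param effort Nominal effort, W m^-2.
#' @param h Harvest rate, g m^-2 yr^-1.
#' @param price $ kg^-1.
#' @param cost $ W^-1 yr^-1.
#' @param params [fc_params()].
#' @param dt Time step, yr.
#' @return Updated effort, W m^-2.
#' @export
step_effort <- function(effort, h, price, cost, params, dt) {
  stopifnot(dt > 0)
  e <- effort + dt * params$k_e * (price * h / 1000 - cost * effort)
  pmax(e, params$E_floor)
}

#' Cost per unit effort from the open-access steady state
#'
#' Under bionomic equilibrium profit is zero, so
#' `cost = price * harvest / effort`. Used to anchor the historical global
#' average cost from observed price, harvest and effort.
#'
#' @param price $ kg^-1.
#' @param global_harvest kg yr^-1.
#' @param global_effort W.
#' @return $ W^-1 yr^-1.
#' @export
cost_from_steady_state <- function(price, global_harvest, global_effort) {
  if (any(global_effort <= 0)) stop("effort must be positive", call. = FALSE)
  price * global_harvest / global_effort
}

#' Scenario schedules for technology, price and cost
#'
#' @param tech_mode "constant", "exponential" (rate %/yr relative to
#'   `tech_t_ref`), or "stabilizing" (exponential until `ramp_start`, growth
#'   rate declining linearly to zero at `ramp_end`, constant after).
#' @param tech_rate Annual catchability growth rate (fraction, e.g. 0.05).
#' @param tech_t_ref Year at which `q = q0`.
#' @param ramp_start,ramp_end Stabilization window.
#' @param price_mode "constant", "linear" (from `p_start` at `price_t_start`
#'   to `p_end` at `price_t_end`), or "table".
#' @param p_start,p_end,price_t_start,price_t_end Linear-price end-members,
#'   $ kg^-1.
#' @param price_table,cost_table Optional two-column data frames
#'   (`year`, `value`) interpolated linearly, constant outside their range.
#' @param cost_mode "constant" or "table".
#' @return List of class `fc_scenario`.
#' @export
scenario <- function(tech_mode = c("exponential", "constant", "stabilizing"),
                     tech_rate = 0.05, tech_t_ref = 1950,
                     ramp_start = 2006, ramp_end = 2036,
                     price_mode = c("constant", "linear", "table"),
                     p_start = 1, p_end = 3,
                     price_t_start = 2006, price_t_end = 2100,
                     price_table = NULL,
                     cost_mode = c("constant", "table"), cost_table = NULL) {
  tech_mode <- match.arg(tech_mode)
  price_mode <- match.arg(price_mode)
  cost_mode <- match.arg(cost_mode)
  if (ramp_end <= ramp_start) stop("ramp_end must exceed ramp_start", call. = FALSE)
  if (tech_rate < 0) stop("tech_rate must be >= 0", call. = FALSE)
  structure(list(tech_mode = tech_mode, tech_rate = tech_rate,
                 tech_t_ref = tech_t_ref,
                 ramp_start = ramp_start, ramp_end = ramp_end,
                 price_mode = price_mode, p_start = p_start, p_end = p_end,
                 price_t_start = price_t_start, price_t_end = price_t_end,
                 price_table = price_table,
                 cost_mode = cost_mode, cost_table = cost_table),
            class = "fc_scenario")
}

#' Catchability schedule q(t)
#'
#' Exponential mode: `q0 * (1 + rate)^(t - t_ref)`. Stabilizing mode: the
#' annual growth rate declines linearly from `rate` at `ramp_start` to zero at
#' `ramp_end` (discrete annual compounding), after which q is constant.
#'
#' @param scn An [scenario()].
#' @param params [fc_params()] (supplies `q0`).
#' @param years Numeric vector of years.
#' @return Catchability per year, m^2 W^-1 yr^-1.
#' @export
catchability_schedule <- function(scn, params, years) {
  q0 <- params$q0
  if (scn$tech_mode == "constant") return(rep(q0, length(years)))
  if (scn$tech_mode == "exponential") {
    return(q0 * (1 + scn$tech_rate)^(years - scn$tech_t_ref))
  }
  # stabilizing: build the full annual path once, then index
  yy <- seq(min(years[1], scn$tech_t_ref), max(years))
  g <- ifelse(yy < scn$ramp_start, scn$tech_rate,
              ifelse(yy >= scn$ramp_end, 0,
                     scn$tech_rate *
                       (1 - (yy - scn$ramp_start) / (scn$ramp_end - scn$ramp_start))))
  # q at year t applies growth over [t-1, t); anchor q(t_ref) = q0
  lq <- cumsum(c(0, log(1 + g[-length(g)])))
  lq <- lq - lq[match(scn$tech_t_ref, yy)]
  q0 * exp(lq[match(years, yy)])
}

#' Ex-vessel price schedule p(t), $ kg^-1
#' @inheritParams catchability_schedule
#' @export
price_schedule <- function(scn, params, years) {
  switch(scn$price_mode,
         constant = rep(scn$p_start, length(years)),
         linear = {
           f <- pmin(pmax((years - scn$price_t_start) /
                            (scn$price_t_end - scn$price_t_start), 0), 1)
           scn$p_start + f * (scn$p_end - scn$p_start)
         },
         table = {
           tb <- scn$price_table
           if (is.null(tb)) stop("price_mode 'table' needs price_table", call. = FALSE)
           approx(tb$year, tb$value, xout = years, rule = 2)$y
         })
}

#' Cost-per-unit-effort schedule c(t), $ W^-1 yr^-1
#' @inheritParams catchability_schedule
#' @export
cost_schedule <- function(scn, params, years) {
  if (scn$cost_mode == "constant") return(rep(params$cost0, length(years)))
  tb <- scn$cost_table
  if (is.null(tb)) stop("cost_mode 'table' needs cost_table", call. = FALSE)
  approx(tb$year, tb$value, xout = years, rule = 2)$y
}
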