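# Shared setup: community structure and per-cell sub-step counts for a run.
fc_run_setup <- function(params, forcing) {
  axis <- mass_axis()
  t_max <- apply(forcing$sst, 1, max)
  list(axis = axis, n_sub = fc_nsub_cells(params, axis, t_max))
}

# Spin all cells of a forcing climatology to the unfished equilibrium.
fc_spinup_global <- function(clim, params, axis, n_sub, settle_years = 20) {
  T_c <- clim$sst[, 1]; npp <- clim$npp[, 1]
  B <- equilibrium_spectrum(T_c, npp, params, axis, dt = 1 / rep_len(n_sub, length(T_c)))
  ny <- settle_years
  out <- fc_cpp_run(B, effort = 0,
                    sst = matrix(T_c, length(T_c), ny),
                    npp = matrix(npp, length(T_c), ny),
                    q_year = rep(0, ny), price_year = rep(0, ny),
                    cost_year = rep(0, ny),
                    params = params, axis = axis, n_sub = n_sub,
                    effort_mode = 1L)
  list(B = out$B, pristine = rowSums(out$B, dims = 1))
}

#' Run the coupled model over all ocean cells
#'
#' Spins every cell up to its unfished equilibrium under the forcing
#' climatology (recording pristine biomass), then integrates the two-way
#' coupled ecology-economics system over the forcing years under the given
#' scenario schedules. Cells are independent: fishing expands spatially only
#' because technology makes low-density cells profitable.
#'
#' Per-year operation order in each cell: ecology step (with the fishing
#' mortality implied by current effort and catchability), harvest accounting,
#' then the profit-driven effort update.
#'
#' @param forcing An [generate_synthetic_forcing()] (or loaded) forcing.
#' @param params [fc_params()].
#' @param scn [scenario()].
#' @param clim_years Years whose mean defines the spin-up climatology
#'   (default: first decade of the forcing).
#' @return List of class `fc_run`: `cells` (tibble: cell, year, harvest
#'   g m^-2 yr^-1, effort W m^-2, biomass g m^-2, biomass_fraction),
#'   `global` (tibble, see [aggregate_global()]), plus grid, schedules,
#'   pristine biomass and final state.
#' @export
run_global <- function(forcing, params = fc_params(), scn = scenario(),
                       clim_years = head(forcing$years, 10)) {
  stopifnot(inherits(forcing, "fc_forcing"))
  su <- fc_run_setup(params, forcing)
  clim <- climatology(forcing, clim_years)
  sp <- fc_spinup_global(clim, params, su$axis, su$n_sub)

  years <- forcing$years
  q_t <- catchability_schedule(scn, params, years)
  p_t <- price_schedule(scn, params, years)
  c_t <- cost_schedule(scn, params, years)

  out <- fc_cpp_run(sp$B, effort = max(params$E_init, params$E_floor),
                    sst = forcing$sst, npp = forcing$npp,
                    q_year = q_t, price_year = p_t, cost_year = c_t,
                    params = params, axis = su$axis, n_sub = su$n_sub,
                    effort_mode = 0L)
  if (!all(is.finite(out$B))) {
    bad <- which(!is.finite(rowSums(out$B, dims = 1)))[1]
    stop("numerical blow-up in cell ", bad, call. = FALSE)
  }

  oc_cells <- forcing$grid$cell[forcing$grid$ocean]
  nc <- length(oc_cells)
  cells <- tibble::tibble(
    cell = rep(oc_cells, times = length(years)),
    year = rep(years, each = nc),
    harvest = as.vector(out$harvest),
    effort = as.vector(out$effort_mean),
    biomass = as.vector(out$biomass),
    biomass_fraction = as.vector(out$biomass / sp$pristine)
  )
  glob <- aggregate_global(cells, forcing$grid, pristine = sp$pristine,
                           q_rel = q_t / params$q0, price = p_t, cost = c_t)
  structure(list(cells = cells, global = glob, grid = forcing$grid,
                 years = years, params = params, scenario = scn,
                 schedules = tibble::tibble(year = years, q = q_t,
                                            price = p_t, cost = c_t),
                 pristine = sp$pristine,
                 final_B = out$B, final_effort = out$effort),
            class = "fc_run")
}

#' @export
print.fc_run <- function(x, ...) {
  pk <- detect_peak(x$global)
  cat(sprintf("<fc_run> %d cells x %d years (%d-%d)\n",
              length(x$pristine), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  peak harvest %.1f Mt yr-1 in %d (x%.2f of first year)\n",
              pk$value, pk$year, pk$ratio))
  invisible(x)
}

#' Run a single cell
#'
#' One-cell version of [run_global()] for process studies and tests; accepts
#' constant or per-year forcing and either open-access or fixed effort.
#'
#' @param T_c,npp Scalars or vectors over `years`.
#' @param years Years to simulate.
#' @param params,scn Configuration.
#' @param effort Initial (open access) or fixed effort, W m^-2.
#' @param effort_mode "open_access" or "fixed".
#' @param B0 Optional initial biomass (group x bin); default: pristine
#'   equilibrium at the first-year forcing.
#' @return Tibble: year, harvest, effort, biomass, biomass_fraction.
#' @export
run_cell <- function(T_c, npp, years, params = fc_params(), scn = scenario(),
                     effort = NULL, effort_mode = c("open_access", "fixed"),
                     B0 = NULL) {
  effort_mode <- match.arg(effort_mode)
  axis <- mass_axis()
  ny <- length(years)
  sst <- matrix(rep_len(T_c, ny), 1, ny)
  nppm <- matrix(rep_len(npp, ny), 1, ny)
  st <- stability_dt(params, axis, T_max = max(sst, params$T_ref))
  sp <- spinup_pristine(sst[1], nppm[1], params, axis)
  if (is.null(B0)) B0 <- sp$B
  if (is.null(effort)) effort <- max(params$E_init, params$E_floor)
  out <- fc_cpp_run(array(B0, c(1, dim(B0))), effort = effort,
                    sst = sst, npp = nppm,
                    q_year = catchability_schedule(scn, params, years),
                    price_year = price_schedule(scn, params, years),
                    cost_year = cost_schedule(scn, params, years),
                    params = params, axis = axis, n_sub = st$n_sub,
                    effort_mode = if (effort_mode == "fixed") 1L else 0L)
  if (!all(is.finite(out$B))) {
    stop("numerical blow-up in single-cell run at year ",
         years[which(!is.finite(colSums(out$harvest)))[1]], call. = FALSE)
  }
  tibble::tibble(year = years,
                 harvest = as.vector(out$harvest),
                 effort = as.vector(out$effort_mean),
                 biomass = as.vector(out$biomass),
                 biomass_fraction = as.vector(out$biomass) / sp$pristine_biomass)
}

#' Historical open-access hindcast
#'
#' The standard experiment: pristine spin-up, then open access with
#' exponential technological progress (default 5 % yr^-1, `q = q0` in 1950),
#' constant or reconstructed price, constant cost. The forcing should start
#' early enough (default generator: 1850) for the industrial fishery to
#' emerge endogenously before 1950.
#'
#' @inheritParams run_global
#' @param tech_rate Annual catchability growth (fraction).
#' @param price_table Optional historical price table (`year`, `value`).
#' @return An `fc_run`.
#' @export
run_hindcast <- function(forcing, params = fc_params(), tech_rate = 0.05,
                         price_table = NULL) {
  scn <- scenario(tech_mode = if (tech_rate > 0) "exponential" else "constant",
                  tech_rate = tech_rate, tech_t_ref = 1950,
                  price_mode = if (is.null(price_table)) "constant" else "table",
                  price_table = price_table)
  run_global(forcing, params, scn)
}

#' Idealized future projection
#'
#' Continues the open-access hindcast through 2100 under one of four scenario
#' corners: technology either keeps growing at 5 % yr^-1 or stabilizes
#' (growth declining to zero over 2006-2036), with price either constant or
#' rising linearly from 1 to 3 $ kg^-1 over 2006-2100. The hindcast and
#' projection are integrated as one run so the 2006 state carries over.
#'
#' @inheritParams run_global
#' @param tech_mode "exponential" or "stabilizing".
#' @param price_mode "constant" or "linear".
#' @return An `fc_run` spanning the forcing years (which should reach 2100).
#' @export
run_projection <- function(forcing, params = fc_params(),
                           tech_mode = c("exponential", "stabilizing"),
                           price_mode = c("constant", "linear")) {
  tech_mode <- match.arg(tech_mode)
  price_mode <- match.arg(price_mode)
  scn <- scenario(tech_mode = tech_mode, tech_rate = 0.05, tech_t_ref = 1950,
                  ramp_start = 2006, ramp_end = 2036,
                  price_mode = price_mode, p_start = 1, p_end = 3,
                  price_t_start = 2006, price_t_end = 2100)
  run_global(forcing, params, scn)
}

#' Maximum sustainable yield by transient catchability ramp
#'
#' Replaces the profit-driven effort by a fixed nominal effort field (the
#' technical harvesting capacity) and ramps catchability slowly upward from a
#' tiny value under a constant climate, so each cell traverses its
#' equilibrium yield curve quasi-statically. The cell's MSY is its running
#' maximum of annual harvest; the global MSY is the area-weighted sum. The
#' result is independent of price and cost by construction.
#'
#' @param forcing Forcing whose climatology defines the climate (use
#'   [climatology()] with a year window for snapshot climates).
#' @param params [fc_params()].
#' @param ramp List: `F_start` (initial fishing mortality at full selectivity,
#'   yr^-1), `rate` (fractional catchability growth per year), `years`. The
#'   defaults span fishing mortalities from well below to far beyond every
#'   cell's yield maximum while remaining slow enough to be quasi-static.
#' @param E_fix Fixed nominal effort, W m^-2 (only the product `q * E` is
#'   dynamically meaningful).
#' @param clim_years Years averaged into the climate (default first 10).
#' @return List of class `fc_msy`: `cells` tibble (cell, msy g m^-2 yr^-1,
#'   q_at_max m^2 W^-1 yr^-1, F_at_max yr^-1, year_at_max index),
#'   `global_Mt`, and `boundary_flag`
#'   (TRUE if >10 % of contributing cells peaked in the final ramp year,
#'   indicating a non-quasi-static ramp).
#' @export
compute_msy <- function(forcing, params = fc_params(),
                        ramp = list(F_start = 3e-3, rate = 0.015, years = 620),
                        E_fix = 1e-5, clim_years = head(forcing$years, 10)) {
  stopifnot(ramp$F_start > 0, ramp$rate > 0, ramp$years > 10)
  su <- fc_run_setup(params, forcing)
  clim <- climatology(forcing, clim_years)
  sp <- fc_spinup_global(clim, params, su$axis, su$n_sub)
  nc <- nrow(clim$sst)

  ny <- ramp$years
  q_t <- (ramp$F_start / E_fix) * (1 + ramp$rate)^(seq_len(ny) - 1)
  out <- fc_cpp_run(sp$B, effort = E_fix,
                    sst = matrix(clim$sst[, 1], nc, ny),
                    npp = matrix(clim$npp[, 1], nc, ny),
                    q_year = q_t, price_year = rep(0, ny),
                    cost_year = rep(0, ny),
                    params = params, axis = su$axis, n_sub = su$n_sub,
                    effort_mode = 1L)
  imax <- max.col(out$harvest, ties.method = "first")
  msy <- out$harvest[cbind(seq_len(nc), imax)]
  area <- forcing$grid$area[forcing$grid$ocean]
  contributing <- msy > 1e-12
  structure(list(
    cells = tibble::tibble(cell = forcing$grid$cell[forcing$grid$ocean],
                           msy = msy, q_at_max = q_t[imax],
                           F_at_max = q_t[imax] * E_fix,
                           year_at_max = imax),
    global_Mt = sum(msy * area) / fc_const$g_per_mt,
    boundary_flag = mean(imax[contributing] == ny) > 0.1
  ), class = "fc_msy")
}

#' @export
print.fc_msy <- function(x, ...) {
  cat(sprintf("<fc_msy> global MSY %.1f Mt yr-1 (%d cells%s)\n",
              x$global_Mt, nrow(x$cells),
              if (x$boundary_flag) ", ramp boundary warning" else ""))
  invisible(x)
}
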