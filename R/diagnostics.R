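#' Aggregate per-cell trajectories to a global time series
#'
#' Area-weighted sums with unit conversion: harvest g m^-2 yr^-1 times m^2
#' to Mt yr^-1 (1e-12), effort W to GW (1e-9); the global biomass fraction is
#' the ratio of area-weighted totals (not the mean of cell fractions); profit
#' is `price * harvest - cost * effort` in billion $ yr^-1.
#'
#' @param cells Tibble with cell, year, harvest, effort, biomass (as in
#'   `fc_run$cells`).
#' @param grid The [make_grid()] grid.
#' @param pristine Per-ocean-cell pristine biomass, g m^-2.
#' @param q_rel Per-year technology factor `q/q0` (for effective effort);
#'   default 1.
#' @param price,cost Per-year price ($ kg^-1) and cost ($ W^-1 yr^-1);
#'   default 0 (profit reported as NA).
#' @return Tibble of class `fc_global`: year, harvest_Mt, nominal_GW,
#'   effective_GW, biomass_fraction, profit_B.
#' @export
aggregate_global <- function(cells, grid, pristine, q_rel = 1,
                             price = 0, cost = 0) {
  oc <- grid$cell[grid$ocean]
  a <- grid$area[grid$ocean][match(cells$cell, oc)]
  d <- cells
  d$a <- a
  g <- dplyr::summarise(
    dplyr::group_by(d, .data$year),
    harvest_g = sum(.data$harvest * .data$a),
    effort_W = sum(.data$effort * .data$a),
    biomass_g = sum(.data$biomass * .data$a),
    .groups = "drop"
  )
  pristine_g <- sum(pristine * grid$area[grid$ocean])
  ny <- nrow(g)
  q_rel <- rep_len(q_rel, ny); price <- rep_len(price, ny); cost <- rep_len(cost, ny)
  out <- tibble::tibble(
    year = g$year,
    harvest_Mt = g$harvest_g / fc_const$g_per_mt,
    nominal_GW = g$effort_W / fc_const$w_per_gw,
    effective_GW = g$effort_W * q_rel / fc_const$w_per_gw,
    biomass_fraction = g$biomass_g / pristine_g,
    profit_B = ifelse(price > 0,
                      (price * g$harvest_g / 1000 - cost * g$effort_W) / 1e9,
                      NA_real_)
  )
  structure(out, class = c("fc_global", class(out)))
}

#' Locate the peak of a time series
#'
#' First-occurrence argmax, with the ratio of the peak to the first value and
#' a boundary warning when the maximum sits on either end of the series
#' (monotone or constant series).
#'
#' @param x A data frame with a `year` column, or a numeric vector.
#' @param value Column to scan (default "harvest_Mt" when present, else
#'   "harvest").
#' @param years Years (when `x` is a vector).
#' @return One-row tibble: year, value, ratio, boundary.
#' @export
detect_peak <- function(x, value = NULL, years = NULL) {
  if (is.data.frame(x)) {
    if (is.null(value)) {
      value <- if ("harvest_Mt" %in% names(x)) "harvest_Mt" else "harvest"
    }
    v <- x[[value]]
    yr <- x$year
  } else {
    v <- x
    yr <- if (is.null(years)) seq_along(x) else years
  }
  i <- which.max(v)
  tibble::tibble(year = yr[i], value = v[i], ratio = v[i] / v[1],
                 boundary = i == 1L || i == length(v))
}

#' Rate of global biomass depletion over the expansion era
#'
#' Fits a linear slope to the global biomass fraction between the start of
#' large-scale fishing (the first year harvest reaches a threshold fraction
#' of its eventual peak) and the harvest peak, and reports it as percent of
#' pristine biomass lost per decade (positive = decline).
#'
#' @param global An `fc_global` (or `fc_run`) trajectory.
#' @param report_start First year of the reporting window (default 1950).
#' @param threshold Expansion threshold as a fraction of peak harvest.
#' @return One-row tibble: `rate_pct_per_decade`, `year_start`, `year_peak`.
#' @export
depletion_rate <- function(global, report_start = 1950, threshold = 0.1) {
  g <- if (inherits(global, "fc_run")) global$global else global
  g <- g[g$year >= report_start, ]
  pk <- detect_peak(g)
  y0 <- min(g$year[g$harvest_Mt >= threshold * pk$value])
  sub <- g[g$year >= y0 & g$year <= pk$year, ]
  slope <- coef(lm(biomass_fraction ~ year, data = sub))[["year"]]
  tibble::tibble(rate_pct_per_decade = -slope * 1000,
                 year_start = y0, year_peak = pk$year)
}

#' Coastal share of global harvest in a year
#'
#' Area-weighted harvest from coastal cells divided by the global total.
#'
#' @param cells `fc_run$cells` tibble.
#' @param grid The grid.
#' @param year Year to evaluate.
#' @return Fraction in `[0, 1]`; errors if total harvest is zero.
#' @export
coastal_share <- function(cells, grid, year) {
  d <- cells[cells$year == year, ]
  if (nrow(d) == 0) stop("year ", year, " not in trajectories", call. = FALSE)
  a <- grid$area[match(d$cell, grid$cell)]
  co <- grid$coastal[match(d$cell, grid$cell)]
  tot <- sum(d$harvest * a)
  if (tot <= 0) stop("total harvest is zero in ", year,
                     "; coastal share undefined", call. = FALSE)
  sum(d$harvest[co] * a[co]) / tot
}

#' Ensemble mean and spread of global trajectories
#'
#' @param runs List of `fc_global` tibbles (or `fc_run` objects) on a common
#'   year axis.
#' @return Tibble: year, then `<var>_mean` and `<var>_sd` (sample s.d., n-1)
#'   for each trajectory variable.
#' @export
ensemble_stats <- function(runs) {
  gl <- lapply(runs, function(r) if (inherits(r, "fc_run")) r$global else r)
  yrs <- gl[[1]]$year
  stopifnot(all(vapply(gl, function(g) identical(g$year, yrs), logical(1))))
  vars <- setdiff(names(gl[[1]]), "year")
  out <- tibble::tibble(year = yrs)
  for (v in vars) {
    mat <- vapply(gl, function(g) g[[v]], numeric(length(yrs)))
    mat <- matrix(mat, nrow = length(yrs))
    out[[paste0(v, "_mean")]] <- rowMeans(mat)
    out[[paste0(v, "_sd")]] <- apply(mat, 1, sd)
  }
  out
}

#' @export
tidy.fc_run <- function(x, ...) x$global

#' @export
glance.fc_run <- function(x, ...) {
  pk <- detect_peak(x$global)
  yrs <- x$global$year
  tibble::tibble(
    peak_year = pk$year, peak_harvest_Mt = pk$value, peak_ratio = pk$ratio,
    final_biomass_fraction = x$global$biomass_fraction[length(yrs)],
    n_years = length(yrs), n_cells = length(x$pristine)
  )
}

#' @export
tidy.fc_msy <- function(x, ...) x$cells

#' @export
glance.fc_msy <- function(x, ...) {
  tibble::tibble(global_Mt = x$global_Mt, boundary_flag = x$boundary_flag,
                 n_cells = nrow(x$cells))
}

#' Plot a global trajectory
#'
#' Harvest, nominal and effective effort, and biomass fraction as stacked
#' panels, mirroring the standard hindcast figure layout.
#'
#' @param object An `fc_run` or `fc_global`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_run <- function(object, ...) autoplot(object$global, ...)

#' @rdname autoplot.fc_run
#' @export
autoplot.fc_global <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object, "year", "harvest_Mt", "nominal_GW",
                  "effective_GW", "biomass_fraction"),
    -"year", names_to = "variable", values_to = "value")
  d$variable <- factor(d$variable,
                       levels = c("harvest_Mt", "nominal_GW", "effective_GW",
                                  "biomass_fraction"),
                       labels = c("Harvest (Mt/yr)", "Nominal effort (GW)",
                                  "Effective effort (GW)",
                                  "Biomass (fraction of pristine)"))
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Map of per-cell harvest in a year
#'
#' @param run An `fc_run`.
#' @param year Year to map.
#' @return A ggplot (t km^-2 yr^-1; 1 g m^-2 yr^-1 = 1 t km^-2 yr^-1).
#' @export
plot_harvest_map <- function(run, year) {
  d <- run$cells[run$cells$year == year, ]
  d <- dplyr::left_join(d, run$grid[, c("cell", "lat", "lon")], by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data$harvest)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "t/km2/yr") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Harvest,", year), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
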