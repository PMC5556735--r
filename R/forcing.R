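#' Specify synthetic ocean forcing
#'
#' Bundles the knobs of the synthetic-Earth forcing generator: a latitudinal
#' sea-surface-temperature gradient, a two-band (coastal vs open ocean) net
#' primary production field with latitudinal modulation, interannual noise, and
#' optional secular trends that stand in for greenhouse-forced climate change.
#'
#' @param resolution Grid resolution in degrees (must divide 180).
#' @param year_start,year_end First and last forcing year (CE, annual steps).
#' @param sst_equator,sst_pole SST at the equator / poles, degC.
#' @param npp_open,npp_coastal NPP of open-ocean / coastal cells,
#'   mmol C m^-2 d^-1, before latitudinal modulation.
#' @param warming_trend Linear SST trend, degC per century (applied uniformly).
#' @param npp_trend Relative NPP trend, percent per century.
#' @param noise_sd Interannual variability: SST noise s.d. as a fraction of the
#'   equator-pole range; NPP multiplicative lognormal noise with this sdlog.
#' @param spatial_sd Static spatial heterogeneity of NPP: a time-invariant
#'   multiplicative lognormal factor per cell with this sdlog, standing in for
#'   basin-scale productivity structure (upwelling systems, oligotrophic
#'   basins) that a zonal-mean profile cannot carry.
#' @param seed Integer seed making the generated fields reproducible.
#' @return List of class `fc_forcing_spec`.
#' @export
forcing_spec <- function(resolution = 4,
                         year_start = 1850, year_end = 2030,
                         sst_equator = 27, sst_pole = -1,
                         npp_open = 12, npp_coastal = 60,
                         warming_trend = 0, npp_trend = 0,
                         noise_sd = 0.05, spatial_sd = 0.8, seed = 1L) {
  if (year_end <= year_start) stop("year_end must exceed year_start", call. = FALSE)
  if (npp_open < 0 || npp_coastal < 0) stop("NPP levels must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(resolution = resolution,
                 year_start = year_start, year_end = year_end,
                 sst_equator = sst_equator, sst_pole = sst_pole,
                 npp_open = npp_open, npp_coastal = npp_coastal,
                 warming_trend = warming_trend, npp_trend = npp_trend,
                 noise_sd = noise_sd, spatial_sd = spatial_sd,
                 seed = as.integer(seed)),
            class = "fc_forcing_spec")
}

#' Generate synthetic gridded SST and NPP forcing
#'
#' SST follows `sst_pole + (sst_equator - sst_pole) * cos^2(lat)` plus the
#' linear warming trend and additive Gaussian noise. NPP is `npp_coastal` on
#' coastal cells and `npp_open` elsewhere, modulated by a latitudinal factor
#' combining the tropical maximum with oligotrophic subtropical-gyre minima
#' near 27 degrees (normalized to an area-weighted ocean mean of one, so the
#' two base levels are true ocean averages), with a linear relative trend and
#' multiplicative lognormal noise. Defaults give a global ocean-integrated
#' NPP near 4e15 mol C yr^-1, the observed order of magnitude.
#'
#' @param spec A [forcing_spec()].
#' @return List of class `fc_forcing`: `grid`, `years`, and matrices `sst`,
#'   `npp` (ocean cells x years, degC and mmol C m^-2 d^-1).
#' @export
generate_synthetic_forcing <- function(spec = forcing_spec()) {
  stopifnot(inherits(spec, "fc_forcing_spec"))
  grid <- make_grid(spec$resolution)
  years <- seq(spec$year_start, spec$year_end)
  oc <- grid[grid$ocean, ]
  nc <- nrow(oc)
  ny <- length(years)
  latr <- oc$lat * pi / 180

  sst0 <- spec$sst_pole + (spec$sst_equator - spec$sst_pole) * cos(latr)^2
  latfac <- fc_npp_latfactor(oc$lat)
  latfac <- latfac / (sum(latfac * oc$area) / sum(oc$area))
  npp0 <- ifelse(oc$coastal, spec$npp_coastal, spec$npp_open) * latfac

  set.seed(spec$seed)
  if (spec$spatial_sd > 0) {
    spat <- rlnorm(nc, 0, spec$spatial_sd)
    # exact area-weighted mean one, so global NPP totals do not depend on
    # the heterogeneity seed
    spat <- spat / (sum(spat * oc$area) / sum(oc$area))
    npp0 <- npp0 * spat
  }

  frac_century <- (years - spec$year_start) / 100
  sst <- outer(sst0, spec$warming_trend * frac_century, `+`)
  npp <- outer(npp0, 1 + (spec$npp_trend / 100) * frac_century)

  if (spec$noise_sd > 0) {
    sst <- sst + matrix(rnorm(nc * ny, 0, spec$noise_sd *
                                (spec$sst_equator - spec$sst_pole)), nc, ny)
    npp <- npp * matrix(rlnorm(nc * ny, -spec$noise_sd^2 / 2, spec$noise_sd), nc, ny)
  }
  sst <- pmin(pmax(sst, -2), 35)
  npp <- pmax(npp, 0)

  structure(list(grid = grid, years = years, sst = sst, npp = npp, spec = spec),
            class = "fc_forcing")
}

# Latitudinal NPP modulation: tropical/subpolar production, oligotrophic
# subtropical gyres centred near +/-27 degrees, and light-limited polar
# oceans. Unnormalized (the generator rescales to ocean mean one).
fc_npp_latfactor <- function(lat) {
  latr <- lat * pi / 180
  (0.4 + 0.9 * cos(latr)^2) *
    (1 - 0.6 * exp(-((abs(lat) - 27) / 12)^2)) *
    (0.25 + 0.75 * cos(latr))
}

#' @export
print.fc_forcing <- function(x, ...) {
  cat(sprintf("<fc_forcing> %d ocean cells x %d years (%d-%d)\n",
              nrow(x$sst), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  area-weighted mean SST %.2f degC, NPP %.1f mmolC m-2 d-1 (first year)\n",
              fc_ocean_mean(x$grid, x$sst[, 1]), fc_ocean_mean(x$grid, x$npp[, 1])))
  invisible(x)
}

#' Global ocean-integrated NPP
#'
#' @param forcing An `fc_forcing`.
#' @param year Year to evaluate (default first).
#' @return Mol C per year, summed over the ocean.
#' @export
global_npp <- function(forcing, year = forcing$years[1]) {
  iy <- match(year, forcing$years)
  a <- forcing$grid$area[forcing$grid$ocean]
  # mmol C m^-2 d^-1 -> mol C yr^-1
  sum(forcing$npp[, iy] * a) * fc_const$days_per_yr / 1000
}

#' Reduce forcing to its climatology
#'
#' Time-mean (noise-averaged) fields over a year window, returned as a
#' single-year `fc_forcing`. Used for spin-up and for MSY snapshot climates.
#'
#' @param forcing An `fc_forcing`.
#' @param years Years to average over (default: first 10 available).
#' @export
climatology <- function(forcing, years = head(forcing$years, 10)) {
  iy <- match(years, forcing$years)
  if (anyNA(iy)) stop("requested years outside forcing range", call. = FALSE)
  out <- forcing
  out$sst <- matrix(rowMeans(forcing$sst[, iy, drop = FALSE]), ncol = 1)
  out$npp <- matrix(rowMeans(forcing$npp[, iy, drop = FALSE]), ncol = 1)
  out$years <- years[1]
  out
}

#' Write forcing to a plain-text file
#'
#' Serializes an `fc_forcing` to CSV with unit metadata in `#` comment headers
#' (year, lat, lon, sst, npp; ocean cells only). Values round-trip exactly:
#' [load_forcing()] on the written file reproduces the object bit-for-bit.
#'
#' @param forcing An `fc_forcing`.
#' @param path Output file path.
#' @export
save_forcing <- function(forcing, path) {
  stopifnot(inherits(forcing, "fc_forcing"))
  oc <- forcing$grid[forcing$grid$ocean, ]
  # %.17g guarantees exact binary round-trip of the doubles
  d <- tibble::tibble(
    year = rep(forcing$years, each = nrow(oc)),
    lat = rep(oc$lat, length(forcing$years)),
    lon = rep(oc$lon, length(forcing$years)),
    sst = sprintf("%.17g", as.vector(forcing$sst)),
    npp = sprintf("%.17g", as.vector(forcing$npp))
  )
  hdr <- c("# fishcast forcing v1",
           paste0("# resolution_deg: ", attr(forcing$grid, "resolution")),
           "# units_sst: degC",
           "# units_npp: mmolC_m-2_d-1")
  writeLines(hdr, path)
  readr::write_csv(d, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read forcing from a plain-text file
#'
#' Reads the CSV layout written by [save_forcing()]. NPP given in
#' `gC_m-2_d-1` is converted to the internal mmol C m^-2 d^-1 convention
#' (factor 1000/12.011). Missing variables, missing unit headers, or
#' non-finite values on ocean cells raise descriptive errors.
#'
#' @param path File path.
#' @return An `fc_forcing`.
#' @export
load_forcing <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) stop("forcing file missing '", key, "' header", call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  res <- as.numeric(get_hdr("resolution_deg"))
  u_sst <- get_hdr("units_sst")
  u_npp <- get_hdr("units_npp")

  d <- utils::read.csv(path, comment.char = "#")  # strtod: correctly rounded
  for (v in c("year", "lat", "lon", "sst", "npp")) {
    if (!v %in% names(d)) stop("forcing file missing variable '", v, "'", call. = FALSE)
  }
  if (u_sst != "degC") stop("unsupported SST units '", u_sst, "'", call. = FALSE)
  conv <- switch(u_npp,
                 "mmolC_m-2_d-1" = 1,
                 "gC_m-2_d-1" = 1000 / fc_const$g_c_per_mol,
                 stop("unsupported NPP units '", u_npp, "'", call. = FALSE))

  grid <- make_grid(res)
  oc <- grid[grid$ocean, ]
  years <- sort(unique(d$year))
  if (all(years == round(years))) years <- as.integer(years)
  if (length(years) > 1 && !all(diff(years) == diff(years)[1])) {
    stop("forcing years are not uniformly spaced", call. = FALSE)
  }
  d <- d[order(d$year, match(paste(d$lat, d$lon), paste(oc$lat, oc$lon))), ]
  key <- paste(d$lat[d$year == years[1]], d$lon[d$year == years[1]])
  if (!identical(key, paste(oc$lat, oc$lon))) {
    stop("forcing cells do not match the built-in ocean layout at ",
         res, " deg", call. = FALSE)
  }
  sst <- matrix(d$sst, nrow = nrow(oc))
  npp <- matrix(d$npp, nrow = nrow(oc)) * conv
  if (anyNA(sst) || anyNA(npp)) stop("NA values on ocean cells", call. = FALSE)
  if (any(npp < 0)) stop("negative NPP on ocean cells", call. = FALSE)
  if (any(sst < -2 - 1e-9 | sst > 35 + 1e-9)) {
    stop("SST outside the physical range [-2, 35] degC", call. = FALSE)
  }
  structure(list(grid = grid, years = years, sst = sst, npp = npp, spec = NULL),
            class = "fc_forcing")
}
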