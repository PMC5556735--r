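#' Build the global latitude-longitude grid
#'
#' Constructs an idealized Earth grid at the requested resolution: cell centres,
#' spherical cell areas, and a deterministic two-continent land template (one
#' wide "Americas-like" landmass, one "Afro-Eurasian" landmass, plus a south
#' polar cap). Ocean cells adjacent to land are flagged `coastal`; the
#' coastal/open-ocean contrast is what drives the spatial expansion of fishing
#' in the coupled experiments.
#'
#' The land template edges sit on multiples of 4 degrees so the continental
#' outline, and hence the ocean fraction, is essentially invariant across
#' supported resolutions.
#'
#' @param resolution_deg Cell size in degrees. Must divide 180
#'   (1, 2, 3, 4, 5, 6, 9, 10, 12, 15, 18 or 20).
#' @return A tibble of class `fc_grid` with one row per cell: `cell`, `lat`,
#'   `lon` (centre degrees), `area` (m^2), `ocean`, `coastal` (logical), and
#'   attributes `resolution`, `nlat`, `nlon`, `ocean_cells` (row indices of
#'   ocean cells).
#' @examples
#' g <- make_grid(10)
#' sum(g$area) / (4 * pi * 6371000^2)  # ~1: spherical geometry identity
#' @export
make_grid <- function(resolution_deg = 4) {
  ok <- c(1, 2, 3, 4, 5, 6, 9, 10, 12, 15, 18, 20)
  if (!(length(resolution_deg) == 1 && resolution_deg %in% ok)) {
    stop("`resolution_deg` must divide 180 (one of ", paste(ok, collapse = ", "),
         "), got ", resolution_deg, call. = FALSE)
  }
  res <- resolution_deg
  nlat <- 180 / res
  nlon <- 360 / res
  lat_c <- -90 + res * (seq_len(nlat) - 0.5)
  lon_c <- -180 + res * (seq_len(nlon) - 0.5)

  # Exact spherical band areas: R^2 * dlon * (sin(lat_n) - sin(lat_s))
  R <- fc_const$earth_radius
  dlon <- res * pi / 180
  lat_s <- (lat_c - res / 2) * pi / 180
  lat_n <- (lat_c + res / 2) * pi / 180
  band_area <- R^2 * dlon * (sin(lat_n) - sin(lat_s))

  grid_lat <- rep(lat_c, times = nlon)
  grid_lon <- rep(lon_c, each = nlat)
  area <- rep(band_area, times = nlon)

  land <- fc_land_template(grid_lat, grid_lon)
  ocean <- !land

  # coastal: ocean cell with at least one land cell among its 8 neighbours
  # (longitude wraps; latitude does not).
  land_m <- matrix(land, nrow = nlat, ncol = nlon)
  near_land <- matrix(FALSE, nlat, nlon)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      shifted <- land_m[pmin(pmax(seq_len(nlat) + di, 1), nlat),
                        ((seq_len(nlon) + dj - 1) %% nlon) + 1]
      near_land <- near_land | shifted
    }
  }
  coastal <- ocean & as.vector(near_land)

  g <- tibble::tibble(
    cell = seq_along(grid_lat),
    lat = grid_lat, lon = grid_lon, area = area,
    ocean = ocean, coastal = coastal
  )
  structure(g,
            class = c("fc_grid", class(g)),
            resolution = res, nlat = nlat, nlon = nlon,
            ocean_cells = which(ocean))
}

# Idealized two-continent land layout. Edges on multiples of 4 degrees.
fc_land_template <- function(lat, lon) {
  (lon >= -96 & lon <= -40 & lat >= -56 & lat <= 72) |
    (lon >= 16 & lon <= 88 & lat >= -32 & lat <= 64) |
    (lat <= -80)
}

#' @export
print.fc_grid <- function(x, ...) {
  of <- sum(x$area[x$ocean]) / sum(x$area)
  cat(sprintf("<fc_grid> %g deg, %d cells (%d ocean, %d coastal), ocean fraction %.3f\n",
              attr(x, "resolution"), nrow(x), sum(x$ocean), sum(x$coastal), of))
  NextMethod()
}

#' Partition coastal cells into contiguous regions
#'
#' Splits the coastal ocean cells into `n_regions` blocks of near-equal cell
#' count, sweeping along the coastline (ordered by longitude, then latitude).
#' The regions play the role of Large-Marine-Ecosystem-scale aggregation units
#' for calibration; open-ocean cells keep `region_id = 0`.
#'
#' @param grid An [make_grid()] grid.
#' @param n_regions Number of coastal regions (default 20).
#' @return Tibble of class `fc_regions`: `cell`, `region_id` for every ocean
#'   cell (0 = unassigned open ocean), with attribute `n_regions`.
#' @export
make_region_mask <- function(grid, n_regions = 20) {
  stopifnot(inherits(grid, "fc_grid"))
  if (n_regions < 1) stop("`n_regions` must be >= 1", call. = FALSE)
  coastal <- grid$cell[grid$coastal]
  if (n_regions > length(coastal)) {
    stop("n_regions (", n_regions, ") exceeds the number of coastal cells (",
         length(coastal), ")", call. = FALSE)
  }
  ord <- coastal[order(grid$lon[match(coastal, grid$cell)],
                       grid$lat[match(coastal, grid$cell)])]
  # near-equal contiguous chunks along the sweep
  rid <- ceiling(seq_along(ord) / (length(ord) / n_regions))
  rid <- pmin(rid, n_regions)
  out <- tibble::tibble(cell = grid$cell[grid$ocean], region_id = 0L)
  out$region_id[match(ord, out$cell)] <- as.integer(rid)
  structure(out, class = c("fc_regions", class(out)), n_regions = n_regions)
}

# Area-weighted mean over ocean cells of a (ncell_ocean x k) matrix or vector.
fc_ocean_mean <- function(grid, x) {
  w <- grid$area[grid$ocean]
  if (is.matrix(x)) colSums(x * w) / sum(w) else sum(x * w) / sum(w)
}
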