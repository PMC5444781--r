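#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# mean Earth radius, km; all planar-area corrections use the same sphere
EARTH_RADIUS_KM <- 6371.0088
KM_PER_DEG <- pi / 180 * EARTH_RADIUS_KM

#' Great-circle distance in kilometres
#'
#' Haversine distance between points given as lon/lat degrees.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees; vectors recycle.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# area of a resolution x resolution cell centred at latitude `lat`, hectares
cell_area_ha <- function(lat, resolution) {
  (KM_PER_DEG * resolution)^2 * cos(lat * pi / 180) * 100
}

# run `code` under a temporary RNG state seeded with `seed`; NULL seed means
# use (and advance) the current RNG stream
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# spawn `n` reproducible child seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  with_seed_or_not(seed, sample.int(.Machine$integer.max - 1L, n))
}

new_grid_axes <- function(lon_range, lat_range, resolution) {
  lon0 <- floor(lon_range[1] / resolution) * resolution
  lon1 <- ceiling(lon_range[2] / resolution) * resolution
  lat0 <- floor(lat_range[1] / resolution) * resolution
  lat1 <- ceiling(lat_range[2] / resolution) * resolution
  list(
    lon = seq(lon0 + resolution / 2, lon1 - resolution / 2, by = resolution),
    lat = seq(lat0 + resolution / 2, lat1 - resolution / 2, by = resolution)
  )
}

#' Construct a habitat-class raster
#'
#' A minimal in-memory raster of reef habitat classes on a regular
#' geographic lattice. `values` holds integer codes (0 = no reef) indexed
#' `[lat, lon]`; `class_ids` maps codes to typology class ids.
#'
#' @param lon,lat Cell-centre coordinate vectors (regular, ascending).
#' @param values Integer matrix `length(lat) x length(lon)` of class codes,
#'   0 where no reef is mapped.
#' @param class_ids Character vector; `class_ids[k]` is the class of code `k`.
#' @param resolution Cell size in degrees; inferred from the axes when they
#'   have at least two cells.
#' @return A `reef_raster` object.
#' @export
reef_raster <- function(lon, lat, values, class_ids, resolution = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon))
  res <- infer_resolution(lon, lat, resolution)
  structure(list(lon = lon, lat = lat, values = values,
                 class_ids = class_ids, resolution = res),
            class = "reef_raster")
}

#' Construct a land mask raster
#'
#' @param lon,lat Cell-centre coordinate vectors (regular, ascending).
#' @param land Logical matrix `length(lat) x length(lon)`; TRUE = land.
#' @param resolution Cell size in degrees; inferred when possible.
#' @return A `land_raster` object.
#' @export
land_raster <- function(lon, lat, land, resolution = NULL) {
  stopifnot(is.matrix(land), nrow(land) == length(lat),
            ncol(land) == length(lon))
  res <- infer_resolution(lon, lat, resolution)
  if (!any(!land)) abort("land_raster has no water cell")
  structure(list(lon = lon, lat = lat, land = land, resolution = res),
            class = "land_raster")
}

infer_resolution <- function(lon, lat, resolution) {
  if (!is.null(resolution)) return(resolution)
  res <- unique(round(c(diff(lon), diff(lat)), 10))
  if (length(res) == 0) return(0.1)
  if (length(res) != 1) abort("raster requires a regular square lattice")
  res
}

# index of the raster cell containing (lon, lat); NA outside the extent
raster_cell_index <- function(r, lon, lat) {
  res <- r$resolution
  i <- round((lat - r$lat[1]) / res) + 1L
  j <- round((lon - r$lon[1]) / res) + 1L
  i[i < 1L | i > length(r$lat)] <- NA_integer_
  j[j < 1L | j > length(r$lon)] <- NA_integer_
  list(row = i, col = j)
}

#' Construct a gridded current field
#'
#' Horizontal current components on a regular lon/lat lattice, either steady
#' (`u`, `v` matrices) or time-varying (3-d arrays `[lat, lon, time]` with
#' `time` in days).
#'
#' @param lon,lat Cell-centre coordinates (degrees).
#' @param u,v Zonal / meridional velocity, m s^-1; matrices or 3-d arrays.
#' @param time Optional numeric vector of times (days) for the third dim.
#' @return A `current_field` object.
#' @export
current_field <- function(lon, lat, u, v, time = NULL) {
  stopifnot(identical(dim(u), dim(v)))
  if (length(dim(u)) == 2) { u <- array(u, c(dim(u), 1)); v <- array(v, c(dim(v), 1)) }
  if (is.null(time)) time <- seq_len(dim(u)[3]) - 1
  stopifnot(dim(u)[1] == length(lat), dim(u)[2] == length(lon),
            dim(u)[3] == length(time))
  if (anyNA(u) || anyNA(v)) abort("current field contains NA values inside the domain")
  structure(list(lon = lon, lat = lat, u = u, v = v, time = time),
            class = "current_field")
}

# bilinear interpolation of one current slice at arbitrary points;
# returns m/s, 0 outside the field's extent
interp_current <- function(field, lon, lat, day) {
  k <- if (length(field$time) == 1) 1L else {
    pmin(findInterval(day, field$time), length(field$time))
  }
  k <- max(1L, k)
  list(u = bilinear_at(field$lon, field$lat, field$u[, , k], lon, lat),
       v = bilinear_at(field$lon, field$lat, field$v[, , k], lon, lat))
}

bilinear_at <- function(glon, glat, zu, lon, lat) {
  nx <- length(glon); ny <- length(glat)
  jx <- findInterval(lon, glon); jy <- findInterval(lat, glat)
  jx <- pmin(pmax(jx, 1L), nx - 1L); jy <- pmin(pmax(jy, 1L), ny - 1L)
  tx <- (lon - glon[jx]) / (glon[jx + 1L] - glon[jx])
  ty <- (lat - glat[jy]) / (glat[jy + 1L] - glat[jy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  z00 <- zu[cbind(jy, jx)];       z01 <- zu[cbind(jy, jx + 1L)]
  z10 <- zu[cbind(jy + 1L, jx)];  z11 <- zu[cbind(jy + 1L, jx + 1L)]
  z00 * (1 - tx) * (1 - ty) + z01 * tx * (1 - ty) +
    z10 * (1 - tx) * ty + z11 * tx * ty
}

# lower-triangle (off-diagonal) entries of a square matrix, column-major
lower_tri <- function(m) m[lower.tri(m)]

# drop subclass tags so derived tables do not inherit container classes
strip_tbl <- function(x) tibble::new_tibble(as.data.frame(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
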