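#' Grid a habitat map into a patch mosaic
#'
#' Aggregates a continuous habitat map onto a regular geographic grid
#' (default 0.25 degrees): every grid cell intersecting mapped reef becomes a
#' habitat patch carrying the per-class reef area (hectares, with a
#' spherical cosine-latitude correction). Cells without reef are absent.
#'
#' @param habitat A [reef_raster()] of class codes, or a data frame of
#'   polygon vertices with columns `poly_id`, `class_id`, `lon`, `lat`
#'   (vertices in ring order, one ring per polygon).
#' @param resolution Grid resolution in degrees (default 0.25).
#' @param land Optional [land_raster()]; if supplied, habitat falling on land
#'   cells raises an error.
#' @return A `patch_grid` tibble in long form, one row per patch x class:
#'   `patch_id`, `lon`, `lat` (cell centre), `class_id`, `area_ha`, `N`
#'   (abundance, NA until [compute_abundance()]), `sampled_site_code`.
#'   Attribute `resolution` records the cell size.
#' @export
grid_habitat <- function(habitat, resolution = 0.25, land = NULL) {
  if (resolution <= 0) abort("resolution must be positive")
  cells <- if (inherits(habitat, "reef_raster")) {
    grid_cells_from_raster(habitat, resolution)
  } else if (is.data.frame(habitat)) {
    grid_cells_from_polygons(habitat, resolution)
  } else {
    abort("habitat must be a reef_raster or a polygon data frame")
  }
  if (nrow(cells) == 0) abort("habitat map does not overlap the grid (no reef found)")
  if (!is.null(land)) {
    idx <- raster_cell_index(land, cells$lon, cells$lat)
    on_land <- !is.na(idx$row) & land$land[cbind(idx$row, idx$col)]
    if (any(on_land)) {
      warn(sprintf("%d patch centroid(s) fall on land cells of the mask", sum(on_land)))
    }
  }
  cells <- cells %>% dplyr::arrange(.data$lat, .data$lon, .data$class_id)
  key <- cells %>% dplyr::distinct(.data$lon, .data$lat) %>%
    dplyr::mutate(patch_id = sprintf("P%03d", dplyr::row_number()))
  grid <- cells %>%
    dplyr::left_join(key, by = c("lon", "lat")) %>%
    dplyr::mutate(N = NA_real_, sampled_site_code = NA_character_) %>%
    dplyr::select("patch_id", "lon", "lat", "class_id", "area_ha",
                  "N", "sampled_site_code")
  new_patch_grid(grid, resolution)
}

new_patch_grid <- function(tb, resolution) {
  structure(as_tibble(tb), resolution = resolution,
            class = c("patch_grid", class(as_tibble(tb))))
}

grid_cells_from_raster <- function(r, resolution) {
  v <- r$values
  keep <- which(v > 0, arr.ind = TRUE)
  if (nrow(keep) == 0) return(tibble())
  code <- v[keep]
  bad <- setdiff(unique(code), seq_along(r$class_ids))
  if (length(bad) > 0) {
    abort(paste0("unknown habitat class code(s): ", paste(bad, collapse = ", ")))
  }
  lon <- r$lon[keep[, 2]]; lat <- r$lat[keep[, 1]]
  tibble(
    lon = (floor(lon / resolution) + 0.5) * resolution,
    lat = (floor(lat / resolution) + 0.5) * resolution,
    class_id = r$class_ids[code],
    area = cell_area_ha(lat, r$resolution)
  ) %>%
    dplyr::group_by(.data$lon, .data$lat, .data$class_id) %>%
    dplyr::summarise(area_ha = sum(.data$area), .groups = "drop")
}

grid_cells_from_polygons <- function(polys, resolution) {
  need <- c("poly_id", "class_id", "lon", "lat")
  if (!all(need %in% names(polys))) {
    abort("polygon habitat needs columns poly_id, class_id, lon, lat")
  }
  out <- polys %>%
    dplyr::group_by(.data$poly_id, .data$class_id) %>%
    dplyr::group_map(function(df, key) {
      cells <- clip_polygon_to_cells(df$lon, df$lat, resolution)
      if (nrow(cells) > 0) cells$class_id <- key$class_id
      cells
    }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0) return(tibble())
  out %>%
    dplyr::group_by(.data$lon, .data$lat, .data$class_id) %>%
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
}

# clip one simple polygon against every overlapped grid cell
clip_polygon_to_cells <- function(px, py, resolution) {
  jx <- floor(range(px) / resolution); jy <- floor(range(py) / resolution)
  res <- list()
  for (cx in jx[1]:jx[2]) for (cy in jy[1]:jy[2]) {
    clip <- sutherland_hodgman(px, py,
                               cx * resolution, (cx + 1) * resolution,
                               cy * resolution, (cy + 1) * resolution)
    if (length(clip$x) >= 3) {
      a_deg2 <- abs(shoelace(clip$x, clip$y))
      if (a_deg2 > 0) {
        clat <- mean(clip$y)
        res[[length(res) + 1]] <- tibble(
          lon = (cx + 0.5) * resolution, lat = (cy + 0.5) * resolution,
          area_ha = a_deg2 * KM_PER_DEG^2 * cos(clat * pi / 180) * 100)
      }
    }
  }
  dplyr::bind_rows(res)
}

shoelace <- function(x, y) {
  n <- length(x)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

# polygon clipping against an axis-aligned rectangle
sutherland_hodgman <- function(px, py, xmin, xmax, ymin, ymax) {
  clip_edge <- function(x, y, inside, intersect) {
    if (length(x) == 0) return(list(x = numeric(0), y = numeric(0)))
    nx <- ny <- numeric(0)
    n <- length(x)
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cur_in <- inside(x[i], y[i]); prev_in <- inside(x[j], y[j])
      if (cur_in) {
        if (!prev_in) {
          p <- intersect(x[j], y[j], x[i], y[i])
          nx <- c(nx, p[1]); ny <- c(ny, p[2])
        }
        nx <- c(nx, x[i]); ny <- c(ny, y[i])
      } else if (prev_in) {
        p <- intersect(x[j], y[j], x[i], y[i])
        nx <- c(nx, p[1]); ny <- c(ny, p[2])
      }
    }
    list(x = nx, y = ny)
  }
  at_x <- function(x0, y0, x1, y1, xc) c(xc, y0 + (y1 - y0) * (xc - x0) / (x1 - x0))
  at_y <- function(x0, y0, x1, y1, yc) c(x0 + (x1 - x0) * (yc - y0) / (y1 - y0), yc)
  p <- list(x = px, y = py)
  p <- clip_edge(p$x, p$y, function(x, y) x >= xmin,
                 function(...) at_x(..., xc = xmin))
  p <- clip_edge(p$x, p$y, function(x, y) x <= xmax,
                 function(...) at_x(..., xc = xmax))
  p <- clip_edge(p$x, p$y, function(x, y) y >= ymin,
                 function(...) at_y(..., yc = ymin))
  p <- clip_edge(p$x, p$y, function(x, y) y <= ymax,
                 function(...) at_y(..., yc = ymax))
  p
}

#' Per-patch summary of a patch grid
#'
#' @param grid A `patch_grid`.
#' @return One row per patch: `patch_id`, `lon`, `lat`, `area_ha` (total),
#'   `N`, `sampled_site_code`.
#' @export
patch_summary <- function(grid) {
  grid %>%
    dplyr::group_by(.data$patch_id, .data$lon, .data$lat) %>%
    dplyr::summarise(area_ha = sum(.data$area_ha),
                     N = .data$N[1],
                     sampled_site_code = .data$sampled_site_code[1],
                     .groups = "drop") %>%
    dplyr::arrange(.data$patch_id)
}

#' Patch identifiers of a grid, in canonical order
#' @param grid A `patch_grid`.
#' @return Character vector of patch ids.
#' @export
patch_ids <- function(grid) patch_summary(grid)$patch_id

#' Attach genetic sampling sites to habitat patches
#'
#' Each site is assigned to the grid cell containing its coordinates; when
#' that cell holds no reef the site is snapped to the nearest reef-bearing
#' cell (with a warning).
#'
#' @param grid A `patch_grid`.
#' @param sites Data frame with columns `site_code`, `lon`, `lat`.
#' @return The grid with `sampled_site_code` filled.
#' @export
attach_sites <- function(grid, sites) {
  res <- attr(grid, "resolution")
  ps <- patch_summary(grid)
  assign <- character(nrow(sites))
  snapped <- character(0)
  for (k in seq_len(nrow(sites))) {
    clon <- (floor(sites$lon[k] / res) + 0.5) * res
    clat <- (floor(sites$lat[k] / res) + 0.5) * res
    hit <- which(abs(ps$lon - clon) < 1e-9 & abs(ps$lat - clat) < 1e-9)
    if (length(hit) == 0) {
      d <- haversine_km(sites$lon[k], sites$lat[k], ps$lon, ps$lat)
      hit <- which.min(d)
      snapped <- c(snapped, sites$site_code[k])
    }
    assign[k] <- ps$patch_id[hit[1]]
  }
  if (length(snapped) > 0) {
    warn(paste0("site(s) snapped to nearest reef-bearing cell: ",
                paste(snapped, collapse = ", ")))
  }
  if (anyDuplicated(assign)) {
    warn("multiple sites share a patch; the last assignment wins")
  }
  map <- stats::setNames(sites$site_code, assign)
  out <- grid %>%
    dplyr::mutate(sampled_site_code = unname(map[.data$patch_id]))
  new_patch_grid(out, res)
}

#' Draw abundances for every habitat patch
#'
#' Abundance is the product of habitat area and a habitat-specific density.
#' One density per class is drawn from a Gaussian with the typology's mean
#' and sd (a single draw per class per realization, representing one
#' plausible regional density field); negative draws are truncated to zero.
#' `N_i = sum_c max(0, density_c) * area_ha(i, c)`.
#'
#' @param grid A `patch_grid`.
#' @param typology A `habitat_typology` covering every class in the grid.
#' @param seed Optional integer for reproducible draws.
#' @return The grid with `N` filled.
#' @export
compute_abundance <- function(grid, typology, seed = NULL) {
  missing_cls <- setdiff(unique(grid$class_id), typology$class_id)
  if (length(missing_cls) > 0) {
    abort(paste0("grid classes absent from typology: ",
                 paste(missing_cls, collapse = ", ")))
  }
  dens <- with_seed_or_not(seed, {
    d <- stats::rnorm(nrow(typology), typology$density_mean, typology$density_sd)
    pmax(d, 0)
  })
  names(dens) <- typology$class_id
  n_by_patch <- grid %>%
    dplyr::mutate(contrib = dens[.data$class_id] * .data$area_ha) %>%
    dplyr::group_by(.data$patch_id) %>%
    dplyr::summarise(N = sum(.data$contrib), .groups = "drop")
  out <- grid %>%
    dplyr::select(-"N") %>%
    dplyr::left_join(n_by_patch, by = "patch_id") %>%
    dplyr::select("patch_id", "lon", "lat", "class_id", "area_ha",
                  "N", "sampled_site_code")
  new_patch_grid(out, attr(grid, "resolution"))
}

#' Degrade habitat composition to a coarser typology level
#'
#' Re-aggregates per-class areas by the parent classes of the next coarser
#' level(s); geometry and patch count are unchanged. Abundances are cleared
#' (they must be re-drawn under the coarser typology).
#'
#' @param grid A `patch_grid` built under `typology`.
#' @param typology The `habitat_typology` the grid currently uses.
#' @param to Target level (`"L2"` or `"L1"`; same level returns the grid).
#' @return A `patch_grid` with class ids at the target level.
#' @export
degrade_composition <- function(grid, typology, to = c("L1", "L2", "L3")) {
  to <- match.arg(to)
  lv <- typology_level(typology)
  order_ <- c(L3 = 3, L2 = 2, L1 = 1)
  if (order_[to] > order_[lv]) abort("cannot refine a grid to a finer level")
  mapping <- stats::setNames(typology$class_id, typology$class_id)
  cur <- lv
  pm <- typology_parent_map(typology)
  while (order_[cur] > order_[to]) {
    orphan <- setdiff(unique(unname(mapping)), names(pm))
    if (length(orphan) > 0) {
      abort(paste0("class(es) without parent mapping: ", paste(orphan, collapse = ", ")))
    }
    mapping <- stats::setNames(pm[unname(mapping)], names(mapping))
    cur <- c(L3 = "L2", L2 = "L1")[cur]
    pm <- if (cur == "L2") c(shallow_reefs = "reef", variable_depth_reefs = "reef") else NULL
  }
  bad <- setdiff(unique(grid$class_id), names(mapping))
  if (length(bad) > 0) {
    abort(paste0("orphan class(es) in grid: ", paste(bad, collapse = ", ")))
  }
  out <- grid %>%
    dplyr::mutate(class_id = unname(mapping[.data$class_id])) %>%
    dplyr::group_by(.data$patch_id, .data$lon, .data$lat, .data$class_id) %>%
    dplyr::summarise(area_ha = sum(.data$area_ha),
                     sampled_site_code = .data$sampled_site_code[1],
                     .groups = "drop") %>%
    dplyr::mutate(N = NA_real_) %>%
    dplyr::select("patch_id", "lon", "lat", "class_id", "area_ha",
                  "N", "sampled_site_code") %>%
    dplyr::arrange(.data$patch_id, .data$class_id)
  new_patch_grid(out, attr(grid, "resolution"))
}

#' Fragment a patch grid by random habitat removal
#'
#' Removes whole unprotected patches, in a seeded random order, until the
#' removed reef area reaches `removal_fraction` of the initial total area
#' (overshooting by at most one patch). Patches carrying a sampling site,
#' plus any explicitly `protected` ids, are never removed. For a fixed seed
#' the removal order is fixed, so removal sets for increasing fractions are
#' nested.
#'
#' @param grid A `patch_grid`.
#' @param removal_fraction Fraction of total reef area to remove, in `[0, 1)`.
#' @param protected Additional patch ids never to remove (sampled patches are
#'   always protected).
#' @param seed Optional integer seed.
#' @return The fragmented `patch_grid`.
#' @export
fragment <- function(grid, removal_fraction, protected = character(0), seed = NULL) {
  if (removal_fraction < 0 || removal_fraction >= 1) {
    abort("removal_fraction must be in [0, 1)")
  }
  if (removal_fraction == 0) return(grid)
  ps <- patch_summary(grid)
  protected <- union(protected, ps$patch_id[!is.na(ps$sampled_site_code)])
  open <- ps %>% dplyr::filter(!.data$patch_id %in% protected)
  total <- sum(ps$area_ha)
  target <- removal_fraction * total
  if (nrow(open) == 0 || sum(open$area_ha) < target) {
    abort("removal_fraction exceeds the unprotected reef area")
  }
  ord <- with_seed_or_not(seed, sample(nrow(open)))
  cum <- cumsum(open$area_ha[ord])
  k <- which(cum >= target)[1]
  removed <- open$patch_id[ord[seq_len(k)]]
  out <- grid %>% dplyr::filter(!.data$patch_id %in% removed)
  new_patch_grid(out, attr(grid, "resolution"))
}

#' Write / read a patch grid as CSV
#'
#' The CSV is the long patch x class table; a JSON sidecar
#' (`<path>.json`) stores the grid resolution.
#'
#' @param grid A `patch_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `patch_grid` (reader).
#' @export
write_patch_grid <- function(grid, path) {
  readr::write_csv(as_tibble(grid), path)
  jsonlite::write_json(list(resolution = attr(grid, "resolution")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patch_grid
#' @export
read_patch_grid <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patch_id = "c", class_id = "c",
                          sampled_site_code = "c", .default = "d"))
  side <- paste0(path, ".json")
  res <- if (file.exists(side)) jsonlite::read_json(side)$resolution else 0.25
  new_patch_grid(tb, res)
}
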