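#' Build the water-traversal graph of a land raster
#'
#' Nodes are water cells; edges connect 8-neighbour water cell pairs and are
#' weighted by the great-circle distance (km) between cell centres, so
#' diagonal moves carry their true geodesic length.
#'
#' @param land A [land_raster()].
#' @return A `water_graph`: list with the `igraph` graph, a `nodes` tibble
#'   (`node`, `row`, `col`, `lon`, `lat`) and the source raster.
#' @export
build_water_graph <- function(land) {
  water <- which(!land$land, arr.ind = TRUE)
  if (nrow(water) == 0) abort("land raster is all land; no water graph exists")
  nr <- length(land$lat); nc <- length(land$lon)
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[water] <- seq_len(nrow(water))
  nodes <- tibble(node = seq_len(nrow(water)),
                  row = water[, 1], col = water[, 2],
                  lon = land$lon[water[, 2]], lat = land$lat[water[, 1]])
  # half the 8-neighbourhood avoids duplicate edges
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- nodes$row + offs[k, 1]; c2 <- nodes$col + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- rep(NA_integer_, nrow(nodes))
    tgt[ok] <- node_id[cbind(r2[ok], c2[ok])]
    keep <- !is.na(tgt)
    if (any(keep)) {
      efrom <- c(efrom, nodes$node[keep])
      eto <- c(eto, tgt[keep])
      ew <- c(ew, haversine_km(nodes$lon[keep], nodes$lat[keep],
                               land$lon[nodes$col[keep] + offs[k, 2]],
                               land$lat[nodes$row[keep] + offs[k, 1]]))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (length(efrom) > 0) {
    g <- igraph::add_edges(g, rbind(efrom, eto))
    igraph::E(g)$weight <- ew
  }
  structure(list(graph = g, nodes = nodes, land = land, node_id = node_id),
            class = "water_graph")
}

# nearest water node for arbitrary coordinates; snap = TRUE allows land cells
water_node_for <- function(wg, lon, lat, snap = TRUE) {
  idx <- raster_cell_index(wg$land, lon, lat)
  out <- integer(length(lon)); snapped <- logical(length(lon))
  for (k in seq_along(lon)) {
    nid <- if (!is.na(idx$row[k])) wg$node_id[idx$row[k], idx$col[k]] else NA_integer_
    if (is.na(nid)) {
      if (!snap) abort("coordinate falls on land and snapping is disabled")
      d <- haversine_km(lon[k], lat[k], wg$nodes$lon, wg$nodes$lat)
      nid <- wg$nodes$node[which.min(d)]
      snapped[k] <- TRUE
    }
    out[k] <- nid
  }
  attr(out, "snapped") <- snapped
  out
}

#' Over-water shortest-path distances between habitat patches
#'
#' Distance between two patches is the length (km) of the shortest path
#' between the water cells holding their centroids that never crosses land.
#' Centroids on land cells are snapped to the nearest water cell (warning).
#' Patches in mutually unreachable basins get `Inf`.
#'
#' @param grid A `patch_grid`.
#' @param land A [land_raster()] (default resolution 0.1 degrees in this
#'   workflow) or a prebuilt [build_water_graph()] result.
#' @return A symmetric matrix of km with patch-id dimnames and zero diagonal.
#' @export
overwater_distance <- function(grid, land) {
  wg <- if (inherits(land, "water_graph")) land else build_water_graph(land)
  ps <- patch_summary(grid)
  nodes <- water_node_for(wg, ps$lon, ps$lat, snap = TRUE)
  if (any(attr(nodes, "snapped"))) {
    warn(paste0("centroid(s) snapped from land to nearest water cell: ",
                paste(ps$patch_id[attr(nodes, "snapped")], collapse = ", ")))
  }
  un <- unique(nodes)
  dm <- igraph::distances(wg$graph, v = un, to = un,
                          weights = igraph::E(wg$graph)$weight)
  ix <- match(nodes, un)
  d <- dm[ix, ix, drop = FALSE]
  dimnames(d) <- list(ps$patch_id, ps$patch_id)
  diag(d) <- 0
  d
}

#' Write / read a distance matrix as CSV with id header row and column
#'
#' @param d Square matrix with id dimnames.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(d, path) {
  tb <- as_tibble(d, rownames = "patch_id")
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb[[1]]
  m
}
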