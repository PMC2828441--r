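#' Generate a synthetic road network
#'
#' Builds a jittered rectangular lattice of road junctions and thins it by
#' random edge removal, never disconnecting the network (an edge whose
#' removal would disconnect the graph is kept). Edge lengths are Euclidean
#' distances between the (jittered) endpoints, in metres.
#'
#' @param n_rows,n_cols lattice dimensions, both at least 2.
#' @param spacing_m lattice spacing in metres.
#' @param jitter_frac node jitter as a fraction of spacing, in \[0, 0.5).
#' @param edge_removal_frac fraction of edges to attempt to remove,
#'   in \[0, 0.3).
#' @param seed integer RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return an object of class `road_graph`: a list with `nodes`
#'   (data.frame `id, x, y`) and `edges` (data.frame `from, to, length_m`).
#' @export
generate_road_graph <- function(n_rows, n_cols, spacing_m,
                                jitter_frac = 0, edge_removal_frac = 0,
                                seed = 1L) {
  if (n_rows < 2 || n_cols < 2) stop("n_rows and n_cols must be >= 2")
  if (jitter_frac < 0 || jitter_frac >= 0.5) {
    stop("jitter_frac must lie in [0, 0.5)")
  }
  if (edge_removal_frac < 0 || edge_removal_frac >= 0.3) {
    stop("edge_removal_frac must lie in [0, 0.3)")
  }
  if (spacing_m <= 0) stop("spacing_m must be positive")
  set.seed(seed)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  n <- nrow(grid)
  x <- (grid$col - 1) * spacing_m
  y <- (grid$row - 1) * spacing_m
  if (jitter_frac > 0) {
    x <- x + stats::runif(n, -jitter_frac, jitter_frac) * spacing_m
    y <- y + stats::runif(n, -jitter_frac, jitter_frac) * spacing_m
  }
  nodes <- data.frame(id = seq_len(n), x = x, y = y)
  idx <- function(r, c) (r - 1L) * n_cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) { from <- c(from, idx(r, c)); to <- c(to, idx(r, c + 1L)) }
      if (r < n_rows) { from <- c(from, idx(r, c)); to <- c(to, idx(r + 1L, c)) }
    }
  }
  edges <- data.frame(from = from, to = to)
  n_remove <- floor(edge_removal_frac * nrow(edges))
  if (n_remove > 0) {
    candidates <- sample.int(nrow(edges), n_remove)
    keep <- rep(TRUE, nrow(edges))
    for (e in candidates) {
      keep[e] <- FALSE
      g <- igraph::graph_from_edgelist(
        as.matrix(edges[keep, c("from", "to")]), directed = FALSE
      )
      g <- g + igraph::vertices(setdiff(nodes$id, unique(unlist(edges[keep, 1:2]))))
      if (!igraph::is_connected(g)) keep[e] <- TRUE   # re-insert
    }
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$length_m <- sqrt((nodes$x[edges$from] - nodes$x[edges$to])^2 +
                           (nodes$y[edges$from] - nodes$y[edges$to])^2)
  stopifnot(all(edges$length_m > 0))
  structure(list(nodes = nodes, edges = edges), class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d nodes, %d edges, total %.1f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000))
  invisible(x)
}

# igraph view of a road_graph, with edge weights in metres.
as_igraph_road <- function(graph) {
  g <- igraph::graph_from_edgelist(
    as.matrix(graph$edges[, c("from", "to")]), directed = FALSE
  )
  missing <- setdiff(graph$nodes$id, as.integer(igraph::V(g)))
  if (length(missing)) g <- g + igraph::vertices(missing)
  igraph::E(g)$weight <- graph$edges$length_m
  g
}

#' Bounding box of a road graph
#' @param graph a `road_graph`.
#' @return named vector `xmin, xmax, ymin, ymax`.
#' @export
graph_bbox <- function(graph) {
  c(xmin = min(graph$nodes$x), xmax = max(graph$nodes$x),
    ymin = min(graph$nodes$y), ymax = max(graph$nodes$y))
}

#' Snap points to the nearest road-network node
#'
#' Nearest node by Euclidean distance; ties are broken by the lowest node
#' id so that snapping is deterministic.
#'
#' @param points matrix or data.frame with columns (x, y).
#' @param graph a `road_graph`.
#' @return integer vector of node ids, with the snap distance in metres
#'   attached as attribute `snap_dist_m`.
#' @export
snap_to_node <- function(points, graph) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  if (nrow(graph$nodes) == 0L) stop("graph has no nodes")
  ids <- integer(nrow(pts)); dd <- numeric(nrow(pts))
  nx <- graph$nodes$x; ny <- graph$nodes$y
  ord <- order(graph$nodes$id)
  for (i in seq_len(nrow(pts))) {
    d2 <- (nx - pts[i, 1])^2 + (ny - pts[i, 2])^2
    best <- which(d2 == min(d2))
    ids[i] <- min(graph$nodes$id[best])       # tie: lowest id
    dd[i] <- sqrt(min(d2))
  }
  structure(ids, snap_dist_m = dd)
}

#' Origin-destination shortest-path distance matrix
#'
#' Network distances between demand points (census-area centroids) and
#' supply points (candidate ambulance stations). Both point sets are
#' snapped to their nearest network node; distances are node-to-node
#' shortest paths (Dijkstra, non-negative edge weights), computed by a
#' single-source search from each destination since stations are few and
#' areas are many.
#'
#' @param graph a `road_graph`.
#' @param origins matrix/data.frame of (x, y) demand points; row identity
#'   is preserved in the result's rownames (use `rownames` or an `ids`
#'   attribute via `origin_ids`).
#' @param destinations matrix/data.frame of (x, y) supply points.
#' @param origin_ids,destination_ids optional identifiers for rows/columns.
#' @return matrix of distances in metres (origins x destinations), with
#'   snap node ids attached as attributes `origin_nodes`, `dest_nodes`.
#' @export
od_matrix <- function(graph, origins, destinations,
                      origin_ids = NULL, destination_ids = NULL) {
  onodes <- snap_to_node(origins, graph)
  dnodes <- snap_to_node(destinations, graph)
  g <- as_igraph_road(graph)
  ou <- unique(as.integer(onodes)); du <- unique(as.integer(dnodes))
  duu <- igraph::distances(g, v = du, to = ou,
                           weights = igraph::E(g)$weight,
                           algorithm = "dijkstra")
  d <- t(duu[match(as.integer(dnodes), du), match(as.integer(onodes), ou),
             drop = FALSE])
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)
    stop(sprintf(
      "network is disconnected: %d unreachable origin-destination pairs (first: origin %s -> destination %s)",
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  rownames(d) <- if (is.null(origin_ids)) seq_len(nrow(d)) else origin_ids
  colnames(d) <- if (is.null(destination_ids)) seq_len(ncol(d)) else destination_ids
  attr(d, "origin_nodes") <- as.integer(onodes)
  attr(d, "dest_nodes") <- as.integer(dnodes)
  attr(d, "origin_snap_m") <- attr(onodes, "snap_dist_m")
  attr(d, "dest_snap_m") <- attr(dnodes, "snap_dist_m")
  d
}

#' Convert network distance to travel time
#'
#' @param distance_m distance in metres.
#' @param speed_kmh average road speed in km/h; the study default is
#'   30 km/h.
#' @return travel time in seconds.
#' @export
distance_to_time <- function(distance_m, speed_kmh = 30) {
  if (any(speed_kmh <= 0)) stop("speed_kmh must be positive")
  distance_m * 3.6 / speed_kmh
}

#' Count points in census-area polygons
#'
#' Assigns each point to at most one area by ray casting; a point on a
#' shared boundary is assigned to the first area in `area_id` order.
#' Points falling outside every polygon are tallied in an `unassigned`
#' attribute (mirroring non-geocodable records in real dispatch data).
#'
#' @param points data.frame/matrix with columns (x, y).
#' @param areas a `census_areas` object.
#' @return named integer vector of counts per `area_id`, with attributes
#'   `assignment` (area id per point, NA if outside) and `unassigned`.
#' @export
count_points_in_polygons <- function(points, areas) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  ids <- areas$table$area_id
  assignment <- rep(NA_integer_, nrow(pts))
  todo <- rep(TRUE, nrow(pts))
  for (i in order(ids)) {
    if (!any(todo)) break
    poly <- areas$polygons[[i]]
    bb_ok <- todo &
      pts[, 1] >= min(poly[, 1]) - 1e-9 & pts[, 1] <= max(poly[, 1]) + 1e-9 &
      pts[, 2] >= min(poly[, 2]) - 1e-9 & pts[, 2] <= max(poly[, 2]) + 1e-9
    if (!any(bb_ok)) next
    hit <- point_in_polygon(pts[bb_ok, 1], pts[bb_ok, 2], poly)
    sel <- which(bb_ok)[hit]
    assignment[sel] <- ids[i]
    todo[sel] <- FALSE
  }
  counts <- table(factor(assignment, levels = ids))
  out <- as.integer(counts)
  names(out) <- ids
  attr(out, "assignment") <- assignment
  attr(out, "unassigned") <- sum(is.na(assignment))
  out
}
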