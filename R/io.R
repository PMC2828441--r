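# File writers/readers for the study artefacts. All formats are plain
# text; numeric CSVs are written at full double precision (%.17g) so a
# write/read round trip is bit-exact.

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write census areas as a GeoJSON FeatureCollection
#'
#' One polygon feature per area, with all demographic/case attributes as
#' properties. Coordinates are the planar metre coordinates of the
#' synthetic city (no CRS is implied).
#'
#' @param areas a `census_areas` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_areas_geojson <- function(areas, path) {
  feats <- lapply(seq_len(nrow(areas$table)), function(i) {
    poly <- areas$polygons[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    props <- as.list(areas$table[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, as.list,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a road graph as node and edge CSV tables
#' @param graph a `road_graph`.
#' @param node_path,edge_path output files.
#' @return invisibly, the two paths.
#' @export
write_road_graph_csv <- function(graph, node_path, edge_path) {
  nodes <- graph$nodes
  nodes$x <- fmt_full(nodes$x); nodes$y <- fmt_full(nodes$y)
  utils::write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  edges <- graph$edges
  edges$length_m <- fmt_full(edges$length_m)
  utils::write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Read a road graph from node and edge CSV tables
#' @param node_path,edge_path files written by [write_road_graph_csv()].
#' @return a `road_graph`.
#' @export
read_road_graph_csv <- function(node_path, edge_path) {
  nodes <- utils::read.csv(node_path)
  edges <- utils::read.csv(edge_path)
  structure(list(nodes = nodes, edges = edges), class = "road_graph")
}

#' Write an OD matrix
#'
#' Two representations: a long CSV (`area_id, site_id, distance_m`) and a
#' dense CSV with area ids as the first column and site ids as header.
#' Distances are written at full precision, so reading the dense file
#' back reproduces the matrix bit-exactly.
#'
#' @param od OD matrix from [od_matrix()].
#' @param long_path,dense_path output files (either may be NULL to skip).
#' @return invisibly, the written paths.
#' @export
write_od_csv <- function(od, long_path = NULL, dense_path = NULL) {
  written <- character(0)
  if (!is.null(long_path)) {
    long <- data.frame(
      area_id = rep(rownames(od), times = ncol(od)),
      site_id = rep(colnames(od), each = nrow(od)),
      distance_m = fmt_full(as.vector(od)))
    utils::write.csv(long, long_path, row.names = FALSE, quote = FALSE)
    written <- c(written, long_path)
  }
  if (!is.null(dense_path)) {
    dense <- data.frame(area_id = rownames(od),
                        apply(od, 2, fmt_full),
                        check.names = FALSE)
    colnames(dense) <- c("area_id", colnames(od))
    utils::write.csv(dense, dense_path, row.names = FALSE, quote = FALSE)
    written <- c(written, dense_path)
  }
  invisible(written)
}

#' Read a dense OD matrix written by [write_od_csv()]
#' @param dense_path the dense CSV file.
#' @return numeric matrix with area-id rownames and site-id colnames.
#' @export
read_od_csv <- function(dense_path) {
  d <- utils::read.csv(dense_path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d$area_id)
  m
}

#' Write a cohort table (long CSV)
#' @param tab cohort table; @param period calendar year label;
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(tab, period, path) {
  out <- data.frame(period = period, tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
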