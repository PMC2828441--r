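# Shared fixtures and independent oracles. All fixtures are built in code
# at test time; oracles deliberately avoid the code paths they check.

# Two areas, two sites, hand-checkable distances (person-metres worked by
# hand: s={1,2} -> 2*1000 + 3*2000 = 8000).
hand_instance <- function() {
  od <- matrix(c(1000, 4000,
                 5000, 2000),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("1", "2")))
  sites <- data.frame(site_id = 1:2, node_id = 1:2, x = c(0, 1),
                      y = c(0, 1), max_slots = 3)
  list(od = od, w = c(A = 2, B = 3), sites = sites,
       slots = emsloc::candidate_slots(sites))
}

# Small synthetic city with OD matrix, for GA/deployment tests.
small_city <- function(seed = 1, k = 30, n_sites = 8, slots_per_site = 1,
                       lambda_cases = 5) {
  g <- emsloc::generate_road_graph(6, 6, 700, 0.1, 0, seed = seed)
  a <- emsloc::generate_census_areas(g, k, seed = seed + 1)
  sites <- emsloc::place_candidate_sites(g, n_sites, slots_per_site,
                                         seed = seed + 2)
  od <- emsloc::od_matrix(g, a$table[, c("centroid_x", "centroid_y")],
                          sites[, c("x", "y")],
                          origin_ids = a$table$area_id,
                          destination_ids = sites$site_id)
  set.seed(seed + 3)
  w <- stats::rpois(k, lambda_cases)
  list(graph = g, areas = a, sites = sites, od = od, w = w,
       slots = emsloc::candidate_slots(sites))
}

# Flood-fill connectivity oracle over an edge list (no igraph).
flood_fill_connected <- function(node_ids, edges) {
  if (length(node_ids) <= 1) return(TRUE)
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  seen <- stats::setNames(rep(FALSE, length(node_ids)), node_ids)
  queue <- node_ids[1]
  seen[as.character(node_ids[1])] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[as.character(v)]]) {
      if (!seen[as.character(u)]) {
        seen[as.character(u)] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  all(seen)
}

# Floyd-Warshall all-pairs shortest paths oracle (dense dynamic program).
floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    u <- edges$from[i]; v <- edges$to[i]; L <- edges$length_m[i]
    d[u, v] <- min(d[u, v], L); d[v, u] <- min(d[v, u], L)
  }
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Random connected weighted graph as a road_graph (coords distinct so
# points placed on nodes snap to themselves).
random_road_graph <- function(n, seed) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n),
                      x = stats::runif(n, 0, 1000),
                      y = stats::runif(n, 0, 1000))
  from <- integer(0); to <- integer(0)
  for (i in 2:n) { from <- c(from, sample(i - 1L, 1L)); to <- c(to, i) }
  extra <- matrix(sample(n, 2 * max(2, n %/% 3), replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  edges <- unique(data.frame(from = c(from, pmin(extra[, 1], extra[, 2])),
                             to = c(to, pmax(extra[, 1], extra[, 2]))))
  edges$length_m <- stats::runif(nrow(edges), 10, 500)
  structure(list(nodes = nodes, edges = edges), class = "road_graph")
}

# Moore-Penrose pseudoinverse OLS oracle via SVD (independent of lm).
ols_pinv <- function(X, y) {
  Xi <- cbind(1, X)
  s <- svd(Xi)
  keep <- s$d > max(dim(Xi)) * .Machine$double.eps * s$d[1]
  beta <- s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
  drop(beta)
}

# Study-scale generator settings used by the parameter-recovery checks.
study_city_config <- function() {
  list(n_rows = 40, n_cols = 40, spacing_m = 600, jitter_frac = 0.2,
       edge_removal_frac = 0.1, n_areas = 2076, total_pop = 814000,
       n_sites = 35, slots_per_site = 5, target_r2 = 0.71)
}
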