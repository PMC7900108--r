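#' Nodal degree
#'
#' Number of neighbours of each node, i.e. the count of nonzero-weight
#' connections incident to it.
#'
#' @param conn A [connectome] (or a weight matrix coercible to one).
#' @return Named integer vector of length N.
#' @export
nodal_degree <- function(conn) {
  conn <- as_connectome(conn)
  deg <- as.integer(rowSums(conn$weights > 0))
  setNames(deg, conn$node_labels)
}

#' Nodal strength
#'
#' Sum of the edge weights incident to each node.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector of length N.
#' @export
nodal_strength <- function(conn) {
  conn <- as_connectome(conn)
  setNames(rowSums(conn$weights), conn$node_labels)
}

#' Edge density
#'
#' Fraction of possible node pairs that are connected.
#'
#' @inheritParams nodal_degree
#' @return Scalar in \[0, 1\].
#' @export
edge_density <- function(conn) {
  conn <- as_connectome(conn)
  n <- n_nodes(conn)
  if (n < 2) abort("edge density is undefined for N < 2 nodes.")
  w <- conn$weights
  sum(w[upper.tri(w)] > 0) / choose(n, 2)
}

#' Total strength
#'
#' Sum of all edge weights, each undirected edge counted once.  Equals
#' `sum(nodal_strength(conn)) / 2`.
#'
#' @inheritParams nodal_degree
#' @return Nonnegative scalar.
#' @export
total_strength <- function(conn) {
  conn <- as_connectome(conn)
  sum(conn$weights) / 2
}

#' Weighted nodal clustering coefficient
#'
#' Onnela's geometric-mean form: for node i with degree k_i,
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h}
#'   (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}}
#' where \eqn{\hat w = w / \max(w)} when `normalize_weights = TRUE` and
#' \eqn{\hat w = w} otherwise.  Nodes with fewer than two neighbours have
#' C_i = 0.  With normalization on, C_i lies in \[0, 1\]; with raw
#' streamline-count weights the values are on the weight scale and can
#' far exceed 1.  The default is unnormalized, matching toolboxes run
#' directly on count-weighted matrices.
#'
#' @inheritParams nodal_degree
#' @param normalize_weights Divide weights by their maximum first?
#' @return Named numeric vector of length N.
#' @export
nodal_clustering <- function(conn, normalize_weights = FALSE) {
  conn <- as_connectome(conn)
  w <- conn$weights
  if (normalize_weights && max(w) > 0) w <- w / max(w)
  cw <- w^(1 / 3)
  cyc <- diag(cw %*% cw %*% cw)   # 2x the weighted triangle count per node
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  setNames(ci, conn$node_labels)
}

#' Network clustering coefficient
#'
#' Mean of the nodal clustering coefficients over all N nodes (isolated
#' and degree-1 nodes contribute 0).
#'
#' @inheritParams nodal_clustering
#' @return Nonnegative scalar.
#' @export
global_clustering <- function(conn, normalize_weights = FALSE) {
  mean(nodal_clustering(conn, normalize_weights = normalize_weights))
}

#' Shortest-path distance matrix
#'
#' Weighted shortest-path distances with the standard
#' connectivity-to-length mapping for streamline-count networks: edge
#' length = 1 / weight, so strong connections are short.  Unreachable
#' pairs are `Inf`; the diagonal is 0.
#'
#' @inheritParams nodal_degree
#' @return Symmetric numeric N x N matrix.
#' @export
shortest_path_matrix <- function(conn) {
  conn <- as_connectome(conn)
  w <- conn$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lens <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = lens, algorithm = "dijkstra")
  dimnames(d) <- list(conn$node_labels, conn$node_labels)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs.  Pairs
#' with no connecting path are excluded with a warning (tractography
#' networks are near-fully connected, so exclusion affects few pairs);
#' a network with no finite pair at all is an error.
#'
#' @inheritParams nodal_degree
#' @return Positive scalar.
#' @export
characteristic_path_length <- function(conn) {
  conn <- as_connectome(conn)
  d <- shortest_path_matrix(conn)
  dv <- d[upper.tri(d)]
  fin <- is.finite(dv)
  if (!any(fin)) {
    abort("no connected node pair: characteristic path length is undefined.")
  }
  if (!all(fin)) {
    warn(sprintf(
      "%d of %d node pairs are unreachable and were excluded from the CPL.",
      sum(!fin), length(dv)
    ))
  }
  mean(dv[fin])
}

#' Small-worldness
#'
#' Defined here as the ratio of the network clustering coefficient to
#' the characteristic path length, C / L.  (The random-network
#' normalized sigma is deliberately not computed.)
#'
#' @inheritParams nodal_clustering
#' @return Nonnegative scalar.
#' @export
small_worldness <- function(conn, normalize_weights = FALSE) {
  global_clustering(conn, normalize_weights = normalize_weights) /
    characteristic_path_length(conn)
}

#' Regional efficiency
#'
#' Mean inverse shortest-path distance from each node to all others:
#' \deqn{E_i = \frac{1}{N - 1} \sum_{j \ne i} 1 / d_{ij},}
#' with 1/Inf = 0 for unreachable pairs.  On a complete unit-weight
#' network every E_i = 1.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector of length N.
#' @export
regional_efficiency <- function(conn) {
  conn <- as_connectome(conn)
  d <- shortest_path_matrix(conn)
  inv <- 1 / d
  diag(inv) <- 0
  setNames(rowSums(inv) / (n_nodes(conn) - 1), conn$node_labels)
}

#' All nodal and global network measures for one subject
#'
#' Bundles the four nodal measures (degree, strength, clustering,
#' efficiency) and five global measures (edge density, total strength,
#' clustering coefficient, characteristic path length, small-worldness)
#' into one long-format table.
#'
#' @inheritParams nodal_clustering
#' @return A tibble with columns `subject_id`, `scope` (`"nodal"` or
#'   `"global"`), `measure`, `node` (`NA` for global rows) and `value`.
#' @export
compute_all_metrics <- function(conn, normalize_weights = FALSE) {
  conn <- as_connectome(conn)
  lab <- conn$node_labels
  # one Dijkstra pass feeds efficiency and the CPL
  d <- shortest_path_matrix(conn)
  inv <- 1 / d
  diag(inv) <- 0
  eff <- rowSums(inv) / (length(lab) - 1)
  dv <- d[upper.tri(d)]
  fin <- is.finite(dv)
  if (!any(fin)) {
    abort("no connected node pair: characteristic path length is undefined.")
  }
  if (!all(fin)) {
    warn(sprintf(
      "%d of %d node pairs are unreachable and were excluded from the CPL.",
      sum(!fin), length(dv)
    ))
  }
  cpl <- mean(dv[fin])
  clust <- nodal_clustering(conn, normalize_weights = normalize_weights)
  nodal <- tibble(
    subject_id = conn$subject_id,
    scope = "nodal",
    measure = rep(c("degree", "strength", "clustering", "efficiency"),
                  each = length(lab)),
    node = rep(lab, times = 4),
    value = unname(c(as.numeric(nodal_degree(conn)), nodal_strength(conn),
                     clust, eff))
  )
  gc <- mean(clust)
  global <- tibble(
    subject_id = conn$subject_id,
    scope = "global",
    measure = c("edge_density", "total_strength", "clustering_coefficient",
                "characteristic_path_length", "small_worldness"),
    node = NA_character_,
    value = c(edge_density(conn), total_strength(conn), gc, cpl, gc / cpl)
  )
  bind_rows(nodal, global)
}

#' Network measures for a list of subjects
#'
#' @param conns List of [connectome] objects (names are ignored; each
#'   connectome carries its own `subject_id`).
#' @inheritParams nodal_clustering
#' @return Long tibble as in [compute_all_metrics()], one block per
#'   subject, in list order.
#' @export
connectome_metrics <- function(conns, normalize_weights = FALSE) {
  purrr::map(conns, compute_all_metrics,
             normalize_weights = normalize_weights) %>%
    bind_rows()
}
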