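#' Shortest-path length matrix of a binary graph
#'
#' Breadth-first-search distances between every pair of nodes (via
#' igraph's unweighted algorithm); unreachable pairs are `Inf`.
#'
#' @param adjacency A `waveconn_adjacency` or symmetric 0/1 matrix.
#' @return `R x R` matrix of hop counts, `0` on the diagonal.
#' @export
shortest_path_lengths <- function(adjacency) {
  adj <- .adjacency_matrix(adjacency)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::distances(g, algorithm = "unweighted")
}

# Mean inverse distance over ordered pairs, with 1/Inf = 0.
.efficiency_from_distances <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency of a binary graph
#'
#' The average over all ordered node pairs of the inverse shortest-path
#' length, with disconnected pairs contributing 0 (the Latora-Marchiori
#' convention): \deqn{E = \frac{1}{n} \sum_{i} \frac{1}{n-1}
#' \sum_{j \ne i} d_{ij}^{-1}.} Equals 1 for a complete graph and 0 for an
#' empty one.
#'
#' @inheritParams shortest_path_lengths
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
#' global_efficiency(path3) # 5/6
global_efficiency <- function(adjacency) {
  adj <- .adjacency_matrix(adjacency)
  if (nrow(adj) < 2) stop("global efficiency needs at least 2 nodes")
  .efficiency_from_distances(shortest_path_lengths(adj))
}

#' Nodal efficiency
#'
#' Average inverse distance from one node to every other node:
#' `E_i = (1/(n-1)) * sum_j 1/d_ij`.
#'
#' @inheritParams shortest_path_lengths
#' @param node Node index (1-based) or node name matching the adjacency
#'   dimnames.
#' @return A number in `[0, 1]`.
#' @export
nodal_efficiency <- function(adjacency, node) {
  adj <- .adjacency_matrix(adjacency)
  n <- nrow(adj)
  if (n < 2) stop("nodal efficiency needs at least 2 nodes")
  if (is.character(node)) {
    node <- match(node, rownames(adj))
  }
  if (is.na(node) || node < 1 || node > n) {
    stop("unknown node: not in the graph")
  }
  d <- shortest_path_lengths(adj)[node, -node]
  mean(1 / d)
}

#' Subnetwork efficiency E_s
#'
#' Evaluates the global-efficiency formula on the node subset of one named
#' functional network. In `"induced"` mode (the default) shortest paths are
#' computed inside the induced subgraph, so E_s measures information
#' exchange within the subnetwork only and not routes through the rest of
#' the brain; `"restricted"` mode keeps whole-graph distances and restricts
#' only the endpoints to network members.
#'
#' @inheritParams shortest_path_lengths
#' @param parcels Parcel table aligning regions to networks (row order must
#'   match the adjacency).
#' @param network Network name present in `parcels$network`.
#' @param mode `"induced"` or `"restricted"`.
#' @return A number in `[0, 1]`.
#' @export
subnetwork_efficiency <- function(adjacency, parcels, network,
                                  mode = c("induced", "restricted")) {
  mode <- match.arg(mode)
  adj <- .adjacency_matrix(adjacency)
  validate_parcel_table(parcels)
  if (nrow(parcels) != nrow(adj)) {
    stop("parcel table and adjacency disagree on the number of regions")
  }
  members <- which(parcels$network == network)
  if (length(members) < 2) {
    stop(sprintf("network '%s' has %d node(s); need at least 2",
                 network, length(members)))
  }
  d <- if (mode == "induced") {
    shortest_path_lengths(adj[members, members, drop = FALSE])
  } else {
    shortest_path_lengths(adj)[members, members, drop = FALSE]
  }
  .efficiency_from_distances(d)
}

#' Per-subject efficiency records for a cohort
#'
#' Computes global efficiency and every named network's E_s for each
#' subject's binary graph.
#'
#' @param adjacencies Named list of `waveconn_adjacency` objects (names =
#'   subject ids).
#' @param parcels Parcel table shared by all subjects.
#' @param mode E_s mode, see [subnetwork_efficiency()].
#' @return Data frame: `subject_id`, `E_global`, then one `E_<network>`
#'   column per named network.
#' @export
cohort_efficiency <- function(adjacencies, parcels,
                              mode = c("induced", "restricted")) {
  mode <- match.arg(mode)
  nets <- named_networks(parcels)
  rows <- lapply(names(adjacencies), function(id) {
    adj <- adjacencies[[id]]
    es <- vapply(nets, function(nm) {
      subnetwork_efficiency(adj, parcels, nm, mode)
    }, numeric(1))
    c(E_global = global_efficiency(adj), stats::setNames(es, paste0("E_", nets)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(subject_id = names(adjacencies), stringsAsFactors = FALSE),
        out)
}
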