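#' Convert connection weights to path lengths
#'
#' Strong connections are short: the default map is length = 1/weight, the
#' standard convention for correlation-derived connectivity weights. Zero
#' weight means no edge and maps to +Inf; the diagonal is 0.
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param map \code{"inverse"} (default) or \code{"neglog"} (-log(w), an
#'   alternative kept out of the default analysis path).
#' @return matrix of edge lengths.
#' @export
weight_to_length <- function(weights, map = c("inverse", "neglog")) {
  map <- match.arg(map)
  w <- as.matrix(weights)
  if (any(w < 0)) stop("negative weights are not allowed")
  len <- switch(map,
    inverse = ifelse(w > 0, 1 / w, Inf),
    neglog = ifelse(w > 0, -log(w), Inf)
  )
  diag(len) <- 0
  len
}

# Dijkstra all-pairs distances through igraph; weights are edge lengths.
shortest_path_lengths <- function(weights, map = "inverse") {
  w <- as.matrix(weights)
  n <- nrow(w)
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lens <- if (igraph::ecount(g) > 0) {
    ew <- igraph::E(g)$weight
    if (map == "inverse") 1 / ew else -log(ew)
  } else {
    numeric(0)
  }
  d <- igraph::distances(g, weights = lens, algorithm = "dijkstra")
  unname(d)
}

#' Weighted global efficiency of a network
#'
#' The mean over nodes of the average inverse shortest weighted path length
#' to every other node: E = (1/n) * sum_i [ sum_{j != i} 1/d_ij / (n - 1) ].
#' Unreachable pairs contribute 0. With connection weights in [0, 1] and the
#' inverse weight-to-length map, the result lies in [0, 1]; the complete
#' unit-weight graph attains exactly 1.
#'
#' @param weights symmetric weight matrix in [0, 1], zero diagonal, at least
#'   2 nodes.
#' @param map weight-to-length convention, see [weight_to_length()].
#' @return scalar global efficiency.
#' @export
global_efficiency <- function(weights, map = "inverse") {
  w <- as.matrix(weights)
  n <- nrow(w)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  if (any(w < 0)) stop("negative weights are not allowed")
  d <- shortest_path_lengths(w, map)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency of one node
#'
#' Measures how efficiently the neighbors of node \code{i} communicate when
#' \code{i} is removed: shortest paths are restricted to the subgraph induced
#' by the neighbor set. The default \code{"product"} variant computes
#' sum over ordered neighbor pairs (j != h) of
#' w_ij * w_ih / d_jh(N_i), divided by k_i * (k_i - 1) with k_i the binary
#' degree (number of links), which keeps the score in [0, 1] for weights in
#' [0, 1]. The \code{"rubinov_sporns"} variant applies the cube root to each
#' product term, the form standard in weighted connectivity analysis.
#' Nodes with fewer than two neighbors score 0.
#'
#' @param weights symmetric weight matrix, zero diagonal.
#' @param i node index (or name).
#' @param variant \code{"product"} or \code{"rubinov_sporns"}.
#' @param map weight-to-length convention.
#' @return scalar local efficiency of node \code{i}.
#' @export
local_efficiency_node <- function(weights, i,
                                  variant = c("product", "rubinov_sporns"),
                                  map = "inverse") {
  variant <- match.arg(variant)
  w <- as.matrix(weights)
  if (is.character(i)) i <- match(i, rownames(w))
  nb <- which(w[i, ] > 0)
  nb <- setdiff(nb, i)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- w[nb, nb, drop = FALSE]
  d <- shortest_path_lengths(sub, map)
  inv_d <- 1 / d
  inv_d[!is.finite(inv_d)] <- 0
  diag(inv_d) <- 0
  wi <- w[i, nb]
  prod_terms <- outer(wi, wi) * inv_d   # ordered pairs j != h
  if (variant == "rubinov_sporns") prod_terms <- prod_terms^(1 / 3)
  sum(prod_terms) / (k * (k - 1))
}

#' Weighted local efficiency of a network
#'
#' Mean of [local_efficiency_node()] over all nodes of the network.
#'
#' @inheritParams local_efficiency_node
#' @return scalar in [0, 1] under the default variant.
#' @export
local_efficiency <- function(weights, variant = c("product", "rubinov_sporns"),
                             map = "inverse") {
  variant <- match.arg(variant)
  w <- as.matrix(weights)
  n <- nrow(w)
  if (n < 1) stop("empty network")
  vals <- vapply(seq_len(n), function(i) {
    local_efficiency_node(w, i, variant, map)
  }, numeric(1))
  mean(vals)
}

#' Efficiency records for a batch of subject-by-network matrices
#'
#' @param networks nested named list: \code{networks[[subject]][[label]]} is a
#'   weight matrix. A flat named list is treated as one anonymous subject.
#' @param variant efficiency variant, see [local_efficiency_node()].
#' @param map weight-to-length convention.
#' @return data frame with one row per subject x network: \code{e_glob},
#'   \code{e_loc}, \code{n_nodes}, \code{n_edges}, \code{variant}, in
#'   deterministic (input) order.
#' @export
efficiency_batch <- function(networks, variant = "product", map = "inverse") {
  if (length(networks) == 0) stop("empty network list")
  if (is.matrix(networks[[1]])) networks <- list(subject = networks)
  rows <- list()
  for (sid in names(networks)) {
    for (lb in names(networks[[sid]])) {
      w <- networks[[sid]][[lb]]
      e_g <- global_efficiency(w, map)
      e_l <- local_efficiency(w, variant, map)
      stopifnot(e_g >= 0, e_l >= 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, network_label = lb,
        e_glob = e_g, e_loc = e_l,
        n_nodes = nrow(w),
        n_edges = sum(w[upper.tri(w)] > 0),
        variant = variant,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
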