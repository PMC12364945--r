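#' Node centrality indices on the weighted network
#'
#' `node_strength()` is the sum of absolute incident edge weights;
#' `expected_influence()` is the signed sum (equal to strength when all
#' edges are positive). `shortest_path_metrics()` computes closeness and
#' betweenness on the weighted graph, using edge length `1/|w|` for
#' shortest paths (strong edges are short): closeness is
#' `(m-1) / sum of distances to reachable nodes`, and betweenness counts
#' the fraction of shortest paths between unordered node pairs passing
#' through a node (Brandes convention, fractional shares over
#' equal-length paths). Disconnected networks are handled over reachable
#' pairs and flagged.
#'
#' @param network A `symptom_network`.
#' @return `node_strength()` and `expected_influence()` return a named
#'   numeric vector; `shortest_path_metrics()` a tibble with columns
#'   `node`, `closeness`, `betweenness` and a `disconnected` attribute.
#' @export
node_strength <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  w <- network$weights
  w[abs(w) <= network$edge_threshold] <- 0
  rowSums(abs(w))
}

#' @rdname node_strength
#' @export
expected_influence <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  w <- network$weights
  w[abs(w) <= network$edge_threshold] <- 0
  rowSums(w)
}

# igraph object with edge length 1/|w| for path-based indices
as_igraph_lengths <- function(network) {
  w <- network$weights
  w[abs(w) <= network$edge_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  }
  g
}

#' @rdname node_strength
#' @export
shortest_path_metrics <- function(network) {
  g <- as_igraph_lengths(network)
  m <- length(network$nodes)
  if (igraph::ecount(g) == 0) {
    out <- tibble::tibble(node = network$nodes, closeness = 0,
                          betweenness = 0)
    attr(out, "disconnected") <- TRUE
    return(out)
  }
  d <- igraph::distances(g, weights = igraph::E(g)$length)
  diag(d) <- NA
  clo <- apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin) == 0) return(0)
    (m - 1) / sum(fin)
  })
  btw <- igraph::betweenness(g, weights = igraph::E(g)$length,
                             directed = FALSE)
  out <- tibble::tibble(node = network$nodes,
                        closeness = as.numeric(clo[network$nodes]),
                        betweenness = as.numeric(btw[network$nodes]))
  attr(out, "disconnected") <- any(!is.finite(d[upper.tri(d)]))
  out
}

#' Per-node centrality table with z-standardized indices
#'
#' Assembles strength, expected influence, closeness, and betweenness
#' for every node, raw and z-standardized across nodes (sample SD;
#' an index with zero spread gets all-zero z-scores and a flag).
#'
#' @param network A `symptom_network`.
#' @return A tibble with raw and `z_`-prefixed columns, of class
#'   `centrality_table`; attribute `degenerate` names indices with zero
#'   spread.
#' @export
centrality_table <- function(network) {
  sp <- shortest_path_metrics(network)
  out <- tibble::tibble(node = network$nodes,
                        strength = as.numeric(node_strength(network)),
                        expected_influence = as.numeric(expected_influence(network)),
                        closeness = sp$closeness,
                        betweenness = sp$betweenness)
  standardize_centrality(out)
}

#' @rdname centrality_table
#' @param table A centrality tibble with columns `strength`,
#'   `expected_influence`, `closeness`, `betweenness`.
#' @export
standardize_centrality <- function(table) {
  if (nrow(table) < 2) abort("need at least 2 nodes to standardize",
                             class = "symptomnet_domain_error")
  idx <- c("strength", "expected_influence", "closeness", "betweenness")
  degenerate <- character()
  for (nm in intersect(idx, names(table))) {
    s <- sd(table[[nm]])
    if (is.na(s) || s == 0) {
      table[[paste0("z_", nm)]] <- rep(0, nrow(table))
      degenerate <- c(degenerate, nm)
    } else {
      table[[paste0("z_", nm)]] <- (table[[nm]] - mean(table[[nm]])) / s
    }
  }
  attr(table, "degenerate") <- degenerate
  class(table) <- unique(c("centrality_table", class(table)))
  table
}

#' Rank core symptoms by strength centrality
#'
#' Orders the symptom nodes by strength, descending: the top nodes are
#' the network's core symptoms. Ties are broken lexicographically and
#' flagged.
#'
#' @param table A [centrality_table()].
#' @param symptom_nodes Optional subset of nodes to rank (use to exclude
#'   covariate nodes of an adjusted network); default all.
#' @return A tibble `node`, `strength`, `rank`; attribute `ties` is
#'   `TRUE` when any strengths tied.
#' @export
rank_core_symptoms <- function(table, symptom_nodes = table$node) {
  sub <- dplyr::filter(table, .data$node %in% symptom_nodes)
  ord <- order(-sub$strength, sub$node)
  out <- tibble::tibble(node = sub$node[ord],
                        strength = sub$strength[ord],
                        rank = seq_along(ord))
  attr(out, "ties") <- anyDuplicated(sub$strength) > 0
  out
}

#' Fruchterman-Reingold layout coordinates
#'
#' Force-directed node coordinates for plotting: repulsion between all
#' node pairs, attraction along edges proportional to `|w|`, rescaled to
#' the unit square `[-1, 1]^2`. Deterministic under a fixed seed.
#'
#' @param network A `symptom_network`.
#' @param seed Integer seed for the random initial placement.
#' @param iterations Number of layout iterations.
#' @return A tibble `node`, `x`, `y` with attributes `seed` and
#'   `iterations`.
#' @export
fruchterman_reingold <- function(network, seed = 1, iterations = 500) {
  w <- abs(network$weights)
  w[w <= network$edge_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  xy <- local_seed(seed, {
    if (igraph::ecount(g) > 0) {
      igraph::layout_with_fr(g, niter = iterations,
                             weights = igraph::E(g)$weight)
    } else {
      igraph::layout_with_fr(g, niter = iterations)
    }
  })
  xy <- igraph::norm_coords(xy, xmin = -1, xmax = 1, ymin = -1, ymax = 1)
  out <- tibble::tibble(node = network$nodes, x = xy[, 1], y = xy[, 2])
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  out
}
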