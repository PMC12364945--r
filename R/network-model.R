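#' The estimated network object
#'
#' A `symptom_network` holds the node labels, the symmetric matrix of
#' regularized partial correlations (zero diagonal, entries in [-1, 1]),
#' and the estimation metadata: selected penalty `lambda`, EBIC
#' hyperparameter `gamma`, the attained EBIC, and the number of
#' observations the correlation matrix was computed from.
#'
#' @param weights m x m symmetric numeric matrix of partial correlations.
#' @param nodes Character vector of node labels.
#' @param lambda,gamma,ebic,n_obs Estimation metadata (may be `NA` for
#'   networks constructed directly from a weight matrix).
#' @param edge_threshold Absolute weights at or below this value are
#'   treated as absent edges (absorbs solver noise).
#' @return An object of class `symptom_network`.
#' @export
new_symptom_network <- function(weights, nodes = colnames(weights),
                                lambda = NA_real_, gamma = NA_real_,
                                ebic = NA_real_, n_obs = NA_integer_,
                                edge_threshold = 1e-8) {
  weights <- as.matrix(weights)
  m <- nrow(weights)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(m))
  stopifnot(m == ncol(weights), length(nodes) == m)
  if (max(abs(weights - t(weights))) > 1e-10) {
    abort("weight matrix must be symmetric (within 1e-10)",
          class = "symptomnet_domain_error")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (max(abs(weights)) > 1 + 1e-8) {
    abort("partial correlations must lie in [-1, 1]",
          class = "symptomnet_domain_error")
  }
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights,
                 lambda = lambda, gamma = gamma, ebic = ebic,
                 n_obs = n_obs, edge_threshold = edge_threshold),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  d <- network_density(x)
  cat("<symptom_network> ", length(x$nodes), " nodes, ",
      d$n_edges, "/", d$n_possible, " edges (density ",
      sprintf("%.2f%%", 100 * d$density), ")\n", sep = "")
  if (!is.na(x$lambda)) {
    cat("  lambda = ", signif(x$lambda, 4), ", gamma = ", x$gamma,
        ", EBIC = ", signif(x$ebic, 6), ", n = ", x$n_obs, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an estimated network into an edge tibble
#'
#' @param x A `symptom_network`.
#' @param all_pairs If `TRUE`, include zero-weight pairs too.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`, one row per
#'   unordered node pair (lexicographic by node index).
#' @export
tidy.symptom_network <- function(x, all_pairs = FALSE, ...) {
  m <- length(x$nodes)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    weight = x$weights[idx]
  )
  if (!all_pairs) out <- dplyr::filter(out, abs(.data$weight) > x$edge_threshold)
  out
}

#' @rdname tidy.symptom_network
#' @export
glance.symptom_network <- function(x, ...) {
  d <- network_density(x)
  tibble::tibble(n_nodes = length(x$nodes), n_edges = d$n_edges,
                 n_possible = d$n_possible, density = d$density,
                 lambda = x$lambda, gamma = x$gamma, ebic = x$ebic,
                 n_obs = x$n_obs)
}

#' Network density
#'
#' Density is the proportion of the m(m-1)/2 possible edges that are
#' present (nonzero after regularization) in the estimated network.
#'
#' @param network A `symptom_network`.
#' @return A list with `n_edges`, `n_possible`, and `density`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.4
#' network_density(new_symptom_network(w, c("a", "b", "c")))
network_density <- function(network) {
  stopifnot(inherits(network, "symptom_network"))
  m <- length(network$nodes)
  if (m < 2) abort("density needs at least 2 nodes",
                   class = "symptomnet_domain_error")
  e <- sum(abs(network$weights[upper.tri(network$weights)]) >
             network$edge_threshold)
  possible <- m * (m - 1) / 2
  list(n_edges = e, n_possible = possible, density = e / possible)
}

#' Partial correlations from a precision matrix
#'
#' Converts a symmetric positive-definite precision (inverse covariance)
#' matrix into the matrix of partial correlations,
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, with zero diagonal.
#'
#' @param theta Symmetric positive-definite matrix.
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @export
partials_from_precision <- function(theta) {
  theta <- as.matrix(theta)
  if (max(abs(theta - t(theta))) > 1e-8) {
    abort("precision matrix must be symmetric",
          class = "symptomnet_domain_error")
  }
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort("precision matrix must be positive definite",
          class = "symptomnet_domain_error")
  }
  d <- 1 / sqrt(diag(theta))
  w <- -theta * tcrossprod(d)
  diag(w) <- 0
  dimnames(w) <- dimnames(theta)
  w
}
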