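#' Graphical lasso fit at a fixed penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |theta_ij|` over positive-definite precision matrices Theta by
#' blockwise coordinate descent (each row/column update is an L1
#' regression sub-problem solved by coordinate descent). The diagonal is
#' not penalized.
#'
#' @param S Correlation (or covariance) matrix; symmetric PSD with unit
#'   diagonal for the intended use.
#' @param lambda Positive penalty.
#' @param tol Convergence tolerance on the working covariance, relative
#'   to the mean absolute off-diagonal of `S`.
#' @param max_iter Maximum outer sweeps.
#' @return A list with `theta` (precision estimate), `partials` (partial
#'   correlation matrix), and `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, max_iter = 200) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8) {
    abort("S must be symmetric", class = "symptomnet_domain_error")
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("S must be positive semidefinite (run nearest_psd first)",
          class = "symptomnet_domain_error")
  }
  if (lambda <= 0) abort("lambda must be positive",
                         class = "symptomnet_domain_error")
  fit <- .glasso_fit_cpp(S, lambda, tol, as.integer(max_iter))
  if (!fit$converged) {
    abort(paste0("graphical lasso did not converge in ", max_iter,
                 " sweeps at lambda = ", signif(lambda, 4)),
          class = "symptomnet_convergence_error")
  }
  theta <- fit$theta
  dimnames(theta) <- dimnames(S)
  list(theta = theta, partials = partials_from_precision(theta),
       converged = fit$converged)
}

#' Extended Bayesian information criterion for a Gaussian graphical model
#'
#' `EBIC = -2 l(Theta) + E log(n) + 4 E gamma log(p)` with Gaussian
#' log-likelihood `l = (n/2) (log det Theta - tr(S Theta))` and `E` the
#' number of nonzero upper-triangle entries of the partial-correlation
#' matrix. `gamma = 0` recovers the ordinary BIC.
#'
#' @param theta Precision estimate.
#' @param S Correlation matrix the model was fitted to.
#' @param n Number of observations.
#' @param gamma EBIC hyperparameter (>= 0).
#' @param edge_threshold Absolute entries at or below this count as zero.
#' @return The EBIC value (finite real).
#' @export
ebic <- function(theta, S, n, gamma = 0.5, edge_threshold = 1e-8) {
  theta <- as.matrix(theta)
  p <- nrow(theta)
  loglik <- (n / 2) * (determinant(theta, logarithm = TRUE)$modulus[1] -
                         sum(S * theta))
  e <- sum(abs(theta[upper.tri(theta)]) > edge_threshold)
  as.numeric(-2 * loglik + e * log(n) + 4 * e * gamma * log(p))
}

#' Regularized network estimation with EBIC penalty selection
#'
#' Fits the graphical lasso along a path of `n_lambdas` log-spaced
#' penalties from `lambda_max` (the largest absolute off-diagonal of
#' `S`, at which the estimated network is empty) down to
#' `lambda_max * lambda_min_ratio`, computes the EBIC of every fit, and
#' returns the network minimizing EBIC. Estimation is deterministic
#' given `S`, `n` and `gamma`.
#'
#' @inheritParams ebic
#' @param n_lambdas Number of penalties on the path.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest.
#' @param tol,max_iter Passed to the solver.
#' @return A `symptom_network` carrying the selected `lambda`, `gamma`,
#'   attained EBIC, `n_obs`, and a `path` attribute summarizing the
#'   whole path (lambda, edge count, EBIC).
#' @export
ebicglasso_select <- function(S, n, gamma = 0.5, n_lambdas = 100,
                              lambda_min_ratio = 0.01,
                              edge_threshold = 1e-8,
                              tol = 1e-4, max_iter = 200) {
  S <- as.matrix(S)
  p <- nrow(S)
  off <- abs(S[upper.tri(S)])
  lambda_max <- max(off)
  if (lambda_max <= edge_threshold) {
    # diagonal input: the empty network at an arbitrary small penalty
    theta <- diag(1 / diag(S))
    dimnames(theta) <- dimnames(S)
    net <- new_symptom_network(partials_from_precision(theta),
                               nodes = colnames(S) %||% paste0("V", 1:p),
                               lambda = 1e-4, gamma = gamma,
                               ebic = ebic(theta, S, n, gamma), n_obs = n,
                               edge_threshold = edge_threshold)
    attr(net, "path") <- tibble::tibble(lambda = 1e-4, n_edges = 0L,
                                        ebic = net$ebic)
    attr(net, "theta") <- theta
    return(net)
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  fit <- .glasso_path_cpp(S, lambdas, tol, as.integer(max_iter))
  if (!all(fit$converged)) {
    abort("graphical lasso failed to converge on part of the path",
          class = "symptomnet_convergence_error")
  }
  ebics <- numeric(n_lambdas)
  edges <- integer(n_lambdas)
  for (k in seq_len(n_lambdas)) {
    th <- fit$thetas[, , k]
    ebics[k] <- ebic(th, S, n, gamma, edge_threshold)
    edges[k] <- sum(abs(th[upper.tri(th)]) > edge_threshold)
  }
  best <- which.min(ebics)
  theta <- fit$thetas[, , best]
  dimnames(theta) <- dimnames(S)
  net <- new_symptom_network(partials_from_precision(theta),
                             nodes = colnames(S) %||% paste0("V", 1:p),
                             lambda = lambdas[best], gamma = gamma,
                             ebic = ebics[best], n_obs = n,
                             edge_threshold = edge_threshold)
  attr(net, "path") <- tibble::tibble(lambda = lambdas, n_edges = edges,
                                      ebic = ebics)
  attr(net, "theta") <- theta
  net
}

#' Estimate the unadjusted and covariate-adjusted symptom networks
#'
#' The unadjusted network uses the symptom columns only. The adjusted
#' network appends the selected covariates as additional nodes, so every
#' symptom-symptom edge conditions on them; its centralities are
#' computed on the full node set and reported for symptoms. Both go
#' through Spearman correlation, PSD repair, and EBIC-selected graphical
#' lasso.
#'
#' @param table A [symptom_table()].
#' @param covariates Character vector of covariate columns to adjust for
#'   (must be present in the table; empty means the two networks
#'   coincide).
#' @param gamma EBIC hyperparameter.
#' @param ... Passed to [ebicglasso_select()].
#' @return A list with elements `unadjusted` and `adjusted`, each a
#'   `symptom_network`.
#' @export
estimate_networks <- function(table, covariates = symptom_covariates(table),
                              gamma = 0.5, ...) {
  p <- length(symptom_items(table))
  if (nrow(table) < p + 1) {
    abort(paste0("need at least p+1 = ", p + 1, " rows, got ", nrow(table)),
          class = "symptomnet_domain_error")
  }
  missing_cov <- setdiff(covariates, symptom_covariates(table))
  if (length(missing_cov) > 0) {
    abort(paste0("covariates not in table: ",
                 paste(missing_cov, collapse = ", ")),
          class = "symptomnet_schema_error")
  }
  n <- nrow(table)
  S_un <- nearest_psd(spearman_matrix(table, include_covariates = FALSE))
  unadj <- ebicglasso_select(S_un, n, gamma = gamma, ...)
  if (length(covariates) == 0) {
    return(list(unadjusted = unadj, adjusted = unadj))
  }
  sub <- table
  attr(sub, "covariates") <- covariates
  S_adj <- nearest_psd(spearman_matrix(sub, include_covariates = TRUE))
  adj <- ebicglasso_select(S_adj, n, gamma = gamma, ...)
  list(unadjusted = unadj, adjusted = adj)
}
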