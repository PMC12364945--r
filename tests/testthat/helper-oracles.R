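# Independent oracles used to cross-check the package's own algorithms.
# These deliberately use different methods from the implementation.

# Graphical lasso by ADMM (eigendecomposition + soft thresholding),
# off-diagonal penalty only -- independent of the coordinate-descent
# solver under test.
oracle_glasso_admm <- function(S, lam, rho = 1, iters = 10000, tol = 1e-10) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  for (i in seq_len(iters)) {
    es <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (es$values + sqrt(es$values^2 + 4 * rho)) / (2 * rho)
    Theta <- es$vectors %*% (d * t(es$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - lam / rho, 0)
    diag(Z) <- diag(A)
    U <- U + Theta - Z
    if (max(abs(Z - Zold)) < tol && max(abs(Theta - Z)) < tol) break
  }
  Z
}

# All-pairs shortest-path distances and Brandes-style betweenness by
# Floyd-Warshall with shortest-path counting (unordered pairs,
# fractional shares over equal-length paths).
oracle_path_metrics <- function(weights, edge_threshold = 1e-8,
                                tol = 1e-9) {
  p <- nrow(weights)
  d <- matrix(Inf, p, p)
  sigma <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j && abs(weights[i, j]) > edge_threshold) {
        d[i, j] <- 1 / abs(weights[i, j])
        sigma[i, j] <- 1
      }
    }
  }
  diag(d) <- 0
  diag(sigma) <- 1
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j || i == k || j == k) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j] - tol) {
          d[i, j] <- alt
          sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (is.finite(alt) && abs(alt - d[i, j]) <= tol) {
          sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
      }
    }
  }
  btw <- numeric(p)
  for (v in seq_len(p)) {
    for (s in seq_len(p - 1)) {
      for (t in (s + 1):p) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) <= tol && sigma[s, t] > 0) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    fin <- d[i, -i][is.finite(d[i, -i])]
    if (length(fin) == 0) return(0)
    (p - 1) / sum(fin)
  }, numeric(1))
  list(distances = d, closeness = clo, betweenness = btw)
}

# Population Spearman correlation of a discretized bivariate-normal pair
# by numerical double integration of the density over the threshold
# rectangles (grade correlation with midrank scores).
oracle_discretized_spearman <- function(rho, thr_x, thr_y) {
  cuts_x <- c(-8, thr_x, 8)
  cuts_y <- c(-8, thr_y, 8)
  k <- length(thr_x) + 1
  dens <- function(x, y) {
    (1 / (2 * pi * sqrt(1 - rho^2))) *
      exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2)))
  }
  P <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      P[a, b] <- pracma::integral2(dens, cuts_x[a], cuts_x[a + 1],
                                   cuts_y[b], cuts_y[b + 1],
                                   reltol = 1e-8)$Q
    }
  }
  px <- rowSums(P)
  py <- colSums(P)
  # midrank (mid-distribution) scores
  u <- cumsum(px) - px / 2
  v <- cumsum(py) - py / 2
  eu <- sum(px * u); evv <- sum(py * v)
  cov_uv <- sum(P * outer(u - eu, v - evv))
  cov_uv / sqrt(sum(px * (u - eu)^2) * sum(py * (v - evv)^2))
}

# Build a synthetic_truth from an arbitrary off-diagonal precision
# pattern, using the same diagonal-repair rule as the generator.
truth_from_pattern <- function(A, items = paste0("v", seq_len(nrow(A)))) {
  A <- (A + t(A)) / 2
  diag(A) <- 0
  lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  dv <- max(1, 1.05 * (-lam_min))
  precision <- A + diag(dv, nrow(A))
  dimnames(precision) <- list(items, items)
  structure(list(precision = precision,
                 true_partials = partials_from_precision(precision),
                 clusters = NULL, items = items, diagonal = dv,
                 thresholds = NULL, covariate_effects = NULL, seed = NA),
            class = "synthetic_truth")
}

upper_vals <- function(m) m[upper.tri(m)]

support_metrics <- function(estimated, truth) {
  st <- abs(upper_vals(truth$true_partials)) > 1e-10
  se <- abs(upper_vals(estimated$weights)) > estimated$edge_threshold
  c(sensitivity = sum(se & st) / sum(st),
    fpr = sum(se & !st) / max(sum(!st), 1))
}
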