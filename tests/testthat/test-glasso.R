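random_corr <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(a) / p + diag(p))
}

test_that("solver saturates above lambda_max and recovers the 2-node identity", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- glasso_fit(S, lambda = 0.6)
  expect_equal(fit$partials[1, 2], 0)
  # for two variables the partial correlation equals the marginal one
  fit0 <- glasso_fit(S, lambda = 1e-7, tol = 1e-7)
  expect_equal(fit0$partials[1, 2], 0.5, tolerance = 1e-4)
})

test_that("coordinate-descent solution matches the independent ADMM solver", {
  for (p in c(3, 4, 5)) {
    S <- random_corr(p, seed = 100 + p)
    for (lam in c(0.05, 0.2)) {
      fit <- glasso_fit(S, lam, tol = 1e-7, max_iter = 500)
      oracle <- oracle_glasso_admm(S, lam)
      expect_lt(max(abs(fit$theta - oracle)), 1e-5)
    }
  }
})

test_that("solver is self-consistent across tolerances and rejects bad input", {
  S <- random_corr(6, seed = 9)
  w1 <- glasso_fit(S, 0.1, tol = 1e-4)$partials
  w2 <- glasso_fit(S, 0.1, tol = 1e-6)$partials
  expect_lt(max(abs(w1 - w2)), 1e-3)
  expect_error(glasso_fit(S, -0.1), class = "symptomnet_domain_error")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(glasso_fit(bad, 0.1), class = "symptomnet_domain_error")
})

test_that("precision-to-partials follows the textbook formulas", {
  expect_equal(partials_from_precision(diag(c(2, 3, 4))),
               matrix(0, 3, 3))
  theta <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(partials_from_precision(theta)[1, 2], 0.5)
  # 3x3: inverse of a known correlation matrix equals the recursive
  # first-order partial-correlation formula
  R <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3)
  w <- partials_from_precision(solve(R))
  r_recursive <- function(rij, rik, rjk) {
    (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  }
  expect_equal(w[1, 2], r_recursive(0.5, 0.3, 0.4))
  expect_equal(w[1, 3], r_recursive(0.3, 0.5, 0.4))
  expect_equal(w[2, 3], r_recursive(0.4, 0.5, 0.3))
  expect_error(partials_from_precision(matrix(c(1, 2, 2, 1), 2)),
               class = "symptomnet_domain_error")
})

test_that("EBIC reduces to the likelihood term at zero edges and is linear in gamma", {
  S <- random_corr(4, seed = 2)
  theta_diag <- diag(1 / diag(S))
  ll <- (50 / 2) * (determinant(theta_diag)$modulus[1] -
                      sum(S * theta_diag))
  expect_equal(ebic(theta_diag, S, n = 50, gamma = 0.5),
               as.numeric(-2 * ll))
  # identity model on identity correlation: loglik = (n/2)(0 - p), no
  # edge penalty, and no dependence on gamma
  expect_equal(ebic(diag(2), diag(2), n = 100, gamma = 0.7), 200)
  expect_equal(ebic(diag(2), diag(2), n = 100, gamma = 0),
               ebic(diag(2), diag(2), n = 100, gamma = 2))
  th <- solve(S)
  e <- sum(abs(th[upper.tri(th)]) > 1e-8)
  expect_equal(ebic(th, S, 50, gamma = 1) - ebic(th, S, 50, gamma = 0),
               4 * e * log(4))
})

test_that("EBIC selection is deterministic, empty on identity, and sparser under larger gamma", {
  S <- diag(5)
  dimnames(S) <- list(letters[1:5], letters[1:5])
  net <- ebicglasso_select(S, n = 200)
  expect_equal(network_density(net)$n_edges, 0)
  S2 <- random_corr(8, seed = 31)
  n1 <- ebicglasso_select(S2, 500)
  n2 <- ebicglasso_select(S2, 500)
  expect_identical(n1$weights, n2$weights)
  counts <- vapply(c(0, 0.25, 0.5, 1),
                   function(g) network_density(
                     ebicglasso_select(S2, 500, gamma = g))$n_edges,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every fit on the path is a valid partial-correlation model", {
  truth <- make_cluster_precision(p = 8, clusters = c(4, 4), seed = 5)
  tab <- sample_likert(truth, 400, seed = 6)
  S <- nearest_psd(spearman_matrix(tab))
  lambda_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * 0.05),
                     length.out = 12))
  edges <- integer(12)
  for (k in seq_along(lambdas)) {
    fit <- glasso_fit(S, lambdas[k])
    expect_lt(max(abs(fit$partials - t(fit$partials))), 1e-10)
    expect_lte(max(abs(fit$partials)), 1)
    expect_gt(min(eigen(fit$theta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    edges[k] <- sum(abs(fit$partials[upper.tri(fit$partials)]) > 1e-8)
  }
  # edge count non-increasing as lambda increases (path stored decreasing)
  expect_true(all(diff(rev(edges)) <= 0))
})

test_that("density counts nonzero edges over possible pairs", {
  w <- matrix(0, 18, 18)
  set.seed(8)
  idx <- sample(which(upper.tri(w)), 85)
  w[idx] <- 0.2
  w <- w + t(w)
  d <- network_density(new_symptom_network(w))
  expect_equal(d$n_possible, 153)
  expect_equal(d$n_edges, 85)
  expect_equal(round(100 * d$density, 2), 55.56)
  w21 <- matrix(0, 21, 21)
  idx21 <- sample(which(upper.tri(w21)), 114)
  w21[idx21] <- -0.1
  w21 <- w21 + t(w21)
  d21 <- network_density(new_symptom_network(w21))
  expect_equal(d21$n_possible, 210)
  expect_equal(round(100 * d21$density, 2), 54.29)
  empty <- new_symptom_network(matrix(0, 4, 4))
  expect_equal(network_density(empty)$density, 0)
  expect_error(network_density(new_symptom_network(matrix(0, 1, 1))),
               class = "symptomnet_domain_error")
})

test_that("covariate adjustment adds nodes and absorbs a planted confounder", {
  # items 1 and 4 are in different clusters with no direct edge; a binary
  # covariate shifts both, inducing a spurious marginal link
  truth <- make_cluster_precision(p = 6, clusters = c(3, 3),
                                  density_between = 0, seed = 77)
  set.seed(78)
  design <- tibble::tibble(confounder = rbinom(1500, 1, 0.5))
  eff <- rep(0, 6); eff[c(1, 4)] <- 1
  tab <- sample_likert(truth, 1500, covariate_design = design,
                       covariate_effects = list(confounder = eff),
                       seed = 79)
  nets <- estimate_networks(tab, covariates = "confounder")
  expect_equal(length(nets$adjusted$nodes), 7)
  expect_equal(network_density(nets$adjusted)$n_possible, 21)
  i1 <- truth$items[1]; i4 <- truth$items[4]
  expect_lte(nets$adjusted$weights[i1, i4],
             nets$unadjusted$weights[i1, i4] + 1e-8)
  # zero covariates: the two networks coincide
  nets0 <- estimate_networks(tab, covariates = character())
  expect_identical(nets0$unadjusted$weights, nets0$adjusted$weights)
})
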