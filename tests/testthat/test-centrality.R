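star_network <- function(w = 0.5, leaves = 4) {
  m <- matrix(0, leaves + 1, leaves + 1)
  m[1, 2:(leaves + 1)] <- w
  m <- m + t(m)
  dimnames(m) <- list(c("hub", paste0("leaf", 1:leaves)),
                      c("hub", paste0("leaf", 1:leaves)))
  new_symptom_network(m)
}

random_network <- function(p, seed, signed = TRUE) {
  set.seed(seed)
  m <- matrix(0, p, p)
  idx <- which(upper.tri(m))
  picks <- sample(idx, round(0.4 * length(idx)))
  m[picks] <- runif(length(picks), 0.05, 0.6) *
    (if (signed) sample(c(-1, 1), length(picks), replace = TRUE) else 1)
  m <- m + t(m)
  dimnames(m) <- list(paste0("n", 1:p), paste0("n", 1:p))
  new_symptom_network(m)
}

test_that("strength sums absolute incident weights", {
  net <- star_network()
  s <- node_strength(net)
  expect_equal(s[["hub"]], 2)
  expect_equal(unname(s[paste0("leaf", 1:4)]), rep(0.5, 4))
  neg <- new_symptom_network(matrix(c(0, -0.3, -0.3, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  expect_equal(node_strength(neg)[["a"]], 0.3)
  net18 <- random_network(18, seed = 1)
  expect_equal(node_strength(net18), rowSums(abs(net18$weights)))
})

test_that("expected influence is the signed sum and equals strength on positive networks", {
  pos <- random_network(10, seed = 2, signed = FALSE)
  expect_equal(expected_influence(pos), node_strength(pos))
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.4; m[1, 3] <- -0.4
  m <- m + t(m)
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- new_symptom_network(m)
  expect_equal(expected_influence(net)[["a"]], 0)
  expect_equal(node_strength(net)[["a"]], 0.8)
  sg <- random_network(12, seed = 3)
  expect_equal(expected_influence(sg), rowSums(sg$weights))
})

test_that("shortest-path metrics match hand computation on a 3-node path", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 3] <- 0.5
  m <- m + t(m)
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  net <- new_symptom_network(m)
  sp <- shortest_path_metrics(net)
  # d(A,B) = 2, d(A,C) = 4 -> closeness(A) = 2/6
  expect_equal(sp$closeness[sp$node == "A"], 2 / 6)
  expect_equal(sp$betweenness[sp$node == "B"], 1)
  expect_equal(sp$betweenness[sp$node %in% c("A", "C")], c(0, 0))
  # equal-weight triangle: full symmetry
  tri <- matrix(0.4, 3, 3); diag(tri) <- 0
  dimnames(tri) <- list(c("a", "b", "c"), c("a", "b", "c"))
  sp_tri <- shortest_path_metrics(new_symptom_network(tri))
  expect_equal(sp_tri$betweenness, rep(0, 3))
  expect_equal(length(unique(round(sp_tri$closeness, 12))), 1)
})

test_that("path metrics agree with the Floyd-Warshall oracle on random graphs", {
  for (seed in 4:6) {
    net <- random_network(10, seed = seed)
    sp <- shortest_path_metrics(net)
    oracle <- oracle_path_metrics(net$weights)
    expect_equal(sp$closeness, oracle$closeness, tolerance = 1e-9)
    expect_equal(sp$betweenness, oracle$betweenness, tolerance = 1e-6)
  }
})

test_that("standardization yields mean-0 sd-1 z-scores and flags degeneracy", {
  two <- tibble::tibble(node = c("a", "b"), strength = c(1, 3),
                        expected_influence = c(1, 3),
                        closeness = c(0.2, 0.2), betweenness = c(0, 0))
  z <- standardize_centrality(two)
  expect_equal(z$z_strength, c(-1, 1) / sqrt(2))
  expect_equal(z$z_closeness, c(0, 0))
  expect_setequal(attr(z, "degenerate"), c("closeness", "betweenness"))
  ct <- centrality_table(random_network(12, seed = 7))
  for (col in c("z_strength", "z_expected_influence", "z_closeness")) {
    expect_equal(mean(ct[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(ct[[col]]), 1, tolerance = 1e-12)
  }
})

test_that("core-symptom ranking orders by strength with lexicographic tie-break", {
  tbl <- tibble::tibble(node = c("weight_loss", "diarrhea", "fatigue"),
                        strength = c(4.414, 4.489, 1.0))
  r <- rank_core_symptoms(tbl)
  expect_equal(r$node, c("diarrhea", "weight_loss", "fatigue"))
  expect_false(attr(r, "ties"))
  tied <- tibble::tibble(node = c("b", "a", "c"), strength = c(1, 1, 1))
  rt <- rank_core_symptoms(tied)
  expect_equal(rt$node, c("a", "b", "c"))
  expect_true(attr(rt, "ties"))
  single <- rank_core_symptoms(tibble::tibble(node = "x", strength = 2))
  expect_equal(single$node, "x")
})

test_that("centrality indices are permutation-equivariant and edge-removal monotone", {
  net <- random_network(9, seed = 8)
  perm <- sample(9)
  w2 <- net$weights[perm, perm]
  net2 <- new_symptom_network(w2)
  expect_equal(node_strength(net2), node_strength(net)[perm])
  expect_equal(expected_influence(net2), expected_influence(net)[perm])
  # remove one edge: no strength increases, no distance decreases
  ed <- which(abs(net$weights) > 0 & upper.tri(net$weights),
              arr.ind = TRUE)[1, ]
  w3 <- net$weights
  w3[ed[1], ed[2]] <- w3[ed[2], ed[1]] <- 0
  net3 <- new_symptom_network(w3)
  expect_true(all(node_strength(net3) <= node_strength(net) + 1e-12))
  d_before <- oracle_path_metrics(net$weights)$distances
  d_after <- oracle_path_metrics(net3$weights)$distances
  expect_true(all(d_after >= d_before - 1e-9))
})

test_that("layout is deterministic under seed and groups heavy-edge pairs", {
  m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 0.5
  dimnames(m) <- list(c("a", "b"), c("a", "b"))
  two <- fruchterman_reingold(new_symptom_network(m), seed = 1)
  expect_gt(sqrt(diff(two$x)^2 + diff(two$y)^2), 0.1)
  net <- random_network(12, seed = 9)
  l1 <- fruchterman_reingold(net, seed = 3)
  l2 <- fruchterman_reingold(net, seed = 3)
  expect_identical(l1, l2)
  # planted 2-cluster network: within-cluster pairs closer on average
  truth <- make_cluster_precision(p = 8, clusters = c(4, 4),
                                  density_between = 0, seed = 10)
  cl_net <- new_symptom_network(truth$true_partials)
  member <- rep(1:2, each = 4)
  ratio <- vapply(1:10, function(s) {
    xy <- fruchterman_reingold(cl_net, seed = s)
    d <- as.matrix(dist(cbind(xy$x, xy$y)))
    same <- outer(member, member, "==") & upper.tri(d)
    diff_cl <- outer(member, member, "!=") & upper.tri(d)
    mean(d[same]) / mean(d[diff_cl])
  }, numeric(1))
  expect_lt(mean(ratio), 1)
})
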