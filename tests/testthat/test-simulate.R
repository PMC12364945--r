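test_that("cluster precision has the requested support and is positive definite", {
  # zero between-cluster density: exactly block-diagonal
  truth <- make_cluster_precision(p = 6, clusters = c(3, 3),
                                  density_between = 0, seed = 1)
  off <- truth$precision
  diag(off) <- 0
  expect_true(all(off[1:3, 4:6] == 0))
  expect_true(all(off[1:3, 1:3][upper.tri(diag(3))] != 0))
  # the 18-item 5-cluster layout: support matches the partition
  sizes <- c(2, 6, 3, 3, 4)
  t18 <- make_cluster_precision(p = 18, clusters = sizes,
                                density_between = 0, seed = 2)
  membership <- rep(seq_along(sizes), sizes)
  same <- outer(membership, membership, "==")
  offd <- abs(t18$true_partials) > 1e-12
  diag(same) <- NA
  expect_true(all(offd[same %in% TRUE]))
  expect_false(any(offd[same %in% FALSE]))
  # PD by eigendecomposition, partials zero exactly where precision is zero
  for (s in 1:3) {
    tt <- make_cluster_precision(p = 10, clusters = c(5, 5),
                                 density_between = 0.2, seed = s)
    expect_gt(min(eigen(tt$precision, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_identical(tt$true_partials == 0,
                     !(abs(tt$precision) > 0 & row(tt$precision) !=
                         col(tt$precision)))
  }
  expect_error(make_cluster_precision(p = 5, clusters = c(3, 3)),
               class = "symptomnet_domain_error")
})

test_that("likert thresholds are increasing and reproduce target marginals", {
  thr <- likert_thresholds(c(0.7, 0.26))
  expect_true(all(apply(thr, 1, diff) > 0))
  truth <- make_cluster_precision(p = 2, clusters = c(2), seed = 3)
  truth$thresholds <- thr
  tab <- sample_likert(truth, 20000, seed = 4)
  # closed-form category probabilities from the normal CDF
  probs1 <- diff(c(0, pnorm(thr[1, ]), 1))
  expect_equal(mean(tab[[truth$items[1]]] == 1), 0.7, tolerance = 0.02)
  expect_equal(mean(tab[[truth$items[1]]]), sum(probs1 * 1:5),
               tolerance = 0.03)
  probs2 <- diff(c(0, pnorm(thr[2, ]), 1))
  expect_equal(mean(tab[[truth$items[2]]]), sum(probs2 * 1:5),
               tolerance = 0.03)
})

test_that("sampling is reproducible, rejects n=0, and accepts n=1", {
  truth <- make_cluster_precision(p = 4, clusters = c(2, 2), seed = 5)
  expect_error(sample_likert(truth, 0), class = "symptomnet_domain_error")
  one <- sample_likert(truth, 1, seed = 6)
  expect_equal(nrow(one), 1)
  a <- sample_likert(truth, 50, seed = 7)
  b <- sample_likert(truth, 50, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("covariate effects shift the observed ratings of targeted items", {
  truth <- make_cluster_precision(p = 4, clusters = c(2, 2), seed = 8)
  design <- tibble::tibble(stage = rep(c(0L, 1L), each = 2500))
  eff <- c(1, 0, 0, 0)
  tab <- sample_likert(truth, 5000, covariate_design = design,
                       covariate_effects = list(stage = eff), seed = 9)
  m_active <- mean(tab[[truth$items[1]]][tab$stage == 1])
  m_rest <- mean(tab[[truth$items[1]]][tab$stage == 0])
  expect_gt(m_active, m_rest + 0.3)
  # untargeted item barely moves
  d2 <- abs(mean(tab[[truth$items[3]]][tab$stage == 1]) -
              mean(tab[[truth$items[3]]][tab$stage == 0]))
  expect_lt(d2, 0.1)
})

test_that("covariate design hits its prevalence and moment targets", {
  d <- make_covariate_design(10000, seed = 10)
  se <- sqrt(0.58 * 0.42 / 10000)
  expect_lt(abs(mean(d$active_stage) - 0.58), 2 * se)
  expect_equal(mean(d$years_since_diagnosis), 5.36, tolerance = 0.25)
  expect_equal(sd(d$years_since_diagnosis), 5.77, tolerance = 0.6)
  expect_true(all(d$years_since_diagnosis >= 0))
  expect_setequal(names(d), c("active_stage", "years_since_diagnosis",
                              "treatment_surgery", "treatment_both",
                              "treatment_otherwise"))
  expect_error(make_covariate_design(10, treatment_probs = c(a = 0.5,
                                                             b = 0.2)),
               class = "symptomnet_domain_error")
  expect_warning(make_covariate_design(50, treatment_probs = c(a = 1, b = 0,
                                                               c = 0, d = 0),
                                       seed = 1),
                 "constant")
})

test_that("discretization preserves monotone association (copula oracle)", {
  skip_if_not_installed("pracma")
  thr_x <- likert_thresholds(0.6)[1, ]
  thr_y <- likert_thresholds(0.4)[1, ]
  for (rho in c(0.5, -0.3)) {
    prec <- solve(matrix(c(1, rho, rho, 1), 2))
    truth <- structure(list(precision = prec,
                            true_partials = partials_from_precision(prec),
                            items = c("x", "y"), diagonal = 1,
                            thresholds = rbind(thr_x, thr_y),
                            covariate_effects = NULL, seed = 1),
                       class = "synthetic_truth")
    tab <- sample_likert(truth, 40000, seed = 12)
    r_hat <- spearman_matrix(tab)["x", "y"]
    r_pop <- oracle_discretized_spearman(rho, thr_x, thr_y)
    expect_equal(sign(r_hat), sign(rho))
    expect_equal(r_hat, r_pop, tolerance = 0.02)
  }
})

test_that("the full study simulation is reproducible with the documented layout", {
  sim <- simulate_symptom_study(n = 60, seed = 42)
  expect_equal(length(symptom_items(sim$table)), 18)
  expect_equal(nrow(sim$table), 60)
  expect_setequal(symptom_covariates(sim$table),
                  c("active_stage", "years_since_diagnosis",
                    "treatment_surgery", "treatment_both",
                    "treatment_otherwise"))
  sim2 <- simulate_symptom_study(n = 60, seed = 42)
  expect_identical(as.data.frame(sim$table), as.data.frame(sim2$table))
  expect_identical(sim$truth$precision, sim2$truth$precision)
})
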