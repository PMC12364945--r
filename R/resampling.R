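#' Bootstrap and stability configuration
#'
#' Bundles every resampling knob: `n_boot` replicates for edge accuracy
#' and difference tests, the CI level, the case-dropping grid and number
#' of subsamples per drop proportion for the CS coefficient, and the CS
#' decision rule (a subsample "agrees" with the full sample when the
#' Pearson correlation of the centrality index across nodes is at least
#' `cor_threshold`; the CS coefficient is the largest drop proportion at
#' which at least `prob_threshold` of subsamples agree).
#'
#' @param n_boot Number of with-replacement bootstrap replicates.
#' @param ci_level Confidence level for edge intervals.
#' @param drop_grid Case-drop proportions (strictly inside (0, 1)).
#' @param n_per_drop Subsamples per drop proportion.
#' @param cor_threshold,prob_threshold CS decision rule, both in (0, 1).
#' @param seed Root seed; per-replicate seeds are derived by counter so
#'   results are identical regardless of execution order.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000, ci_level = 0.95,
                             drop_grid = seq(0.05, 0.75, by = 0.05),
                             n_per_drop = 250, cor_threshold = 0.7,
                             prob_threshold = 0.95, seed = 1) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1,
            all(drop_grid > 0), all(drop_grid < 1),
            cor_threshold > 0, cor_threshold < 1,
            prob_threshold > 0, prob_threshold < 1)
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 drop_grid = drop_grid, n_per_drop = as.integer(n_per_drop),
                 cor_threshold = cor_threshold,
                 prob_threshold = prob_threshold, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Network estimation configuration
#'
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas,lambda_min_ratio Penalty path layout.
#' @param edge_threshold Nonzero-edge threshold defining edge presence.
#' @param include_covariates Whether covariate columns enter as nodes.
#' @return A list of class `network_config`.
#' @export
network_config <- function(gamma = 0.5, n_lambdas = 100,
                           lambda_min_ratio = 0.01, edge_threshold = 1e-8,
                           include_covariates = FALSE) {
  structure(list(gamma = gamma, n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 edge_threshold = edge_threshold,
                 include_covariates = include_covariates),
            class = "network_config")
}

# Estimate a network straight from a ratings matrix (bootstrap hot path).
# Constant columns or other estimation failures raise a classed condition
# so replicate loops can record and skip them.
estimate_from_matrix <- function(x, cfg) {
  if (nrow(x) < 3) {
    abort("too few rows", class = "symptomnet_estimation_failure")
  }
  r <- suppressWarnings(cor(x, method = "spearman"))
  if (anyNA(r)) {
    abort("undefined correlations (constant column in resample)",
          class = "symptomnet_estimation_failure")
  }
  diag(r) <- 1
  r <- nearest_psd(r)
  ebicglasso_select(r, nrow(x), gamma = cfg$gamma,
                    n_lambdas = cfg$n_lambdas,
                    lambda_min_ratio = cfg$lambda_min_ratio,
                    edge_threshold = cfg$edge_threshold)
}

# Run B with-replacement bootstrap replicates; returns an m x m x B array
# of edge weights (NA slices for failed replicates) plus the failure count.
boot_weight_array <- function(table, net_cfg, boot_cfg) {
  x <- ratings_matrix(table, include_covariates = net_cfg$include_covariates)
  n <- nrow(x)
  m <- ncol(x)
  B <- boot_cfg$n_boot
  arr <- array(NA_real_, dim = c(m, m, B),
               dimnames = list(colnames(x), colnames(x), NULL))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- local_seed(sub_seed(boot_cfg$seed, b),
                      sample.int(n, n, replace = TRUE))
    net <- tryCatch(estimate_from_matrix(x[idx, , drop = FALSE], net_cfg),
                    symptomnet_estimation_failure = function(e) NULL,
                    symptomnet_convergence_error = function(e) NULL)
    if (is.null(net)) {
      failures <- failures + 1L
    } else {
      arr[, , b] <- net$weights
    }
  }
  if (failures > 0.05 * B) {
    abort(paste0(failures, "/", B, " bootstrap replicates failed estimation"),
          class = "symptomnet_bootstrap_error")
  }
  attr(arr, "failures") <- failures
  arr
}

#' Bootstrap edge-weight accuracy
#'
#' Nonparametric bootstrap: resample persons with replacement, re-run the
#' whole estimation (Spearman, PSD repair, EBIC-selected graphical
#' lasso), and summarize each edge's replicate distribution by quantile
#' confidence intervals around the full-sample point estimate.
#'
#' @param table A [symptom_table()] (needs at least p+1 rows).
#' @param net_cfg A [network_config()].
#' @param boot_cfg A [bootstrap_config()].
#' @return A tibble of class `edge_ci`: `from`, `to`, `estimate`,
#'   `lower`, `upper`, `boot_mean`, one row per unordered node pair;
#'   attributes `failures` and `n_boot`. With `n_boot = 1` the interval
#'   degenerates to the single replicate and is flagged.
#' @export
bootstrap_edges <- function(table, net_cfg = network_config(),
                            boot_cfg = bootstrap_config()) {
  check_estimable(table, net_cfg)
  x <- ratings_matrix(table, include_covariates = net_cfg$include_covariates)
  point <- estimate_from_matrix(x, net_cfg)
  arr <- boot_weight_array(table, net_cfg, boot_cfg)
  a <- (1 - boot_cfg$ci_level) / 2
  idx <- which(upper.tri(point$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nodes <- point$nodes
  qs <- apply(arr, c(1, 2), quantile, probs = c(a, 1 - a), na.rm = TRUE)
  means <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  out <- tibble::tibble(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    estimate = point$weights[idx],
    lower = qs[1, , ][idx], upper = qs[2, , ][idx],
    boot_mean = means[idx]
  )
  attr(out, "failures") <- attr(arr, "failures")
  attr(out, "n_boot") <- boot_cfg$n_boot
  attr(out, "degenerate") <- boot_cfg$n_boot == 1
  class(out) <- unique(c("edge_ci", class(out)))
  out
}

check_estimable <- function(table, net_cfg) {
  p <- length(symptom_items(table)) +
    if (net_cfg$include_covariates) length(symptom_covariates(table)) else 0
  if (nrow(table) < p + 1) {
    abort(paste0("need at least ", p + 1, " rows, got ", nrow(table)),
          class = "symptomnet_domain_error")
  }
  invisible(TRUE)
}

#' Case-dropping correlation-stability (CS) coefficient
#'
#' For each drop proportion q in the grid, draws subsamples without
#' replacement of size `round((1-q) n)`, re-estimates the network, and
#' correlates each centrality index across nodes with the full-sample
#' values. The CS coefficient of an index is the largest q such that at
#' every q' up to q, at least `prob_threshold` of subsamples correlate
#' at `cor_threshold` or better. CS below 0.25 is unstable, 0.25-0.5
#' minimal stability, 0.5 and above strong stability.
#'
#' @inheritParams bootstrap_edges
#' @param indices Centrality indices to evaluate.
#' @return A tibble of class `cs_table`: `index`, `cs`,
#'   `classification`; attribute `detail` holds the per-proportion
#'   agreement rates, attribute `degenerate` any index with zero spread
#'   in the full sample (CS undefined, `NA`).
#' @export
cs_coefficient <- function(table, net_cfg = network_config(),
                           boot_cfg = bootstrap_config(),
                           indices = c("strength", "expected_influence",
                                       "closeness", "betweenness")) {
  check_estimable(table, net_cfg)
  x <- ratings_matrix(table, include_covariates = net_cfg$include_covariates)
  n <- nrow(x)
  p <- ncol(x)
  full <- centrality_table(estimate_from_matrix(x, net_cfg))
  degenerate <- indices[vapply(indices, function(i) sd(full[[i]]) == 0,
                               logical(1))]
  if (length(degenerate) == length(indices)) {
    # nothing to correlate against (e.g. an empty estimated network):
    # no stability can be attributed to any index
    out <- tibble::tibble(index = indices, cs = NA_real_,
                          classification = "undefined")
    attr(out, "detail") <- tibble::tibble(drop = numeric(0))
    attr(out, "degenerate") <- degenerate
    class(out) <- unique(c("cs_table", class(out)))
    return(out)
  }
  grid <- boot_cfg$drop_grid[round((1 - boot_cfg$drop_grid) * n) >= p + 1]
  grid <- sort(grid)
  if (length(grid) == 0) {
    abort("no feasible drop proportion (sample too small)",
          class = "symptomnet_domain_error")
  }
  agree <- matrix(NA_real_, length(grid), length(indices),
                  dimnames = list(NULL, indices))
  counter <- 0L
  for (gi in seq_along(grid)) {
    q <- grid[gi]
    nsub <- round((1 - q) * n)
    ok <- matrix(FALSE, boot_cfg$n_per_drop, length(indices))
    for (s in seq_len(boot_cfg$n_per_drop)) {
      counter <- counter + 1L
      idx <- local_seed(sub_seed(boot_cfg$seed + 7L, counter),
                        sample.int(n, nsub, replace = FALSE))
      net <- tryCatch(estimate_from_matrix(x[idx, , drop = FALSE], net_cfg),
                      symptomnet_estimation_failure = function(e) NULL,
                      symptomnet_convergence_error = function(e) NULL)
      if (is.null(net)) next
      ct <- centrality_table(net)
      for (ii in seq_along(indices)) {
        v <- ct[[indices[ii]]]
        if (sd(v) == 0 || sd(full[[indices[ii]]]) == 0) next
        r <- cor(v, full[[indices[ii]]])
        ok[s, ii] <- !is.na(r) && r >= boot_cfg$cor_threshold
      }
    }
    agree[gi, ] <- colMeans(ok)
  }
  cs <- vapply(seq_along(indices), function(ii) {
    if (indices[ii] %in% degenerate) return(NA_real_)
    pass <- agree[, ii] >= boot_cfg$prob_threshold
    run <- cumprod(pass) # all q' <= q must pass
    if (!any(run == 1)) return(0)
    grid[max(which(run == 1))]
  }, numeric(1))
  out <- tibble::tibble(
    index = indices, cs = cs,
    classification = dplyr::case_when(
      is.na(cs) ~ "undefined",
      cs >= 0.5 ~ "strong stability",
      cs >= 0.25 ~ "minimal stability",
      TRUE ~ "unstable"
    )
  )
  attr(out, "detail") <- tibble::as_tibble(cbind(drop = grid, agree))
  attr(out, "degenerate") <- degenerate
  class(out) <- unique(c("cs_table", class(out)))
  out
}

#' Bootstrapped difference tests for edges and node strengths
#'
#' For every pair of edges present in the full-sample network (or every
#' pair of nodes), the bootstrap distribution of the difference is
#' summarized by a quantile interval; the pair differs significantly
#' when the interval excludes zero. No multiplicity correction is
#' applied (the convention for these descriptive bootstrap tests).
#'
#' @inheritParams bootstrap_edges
#' @param weight_array Optional precomputed replicate array from an
#'   earlier bootstrap run with the same configs (avoids refitting).
#' @return A tibble with one row per pair: the two members, `lower`,
#'   `upper` of the difference interval, and `significant`.
#' @export
difference_test_edges <- function(table, net_cfg = network_config(),
                                  boot_cfg = bootstrap_config(),
                                  weight_array = NULL) {
  check_estimable(table, net_cfg)
  x <- ratings_matrix(table, include_covariates = net_cfg$include_covariates)
  point <- estimate_from_matrix(x, net_cfg)
  if (is.null(weight_array)) {
    weight_array <- boot_weight_array(table, net_cfg, boot_cfg)
  }
  ed <- tidy(point)
  if (nrow(ed) < 2) {
    return(tibble::tibble(edge1 = character(), edge2 = character(),
                          lower = numeric(), upper = numeric(),
                          significant = logical()))
  }
  nodes <- point$nodes
  # replicate matrix: one column per present edge
  reps <- vapply(seq_len(nrow(ed)), function(k) {
    weight_array[match(ed$from[k], nodes), match(ed$to[k], nodes), ]
  }, numeric(dim(weight_array)[3]))
  labels <- paste0(ed$from, "--", ed$to)
  pairs <- utils::combn(nrow(ed), 2)
  a <- (1 - boot_cfg$ci_level) / 2
  lower <- upper <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    d <- reps[, pairs[1, k]] - reps[, pairs[2, k]]
    q <- quantile(d, probs = c(a, 1 - a), na.rm = TRUE)
    lower[k] <- q[1]; upper[k] <- q[2]
  }
  tibble::tibble(edge1 = labels[pairs[1, ]], edge2 = labels[pairs[2, ]],
                 lower = lower, upper = upper,
                 significant = lower > 0 | upper < 0)
}

#' @rdname difference_test_edges
#' @export
difference_test_nodes <- function(table, net_cfg = network_config(),
                                  boot_cfg = bootstrap_config(),
                                  weight_array = NULL) {
  check_estimable(table, net_cfg)
  if (is.null(weight_array)) {
    weight_array <- boot_weight_array(table, net_cfg, boot_cfg)
  }
  nodes <- dimnames(weight_array)[[1]]
  B <- dim(weight_array)[3]
  # per-replicate node strengths
  strengths <- vapply(seq_len(B), function(b) {
    w <- weight_array[, , b]
    if (anyNA(w)) return(rep(NA_real_, length(nodes)))
    rowSums(abs(w))
  }, numeric(length(nodes)))
  pairs <- utils::combn(length(nodes), 2)
  a <- (1 - boot_cfg$ci_level) / 2
  lower <- upper <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    d <- strengths[pairs[1, k], ] - strengths[pairs[2, k], ]
    q <- quantile(d, probs = c(a, 1 - a), na.rm = TRUE)
    lower[k] <- q[1]; upper[k] <- q[2]
  }
  tibble::tibble(node1 = nodes[pairs[1, ]], node2 = nodes[pairs[2, ]],
                 lower = lower, upper = upper,
                 significant = lower > 0 | upper < 0)
}
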