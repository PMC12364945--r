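#' Per-item descriptive statistics
#'
#' Symptom "presence" is a rating of 2 or more (1 = not at all), so
#' prevalence is the share of persons rating an item above 1. Continuous
#' summaries use mean (SD) and median (IQR: P25-P75) with the
#' linear-interpolation (type 7) quantile convention.
#'
#' @param table A [symptom_table()].
#' @return A tibble: `item`, `n_present`, `prevalence_pct`, `mean`,
#'   `sd`, `median`, `p25`, `p75`.
#' @export
descriptives <- function(table) {
  x <- ratings_matrix(table)
  purrr::map_dfr(colnames(x), function(nm) {
    v <- x[, nm]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
    tibble::tibble(item = nm,
                   n_present = sum(v >= 2),
                   prevalence_pct = 100 * mean(v >= 2),
                   mean = mean(v), sd = sd(v),
                   median = q[[2]], p25 = q[[1]], p75 = q[[3]])
  })
}

#' Run the full symptom-network analysis pipeline
#'
#' Sequences every stage on one table: descriptives, the
#' covariate-screening severity regression, unadjusted and
#' covariate-adjusted network estimation, centrality and core-symptom
#' ranking, layout coordinates, bootstrap accuracy / CS stability /
#' difference tests, and node predictability. The whole run is
#' deterministic given the seed and configuration.
#'
#' @param table A [symptom_table()].
#' @param gamma EBIC hyperparameter for network estimation.
#' @param alpha_screen Significance level of the covariate screen.
#' @param seed Root seed; stage seeds are derived from it.
#' @param boot_cfg A [bootstrap_config()]; its `seed` field is
#'   overridden by a seed derived from `seed` so one number controls
#'   the run.
#' @param resample If `FALSE`, the bootstrap/stability stage is skipped
#'   (fast runs, e.g. determinism checks).
#' @param cs_indices Centrality indices for the CS coefficient.
#' @param cross_validated_r2 Use cross-validated node predictability.
#' @return A list of class `symptom_run` with one element per stage.
#' @export
run_pipeline <- function(table, gamma = 0.5, alpha_screen = 0.001,
                         seed = 1, boot_cfg = bootstrap_config(),
                         resample = TRUE,
                         cs_indices = c("strength", "expected_influence",
                                        "closeness"),
                         cross_validated_r2 = FALSE) {
  stopifnot(inherits(table, "symptom_table"))
  covs <- symptom_covariates(table)
  desc <- descriptives(table)

  regression <- NULL
  selected <- character()
  if (length(covs) > 0) {
    regression <- fit_severity_model(table)
    selected <- screen_covariates(regression, alpha_screen)
  }

  nets <- estimate_networks(table, covariates = selected, gamma = gamma)
  cent_un <- centrality_table(nets$unadjusted)
  core <- rank_core_symptoms(cent_un)
  cent_adj <- NULL
  core_adj <- NULL
  if (length(selected) > 0) {
    cent_adj <- centrality_table(nets$adjusted)
    core_adj <- rank_core_symptoms(cent_adj,
                                   symptom_nodes = symptom_items(table))
  }
  layout <- fruchterman_reingold(nets$unadjusted, seed = sub_seed(seed, 11))

  resampling <- NULL
  if (resample) {
    net_cfg <- network_config(gamma = gamma)
    boot_cfg$seed <- sub_seed(seed, 13)
    arr <- boot_weight_array(table, net_cfg, boot_cfg)
    edge_ci <- bootstrap_edges_from_array(table, net_cfg, boot_cfg, arr)
    edge_diff <- difference_test_edges(table, net_cfg, boot_cfg,
                                       weight_array = arr)
    node_diff <- difference_test_nodes(table, net_cfg, boot_cfg,
                                       weight_array = arr)
    cs <- cs_coefficient(table, net_cfg, boot_cfg, indices = cs_indices)
    resampling <- list(edge_ci = edge_ci, edge_diff = edge_diff,
                       node_diff = node_diff, cs = cs)
  }
  predict_tbl <- node_predictability(table, nets$unadjusted,
                                     cross_validated = cross_validated_r2,
                                     seed = sub_seed(seed, 17))

  structure(list(
    seed = seed,
    config = list(gamma = gamma, alpha_screen = alpha_screen,
                  n_boot = boot_cfg$n_boot,
                  n_per_drop = boot_cfg$n_per_drop,
                  drop_grid = boot_cfg$drop_grid,
                  cor_threshold = boot_cfg$cor_threshold,
                  prob_threshold = boot_cfg$prob_threshold,
                  cross_validated_r2 = cross_validated_r2),
    n = nrow(table),
    descriptives = desc,
    regression = regression,
    selected_covariates = as.character(selected),
    networks = nets,
    centrality = list(unadjusted = cent_un, adjusted = cent_adj),
    core_symptoms = list(unadjusted = core, adjusted = core_adj),
    layout = layout,
    resampling = resampling,
    predictability = predict_tbl
  ), class = "symptom_run")
}

# edge CI tibble from a precomputed replicate array (shared bootstrap)
bootstrap_edges_from_array <- function(table, net_cfg, boot_cfg, arr) {
  x <- ratings_matrix(table, include_covariates = net_cfg$include_covariates)
  point <- estimate_from_matrix(x, net_cfg)
  a <- (1 - boot_cfg$ci_level) / 2
  idx <- which(upper.tri(point$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  qs <- apply(arr, c(1, 2), quantile, probs = c(a, 1 - a), na.rm = TRUE)
  means <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  out <- tibble::tibble(
    from = point$nodes[idx[, 1]], to = point$nodes[idx[, 2]],
    estimate = point$weights[idx],
    lower = qs[1, , ][idx], upper = qs[2, , ][idx],
    boot_mean = means[idx]
  )
  attr(out, "failures") <- attr(arr, "failures")
  attr(out, "n_boot") <- boot_cfg$n_boot
  class(out) <- unique(c("edge_ci", class(out)))
  out
}

#' @export
print.symptom_run <- function(x, ...) {
  d <- network_density(x$networks$unadjusted)
  cat("<symptom_run> n = ", x$n, ", seed = ", x$seed, "\n", sep = "")
  cat("  unadjusted network: ", d$n_edges, "/", d$n_possible,
      " edges (", sprintf("%.2f%%", 100 * d$density), ")\n", sep = "")
  if (length(x$selected_covariates) > 0) {
    da <- network_density(x$networks$adjusted)
    cat("  adjusted network (+", paste(x$selected_covariates, collapse = ", "),
        "): ", da$n_edges, "/", da$n_possible, " edges (",
        sprintf("%.2f%%", 100 * da$density), ")\n", sep = "")
  }
  cat("  core symptoms: ",
      paste(head(x$core_symptoms$unadjusted$node, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serializes a pipeline run to a single JSON file: seed and
#' configuration header, descriptives, the regression table, both
#' networks (density plus edge lists), centrality and core-symptom
#' tables, layout coordinates, bootstrap CIs, CS coefficients,
#' difference-test summaries, and predictability. The output carries no
#' timestamps, so identical seed and config give byte-identical files.
#'
#' @param run A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "symptom_run"))
  net_block <- function(net) {
    d <- network_density(net)
    list(n_nodes = length(net$nodes), n_edges = d$n_edges,
         n_possible = d$n_possible, density = d$density,
         lambda = net$lambda, gamma = net$gamma, ebic = net$ebic,
         edges = tidy(net))
  }
  report <- list(
    schema_version = "1.0",
    seed = run$seed,
    config = run$config,
    n = run$n,
    descriptives = run$descriptives,
    regression = if (!is.null(run$regression)) {
      list(coefficients = tidy(run$regression),
           r_squared = run$regression$r_squared,
           diagnostics = run$regression$diagnostics,
           selected_covariates = run$selected_covariates)
    },
    networks = c(list(unadjusted = net_block(run$networks$unadjusted)),
                 if (length(run$selected_covariates) > 0) {
                   list(adjusted = net_block(run$networks$adjusted))
                 }),
    centrality = run$centrality[!vapply(run$centrality, is.null, logical(1))],
    core_symptoms = run$core_symptoms[!vapply(run$core_symptoms, is.null,
                                              logical(1))],
    layout = run$layout,
    resampling = if (!is.null(run$resampling)) {
      list(edge_ci = run$resampling$edge_ci,
           cs = run$resampling$cs,
           n_significant_edge_diffs = sum(run$resampling$edge_diff$significant),
           n_edge_diff_pairs = nrow(run$resampling$edge_diff),
           n_significant_node_diffs = sum(run$resampling$node_diff$significant),
           n_node_diff_pairs = nrow(run$resampling$node_diff))
    },
    predictability = run$predictability
  )
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
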