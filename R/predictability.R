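#' Node predictability (variance explained by network neighbors)
#'
#' For every node of the estimated network, regresses its ratings on the
#' ratings of its nonzero-edge neighbors (ordinary least squares on the
#' 1-5 scale, treating ordinal ratings as numeric) and reports the
#' determination coefficient R-squared, clipped to [0, 1]. Nodes are
#' categorized against the conventional predictability thresholds:
#' R-squared of 0.65 or more indicates high network-embeddedness
#' (neighboring symptoms largely determine the node), 0.30 or less
#' indicates prominent external influences, the rest is intermediate.
#' Isolated nodes (no neighbors) get R-squared 0 and a flag.
#'
#' @param table A [symptom_table()] whose columns include every network
#'   node.
#' @param network A `symptom_network` estimated from the table.
#' @param cross_validated If `TRUE`, R-squared is computed from 10-fold
#'   cross-validated predictions instead of in-sample fits.
#' @param folds Number of folds for the cross-validated variant.
#' @param seed Seed for fold assignment.
#' @return A tibble of class `predictability_table`: `node`,
#'   `n_neighbors`, `r2`, `category`, `isolated`.
#' @export
node_predictability <- function(table, network, cross_validated = FALSE,
                                folds = 10, seed = 1) {
  stopifnot(inherits(network, "symptom_network"))
  cols <- c(symptom_items(table), symptom_covariates(table))
  missing_nodes <- setdiff(network$nodes, cols)
  if (length(missing_nodes) > 0) {
    abort(paste0("network nodes not in table: ",
                 paste(missing_nodes, collapse = ", ")),
          class = "symptomnet_schema_error")
  }
  x <- as.matrix(table[, network$nodes, drop = FALSE])
  n <- nrow(x)
  w <- network$weights
  out <- purrr::map_dfr(seq_along(network$nodes), function(i) {
    nbrs <- which(abs(w[i, ]) > network$edge_threshold)
    node <- network$nodes[i]
    if (length(nbrs) == 0) {
      return(tibble::tibble(node = node, n_neighbors = 0L, r2 = 0,
                            isolated = TRUE))
    }
    if (n <= length(nbrs)) {
      abort(paste0("node '", node, "' has ", length(nbrs),
                   " neighbors but only ", n, " rows"),
            class = "symptomnet_domain_error")
    }
    y <- x[, i]
    X <- x[, nbrs, drop = FALSE]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) {
      return(tibble::tibble(node = node, n_neighbors = length(nbrs),
                            r2 = 0, isolated = FALSE))
    }
    if (!cross_validated) {
      fit <- lm.fit(cbind(1, X), y)
      rss <- sum(fit$residuals^2)
    } else {
      fold_id <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        test <- fold_id == f
        cf <- lm.fit(cbind(1, X[!test, , drop = FALSE]), y[!test])$coefficients
        cf[is.na(cf)] <- 0
        pred[test] <- cbind(1, X[test, , drop = FALSE]) %*% cf
      }
      rss <- sum((y - pred)^2)
    }
    tibble::tibble(node = node, n_neighbors = length(nbrs),
                   r2 = min(max(1 - rss / tss, 0), 1), isolated = FALSE)
  })
  out$category <- dplyr::case_when(
    out$r2 >= 0.65 ~ "network-embedded",
    out$r2 <= 0.30 ~ "external-driven",
    TRUE ~ "intermediate"
  )
  out <- out[, c("node", "n_neighbors", "r2", "category", "isolated")]
  class(out) <- unique(c("predictability_table", class(out)))
  out
}
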