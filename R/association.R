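#' Spearman correlation matrix of a symptom table
#'
#' Pairwise Spearman rank correlations (average ranks for ties, the
#' standard treatment for 5-point data where ties are guaranteed) among
#' the item columns, optionally with covariate columns appended as
#' additional nodes. Rank correlation is used because symptom severity
#' ratings are ordinal and typically strongly right-skewed.
#'
#' @param table A [symptom_table()].
#' @param include_covariates If `TRUE`, covariate columns enter as nodes.
#' @return A symmetric correlation matrix with unit diagonal and a
#'   `method` attribute `"spearman"`.
#' @export
spearman_matrix <- function(table, include_covariates = FALSE) {
  x <- ratings_matrix(table, include_covariates = include_covariates)
  if (nrow(x) < 3) abort("need at least 3 rows for rank correlation",
                         class = "symptomnet_domain_error")
  n_distinct <- apply(x, 2, function(col) length(unique(col)))
  if (any(n_distinct < 2)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(x)[n_distinct < 2], collapse = ", "),
                 " (Spearman rho undefined)"),
          class = "symptomnet_domain_error")
  }
  r <- cor(x, method = "spearman")
  diag(r) <- 1
  attr(r, "method") <- "spearman"
  r
}

#' Repair a symmetric matrix to the nearest positive semidefinite one
#'
#' Spearman matrices of discretized data can be indefinite, while the
#' graphical lasso requires a PSD input. Negative eigenvalues are
#' clipped at zero, the matrix is reconstructed, and rescaled back to
#' unit diagonal. An already-PSD input is returned unchanged.
#'
#' @param values Symmetric matrix (e.g. a correlation matrix).
#' @param tol Eigenvalues above `-tol` count as nonnegative.
#' @return A PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(values, tol = 1e-10) {
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-8) {
    abort("input must be symmetric", class = "symptomnet_domain_error")
  }
  es <- eigen((values + t(values)) / 2, symmetric = TRUE)
  if (min(es$values) >= -tol) return(values)
  ev <- pmax(es$values, 0)
  out <- es$vectors %*% (ev * t(es$vectors))
  # rescale to unit diagonal (guard against zero diagonal)
  d <- 1 / sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out * tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(values)
  attr(out, "method") <- attr(values, "method")
  out
}
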