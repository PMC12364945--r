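#' Build a validated symptom rating table
#'
#' A symptom table is the single raw input of the pipeline: one row per
#' person, one column per symptom item rated on the 1-5 Likert scale
#' (1 = not at all, 5 = very severely), plus optional person-level
#' covariate columns (binary 0/1 indicators or continuous values).
#' The analysis contract is complete-case: any missing cell is an error,
#' never imputed.
#'
#' @param data A data frame containing the item columns (and optionally
#'   covariate and id columns).
#' @param items Character vector of item column names (length >= 3 for
#'   network estimation entry points). Defaults to all columns not named
#'   as covariates or id.
#' @param covariates Character vector of covariate column names already in
#'   numeric (binary 0/1 or continuous) form. Use [read_symptom_table()] to
#'   expand categorical covariates into reference-coded indicators.
#' @param person_ids Optional vector of person identifiers (defaults to the
#'   `person_id` column if present, else row numbers).
#'
#' @return A tibble of class `symptom_table` with attributes `items` and
#'   `covariates`.
#' @export
#' @examples
#' df <- data.frame(a = c(1L, 2L, 3L), b = c(2L, 2L, 5L), c = c(1L, 1L, 4L))
#' tab <- symptom_table(df, items = c("a", "b", "c"))
#' symptom_items(tab)
symptom_table <- function(data, items = NULL, covariates = character(),
                          person_ids = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(person_ids)) {
    person_ids <- if ("person_id" %in% names(data)) data$person_id else seq_len(nrow(data))
  }
  if (is.null(items)) {
    items <- setdiff(names(data), c(covariates, "person_id"))
  }
  missing_cols <- setdiff(c(items, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")),
          class = "symptomnet_schema_error")
  }
  if (anyDuplicated(items)) abort("item names must be unique",
                                  class = "symptomnet_validation_error")
  clash <- intersect(items, covariates)
  if (length(clash) > 0) {
    abort(paste0("covariate names clash with item names: ",
                 paste(clash, collapse = ", ")),
          class = "symptomnet_validation_error")
  }
  out <- tibble::as_tibble(data[, c(items, covariates), drop = FALSE])
  out <- tibble::add_column(out, person_id = person_ids, .before = 1)
  out <- structure(out,
                   items = items, covariates = covariates,
                   class = c("symptom_table", class(out)))
  validate_symptom_table(out)
  out
}

#' @rdname symptom_table
#' @param x A `symptom_table`.
#' @export
symptom_items <- function(x) attr(x, "items")

#' @rdname symptom_table
#' @export
symptom_covariates <- function(x) attr(x, "covariates")

validate_symptom_table <- function(x) {
  items <- attr(x, "items")
  covs <- attr(x, "covariates")
  for (nm in c(items, covs)) {
    col <- x[[nm]]
    if (!is.numeric(col)) {
      abort(paste0("column '", nm, "' is not numeric"),
            class = "symptomnet_validation_error")
    }
    if (anyNA(col)) {
      abort(paste0("missing value in column '", nm, "' (row ",
                   which(is.na(col))[1], "); complete cases are required"),
            class = "symptomnet_validation_error")
    }
  }
  for (nm in items) {
    col <- x[[nm]]
    bad <- which(col != round(col) | col < 1 | col > 5)
    if (length(bad) > 0) {
      abort(paste0("rating out of the integer range 1-5 in column '", nm,
                   "', row ", bad[1], " (value ", col[bad[1]], ")"),
            class = "symptomnet_validation_error")
    }
  }
  invisible(x)
}

# Matrix of item ratings (n x p), used by estimation stages.
ratings_matrix <- function(x, include_covariates = FALSE) {
  cols <- symptom_items(x)
  if (include_covariates) cols <- c(cols, symptom_covariates(x))
  as.matrix(x[, cols, drop = FALSE])
}

#' Read a symptom table from a delimited file
#'
#' Reads a CSV with one row per participant, validates the named item
#' columns as integer 1-5 ratings, and reference-codes categorical
#' covariates into indicator columns named `<column>_<level>` (the
#' reference level gets no column, mirroring the usual regression
#' contrast layout).
#'
#' @param path Path to a CSV file with a header row.
#' @param item_columns Character vector of item column names.
#' @param covariate_spec Optional named list describing covariates. Each
#'   element is a list with `type` in `"binary"`, `"continuous"`,
#'   `"categorical"`, and for categorical covariates a `reference` level.
#' @return A [symptom_table()].
#' @export
#' @examples
#' # a small synthetic demo cohort shipped with the package
#' path <- system.file("extdata", "synthetic_ibd_cohort.csv",
#'                     package = "symptomnet")
#' items <- setdiff(names(read.csv(path))[1:18], character())
#' tab <- read_symptom_table(path, item_columns = items)
#' nrow(tab)
read_symptom_table <- function(path, item_columns, covariate_spec = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "symptomnet_io_error")
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  missing_cols <- setdiff(c(item_columns, names(covariate_spec)), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "symptomnet_schema_error")
  }
  cov_cols <- character()
  for (nm in names(covariate_spec)) {
    spec <- covariate_spec[[nm]]
    type <- spec$type %||% "continuous"
    if (type == "categorical") {
      expanded <- reference_code(df[[nm]], nm, reference = spec$reference)
      df[[nm]] <- NULL
      df <- cbind(df, expanded)
      cov_cols <- c(cov_cols, names(expanded))
    } else {
      if (type == "binary" && !all(df[[nm]] %in% c(0, 1))) {
        abort(paste0("binary covariate '", nm, "' has values outside {0,1}"),
              class = "symptomnet_validation_error")
      }
      cov_cols <- c(cov_cols, nm)
    }
  }
  symptom_table(df, items = item_columns, covariates = cov_cols)
}

# Expand a categorical vector into reference-coded 0/1 indicator columns.
reference_code <- function(x, name, reference = NULL) {
  lev <- unique(as.character(x))
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) {
    abort(paste0("reference level '", reference, "' not present in '",
                 name, "'"), class = "symptomnet_validation_error")
  }
  others <- setdiff(lev, reference)
  out <- lapply(others, function(l) as.integer(x == l))
  names(out) <- paste0(name, "_", others)
  as.data.frame(out, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of parameters of a partial-correlation network
#'
#' For an m-node Gaussian graphical model the free parameters are the m
#' node variances plus the m(m-1)/2 pairwise partial correlations, i.e.
#' m + m(m-1)/2 in total. This count is the conventional minimum sample
#' size for estimating such a network (one case per parameter).
#'
#' @param n_nodes Number of network nodes (positive integer).
#' @return Integer parameter count, `n_nodes + choose(n_nodes, 2)`.
#' @export
#' @examples
#' required_sample_size(21) # 231
required_sample_size <- function(n_nodes) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 1 ||
      n_nodes != round(n_nodes)) {
    abort("n_nodes must be a positive integer",
          class = "symptomnet_domain_error")
  }
  as.integer(n_nodes + n_nodes * (n_nodes - 1) / 2)
}

#' Write and read a network edge list
#'
#' `write_edge_list()` writes one row per unordered node pair with a
#' nonzero weight, ordered lexicographically by node index, preceded by
#' commented header lines recording the node set and estimation metadata
#' so that `read_edge_list()` can reconstruct the full weight matrix
#' exactly (round trip is bit-faithful to better than 1e-12).
#'
#' @param network A `symptom_network` (see [ebicglasso_select()]).
#' @param path Output file path.
#' @return `write_edge_list()` returns `path` invisibly;
#'   `read_edge_list()` returns a `symptom_network`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "symptom_network"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open '", path, "' for writing"),
          class = "symptomnet_io_error")
  })
  on.exit(close(con))
  nodes <- network$nodes
  writeLines(c(
    paste0("# nodes: ", paste(nodes, collapse = ",")),
    paste0("# lambda: ", format(network$lambda %||% NA, digits = 17)),
    paste0("# gamma: ", format(network$gamma %||% NA, digits = 17)),
    paste0("# n_obs: ", network$n_obs %||% NA)
  ), con)
  ed <- tidy(network)
  writeLines("from,to,weight", con)
  if (nrow(ed) > 0) {
    writeLines(paste(ed$from, ed$to, format(ed$weight, digits = 17),
                     sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "symptomnet_io_error")
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NA)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  nodes <- strsplit(get_field("nodes"), ",")[[1]]
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(df) > 0) {
    for (k in seq_len(nrow(df))) {
      w[df$from[k], df$to[k]] <- df$weight[k]
      w[df$to[k], df$from[k]] <- df$weight[k]
    }
  }
  new_symptom_network(w, nodes,
                      lambda = suppressWarnings(as.numeric(get_field("lambda"))),
                      gamma = suppressWarnings(as.numeric(get_field("gamma"))),
                      n_obs = suppressWarnings(as.integer(get_field("n_obs"))))
}
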