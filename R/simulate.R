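#' @keywords internal
# Evaluate code under a seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a per-replicate sub-seed from a root seed (keeps results identical
# whether replicates run serially or are re-run in isolation).
sub_seed <- function(seed, counter) {
  (seed * 48271 + counter * 1009) %% 2147483563L
}

#' Construct a clustered sparse precision matrix with known partials
#'
#' Builds the ground truth for simulation: a symmetric positive-definite
#' precision matrix whose off-diagonal support is dense within the given
#' item clusters and sparse (Bernoulli with probability `density_between`)
#' across clusters. Off-diagonal entries are set to minus the requested
#' connection strength so the implied partial correlations are positive
#' (symptom networks are positive-dominant); a `negative_fraction` of
#' edges can be flipped. Positive definiteness is enforced by setting the
#' common diagonal value to 1.05 times the spectral requirement (the
#' smallest diagonal making the matrix PD), recorded in the result.
#'
#' @param p Number of items.
#' @param clusters Integer vector of cluster sizes summing to `p`, or a
#'   list of item-index vectors partitioning `1:p`.
#' @param within_strength Magnitude of within-cluster off-diagonal
#'   precision entries (before diagonal scaling).
#' @param between_strength Magnitude for between-cluster edges.
#' @param density_between Probability that a between-cluster pair gets an
#'   edge.
#' @param negative_fraction Fraction of edges flipped to negative sign.
#' @param items Optional item names.
#' @param seed Integer seed for the random between-cluster support.
#' @return An object of class `synthetic_truth`: a list with `precision`,
#'   `true_partials`, `clusters`, `items`, `diagonal`, and `seed`.
#'   Thresholds and covariate effects are attached by
#'   [simulate_symptom_study()] or manually.
#' @export
make_cluster_precision <- function(p, clusters, within_strength = 0.3,
                                   between_strength = 0.15,
                                   density_between = 0.1,
                                   negative_fraction = 0,
                                   items = NULL, seed = 1) {
  if (!is.list(clusters)) {
    sizes <- as.integer(clusters)
    if (sum(sizes) != p) abort("cluster sizes must sum to p",
                               class = "symptomnet_domain_error")
    ends <- cumsum(sizes)
    clusters <- purrr::map2(ends - sizes + 1, ends, seq)
  }
  if (!setequal(unlist(clusters), seq_len(p))) {
    abort("clusters must partition 1:p", class = "symptomnet_domain_error")
  }
  if (is.null(items)) items <- paste0("item", sprintf("%02d", seq_len(p)))
  membership <- integer(p)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k

  A <- matrix(0, p, p)
  local_seed(seed, {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (membership[i] == membership[j]) {
          A[i, j] <- -within_strength
        } else if (runif(1) < density_between) {
          A[i, j] <- -between_strength
        }
        if (A[i, j] != 0 && negative_fraction > 0 &&
            runif(1) < negative_fraction) {
          A[i, j] <- -A[i, j]
        }
      }
    }
  })
  A <- A + t(A)
  lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  diag_value <- max(1, 1.05 * (-lam_min))
  precision <- A + diag(diag_value, p)
  ev_min <- min(eigen(precision, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    abort("could not repair precision matrix to positive definite",
          class = "symptomnet_construction_error")
  }
  dimnames(precision) <- list(items, items)
  structure(list(precision = precision,
                 true_partials = partials_from_precision(precision),
                 clusters = clusters, items = items,
                 diagonal = diag_value, thresholds = NULL,
                 covariate_effects = NULL, seed = seed),
            class = "synthetic_truth")
}

#' Likert discretization thresholds from a target floor probability
#'
#' Four strictly increasing standard-normal cut-points assigning latent
#' mass `p_first` to category 1 ("not at all") and splitting the rest
#' over categories 2-5 with geometric decay, reproducing the strongly
#' right-skewed marginals typical of symptom severity ratings.
#'
#' @param p_first Probability of category 1 (one value per item,
#'   recycled).
#' @param decay Geometric decay of the upper-category probabilities.
#' @return A matrix with one row per item and 4 increasing cut-points.
#' @export
likert_thresholds <- function(p_first, decay = 0.5) {
  stopifnot(all(p_first > 0 & p_first < 1), decay > 0)
  t(vapply(p_first, function(p1) {
    rest <- decay^(0:3)
    probs <- c(p1, (1 - p1) * rest / sum(rest))
    qnorm(cumsum(probs)[1:4])
  }, numeric(4)))
}

#' Covariate design emulating an IBD cohort
#'
#' Generates person-level covariates: a binary active-disease-stage
#' indicator, non-negative right-skewed years since diagnosis
#' (log-normal, parameterized by target mean and SD), and a 4-level
#' treatment factor reference-coded against its first level.
#'
#' @param n Number of persons.
#' @param p_active Expected prevalence of the active stage.
#' @param years_mean,years_sd Target mean and SD of years since
#'   diagnosis.
#' @param treatment_probs Named probabilities of the treatment levels
#'   (first level is the reference); must sum to 1 within 0.01 (they are
#'   renormalized).
#' @param seed Integer seed.
#' @return A tibble of numeric covariate columns (`active_stage`,
#'   `years_since_diagnosis`, and one indicator per non-reference
#'   treatment level). Constant columns are dropped with a warning.
#' @export
make_covariate_design <- function(n, p_active = 0.58,
                                  years_mean = 5.36, years_sd = 5.77,
                                  treatment_probs = c(medication = 0.543,
                                                      surgery = 0.049,
                                                      both = 0.247,
                                                      otherwise = 0.16),
                                  seed = 1) {
  if (any(treatment_probs < 0) || abs(sum(treatment_probs) - 1) > 0.01) {
    abort("treatment_probs must be nonnegative and sum to 1",
          class = "symptomnet_domain_error")
  }
  treatment_probs <- treatment_probs / sum(treatment_probs)
  cv2 <- (years_sd / years_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(years_mean) - sdlog^2 / 2
  local_seed(seed, {
    active <- rbinom(n, 1, p_active)
    years <- rlnorm(n, meanlog, sdlog)
    treatment <- sample(names(treatment_probs), n, replace = TRUE,
                        prob = treatment_probs)
  })
  df <- tibble::tibble(active_stage = active,
                       years_since_diagnosis = years)
  ref <- names(treatment_probs)[1]
  for (lev in setdiff(names(treatment_probs), ref)) {
    df[[paste0("treatment_", lev)]] <- as.integer(treatment == lev)
  }
  constant <- names(df)[vapply(df, function(c) length(unique(c)) < 2,
                               logical(1))]
  if (length(constant) > 0) {
    warn(paste0("dropping constant covariate column(s): ",
                paste(constant, collapse = ", ")))
    df <- df[, setdiff(names(df), constant), drop = FALSE]
  }
  df
}

#' Sample ordinal symptom ratings from a synthetic truth
#'
#' Draws latent vectors from the zero-mean Gaussian whose precision is
#' the truth matrix (correlation-scaled), adds covariate shifts to the
#' latent means, and discretizes each item by its thresholds into the
#' 1-5 rating scale (a Gaussian copula for ordinal data).
#'
#' @param truth A `synthetic_truth` with a `thresholds` matrix (set one
#'   with [likert_thresholds()] if absent; a default skewed set is used
#'   otherwise).
#' @param n Number of persons (>= 1).
#' @param covariate_design Optional data frame of covariate columns.
#' @param covariate_effects Optional named list: covariate column ->
#'   latent mean shift per unit, either a single number applied to all
#'   items or a vector of length p.
#' @param seed Integer seed.
#' @return A [symptom_table()]; the latent matrix is attached as
#'   attribute `"latent"` for testing.
#' @export
sample_likert <- function(truth, n, covariate_design = NULL,
                          covariate_effects = truth$covariate_effects,
                          seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 1) abort("n must be >= 1", class = "symptomnet_domain_error")
  p <- nrow(truth$precision)
  thr <- truth$thresholds
  if (is.null(thr)) thr <- likert_thresholds(rep(0.45, p))
  stopifnot(nrow(thr) == p, ncol(thr) == 4)
  if (any(apply(thr, 1, diff) <= 0)) {
    abort("thresholds must be strictly increasing per item",
          class = "symptomnet_domain_error")
  }
  sigma <- cov2cor(solve(truth$precision))
  z <- local_seed(seed, MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma))
  z <- matrix(z, nrow = n, ncol = p)
  if (!is.null(covariate_design) && length(covariate_effects) > 0) {
    for (nm in names(covariate_effects)) {
      eff <- covariate_effects[[nm]]
      if (length(eff) == 1) eff <- rep(eff, p)
      z <- z + outer(covariate_design[[nm]], eff)
    }
  }
  ratings <- matrix(1L, n, p, dimnames = list(NULL, truth$items))
  for (j in seq_len(p)) {
    ratings[, j] <- findInterval(z[, j], thr[j, ]) + 1L
  }
  df <- as.data.frame(ratings)
  covs <- character()
  if (!is.null(covariate_design)) {
    df <- cbind(df, as.data.frame(covariate_design))
    covs <- names(covariate_design)
  }
  out <- symptom_table(df, items = truth$items, covariates = covs)
  attr(out, "latent") <- z
  out
}

# Category-1 target probabilities per item, emulating the skewed
# prevalence profile of an IBD symptom checklist (higher p_first =
# rarer symptom); paired with the 18 canonical item names.
ibd_item_profile <- function() {
  tibble::tibble(
    item = c("diarrhea", "abdominal_pain", "abdominal_distension",
             "bloody_purulent_stool", "tenesmus", "perianal_abscess",
             "anal_fissure", "anal_fistula", "nutritional_deficiency",
             "weight_loss", "anemia", "skin_lesions",
             "oral_mucosal_lesions", "ocular_lesions", "fatigue",
             "anxiety", "depression", "disturbed_sleep"),
    cluster = rep(c("abdominal", "intestinal", "nutritional", "systemic",
                    "psychosomatic"), c(2, 6, 3, 3, 4)),
    p_first = 1 - c(0.668, 0.580, 0.469, 0.444, 0.617, 0.111, 0.062,
                    0.148, 0.630, 0.556, 0.407, 0.111, 0.161, 0.111,
                    0.741, 0.519, 0.247, 0.679)
  )
}

#' Simulate a full synthetic symptom-study cohort
#'
#' Generates a complete analysis-ready dataset emulating an IBD symptom
#' cohort: 18 symptom items in 5 clusters (abdominal, intestinal,
#' nutritional, systemic, psychosomatic) rated 1-5 with right-skewed
#' marginals, plus disease-stage, years-since-diagnosis, and treatment
#' covariates with additive latent effects on overall severity.
#'
#' @param n Cohort size.
#' @param seed Integer seed controlling every random draw.
#' @param within_strength,between_strength,density_between Passed to
#'   [make_cluster_precision()].
#' @param covariate_effects Named list of latent shifts per covariate
#'   unit (defaults: active stage +0.4, years +0.02 per year, treatment
#'   "otherwise" +0.3, all uniform across items).
#' @return A list with `table` (a [symptom_table()]) and `truth` (the
#'   `synthetic_truth`, with thresholds and covariate effects recorded).
#' @export
simulate_symptom_study <- function(n = 324, seed = 1,
                                   within_strength = 0.3,
                                   between_strength = 0.15,
                                   density_between = 0.1,
                                   covariate_effects = list(
                                     active_stage = 0.4,
                                     years_since_diagnosis = 0.02,
                                     treatment_otherwise = 0.3)) {
  prof <- ibd_item_profile()
  sizes <- as.integer(table(factor(prof$cluster, levels = unique(prof$cluster))))
  truth <- make_cluster_precision(p = nrow(prof), clusters = sizes,
                                  within_strength = within_strength,
                                  between_strength = between_strength,
                                  density_between = density_between,
                                  items = prof$item, seed = seed)
  truth$thresholds <- likert_thresholds(prof$p_first)
  truth$covariate_effects <- covariate_effects
  design <- make_covariate_design(n, seed = sub_seed(seed, 1))
  table <- sample_likert(truth, n, covariate_design = design,
                         covariate_effects = covariate_effects,
                         seed = sub_seed(seed, 2))
  list(table = table, truth = truth)
}
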