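#' Patient-state model: k-means clusters plus two absorbing terminals
#'
#' Clusters the standardized clinical features of every timestep into `k`
#' patient states. Two additional absorbing terminal states represent the
#' stay outcome: state `k + 1` (survival) and `k + 2` (death); each stay's
#' trajectory terminates in the terminal matching its outcome. The cluster
#' count used in full-scale treatment-policy work is typically in the
#' hundreds (750 in the AI Clinician line of work); it is a configuration
#' key here and desk-scale analyses use far fewer.
#'
#' Standardization parameters (mean, SD per feature) come from the fitting
#' cohort only, so held-out data is mapped into the same state space.
#'
#' @param cohort a validated cohort.
#' @param k number of clusters (>= 2, < number of timesteps).
#' @param seed integer seed for the k-means initialization.
#' @param features character vector of feature columns to cluster on.
#' @param nstart,iter_max passed to [stats::kmeans()].
#' @return a `sepsafe_state_model` with centroids, standardization
#'   parameters, and terminal state ids.
#' @export
fit_state_clusters <- function(cohort, k, seed = 1L,
                               features = c("map", "cvp",
                                            "cumulative_balance",
                                            "urine_output", "sofa",
                                            "lactate", "sedation",
                                            "total_fluid_input", "weight"),
                               nstart = 10L, iter_max = 100L) {
  validate_cohort(cohort)
  k <- check_count(k, "k")
  if (k < 2L) stop_sepsafe("k must be >= 2", class = "sepsafe_config_error")
  if (k >= nrow(cohort)) {
    stop_sepsafe("k (", k, ") must be smaller than the number of timesteps (",
                 nrow(cohort), ")", class = "sepsafe_config_error")
  }
  missing <- setdiff(features, names(cohort))
  if (length(missing)) {
    stop_sepsafe("clustering feature(s) absent from cohort: ",
                 paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(cohort)[, features, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1   # constant feature: leave as-is
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  set.seed(seed)
  km <- suppressWarnings(
    kmeans(xs, centers = k, nstart = nstart, iter.max = iter_max)
  )
  structure(
    list(k = k, features = features, center = center, scale = scale,
         centroids = km$centers, seed = as.integer(seed),
         terminal_survival = k + 1L, terminal_death = k + 2L),
    class = "sepsafe_state_model"
  )
}

#' Assign every timestep to its nearest patient-state centroid
#'
#' Distances are Euclidean in the standardized feature space of the fitted
#' model; exact ties go to the lowest centroid id.
#'
#' @param model a `sepsafe_state_model`.
#' @param cohort a validated cohort carrying the model's features.
#' @return integer vector of state ids in `1..k`, one per cohort row.
#' @export
assign_states <- function(model, cohort) {
  stopifnot(inherits(model, "sepsafe_state_model"))
  validate_cohort(cohort)
  x <- as.matrix(as.data.frame(cohort)[, model$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  cent <- model$centroids
  # squared distances via ||x||^2 - 2 x.c + ||c||^2; the ||x||^2 term is
  # constant per row and dropped before the argmin.
  d2 <- -2 * xs %*% t(cent)
  d2 <- sweep(d2, 2, rowSums(cent^2), "+")
  as.integer(max.col(-d2, ties.method = "first"))
}
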