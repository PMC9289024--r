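#' Gradient-boosting model of unsafe clinician behaviour
#'
#' Fits a gradient-boosted tree ensemble predicting, among at-risk steps of
#' one hazard scenario, whether the clinician took the scenario's unsafe
#' action, from the patient features. One model is fitted per scenario.
#' Hyperparameters are fixed, documented configuration; `nthread = 1`
#' together with the seed makes refits bit-reproducible.
#'
#' @param features data frame or matrix of numeric patient features
#'   (rows = at-risk steps).
#' @param labels 0/1 vector: unsafe decision taken.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return a `sepsafe_unsafe_classifier` wrapping the fitted booster and its
#'   feature schema.
#' @export
fit_unsafe_classifier <- function(features, labels, seed = 1L,
                                  nrounds = 60L, max_depth = 3L, eta = 0.2) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) {
    stop_sepsafe("labels must contain both classes",
                 class = "sepsafe_model_error")
  }
  if (nrow(x) != length(y)) stop_sepsafe("features/labels length mismatch")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, feature_names = colnames(x),
                 seed = as.integer(seed)),
            class = "sepsafe_unsafe_classifier")
}

#' @rdname fit_unsafe_classifier
#' @param model a fitted `sepsafe_unsafe_classifier`.
#' @param newdata feature table with the training schema.
#' @return predicted unsafe probabilities.
#' @export
predict_unsafe <- function(model, newdata) {
  stopifnot(inherits(model, "sepsafe_unsafe_classifier"))
  x <- as.matrix(newdata)
  if (!identical(colnames(x), model$feature_names)) {
    stop_sepsafe("feature columns do not match the training schema",
                 class = "sepsafe_model_error")
  }
  storage.mode(x) <- "double"
  predict(model$booster, x)
}

#' SHAP attribution of unsafe clinician decisions
#'
#' Computes per-observation signed SHAP values (tree SHAP, via the
#' booster's prediction contributions) and summarises them into a global
#' ranking by mean absolute attribution. The `relative_importance` column is
#' normalized to the top-ranked feature; `direction` is the sign of the
#' correlation between feature value and SHAP value (positive: high feature
#' values push toward "unsafe").
#'
#' @param model a `sepsafe_unsafe_classifier`.
#' @param features feature table with the training schema.
#' @return a `sepsafe_attribution`: list with `shap` (observations x
#'   features matrix of signed attributions) and `ranking` (data frame
#'   sorted by descending mean absolute attribution).
#' @export
attribution <- function(model, features) {
  stopifnot(inherits(model, "sepsafe_unsafe_classifier"))
  x <- as.matrix(features)
  if (!identical(colnames(x), model$feature_names)) {
    stop_sepsafe("feature columns do not match the training schema",
                 class = "sepsafe_model_error")
  }
  storage.mode(x) <- "double"
  contrib <- predict(model$booster, x, predcontrib = TRUE)
  shap <- contrib[, model$feature_names, drop = FALSE]
  mean_abs <- colMeans(abs(shap))
  direction <- vapply(model$feature_names, function(f) {
    if (sd(x[, f]) == 0 || sd(shap[, f]) == 0) return(0)
    sign(cor(x[, f], shap[, f]))
  }, numeric(1))
  ord <- order(mean_abs, decreasing = TRUE)
  ranking <- data.frame(
    feature = model$feature_names[ord],
    mean_abs_shap = unname(mean_abs[ord]),
    relative_importance = unname(mean_abs[ord] / max(mean_abs[ord][1], .Machine$double.eps)),
    direction = unname(direction[ord])
  )
  structure(list(shap = shap, ranking = ranking),
            class = "sepsafe_attribution")
}
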