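#' Forecaster specification
#'
#' L2-regularized logistic regression. The default penalty `lambda = NULL`
#' resolves at fit time to 1/n_train, the glmnet equivalent of the common
#' reference parameterisation C = 1, and rows are unweighted by default —
#' the behaviour of a stock logistic-regression classifier. Unweighted
#' fitting also keeps uninformative (chance-level) forecasts near the
#' pre-ictal base rate, safely below the 0.4-0.8 alarm-threshold grid, so
#' that a null forecaster raises no alarms instead of warning half the
#' time. Inverse-class-frequency weighting is available as a flag for
#' sensitivity analyses.
#'
#' @param lambda ridge penalty passed to glmnet (alpha = 0); NULL means
#'   1/n_train.
#' @param class_weighted if TRUE, rows are weighted inversely to their class
#'   frequency in the training fold.
#' @param thresh glmnet convergence tolerance (tight, for reproducibility).
#' @return list of class `spes_model_spec`.
#' @export
model_spec <- function(lambda = NULL, class_weighted = FALSE,
                       thresh = 1e-12) {
  structure(list(lambda = lambda, class_weighted = class_weighted,
                 thresh = thresh), class = "spes_model_spec")
}

fit_logistic <- function(X, y, spec) {
  w <- rep(1, length(y))
  if (spec$class_weighted) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    w[y == 1] <- length(y) / (2 * n1)
    w[y == 0] <- length(y) / (2 * n0)
  }
  lam <- if (is.null(spec$lambda)) 1 / nrow(X) else spec$lambda
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE,
                        weights = w, thresh = spec$thresh)
  cf <- as.numeric(stats::coef(fit, s = lam))
  structure(list(intercept = cf[1],
                 coef = stats::setNames(cf[-1], colnames(X)),
                 features = colnames(X)),
            class = "spes_model")
}

model_matrix <- function(tbl, rows = NULL) {
  if (is.null(rows)) rows <- rep(TRUE, nrow(tbl))
  as.matrix(tbl[rows, FEATURE_COLS])
}

#' Predict seizure likelihood for one patient
#'
#' Deterministic logistic probabilities for the valid, non-excluded rows of
#' a normalized feature table.
#'
#' @param model a `spes_model` (from the LOSO fit).
#' @param tbl normalized FeatureTable.
#' @param patient_id identifier carried into the output.
#' @return ForecastSeries data.frame: patient_id, stim_index, t_s, p, label.
#' @export
predict_single <- function(model, tbl, patient_id = "patient") {
  if (!identical(model$features, FEATURE_COLS) ||
      !all(FEATURE_COLS %in% names(tbl)))
    stop("feature-name mismatch between model and table", call. = FALSE)
  rows <- tbl$valid & tbl$label %in% c("preictal", "interictal")
  X <- model_matrix(tbl, rows)
  p <- as.numeric(stats::plogis(model$intercept +
                                  X %*% model$coef[FEATURE_COLS]))
  data.frame(patient_id = patient_id,
             stim_index = tbl$stim_index[rows],
             t_s = tbl$t_s[rows], p = p,
             label = tbl$label[rows], stringsAsFactors = FALSE)
}

#' Leave-one-patient-out logistic forecasting
#'
#' For each patient, fits the logistic model on the pooled valid labeled
#' rows of all *other* patients' normalized feature tables and predicts the
#' held-out patient's seizure likelihood per stimulus. Nothing derived from
#' the held-out patient enters training: the fold's design matrix is
#' assembled exclusively from the remaining tables (and each table was
#' normalized within its own patient).
#'
#' @param tables named list of normalized FeatureTables (one per patient).
#' @param spec a `spes_model_spec`.
#' @return list with `series` (named list of ForecastSeries) and `models`
#'   (named list of per-fold `spes_model`s).
#' @export
fit_loso <- function(tables, spec = model_spec()) {
  if (length(tables) < 2)
    stop("LOSO needs at least 2 patients", call. = FALSE)
  ids <- names(tables)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(tables))
  series <- list(); models <- list()
  for (i in seq_along(tables)) {
    train <- do.call(rbind, lapply(tables[-i], function(tb) {
      rows <- tb$valid & tb$label %in% c("preictal", "interictal")
      cbind(tb[rows, c(FEATURE_COLS, "label")])
    }))
    y <- as.integer(train$label == "preictal")
    if (length(unique(y)) < 2)
      stop(sprintf("training fold for held-out patient %s has a single label",
                   ids[i]), call. = FALSE)
    model <- fit_logistic(as.matrix(train[, FEATURE_COLS]), y, spec)
    models[[ids[i]]] <- model
    series[[ids[i]]] <- predict_single(model, tables[[i]], ids[i])
  }
  list(series = series, models = models)
}
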