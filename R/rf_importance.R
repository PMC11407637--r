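#' Add negative-control feature columns
#'
#' Appends one uniform continuous column (`nc_random_number`) and one 4-level
#' categorical column (`nc_random_factor`) drawn independently of any
#' response, so a calibrated importance analysis should never flag them.
#'
#' @param features feature `data.table`.
#' @param seed RNG seed for the control columns.
#' @return copy of `features` with the two control columns.
#' @export
augment_negative_controls <- function(features, seed = 1L) {
  ft <- data.table::as.data.table(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ft[, nc_random_number := stats::runif(.N)]
  ft[, nc_random_factor := factor(sample(paste0("lvl", 1:4), .N, replace = TRUE))]
  ft[]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# prepare a model frame: factors from characters/logicals, drop single-level
# features with a warning
rf_model_frame <- function(features, feature_cols) {
  df <- as.data.frame(features)[, feature_cols, drop = FALSE]
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.logical(df[[j]])) df[[j]] <- factor(df[[j]])
  }
  single <- vapply(df, function(x)
    (is.factor(x) && nlevels(droplevels(x)) < 2) ||
    (is.numeric(x) && length(unique(x)) < 2), logical(1))
  if (any(single)) {
    warning("single-level feature(s) dropped: ",
            paste(names(df)[single], collapse = ", "))
    df <- df[, !single, drop = FALSE]
  }
  df
}

# deterministic quantile-stratified fold assignment
make_stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_strata <- max(1L, min(5L, length(y) %/% (2L * k)))
  strata <- cut(rank(y, ties.method = "first"), breaks = n_strata,
                labels = FALSE)
  fold <- integer(length(y))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train repeated cross-validated random-forest regression models
#'
#' Fits `folds x repeats` random-forest regression models (default 5 x 5 =
#' 25) predicting the response from the feature table. Folds are stratified
#' by response quantile; each model is trained on the out-of-fold data with
#' `ntree` trees and `mtry = floor(sqrt(p))`, and evaluated on its held-out
#' fold by RMSE normalized to the range of the full response (NRMSE). All
#' per-model seeds derive deterministically from `seed`.
#'
#' @param features feature table (one row per observation).
#' @param response numeric response (readthrough efficiency), no missing
#'   values.
#' @param feature_cols character vector of feature column names (default:
#'   all columns except `transcript_id`).
#' @param folds,repeats cross-validation scheme (defaults 5, 5).
#' @param ntree trees per model (default 100).
#' @param seed master seed.
#' @return list of model fits, each with `repeat_id`, `fold_id`, `fit`
#'   (randomForest object), `train_idx`, `test_idx`, `nrmse`, `seed`; the
#'   list carries attributes `response_range` and `model_frame`.
#' @export
train_cv_models <- function(features, response, feature_cols = NULL,
                            folds = 5L, repeats = 5L, ntree = 100L,
                            seed = 1L) {
  if (anyNA(response)) stop("response contains missing values")
  if (length(response) < 50)
    warning("fewer than 50 observations; cross-validated estimates will be noisy")
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features), "transcript_id")
  df <- rf_model_frame(features, feature_cols)
  rng <- diff(range(response))
  fits <- list()
  for (r in seq_len(repeats)) {
    fold <- make_stratified_folds(response, folds, seed = seed * 1000L + r)
    for (f in seq_len(folds)) {
      mseed <- seed * 10000L + r * 100L + f
      old <- .Random.seed_save()
      set.seed(mseed)
      test <- which(fold == f); train <- which(fold != f)
      fit <- randomForest::randomForest(
        x = df[train, , drop = FALSE], y = response[train],
        ntree = ntree, mtry = max(1L, floor(sqrt(ncol(df)))),
        importance = TRUE)
      pred <- stats::predict(fit, df[test, , drop = FALSE])
      .Random.seed_restore(old)
      fits[[length(fits) + 1L]] <- list(
        repeat_id = r, fold_id = f, fit = fit,
        train_idx = train, test_idx = test,
        nrmse = sqrt(mean((pred - response[test])^2)) / rng,
        seed = mseed)
    }
  }
  attr(fits, "response_range") <- rng
  attr(fits, "model_frame") <- df
  attr(fits, "response") <- response
  fits
}

# %IncMSE per feature for one fitted forest: 100 * unscaled permutation
# importance (mean over trees of OOB MSE increase) / baseline OOB MSE
pct_inc_mse <- function(fit) {
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  base_mse <- utils::tail(fit$mse, 1)
  100 * imp / base_mse
}

# variance-scaled permutation importance (mean OOB MSE increase / its SE);
# scale-free, so observed and permutation-null fits are comparable
scaled_importance <- function(fit) {
  randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
}

#' Permutation importance with empirical p-values for one model
#'
#' The reported importance of each feature is the percent increase in
#' out-of-bag MSE when that feature is permuted (%IncMSE). The null
#' distribution for the empirical p-value is built by refitting the forest
#' on permuted responses (`n_perm` refits); the comparison uses the
#' variance-scaled importance (mean OOB MSE increase over its standard
#' error), which is scale-free and hence comparable between the observed fit
#' and null refits whose baseline MSE differs. The empirical p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param model one element of [train_cv_models()] output.
#' @param model_frame the model frame attribute of the fit list.
#' @param response full response vector.
#' @param n_perm permutation refits (>= 20; default 100 -- the full-scale
#'   analysis uses 1000).
#' @param ntree trees per null refit (defaults to the fitted model's).
#' @return `data.table`: `feature`, `pct_inc_mse`, `empirical_p`.
#' @export
permutation_importance <- function(model, model_frame, response,
                                   n_perm = 100L, ntree = NULL) {
  if (n_perm < 20L) stop("n_perm < 20 gives too coarse a p-value resolution")
  if (is.null(ntree)) ntree <- model$fit$ntree
  train <- model$train_idx
  x <- model_frame[train, , drop = FALSE]
  y <- response[train]
  obs <- pct_inc_mse(model$fit)
  obs_scaled <- scaled_importance(model$fit)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(model$seed + 5e6L)
  null_ge <- numeric(length(obs)); names(null_ge) <- names(obs)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    nf <- randomForest::randomForest(x = x, y = yp, ntree = ntree,
                                     mtry = max(1L, floor(sqrt(ncol(x)))),
                                     importance = TRUE)
    null_imp <- scaled_importance(nf)
    null_ge <- null_ge + as.numeric(null_imp[names(obs)] >= obs_scaled)
  }
  data.table::data.table(feature = names(obs),
                         pct_inc_mse = unname(obs),
                         empirical_p = unname((1 + null_ge) / (1 + n_perm)))
}

#' Aggregate importance records across cross-validation models
#'
#' Averages %IncMSE over models and applies the significance rule: a feature
#' is overall significant when its empirical p-value is below `p_threshold`
#' in at least `min_significant` of `n_expected` models (default 15 of 25).
#' With fewer models than expected the rule is rescaled proportionally and
#' flagged.
#'
#' @param records list of per-model importance tables from
#'   [permutation_importance()].
#' @param p_threshold per-model significance level (default 0.05).
#' @param min_significant,n_expected the aggregate rule (defaults 15, 25).
#' @return `data.table`: `feature`, `mean_pct_inc_mse`, `n_models`,
#'   `n_models_significant`, `overall_significant`, `rule_rescaled`.
#' @export
aggregate_importance <- function(records, p_threshold = 0.05,
                                 min_significant = 15L, n_expected = 25L) {
  all <- data.table::rbindlist(records)
  n_models <- length(records)
  rescaled <- n_models != n_expected
  thr <- if (rescaled) {
    warning("aggregating ", n_models, " models (expected ", n_expected,
            "); significance rule rescaled proportionally")
    ceiling(min_significant / n_expected * n_models)
  } else min_significant
  out <- all[, .(mean_pct_inc_mse = mean(pct_inc_mse),
                 n_models = .N,
                 n_models_significant = sum(empirical_p < p_threshold)),
             by = feature]
  out[, overall_significant := n_models_significant >= thr]
  out[, rule_rescaled := rescaled]
  out[]
}

#' Full random-forest importance analysis of readthrough efficiency
#'
#' Convenience wrapper: trains the repeated-CV forests, computes per-model
#' permutation importance, and aggregates. Returns the aggregate table, the
#' per-model NRMSE values and the fit list.
#'
#' @inheritParams train_cv_models
#' @inheritParams permutation_importance
#' @param p_threshold per-model empirical-p significance level.
#' @return list: `importance` (aggregate table), `nrmse` (per model),
#'   `mean_nrmse`, `fits`.
#' @export
rf_readthrough_analysis <- function(features, response, feature_cols = NULL,
                                    folds = 5L, repeats = 5L, ntree = 100L,
                                    n_perm = 100L, p_threshold = 0.05,
                                    seed = 1L) {
  fits <- train_cv_models(features, response, feature_cols = feature_cols,
                          folds = folds, repeats = repeats, ntree = ntree,
                          seed = seed)
  mf <- attr(fits, "model_frame")
  records <- lapply(fits, permutation_importance, model_frame = mf,
                    response = response, n_perm = n_perm)
  imp <- aggregate_importance(records, p_threshold = p_threshold,
                              min_significant = 15L,
                              n_expected = folds * repeats)
  nrmse <- vapply(fits, `[[`, numeric(1), "nrmse")
  list(importance = imp, nrmse = nrmse, mean_nrmse = mean(nrmse), fits = fits)
}
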