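#' Feature filter: keep features with more than 3 non-zero values
#'
#' @param X feature matrix (rows = mutations).
#' @param min_nonzero retention threshold: a feature is kept when its
#'   non-zero count is strictly greater than this (default 3).
#' @return character vector of retained feature names.
#' @export
filter_features <- function(X, min_nonzero = 3) {
  nz <- colSums(X != 0)
  keep <- colnames(X)[nz > min_nonzero]
  if (length(keep) == 0) stop("no features retained by the non-zero filter")
  keep
}

#' Train the hot-spot random-forest regressor
#'
#' A regression forest on the retained features (non-zero filter applied
#' to the training rows), predicting ddG in kcal/mol: 500 trees, terminal
#' nodes of at least 3 mutations, mtry = one third of the retained
#' features (the regression convention). Deterministic given `seed`.
#'
#' @param X feature matrix.
#' @param ddg observed ddG (kcal/mol), one per row of `X`.
#' @param params a [hotspot_params()] list (`ntree`, `nodesize`, `seed`).
#' @return list of class `hotspot_model`: `forest`, `features`
#'   (retained-schema names), `params`.
#' @export
train_hotspot_model <- function(X, ddg, params = hotspot_params()) {
  stopifnot(nrow(X) == length(ddg))
  if (nrow(X) < 10) stop("need at least 10 mutations to train")
  if (stats::sd(ddg) == 0) stop("degenerate response: constant ddG")
  keep <- filter_features(X)
  Xk <- X[, keep, drop = FALSE]
  set.seed(params$seed)
  forest <- randomForest::randomForest(
    x = Xk, y = ddg, ntree = params$ntree, nodesize = params$nodesize,
    mtry = max(1L, floor(length(keep) / 3)), keep.inbag = TRUE,
    importance = FALSE)
  structure(list(forest = forest, features = keep, params = params),
            class = "hotspot_model")
}

#' Predict ddG for new mutations
#'
#' @param object a `hotspot_model`.
#' @param newdata feature matrix containing (at least, in any order) the
#'   model's retained features, keyed by name.
#' @param ... unused.
#' @return numeric vector of predicted ddG (kcal/mol).
#' @export
predict.hotspot_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f) > 0)
    stop("feature schema mismatch; missing: ",
         paste(utils::head(missing_f, 5), collapse = ", "))
  as.numeric(predict(object$forest,
                     newdata[, object$features, drop = FALSE]))
}

#' Leave-complex-out cross-validation
#'
#' All mutations of one complex form the test fold while the model is
#' trained on every other complex; the feature filter is re-applied inside
#' each training fold (no test-fold leakage). Every row is predicted
#' exactly once.
#'
#' @param X feature matrix.
#' @param ddg observed ddG.
#' @param complex_id complex identifier per row.
#' @param params a [hotspot_params()] list.
#' @return data frame with `complex_id`, `observed` and `predicted`, in
#'   input row order.
#' @export
loco_cv <- function(X, ddg, complex_id, params = hotspot_params()) {
  stopifnot(nrow(X) == length(ddg), length(ddg) == length(complex_id))
  folds <- unique(complex_id)
  if (length(folds) < 2) stop("leave-complex-out needs at least 2 complexes")
  pred <- rep(NA_real_, length(ddg))
  for (k in seq_along(folds)) {
    test <- complex_id == folds[k]
    fold_params <- params
    fold_params$seed <- params$seed + k
    model <- train_hotspot_model(X[!test, , drop = FALSE], ddg[!test],
                                 fold_params)
    pred[test] <- predict(model, X[test, , drop = FALSE])
  }
  data.frame(complex_id = complex_id, observed = ddg, predicted = pred,
             stringsAsFactors = FALSE)
}

#' Permutation importance (%IncMSE)
#'
#' For each retained feature, its values are permuted and the forest's
#' out-of-bag mean squared error is recomputed; the score is the mean
#' relative MSE increase over repeats, in percent:
#' `(MSE_permuted - MSE_oob) / MSE_oob * 100`. Out-of-bag predictions come
#' from the per-tree in-bag records of the trained forest.
#'
#' @param model a `hotspot_model` (trained with `keep.inbag`, the default
#'   here).
#' @param X the training feature matrix.
#' @param ddg the training response.
#' @param n_repeats permutation repeats per feature (default 5).
#' @param seed RNG seed for the permutations.
#' @return data frame with `feature` and `inc_mse_pct`, sorted by
#'   decreasing score.
#' @export
permutation_importance <- function(model, X, ddg, n_repeats = 5,
                                   seed = model$params$seed) {
  Xk <- X[, model$features, drop = FALSE]
  inbag <- model$forest$inbag
  if (is.null(inbag)) stop("model was trained without keep.inbag")
  oob <- inbag == 0
  oob_mean <- function(per_tree) {
    p <- rowSums(per_tree * oob) / rowSums(oob)
    p
  }
  base_pred <- oob_mean(predict(model$forest, Xk, predict.all = TRUE)$individual)
  mse0 <- mean((base_pred - ddg)^2, na.rm = TRUE)
  set.seed(seed)
  scores <- vapply(model$features, function(f) {
    reps <- vapply(seq_len(n_repeats), function(r) {
      Xp <- Xk
      Xp[, f] <- sample(Xp[, f])
      p <- oob_mean(predict(model$forest, Xp, predict.all = TRUE)$individual)
      mean((p - ddg)^2, na.rm = TRUE)
    }, numeric(1))
    mean((reps - mse0) / mse0 * 100)
  }, numeric(1))
  out <- data.frame(feature = model$features, inc_mse_pct = scores,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$inc_mse_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}
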