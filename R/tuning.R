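#' Class-stratified cross-validation folds
#'
#' Assigns each training sample to one of `folds` folds, stratifying by
#' class so every fold contains both classes. Stratification is not
#' optional here: an unstratified 3-fold split of a 12-sample pooled
#' training set can easily produce a single-class fold, which would make
#' tuning impossible for the smallest pooled designs.
#'
#' @param y Factor of class labels.
#' @param folds Number of folds (>= 2).
#' @return Integer vector of fold ids, same length as `y`.
#' @export
make_cv_folds <- function(y, folds = 3L) {
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) {
    rlang::abort("`folds` must be >= 2", class = "poolsim_error_config")
  }
  if (any(table(y) < folds)) {
    rlang::abort(
      sprintf("too few samples: every class needs >= %d samples for %d-fold CV",
              folds, folds),
      class = "poolsim_error_degenerate"
    )
  }
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

subset_dataset <- function(data, idx) {
  new_omics_dataset(
    data$values[idx, , drop = FALSE],
    data$bio[idx, , drop = FALSE],
    data$labels[idx],
    data$marker_indices, data$gamma_values,
    data$pool_size, data$scenario
  )
}

#' Choose hyperparameters by internal cross-validation
#'
#' Evaluates every grid point by class-stratified k-fold cross-validation
#' on the training set (only), and returns the point with the smallest
#' mean misclassification rate over folds. Ties are broken by grid order —
#' the default grids are ordered by increasing parameter value (kernel
#' width varying within soft margin for the radial SVM), so the smallest
#' tied parameter wins and tuning is deterministic given the fold
#' assignment.
#'
#' Two grids get a fast path that avoids refitting per grid point: the
#' k-NN 1..k grid is evaluated in a single distance pass per fold, and the
#' ridge logistic path is fitted once per fold for all lambdas.
#'
#' @param spec A [classifier_spec()].
#' @param train Training `omics_dataset`.
#' @param features Feature column indices available to the model.
#' @param folds Number of CV folds (default 3).
#' @return List with `params` (chosen values), `cv_error`, and
#'   `grid_errors` (tibble of all candidates with their CV error).
#' @export
tune_by_internal_cv <- function(spec, train, features, folds = 3L) {
  stopifnot(inherits(spec, "classifier_spec"))
  grid <- spec$grid %||%
    default_grid(spec$name, length(features), nrow(train$values), folds)
  if (nrow(grid) == 1L) {
    return(list(params = as.list(grid[1L, ]), cv_error = NA_real_,
                grid_errors = tibble::tibble(grid, cv_error = NA_real_)))
  }
  fold_id <- make_cv_folds(train$labels, folds)
  errs <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- subset_dataset(train, fold_id != f)
    te <- subset_dataset(train, fold_id == f)
    truth <- te$labels
    if (spec$name == "knn" && identical(names(grid), "k")) {
      ks <- pmin(grid$k, nrow(tr$values))
      pred <- knn_predict_all(tr$values[, features, drop = FALSE],
                              tr$labels,
                              te$values[, features, drop = FALSE],
                              ks)
      errs[, f] <- colMeans(pred != as.character(truth))
    } else if (spec$name == "plr" && identical(names(grid), "lambda")) {
      x <- tr$values[, features, drop = FALSE]
      fit <- fit_plr(x, tr$labels, grid$lambda[1L], lambdas = grid$lambda)
      for (g in seq_len(nrow(grid))) {
        fit$s <- grid$lambda[g] / nrow(x)
        pred <- predict_plr(fit, te$values[, features, drop = FALSE])
        errs[g, f] <- mean(pred != truth)
      }
    } else {
      for (g in seq_len(nrow(grid))) {
        model <- train_classifier(spec, grid[g, ], tr, features)
        errs[g, f] <- mean(predict(model, te) != truth)
      }
    }
  }
  mean_err <- rowMeans(errs)
  best <- which.min(mean_err)                 # first minimum = tie-break
  list(
    params = as.list(grid[best, ]),
    cv_error = mean_err[best],
    grid_errors = tibble::tibble(grid, cv_error = mean_err)
  )
}
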