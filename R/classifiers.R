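#' The six supported classifier names
#'
#' @return Character vector: linear/radial SVM, random forest, k-nearest
#'   neighbours, L2-penalized logistic regression, nearest shrunken
#'   centroids.
#' @export
classifier_names <- function() {
  c("svm_linear", "svm_radial", "random_forest", "knn", "plr", "pam")
}

#' Describe a classifier and its tuning grid
#'
#' A spec names one of the six algorithms, the hyperparameter grid searched
#' by internal cross-validation, and fixed (non-tuned) settings. When
#' `grid` is `NULL` the default grid is built at tuning time because two
#' grids depend on the data: the k-NN grid runs from 1 up to the number of
#' selected features (capped at the samples available to a CV training
#' fold), and the random-forest `mtry` grid is clipped to the number of
#' selected features.
#'
#' Default grids: SVM soft margin `c` in \{0.1, 1, 5, 10, 50, 100, 500\}
#' (both kernels); radial kernel width `gamma` in \{0.25, 0.5, 1, 2, 4\};
#' random forest `mtry` in \{4, 8, 16, 32, 64\} with 1000 trees fixed;
#' k-NN `k` in 1..top-k; ridge logistic `lambda` in
#' \{0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16\}; shrunken-centroid
#' threshold `delta` in \{0.1, 0.25, 0.5, 1, 2, 5\}.
#'
#' @param name One of [classifier_names()].
#' @param grid Optional tibble of candidate hyperparameter combinations
#'   (one column per hyperparameter, rows in tie-break order).
#' @param fixed Named list of non-tuned settings (`num_trees` for the
#'   random forest, default 1000).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name, grid = NULL, fixed = list()) {
  name <- match.arg(name, classifier_names())
  if (!is.null(grid)) grid <- tibble::as_tibble(grid)
  structure(list(name = name, grid = grid, fixed = fixed),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (%s grid)\n", x$name,
              if (is.null(x$grid)) "default" else
                paste(nrow(x$grid), "point")))
  invisible(x)
}

default_grid <- function(name, n_features_used, n_train, cv_folds = 3L) {
  costs <- c(0.1, 1, 5, 10, 50, 100, 500)
  switch(name,
    svm_linear = tibble::tibble(cost = costs),
    # gamma varies fastest: tie-break order is smallest cost, then gamma
    svm_radial = tidyr::expand_grid(cost = costs,
                                    gamma = c(0.25, 0.5, 1, 2, 4)),
    random_forest = tibble::tibble(
      mtry = unique(pmin(c(4L, 8L, 16L, 32L, 64L),
                         as.integer(n_features_used)))
    ),
    knn = {
      # k cannot exceed the samples seen by a CV training fold
      cap <- min(n_features_used,
                 n_train - ceiling(n_train / cv_folds))
      tibble::tibble(k = seq_len(max(1L, cap)))
    },
    plr = tibble::tibble(lambda = c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16)),
    pam = tibble::tibble(delta = c(0.1, 0.25, 0.5, 1, 2, 5)),
    rlang::abort(paste0("unknown classifier: ", name),
                 class = "poolsim_error_config")
  )
}

#' Train one classifier at fixed hyperparameters
#'
#' Fits the named algorithm on the training samples restricted to the given
#' feature columns. No per-feature standardization is applied beyond what
#' each algorithm defines internally — classifiers see the simulated
#' log-scale values directly (`scale = FALSE` for the SVMs,
#' `standardize = FALSE` for the ridge fit).
#'
#' The random forest draws its seed from the current R random stream, so a
#' pipeline seeded upstream is fully reproducible.
#'
#' @param spec A [classifier_spec()].
#' @param params Named list/one-row data frame of hyperparameter values
#'   (one entry per grid column).
#' @param train An `omics_dataset` containing both classes.
#' @param features Integer vector of feature column indices to train on.
#' @return A `tuned_model` holding the fitted state, the chosen
#'   parameters, and the feature set (predictions use exactly these
#'   features, in this order).
#' @export
train_classifier <- function(spec, params, train, features) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "omics_dataset"))
  params <- as.list(params)
  if (length(features) < 1L) {
    rlang::abort("`features` must be nonempty", class = "poolsim_error_config")
  }
  x <- train$values[, features, drop = FALSE]
  y <- droplevels(train$labels)
  if (nlevels(y) < 2L) {
    rlang::abort("training data contain a single class",
                 class = "poolsim_error_degenerate")
  }
  y <- factor(y, levels = class_levels())
  fit <- switch(spec$name,
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = params$cost,
                            scale = FALSE),
    svm_radial = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                            gamma = params$gamma, scale = FALSE),
    random_forest = {
      num_trees <- spec$fixed$num_trees %||% 1000L
      ranger::ranger(
        x = x, y = y, num.trees = num_trees,
        mtry = min(params$mtry, ncol(x)),
        seed = sample.int(.Machine$integer.max, 1L),
        num.threads = 1L, verbose = FALSE
      )
    },
    knn = list(x = x, y = y, k = params$k),
    plr = fit_plr(x, y, params$lambda),
    pam = nsc_shrink_centroids(x, y, params$delta)
  )
  structure(
    list(name = spec$name, spec = spec, params = params,
         features = features, fit = fit, levels = levels(y)),
    class = "tuned_model"
  )
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf("<tuned_model> %s (%s), %d features\n", x$name,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              length(x$features)))
  invisible(x)
}

#' Predict class labels for individual test samples
#'
#' @param object A `tuned_model` from [train_classifier()].
#' @param newdata An `omics_dataset` (its feature columns must cover the
#'   model's feature set) or a numeric matrix of all original features.
#' @param ... Unused.
#' @return Factor of predicted labels (`control`/`case`), one per sample.
#' @export
predict.tuned_model <- function(object, newdata, ...) {
  xt <- if (inherits(newdata, "omics_dataset")) newdata$values else newdata
  if (max(object$features) > ncol(xt)) {
    rlang::abort("test data lack features the model was trained on",
                 class = "poolsim_error_config")
  }
  xt <- xt[, object$features, drop = FALSE]
  pred <- switch(object$name,
    svm_linear = ,
    svm_radial = stats::predict(object$fit, xt),
    random_forest = stats::predict(object$fit, data = xt,
                                   num.threads = 1L,
                                   verbose = FALSE)$predictions,
    knn = knn_predict(object$fit$x, object$fit$y, xt, object$fit$k),
    plr = predict_plr(object$fit, xt),
    pam = nsc_predict(object$fit, xt)
  )
  factor(as.character(pred), levels = object$levels)
}

# ---- k-nearest neighbours ------------------------------------------------
# Euclidean distance, majority vote; a voting tie falls back to the class
# of the single nearest neighbour, making predictions deterministic.

knn_neighbour_order <- function(xtr, xte) {
  d2 <- outer(rowSums(xte^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xte)), rowSums(xtr^2)) -
    2 * tcrossprod(xte, xtr)
  t(apply(d2, 1L, order))                     # n_te x n_tr neighbour ranks
}

#' k-NN predictions for one or many values of k
#'
#' Computes, in a single distance pass, the Euclidean k-NN prediction of
#' each test sample for every requested `k`. Used both for prediction and
#' for the 1..k tuning grid, where evaluating each `k` separately would
#' recompute the same distance matrix.
#'
#' @param xtr,ytr Training matrix and labels.
#' @param xte Test matrix (same columns as `xtr`).
#' @param ks Integer vector of neighbourhood sizes.
#' @return A `nrow(xte) x length(ks)` character matrix of labels.
#' @keywords internal
knn_predict_all <- function(xtr, ytr, xte, ks) {
  ord <- knn_neighbour_order(xtr, xte)
  kmax <- max(ks)
  lab <- matrix(ytr[ord[, seq_len(kmax), drop = FALSE]] == class_levels()[2],
                nrow = nrow(xte))
  case_cum <- if (kmax == 1L) {
    matrix(as.numeric(lab), ncol = 1L)
  } else {
    t(apply(lab, 1L, cumsum))
  }
  nearest <- ifelse(lab[, 1L], class_levels()[2], class_levels()[1])
  out <- matrix(NA_character_, nrow(xte), length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    votes <- case_cum[, k]
    out[, j] <- ifelse(votes * 2L > k, class_levels()[2],
                ifelse(votes * 2L < k, class_levels()[1], nearest))
  }
  out
}

knn_predict <- function(xtr, ytr, xte, k) {
  k <- min(as.integer(k), nrow(xtr))
  factor(knn_predict_all(xtr, ytr, xte, k)[, 1L], levels = class_levels())
}

# ---- L2-penalized (ridge) logistic regression ----------------------------
# Grid lambdas are stated for the objective  -loglik + lambda/2 * ||beta||^2
# (intercept unpenalized); glmnet scales its penalty per observation, so
# lambda is divided by n. The fit uses the full decreasing lambda path for
# warm starts and predicts at the requested value. Convergence tolerance
# 1e-8.

plr_lambda_grid <- function() c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16)

fit_plr <- function(x, y, lambda, lambdas = plr_lambda_grid()) {
  padded <- ncol(x) < 2L
  if (padded) x <- cbind(x, `.pad` = 0)
  lambdas <- sort(unique(c(lambdas, lambda)), decreasing = TRUE)
  # small pooled designs (e.g. 12 pools) trip glmnet's small-class caution;
  # they are intended use here
  fit <- withCallingHandlers(
    glmnet::glmnet(
      x, y, family = "binomial", alpha = 0,
      lambda = lambdas / nrow(x), standardize = FALSE, thresh = 1e-8
    ),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  list(glmnet = fit, s = lambda / nrow(x), padded = padded,
       levels = levels(y))
}

predict_plr <- function(fit, xt) {
  if (fit$padded) xt <- cbind(xt, `.pad` = 0)
  cls <- stats::predict(fit$glmnet, xt, s = fit$s, type = "class",
                        exact = FALSE)
  factor(as.character(cls), levels = fit$levels)
}

# ---- nearest shrunken centroids (PAM) ------------------------------------

#' Shrunken class centroids for nearest-centroid classification
#'
#' Implements the nearest-shrunken-centroid construction: per feature, the
#' difference between each class centroid and the overall centroid is
#' standardized by `m_k * (s_j + s0)` — where `s_j` is the pooled
#' within-class standard deviation, `s0` its median across features (a
#' guard against near-zero denominators), and `m_k = sqrt(1/n_k - 1/n)`
#' puts the difference on the scale of its standard error — then
#' soft-thresholded by `delta`. Features whose standardized differences
#' shrink to zero in every class no longer influence classification, so
#' the shrinkage performs internal feature elimination. Class priors are
#' uniform (the generative model is balanced).
#'
#' @param x Training matrix (samples x features).
#' @param y Factor of class labels (both classes present).
#' @param delta Non-negative soft-threshold.
#' @return An `nsc_model`: shrunken centroids, standardization quantities,
#'   and the surviving-feature mask.
#' @export
nsc_shrink_centroids <- function(x, y, delta) {
  if (!is.numeric(delta) || is.na(delta) || delta < 0) {
    rlang::abort("`delta` must be >= 0", class = "poolsim_error_config")
  }
  y <- droplevels(y)
  lv <- levels(y)
  if (length(lv) < 2L) {
    rlang::abort("both classes must be present",
                 class = "poolsim_error_degenerate")
  }
  n <- nrow(x)
  nk <- as.vector(table(y))
  centroids <- do.call(rbind, lapply(lv, function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  overall <- colMeans(x)
  within_ss <- Reduce(`+`, lapply(seq_along(lv), function(i) {
    xi <- x[y == lv[i], , drop = FALSE]
    colSums(sweep(xi, 2L, centroids[i, ])^2)
  }))
  s <- sqrt(within_ss / (n - length(lv)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(centroids, 2L, overall) /
    (mk %o% (s + s0))
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- sweep(d_shrunk * (mk %o% (s + s0)), 2L, overall, `+`)
  structure(
    list(centroids = shrunken, s = s, s0 = s0, levels = lv,
         delta = delta, d_shrunk = d_shrunk,
         surviving = colSums(d_shrunk != 0) > 0),
    class = "nsc_model"
  )
}

#' Number of features surviving shrinkage
#' @param model An `nsc_model`.
#' @return Count of features with a nonzero shrunken difference in at
#'   least one class; non-increasing in `delta`.
#' @export
nsc_surviving_features <- function(model) sum(model$surviving)

nsc_predict <- function(model, xt) {
  denom2 <- (model$s + model$s0)^2
  scores <- vapply(seq_along(model$levels), function(i) {
    rowSums(sweep(xt, 2L, model$centroids[i, ])^2 / denom2[col(xt)])
  }, numeric(nrow(xt)))
  scores <- matrix(scores, nrow = nrow(xt))
  # smallest squared distance wins; exact ties go to the first level
  idx <- max.col(-scores, ties.method = "first")
  factor(model$levels[idx], levels = model$levels)
}
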