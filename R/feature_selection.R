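#' Rank features by the two-sample Student t-statistic
#'
#' Filter-style feature selection: every feature gets a pooled-variance
#' (equal-variance) two-sample t-statistic comparing cases against
#' controls on the training data, and features are ranked by decreasing
#' `|t|`. The ranking must come from training data only; applying it to a
#' held-out test set is the caller's responsibility (see the evaluation
#' pipeline, which carries a ranking computed on possibly pooled training
#' data over to the individual-sample test set).
#'
#' Degenerate features with zero pooled within-class variance get
#' `|t| = Inf` when the class means differ and `0` when they are equal;
#' remaining ties are broken by lower feature index, so the ranking is
#' deterministic.
#'
#' @param train An `omics_dataset` with at least 2 samples per class.
#' @return A `feature_ranking`: a tibble with columns `rank`, `feature`
#'   (column index), `name`, `statistic` (signed t, case minus control) and
#'   `abs_t`, ordered by non-increasing `abs_t`, with attribute
#'   `source_pool_size`.
#' @examples
#' set.seed(2)
#' sc <- scenario_config(label = "toy", n_features = 30, n_per_class = 10,
#'                       bio_variance = 0.2, n_markers = 5)
#' rank_by_ttest(simulate_individuals(sc))
#' @export
rank_by_ttest <- function(train) {
  stopifnot(inherits(train, "omics_dataset"))
  x <- train$values
  y <- train$labels
  n1 <- sum(y == levels(y)[1])
  n2 <- sum(y == levels(y)[2])
  if (n1 < 2L || n2 < 2L) {
    rlang::abort("each class needs >= 2 samples to compute t-statistics",
                 class = "poolsim_error_degenerate")
  }
  x1 <- x[y == levels(y)[1], , drop = FALSE]
  x2 <- x[y == levels(y)[2], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  zero <- se == 0
  if (any(zero)) {
    tstat[zero] <- ifelse(m2[zero] != m1[zero],
                          sign(m2[zero] - m1[zero]) * Inf, 0)
  }
  tstat <- unname(tstat)
  abs_t <- abs(tstat)
  ord <- order(-abs_t, seq_along(abs_t))
  out <- tibble::tibble(
    rank = seq_along(ord),
    feature = ord,
    name = colnames(x)[ord],
    statistic = tstat[ord],
    abs_t = abs_t[ord]
  )
  attr(out, "source_pool_size") <- train$pool_size
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Select the top-k features of a ranking
#'
#' Returns the first `k` feature indices of a [rank_by_ttest()] ranking.
#' Selecting all features reproduces the no-feature-selection setting.
#' Selections are nested: the top-`k1` set is a prefix of the top-`k2`
#' set whenever `k1 <= k2`.
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of features to keep, `1 <= k <= n_features`.
#' @return Integer vector of `k` feature column indices, best first.
#' @export
select_top <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(ranking)) {
    rlang::abort(
      sprintf("`k` must be between 1 and %d", nrow(ranking)),
      class = "poolsim_error_config"
    )
  }
  ranking$feature[seq_len(k)]
}
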