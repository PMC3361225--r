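#' Randomly partition a training set into class-pure pools
#'
#' Builds a pooling plan: a uniformly random partition of the training
#' samples into groups of exactly `p`, pooled only within class (the class
#' of a training subject is known, so pooling within class is possible by
#' design). Only exhaustive designs are supported — `p` must divide the
#' per-class sample count; indivisible combinations are rejected rather
#' than padded.
#'
#' With `p = 1` the plan is the identity partition and consumes no random
#' numbers, so a pool-size-1 run is bitwise identical to the non-pooled
#' path.
#'
#' @param data An individual-sample `omics_dataset`.
#' @param p Pool size (number of individuals per pooled measurement).
#' @return A `pooling_plan`: list with `pool_size`, `groups` (list of
#'   sample-index vectors), and `group_class`.
#' @examples
#' set.seed(1)
#' sc <- scenario_config(label = "toy", n_features = 10, n_per_class = 6,
#'                       bio_variance = 0.2, n_markers = 2)
#' d <- simulate_individuals(sc)
#' make_pooling_plan(d, 3)
#' @export
make_pooling_plan <- function(data, p) {
  stopifnot(inherits(data, "omics_dataset"))
  p <- as.integer(p)
  if (is.na(p) || p < 1L) {
    rlang::abort("pool size `p` must be a positive integer",
                 class = "poolsim_error_config")
  }
  counts <- table(data$labels)
  if (any(counts %% p != 0L)) {
    rlang::abort(
      sprintf(
        "indivisible design: pool size %d does not divide per-class sample counts (%s)",
        p, paste(counts, collapse = ", ")
      ),
      class = "poolsim_error_indivisible"
    )
  }
  if (p == 1L) {
    groups <- as.list(seq_along(data$labels))
    group_class <- data$labels
  } else {
    groups <- list()
    group_class <- factor(character(0), levels = levels(data$labels))
    for (cl in levels(data$labels)) {
      idx <- which(data$labels == cl)
      idx <- sample(idx)                       # uniform random membership
      gs <- split(idx, rep(seq_len(length(idx) / p), each = p))
      groups <- c(groups, unname(gs))
      group_class <- c(group_class,
                       factor(rep(cl, length(gs)),
                              levels = levels(data$labels)))
    }
  }
  structure(
    list(pool_size = p, groups = groups, group_class = group_class),
    class = "pooling_plan"
  )
}

#' Pool a training set by exp-average-log with fresh technical noise
#'
#' Mimics wet-lab pooling performed before measurement: the simulated
#' log-scale biological values `z` of each group are transformed to the
#' natural scale, averaged, and transformed back,
#' `y' = log((1/p) * sum(exp(z_i))) + eps`, with one fresh technical error
#' `eps ~ N(0, tech_variance)` per pooled measurement (a pool is a single
#' experiment, so it incurs one measurement error regardless of `p`).
#' Pooling averages the noise-free biological values, not noisy
#' measurements — the pool is physically formed before the assay runs.
#'
#' With `p = 1` the input is returned unchanged (each "pool" is a single
#' individual whose measurement already exists).
#'
#' @param data Individual-sample `omics_dataset` (`pool_size` 1).
#' @param plan A [make_pooling_plan()] for `data`.
#' @param tech_variance Variance of the fresh per-pool technical error;
#'   defaults to the scenario's `tech_variance`.
#' @return An `omics_dataset` of `n / p` pooled samples with
#'   `pool_size = p`; marker bookkeeping is carried over.
#' @export
pool_dataset <- function(data, plan, tech_variance = NULL) {
  stopifnot(inherits(data, "omics_dataset"), inherits(plan, "pooling_plan"))
  if (data$pool_size != 1L) {
    rlang::abort("can only pool individual-sample datasets (pool_size 1)",
                 class = "poolsim_error_config")
  }
  p <- plan$pool_size
  if (p == 1L) return(data)
  if (length(unlist(plan$groups)) != nrow(data$values)) {
    rlang::abort("pooling plan does not cover the dataset",
                 class = "poolsim_error_corrupt_plan")
  }
  for (i in seq_along(plan$groups)) {
    g <- plan$groups[[i]]
    if (length(unique(data$labels[g])) != 1L ||
        data$labels[g][1] != plan$group_class[i]) {
      rlang::abort("corrupt plan: mixed-class pooling group",
                   class = "poolsim_error_corrupt_plan")
    }
  }
  if (is.null(tech_variance)) tech_variance <- data$scenario$tech_variance
  gid <- integer(nrow(data$values))
  for (i in seq_along(plan$groups)) gid[plan$groups[[i]]] <- i
  z_pooled <- log(rowsum(exp(data$bio), gid, reorder = TRUE) / p)
  eps <- matrix(
    stats::rnorm(length(z_pooled), 0, sqrt(tech_variance)),
    nrow = nrow(z_pooled)
  )
  values <- z_pooled + eps
  colnames(values) <- colnames(z_pooled) <- colnames(data$bio)
  new_omics_dataset(values, z_pooled, plan$group_class,
                    data$marker_indices, data$gamma_values,
                    pool_size = p, scenario = data$scenario)
}

#' Biological variance of a pooled sample
#'
#' Averaging `p` independent subjects reduces the between-subject variance
#' of the straight (arithmetic, log-scale) average from `sigma2` to
#' `sigma2 / p`. This is the reference value used by diagnostics; the
#' exp-average-log pooled values follow it closely for the small variances
#' typical of log-scale omics data.
#'
#' @param sigma2 Biological variance of an individual sample.
#' @param p Pool size.
#' @return `sigma2 / p`.
#' @export
pooled_bio_variance <- function(sigma2, p) {
  stopifnot(is.numeric(sigma2), sigma2 > 0, p >= 1)
  sigma2 / p
}

#' Empirical variance of straight-averaged pools
#'
#' Monte-Carlo check of the `sigma2 / p` law: simulates `n_pools` pools of
#' `p` independent `N(0, sigma2)` biological values and returns the
#' empirical variance of their arithmetic means.
#'
#' @param sigma2 Biological variance.
#' @param p Pool size.
#' @param n_pools Number of simulated pools.
#' @return Empirical variance (a number near `pooled_bio_variance(sigma2, p)`).
#' @export
empirical_pooled_variance <- function(sigma2, p, n_pools = 1e5) {
  draws <- matrix(stats::rnorm(p * n_pools, 0, sqrt(sigma2)), nrow = p)
  stats::var(colMeans(draws))
}
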