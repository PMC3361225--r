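#' @keywords internal
new_omics_dataset <- function(values, bio, labels, marker_indices,
                              gamma_values, pool_size, scenario) {
  stopifnot(
    is.matrix(values), is.matrix(bio),
    nrow(values) == length(labels),
    all(dim(values) == dim(bio)),
    length(gamma_values) == length(marker_indices)
  )
  structure(
    list(
      values = values,
      bio = bio,
      labels = labels,
      marker_indices = as.integer(marker_indices),
      gamma_values = as.numeric(gamma_values),
      pool_size = as.integer(pool_size),
      scenario = scenario
    ),
    class = "omics_dataset"
  )
}

class_levels <- function() c("control", "case")

#' Draw marker effect sizes for one replication
#'
#' Effect sizes are drawn independently from
#' `U(gamma_low, gamma_high)`, one per marker feature. A fresh draw is
#' intended per simulation replication, shared between that replication's
#' training and test sets.
#'
#' @param scenario A [scenario_config()].
#' @return Numeric vector of length `n_markers` (length 0 when the scenario
#'   has no markers). Uses the current R random stream; call `set.seed()`
#'   upstream for reproducibility.
#' @examples
#' set.seed(1)
#' draw_gammas(scenario_preset("human"))
#' @export
draw_gammas <- function(scenario) {
  validate_scenario_config(scenario)
  if (scenario$n_markers == 0L) return(numeric(0))
  stats::runif(scenario$n_markers, scenario$gamma_low, scenario$gamma_high)
}

simulate_dataset <- function(scenario, gammas, n_control, n_case, pool_size = 1L) {
  validate_scenario_config(scenario)
  if (length(gammas) != scenario$n_markers) {
    rlang::abort(
      sprintf("expected %d effect sizes, got %d",
              scenario$n_markers, length(gammas)),
      class = "poolsim_error_config"
    )
  }
  n <- n_control + n_case
  a <- scenario$n_features
  z <- matrix(stats::rnorm(n * a, mean = 0, sd = sqrt(scenario$bio_variance)),
              nrow = n, ncol = a)
  markers <- seq_len(scenario$n_markers)
  if (scenario$n_markers > 0L && n_case > 0L) {
    case_rows <- seq.int(n_control + 1L, n)
    z[case_rows, markers] <- z[case_rows, markers, drop = FALSE] +
      matrix(gammas, nrow = n_case, ncol = length(markers), byrow = TRUE)
  }
  eps <- matrix(stats::rnorm(n * a, mean = 0, sd = sqrt(scenario$tech_variance)),
                nrow = n, ncol = a)
  values <- z + eps
  colnames(values) <- colnames(z) <- paste0("f", seq_len(a))
  labels <- factor(rep(class_levels(), c(n_control, n_case)),
                   levels = class_levels())
  new_omics_dataset(values, z, labels, markers, gammas, pool_size, scenario)
}

#' Simulate an individual-sample training set
#'
#' Generates a balanced two-class dataset of `2 * n_per_class` individual
#' samples under the scenario's generative model. For every feature the
#' biological value is `N(0, bio_variance)` in controls; in cases, marker
#' features get their class mean shifted by the feature's effect size.
#' Each measured value is the biological value plus technical noise
#' `N(0, tech_variance)`. Marker features occupy the first `n_markers`
#' feature columns (positions carry no meaning in the model; fixed indices
#' keep the bookkeeping deterministic). Biological values are retained
#' internally alongside the measured matrix because pooling operates on
#' them (see [pool_dataset()]).
#'
#' @param scenario A [scenario_config()].
#' @param gammas Marker effect sizes, typically from [draw_gammas()].
#' @return An `omics_dataset` with `pool_size = 1`.
#' @examples
#' set.seed(7)
#' sc <- scenario_config(label = "toy", n_features = 20, n_per_class = 5,
#'                       bio_variance = 0.2, n_markers = 3)
#' d <- simulate_individuals(sc, draw_gammas(sc))
#' dim(d$values)
#' @export
simulate_individuals <- function(scenario, gammas = draw_gammas(scenario)) {
  simulate_dataset(scenario, gammas,
                   n_control = scenario$n_per_class,
                   n_case = scenario$n_per_class)
}

#' Simulate an individual-sample test set
#'
#' Test samples are always individual (never pooled): in practice a trained
#' classifier is applied to single future subjects, whose class is unknown
#' and who therefore cannot be pooled. The test set shares the training
#' set's marker effect sizes and is balanced (controls get the extra sample
#' when `n_test` is odd).
#'
#' @param scenario A [scenario_config()].
#' @param gammas The same effect sizes used for the paired training set.
#' @param n_test Number of test samples (default 450).
#' @return An `omics_dataset` with `pool_size = 1`.
#' @export
simulate_test_set <- function(scenario, gammas = draw_gammas(scenario),
                              n_test = 450L) {
  n_test <- as.integer(n_test)
  if (is.na(n_test) || n_test <= 0L) {
    rlang::abort("`n_test` must be a positive integer",
                 class = "poolsim_error_config")
  }
  n_control <- as.integer(ceiling(n_test / 2))
  simulate_dataset(scenario, gammas,
                   n_control = n_control, n_case = n_test - n_control)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(
    "<omics_dataset> %d samples x %d features (%s), pool size %d, %d markers\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%d %s", as.vector(table(x$labels)), levels(x$labels)),
          collapse = ", "),
    x$pool_size, length(x$marker_indices)
  ))
  invisible(x)
}

#' Convert a dataset to a tibble
#'
#' One row per sample: the measured feature columns followed by a `label`
#' column. Handy for piping into dplyr/ggplot2.
#'
#' @param x An `omics_dataset`.
#' @param ... Unused.
#' @return A tibble with `n_samples` rows and `n_features + 1` columns.
#' @importFrom tibble as_tibble
#' @method as_tibble omics_dataset
#' @export
as_tibble.omics_dataset <- function(x, ...) {
  out <- tibble::as_tibble(x$values)
  out$label <- x$labels
  out
}

#' Write a dataset to a delimited text file
#'
#' Writes the measured sample-by-feature matrix with a header row of
#' feature IDs and a final `label` column, tab-separated. Optionally also
#' writes the noise-free biological values to a companion file; the
#' biological values are what [pool_dataset()] averages, so the companion
#' file is required to pool a previously dumped dataset from the command
#' line.
#'
#' @param data An `omics_dataset`.
#' @param path Output path for the measured values.
#' @param bio_path Optional path for the biological (pre-noise) values.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, bio_path = NULL) {
  stopifnot(inherits(data, "omics_dataset"))
  df <- as.data.frame(data$values)
  df$label <- as.character(data$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bio_path)) {
    bf <- as.data.frame(data$bio)
    bf$label <- as.character(data$labels)
    utils::write.table(bf, bio_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a dumped dataset back into an `omics_dataset`
#'
#' Counterpart of [write_dataset()]. Marker bookkeeping is not stored in
#' the dump, so `marker_indices`/`gamma_values` are empty unless a
#' scenario is supplied (in which case the first `n_markers` columns are
#' assumed, matching the generator's placement).
#'
#' @param path Measured-values file written by [write_dataset()].
#' @param bio_path Optional companion file of biological values; when
#'   absent, the measured values stand in (pooling such data conflates
#'   technical noise into the pooled average).
#' @param scenario Optional [scenario_config()] used for marker bookkeeping.
#' @param pool_size Pool size to record (1 for individual samples).
#' @return An `omics_dataset`.
#' @export
read_dataset <- function(path, bio_path = NULL, scenario = NULL,
                         pool_size = 1L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  labels <- factor(df$label, levels = class_levels())
  values <- as.matrix(df[setdiff(names(df), "label")])
  bio <- values
  if (!is.null(bio_path)) {
    bf <- utils::read.table(bio_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    bio <- as.matrix(bf[setdiff(names(bf), "label")])
  }
  markers <- integer(0)
  gammas <- numeric(0)
  if (!is.null(scenario)) {
    markers <- seq_len(scenario$n_markers)
    gammas <- rep(NA_real_, scenario$n_markers)
  }
  new_omics_dataset(values, bio, labels, markers, gammas, pool_size,
                    scenario)
}
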