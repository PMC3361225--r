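#' Configure a full pooling experiment
#'
#' An experiment crosses pool sizes, top-k feature counts, and classifiers
#' over `n_reps` Monte-Carlo replications. Each replication redraws the
#' marker effect sizes, simulates one individual training set and one
#' individual test set, pools the training set at each pool size (pool
#' membership re-randomized every replication), ranks features on the
#' (pooled) training data, and for every cell tunes, trains, and scores
#' misclassification on the individual test samples.
#'
#' @param scenario A [scenario_config()], default the human preset.
#' @param pool_sizes Pool sizes to evaluate; each must divide
#'   `n_per_class`. Default `c(1, 2, 3, 5)`.
#' @param top_ks Feature counts retained after t-test ranking; the full
#'   feature count means no selection. Default `c(10, 100, 1000)`.
#' @param classifiers Character vector of [classifier_names()] and/or a
#'   list of [classifier_spec()] objects. Default: all six.
#' @param n_reps Number of replications (default 300). Reduced-replication
#'   runs are first-class: the default is a convention, not a structural
#'   constant, and the Monte-Carlo standard error of a cell mean scales as
#'   `sd / sqrt(n_reps)` (roughly `0.04 / sqrt(n_reps)` in the presets).
#' @param n_test Individual test samples per replication (default 450).
#' @param cv_folds Internal CV folds for tuning (default 3).
#' @param master_seed Integer master seed; spawns one seed per replication
#'   so any replication is reproducible in isolation.
#' @param cells Optional tibble with columns `classifier`, `pool_size`,
#'   `top_k` restricting the evaluated cells to a subset of the full
#'   cross (used to reproduce selected table cells without paying for the
#'   whole grid).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(scenario = scenario_preset("human"),
                              pool_sizes = c(1L, 2L, 3L, 5L),
                              top_ks = c(10L, 100L, 1000L),
                              classifiers = classifier_names(),
                              n_reps = 300L,
                              n_test = 450L,
                              cv_folds = 3L,
                              master_seed = 1L,
                              cells = NULL) {
  validate_scenario_config(scenario)
  pool_sizes <- sort(unique(as.integer(pool_sizes)))
  top_ks <- unique(as.integer(top_ks))
  if (any(pool_sizes < 1L)) {
    rlang::abort("pool sizes must be positive", class = "poolsim_error_config")
  }
  bad <- pool_sizes[scenario$n_per_class %% pool_sizes != 0L]
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("pool size(s) %s do not divide n_per_class = %d (designs must satisfy n = p * m)",
              paste(bad, collapse = ", "), scenario$n_per_class),
      class = "poolsim_error_indivisible"
    )
  }
  if (any(top_ks < 1L | top_ks > scenario$n_features)) {
    rlang::abort("`top_ks` must lie in 1..n_features",
                 class = "poolsim_error_config")
  }
  specs <- normalize_classifiers(classifiers)
  full <- tidyr::expand_grid(
    classifier = names(specs), pool_size = pool_sizes, top_k = top_ks
  )
  if (is.null(cells)) {
    cells <- full
  } else {
    cells <- dplyr::distinct(
      tibble::as_tibble(cells)[, c("classifier", "pool_size", "top_k")]
    )
    unknown <- dplyr::anti_join(cells, full,
                                by = c("classifier", "pool_size", "top_k"))
    if (nrow(unknown) > 0) {
      rlang::abort("`cells` contains combinations outside the configured grid",
                   class = "poolsim_error_config")
    }
  }
  structure(
    list(
      scenario = scenario, pool_sizes = pool_sizes, top_ks = top_ks,
      classifier_specs = specs, n_reps = as.integer(n_reps),
      n_test = as.integer(n_test), cv_folds = as.integer(cv_folds),
      master_seed = as.integer(master_seed), cells = cells
    ),
    class = "experiment_config"
  )
}

normalize_classifiers <- function(classifiers) {
  if (is.character(classifiers)) {
    classifiers <- lapply(classifiers, classifier_spec)
  }
  if (inherits(classifiers, "classifier_spec")) classifiers <- list(classifiers)
  stopifnot(all(vapply(classifiers, inherits, logical(1), "classifier_spec")))
  stats::setNames(classifiers, vapply(classifiers, `[[`, character(1), "name"))
}

#' Per-replication seeds spawned from the master seed
#'
#' @param master_seed Integer master seed.
#' @param n_reps Number of replications.
#' @return Integer vector of `n_reps` seeds. The global random state is
#'   restored afterwards.
#' @export
replication_seeds <- function(master_seed, n_reps) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  )
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n_reps)
}

#' Run one replication of the experiment
#'
#' Executes simulate -> pool -> rank -> tune -> train -> test for every
#' configured cell, entirely under the replication's own seed: the same
#' config, master seed, and replication index always reproduce the same
#' rates bit for bit.
#'
#' @param config An [experiment_config()].
#' @param rep_index Replication number (1-based).
#' @param seed Seed for this replication; defaults to the `rep_index`-th
#'   seed spawned by [replication_seeds()].
#' @return Tibble with one row per cell: `rep`, `classifier`, `pool_size`,
#'   `top_k`, `error_rate`, `chosen_params`, `seed`.
#' @export
run_replication <- function(config, rep_index,
                            seed = replication_seeds(config$master_seed,
                                                     config$n_reps)[rep_index]) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed)
  scenario <- config$scenario
  gammas <- draw_gammas(scenario)
  train_ind <- simulate_individuals(scenario, gammas)
  test <- simulate_test_set(scenario, gammas, config$n_test)
  truth <- test$labels
  rows <- list()
  for (p in sort(unique(config$cells$pool_size))) {
    plan <- make_pooling_plan(train_ind, p)
    train <- pool_dataset(train_ind, plan)
    ranking <- rank_by_ttest(train)
    cells_p <- config$cells[config$cells$pool_size == p, ]
    for (k in config$top_ks[config$top_ks %in% cells_p$top_k]) {
      feats <- select_top(ranking, k)
      for (nm in names(config$classifier_specs)) {
        if (!any(cells_p$top_k == k & cells_p$classifier == nm)) next
        spec <- config$classifier_specs[[nm]]
        tuned <- tune_by_internal_cv(spec, train, feats, config$cv_folds)
        model <- train_classifier(spec, tuned$params, train, feats)
        rate <- mean(predict(model, test) != truth)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = rep_index, classifier = nm, pool_size = p, top_k = k,
          error_rate = rate,
          chosen_params = paste(names(tuned$params),
                                unlist(tuned$params),
                                sep = "=", collapse = ";"),
          seed = seed
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full experiment
#'
#' Runs all replications, aggregates per-cell mean misclassification rates
#' with normal-approximation 95% confidence intervals, and computes
#' two-sided Wilcoxon rank-sum comparisons between pool sizes (per
#' classifier and top-k) and between top-k settings (per classifier and
#' pool size). Optionally writes `replicates.csv`, `summary.csv`,
#' `wilcoxon_pool_sizes.csv`, `wilcoxon_top_k.csv` and a reproducibility
#' manifest to `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @param verbose Print per-replication progress.
#' @return A `pool_experiment`: list with `config`, `replicates`,
#'   `summary`, `wilcoxon_pool_sizes`, `wilcoxon_top_k`, `seeds`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- replication_seeds(config$master_seed, config$n_reps)
  replicates <- purrr::map_dfr(seq_len(config$n_reps), function(i) {
    if (verbose) {
      message(sprintf("replication %d/%d", i, config$n_reps))
    }
    run_replication(config, i, seed = seeds[i])
  })
  out <- structure(
    list(
      config = config,
      replicates = replicates,
      summary = summarize_replicates(replicates),
      wilcoxon_pool_sizes = wilcoxon_pool_sizes(replicates),
      wilcoxon_top_k = wilcoxon_top_k(replicates),
      seeds = seeds
    ),
    class = "pool_experiment"
  )
  if (!is.null(out_dir)) {
    write_experiment(out, out_dir)
  }
  out
}

#' Aggregate replicate misclassification rates per cell
#'
#' @param replicates Tibble of replicate results (from
#'   [run_replication()]/[run_experiment()]) with columns `classifier`,
#'   `pool_size`, `top_k`, `error_rate`.
#' @return Tibble with per-cell `n_reps`, `mean_rate`, `sd_rate` and the
#'   normal-approximation 95% confidence interval
#'   (`mean +- 1.96 * sd / sqrt(n)`).
#' @export
summarize_replicates <- function(replicates) {
  if (nrow(replicates) == 0) {
    rlang::abort("no replicate results to summarize",
                 class = "poolsim_error_config")
  }
  replicates |>
    dplyr::group_by(.data$classifier, .data$pool_size, .data$top_k) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_rate = mean(.data$error_rate),
      sd_rate = stats::sd(.data$error_rate),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = dplyr::if_else(.data$n_reps > 1,
                          .data$sd_rate / sqrt(.data$n_reps), 0),
      ci_lower = .data$mean_rate - 1.96 * .data$se,
      ci_upper = .data$mean_rate + 1.96 * .data$se
    ) |>
    dplyr::select(-"se")
}

pairwise_wilcoxon <- function(replicates, compare, within) {
  groups <- dplyr::distinct(replicates[, within, drop = FALSE])
  purrr::pmap_dfr(groups, function(...) {
    g <- list(...)
    sub <- replicates
    for (v in within) sub <- sub[sub[[v]] == g[[v]], ]
    lvls <- sort(unique(sub[[compare]]))
    if (length(lvls) < 2) return(tibble::tibble())
    pairs <- utils::combn(lvls, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      xa <- sub$error_rate[sub[[compare]] == pr[1]]
      xb <- sub$error_rate[sub[[compare]] == pr[2]]
      p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      if (is.nan(p)) p <- 1       # identical constant samples
      tibble::tibble(!!!g,
                     a = pr[1], b = pr[2], p_value = p)
    })
  })
}

#' Wilcoxon rank-sum comparisons between pool sizes
#'
#' Two-sided rank-sum test of the replicate misclassification rates for
#' every pair of pool sizes, separately per classifier and top-k. Raw
#' p-values, no multiplicity correction (significance is reported as-is,
#' star-style).
#'
#' @inheritParams summarize_replicates
#' @return Tibble: `classifier`, `top_k`, `a`, `b` (pool sizes), `p_value`.
#' @export
wilcoxon_pool_sizes <- function(replicates) {
  out <- pairwise_wilcoxon(replicates, "pool_size",
                           c("classifier", "top_k"))
  if (nrow(out) > 0) {
    out <- dplyr::rename(out, pool_a = "a", pool_b = "b")
  }
  out
}

#' Wilcoxon rank-sum comparisons between feature-selection settings
#'
#' @inheritParams summarize_replicates
#' @return Tibble: `classifier`, `pool_size`, `a`, `b` (top-k values),
#'   `p_value`.
#' @export
wilcoxon_top_k <- function(replicates) {
  out <- pairwise_wilcoxon(replicates, "top_k",
                           c("classifier", "pool_size"))
  if (nrow(out) > 0) {
    out <- dplyr::rename(out, top_k_a = "a", top_k_b = "b")
  }
  out
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$replicates, file.path(out_dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(x$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(x$wilcoxon_pool_sizes,
                   file.path(out_dir, "wilcoxon_pool_sizes.csv"),
                   row.names = FALSE)
  utils::write.csv(x$wilcoxon_top_k,
                   file.path(out_dir, "wilcoxon_top_k.csv"),
                   row.names = FALSE)
  emit_manifest(x$config, out_dir)
  invisible(out_dir)
}

#' @export
print.pool_experiment <- function(x, ...) {
  cat(sprintf(
    "<pool_experiment> %s scenario, %d replications, %d cells\n",
    x$config$scenario$label, x$config$n_reps, nrow(x$config$cells)
  ))
  print(x$summary, n = 12)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-cell summary of an experiment
#'
#' @param x A `pool_experiment`.
#' @param ... Unused.
#' @return The per-cell summary tibble (one row per
#'   classifier x pool size x top-k).
#' @method tidy pool_experiment
#' @export
tidy.pool_experiment <- function(x, ...) x$summary

#' One-row overview of an experiment
#'
#' @param x A `pool_experiment`.
#' @param ... Unused.
#' @return Tibble with scenario label, replication count, cell count, and
#'   the best (lowest mean error) cell.
#' @method glance pool_experiment
#' @export
glance.pool_experiment <- function(x, ...) {
  best <- x$summary[which.min(x$summary$mean_rate), ]
  tibble::tibble(
    scenario = x$config$scenario$label,
    n_reps = x$config$n_reps,
    n_cells = nrow(x$config$cells),
    n_test = x$config$n_test,
    best_classifier = best$classifier,
    best_pool_size = best$pool_size,
    best_top_k = best$top_k,
    best_mean_rate = best$mean_rate
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean misclassification against pool size
#'
#' One line per classifier, faceted by the number of selected features,
#' with 95% confidence-interval error bars — the standard way to read a
#' pooling experiment: flat lines mean pooling is cheap, steep lines mean
#' the design is paying for it.
#'
#' @param object A `pool_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pool_experiment
#' @export
autoplot.pool_experiment <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = factor(.data$pool_size), y = .data$mean_rate,
                 colour = .data$classifier, group = .data$classifier)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~top_k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "pool size", y = "mean misclassification rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate-rate distributions per cell
#'
#' @param replicates Replicate tibble from [run_experiment()].
#' @return A ggplot object (boxplots of replicate rates by pool size and
#'   classifier, faceted by top-k).
#' @export
plot_replicate_rates <- function(replicates) {
  ggplot2::ggplot(
    replicates,
    ggplot2::aes(x = factor(.data$pool_size), y = .data$error_rate,
                 fill = .data$classifier)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~top_k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "pool size", y = "misclassification rate",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
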