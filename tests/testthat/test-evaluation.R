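eval_scenario <- function(...) {
  toy_scenario(n_features = 30, n_per_class = 12, n_markers = 6, ...)
}

quick_config <- function(...) {
  args <- utils::modifyList(
    list(scenario = eval_scenario(), pool_sizes = c(1L, 2L),
         top_ks = c(5L, 30L), classifiers = c("knn", "pam"),
         n_reps = 2L, n_test = 30L, master_seed = 7L),
    list(...)
  )
  do.call(experiment_config, args)
}

test_that("experiment configs validate the pooling design", {
  expect_error(quick_config(pool_sizes = c(1, 5)),
               class = "poolsim_error_indivisible")
  expect_error(quick_config(top_ks = 31), class = "poolsim_error_config")
  expect_error(
    quick_config(cells = data.frame(classifier = "plr", pool_size = 1,
                                    top_k = 5)),
    class = "poolsim_error_config"
  )
  cfg <- quick_config()
  expect_equal(nrow(cfg$cells), 2 * 2 * 2)
})

test_that("replications are reproducible and carry their own seeds", {
  cfg <- quick_config()
  r1 <- run_replication(cfg, 1)
  r2 <- run_replication(cfg, 1)
  expect_identical(r1, r2)
  expect_true(all(r1$error_rate >= 0 & r1$error_rate <= 1))
  expect_equal(nrow(r1), 8L)
  r_other <- run_replication(cfg, 2)
  expect_false(identical(r1$error_rate, r_other$error_rate))
})

test_that("a single-cell experiment reduces to plain train/test evaluation", {
  cfg <- quick_config(pool_sizes = 1L, top_ks = 30L, classifiers = "pam",
                      n_reps = 3L)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$replicates), 3L)
  expect_equal(nrow(res$summary), 1L)
  expect_equal(res$summary$n_reps, 3L)
  # rank/tune/train on the individual data directly, same seed
  seed <- replication_seeds(cfg$master_seed, 3)[1]
  set.seed(seed)
  g <- draw_gammas(cfg$scenario)
  d <- simulate_individuals(cfg$scenario, g)
  te <- simulate_test_set(cfg$scenario, g, 30)
  feats <- select_top(rank_by_ttest(d), 30)
  tuned <- tune_by_internal_cv(classifier_spec("pam"), d, feats, 3)
  m <- train_classifier(classifier_spec("pam"), tuned$params, d, feats)
  expect_equal(res$replicates$error_rate[1],
               mean(predict(m, te) != te$labels))
})

test_that("the pool-size-1 cells match a pools-only-1 run bit for bit", {
  cfg_both <- quick_config(n_reps = 3L)
  cfg_one <- quick_config(pool_sizes = 1L, n_reps = 3L)
  both <- run_experiment(cfg_both)$replicates
  one <- run_experiment(cfg_one)$replicates
  p1 <- both[both$pool_size == 1, c("rep", "classifier", "top_k", "error_rate")]
  expect_equal(
    dplyr::arrange(p1, rep, classifier, top_k),
    dplyr::arrange(one[, c("rep", "classifier", "top_k", "error_rate")],
                   rep, classifier, top_k)
  )
})

test_that("summaries aggregate rates with normal-theory intervals", {
  reps <- tibble::tibble(
    rep = rep(1:2, each = 2),
    classifier = "knn",
    pool_size = rep(c(1L, 2L), 2),
    top_k = 10L,
    error_rate = c(0.2, 0.4, 0.3, 0.4)
  )
  s <- summarize_replicates(reps)
  expect_equal(s$mean_rate[s$pool_size == 1], 0.25)
  cell2 <- s[s$pool_size == 2, ]
  expect_equal(cell2$mean_rate, 0.4)
  expect_equal(cell2$ci_lower, 0.4)       # zero spread, zero-width interval
  expect_equal(cell2$ci_upper, 0.4)
  expect_true(all(s$ci_lower <= s$mean_rate & s$mean_rate <= s$ci_upper))
  expect_error(summarize_replicates(reps[0, ]),
               class = "poolsim_error_config")
})

test_that("Wilcoxon tables flag separated rate distributions", {
  set.seed(55)
  reps <- tibble::tibble(
    rep = rep(1:50, 2),
    classifier = "knn",
    pool_size = rep(c(1L, 5L), each = 50),
    top_k = 10L,
    error_rate = c(rnorm(50, 0.25, 0.02), rnorm(50, 0.35, 0.02))
  )
  wp <- wilcoxon_pool_sizes(reps)
  expect_equal(nrow(wp), 1L)
  expect_lt(wp$p_value, 0.05)

  same <- reps
  same$error_rate <- 0.3                   # identical constant rates
  expect_equal(wilcoxon_pool_sizes(same)$p_value, 1)

  wk <- wilcoxon_top_k(dplyr::mutate(reps, top_k = pool_size * 10L,
                                     pool_size = 1L))
  expect_equal(nrow(wk), 1L)
  expect_lt(wk$p_value, 0.05)
})

test_that("experiments archive replicates, summaries and a manifest", {
  out <- withr::local_tempdir()
  cfg <- quick_config(n_reps = 2L)
  res <- run_experiment(cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("replicates.csv", "summary.csv", "wilcoxon_pool_sizes.csv",
           "wilcoxon_top_k.csv", "manifest.json")
  ))))
  back <- utils::read.csv(file.path(out, "replicates.csv"))
  expect_equal(nrow(back), nrow(res$replicates))
  expect_equal(back$error_rate, res$replicates$error_rate)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(length(manifest$replication_seeds), 2L)
  expect_equal(manifest$replication_seeds, res$seeds)
})

test_that("tidy, glance and autoplot expose the results", {
  cfg <- quick_config(n_reps = 2L)
  res <- run_experiment(cfg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(cfg$cells))
  gl <- glance(res)
  expect_equal(gl$n_reps, 2L)
  expect_true(gl$best_classifier %in% c("knn", "pam"))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_replicate_rates(res$replicates), "ggplot")
})
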