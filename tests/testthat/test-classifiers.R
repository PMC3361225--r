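test_that("shrunken centroids match the soft-threshold construction", {
  # single feature, hand-evaluated: controls (0, 0.2), cases (1, 1.2)
  x <- matrix(c(0, 0.2, 1, 1.2), ncol = 1)
  y <- factor(c("control", "control", "case", "case"),
              levels = c("control", "case"))

  # independent arithmetic oracle
  s <- sqrt((0.02 + 0.02) / 2)          # pooled within-class sd
  s0 <- s                                # median over one feature
  mk <- sqrt(1 / 2 - 1 / 4)
  d_ctrl <- (0.1 - 0.6) / (mk * (s + s0))
  d_shrunk <- sign(d_ctrl) * max(abs(d_ctrl) - 0.5, 0)
  cent_ctrl <- 0.6 + mk * (s + s0) * d_shrunk

  m <- nsc_shrink_centroids(x, y, delta = 0.5)
  expect_equal(unname(m$centroids[1, 1]), cent_ctrl, tolerance = 1e-10)
  expect_equal(unname(m$centroids[2, 1]), 2 * 0.6 - cent_ctrl,
               tolerance = 1e-10)

  # no shrinkage reproduces the raw class means
  m0 <- nsc_shrink_centroids(x, y, delta = 0)
  expect_equal(unname(m0$centroids[, 1]), c(0.1, 1.1), tolerance = 1e-10)
  expect_error(nsc_shrink_centroids(x, y, delta = -1),
               class = "poolsim_error_config")
})

test_that("total shrinkage collapses centroids and predicts the tie class", {
  set.seed(41)
  d <- separated_dataset(n_per_class = 8, gap = 1)
  m <- nsc_shrink_centroids(d$values, d$labels, delta = 1e6)
  expect_equal(nsc_surviving_features(m), 0L)
  expect_equal(unname(m$centroids[1, ]), unname(m$centroids[2, ]))
  pred <- poolsim:::nsc_predict(m, d$values)
  expect_true(all(pred == "control"))
})

test_that("feature survival is non-increasing in the shrinkage threshold", {
  set.seed(42)
  d <- simulate_individuals(toy_scenario(n_per_class = 15))
  surv <- vapply(c(0, 0.1, 0.25, 0.5, 1, 2, 5), function(delta) {
    nsc_surviving_features(
      nsc_shrink_centroids(d$values, d$labels, delta)
    )
  }, integer(1))
  expect_true(all(diff(surv) <= 0))
  expect_equal(surv[1], 40L)
})

test_that("nearest-centroid predictions match hand-computed distances", {
  # centroids engineered at (0,0) and (1,1); unit within-class sd scale
  xtr <- rbind(c(-0.5, 0.5), c(0.5, -0.5), c(0.5, 1.5), c(1.5, 0.5))
  ytr <- factor(c("control", "control", "case", "case"),
                levels = c("control", "case"))
  m <- nsc_shrink_centroids(xtr, ytr, delta = 0)
  xte <- rbind(c(0.1, 0.1), c(0.9, 0.9), c(0.5, 0.5))
  pred <- poolsim:::nsc_predict(m, xte)
  # (0.5, 0.5) is equidistant: tie resolves to the first level
  expect_equal(as.character(pred), c("control", "case", "control"))
})

test_that("k-NN follows Euclidean votes with the nearest-neighbour tie rule", {
  set.seed(43)
  d <- separated_dataset(n_per_class = 6)
  spec <- classifier_spec("knn")

  m1 <- train_classifier(spec, list(k = 1), d, 1:2)
  expect_equal(mean(predict(m1, d) != d$labels), 0)  # self-neighbour

  # k = n on balanced data: every vote ties, nearest neighbour decides
  mall <- train_classifier(spec, list(k = 12), d, 1:2)
  expect_equal(predict(mall, d), predict(m1, d))
})

test_that("a large-margin linear SVM separates a separable toy set", {
  set.seed(44)
  d <- separated_dataset(n_per_class = 10)
  m <- train_classifier(classifier_spec("svm_linear"), list(cost = 500), d, 1:2)
  expect_equal(mean(predict(m, d) != d$labels), 0)
})

test_that("ridge logistic coefficients shrink with the penalty", {
  set.seed(45)
  d <- simulate_individuals(toy_scenario(n_per_class = 20))
  spec <- classifier_spec("plr")
  norms <- vapply(c(0.0625, 1, 16), function(lam) {
    m <- train_classifier(spec, list(lambda = lam), d, 1:40)
    sum(as.numeric(glmnet::coef.glmnet(m$fit$glmnet, s = m$fit$s))[-1]^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("deterministic classifiers repeat exactly; the forest repeats under a seed", {
  set.seed(46)
  sc <- toy_scenario(n_per_class = 12)
  d <- simulate_individuals(sc)
  te <- simulate_test_set(sc, d$gamma_values, 30)
  cases <- list(
    list("knn", list(k = 3)),
    list("svm_linear", list(cost = 10)),
    list("svm_radial", list(cost = 10, gamma = 0.25)),
    list("plr", list(lambda = 1)),
    list("pam", list(delta = 0.5))
  )
  for (cs in cases) {
    spec <- classifier_spec(cs[[1]])
    p1 <- predict(train_classifier(spec, cs[[2]], d, 1:40), te)
    p2 <- predict(train_classifier(spec, cs[[2]], d, 1:40), te)
    expect_identical(p1, p2)
  }
  rf <- classifier_spec("random_forest", fixed = list(num_trees = 100))
  set.seed(5); q1 <- predict(train_classifier(rf, list(mtry = 4), d, 1:40), te)
  set.seed(5); q2 <- predict(train_classifier(rf, list(mtry = 4), d, 1:40), te)
  expect_identical(q1, q2)
})

test_that("every classifier beats chance on marker-bearing data", {
  set.seed(47)
  sc <- scenario_config(label = "small", n_features = 100, n_per_class = 30,
                        bio_variance = 0.2, tech_variance = 0.04,
                        n_markers = 10)
  g <- draw_gammas(sc)
  d <- simulate_individuals(sc, g)
  te <- simulate_test_set(sc, g, 200)
  feats <- select_top(rank_by_ttest(d), 20)
  cases <- list(
    svm_linear = list(cost = 10),
    svm_radial = list(cost = 10, gamma = 0.25),
    random_forest = list(mtry = 4),
    knn = list(k = 5),
    plr = list(lambda = 1),
    pam = list(delta = 0.5)
  )
  for (nm in names(cases)) {
    spec <- classifier_spec(nm, fixed = list(num_trees = 300))
    m <- train_classifier(spec, cases[[nm]], d, feats)
    expect_lt(mean(predict(m, te) != te$labels), 0.45)
  }
})

test_that("label permutation drives accuracy to chance", {
  set.seed(48)
  sc <- scenario_config(label = "null", n_features = 100, n_per_class = 20,
                        bio_variance = 0.2, tech_variance = 0.04,
                        n_markers = 10)
  rates <- replicate(8, {
    g <- draw_gammas(sc)
    d <- simulate_individuals(sc, g)
    d$labels <- sample(d$labels)          # break the label-feature link
    te <- simulate_test_set(sc, g, 100)
    feats <- select_top(rank_by_ttest(d), 10)
    m <- train_classifier(classifier_spec("pam"), list(delta = 0.5), d, feats)
    mean(predict(m, te) != te$labels)
  })
  expect_lt(abs(mean(rates) - 0.5), 0.1)
})

test_that("prediction demands the training features", {
  set.seed(49)
  d <- simulate_individuals(toy_scenario())
  m <- train_classifier(classifier_spec("knn"), list(k = 3), d, 35:40)
  expect_error(predict(m, d$values[, 1:10]), class = "poolsim_error_config")
  expect_error(train_classifier(classifier_spec("knn"), list(k = 3), d,
                                integer(0)),
               class = "poolsim_error_config")
})
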