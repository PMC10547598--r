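# feature rows derived directly from the anchor palette (fast stand-in for
# the imaging stages when testing model behaviour alone)
palette_features <- function(scores, noise_sd = 5, seed = 1) {
  set.seed(seed)
  X <- t(vapply(scores, colour_score_to_rgb, numeric(3)))
  X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow(X))
  colnames(X) <- c("r", "g", "b")
  X
}

test_that("floor-allocation split reproduces the published 91/38/23 counts", {
  parts <- split_dataset(152, c(0.60, 0.25, 0.15), seed = 1)
  expect_identical(lengths(parts), c(91L, 38L, 23L))
  parts2 <- split_dataset(100, c(0.8, 0.2), seed = 1)
  expect_identical(lengths(parts2), c(80L, 20L))
  # disjoint, exhaustive, deterministic
  expect_identical(sort(unlist(parts)), 1:152)
  expect_identical(split_dataset(152, c(0.60, 0.25, 0.15), seed = 1), parts)
  expect_false(identical(split_dataset(152, c(0.6, 0.25, 0.15), seed = 2), parts))
  expect_error(split_dataset(2, c(0.4, 0.3, 0.3)), class = "rootsense_input_error")
  expect_error(split_dataset(10, c(0.6, 0.3)), class = "rootsense_input_error")
})

test_that("regression metrics match definitional arithmetic", {
  expect_equal(regression_metrics(1:5, 1:5), list(mae = 0, mse = 0, r2 = 1))
  # hand arithmetic: y=(0,10), yhat=(1,9)
  m <- regression_metrics(c(0, 10), c(1, 9))
  expect_equal(m$mae, 1); expect_equal(m$mse, 1)
  expect_equal(m$r2, 1 - 2 / 50)
  y <- c(2, 4, 9)
  m2 <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(m2$r2, 0)
  expect_error(regression_metrics(c(3, 3), c(1, 2)),
               class = "rootsense_undefined_error")
  # random vectors vs brute-force oracle to 1e-12
  set.seed(6)
  for (i in 1:10) {
    n <- sample(3:50, 1)
    y <- runif(n, 0, 10); yh <- y + rnorm(n)
    got <- regression_metrics(y, yh)
    ref <- regression_metrics_ref(y, yh)
    expect_equal(got$mae, ref$mae, tolerance = 1e-12)
    expect_equal(got$mse, ref$mse, tolerance = 1e-12)
    expect_equal(got$r2, ref$r2, tolerance = 1e-12)
  }
})

test_that("classification metrics match definitional counts", {
  y <- c(0, 0, 0)
  expect_equal(classification_metrics(y, y)$f1, 1)
  # one-vs-rest for class 8: TP=3, FP=1, FN=2
  y2 <- c(8, 8, 8, 8, 8, 0, 0)
  yh2 <- c(8, 8, 8, 0, 0, 8, 0)
  pc <- classification_metrics(y2, yh2)$per_class
  row8 <- pc[pc$class == 8, ]
  expect_equal(row8$precision, 0.75)
  expect_equal(row8$recall, 0.6)
  expect_equal(row8$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  # all-one-class predictions: that class's precision equals its prevalence
  y3 <- c(0, 0, 1, 3, 3, 3)
  yh3 <- rep(3, 6)
  pc3 <- classification_metrics(y3, yh3)$per_class
  expect_equal(pc3$precision[pc3$class == 3], 0.5)
  # classes absent from both y and yhat are excluded from the macro mean
  expect_identical(nrow(pc3), 3L)
  expect_error(classification_metrics(numeric(0), numeric(0)),
               class = "rootsense_input_error")
})

test_that("linear regression recovers exact linear structure", {
  set.seed(2)
  X <- matrix(runif(120, 0, 10), ncol = 3)
  y <- 2.5 + X %*% c(1.5, -0.5, 3)
  m <- train_regressor(X, as.numeric(y), model_config("linear"))
  expect_equal(unname(m$fit$coef), c(2.5, 1.5, -0.5, 3), tolerance = 1e-8)
  expect_equal(regression_metrics(as.numeric(y), predict(m, X))$r2, 1,
               tolerance = 1e-12)
})

test_that("constant targets give constant predictions for every family", {
  set.seed(3)
  X <- matrix(runif(90, 0, 255), ncol = 3)
  y <- rep(4.2, 30)
  for (fam in c("linear", "knn", "decision_tree", "random_forest",
                "gradient_boosting", "svm")) {
    m <- train_regressor(X, y, model_config(fam, seed = 1))
    expect_equal(predict(m, X), y, tolerance = 1e-6,
                 label = paste(fam, "train predictions"))
  }
})

test_that("an unlimited-depth tree memorizes its training rows", {
  set.seed(4)
  X <- matrix(runif(60, 0, 255), ncol = 3)
  y <- runif(20, 0, 10)
  m <- train_regressor(X, y, model_config("decision_tree"))
  expect_equal(predict(m, X), y, tolerance = 1e-12)
})

test_that("SVR and KNN fit smooth structure sensibly", {
  scores <- seq(0.2, 9.8, length.out = 80)
  X <- palette_features(scores, noise_sd = 3, seed = 5)
  te <- seq(4, 80, by = 4); tr <- setdiff(1:80, te)
  for (fam in c("svm", "knn")) {
    m <- train_regressor(X[tr, ], scores[tr], model_config(fam))
    r2 <- regression_metrics(scores[te], predict(m, X[te, ]))$r2
    expect_gt(r2, 0.9)
  }
})

test_that("training is deterministic at the prediction level", {
  scores <- runif(40, 0, 10)
  X <- palette_features(scores, seed = 7)
  for (fam in c("random_forest", "gradient_boosting", "neural_net")) {
    cfg <- if (fam == "neural_net") {
      model_config(fam, seed = 3, epochs = 150L)
    } else model_config(fam, seed = 3, n_estimators = 15L)
    m1 <- train_regressor(X, scores, cfg)
    m2 <- train_regressor(X, scores, cfg)
    Xnew <- palette_features(runif(10, 0, 10), seed = 8)
    expect_identical(predict(m1, Xnew), predict(m2, Xnew))
  }
})

test_that("input validation catches shape and finiteness problems", {
  X <- matrix(1:12, 4)
  expect_error(train_regressor(X, 1:3, model_config("linear")),
               class = "rootsense_input_error")
  X2 <- X; X2[1] <- NA
  expect_error(train_regressor(X2, 1:4, model_config("linear")),
               class = "rootsense_input_error")
  expect_error(model_config("linear", bogus = 1),
               class = "rootsense_config_error")
  expect_error(model_config("svm", task = "classification"),
               class = "rootsense_config_error")
})

test_that("NN early stopping halts at epoch 101 under constant validation MAE", {
  set.seed(9)
  X <- matrix(runif(150, 0, 10), ncol = 3)
  y <- runif(50, 0, 10)
  m <- rootsense:::fit_mlp(X, y, epochs = 5000L, seed = 1,
                           val_mae_fn = function(ep) 1.0)
  expect_identical(m$log$stop_epoch, 101L)
  # an improvement over the best of exactly min_delta does NOT reset patience
  # (strict >); a binary-representable delta keeps the boundary exact
  m2 <- rootsense:::fit_mlp(X, y, epochs = 5000L, seed = 1, min_delta = 0.25,
                            val_mae_fn = function(ep) if (ep == 1) 1 else 0.75)
  expect_identical(m2$log$stop_epoch, 101L)
  # a strictly larger improvement does reset it
  m3 <- rootsense:::fit_mlp(X, y, epochs = 5000L, seed = 1, min_delta = 0.25,
                            val_mae_fn = function(ep) {
                              if (ep == 1) 1 else if (ep == 100) 0.4 else 0.75
                            })
  expect_identical(m3$log$stop_epoch, 200L)
})

test_that("NN training reduces validation MAE on linear data", {
  scores <- runif(60, 0, 10)
  X <- palette_features(scores, noise_sd = 2, seed = 10)
  m <- train_nn_with_early_stopping(X, scores,
                                    model_config("neural_net", seed = 2,
                                                 epochs = 800L))
  log <- m$fit$log
  expect_lt(log$val_mae[log$stop_epoch], log$val_mae[1])
  expect_lte(log$stop_epoch, 800L)
  expect_error(train_nn_with_early_stopping(X[1:5, ], scores[1:5]),
               class = "rootsense_input_error")
})

test_that("cross_validate partitions samples into balanced folds", {
  scores <- runif(100, 0, 10)
  X <- palette_features(scores, seed = 11)
  cv <- cross_validate(X, scores, model_config("linear"), folds = 5, seed = 1)
  expect_identical(length(cv$reports), 5L)
  expect_true(all(vapply(cv$reports, function(r) r$n_test, numeric(1)) == 20))
  expect_identical(sort(unique(cv$fold_assignment)), 1:5)
  expect_identical(length(cv$fold_assignment), 100L)
  expect_gt(cv$summary$mean["r2"], 0.9)
  expect_error(cross_validate(X[1:3, ], scores[1:3], model_config("linear"),
                              folds = 5), class = "rootsense_input_error")
})

test_that("label policy: mean for regression, lower-code mode for classes", {
  expect_equal(label_policy(c(7, 9), "mean"), 8)
  expect_identical(label_policy(c(8, 8, 5), "mode"), 8)
  expect_identical(label_policy(c(5, 8), "mode"), 5)  # tie -> lower code
  expect_error(label_policy(numeric(0)), class = "rootsense_empty_error")
})

test_that("error analysis reproduces published worked rows", {
  truths <- data.frame(
    variety_name = c("C_P_UGP20170334-27 R3", "BEAUREGARD", "C_C_EJUMULA R1"),
    flesh_colour_mean = c(0.400, 1.0, 8.182),
    mealiness_by_hand_mean = c(5, 6.376, 2),
    positive_force_1r = c(100, 200, 300))
  preds <- data.frame(
    variety_name = c("C_P_UGP20170334-27 R3", "C_C_EJUMULA R1"),
    predicted = c(0.886, 7.472))
  ea <- error_analysis(preds, truths, "flesh_colour")
  expect_equal(ea$absolute_error[ea$variety_name == "C_P_UGP20170334-27 R3"],
               0.486)
  # |8.182 - 7.472| = 0.710 exactly; the published table prints 0.709 because
  # its operands were rounded for display
  expect_equal(ea$absolute_error[ea$variety_name == "C_C_EJUMULA R1"],
               abs(7.472 - 8.182))
  # worst mealiness prediction: 0.727 vs 6.376 -> 5.649
  eb <- error_analysis(data.frame(variety_name = "BEAUREGARD",
                                  predicted = 0.727), truths, "mealiness")
  expect_equal(eb$absolute_error, 5.649)
  # ranking: a perfect prediction comes first
  ec <- error_analysis(data.frame(variety_name = truths$variety_name,
                                  predicted = c(0.5, 6.376, 9)),
                       truths, "mealiness")
  expect_identical(ec$variety_name[1], "BEAUREGARD")
  expect_equal(ec$absolute_error[1], 0)
  expect_identical(nrow(best_k(ec, 2)), 2L)
  expect_gte(worst_k(ec, 2)$absolute_error[1], worst_k(ec, 2)$absolute_error[2])
  expect_error(error_analysis(data.frame(variety_name = "NOPE", predicted = 1),
                              truths, "mealiness"),
               class = "rootsense_input_error")
})

test_that("predict_scores clips to the attribute range (and not for force)", {
  X <- matrix(c(0, 0), 2, 1)
  m <- structure(list(family = "linear", task = "regression",
                      fit = list(coef = c(20, 0), intercept = TRUE),
                      feature_names = NULL), class = "rs_model")
  expect_equal(predict_scores(m, X), c(10, 10))
  expect_equal(predict_scores(m, X, clip = NULL), c(20, 20))
  m$fit$coef <- c(-4, 0)
  expect_equal(predict_scores(m, X), c(0, 0))
})

test_that("under class imbalance regression holds up while macro-F1 degrades", {
  # 70% of samples in the 0-5 score range, the published imbalance regime
  set.seed(13)
  n <- 150
  scores <- c(runif(round(0.7 * n), 0, 5), runif(n - round(0.7 * n), 5, 10))
  X <- palette_features(scores, noise_sd = 5, seed = 13)
  classes <- nearest_scale_class(scores)
  parts <- split_dataset(n, c(0.8, 0.2), seed = 3)
  tr <- parts[[1]]; te <- parts[[2]]
  reg <- train_regressor(X[tr, ], scores[tr],
                         model_config("random_forest", seed = 4))
  r2 <- regression_metrics(scores[te], predict_scores(reg, X[te, ]))$r2
  clf <- train_classifier(X[tr, ], classes[tr],
                          model_config("random_forest",
                                       task = "classification", seed = 4))
  f1 <- classification_metrics(classes[te], predict_scores(clf, X[te, ]))$f1
  expect_gte(r2, 0.8)      # regression stays comparable to ground truth
  expect_lt(f1, r2)        # macro-F1 visibly degrades below the R^2 level
})
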