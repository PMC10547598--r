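#' Model configuration
#'
#' Families and defaults follow the published training setups: the
#' flesh-colour experiments (linear regression with intercept; KNN with 5
#' neighbours, uniform weights, Minkowski metric; decision tree with
#' squared-error criterion, best splitter, unlimited depth, min split 2;
#' RBF-SVM with C = 1; random forest with 100 estimators) and the mealiness
#' experiments (random forest with depth 8 and 20 estimators; gradient
#' boosting with learning rate 0.1, depth 8, 200 estimators; a 5-layer
#' neural network trained with Adam at learning rate 1e-4, MSE loss, up to
#' 5000 epochs with early stopping). Any hyperparameter can be overridden.
#'
#' @param family one of `"linear"`, `"knn"`, `"decision_tree"`, `"svm"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"neural_net"`.
#' @param task `"regression"` or `"classification"` (classification supports
#'   the tree families).
#' @param seed integer seed (bootstraps, feature subsampling, NN init).
#' @param ... hyperparameter overrides (validated per family).
#' @return list of class `model_config`.
#' @export
model_config <- function(family = c("linear", "knn", "decision_tree", "svm",
                                    "random_forest", "gradient_boosting",
                                    "neural_net"),
                         task = c("regression", "classification"),
                         seed = 1L, ...) {
  family <- match.arg(family)
  task <- match.arg(task)
  defaults <- switch(family,
    linear = list(fit_intercept = TRUE),
    knn = list(n_neighbors = 5L),
    decision_tree = list(max_depth = Inf, min_samples_split = 2L,
                         min_samples_leaf = 1L),
    svm = list(C = 1, epsilon = 0.1, gamma = NULL),
    random_forest = list(n_estimators = 100L, max_depth = Inf,
                         min_samples_split = 2L, min_samples_leaf = 1L,
                         max_features = NULL),
    gradient_boosting = list(n_estimators = 200L, learning_rate = 0.1,
                             max_depth = 8L),
    neural_net = list(hidden = c(64L, 32L, 16L), learning_rate = 1e-4,
                      epochs = 5000L, val_frac = 0.1, min_delta = 0.005,
                      patience = 100L))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort_rs(paste0("unknown hyperparameter(s) for ", family, ": ",
                    paste(unknown, collapse = ", ")), "rootsense_config_error")
  }
  hp <- utils::modifyList(defaults, over)
  if (task == "classification" &&
      !family %in% c("decision_tree", "random_forest")) {
    abort_rs("classification supports decision_tree and random_forest",
             "rootsense_config_error")
  }
  structure(list(family = family, task = task, hyperparameters = hp,
                 seed = as.integer(seed)), class = "model_config")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    abort_rs("X rows must equal length(y)", "rootsense_input_error")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort_rs("non-finite values in features", "rootsense_input_error")
  }
  if (anyNA(y) || any(!is.finite(y))) {
    abort_rs("non-finite values in target", "rootsense_input_error")
  }
  X
}

#' Train a regression model
#'
#' @param X numeric feature matrix (columns are the documented feature
#'   schema; column names are stored and re-validated at prediction time).
#' @param y numeric target.
#' @param config a [model_config()].
#' @return object of class `rs_model`.
#' @export
train_regressor <- function(X, y, config = model_config("random_forest")) {
  stopifnot(inherits(config, "model_config"))
  X <- check_xy(X, y)
  hp <- config$hyperparameters
  fit <- with_seed(config$seed, switch(config$family,
    linear = {
      f <- stats::lsfit(X, y, intercept = isTRUE(hp$fit_intercept))
      list(coef = f$coefficients, intercept = isTRUE(hp$fit_intercept))
    },
    knn = fit_knn(X, y, k = hp$n_neighbors),
    decision_tree = fit_cart(X, y, max_depth = hp$max_depth,
                             min_split = hp$min_samples_split,
                             min_leaf = hp$min_samples_leaf),
    svm = fit_svr(X, y, C = hp$C, epsilon = hp$epsilon, gamma = hp$gamma),
    random_forest = fit_forest(X, y, n_estimators = hp$n_estimators,
                               max_depth = hp$max_depth,
                               min_split = hp$min_samples_split,
                               min_leaf = hp$min_samples_leaf,
                               max_features = hp$max_features),
    gradient_boosting = fit_gbm(X, y, n_estimators = hp$n_estimators,
                                learning_rate = hp$learning_rate,
                                max_depth = hp$max_depth),
    neural_net = fit_mlp(X, y, hidden = hp$hidden, lr = hp$learning_rate,
                         epochs = hp$epochs, val_frac = hp$val_frac,
                         min_delta = hp$min_delta, patience = hp$patience,
                         seed = config$seed)
  ))
  structure(list(family = config$family, task = "regression", fit = fit,
                 config = config, feature_names = colnames(X)),
            class = "rs_model")
}

#' Train a classification model on the anchor class codes
#'
#' @inheritParams train_regressor
#' @param y integer class codes (a subset of the anchor codes).
#' @param classes the full class-code set.
#' @export
train_classifier <- function(X, y,
                             config = model_config("random_forest",
                                                   task = "classification"),
                             classes = c(0, 1, 3, 5, 8, 10)) {
  stopifnot(inherits(config, "model_config"), config$task == "classification")
  X <- check_xy(X, y)
  hp <- config$hyperparameters
  fit <- with_seed(config$seed, switch(config$family,
    decision_tree = fit_cart(X, y, max_depth = hp$max_depth,
                             min_split = hp$min_samples_split,
                             min_leaf = hp$min_samples_leaf,
                             classification = TRUE, classes = classes),
    random_forest = fit_forest(X, y, n_estimators = hp$n_estimators,
                               max_depth = hp$max_depth,
                               min_split = hp$min_samples_split,
                               min_leaf = hp$min_samples_leaf,
                               max_features = hp$max_features %||%
                                 max(1L, floor(sqrt(ncol(X)))),
                               classification = TRUE, classes = classes)
  ))
  structure(list(family = config$family, task = "classification", fit = fit,
                 config = config, feature_names = colnames(X),
                 classes = classes), class = "rs_model")
}

#' Train the mealiness neural network with early stopping
#'
#' Splits the training set 90/10 into fit/validation parts (seeded), trains
#' with Adam and MSE loss, and halts at 5000 epochs or once the best
#' validation MAE has not improved by strictly more than 0.005 for 100
#' consecutive epochs. Returns the model plus a per-epoch validation-MAE log
#' and the stopping epoch.
#'
#' @inheritParams train_regressor
#' @return `rs_model` whose `fit$log` holds `val_mae`, `stop_epoch`,
#'   `best_val_mae`.
#' @export
train_nn_with_early_stopping <- function(X, y,
                                         config = model_config("neural_net")) {
  stopifnot(config$family == "neural_net")
  if (length(y) < 10) {
    abort_rs("need at least 10 samples for a 90/10 split",
             "rootsense_input_error")
  }
  train_regressor(X, y, config)
}

#' Predict from a trained model
#'
#' @param object an `rs_model`.
#' @param newdata feature matrix with the training schema.
#' @param ... unused.
#' @export
predict.rs_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    abort_rs(paste0("feature schema mismatch; expected: ",
                    paste(object$feature_names, collapse = ", "),
                    " got: ", paste(colnames(X), collapse = ", ")),
             "rootsense_schema_error")
  }
  switch(object$family,
    linear = {
      cf <- object$fit$coef
      if (object$fit$intercept) {
        as.numeric(cf[1] + X %*% cf[-1])
      } else as.numeric(X %*% cf)
    },
    knn = predict_knn(object$fit, X),
    decision_tree = predict_cart(object$fit, X),
    svm = predict_svr(object$fit, X),
    random_forest = predict_forest(object$fit, X),
    gradient_boosting = predict_gbm(object$fit, X),
    neural_net = predict_mlp(object$fit, X))
}

#' Predict attribute scores with range clipping
#'
#' Raw model outputs are clipped to the attribute range (default \[0, 10\];
#' pass `clip = NULL` for unclipped targets such as positive force 1R).
#' Classification outputs additionally snap to the nearest anchor class code.
#'
#' @param model an `rs_model`.
#' @param X feature matrix.
#' @param clip length-2 range or `NULL`.
#' @export
predict_scores <- function(model, X, clip = c(0, 10)) {
  p <- predict(model, X)
  if (!is.null(clip)) p <- pmin(clip[2], pmax(clip[1], p))
  if (model$task == "classification") p <- nearest_scale_class(p)
  p
}

#' Deterministic floor-allocation dataset split
#'
#' Shuffles with the seed, allocates `floor(f_i * n)` items to each part and
#' the remainder to the last part. With 152 items and fractions
#' (0.60, 0.25, 0.15) this yields parts of 91, 38 and 23 — the published
#' train/validation/test counts.
#'
#' @param items vector (or anything with length) to split, or an integer n.
#' @param fractions positive fractions summing to 1.
#' @param seed integer seed.
#' @return list of index vectors, one per fraction (disjoint, exhaustive).
#' @export
split_dataset <- function(items, fractions, seed = 1L) {
  n <- if (length(items) == 1 && is.numeric(items)) as.integer(items)
       else NROW(items)
  if (n < length(fractions)) {
    abort_rs("fewer items than parts", "rootsense_input_error")
  }
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    abort_rs("fractions must be positive and sum to 1", "rootsense_input_error")
  }
  perm <- with_seed(seed, sample.int(n))
  sizes <- floor(fractions * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(sizes), function(i) sort(perm[starts[i]:ends[i]]))
}

#' Regression metrics
#'
#' `MAE = mean |e|`, `MSE = mean e^2`,
#' `R^2 = 1 - sum e^2 / sum (y - ybar)^2`. A constant ground truth makes
#' R^2 undefined and raises an error.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return named list `mae`, `mse`, `r2`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    abort_rs("y and yhat must be non-empty and equal length",
             "rootsense_input_error")
  }
  e <- yhat - y
  ss <- sum((y - mean(y))^2)
  if (ss == 0) abort_rs("zero variance in y: R^2 undefined",
                        "rootsense_undefined_error")
  list(mae = mean(abs(e)), mse = mean(e^2), r2 = 1 - sum(e^2) / ss)
}

#' Classification metrics (one-vs-rest, macro-averaged)
#'
#' Per-class precision, recall and F1 with macro averages over the classes
#' present in either `y` or `yhat`; a class absent from both is excluded from
#' the macro mean. Empty denominators give 0 for that class.
#'
#' @param y,yhat class-code vectors.
#' @param classes the full class-code set.
#' @return list with `precision`, `recall`, `f1` (macro) and `per_class`
#'   data.frame.
#' @export
classification_metrics <- function(y, yhat, classes = c(0, 1, 3, 5, 8, 10)) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    abort_rs("y and yhat must be non-empty and equal length",
             "rootsense_input_error")
  }
  present <- classes[classes %in% c(y, yhat)]
  rows <- lapply(present, function(cl) {
    tp <- sum(y == cl & yhat == cl)
    fp <- sum(y != cl & yhat == cl)
    fn <- sum(y == cl & yhat != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f,
               support = sum(y == cl))
  })
  per_class <- do.call(rbind, rows)
  list(precision = mean(per_class$precision), recall = mean(per_class$recall),
       f1 = mean(per_class$f1), per_class = per_class)
}

#' Seeded k-fold cross-validation
#'
#' Shuffled fold assignment; one [regression_metrics()] report per fold plus
#' a mean/sd summary.
#'
#' @inheritParams train_regressor
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @return list with `reports` (per fold), `summary` (mean and sd of each
#'   metric) and `fold_assignment`.
#' @export
cross_validate <- function(X, y, config, folds = 5L, seed = 1L) {
  X <- check_xy(X, y)
  n <- length(y)
  if (folds > n) abort_rs("more folds than samples", "rootsense_input_error")
  assign_f <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  reports <- lapply(seq_len(folds), function(f) {
    te <- which(assign_f == f)
    m <- train_regressor(X[-te, , drop = FALSE], y[-te], config)
    c(regression_metrics(y[te], predict(m, X[te, , drop = FALSE])),
      list(n_test = length(te)))
  })
  vals <- sapply(reports, function(r) c(mae = r$mae, mse = r$mse, r2 = r$r2))
  list(reports = reports,
       summary = list(mean = rowMeans(vals), sd = apply(vals, 1, stats::sd)),
       fold_assignment = assign_f)
}

#' Panel-score label policy
#'
#' The regression target is the arithmetic mean of the panel's scores; the
#' classification target is the mode over anchor class codes, ties resolved
#' toward the lower (paler) code.
#'
#' @param scores numeric panel scores for one sample.
#' @param type `"mean"` or `"mode"`.
#' @export
label_policy <- function(scores, type = c("mean", "mode")) {
  type <- match.arg(type)
  if (length(scores) == 0) abort_rs("no scores", "rootsense_empty_error")
  if (type == "mean") return(mean(scores))
  u <- sort(unique(scores))
  counts <- vapply(u, function(s) sum(scores == s), numeric(1))
  u[which.max(counts)]   # first maximum = lowest code on ties
}

#' Per-variety error analysis
#'
#' Joins predictions to the sensory ground truth, computes absolute errors,
#' and returns rows ranked by ascending error (so the best predictions come
#' first). `best_k` / `worst_k` helpers subset the ranked table.
#'
#' @param predictions data.frame with `variety_name` and `predicted`.
#' @param truths sensory table (see [read_sensory_table()]).
#' @param attribute `"flesh_colour"`, `"mealiness"` or `"positive_force"`.
#' @return data.frame `variety_name, predicted, ground_truth, absolute_error`,
#'   sorted ascending by error.
#' @export
error_analysis <- function(predictions, truths,
                           attribute = c("flesh_colour", "mealiness",
                                         "positive_force")) {
  attribute <- match.arg(attribute)
  col <- switch(attribute, flesh_colour = "flesh_colour_mean",
                mealiness = "mealiness_by_hand_mean",
                positive_force = "positive_force_1r")
  hit <- match(predictions$variety_name, truths$variety_name)
  if (anyNA(hit)) {
    abort_rs(paste0("unmatched variety: ",
                    paste(predictions$variety_name[is.na(hit)], collapse = ", ")),
             "rootsense_input_error")
  }
  out <- data.frame(variety_name = predictions$variety_name,
                    predicted = predictions$predicted,
                    ground_truth = truths[[col]][hit])
  out$absolute_error <- abs(out$predicted - out$ground_truth)
  out[order(out$absolute_error), , drop = FALSE]
}

#' @rdname error_analysis
#' @param ranked output of `error_analysis`.
#' @param k rows to keep.
#' @export
best_k <- function(ranked, k = 3) utils::head(ranked, k)

#' @rdname error_analysis
#' @export
worst_k <- function(ranked, k = 3) {
  tl <- utils::tail(ranked, k)
  tl[order(-tl$absolute_error), , drop = FALSE]
}
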