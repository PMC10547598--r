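# CART trees (regression: squared-error criterion; classification: Gini),
# best-split search with prefix sums, optional per-split feature subsampling.
# These back the decision-tree, random-forest and gradient-boosting families;
# the environment ships no tree package, so the engine lives here.

# returns best (feature, threshold, gain) for one node, or NULL
best_split <- function(X, y, idx, min_leaf, feat_idx, classification, classes) {
  n <- length(idx)
  best <- NULL
  if (classification) {
    counts_all <- tabulate(match(y[idx], classes), nbins = length(classes))
    imp_parent <- 1 - sum((counts_all / n)^2)
  } else {
    imp_parent <- sum((y[idx] - mean(y[idx]))^2)
  }
  for (j in feat_idx) {
    v <- X[idx, j]
    o <- order(v)
    vs <- v[o]; ys <- y[idx][o]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) next
    if (classification) {
      onehot <- outer(ys, classes, "==") * 1
      cl <- apply(onehot, 2, cumsum)
      nl <- seq_len(n)
      gini_l <- 1 - rowSums((cl / nl)^2)
      cr <- matrix(rep(colSums(onehot), each = n), n) - cl
      nr <- n - nl
      gini_r <- 1 - rowSums((cr / pmax(nr, 1))^2)
      score <- (nl * gini_l + nr * gini_r) / n
      cand <- distinct[nl[distinct] >= min_leaf & nr[distinct] >= min_leaf]
      if (length(cand) == 0) next
      k <- cand[which.min(score[cand])]
      gain <- imp_parent - score[k]
    } else {
      cs <- cumsum(ys); cs2 <- cumsum(ys^2)
      nl <- seq_len(n)
      tot <- cs[n]; tot2 <- cs2[n]
      sse_l <- cs2 - cs^2 / nl
      nr <- n - nl
      sse_r <- (tot2 - cs2) - (tot - cs)^2 / pmax(nr, 1)
      sse_r[nr == 0] <- 0
      score <- sse_l + sse_r
      cand <- distinct[nl[distinct] >= min_leaf & nr[distinct] >= min_leaf]
      if (length(cand) == 0) next
      k <- cand[which.min(score[cand])]
      gain <- imp_parent - score[k]
    }
    if (gain > 1e-12 && (is.null(best) || gain > best$gain)) {
      best <- list(feature = j, threshold = (vs[k] + vs[k + 1]) / 2,
                   gain = gain)
    }
  }
  best
}

fit_cart <- function(X, y, max_depth = Inf, min_split = 2L, min_leaf = 1L,
                     max_features = NULL, classification = FALSE,
                     classes = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  mtry <- if (is.null(max_features)) p else max(1L, min(p, as.integer(max_features)))
  leaf_value <- function(idx) {
    if (classification) {
      counts <- tabulate(match(y[idx], classes), nbins = length(classes))
      classes[which.max(counts)]  # ties -> first (lower code: classes ascend)
    } else mean(y[idx])
  }
  grow <- function(idx, depth) {
    if (length(idx) < min_split || depth >= max_depth ||
        length(unique(y[idx])) == 1) {
      return(list(leaf = TRUE, value = leaf_value(idx)))
    }
    feat_idx <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- best_split(X, y, idx, min_leaf, feat_idx, classification, classes)
    if (is.null(sp) && mtry < p) {
      # random subset had no usable split; fall back to all features
      sp <- best_split(X, y, idx, min_leaf, seq_len(p), classification, classes)
    }
    if (is.null(sp)) return(list(leaf = TRUE, value = leaf_value(idx)))
    left <- idx[X[idx, sp$feature] <= sp$threshold]
    right <- setdiff(idx, left)
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  structure(list(root = grow(seq_len(nrow(X)), 0),
                 classification = classification, classes = classes),
            class = "rs_cart")
}

predict_cart <- function(tree, X) {
  X <- as.matrix(X)
  one <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
    node$value
  }
  apply(X, 1, one, node = tree$root)
}

fit_forest <- function(X, y, n_estimators, max_depth = Inf, min_split = 2L,
                       min_leaf = 1L, max_features = NULL,
                       classification = FALSE, classes = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  trees <- vector("list", n_estimators)
  for (t in seq_len(n_estimators)) {
    bs <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- fit_cart(X[bs, , drop = FALSE], y[bs],
                           max_depth = max_depth, min_split = min_split,
                           min_leaf = min_leaf, max_features = max_features,
                           classification = classification, classes = classes)
  }
  structure(list(trees = trees, classification = classification,
                 classes = classes), class = "rs_forest")
}

predict_forest <- function(forest, X) {
  Xm <- as.matrix(X)
  preds <- vapply(forest$trees, function(tr) predict_cart(tr, Xm),
                  numeric(nrow(Xm)))
  preds <- matrix(preds, nrow = nrow(Xm))
  if (forest$classification) {
    apply(preds, 1, function(row) {
      counts <- tabulate(match(row, forest$classes),
                         nbins = length(forest$classes))
      forest$classes[which.max(counts)]
    })
  } else rowMeans(preds)
}

fit_gbm <- function(X, y, n_estimators = 200L, learning_rate = 0.1,
                    max_depth = 8L, min_split = 2L, min_leaf = 1L) {
  X <- as.matrix(X)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_estimators)
  for (t in seq_len(n_estimators)) {
    tr <- fit_cart(X, resid, max_depth = max_depth, min_split = min_split,
                   min_leaf = min_leaf)
    step <- predict_cart(tr, X)
    resid <- resid - learning_rate * step
    trees[[t]] <- tr
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = "rs_gbm")
}

predict_gbm <- function(model, X) {
  out <- rep(model$f0, nrow(as.matrix(X)))
  for (tr in model$trees) out <- out + model$learning_rate * predict_cart(tr, X)
  out
}
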