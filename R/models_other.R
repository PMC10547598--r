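# Non-tree model families: epsilon-SVR with an RBF kernel solved as a QP
# (quadprog), k-nearest-neighbour regression, and a dense MLP trained with
# Adam. All deterministic for a fixed seed.

rbf_kernel <- function(A, B, gamma) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

fit_svr <- function(X, y, C = 1, epsilon = 0.1, gamma = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(X)) * (length(X) - 1) / length(X)
    gamma <- 1 / (ncol(X) * max(v, 1e-12))   # sklearn's "scale"
  }
  K <- rbf_kernel(X, X, gamma)
  # dual in z = (alpha, alpha*): min 1/2 z' D z - d' z
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  d <- c(y - epsilon, -y - epsilon)
  # constraints: sum(alpha) - sum(alpha*) = 0 (eq); z >= 0; z <= C
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b, meq = 1)
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  f0 <- as.numeric(K %*% beta)
  sv_lo <- sol$solution[1:n]; sv_hi <- sol$solution[(n + 1):(2 * n)]
  tolc <- 1e-6 * C
  free_a <- which(sv_lo > tolc & sv_lo < C - tolc)
  free_as <- which(sv_hi > tolc & sv_hi < C - tolc)
  b0 <- if (length(free_a) + length(free_as) > 0) {
    mean(c(y[free_a] - f0[free_a] - epsilon, y[free_as] - f0[free_as] + epsilon))
  } else mean(y - f0)
  structure(list(X = X, beta = beta, b = b0, gamma = gamma), class = "rs_svr")
}

predict_svr <- function(model, X) {
  K <- rbf_kernel(as.matrix(X), model$X, model$gamma)
  as.numeric(K %*% model$beta + model$b)
}

fit_knn <- function(X, y, k = 5L) {
  structure(list(X = as.matrix(X), y = y, k = as.integer(k)), class = "rs_knn")
}

predict_knn <- function(model, X) {
  X <- as.matrix(X)
  tr <- model$X
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(min(model$k, length(row)))]
    mean(model$y[nb])   # uniform weights (Minkowski p = 2 metric)
  })
}

# ---- dense MLP with Adam ----------------------------------------------------

mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialisation for the rectified-linear layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  acts
}

mlp_grad <- function(net, acts, y) {
  L <- length(net$W)
  n <- nrow(acts[[1]])
  delta <- 2 * (acts[[L + 1]] - y) / n       # d MSE / d output
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(acts[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# Train an MLP with Adam and the fixed early-stopping rule:
# stop after `epochs` epochs or once the best validation MAE has not improved
# by MORE than `min_delta` for `patience` consecutive epochs.
fit_mlp <- function(X, y, hidden = c(64L, 32L, 16L), lr = 1e-4,
                    epochs = 5000L, val_frac = 0.1, min_delta = 0.005,
                    patience = 100L, seed = 1L,
                    val_mae_fn = NULL) {
  X <- as.matrix(X)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  with_seed(seed, {
    n <- nrow(Xs)
    n_val <- max(1L, floor(val_frac * n))
    vid <- sample.int(n, n_val)
    Xtr <- Xs[-vid, , drop = FALSE]; ytr <- y[-vid]
    Xva <- Xs[vid, , drop = FALSE]; yva <- y[vid]
    sizes <- c(ncol(Xs), hidden, 1L)
    net <- mlp_init(sizes)
    m <- lapply(c(net$W, net$b), function(w) w * 0)
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- Inf; wait <- 0L
    log_mae <- numeric(0)
    ytr_m <- matrix(ytr, ncol = 1)
    stop_epoch <- epochs
    for (ep in seq_len(epochs)) {
      acts <- mlp_forward(net, Xtr)
      g <- mlp_grad(net, acts, ytr_m)
      params <- c(net$W, net$b)
      grads <- c(g$W, g$b)
      for (i in seq_along(params)) {
        m[[i]] <- beta1 * m[[i]] + (1 - beta1) * grads[[i]]
        v[[i]] <- beta2 * v[[i]] + (1 - beta2) * grads[[i]]^2
        mh <- m[[i]] / (1 - beta1^ep)
        vh <- v[[i]] / (1 - beta2^ep)
        params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
      }
      L <- length(net$W)
      net$W <- params[1:L]; net$b <- params[(L + 1):(2 * L)]
      pred_va <- mlp_forward(net, Xva)[[L + 1]]
      if (any(!is.finite(pred_va))) {
        abort_rs("neural-network training diverged (non-finite loss)",
                 "rootsense_training_error")
      }
      val_mae <- if (is.null(val_mae_fn)) mean(abs(pred_va - yva))
                 else val_mae_fn(ep)
      log_mae <- c(log_mae, val_mae)
      if (val_mae < best - min_delta) {
        best <- val_mae; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) { stop_epoch <- ep; break }
      }
    }
    structure(list(net = net, mu = mu, sd = sdv,
                   log = list(val_mae = log_mae,
                              stop_epoch = min(stop_epoch, length(log_mae)),
                              best_val_mae = best)),
              class = "rs_mlp")
  })
}

predict_mlp <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$mu, "-"), 2, model$sd, "/")
  as.numeric(mlp_forward(model$net, Xs)[[length(model$net$W) + 1]])
}
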