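#' K-means over pixel colours (Lloyd + k-means++, restarted)
#'
#' The clustering engine behind background elimination and dominant-colour
#' extraction. Lloyd iterations from k-means++ starts, `n_init` restarts,
#' keeping the lowest within-cluster sum of squares (inertia). Deterministic
#' for a fixed seed; the caller's RNG state is untouched.
#'
#' @param pixels n x d numeric matrix (rows = pixels, d = 3 for RGB).
#' @param k number of clusters (>= 2 distinct pixel values required).
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts (best inertia kept).
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol convergence tolerance on total centroid movement.
#' @return list with `labels` (integer vector, 1..k), `centroids` (k x d),
#'   `inertia` (total within-cluster SSE).
#' @export
kmeans_pixels <- function(pixels, k = 2L, seed = 1L, n_init = 5L,
                          max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(pixels)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (nrow(unique(X)) < k) {
    abort_rs(paste0("need at least ", k, " distinct pixel values for k = ", k),
             "rootsense_degenerate_error")
  }
  sq <- rowSums(X^2)
  dist_to <- function(C) {
    # n x k squared distances
    outer(sq, rowSums(C^2), "+") - 2 * X %*% t(C)
  }
  run_once <- function() {
    # k-means++ seeding
    C <- X[sample.int(n, 1L), , drop = FALSE]
    while (nrow(C) < k) {
      d2 <- pmax(0, apply(dist_to(C), 1, min))
      if (sum(d2) == 0) {
        # all points coincide with chosen centres; pick any distinct row
        cand <- which(!duplicated(X))
        C <- rbind(C, X[sample(cand, 1L), , drop = FALSE])
      } else {
        C <- rbind(C, X[sample.int(n, 1L, prob = d2), , drop = FALSE])
      }
    }
    lab <- max.col(-dist_to(C), ties.method = "first")
    for (it in seq_len(max_iter)) {
      newC <- C
      for (j in seq_len(k)) {
        hit <- lab == j
        if (any(hit)) newC[j, ] <- colMeans(X[hit, , drop = FALSE])
      }
      moved <- sum((newC - C)^2)
      C <- newC
      lab <- max.col(-dist_to(C), ties.method = "first")
      if (moved < tol) break
    }
    d <- dist_to(C)
    inertia <- sum(pmax(0, d[cbind(seq_len(n), lab)]))
    list(labels = lab, centroids = C, inertia = inertia)
  }
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_init)) {
      res <- run_once()
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
    dimnames(best$centroids) <- list(NULL, colnames(X))
    best
  })
}
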