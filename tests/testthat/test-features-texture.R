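test_that("to_grayscale uses the documented luminance weights", {
  red <- array(c(255, 0, 0), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(red)), 0.299 * 255)
  g <- array(77, dim = c(3, 3, 3))
  expect_equal(to_grayscale(g), matrix(77, 3, 3))
  # linear in channel scaling
  img <- with_seed_arr(3, c(5L, 5L))
  expect_equal(to_grayscale(img / 2 + 0), to_grayscale(img) / 2)
})

test_that("edge_params validates thresholds", {
  expect_error(edge_params(low_threshold = 30, high_threshold = 20),
               class = "rootsense_input_error")
  expect_error(edge_params(gaussian_sigma = -1),
               class = "rootsense_input_error")
})

test_that("canny on constant regions is empty; a step edge is one thin component", {
  mask <- matrix(TRUE, 24, 24)
  flat <- matrix(100, 24, 24)
  expect_identical(sum(canny_edges(flat, edge_params(), mask)), 0L)
  step <- matrix(50, 24, 24); step[, 13:24] <- 180
  e <- canny_edges(step, edge_params(), mask)
  expect_gt(sum(e), 0)
  lab <- label_components(e, 8L)
  expect_identical(attr(lab, "n_components"), 1L)
  # one pixel wide: each edge row contains exactly one edge pixel
  rows_with_edges <- which(rowSums(e) > 0)
  expect_true(all(rowSums(e)[rows_with_edges] == 1))
  # output is binary and confined to the 2-px eroded mask
  m2 <- mask; m2[1:12, ] <- FALSE
  e2 <- canny_edges(step, edge_params(), m2)
  expect_true(all(which(e2) %in% which(rootsense:::erode(m2, 2L))))
  expect_error(canny_edges(matrix(1, 3, 3), edge_params(gaussian_sigma = 2),
                           matrix(TRUE, 3, 3)),
               class = "rootsense_input_error")
})

test_that("canny matches the naive reference pixel-for-pixel (<= 32x32)", {
  for (s in 1:3) {
    set.seed(s)
    H <- sample(16:32, 1); W <- sample(16:32, 1)
    gray <- matrix(runif(H * W, 0, 255), H, W)
    # blocky structure so real edges exist
    gray[1:floor(H / 2), ] <- gray[1:floor(H / 2), ] / 4
    mask <- matrix(TRUE, H, W)
    p <- edge_params(gaussian_sigma = 1, low_threshold = 8, high_threshold = 20)
    got <- canny_edges(gray, p, mask)
    ref <- canny_reference(gray, 1, 8, 20, mask)
    expect_identical(got, ref)
  }
})

test_that("find_contours traces squares, blobs and holes", {
  expect_identical(find_contours(matrix(FALSE, 10, 10)), list())
  sq <- matrix(FALSE, 12, 12); sq[3:8, 3:8] <- TRUE  # filled 6x6 square
  ct <- find_contours(sq)
  expect_identical(length(ct), 1L)
  expect_identical(nrow(ct[[1]]), 4L * (6L - 1L))  # perimeter 4(s-1) steps
  two <- matrix(FALSE, 12, 12); two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  expect_identical(length(find_contours(two)), 2L)
  ring <- matrix(FALSE, 12, 12); ring[3:9, 3:9] <- TRUE; ring[5:7, 5:7] <- FALSE
  expect_identical(length(find_contours(ring)), 2L)  # outline + hole
})

test_that("smooth noiseless roots have zero graininess", {
  sc <- tiny_scene(colour = 5, mealiness = 0, noise = 0, seed = 3)
  tf <- graininess_features(sc$image, sc$truth$mask)
  expect_equal(tf$edge_density, 0)
  expect_identical(tf$component_count, 0L)
  expect_identical(length(tf$feature_row), 3L)
})

test_that("all four graininess statistics grow from mealiness 2 to 8 (20 seeds)", {
  stat4 <- function(m) {
    v <- vapply(1:20, function(s) {
      sc <- tiny_scene(colour = 5, mealiness = m, noise = 5, seed = 200 + s,
                       size = c(80L, 80L))
      tf <- graininess_features(sc$image, sc$truth$mask)
      c(tf$edge_density, tf$component_count, tf$mean_gradient_magnitude,
        tf$local_variance_mean)
    }, numeric(4))
    rowMeans(v)
  }
  lo <- stat4(2); hi <- stat4(8)
  expect_true(all(hi > lo))
})

test_that("seed-averaged edge density is monotone across the mealiness range", {
  grid <- c(0, 3, 7, 10)
  dens <- vapply(grid, function(m) {
    mean(vapply(1:20, function(s) {
      sc <- tiny_scene(colour = 5, mealiness = m, noise = 5, seed = 300 + s,
                       size = c(80L, 80L))
      graininess_features(sc$image, sc$truth$mask)$edge_density
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dens) >= 0))
})

test_that("graininess is invariant to translating the root", {
  sc <- tiny_scene(colour = 5, mealiness = 6, noise = 0, seed = 9,
                   size = c(80L, 80L))
  tf <- graininess_features(sc$image, sc$truth$mask)
  shift <- function(a, d) {
    out <- array(12, dim = dim(a))
    out[(1 + d):dim(a)[1], (1 + d):dim(a)[2], ] <-
      a[1:(dim(a)[1] - d), 1:(dim(a)[2] - d), ]
    out
  }
  img2 <- shift(sc$image, 4)
  mask2 <- matrix(FALSE, 80, 80)
  mask2[5:80, 5:80] <- sc$truth$mask[1:76, 1:76]
  tf2 <- graininess_features(img2, mask2)
  expect_equal(tf2$feature_row, tf$feature_row, tolerance = 1e-10)
  expect_identical(tf2$component_count, tf$component_count)
})

test_that("embedding provider registry works and masks out the background", {
  sc <- tiny_scene(colour = 7, mealiness = 4, noise = 0, seed = 12)
  v <- extract_embedding(sc$image, sc$truth$mask)
  expect_identical(attr(v, "provider"), "handcrafted")
  expect_identical(length(v), 28L)
  v2 <- extract_embedding(sc$image, sc$truth$mask)
  expect_identical(as.numeric(v), as.numeric(v2))
  # changing only pixels outside the mask leaves the embedding unchanged
  img2 <- sc$image
  img2[, , 1][!sc$truth$mask] <- 90
  v3 <- extract_embedding(img2, sc$truth$mask)
  expect_equal(as.numeric(v3), as.numeric(v))
  expect_error(extract_embedding(sc$image, sc$truth$mask, "resnet"),
               class = "rootsense_config_error")
  register_embedding_provider("toy", function(image, mask) c(1, 2, 3))
  expect_identical(length(extract_embedding(sc$image, sc$truth$mask, "toy")), 3L)
})
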