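test_that("PNG round trip is bit-exact and channel order is R,G,B", {
  d <- withr::local_tempdir()
  img <- with_seed_arr(42, c(17L, 23L))
  p <- file.path(d, "x.png")
  write_image(img, p)
  expect_identical(read_image(p), img)
  # 1x1 pure red
  red <- array(c(255, 0, 0), dim = c(1, 1, 3))
  write_image(red, file.path(d, "red.png"))
  expect_equal(as.numeric(read_image(file.path(d, "red.png"))), c(255, 0, 0))
})

test_that("JPEG round trip stays within the documented lossy tolerance", {
  d <- withr::local_tempdir()
  sc <- tiny_scene(noise = 0, mealiness = 0)
  p <- file.path(d, "x.jpg")
  write_image(sc$image, p)
  back <- read_image(p)
  expect_lt(mean(abs(back - sc$image)), 3)  # mean abs deviation < 3 levels
})

test_that("minimal TIFF codec round-trips bit-exactly", {
  d <- withr::local_tempdir()
  img <- with_seed_arr(7, c(11L, 13L))
  p <- file.path(d, "x.tiff")
  write_image(img, p)
  expect_identical(read_image(p), img)
})

test_that("greyscale images are replicated to 3 channels; errors are actionable", {
  d <- withr::local_tempdir()
  g <- matrix(runif(48), 6, 8)
  png::writePNG(g, file.path(d, "g.png"))
  img <- read_image(file.path(d, "g.png"))
  expect_identical(dim(img), c(6L, 8L, 3L) + 0L)
  expect_identical(img[, , 1], img[, , 2])
  expect_error(read_image(file.path(d, "missing.png")),
               class = "rootsense_io_error")
  writeLines("not an image", file.path(d, "bad.png"))
  expect_error(read_image(file.path(d, "bad.png")), class = "rootsense_io_error")
})

test_that("sensory table parses published rows with header aliases", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sensory.csv")
  writeLines(c("Variety Name,Flesh-colour,Mealiness by hand,Positive force 1R",
               "EJUMULA,8.1,2.0,4565",
               "RESISTO CIP,9.0,0.7,1850",
               "UGP20170334-27,0.4,8.2,8525"), p)
  tab <- read_sensory_table(p)
  expect_identical(names(tab), c("variety_name", "flesh_colour_mean",
                                 "mealiness_by_hand_mean", "positive_force_1r"))
  expect_equal(tab$flesh_colour_mean[tab$variety_name == "EJUMULA"], 8.1)
  expect_equal(tab$mealiness_by_hand_mean[tab$variety_name == "EJUMULA"], 2.0)
  expect_equal(tab$positive_force_1r[tab$variety_name == "EJUMULA"], 4565)
  expect_equal(tab$flesh_colour_mean[tab$variety_name == "RESISTO CIP"], 9.0)
})

test_that("sensory table rejects bad schemas and bad rows", {
  d <- withr::local_tempdir()
  p <- file.path(d, "s.csv")
  writeLines("variety_name,flesh_colour_mean,mealiness_by_hand_mean,positive_force_1r", p)
  expect_identical(nrow(read_sensory_table(p)), 0L)
  writeLines(c("variety,flesh_colour", "A,5"), p)
  expect_error(read_sensory_table(p), class = "rootsense_schema_error")
  writeLines(c("variety,flesh_colour,mealiness,positive_force",
               "A,abc,5,100"), p)
  expect_error(read_sensory_table(p), class = "rootsense_parse_error")
  writeLines(c("variety,flesh_colour,mealiness,positive_force",
               "A,12,5,100"), p)
  expect_error(read_sensory_table(p), class = "rootsense_parse_error")
})

test_that("annotation conversion matches hand normalization", {
  d <- withr::local_tempdir()
  p <- file.path(d, "a.txt")
  # full-frame box on a 100x100 image
  writeLines("0 0.5 0.5 1.0 1.0", p)
  b <- read_annotations(p, c(100L, 100L))
  expect_equal(unname(b[1, 1:4]), c(0, 0, 100, 100))
  # hand-normalized example: box (10,20,30,60) on height 100, width 200
  write_annotations(matrix(c(10, 20, 30, 60), 1), c(100L, 200L), p)
  expect_identical(readLines(p), "0 0.100000 0.400000 0.100000 0.400000")
  # lossless round trip
  boxes <- matrix(c(3, 5, 40, 61,
                    10, 0, 90, 88), 2, byrow = TRUE)
  write_annotations(boxes, c(96L, 128L), p)
  back <- read_annotations(p, c(96L, 128L))
  expect_equal(unname(back[, 1:4]), unname(boxes))
  # validation with line numbers
  writeLines(c("0 0.5 0.5 0.2 0.2", "0 1.5 0.5 0.2 0.2"), p)
  err <- tryCatch(read_annotations(p, c(100L, 100L)), error = identity)
  expect_s3_class(err, "rootsense_validation_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("prediction CSV has the deployed tool's download format", {
  d <- withr::local_tempdir()
  p <- file.path(d, "pred.csv")
  recs <- data.frame(
    image_name = c("Bulindi_8.png", "a.png", "b.png"),
    mean_r = c(165, 10, 20), mean_g = c(103, 10, 20), mean_b = c(54, 10, 20),
    predicted_score = c(8.467, 1.2, 3.4),
    height = 1000L, width = 1500L,
    attribute = "flesh_colour")
  write_predictions_csv(recs, p)
  lines <- readLines(p)
  expect_identical(length(lines), 4L)  # header + 3 records
  # the worked example: RGB 165,103,54 with orange intensity 8.467
  expect_match(lines[2], "165,103,54,8.467")
  back <- utils::read.csv(p)
  expect_equal(back$predicted_score, recs$predicted_score)
  expect_equal(back$mean_r, recs$mean_r)
  expect_error(write_predictions_csv(recs[0, ], p),
               class = "rootsense_input_error")
  expect_error(write_predictions_csv(recs[, 1:3], p),
               class = "rootsense_schema_error")
})
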