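test_that("factorial stimulus sets have the study's cardinalities", {
  l10s <- generateSnakeDataset(snakeDatasetConfig(10, "straight"))
  expect_equal(nrow(l10s), 400)                       # 5 x 2 x 2 x 2 x 10
  expect_equal(as.vector(table(l10s$ordinality)), rep(80L, 5))

  l10i <- generateSnakeDataset(snakeDatasetConfig(10, "irregular"))
  expect_equal(nrow(l10i), 400)                       # 20 x 2 x 10

  l16i <- generateSnakeDataset(snakeDatasetConfig(16, "irregular"))
  expect_equal(nrow(l16i), 640)                       # 20 x 2 x 16
  expect_equal(max(l16i$ordinality), 8)

  l20i <- generateSnakeDataset(snakeDatasetConfig(20, "irregular"))
  expect_equal(nrow(l20i), 800)                       # 20 x 2 x 20
  expect_equal(max(l20i$ordinality), 10)

  lvar <- generateSnakeDataset(snakeDatasetConfig(10, repetitions = 20,
                                                  variableLengths = TRUE))
  expect_equal(nrow(lvar), 200)                       # 20 x 10
})

test_that("counts are a pure function of the configuration, not the seed", {
  a <- generateSnakeDataset(snakeDatasetConfig(16, "irregular", seed = 1))
  b <- generateSnakeDataset(snakeDatasetConfig(16, "irregular", seed = 99))
  expect_equal(nrow(a), nrow(b))
  expect_equal(table(a$ordinality), table(b$ordinality))
})

test_that("ordinality is counted from the nearer end", {
  expect_equal(ordinalityFromPosition(8, 10), 3L)     # min(8, 11 - 8)
  expect_equal(ordinalityFromPosition(1:10, 10),
               as.integer(c(1:5, 5:1)))
  expect_equal(max(ordinalityFromPosition(1:10, 10)), 5L)
})

test_that("dataset images are deterministic and white-on-gray with a red marker", {
  cfg <- snakeDatasetConfig(10, "irregular", repetitions = 1, seed = 12)
  lab <- generateSnakeDataset(cfg)
  i1 <- datasetImage(cfg, lab, 3)
  expect_identical(i1, datasetImage(cfg, lab, 3))
  px <- matrix(i1, ncol = 3)
  kinds <- unique(round(px, 3))
  expect_true(all(apply(kinds, 1, function(v)
    isTRUE(all.equal(v, c(0.5, 0.5, 0.5))) ||
      isTRUE(all.equal(v, c(1, 1, 1))) ||
      isTRUE(all.equal(v, c(1, 0, 0))))))
  expect_gt(sum(px[, 1] == 1 & px[, 2] == 0), 0)      # marker present
})

test_that("variable-length compartments dissociate chain distance from rank", {
  lab <- generateSnakeDataset(snakeDatasetConfig(10, repetitions = 20,
                                                 variableLengths = TRUE, seed = 2))
  labFixed <- generateSnakeDataset(snakeDatasetConfig(10, "irregular", seed = 2))
  # with fixed lengths, distance from the nearer end is (nearly) a
  # deterministic function of ordinality; varied lengths break that:
  # the same rank occurs at clearly different chain distances
  withinSd <- function(l) mean(tapply(l$distance_to_marker, l$ordinality, sd))
  expect_gt(withinSd(lab), 2.5 * withinSd(labFixed))
  rVar <- abs(cor(lab$ordinality, lab$distance_to_marker))
  rFix <- abs(cor(labFixed$ordinality, labFixed$distance_to_marker))
  expect_lt(rVar, rFix)
})

test_that("preprocessing normalizes without touching 224x224 geometry", {
  img <- array(0.5, dim = c(224, 224, 3))
  out <- preprocessImages(img)
  expect_equal(dim(out), c(224, 224, 3))
  for (ch in 1:3) {
    m <- c(0.485, 0.456, 0.406)[ch]; s <- c(0.229, 0.224, 0.225)[ch]
    expect_equal(unique(as.vector(out[, , ch])), (0.5 - m) / s)
  }
  expect_error(preprocessImages(array(1, dim = c(10, 10))), "RGB")
})

test_that("normalization round-trips within float tolerance", {
  set.seed(3)
  img <- array(runif(224 * 224 * 3), dim = c(224, 224, 3))
  expect_equal(denormalizeImages(preprocessImages(img)), img,
               tolerance = 1e-12)
})

test_that("larger inputs are resized and center-cropped to 224", {
  img <- array(runif(300 * 260 * 3), dim = c(300, 260, 3))
  out <- preprocessImages(img)
  expect_equal(dim(out), c(224, 224, 3))
})
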