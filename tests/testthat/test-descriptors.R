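test_that("centred-difference gradients behave on hand-computable images", {
  # derivative of a constant image is zero everywhere
  g <- compute_gradients(matrix(5, 4, 8))
  expect_true(all(g$magnitude == 0))
  expect_true(all(g$orientation == 0))
  # single row [0,0,1,1]: centred difference at the third column is 1
  gr <- compute_gradients(matrix(c(0, 0, 1, 1), 1, 4))
  expect_equal(gr$ix[1, ], c(0, 1, 1, 0))  # replicate-edge borders
  expect_true(all(gr$iy == 0))
  # 3-4-5 magnitude
  expect_equal(sqrt(3^2 + 4^2), 5)
  f <- list(ix = matrix(3), iy = matrix(4))
  expect_equal(sqrt(f$ix^2 + f$iy^2)[1, 1], 5)
  expect_error(compute_gradients(matrix(1, 4, 2)), ">= 3 columns")
})

test_that("gradients match the per-pixel loop oracle on random images", {
  withr::with_seed(8, {
    for (i in 1:20) {
      img <- matrix(sample(0:1, 4 * 15, replace = TRUE), 4, 15)
      fast <- compute_gradients(img)
      slow <- oracle_gradients(img)
      expect_equal(fast$ix, slow$ix)
      expect_equal(fast$iy, slow$iy)
      expect_equal(fast$magnitude, slow$magnitude)
      expect_equal(fast$orientation, slow$orientation)
    }
  })
})

test_that("orientation binning conserves gradient mass in the voted histogram", {
  cfg <- hog_config()
  # 20-degree bins over the unsigned 180-degree range give 9 channels
  expect_equal(cfg$angular_range / (cfg$angular_range / cfg$n_bins), 9 * 20 / 20)
  expect_equal(cfg$n_bins, 9)
  field <- list(magnitude = matrix(0, 4, 10), orientation = matrix(0, 4, 10))
  expect_equal(orientation_binning(field, cfg = cfg), rep(0, 9))
  # five pixels at 10 degrees with magnitude 2: bin 1 holds mass 10
  field2 <- list(magnitude = matrix(2, 1, 5), orientation = matrix(10, 1, 5))
  expect_equal(orientation_binning(field2, cfg = cfg),
               c(10, rep(0, 8)))
  # mass conservation on a random field
  withr::with_seed(3, {
    field3 <- list(magnitude = matrix(runif(40), 4, 10),
                   orientation = matrix(runif(40, 0, 179.99), 4, 10))
    h <- orientation_binning(field3, cfg = cfg)
    expect_equal(sum(h), sum(field3$magnitude))
  })
  expect_error(orientation_binning(field, cols = integer(0), cfg = cfg),
               "empty")
})

test_that("block normalisation implements the three schemes", {
  expect_equal(block_normalize(c(3, 4), "L2", epsilon = 0), c(0.6, 0.8))
  expect_equal(block_normalize(c(1, 3), "L1", epsilon = 0), c(0.25, 0.75))
  expect_equal(block_normalize(rep(0, 9), "L2", epsilon = 1e-5), rep(0, 9))
  expect_equal(block_normalize(rep(0, 9), "L1-sqrt", epsilon = 1e-5), rep(0, 9))
  expect_equal(block_normalize(c(1, 3), "L1-sqrt", epsilon = 0),
               sqrt(c(0.25, 0.75)))
  expect_error(block_normalize(c(1, 2), "L3"))
  expect_error(block_normalize(c(0, 0), "L2", epsilon = 0), "non-zero")
  # L2-normalised vectors are bounded by unit norm whenever epsilon > 0
  withr::with_seed(4, {
    for (i in 1:50) {
      v <- runif(9, 0, 100)
      expect_lt(sqrt(sum(block_normalize(v, "L2")^2)), 1 + 1e-12)
    }
  })
})

test_that("the HOG descriptor has fixed length 81 for any admissible sequence length", {
  for (n in c(10, 13, 40, 200, 567)) {
    withr::with_seed(n, d <- hog_descriptor(voss_encode(random_bases(n))))
    expect_length(d, 81)
    expect_true(all(d >= 0))
  }
  expect_error(hog_descriptor(voss_encode("ACGT")), "minimum 5")
  # a homopolymer has constant rows: the horizontal derivative vanishes and
  # every gradient is purely vertical (90 degrees)
  hp <- voss_encode(strrep("A", 50))
  g <- compute_gradients(hp)
  expect_true(all(g$ix == 0))
  expect_true(all(g$orientation[g$magnitude > 0] == 90))
  expect_equal(hog_descriptor(hp), oracle_hog(hp), tolerance = 1e-12)
})

test_that("HOG matches the brute-force oracle on random binary matrices", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      b <- random_bases(n)
      m <- voss_encode(b)
      expect_equal(hog_descriptor(m), oracle_hog(m), tolerance = 1e-12)
    }
  })
})

test_that("LBP codes interior pixels and matches the brute-force oracle", {
  # constant image: every interior pixel gets code 255 under >= thresholding
  h <- lbp_descriptor(matrix(1, 4, 10))
  expect_equal(h[256], 2 * 8)
  expect_equal(sum(h), (4 - 2) * (10 - 2))
  expect_length(h, 256)
  expect_error(lbp_descriptor(matrix(1, 2, 5)), "3 x 3")
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      m <- matrix(sample(0:1, 4 * n, replace = TRUE), 4, n)
      expect_equal(lbp_descriptor(m), oracle_lbp(m), tolerance = 1e-12)
      expect_equal(sum(lbp_descriptor(m)), 2 * (n - 2))
    }
  })
})

test_that("descriptor tables carry ids and labels with the right widths", {
  corp <- generate_corpus(tiny_corpus_config())
  hf <- hog_features(corp$samples)
  expect_equal(nrow(hf), nrow(corp$samples))
  expect_equal(sum(grepl("^hog", names(hf))), 81)
  expect_true(all(c("id", "class") %in% names(hf)))
  lf <- lbp_features(corp$samples)
  expect_equal(sum(grepl("^lbp", names(lf))), 256)
  expect_equal(dim(feature_matrix(hf)), c(nrow(corp$samples), 81))
  # purity: identical input, identical descriptors
  expect_identical(hog_features(corp$samples), hf)
  # the three reference genes have pairwise distinct descriptors
  rd <- feature_matrix(hog_features(corp$references))
  expect_gt(min(dist(rd)), 0)
})
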