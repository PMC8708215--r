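test_that("metrics match hand computations and their invariances", {
  expect_equal(mae(c(2, 4), c(1, 2)), 1.5)
  expect_equal(mae(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_equal(rmse(matrix(c(3, 4), 1), matrix(c(0, 0), 1)), sqrt(25 / 2))
  expect_equal(nmad(matrix(c(2, 3), 1), matrix(c(1, 3), 1)), 0.25)

  set.seed(2)
  a <- matrix(runif(36), 6, 6); b <- matrix(runif(36), 6, 6)
  # rmse dominates the L1 mean (power-mean inequality)
  expect_gte(rmse(a, b), mae(a, b))
  # nmad is invariant to a common positive rescaling
  expect_equal(nmad(3.3 * a, 3.3 * b), nmad(a, b))
  # region-restricted MAE ignores changes outside the region
  r <- matrix(0L, 6, 6); r[2:3, 2:4] <- 1L
  a2 <- a; a2[r == 0] <- a2[r == 0] + 100
  expect_equal(mae(a2, b, r), mae(a, b, r))
  expect_error(mae(a, b, matrix(0L, 6, 6)), "empty")
  expect_error(nmad(a, matrix(0, 6, 6)), "zero")
})

test_that("ROI extraction validates its bounds", {
  img <- matrix(1:36, 6, 6)
  roi <- roi_spec(2, 3, 2, 2)
  expect_equal(rmse(img, img, roi), 0)
  expect_error(rmse(img, img, roi_spec(5, 5, 4, 4)), "bounds")
  expect_error(roi_spec(0, 1, 2, 2))
})

test_that("method comparison orders oracle, LI and zero-fill correctly", {
  g <- small_geometry(96, 60)
  pair <- make_sinogram_pair(sample_random_phantom(13, metal_config()), g,
                             dilation_px = 1)
  methods <- list(
    oracle = function(s, m) pair$label,
    li = function(s, m) li_mar(s, m),
    zero_fill = function(s, m) s)
  tb <- compare_methods(pair, methods, roi = roi_spec(17, 17, 32, 32))
  expect_equal(nrow(tb), 3)
  expect_equal(tb$mae_sino[tb$method == "oracle"], 0)
  expect_equal(tb$rmse_image[tb$method == "oracle"], 0)
  # zero-fill is strictly worse than interpolation on positive labels
  expect_gt(tb$mae_trace[tb$method == "zero_fill"],
            tb$mae_trace[tb$method == "li"])
  expect_gt(tb$mae_sino[tb$method == "zero_fill"],
            tb$mae_sino[tb$method == "li"])
  # deterministic given fixed inputs
  tb2 <- compare_methods(pair, methods, roi = roi_spec(17, 17, 32, 32))
  expect_identical(tb, tb2)
})
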