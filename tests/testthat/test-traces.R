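test_that("threshold segmentation follows the >= convention and finds components", {
  img <- atten_image(matrix(c(0, 1, 2, 3), 2, 2))
  expect_equal(sum(segment_metal(img, 5)), 0)
  expect_equal(unclass(segment_metal(img, 2)), (img$values >= 2) * 1L,
               ignore_attr = TRUE)

  two <- phantom_spec(list(ellipse_spec(0, 0, 0.8, 0.6, 0, 0.5)),
                      metal_inserts = list(
                        ellipse_spec(-0.3, 0, 0.08, 0.08, 0, 6),
                        ellipse_spec(0.3, 0.1, 0.1, 0.06, 20, 6)),
                      image_size = 64)
  seg <- segment_metal(render_phantom(two), 3)
  expect_equal(flood_components(seg), 2)
})

test_that("trace masks have the analytic shadow width and exact dilation", {
  g <- small_geometry(96, 48)
  empty <- structure(matrix(0L, 64, 64), class = "metal_map")
  expect_equal(sum(trace_mask(empty, g, 2)), 0)

  # centred metal disk of radius r px: shadow width ~ 2r + 2*dilation
  r_px <- 6
  disk <- structure((render_phantom(disk_phantom(r_px / 32, 1, 64))$values > 0) * 1L,
                    class = "metal_map")
  for (dil in c(0, 2)) {
    tm <- trace_mask(disk, g, dilation_px = dil)
    widths <- colSums(tm)
    expect_true(all(abs(widths - (2 * r_px + 2 * dil)) <= 2))
  }

  # dilation extends every per-angle interval by exactly d bins per side
  tm0 <- trace_mask(disk, g, 0)
  tm3 <- trace_mask(disk, g, 3)
  for (j in c(1, 17, 40)) {
    run <- range(which(tm0[, j] == 1))
    run3 <- range(which(tm3[, j] == 1))
    expect_equal(run3, c(max(1, run[1] - 3), min(96, run[2] + 3)))
  }

  # metal projecting outside the detector span is an error
  big <- structure((render_phantom(disk_phantom(0.9, 1, 64))$values > 0) * 1L,
                   class = "metal_map")
  expect_error(trace_mask(big, small_geometry(40, 12), 0), "detector span")
})

test_that("corrupt and composite preserve unaffected data bit-exactly", {
  g <- small_geometry(32, 20)
  set.seed(1)
  lab <- sinogram(matrix(runif(32 * 20, 0.1, 2), 32, 20), g)
  mask <- structure((matrix(runif(32 * 20), 32, 20) < 0.25) * 1L,
                    class = "trace_mask")

  cor <- corrupt_sinogram(lab, mask)
  expect_true(all(cor$values[mask == 1] == 0))
  expect_identical(cor$values[mask == 0], lab$values[mask == 0])
  expect_equal(sum(cor$values == 0), sum(mask))  # label strictly positive
  # idempotence
  expect_identical(corrupt_sinogram(cor, mask)$values, cor$values)

  set.seed(2)
  completed <- sinogram(matrix(runif(32 * 20), 32, 20), g)
  comp <- composite_sinogram(completed, cor, mask)
  expect_identical(comp$values[mask == 0], cor$values[mask == 0])
  expect_identical(comp$values[mask == 1], completed$values[mask == 1])
  # all-zero / all-one masks
  m0 <- structure(matrix(0L, 32, 20), class = "trace_mask")
  m1 <- structure(matrix(1L, 32, 20), class = "trace_mask")
  expect_identical(composite_sinogram(completed, lab, m0)$values, lab$values)
  expect_identical(composite_sinogram(completed, lab, m1)$values,
                   completed$values)
  expect_error(corrupt_sinogram(lab, structure(matrix(0L, 5, 5),
                                               class = "trace_mask")),
               "incongruent")
})

test_that("simulated pairs satisfy the pairing invariants and track the metal sinusoid", {
  g <- small_geometry(96, 60)
  sp <- sample_random_phantom(21, metal_config())
  pair <- make_sinogram_pair(sp, g, dilation_px = 1)
  expect_true(all(pair$corrupted$values[pair$mask == 1] == 0))
  expect_identical(pair$corrupted$values[pair$mask == 0],
                   pair$label$values[pair$mask == 0])

  # determinism from the seed
  pair2 <- make_sinogram_pair(sample_random_phantom(21, metal_config()), g,
                              dilation_px = 1)
  expect_identical(pair$corrupted$values, pair2$corrupted$values)
  expect_identical(unclass(pair$mask), unclass(pair2$mask))

  # no metal -> empty mask, corrupted == label
  pb <- make_sinogram_pair(sample_random_phantom(5, body_config()), g)
  expect_equal(sum(pb$mask), 0)
  expect_identical(pb$corrupted$values, pb$label$values)

  # single compact insert: per-angle trace centre follows x0 cos + y0 sin
  one <- phantom_spec(list(ellipse_spec(0, 0, 0.8, 0.7, 0, 0.5)),
                      metal_inserts = list(ellipse_spec(0.3, -0.15, 0.06, 0.06, 0, 6)),
                      image_size = 64)
  po <- make_sinogram_pair(one, g, dilation_px = 0)
  th <- g$angles_deg * pi / 180
  l <- detector_offsets(g)
  centers <- apply(unclass(po$mask), 2, function(col) mean(l[col == 1]))
  expected <- 0.3 * 32 * cos(th) - 0.15 * 32 * sin(th)
  expect_true(all(abs(centers - expected) <= 1.5))

  # body-only label mode leaves the metal out of the label
  pf <- make_sinogram_pair(one, g, label_mode = "full")
  pbod <- make_sinogram_pair(one, g, label_mode = "body")
  expect_gt(sum(pf$label$values), sum(pbod$label$values))
})
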