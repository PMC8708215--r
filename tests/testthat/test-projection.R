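test_that("forward projection matches analytic chords and a brute-force ray oracle", {
  g <- small_geometry(64, 36)
  zero <- forward_project(atten_image(matrix(0, 64, 64)), g)
  expect_equal(zero$values, matrix(0, 64, 36))

  # disk of radius 16 px: central bins read the chord 2*sqrt(r^2 - l^2)
  img <- render_phantom(disk_phantom(0.5, 1, 64))
  s <- forward_project(img, g)
  l <- detector_offsets(g)
  for (d in c(32, 33)) {
    chord <- 2 * sqrt(256 - l[d]^2)
    expect_true(all(abs(s$values[d, ] - chord) / chord < 0.02))
  }
  # off-centre bin, slightly looser (interpolation near the disk edge)
  chord40 <- 2 * sqrt(256 - l[40]^2)
  expect_true(all(abs(s$values[40, ] - chord40) / chord40 < 0.03))

  # off-centre blob: per-angle argmax tracks x0 cos + y0 sin within 1 bin
  blob <- render_phantom(phantom_spec(list(ellipse_spec(0.4, -0.2, 0.06, 0.06, 0, 1)),
                                      image_size = 64))
  sb <- forward_project(blob, g)
  th <- g$angles_deg * pi / 180
  expected_l <- 0.4 * 32 * cos(th) + (-0.2) * 32 * sin(th)
  got_l <- l[apply(sb$values, 2, which.max)]
  expect_true(all(abs(got_l - expected_l) <= 1.5))

  # spot-check raw values against the independent fine-sampled ray oracle
  for (k in c(10, 45, 80)) {
    d <- 20 + (3 * k) %% 25
    j <- k %% 36 + 1
    expect_lt(abs(s$values[d, j] -
                    brute_ray_integral(img$values, g$angles_deg[j], l[d])),
              0.35)
  }
})

test_that("projection is linear and even under a half-turn", {
  g <- small_geometry(64, 40)
  a <- render_phantom(sample_random_phantom(1, body_config()))
  b <- render_phantom(sample_random_phantom(2, body_config()))
  sa <- forward_project(a, g)$values
  sb <- forward_project(b, g)$values
  sab <- forward_project(atten_image(2 * a$values + 0.5 * b$values), g)$values
  expect_lt(max(abs(sab - 2 * sa - 0.5 * sb)), 1e-8 * max(abs(sab)))

  # g(theta + 180, l) == g(theta, -l)
  g2 <- small_geometry(64, 8)
  s <- forward_project(a, g2)$values
  flip <- scan_geometry(64, angles_deg = g2$angles_deg[1:4] + 180)
  s2 <- forward_project(a, flip)$values
  expect_lt(max(abs(s2 - s[64:1, 1:4])), 0.02 * max(s))
})

test_that("truncated support raises the sinogram warning flag", {
  wide <- atten_image(matrix(1, 64, 64))
  expect_warning(s <- forward_project(wide, small_geometry(48, 12)),
                 "truncation")
  expect_true(s$truncated)
})

test_that("image moments agree with the brute-force oracle and translation rule", {
  img <- render_phantom(disk_phantom(0.5, 1, 64))
  m <- image_moments(img, 2)
  expect_lt(abs(moment_get(m, 0, 0) - pi * 16^2) / (pi * 16^2), 0.01)
  expect_lt(abs(moment_get(m, 1, 0)), 1e-9)
  expect_lt(abs(moment_get(m, 0, 1)), 1e-9)

  blob <- render_phantom(phantom_spec(list(ellipse_spec(0.3, -0.1, 0.2, 0.15, 25, 0.7)),
                                      image_size = 48))
  mb <- image_moments(blob, 2)
  for (ij in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2))) {
    expect_equal(moment_get(mb, ij[1], ij[2]),
                 brute_moment(blob$values, ij[1], ij[2]), tolerance = 1e-12)
  }

  # translation identity: shifting by +d columns adds d*m00 to m10
  shifted <- blob$values[, c(5:48, 1:4)] * 0  # build explicit shifted copy
  shifted[, 5:48] <- blob$values[, 1:44]
  ms <- image_moments(atten_image(shifted), 1)
  expect_equal(moment_get(ms, 1, 0),
               moment_get(mb, 1, 0) + 4 * moment_get(mb, 0, 0),
               tolerance = 1e-6)
})

test_that("Helgason-Ludwig consistency holds for orders 0-2 and degrades under trace zeroing", {
  g <- small_geometry(64, 90)
  img <- render_phantom(sample_random_phantom(4, body_config()))
  s <- forward_project(img, g)

  r0 <- hlcc_residual(s, img, 0)
  expect_lt(max(abs(r0$residual)) / moment_get(image_moments(img, 0), 0, 0),
            0.01)
  expect_lt(v0_consistency(s), 0.01)

  off <- render_phantom(phantom_spec(list(ellipse_spec(0.35, 0.2, 0.08, 0.06, 10, 1)),
                                     image_size = 64))
  so <- forward_project(off, g)
  r1 <- hlcc_residual(so, off, 1)
  expect_lt(max(abs(r1$residual)) / max(abs(r1$Vk)), 0.01)

  # zeroing metal traces breaks the angle-independence of V0
  sp <- sample_random_phantom(9, metal_config())
  pair <- make_sinogram_pair(sp, g, dilation_px = 2)
  expect_gt(v0_consistency(pair$corrupted), v0_consistency(pair$label))
})

test_that("FBP inverts the projector on smooth phantoms", {
  g <- scan_geometry(128, 360)
  spec <- sample_random_phantom(11, body_config(128))
  img <- render_phantom(spec)
  rec <- fbp_reconstruct(forward_project(img, g), size = 128)
  interior <- interior_mask(spec)
  rel <- sqrt(mean((rec$values[interior] - img$values[interior])^2)) /
    sqrt(mean(img$values[interior]^2))
  expect_lt(rel, 0.05)

  # central value of a disk reconstructs to its attenuation
  disk <- render_phantom(disk_phantom(0.4, 1, 128))
  rd <- fbp_reconstruct(forward_project(disk, g), size = 128)
  expect_lt(abs(rd$values[64, 64] - 1), 0.1)

  # half-turn scans carry the same information for parallel beams
  gh <- scan_geometry(128, 180, span = "half")
  rh <- fbp_reconstruct(forward_project(disk, gh), size = 128)
  expect_lt(abs(rh$values[64, 64] - 1), 0.1)

  # zero in, zero out; single angle rejected
  zs <- sinogram(matrix(0, 128, 360), g)
  expect_equal(max(abs(fbp_reconstruct(zs)$values)), 0)
  expect_error(fbp_reconstruct(sinogram(matrix(0, 16, 1),
                                        scan_geometry(16, 1))),
               "at least 2")
})
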