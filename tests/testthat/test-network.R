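test_that("losses reproduce the worked example and their symmetries", {
  fx <- loss_fixture()
  expect_equal(loss_l2(fx$f, fx$fhat, fx$M), 4)
  expect_equal(loss_amp(fx$f, fx$fhat), 4)
  expect_equal(loss_diff(fx$f, fx$fhat), 4)
  tl <- total_loss(fx$f, fx$fhat, fx$M)
  expect_equal(unlist(tl[c("l2", "amp", "diff", "total")]),
               c(l2 = 4, amp = 4, diff = 4, total = 12))

  # identical arguments vanish; all-zero mask kills the L2 term
  expect_equal(total_loss(fx$f, fx$f, fx$M)$total, 0)
  expect_equal(loss_l2(fx$f, fx$fhat, fx$M * 0), 0)

  # adding a constant to a whole column leaves the amplitude term unchanged
  g <- fx$f; g[, 2] <- g[, 2] + 3.7
  expect_equal(loss_amp(g, fx$fhat), loss_amp(fx$f, fx$fhat))
  # permuting within a column (sum preserved) leaves the difference term
  set.seed(1)
  h <- matrix(runif(40), 8, 5)
  hp <- h; hp[, 3] <- h[sample(8), 3]
  expect_equal(loss_diff(hp, matrix(0, 8, 5)), loss_diff(h, matrix(0, 8, 5)))

  # weight contract: (1, 0, 0) reduces the total to the masked L2
  expect_equal(total_loss(fx$f, fx$fhat, fx$M,
                          c(l2 = 1, amp = 0, diff = 0))$total, 4)
  expect_error(total_loss(fx$f, fx$fhat, fx$M, c(l2 = -1, amp = 1, diff = 1)),
               "non-negative")
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(4)
  out <- matrix(runif(60), 10, 6)
  lab <- matrix(runif(60), 10, 6)
  m <- matrix(rbinom(60, 1, 0.3), 10, 6)
  w <- c(l2 = 1, amp = 0.7, diff = 1.3)
  g <- total_loss_grad(out, lab, m, w)
  h <- 1e-6
  for (idx in sample(60, 12)) {
    p <- out; p[idx] <- p[idx] + h
    q <- out; q[idx] <- q[idx] - h
    fd <- (total_loss(p, lab, m, w)$total - total_loss(q, lab, m, w)$total) / (2 * h)
    expect_equal(g[idx], fd, tolerance = 1e-6)
  }
})

test_that("network construction is seeded and shape-preserving", {
  cfg <- net_config(depth = 4, base_channels = 16)
  expect_equal(cfg$channel_schedule, c(16L, 32L, 64L, 128L))
  expect_equal(cfg$bottleneck_channels, 128L)

  n1 <- build_unet(cfg, seed = 11)
  n2 <- build_unet(cfg, seed = 11)
  n3 <- build_unet(cfg, seed = 12)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, n3$params))

  # output shape equals input shape (single-channel in, single-channel out)
  tiny <- tiny_net(seed = 2)
  x <- matrix(runif(16 * 24), 16, 24)
  y <- unet_forward(tiny, x)
  expect_equal(dim(y), c(16, 24, 1))
  expect_true(all(is.finite(y)))
  expect_error(unet_forward(tiny, matrix(0, 15, 24)), "divisible")
})

test_that("the forward pass agrees with an independent plain-R network", {
  cfg <- net_config(depth = 2, base_channels = 3, leaky_slope = 0.2)
  net <- build_unet(cfg, seed = 5)
  set.seed(6)
  x <- matrix(runif(12 * 16), 12, 16)
  y <- unet_forward(net, x)[, , 1]
  yref <- ref_unet_forward(net$params, x, 2, sinomar:::net_channels(cfg), 0.2)
  expect_lt(max(abs(y - yref)), 1e-5 * max(1, max(abs(yref))))
})

test_that("backpropagation matches finite differences of the reference network", {
  cfg <- net_config(depth = 2, base_channels = 2, leaky_slope = 0.2)
  net <- build_unet(cfg, seed = 7)
  ch <- sinomar:::net_channels(cfg)
  set.seed(42)
  H <- 8; W <- 8
  x <- matrix(runif(H * W), H, W)
  lab <- matrix(runif(H * W), H, W)
  msk <- matrix(rbinom(H * W, 1, 0.3), H, W)
  res <- sinomar:::unet_step_cpp(net$params, x, lab, msk,
                                 as.integer(c(H, W, 1)), 2, ch, 0.2,
                                 1, 1, 1, TRUE)
  reflo <- function(params)
    total_loss(ref_unet_forward(params, x, 2, ch, 0.2), lab, msk)$total
  expect_equal(res$total, reflo(net$params), tolerance = 1e-5)
  h <- 1e-6
  for (k in seq_along(net$params)) {
    i <- (13 * k) %% length(net$params[[k]]$W) + 1
    p1 <- net$params; p1[[k]]$W[i] <- p1[[k]]$W[i] + h
    p2 <- net$params; p2[[k]]$W[i] <- p2[[k]]$W[i] - h
    fd <- (reflo(p1) - reflo(p2)) / (2 * h)
    an <- res$grads[[k]]$W[i]
    # single precision forward: tolerance scales with the gradient size
    expect_lt(abs(fd - an), 2e-3 * max(1, abs(fd)))
  }
})

test_that("padding for the network inverts exactly", {
  g <- scan_geometry(96, 90)
  set.seed(9)
  s <- sinogram(matrix(runif(96 * 90), 96, 90), g)
  p <- pad_for_net(s, 5)
  expect_equal(dim(p$values), c(96, 96))
  # circular angle continuation: padded column 90 + j equals column j
  expect_identical(p$values[, 91:96], s$values[, 1:6])
  expect_identical(crop_from_net(p$values, p$crop), s$values)

  # already divisible input is unchanged
  p2 <- pad_for_net(matrix(1, 32, 32), 5)
  expect_identical(p2$values, matrix(1, 32, 32))

  # detector axis pads with zeros, split symmetrically
  p3 <- pad_for_net(matrix(1, 30, 32), 4)
  expect_equal(dim(p3$values), c(32, 32))
  expect_equal(p3$crop[1], 1)
  expect_true(all(p3$values[c(1, 32), ] == 0))
})

test_that("a short training run is reproducible and reduces the loss", {
  g <- small_geometry(32, 32)
  pairs <- simulate_pairs(12, 31, metal_config(32), g, dilation_px = 1)
  cfg <- net_config(depth = 2, base_channels = 4)
  tc <- train_config(steps = 40, batch_size = 4, lr = 1e-3, seed = 5)
  n1 <- train_unet(pairs, build_unet(cfg, 5), tc)
  n2 <- train_unet(pairs, build_unet(cfg, 5), tc)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$history, n2$history)
  expect_true(all(is.finite(n1$history$total)))
  # loss decreases over the run
  expect_lt(mean(tail(n1$history$total, 5)), mean(head(n1$history$total, 5)))
  expect_equal(n1$scale, max(vapply(pairs, function(p) max(p$label$values),
                                    numeric(1))))

  # ablation flags produce distinct configurations
  tcs <- list(train_config(use_mask = TRUE),
              train_config(use_mask = FALSE),
              train_config(use_amp = FALSE, use_diff = FALSE),
              train_config(use_amp = FALSE, use_diff = FALSE,
                           use_mask = FALSE))
  keys <- vapply(tcs, function(t) paste(t$use_mask, t$w_amp, t$w_diff),
                 character(1))
  expect_equal(length(unique(keys)), 4)
})

test_that("completion preserves unaffected entries bit-exactly", {
  g <- small_geometry(32, 32)
  net <- tiny_net(seed = 3)
  net$scale <- 1.7
  set.seed(10)
  for (i in 1:5) {
    vals <- matrix(runif(32 * 32, 0, 3), 32, 32)
    m <- structure((matrix(runif(32 * 32), 32, 32) < 0.2) * 1L,
                   class = "trace_mask")
    s <- corrupt_sinogram(sinogram(vals, g), m)
    comp <- complete_sinogram(s, m, net)
    expect_identical(comp$values[m == 0], s$values[m == 0])
    expect_true(all(is.finite(comp$values)))
  }
  net$scale <- NA_real_
  s <- sinogram(matrix(1, 32, 32), g)
  m <- structure(matrix(0L, 32, 32), class = "trace_mask")
  expect_error(complete_sinogram(s, m, net), "scale")
})
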