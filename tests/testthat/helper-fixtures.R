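# Shared fixtures and independent oracles for the test suite.

# centred disk phantom: radius as image fraction, attenuation mu
disk_phantom <- function(radius = 0.5, mu = 1, size = 64) {
  phantom_spec(list(ellipse_spec(0, 0, radius, radius, 0, mu)),
               image_size = size)
}

small_geometry <- function(n_det = 64, n_ang = 90, span = "full") {
  scan_geometry(n_detectors = n_det, n_angles = n_ang, span = span)
}

# body-only generator configs used across tests
body_config <- function(size = 64) {
  phantom_gen_config(image_size = size, metal_count = c(0, 0))
}

metal_config <- function(size = 64, metal_count = c(1, 2)) {
  phantom_gen_config(image_size = size, metal_count = metal_count)
}

# brute-force ray integral oracle: fine sampling, bilinear interpolation,
# independent of the C++ projector
brute_ray_integral <- function(img, theta_deg, l, step = 0.25) {
  n <- nrow(img)
  cen <- (n - 1) / 2
  th <- theta_deg * pi / 180
  t <- seq(-n / 2 - 2, n / 2 + 2, by = step)
  xs <- l * cos(th) - t * sin(th)
  ys <- l * sin(th) + t * cos(th)
  rows <- cen - ys
  cols <- xs + cen
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- function(r, c) {
    ok <- r >= 0 & r < n & c >= 0 & c < n
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  s <- (1 - fr) * ((1 - fc) * val(r0, c0) + fc * val(r0, c0 + 1)) +
    fr * ((1 - fc) * val(r0 + 1, c0) + fc * val(r0 + 1, c0 + 1))
  sum(s) * step
}

# brute-force geometric moments by explicit double loop (oracle)
brute_moment <- function(img, i, j) {
  n <- nrow(img)
  acc <- 0
  for (r in seq_len(n)) {
    y <- (n - 1) / 2 - (r - 1)
    for (c in seq_len(n)) {
      x <- (c - 1) - (n - 1) / 2
      acc <- acc + x^i * y^j * img[r, c]
    }
  }
  acc
}

# connected-component count by flood fill (oracle for segmentation tests)
flood_components <- function(mask) {
  m <- mask != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  for (r0 in seq_len(nrow(m))) for (c0 in seq_len(ncol(m))) {
    if (!m[r0, c0] || lab[r0, c0] != 0) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && lab[r, c] == 0) {
          lab[r, c] <- k
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  k
}

# interior-of-support mask: the phantom's body outline (first ellipse)
# shrunk towards its centre, so reconstruction error is measured strictly
# inside the support, away from the boundary discontinuity
interior_mask <- function(spec, shrink = 0.85) {
  e <- spec$ellipses[[1]]
  n <- spec$image_size
  xf <- (seq_len(n) - 1 - (n - 1) / 2) / (n / 2)
  yf <- -xf
  th <- e$rotation * pi / 180
  dx <- outer(rep(1, n), xf) - e$center_x
  dy <- outer(yf, rep(1, n)) - e$center_y
  u <- (dx * cos(th) + dy * sin(th)) / (e$semi_axis_a * shrink)
  v <- (-dx * sin(th) + dy * cos(th)) / (e$semi_axis_b * shrink)
  u * u + v * v <= 1
}

# tiny network fixture (fast to build and run)
tiny_net <- function(seed = 1, depth = 2, base = 2) {
  build_unet(net_config(depth = depth, base_channels = base), seed = seed)
}

# reference forward pass of the network in plain R (independent oracle)
ref_conv_s1 <- function(x, W, b, slope) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Ci <- dim(x)[3]; Co <- nrow(W)
  y <- array(0, c(H, Wd, Co))
  xp <- array(0, c(H + 2, Wd + 2, Ci)); xp[2:(H + 1), 2:(Wd + 1), ] <- x
  for (co in 1:Co) for (t in 0:8) {
    dy <- t %% 3; dx <- t %/% 3
    for (ci in 1:Ci) {
      w <- W[co, t * Ci + ci]
      if (w != 0) y[, , co] <- y[, , co] + w * xp[(1:H) + dy, (1:Wd) + dx, ci]
    }
  }
  for (co in 1:Co) y[, , co] <- y[, , co] + b[co]
  ifelse(y > 0, y, slope * y)
}

ref_down <- function(x, W, b, slope) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Ci <- dim(x)[3]; Co <- nrow(W)
  Hc <- H / 2; Wc <- Wd / 2
  y <- array(0, c(Hc, Wc, Co))
  xp <- array(0, c(H + 2, Wd + 2, Ci)); xp[2:(H + 1), 2:(Wd + 1), ] <- x
  for (co in 1:Co) for (t in 0:8) {
    dy <- t %% 3; dx <- t %/% 3
    for (ci in 1:Ci) {
      w <- W[co, t * Ci + ci]
      if (w != 0)
        y[, , co] <- y[, , co] + w * xp[2 * (1:Hc) - 1 + dy, 2 * (1:Wc) - 1 + dx, ci]
    }
  }
  for (co in 1:Co) y[, , co] <- y[, , co] + b[co]
  ifelse(y > 0, y, slope * y)
}

ref_up <- function(x, W, b) {
  Hc <- dim(x)[1]; Wc <- dim(x)[2]; Clo <- ncol(W) / 9
  Hf <- 2 * Hc; Wf <- 2 * Wc
  u <- array(0, c(Hf, Wf, Clo))
  for (oy in 1:Hc) for (ox in 1:Wc) {
    v <- drop(t(W) %*% x[oy, ox, ])
    for (t in 0:8) {
      dy <- t %% 3; dx <- t %/% 3
      rf <- 2 * oy - 2 + dy; cf <- 2 * ox - 2 + dx
      if (rf >= 1 && rf <= Hf && cf >= 1 && cf <= Wf)
        u[rf, cf, ] <- u[rf, cf, ] + v[t * Clo + 1:Clo]
    }
  }
  for (c in 1:Clo) u[, , c] <- u[, , c] + b[c]
  pmax(u, 0)
}

ref_unet_forward <- function(params, x, depth, channels, slope) {
  d <- depth
  idx_a <- function(i) 3 * (i - 1) + 1
  idx_b <- function(i) 3 * (i - 1) + 2
  idx_dn <- function(i) 3 * (i - 1) + 3
  idx_up <- function(i) 3 * d + 3 + 2 * (d - i)
  idx_dc <- function(i) 3 * d + 4 + 2 * (d - i)
  cur <- array(x, c(dim(x), 1))
  skips <- list()
  for (i in 1:d) {
    a <- ref_conv_s1(cur, params[[idx_a(i)]]$W, params[[idx_a(i)]]$b, slope)
    s <- ref_conv_s1(a, params[[idx_b(i)]]$W, params[[idx_b(i)]]$b, slope)
    skips[[i]] <- s
    cur <- ref_down(s, params[[idx_dn(i)]]$W, params[[idx_dn(i)]]$b, slope)
  }
  cur <- ref_conv_s1(cur, params[[3 * d + 1]]$W, params[[3 * d + 1]]$b, slope)
  cur <- ref_conv_s1(cur, params[[3 * d + 2]]$W, params[[3 * d + 2]]$b, slope)
  for (i in d:1) {
    u <- ref_up(cur, params[[idx_up(i)]]$W, params[[idx_up(i)]]$b)
    cat_ <- array(c(u, skips[[i]]),
                  c(dim(u)[1], dim(u)[2], dim(u)[3] + dim(skips[[i]])[3]))
    cur <- ref_conv_s1(cat_, params[[idx_dc(i)]]$W, params[[idx_dc(i)]]$b, 0)
  }
  y <- ref_conv_s1(cur, params[[5 * d + 3]]$W, params[[5 * d + 3]]$b, 1)
  y[, , 1]
}

# hand fixture used for the loss worked example
loss_fixture <- function() {
  list(f = matrix(c(1, 3, 2, 4), 2, 2),      # rows = detector bins
       fhat = matrix(c(1, 5, 2, 4), 2, 2),
       M = matrix(c(0, 1, 0, 0), 2, 2))
}
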