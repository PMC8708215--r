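test_that("linear interpolation recovers affine columns and never overshoots", {
  g <- small_geometry(32, 6)
  set.seed(3)
  m <- structure(matrix(0L, 32, 6), class = "trace_mask")
  m[10:15, 2] <- 1L
  m[c(3:5, 20:26), 3] <- 1L
  m[1:4, 4] <- 1L          # boundary gap
  m[, 5] <- 1L             # fully masked column

  # affine-in-detector data: interior gaps recovered to machine precision
  affine <- outer(seq_len(32), seq_len(6), function(i, j) 2 * i + 10 * j)
  s <- sinogram(affine, g)
  expect_warning(out <- li_mar(corrupt_sinogram(s, m), m), "fully masked")
  for (j in c(2, 3)) {
    interior <- m[, j] == 1 & seq_len(32) > 1 & seq_len(32) < 32
    expect_equal(out$values[interior, j], affine[interior, j],
                 tolerance = 1e-12)
  }
  # boundary gap: constant extrapolation from the lone anchor side
  expect_equal(out$values[1:4, 4], rep(affine[5, 4], 4))
  # fully masked column filled with zeros and flagged
  expect_equal(out$values[, 5], rep(0, 32))
  expect_equal(attr(out, "empty_columns"), 5L)

  # unmasked entries bit-exact, and empty mask is the identity
  expect_identical(out$values[m == 0 & col(m) != 5],
                   affine[m == 0 & col(m) != 5])
  m0 <- structure(matrix(0L, 32, 6), class = "trace_mask")
  expect_identical(li_mar(s, m0)$values, affine)
})

test_that("interpolation is bounded by its anchors and idempotent", {
  g <- small_geometry(48, 30)
  set.seed(8)
  vals <- matrix(runif(48 * 30, 0, 5), 48, 30)
  m <- structure(matrix(0L, 48, 30), class = "trace_mask")
  for (j in seq_len(30)) {
    a <- sample(2:40, 1)
    m[a:(a + sample(2:6, 1)), j] <- 1L
  }
  s <- sinogram(vals, g)
  out <- li_mar(corrupt_sinogram(s, m), m)
  for (j in seq_len(30)) {
    runs <- rle(m[, j] == 1)
    pos <- cumsum(c(1, runs$lengths))
    for (k in which(runs$values)) {
      lo <- pos[k] - 1; hi <- pos[k + 1]
      if (lo < 1 || hi > 48) next
      lohi <- range(vals[c(lo, hi), j])
      seg <- out$values[pos[k]:(pos[k + 1] - 1), j]
      expect_true(all(seg >= lohi[1] - 1e-12 & seg <= lohi[2] + 1e-12))
    }
  }
  again <- li_mar(out, m)
  expect_identical(again$values, out$values)
})
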