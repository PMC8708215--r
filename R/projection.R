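#' Parallel-beam scan geometry
#'
#' The detector array is centred on the rotation axis with spacing 1 pixel
#' unit; detector bin d (1-based) sits at signed offset
#' `(d - 1 - (n_detectors - 1)/2) * detector_spacing`.  Angles are uniform
#' over \[0, 360) degrees by default; parallel-beam data are redundant over
#' 360 degrees, so a \[0, 180) mode is also available.
#'
#' @param n_detectors number of detector bins
#' @param n_angles number of projection angles
#' @param span `"full"` for \[0, 360) or `"half"` for \[0, 180)
#' @param detector_spacing detector bin spacing in pixel units
#' @param angles_deg optional explicit angle list (degrees, strictly
#'   increasing, within one period); overrides `n_angles`/`span`
#' @return a `scan_geometry` object
#' @export
scan_geometry <- function(n_detectors = 512, n_angles = 360,
                          span = c("full", "half"), detector_spacing = 1,
                          angles_deg = NULL) {
  span <- match.arg(span)
  if (is.null(angles_deg)) {
    period <- if (span == "full") 360 else 180
    angles_deg <- seq(0, period - period / n_angles, length.out = n_angles)
  } else {
    if (any(diff(angles_deg) <= 0))
      stop("angles must be strictly increasing")
    if (max(angles_deg) - min(angles_deg) >= 360)
      stop("angles must lie within one period")
  }
  stopifnot(n_detectors >= 2)
  structure(list(n_detectors = as.integer(n_detectors),
                 angles_deg = angles_deg,
                 detector_spacing = detector_spacing, span = span),
            class = "scan_geometry")
}

#' Signed detector offsets of a geometry (pixel units)
#' @param geometry a [scan_geometry()]
#' @export
detector_offsets <- function(geometry) {
  (seq_len(geometry$n_detectors) - 1 -
     (geometry$n_detectors - 1) / 2) * geometry$detector_spacing
}

#' Sinogram container
#'
#' Values are stored as an `(n_detectors, n_angles)` matrix: rows index the
#' detector position x, columns the projection angle.  `scale` records the
#' normalization used for network input (global maximum of the clean
#' training sinograms), so completed sinograms can be un-normalized before
#' reconstruction.
#'
#' @param values numeric matrix, shape `(n_detectors, n_angles)`
#' @param geometry the [scan_geometry()] the values were measured on
#' @param scale recorded normalization factor (NA until set by training)
#' @export
sinogram <- function(values, geometry, scale = NA_real_) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "scan_geometry"))
  if (nrow(values) != geometry$n_detectors ||
      ncol(values) != length(geometry$angles_deg))
    stop("sinogram shape does not match its geometry")
  if (any(!is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, geometry = geometry, scale = scale,
                 truncated = FALSE),
            class = "sinogram")
}

#' @export
as.matrix.sinogram <- function(x, ...) x$values

#' @export
as.matrix.atten_image <- function(x, ...) x$values

#' Forward projection (Radon transform)
#'
#' Ray-driven line integrals with bilinear sampling along each ray
#' (step 0.5 pixel).  Non-negative images give non-negative sinograms up to
#' interpolation tolerance.  If mass is detected in the two outermost
#' detector bins (support truncation) the returned sinogram carries a
#' `truncated = TRUE` flag and a warning is raised.
#'
#' @param image an [atten_image()] (square)
#' @param geometry a [scan_geometry()] whose detector span covers the
#'   image support
#' @param step ray sampling step in pixel units
#' @return a [sinogram()]
#' @export
forward_project <- function(image, geometry, step = 0.5) {
  stopifnot(inherits(image, "atten_image"), inherits(geometry, "scan_geometry"))
  vals <- radon_forward_cpp(image$values, geometry$angles_deg * pi / 180,
                            geometry$n_detectors, geometry$detector_spacing,
                            step)
  s <- sinogram(vals, geometry)
  edge <- max(abs(vals[c(1, nrow(vals)), ]))
  if (edge > 1e-6 * max(abs(vals), 1e-12)) {
    warning("support truncation: nonzero mass at the outermost detector bins")
    s$truncated <- TRUE
  }
  s
}

# discrete ramp (Ram-Lak) convolution kernel evaluated in frequency space;
# the spatial form (1/4 at 0, -1/(pi n)^2 at odd lags) avoids the DC bias
# of sampling |w| directly
ramp_filter_freq <- function(L, spacing) {
  h <- numeric(L)
  h[1] <- 1 / (4 * spacing^2)
  n <- seq_len(L - 1)
  lag <- ifelse(n <= L / 2, n, n - L)     # circular lags
  odd <- lag %% 2 != 0
  h[1 + n[odd]] <- -1 / (pi * lag[odd] * spacing)^2
  Re(fft(h))
}

#' Filtered back projection reconstruction
#'
#' Ramp (Ram-Lak) filtering of each projection followed by pixel-driven
#' linear-interpolation back projection on the sinogram's own geometry.
#' For a full 360-degree scan conjugate rays are implicitly averaged by the
#' `pi / n_angles` quadrature weight.
#'
#' @param sino a [sinogram()] (untruncated, at least 2 angles)
#' @param size output image side in pixels (defaults to `n_detectors`)
#' @return an [atten_image()]
#' @export
fbp_reconstruct <- function(sino, size = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  if (length(g$angles_deg) < 2)
    stop("FBP needs at least 2 projection angles")
  nd <- g$n_detectors
  size <- size %||% nd
  L <- 2^ceiling(log2(2 * nd))
  H <- ramp_filter_freq(L, g$detector_spacing)
  padded <- rbind(sino$values, matrix(0, L - nd, ncol(sino$values)))
  q <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / L
  q <- q[seq_len(nd), , drop = FALSE] * g$detector_spacing
  vals <- backproject_cpp(q, g$angles_deg * pi / 180, as.integer(size),
                          g$detector_spacing)
  atten_image(vals)
}

#' Projection moments of a sinogram
#'
#' The k-order moment of the projection at angle theta is the discrete
#' quadrature `V_k(theta) = sum_x l(x)^k g(x, theta) * detector_spacing`,
#' with l(x) the signed detector offset.  Order 0 is the total projected
#' mass per angle, which for consistent parallel-beam data is independent
#' of the angle.
#'
#' @param sino a [sinogram()]
#' @param k moment order (integer >= 0)
#' @return numeric vector `V_k(theta)`, one entry per geometry angle
#' @export
projection_moment <- function(sino, k) {
  stopifnot(inherits(sino, "sinogram"))
  if (k < 0) stop("moment order k must be >= 0")
  l <- detector_offsets(sino$geometry)
  colSums(l^k * sino$values) * sino$geometry$detector_spacing
}

#' Geometric image moments
#'
#' `m_ij = sum_pixels x^i y^j f(x, y) * pixel_area` in the centred physical
#' frame shared with the projector (x rightward, y upward, origin at the
#' image centre, pixel units).
#'
#' @param image an [atten_image()]
#' @param k_max maximum total order i + j
#' @return data frame with columns `i`, `j`, `value`, class `image_moments`
#' @export
image_moments <- function(image, k_max) {
  stopifnot(inherits(image, "atten_image"), k_max >= 0)
  n <- nrow(image$values)
  sp <- image$pixel_spacing
  x <- (seq_len(n) - 1 - (n - 1) / 2) * sp   # by column
  y <- ((n - 1) / 2 - (seq_len(n) - 1)) * sp # by row
  out <- expand.grid(i = 0:k_max, j = 0:k_max)
  out <- out[out$i + out$j <= k_max, , drop = FALSE]
  out$value <- mapply(function(i, j) {
    sum((y^j %o% x^i) * image$values) * sp^2
  }, out$i, out$j)
  structure(out[order(out$i + out$j, out$i), ],
            class = c("image_moments", "data.frame"))
}

#' Look up one geometric moment
#' @param m an [image_moments()] table
#' @param i,j orders
#' @export
moment_get <- function(m, i, j) {
  v <- m$value[m$i == i & m$j == j]
  if (length(v) != 1) stop(sprintf("moment (%d, %d) not in table", i, j))
  v
}

#' Helgason-Ludwig consistency residuals
#'
#' For order k the projection moment must equal the angular polynomial of
#' image moments: `V_k(theta) = sum_r C(k, r) m_{r, k-r} cos^r(theta)
#' sin^{k-r}(theta)`.  The residual per angle is `V_k - M_k`.  Order 0
#' states that the projected mass is the same constant `m_00` at every
#' angle.
#'
#' @param sino a [sinogram()] of `image` on a congruent frame
#' @param image the [atten_image()] the sinogram was projected from
#' @param k moment order
#' @return list with `residual` (per angle), `Vk`, `Mk`
#' @export
hlcc_residual <- function(sino, image, k) {
  stopifnot(inherits(sino, "sinogram"), inherits(image, "atten_image"))
  if (nrow(image$values) > sino$geometry$n_detectors *
        sino$geometry$detector_spacing * sqrt(2) + 2)
    stop("geometry mismatch: detector span cannot cover the image frame")
  Vk <- projection_moment(sino, k)
  m <- image_moments(image, k)
  th <- sino$geometry$angles_deg * pi / 180
  Mk <- rowSums(vapply(0:k, function(r) {
    choose(k, r) * moment_get(m, r, k - r) * cos(th)^r * sin(th)^(k - r)
  }, numeric(length(th))))
  list(residual = Vk - Mk, Vk = Vk, Mk = Mk)
}

#' Angle-independence score of the zeroth projection moment
#'
#' Coefficient of variation of `V_0(theta)` across angles; a sinogram-only
#' consistency score that needs no reference image.  Zeroing metal traces
#' removes angle-dependent mass and strictly increases this score.
#'
#' @param sino a [sinogram()]
#' @export
v0_consistency <- function(sino) {
  v0 <- projection_moment(sino, 0)
  sd(v0) / mean(v0)
}
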