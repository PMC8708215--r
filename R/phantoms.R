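#' Ellipse component of a phantom
#'
#' Coordinates are image fractions in \[-1, 1\] with the origin at the image
#' centre, x rightward and y upward; a length of 1 equals half the image
#' side, so the unit disk is the inscribed disk of the image.  Attenuation
#' is additive where ellipses overlap.
#'
#' @param center_x,center_y ellipse centre (image-fraction coordinates)
#' @param semi_axis_a,semi_axis_b semi-axes (image fractions, > 0)
#' @param rotation rotation of the first axis, degrees counter-clockwise
#' @param attenuation_delta additive attenuation inside the ellipse
#'   (arbitrary units per pixel length)
#' @return an `ellipse_spec` object
#' @export
ellipse_spec <- function(center_x, center_y, semi_axis_a, semi_axis_b,
                         rotation = 0, attenuation_delta = 1) {
  if (!(semi_axis_a > 0 && semi_axis_b > 0))
    stop("ellipse semi-axes must be strictly positive")
  e <- structure(list(center_x = center_x, center_y = center_y,
                      semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                      rotation = rotation,
                      attenuation_delta = attenuation_delta),
                 class = "ellipse_spec")
  if (!ellipse_in_unit_disk(e))
    stop(sprintf(paste0("ellipse at (%.3f, %.3f) with semi-axes (%.3f, %.3f)",
                        " extends outside the unit disk; projections would",
                        " be truncated"),
                 center_x, center_y, semi_axis_a, semi_axis_b))
  e
}

# conservative bound: centre distance + major semi-axis
ellipse_in_unit_disk <- function(e, limit = 1) {
  sqrt(e$center_x^2 + e$center_y^2) +
    max(e$semi_axis_a, e$semi_axis_b) <= limit
}

#' Phantom specification: body ellipses plus metal inserts
#'
#' @param ellipses list of [ellipse_spec()] forming the body (attenuations
#'   sum where they overlap)
#' @param metal_inserts list of [ellipse_spec()] with high attenuation
#' @param image_size pixels per side (>= 16)
#' @param seed integer recorded for provenance (not consumed here)
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(ellipses, metal_inserts = list(), image_size = 256,
                         seed = NA_integer_) {
  if (image_size < 16) stop("image_size must be at least 16")
  stopifnot(all(vapply(ellipses, inherits, logical(1), "ellipse_spec")),
            all(vapply(metal_inserts, inherits, logical(1), "ellipse_spec")))
  structure(list(ellipses = ellipses, metal_inserts = metal_inserts,
                 image_size = image_size, seed = seed),
            class = "phantom_spec")
}

#' Attenuation image
#'
#' @param values square non-negative numeric matrix (attenuation per pixel)
#' @param pixel_spacing pixel spacing (defaults to 1 pixel unit)
#' @return an `atten_image` object
#' @export
atten_image <- function(values, pixel_spacing = 1) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("attenuation image must be square")
  if (any(!is.finite(values))) stop("attenuation image must be finite")
  structure(list(values = values, pixel_spacing = pixel_spacing),
            class = "atten_image")
}

# pixel-centre coordinates in image fractions, for an n-px image.
# array row r (1-based) has y = ((n-1)/2 - (r-1)) / (n/2); column likewise.
pixel_centers_frac <- function(n) {
  (seq_len(n) - 1 - (n - 1) / 2) / (n / 2)
}

# indicator matrix of pixel centres inside one ellipse (boundary included)
ellipse_mask <- function(e, n) {
  xf <- pixel_centers_frac(n)          # by column
  yf <- -pixel_centers_frac(n)         # by row (y up)
  th <- e$rotation * pi / 180
  ct <- cos(th); st <- sin(th)
  dx <- outer(rep(1, n), xf) - e$center_x   # (row, col)
  dy <- outer(yf, rep(1, n)) - e$center_y
  u <- (dx * ct + dy * st) / e$semi_axis_a
  v <- (-dx * st + dy * ct) / e$semi_axis_b
  u * u + v * v <= 1
}

#' Render a phantom specification to an attenuation image
#'
#' Pixel-centre point sampling: a pixel receives the summed
#' `attenuation_delta` of every ellipse whose boundary contains its centre.
#' Deterministic and pure.
#'
#' @param spec a [phantom_spec()]
#' @param include_metal include the metal inserts (set `FALSE` for a
#'   body-only rendering)
#' @param metal_only render only the metal inserts
#' @return an [atten_image()]
#' @export
render_phantom <- function(spec, include_metal = TRUE, metal_only = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  parts <- if (metal_only) spec$metal_inserts
           else if (include_metal) c(spec$ellipses, spec$metal_inserts)
           else spec$ellipses
  img <- matrix(0, n, n)
  for (k in seq_along(parts)) {
    e <- parts[[k]]
    if (!ellipse_in_unit_disk(e))
      stop(sprintf("ellipse %d extends outside the unit disk", k))
    img <- img + e$attenuation_delta * ellipse_mask(e, n)
  }
  atten_image(img)
}

#' Generation ranges for random phantoms
#'
#' Defaults describe a soft-tissue ellipse composite (one body outline plus
#' a few interior ellipses, summed attenuation within about \[0.2, 1.3\])
#' with 1-2 compact metal inserts whose attenuation (>= 5) exceeds any
#' soft-tissue pixel by a margin of at least 2, so threshold segmentation
#' is unambiguous.
#'
#' @param image_size pixels per side
#' @param inner_count inclusive range for the number of interior ellipses
#' @param body_delta range of the body outline's attenuation
#' @param inner_delta range of interior ellipse attenuations
#' @param inner_axis range of interior semi-axes (image fractions)
#' @param metal_count inclusive range for the number of metal inserts
#' @param metal_axis range of metal semi-axes (image fractions)
#' @param metal_delta range of metal attenuations (each must stay above any
#'   summed soft-tissue value by `margin`)
#' @param margin required separation between the smallest metal pixel and
#'   the largest non-metal pixel
#' @param max_tries bounded rejection-sampling attempts per component
#' @return a `phantom_gen_config` object
#' @export
phantom_gen_config <- function(image_size = 64, inner_count = c(2, 4),
                               body_delta = c(0.2, 0.5),
                               inner_delta = c(0.05, 0.2),
                               inner_axis = c(0.08, 0.3),
                               metal_count = c(1, 2),
                               metal_axis = c(0.05, 0.12),
                               metal_delta = c(5, 8), margin = 2,
                               max_tries = 200) {
  stopifnot(image_size >= 16, all(inner_count >= 0), all(metal_count >= 0),
            all(inner_axis > 0), all(metal_axis > 0), max_tries >= 1)
  worst_body <- max(body_delta) + max(inner_count) * max(inner_delta)
  if (min(metal_delta) < worst_body + margin)
    stop("metal_delta too low: threshold segmentation would be ill-posed")
  structure(list(image_size = image_size, inner_count = inner_count,
                 body_delta = body_delta, inner_delta = inner_delta,
                 inner_axis = inner_axis, metal_count = metal_count,
                 metal_axis = metal_axis, metal_delta = metal_delta,
                 margin = margin, max_tries = max_tries),
            class = "phantom_gen_config")
}

runif1 <- function(r) runif(1, r[1], r[2])

#' Draw a random phantom specification
#'
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#' The body is one large outline ellipse plus a few interior ellipses;
#' metal inserts are placed around the body centre so their support lies
#' inside the body and inside the unit disk.
#'
#' @param seed integer seed
#' @param config a [phantom_gen_config()]
#' @return a [phantom_spec()]
#' @export
sample_random_phantom <- function(seed, config = phantom_gen_config()) {
  stopifnot(inherits(config, "phantom_gen_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  body <- NULL
  for (i in seq_len(config$max_tries)) {
    cand <- try(ellipse_spec(runif(1, -0.08, 0.08), runif(1, -0.08, 0.08),
                             runif(1, 0.55, 0.8), runif(1, 0.45, 0.7),
                             runif(1, 0, 180), runif1(config$body_delta)),
                silent = TRUE)
    if (!inherits(cand, "try-error")) { body <- cand; break }
  }
  if (is.null(body)) stop("could not place a body ellipse inside the unit disk")

  ellipses <- list(body)
  n_inner <- sample(seq(config$inner_count[1], config$inner_count[2]), 1)
  for (k in seq_len(n_inner)) {
    placed <- FALSE
    for (i in seq_len(config$max_tries)) {
      ax <- sort(c(runif1(config$inner_axis), runif1(config$inner_axis)),
                 decreasing = TRUE)
      r <- runif(1, 0, 0.45); phi <- runif(1, 0, 2 * pi)
      cand <- try(ellipse_spec(body$center_x + r * cos(phi),
                               body$center_y + r * sin(phi),
                               ax[1], ax[2], runif(1, 0, 180),
                               runif1(config$inner_delta)), silent = TRUE)
      if (!inherits(cand, "try-error")) {
        ellipses <- c(ellipses, list(cand)); placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place an interior ellipse; ranges infeasible")
  }

  metals <- list()
  n_metal <- if (config$metal_count[2] == 0) 0 else
    sample(seq(config$metal_count[1], config$metal_count[2]), 1)
  for (k in seq_len(n_metal)) {
    placed <- FALSE
    for (i in seq_len(config$max_tries)) {
      ax <- sort(c(runif1(config$metal_axis), runif1(config$metal_axis)),
                 decreasing = TRUE)
      r <- runif(1, 0, 0.4); phi <- runif(1, 0, 2 * pi)
      cx <- body$center_x + r * cos(phi) * body$semi_axis_a
      cy <- body$center_y + r * sin(phi) * body$semi_axis_b
      cand <- try(ellipse_spec(cx, cy, ax[1], ax[2], runif(1, 0, 180),
                               runif1(config$metal_delta)), silent = TRUE)
      if (!inherits(cand, "try-error") &&
          point_in_ellipse(cx, cy, body, shrink = 0.8)) {
        metals <- c(metals, list(cand)); placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place a metal insert inside the body; ",
                      "ranges infeasible")
  }

  phantom_spec(ellipses, metals, config$image_size, seed)
}

point_in_ellipse <- function(x, y, e, shrink = 1) {
  th <- e$rotation * pi / 180
  dx <- x - e$center_x; dy <- y - e$center_y
  u <- (dx * cos(th) + dy * sin(th)) / (e$semi_axis_a * shrink)
  v <- (-dx * sin(th) + dy * cos(th)) / (e$semi_axis_b * shrink)
  u * u + v * v <= 1
}
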