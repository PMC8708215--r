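#' Threshold segmentation of metal
#'
#' Pixels with attenuation greater than or equal to the threshold are
#' marked as metal (the boundary value is included).
#'
#' @param image an [atten_image()]
#' @param threshold attenuation threshold (> 0)
#' @return binary matrix of class `metal_map` (1 = metal)
#' @export
segment_metal <- function(image, threshold) {
  stopifnot(inherits(image, "atten_image"))
  if (threshold <= 0) stop("threshold must be positive")
  structure((image$values >= threshold) * 1L, class = "metal_map")
}

#' Metal-trace mask by reprojection
#'
#' Forward-projects the binary metal map, binarizes the projected path
#' length at a small positive cutoff (0.5 detector bins), then dilates
#' along the detector axis by `dilation_px` bins per side so the damaged
#' region is covered with a safety margin.
#'
#' @param metal a `metal_map` from [segment_metal()] (or binary matrix)
#' @param geometry a [scan_geometry()]
#' @param dilation_px detector-axis dilation per side (integer >= 0)
#' @param cutoff binarization cutoff on projected path length
#' @return binary matrix of class `trace_mask`, shape
#'   `(n_detectors, n_angles)`, attribute `dilation_px`
#' @export
trace_mask <- function(metal, geometry, dilation_px = 2, cutoff = 0.5) {
  stopifnot(dilation_px >= 0)
  m <- unclass(metal)
  if (!all(m %in% c(0, 1))) stop("metal map must be binary")
  proj <- radon_forward_cpp(m, geometry$angles_deg * pi / 180,
                            geometry$n_detectors, geometry$detector_spacing,
                            0.5)
  if (any(m != 0) &&
      max(proj[c(1, nrow(proj)), ]) > 1e-6 * max(proj))
    stop("metal support projects outside the detector span")
  mask <- (proj > cutoff) * 1L
  mask <- dilate_detector_axis(mask, dilation_px)
  structure(mask, dilation_px = as.integer(dilation_px),
            class = "trace_mask")
}

# 1-D morphological dilation along the detector (row) axis
dilate_detector_axis <- function(mask, d) {
  if (d == 0 || !any(mask != 0)) return(mask)
  out <- mask
  nd <- nrow(mask)
  for (k in seq_len(d)) {
    up <- rbind(mask[-seq_len(k), , drop = FALSE],
                matrix(0L, k, ncol(mask)))
    dn <- rbind(matrix(0L, k, ncol(mask)),
                mask[seq_len(nd - k), , drop = FALSE])
    out <- pmax(out, up, dn)
  }
  out
}

#' Zero the metal-damaged traces of a sinogram
#'
#' Entries under the mask are set to zero; all other entries are preserved
#' bit-exactly.
#'
#' @param label a [sinogram()] (the complete data)
#' @param mask a `trace_mask` congruent with the sinogram
#' @return the corrupted [sinogram()]
#' @export
corrupt_sinogram <- function(label, mask) {
  v <- as_vals(label)
  check_congruent(v, unclass(mask), "sinogram and trace mask")
  v[mask == 1] <- 0
  if (inherits(label, "sinogram")) {
    out <- label; out$values <- v; out
  } else v
}

#' Composite completed and original sinograms
#'
#' Takes the completed values under the mask and the original values
#' everywhere else (bit-exact preservation of unaffected data).
#'
#' @param completed completed [sinogram()] (network or baseline output)
#' @param original the measured/corrupted [sinogram()]
#' @param mask a `trace_mask`
#' @return composited [sinogram()]
#' @export
composite_sinogram <- function(completed, original, mask) {
  cv <- as_vals(completed); ov <- as_vals(original)
  check_congruent(cv, ov, "completed and original sinograms")
  check_congruent(ov, unclass(mask), "sinogram and trace mask")
  out <- ov
  sel <- mask == 1
  out[sel] <- cv[sel]
  if (inherits(original, "sinogram")) {
    res <- original; res$values <- out; res
  } else out
}

#' Build a (corrupted, mask, label) sinogram pair from a phantom
#'
#' The label sinogram is the forward projection of the full object (body
#' plus metal) by default, so a completion network learns to fill traces
#' with values consistent with the whole object; `label_mode = "body"`
#' projects the body only.  The trace mask comes from reprojecting the
#' known metal map; the corrupted sinogram zeroes the label under the
#' mask.
#'
#' @param spec a [phantom_spec()]
#' @param geometry a [scan_geometry()]
#' @param dilation_px trace dilation per side (detector bins)
#' @param label_mode `"full"` (body + metal) or `"body"`
#' @return a `sinogram_pair`: list(corrupted, mask, label, spec)
#' @export
make_sinogram_pair <- function(spec, geometry, dilation_px = 2,
                               label_mode = c("full", "body")) {
  label_mode <- match.arg(label_mode)
  full <- render_phantom(spec, include_metal = label_mode == "full")
  label <- forward_project(full, geometry)
  if (length(spec$metal_inserts) > 0) {
    metal <- structure((render_phantom(spec, metal_only = TRUE)$values > 0) * 1L,
                       class = "metal_map")
    mask <- trace_mask(metal, geometry, dilation_px)
  } else {
    mask <- structure(matrix(0L, geometry$n_detectors,
                             length(geometry$angles_deg)),
                      dilation_px = as.integer(dilation_px),
                      class = "trace_mask")
  }
  corrupted <- corrupt_sinogram(label, mask)
  structure(list(corrupted = corrupted, mask = mask, label = label,
                 spec = spec),
            class = "sinogram_pair")
}

#' Simulate a dataset of sinogram pairs
#'
#' Per-pair phantom seeds are drawn from one seeded stream, so a dataset is
#' reproducible from `(n, seed, config, geometry)` alone.
#'
#' @param n number of pairs
#' @param seed master seed
#' @param config a [phantom_gen_config()]
#' @param geometry a [scan_geometry()]
#' @param dilation_px trace dilation per side
#' @param label_mode see [make_sinogram_pair()]
#' @return list of `sinogram_pair` objects
#' @export
simulate_pairs <- function(n, seed, config = phantom_gen_config(),
                           geometry, dilation_px = 2,
                           label_mode = "full") {
  if (n == 0) return(list())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max, n)
  lapply(pair_seeds, function(s) {
    make_sinogram_pair(sample_random_phantom(s, config), geometry,
                       dilation_px = dilation_px, label_mode = label_mode)
  })
}
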