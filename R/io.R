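# File formats: arrays are stored as single-channel 32-bit float TIFF with
# values affinely mapped into [0, 1]; the mapping and all geometry metadata
# live in a JSON sidecar (same path with extension .json).  Sinogram axis
# order on disk matches memory: rows = detector bins, columns = angles.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

write_array_tiff <- function(values, path, meta = list()) {
  lo <- min(values, 0)
  hi <- max(values, lo + 1e-12)
  enc <- (values - lo) / (hi - lo)
  tiff::writeTIFF(enc, path, bits.per.sample = 32, compression = "none")
  meta$value_range <- c(lo, hi)
  meta$axis_order <- meta$axis_order %||% "rows=detector,cols=angle"
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_array_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  enc <- tiff::readTIFF(path)
  lo <- meta$value_range[1]; hi <- meta$value_range[2]
  list(values = enc * (hi - lo) + lo, meta = meta)
}

geometry_meta <- function(geometry) {
  list(n_detectors = geometry$n_detectors,
       angles_deg = geometry$angles_deg,
       detector_spacing = geometry$detector_spacing, span = geometry$span)
}

geometry_from_meta <- function(meta) {
  scan_geometry(n_detectors = meta$n_detectors,
                angles_deg = meta$angles_deg,
                span = meta$span %||% "full",
                detector_spacing = meta$detector_spacing %||% 1)
}

#' Write / read a sinogram as float TIFF plus JSON sidecar
#'
#' @param sino a [sinogram()]
#' @param path output path (`.tif`); the sidecar uses the same stem
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_array_tiff(sino$values, path,
                   c(list(kind = "sinogram", scale = sino$scale),
                     geometry_meta(sino$geometry)))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  r <- read_array_tiff(path)
  s <- sinogram(r$values, geometry_from_meta(r$meta))
  s$scale <- r$meta$scale %||% NA_real_
  s
}

#' Write / read an attenuation image as float TIFF plus JSON sidecar
#'
#' @param image an [atten_image()]
#' @param path output path (`.tif`)
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "atten_image"))
  write_array_tiff(image$values, path,
                   list(kind = "attenuation_image",
                        pixel_spacing = image$pixel_spacing,
                        axis_order = "rows=y(top-down),cols=x"))
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  r <- read_array_tiff(path)
  atten_image(r$values, r$meta$pixel_spacing %||% 1)
}

#' PNG preview of an image or sinogram with a display window
#'
#' @param x an [atten_image()], [sinogram()] or matrix
#' @param path output `.png`
#' @param window display window `c(lo, hi)`; values are clipped
#' @export
write_preview <- function(x, path, window = NULL) {
  v <- as_vals(x)
  window <- window %||% range(v)
  enc <- pmin(pmax((v - window[1]) / max(window[2] - window[1], 1e-12), 0), 1)
  png::writePNG(enc, path)
  invisible(path)
}

#' Write a dataset of sinogram pairs to a directory
#'
#' One float TIFF per array (`corrupted_0001.tif`, `mask_0001.tif`,
#' `label_0001.tif`) plus a `manifest.json` recording geometry, phantom
#' seeds and generation settings.  The corrupted and label arrays of one
#' pair share the same value encoding, so their equality off the trace is
#' preserved exactly on disk.
#'
#' @param pairs list of `sinogram_pair` objects
#' @param dir output directory
#' @param manifest_extra named list merged into the manifest
#' @param force overwrite an existing non-empty directory
#' @export
write_pairs <- function(pairs, dir, manifest_extra = list(), force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)", dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    lo <- 0; hi <- max(p$label$values, 1e-12)
    stem <- sprintf("%04d", i)
    wr <- function(vals, name, extra = list()) {
      enc <- pmin(pmax((vals - lo) / (hi - lo), 0), 1)
      path <- file.path(dir, sprintf("%s_%s.tif", name, stem))
      tiff::writeTIFF(enc, path, bits.per.sample = 32, compression = "none")
      jsonlite::write_json(c(list(value_range = c(lo, hi)), extra,
                             geometry_meta(p$label$geometry)),
                           sidecar_path(path), auto_unbox = TRUE, digits = NA)
    }
    wr(p$corrupted$values, "corrupted")
    wr(p$label$values, "label")
    mp <- file.path(dir, sprintf("mask_%s.tif", stem))
    tiff::writeTIFF(unclass(p$mask) * 1.0, mp, bits.per.sample = 32,
                    compression = "none")
    jsonlite::write_json(c(list(value_range = c(0, 1),
                                dilation_px = attr(p$mask, "dilation_px")),
                           geometry_meta(p$label$geometry)),
                         sidecar_path(mp), auto_unbox = TRUE, digits = NA)
  }
  manifest <- c(list(n_pairs = length(pairs),
                     phantom_seeds = vapply(pairs, function(p)
                       p$spec$seed %||% NA_integer_, numeric(1)),
                     geometry = if (length(pairs) > 0)
                       geometry_meta(pairs[[1]]$label$geometry)),
                manifest_extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$n_pairs
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) {
    stem <- sprintf("%04d", i)
    rd <- function(name) {
      path <- file.path(dir, sprintf("%s_%s.tif", name, stem))
      meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
      vr <- meta$value_range
      list(values = tiff::readTIFF(path) * (vr[2] - vr[1]) + vr[1],
           meta = meta)
    }
    lab <- rd("label"); cor <- rd("corrupted"); msk <- rd("mask")
    geom <- geometry_from_meta(lab$meta)
    structure(list(
      corrupted = sinogram(cor$values, geom),
      mask = structure((msk$values > 0.5) * 1L,
                       dilation_px = msk$meta$dilation_px %||% NA_integer_,
                       class = "trace_mask"),
      label = sinogram(lab$values, geom),
      spec = NULL), class = "sinogram_pair")
  })
}

#' Write / read a phantom specification as JSON
#'
#' @param spec a [phantom_spec()]
#' @param path output `.json` path
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  as_plain <- function(e) e[c("center_x", "center_y", "semi_axis_a",
                              "semi_axis_b", "rotation",
                              "attenuation_delta")]
  jsonlite::write_json(
    list(image_size = spec$image_size, seed = spec$seed,
         ellipses = lapply(spec$ellipses, as_plain),
         metal_inserts = lapply(spec$metal_inserts, as_plain)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk <- function(e) do.call(ellipse_spec, e)
  phantom_spec(lapply(j$ellipses, mk), lapply(j$metal_inserts, mk),
               image_size = j$image_size,
               seed = j$seed %||% NA_integer_)
}
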