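#' Rectangular region of interest
#'
#' @param row,col 1-based start of the rectangle
#' @param nrow,ncol extents (half-open: rows `row .. row + nrow - 1`)
#' @export
roi_spec <- function(row, col, nrow, ncol) {
  stopifnot(row >= 1, col >= 1, nrow >= 1, ncol >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "roi_spec")
}

roi_extract <- function(values, roi) {
  if (is.null(roi)) return(values)
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$row + roi$nrow - 1 > nrow(values) ||
      roi$col + roi$ncol - 1 > ncol(values))
    stop("ROI extends outside the image bounds")
  values[roi$row + seq_len(roi$nrow) - 1, roi$col + seq_len(roi$ncol) - 1,
         drop = FALSE]
}

#' Mean absolute error between sinograms
#'
#' Full-array MAE by default (`sum |fhat - f| / N` over all entries); with
#' a binary `region` (typically the trace mask) only those entries are
#' averaged, which isolates completion error inside the damaged traces.
#'
#' @param output,label congruent sinograms or matrices
#' @param region optional binary matrix selecting the evaluated entries
#' @return scalar MAE
#' @export
mae <- function(output, label, region = NULL) {
  o <- as_vals(output); l <- as_vals(label)
  check_congruent(o, l, "output and label")
  d <- abs(o - l)
  if (is.null(region)) return(mean(d))
  r <- unclass(region)
  check_congruent(o, r, "output and region")
  n <- sum(r == 1)
  if (n == 0) stop("empty evaluation region")
  sum(d[r == 1]) / n
}

#' Root-mean-square error between images
#'
#' @param recon reconstructed [atten_image()] (or matrix)
#' @param ref reference [atten_image()] (or matrix)
#' @param roi optional [roi_spec()]
#' @export
rmse <- function(recon, ref, roi = NULL) {
  a <- roi_extract(as_vals(recon), roi)
  b <- roi_extract(as_vals(ref), roi)
  check_congruent(a, b, "reconstruction and reference")
  sqrt(mean((b - a)^2))
}

#' Normalized mean absolute distance between images
#'
#' `sum |ref - recon| / sum |ref|`; invariant to a common positive
#' rescaling of both images.
#'
#' @inheritParams rmse
#' @export
nmad <- function(recon, ref, roi = NULL) {
  a <- roi_extract(as_vals(recon), roi)
  b <- roi_extract(as_vals(ref), roi)
  check_congruent(a, b, "reconstruction and reference")
  denom <- sum(abs(b))
  if (denom == 0) stop("reference has zero absolute sum on the region")
  sum(abs(b - a)) / denom
}

#' Compare completion methods on one sinogram pair
#'
#' Each method maps `(corrupted, mask)` to a completed sinogram.  Reported
#' per method: full-array and trace-restricted sinogram MAE, then RMSE and
#' NMAD of the FBP reconstruction against the FBP reconstruction of the
#' label (so completion error is isolated from FBP discretization error),
#' on the full image and on the ROI if one is given.
#'
#' @param pair a `sinogram_pair`
#' @param methods named list of functions `(sino, mask) -> sinogram`
#' @param roi optional [roi_spec()] in image coordinates
#' @param recon_size FBP output side (defaults to the phantom size if
#'   known, else the detector count)
#' @return data frame, one row per method
#' @export
compare_methods <- function(pair, methods, roi = NULL, recon_size = NULL) {
  stopifnot(inherits(pair, "sinogram_pair"), length(methods) > 0,
            !is.null(names(methods)))
  recon_size <- recon_size %||%
    (if (!is.null(pair$spec)) pair$spec$image_size
     else pair$label$geometry$n_detectors)
  ref_img <- fbp_reconstruct(pair$label, size = recon_size)
  has_trace <- any(unclass(pair$mask) == 1)
  rows <- lapply(names(methods), function(nm) {
    completed <- methods[[nm]](pair$corrupted, pair$mask)
    rec <- fbp_reconstruct(
      if (inherits(completed, "sinogram")) completed
      else sinogram(as_vals(completed), pair$label$geometry),
      size = recon_size)
    data.frame(
      method = nm,
      mae_sino = mae(completed, pair$label),
      mae_trace = if (has_trace) mae(completed, pair$label, pair$mask)
                  else NA_real_,
      rmse_image = rmse(rec, ref_img),
      nmad_image = nmad(rec, ref_img),
      rmse_roi = if (is.null(roi)) NA_real_ else rmse(rec, ref_img, roi),
      nmad_roi = if (is.null(roi)) NA_real_ else nmad(rec, ref_img, roi))
  })
  do.call(rbind, rows)
}
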