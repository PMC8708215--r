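#' LI-MAR: linear interpolation across metal traces
#'
#' For each projection angle, every maximal run of masked detector bins is
#' replaced by the linear interpolant between the nearest unmasked values
#' on either side (Kalender's classic baseline).  A run touching the
#' detector boundary is filled with the lone available anchor value
#' (constant extrapolation).  Unmasked entries are returned bit-exactly.
#' A fully masked angle column has no anchors; it is filled with zeros and
#' recorded in the `empty_columns` attribute with a warning.
#'
#' @param sino a [sinogram()] (or matrix) with zeroed metal traces
#' @param mask a `trace_mask` congruent with the sinogram
#' @return the interpolated sinogram (same class as the input)
#' @export
li_mar <- function(sino, mask) {
  v <- as_vals(sino)
  m <- unclass(mask)
  check_congruent(v, m, "sinogram and trace mask")
  nd <- nrow(v)
  empty <- integer(0)
  for (j in seq_len(ncol(v))) {
    gaps <- which(m[, j] == 1)
    if (length(gaps) == 0) next
    anchors <- which(m[, j] == 0)
    if (length(anchors) == 0) {
      v[, j] <- 0
      empty <- c(empty, j)
      next
    }
    if (length(anchors) == 1) {
      v[gaps, j] <- v[anchors, j]
    } else {
      v[gaps, j] <- approx(anchors, v[anchors, j], xout = gaps,
                           method = "linear", rule = 2)$y
    }
  }
  if (length(empty) > 0)
    warning(sprintf("%d fully masked angle column(s) filled with zeros",
                    length(empty)))
  if (inherits(sino, "sinogram")) {
    out <- sino; out$values <- v
    attr(out, "empty_columns") <- empty
    out
  } else {
    attr(v, "empty_columns") <- empty
    v
  }
}
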