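#' Encoder-decoder network configuration
#'
#' The completion network is a U-net-style encoder-decoder on single
#' channel sinograms.  Each encoder block applies two 3x3 stride-1
#' convolutions followed by one 3x3 stride-2 convolution (no pooling);
#' encoder activations are leaky rectifiers with negative slope 0.2.  Each
#' decoder block applies a 3x3 stride-2 transposed convolution, merges the
#' matching encoder skip connection, and fuses with a 3x3 convolution;
#' decoder activations are plain rectifiers.  The channel schedule is
#' `base, 2*base, 4*base` then `8*base` repeated, mirrored in the decoder.
#' Output and input have identical shape.
#'
#' @param depth number of down/up levels (full scale 5, desk scale 4)
#' @param base_channels channels at the first level (full scale 64, desk
#'   scale 16)
#' @param leaky_slope negative-side slope of the encoder activation
#' @return a `net_config` object
#' @export
net_config <- function(depth = 5, base_channels = 64, leaky_slope = 0.2) {
  stopifnot(depth >= 1, base_channels >= 1, leaky_slope >= 0)
  schedule <- pmin(base_channels * 2^(seq_len(depth) - 1), 8 * base_channels)
  bottleneck <- min(base_channels * 2^depth, 8 * base_channels)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 channel_schedule = as.integer(schedule),
                 bottleneck_channels = as.integer(bottleneck),
                 leaky_slope = leaky_slope),
            class = "net_config")
}

# channels vector handed to the C++ core: levels 1..depth then bottleneck
net_channels <- function(config) {
  as.integer(c(config$channel_schedule, config$bottleneck_channels))
}

#' Build a completion network with seeded He-normal initialization
#'
#' Two builds with the same seed produce identical parameters.
#'
#' @param config a [net_config()]
#' @param seed integer seed for the parameter draw
#' @return a `sinomar_unet`: list(config, params, scale, seed)
#' @export
build_unet <- function(config = net_config(), seed = 1) {
  stopifnot(inherits(config, "net_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  d <- config$depth
  ch <- net_channels(config)
  lvl <- function(i) ch[i]               # level channels, i in 1..d
  conv <- function(cin, cout, gain = 2) {
    list(W = matrix(rnorm(cout * 9 * cin, 0, sqrt(gain / (9 * cin))),
                    cout, 9 * cin),
         b = numeric(cout))
  }
  # transposed conv stored as the matching stride-2 conv weight
  # (c_deep x 9*c_level); each output unit receives ~9/4 * c_deep terms
  tconv <- function(cdeep, clevel) {
    list(W = matrix(rnorm(cdeep * 9 * clevel, 0, sqrt(2 / (2.25 * cdeep))),
                    cdeep, 9 * clevel),
         b = numeric(clevel))
  }
  params <- list()
  cin <- 1L
  for (i in seq_len(d)) {
    params <- c(params, list(conv(cin, lvl(i)), conv(lvl(i), lvl(i)),
                             conv(lvl(i), if (i < d) lvl(i + 1) else ch[d + 1])))
    cin <- if (i < d) lvl(i + 1) else ch[d + 1]
  }
  params <- c(params, list(conv(ch[d + 1], ch[d + 1]),
                           conv(ch[d + 1], ch[d + 1])))
  for (i in rev(seq_len(d))) {
    cdeep <- if (i == d) ch[d + 1] else lvl(i + 1)
    params <- c(params, list(tconv(cdeep, lvl(i)),
                             conv(2 * lvl(i), lvl(i))))
  }
  params <- c(params, list(conv(lvl(1), 1, gain = 1)))
  structure(list(config = config, params = params, scale = NA_real_,
                 seed = as.integer(seed)),
            class = "sinomar_unet")
}

#' Pad a sinogram for the network and invert the padding
#'
#' The network halves each spatial side `depth` times, so both sides must
#' be divisible by `2^depth`.  The detector axis is zero-padded
#' symmetrically (physical zero outside the detector support); the angle
#' axis is padded circularly at the end (a full-scan sinogram is periodic
#' in the angle).  The returned crop record inverts the padding exactly.
#'
#' @param sino a [sinogram()] or matrix
#' @param depth network depth
#' @return list(values, crop) where crop = c(row offset, col offset,
#'   original rows, original cols)
#' @export
pad_for_net <- function(sino, depth) {
  v <- as_vals(sino)
  mult <- 2^depth
  nr <- nrow(v); nc <- ncol(v)
  tr <- ceiling(nr / mult) * mult
  tc <- ceiling(nc / mult) * mult
  top <- (tr - nr) %/% 2
  out <- matrix(0, tr, tc)
  out[top + seq_len(nr), seq_len(nc)] <- v
  if (tc > nc)  # circular continuation of the angle axis
    out[top + seq_len(nr), nc + seq_len(tc - nc)] <-
      v[, seq_len(tc - nc), drop = FALSE]
  list(values = out, crop = c(top, 0L, nr, nc))
}

#' @rdname pad_for_net
#' @param padded padded matrix
#' @param crop crop record from [pad_for_net()]
#' @export
crop_from_net <- function(padded, crop) {
  padded[crop[1] + seq_len(crop[3]), crop[2] + seq_len(crop[4]),
         drop = FALSE]
}

# ------------------------------------------------------------------ losses

#' Masked L2 completion loss
#'
#' `sum_x sum_theta (M * f - M * fhat)^2`: only entries under the metal
#' trace mask contribute, so the loss focuses on the damaged traces.
#'
#' @param output network output sinogram (or matrix)
#' @param label complete (label) sinogram
#' @param mask binary trace mask (1 = damaged)
#' @return scalar loss
#' @export
loss_l2 <- function(output, label, mask) {
  o <- as_vals(output); l <- as_vals(label); m <- unclass(mask)
  check_congruent(o, l, "output and label")
  check_congruent(o, m, "output and mask")
  sum((m * o - m * l)^2)
}

#' Amplitude (continuity) loss
#'
#' Sum of squared differences between the detector-axis first differences
#' of output and label: penalizes discontinuities at trace boundaries.
#' Applied unmasked.
#'
#' @inheritParams loss_l2
#' @export
loss_amp <- function(output, label) {
  o <- as_vals(output); l <- as_vals(label)
  check_congruent(o, l, "output and label")
  if (nrow(o) < 2) stop("amplitude loss needs at least 2 detector bins")
  sum((diff(o) - diff(l))^2)
}

#' Difference (consistency) loss
#'
#' Per-angle detector sums of output and label are compared and squared:
#' the discrete order-0 projection-moment matching that enforces the
#' Helgason-Ludwig angle-independence of the projected mass.
#'
#' @inheritParams loss_l2
#' @export
loss_diff <- function(output, label) {
  o <- as_vals(output); l <- as_vals(label)
  check_congruent(o, l, "output and label")
  sum((colSums(o) - colSums(l))^2)
}

#' Composite training loss
#'
#' `total = w_l2 * L2 + w_amp * Amp + w_diff * Diff`; unit weights give the
#' plain sum of the three terms.
#'
#' @inheritParams loss_l2
#' @param weights named vector `c(l2 = , amp = , diff = )`, all >= 0
#' @return a `loss_report`: list(l2, amp, diff, total)
#' @export
total_loss <- function(output, label, mask,
                       weights = c(l2 = 1, amp = 1, diff = 1)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  l2 <- loss_l2(output, label, mask)
  amp <- loss_amp(output, label)
  dif <- loss_diff(output, label)
  structure(list(l2 = l2, amp = amp, diff = dif,
                 total = weights[["l2"]] * l2 + weights[["amp"]] * amp +
                   weights[["diff"]] * dif),
            class = "loss_report")
}

#' Analytic gradient of the composite loss with respect to the output
#'
#' @inheritParams total_loss
#' @return matrix of the same shape as the output
#' @export
total_loss_grad <- function(output, label, mask,
                            weights = c(l2 = 1, amp = 1, diff = 1)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  o <- as_vals(output); l <- as_vals(label); m <- unclass(mask)
  d <- o - l
  g <- weights[["l2"]] * 2 * m * d
  if (nrow(o) >= 2) {
    a <- diff(d)                       # (nd - 1) x na
    n <- nrow(o)
    g[-n, ] <- g[-n, ] - weights[["amp"]] * 2 * a
    g[-1, ] <- g[-1, ] + weights[["amp"]] * 2 * a
  }
  s <- colSums(d)
  g + weights[["diff"]] * 2 * matrix(s, nrow(o), ncol(o), byrow = TRUE)
}

# ---------------------------------------------------------------- training

#' Training configuration
#'
#' Unit loss weights reproduce the composite objective exactly; the
#' ablation flags zero out individual terms (`use_mask = FALSE` turns the
#' L2 term into an unmasked global L2).
#'
#' @param steps optimization steps
#' @param batch_size images per step
#' @param lr Adam learning rate
#' @param seed seed for shuffling (network init has its own seed)
#' @param w_l2,w_amp,w_diff loss weights (>= 0)
#' @param use_mask restrict the L2 term to the trace mask
#' @param use_amp,use_diff include the continuity / consistency terms
#' @param log_every record the loss every this many steps (1 = all)
#' @return a `train_config` object
#' @export
train_config <- function(steps = 500, batch_size = 8, lr = 1e-4, seed = 1,
                         w_l2 = 1, w_amp = 1, w_diff = 1, use_mask = TRUE,
                         use_amp = TRUE, use_diff = TRUE, log_every = 1) {
  stopifnot(steps >= 1, batch_size >= 1, lr > 0,
            w_l2 >= 0, w_amp >= 0, w_diff >= 0)
  structure(list(steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), w_l2 = w_l2,
                 w_amp = if (use_amp) w_amp else 0,
                 w_diff = if (use_diff) w_diff else 0,
                 use_mask = isTRUE(use_mask),
                 log_every = as.integer(log_every)),
            class = "train_config")
}

# stack a list of sinogram_pair into (H, W, n) arrays
stack_pairs <- function(pairs) {
  stopifnot(length(pairs) > 0)
  d <- dim(pairs[[1]]$label$values)
  arr <- function(get) {
    a <- array(0, c(d, length(pairs)))
    for (i in seq_along(pairs)) a[, , i] <- get(pairs[[i]])
    a
  }
  list(corrupted = arr(function(p) p$corrupted$values),
       mask = arr(function(p) unclass(p$mask)),
       label = arr(function(p) p$label$values),
       dim = d, n = length(pairs))
}

#' Train the completion network
#'
#' Adam optimization of the composite loss on (corrupted, mask, label)
#' sinogram pairs.  Inputs and labels are normalized by the global maximum
#' of the training labels; that scale is stored on the returned network so
#' completed sinograms can be un-normalized before reconstruction.  A
#' fixed seed gives a reproducible loss history on a fixed machine.
#'
#' @param pairs list of `sinogram_pair` objects (see
#'   [make_sinogram_pair()])
#' @param net a [build_unet()] network
#' @param tc a [train_config()]
#' @return the trained network, with `scale` set and a `history` data
#'   frame (step and per-image mean loss terms) attached
#' @export
train_unet <- function(pairs, net, tc = train_config()) {
  stopifnot(inherits(net, "sinomar_unet"), inherits(tc, "train_config"),
            length(pairs) > 0)
  d <- net$config$depth
  data <- stack_pairs(pairs)
  if (any(data$dim %% 2^d != 0))
    stop(sprintf("sinogram sides %s must be divisible by 2^depth = %d; %s",
                 paste(data$dim, collapse = "x"), 2^d,
                 "pad with pad_for_net() first"))
  scale <- max(data$label)
  if (scale <= 0) scale <- 1
  ch <- net_channels(net$config)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(tc$seed)
  res <- unet_train_cpp(net$params, data$corrupted / scale,
                        data$label / scale, data$mask,
                        as.integer(c(data$dim, data$n)), d, ch,
                        net$config$leaky_slope, tc$w_l2, tc$w_amp,
                        tc$w_diff, tc$use_mask, tc$steps, tc$batch_size,
                        tc$lr)
  net$params <- res$params
  net$scale <- scale
  net$train_config <- tc
  keep <- seq(1, tc$steps, by = tc$log_every)
  keep <- sort(unique(c(keep, tc$steps)))
  net$history <- data.frame(step = keep,
                            l2 = res$history[keep, 1] / tc$batch_size,
                            amp = res$history[keep, 2] / tc$batch_size,
                            diff = res$history[keep, 3] / tc$batch_size,
                            total = res$history[keep, 4] / tc$batch_size)
  net
}

#' Raw network forward pass on a normalized sinogram matrix
#'
#' Low-level access; most callers want [complete_sinogram()], which also
#' handles padding, normalization and compositing.
#'
#' @param net a `sinomar_unet`
#' @param x matrix (or (H, W, N) array) with sides divisible by
#'   `2^depth`, already normalized
#' @return array of network outputs, same shape
#' @export
unet_forward <- function(net, x) {
  dims <- dim(x)
  if (length(dims) == 2) dims <- c(dims, 1L)
  d <- net$config$depth
  if (any(dims[1:2] %% 2^d != 0))
    stop(sprintf("input sides %s not divisible by 2^depth = %d; pad to %s",
                 paste(dims[1:2], collapse = "x"), 2^d,
                 paste(ceiling(dims[1:2] / 2^d) * 2^d, collapse = "x")))
  y <- unet_predict_cpp(net$params, as.numeric(x), as.integer(dims), d,
                        net_channels(net$config), net$config$leaky_slope)
  array(y, dims)
}

#' Complete the metal-damaged traces of a sinogram
#'
#' Normalizes by the training scale, pads for the network, runs the
#' forward pass, crops, un-normalizes, then composites with the original
#' so every unmasked entry is returned bit-exactly.
#'
#' @param sino corrupted [sinogram()] (traces zeroed)
#' @param mask the `trace_mask` marking the damage
#' @param net a trained `sinomar_unet` (its `scale` must be set)
#' @return completed [sinogram()]
#' @export
complete_sinogram <- function(sino, mask, net) {
  stopifnot(inherits(net, "sinomar_unet"))
  if (!is.finite(net$scale))
    stop("network has no normalization scale; train it or set net$scale")
  v <- as_vals(sino)
  check_congruent(v, unclass(mask), "sinogram and trace mask")
  p <- pad_for_net(v / net$scale, net$config$depth)
  y <- unet_forward(net, p$values)[, , 1]
  filled <- crop_from_net(y, p$crop) * net$scale
  composite_sinogram(filled, sino, mask)
}
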