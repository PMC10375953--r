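#' Preprocessing configuration
#'
#' Intensity windowing and stochastic augmentation settings applied before
#' every forward pass.
#'
#' @param hu_window Length-2 numeric `(low, high)` Hounsfield-unit window;
#'   default `c(-1000, 250)`, the standard lung window used for interstitial
#'   patterns.
#' @param augmentations Character subset of
#'   `c("noise", "flip", "rotation", "shift")`; which stochastic augmentations
#'   [augment()] applies.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise on
#'   the `[0, 1]` scale (default 0.02).
#' @param max_rotation_deg Maximum absolute rotation angle in degrees
#'   (default 15).
#' @param max_shift_px Maximum absolute shift in pixels (default 8).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_window = c(-1000, 250),
                              augmentations = c("noise", "flip", "rotation", "shift"),
                              noise_sd = 0.02,
                              max_rotation_deg = 15,
                              max_shift_px = 8) {
  if (length(hu_window) != 2L || !all(is.finite(hu_window)) || hu_window[1] >= hu_window[2])
    stop("'hu_window' must be (low, high) with low < high")
  augmentations <- if (length(augmentations))
    match.arg(augmentations, c("noise", "flip", "rotation", "shift"),
              several.ok = TRUE) else character(0)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  structure(list(hu_window = hu_window, augmentations = augmentations,
                 noise_sd = noise_sd, max_rotation_deg = max_rotation_deg,
                 max_shift_px = max_shift_px),
            class = "preprocess_config")
}

#' Hounsfield-unit window normalization
#'
#' Linearly maps raw Hounsfield values through the window `(low, high)` to
#' `[0, 1]`, clamping outside the window:
#' `clamp((v - low) / (high - low), 0, 1)`. With the default lung window,
#' -1000 HU maps to 0, 250 HU to 1 and -375 HU to 0.5.
#'
#' @param raw Numeric matrix (or vector) of raw HU intensities; must be
#'   finite.
#' @param config A [preprocess_config()].
#' @return An object of the same shape with values in `[0, 1]`.
#' @export
hu_window_normalize <- function(raw, config = preprocess_config()) {
  if (any(!is.finite(raw))) stop("raw HU input contains non-finite values")
  lo <- config$hu_window[1]; hi <- config$hu_window[2]
  pmin(pmax((raw - lo) / (hi - lo), 0), 1)
}

#' Inverse of the HU window map
#'
#' Sends normalized `[0, 1]` intensities back to Hounsfield units so that
#' synthetic data generated on the normalized scale can exercise the HU
#' reading path.
#'
#' @param x Numeric matrix/vector in `[0, 1]`.
#' @inheritParams hu_window_normalize
#' @return Values on the HU scale.
#' @export
hu_from_normalized <- function(x, config = preprocess_config()) {
  lo <- config$hu_window[1]; hi <- config$hu_window[2]
  x * (hi - lo) + lo
}

#' Segmentation record
#'
#' One slice of data: the image, an optional dense label mask, an optional
#' binary region-of-interest mask, and provenance metadata distinguishing
#' human labels from admitted pseudo-labels.
#'
#' @param image Numeric `H x W` matrix of normalized intensities.
#' @param label Optional integer `H x W` label mask (`0..T-1` or
#'   [ignore_label()]); `NULL` for unlabeled slices.
#' @param roi Optional binary `H x W` region-of-interest mask; `NULL` means
#'   the whole image.
#' @param id Character record identifier, unique within a dataset.
#' @param provenance `"human"` or `"pseudo"`.
#' @param round_admitted Training round at which a pseudo-labeled record was
#'   admitted (`NA` for human labels).
#' @return An object of class `segmentation_record`.
#' @export
segmentation_record <- function(image, label = NULL, roi = NULL, id = "",
                                provenance = c("human", "pseudo"),
                                round_admitted = NA_integer_) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (!is.null(label)) {
    label <- matrix(as.integer(label), nrow(image), ncol(image))
    if (!all(dim(label) == dim(image))) stop("label shape must match image")
  }
  if (!is.null(roi) && !all(dim(roi) == dim(image))) stop("ROI shape must match image")
  structure(list(image = image, label = label, roi = roi, id = id,
                 provenance = match.arg(provenance),
                 round_admitted = round_admitted),
            class = "segmentation_record")
}

#' Restrict a slice to its region of interest
#'
#' Zeroes image intensities outside the ROI and sets the label to the ignore
#' value there, so downstream losses and metrics exclude those pixels.
#'
#' @param image Numeric `H x W` intensity matrix.
#' @param label Integer `H x W` label mask, or `NULL`.
#' @param roi_mask Binary `H x W` mask (1 = inside the organ/ROI).
#' @param id Record identifier.
#' @return A [segmentation_record()] with masked image and label.
#' @export
apply_roi <- function(image, label, roi_mask, id = "") {
  if (!all(dim(image) == dim(roi_mask))) stop("image and ROI shapes disagree")
  if (!is.null(label) && !all(dim(label) == dim(image))) stop("label shape disagrees")
  out_img <- image
  out_img[roi_mask == 0] <- 0
  out_lab <- label
  if (!is.null(out_lab)) out_lab[roi_mask == 0] <- IGNORE_LABEL
  segmentation_record(out_img, out_lab, roi_mask, id = id)
}

## Affine warp shared by rotation and shift.  The forward transform rotates
## by `angle_deg` about the image centre and then translates by (dy, dx)
## pixels; sampling is inverse-mapped.  Images are sampled bilinearly, label
## and ROI masks with nearest-neighbour; out-of-border pixels get 0 intensity,
## the ignore label, and 0 ROI.
warp_affine <- function(image, label, roi, angle_deg, dy, dx) {
  H <- nrow(image); W <- ncol(image)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  yc <- i - (H + 1) / 2 - dy
  xc <- j - (W + 1) / 2 - dx
  ## inverse rotation
  ys <- ct * yc + st * xc + (H + 1) / 2
  xs <- -st * yc + ct * xc + (W + 1) / 2

  ## bilinear sample for the image
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  inb <- function(y, x) y >= 1 & y <= H & x >= 1 & x <= W
  val <- function(y, x) {
    ok <- inb(y, x)
    v <- numeric(length(y))
    v[ok] <- image[cbind(y[ok], x[ok])]
    v
  }
  img_w <- (1 - fy) * (1 - fx) * val(y0, x0) +
    (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) +
    fy * fx * val(y0 + 1, x0 + 1)
  img_out <- matrix(img_w, H, W)

  ## nearest-neighbour sample for masks
  yn <- round(ys); xn <- round(xs)
  okn <- inb(yn, xn)
  samp_mask <- function(m, fill) {
    v <- rep(fill, H * W)
    v[okn] <- m[cbind(yn[okn], xn[okn])]
    matrix(v, H, W)
  }
  lab_out <- if (is.null(label)) NULL else samp_mask(label, IGNORE_LABEL)
  roi_out <- if (is.null(roi)) NULL else samp_mask(roi, 0)
  list(image = img_out, label = lab_out, roi = roi_out)
}

#' Stochastic augmentation of a slice
#'
#' Applies, in order: a horizontal flip (probability 1/2), a joint
#' rotation/shift affine warp, and additive Gaussian intensity noise. The
#' identical geometric transform is applied to image, label and ROI; noise is
#' added to the image only. Labels and ROI are resampled with
#' nearest-neighbour interpolation, the image bilinearly; pixels entering
#' from outside the border receive intensity 0, the ignore label, and ROI 0.
#' Randomness is drawn from R's global stream, so results are reproducible
#' under [set.seed()].
#'
#' @param record A [segmentation_record()].
#' @param config A [preprocess_config()]; its `augmentations` set selects
#'   which transforms are active (an empty set is the identity).
#' @return The augmented [segmentation_record()].
#' @export
augment <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "segmentation_record"))
  augs <- config$augmentations
  img <- record$image; lab <- record$label; roi <- record$roi
  if ("flip" %in% augs && stats::runif(1) < 0.5) {
    img <- img[, ncol(img):1, drop = FALSE]
    if (!is.null(lab)) lab <- lab[, ncol(lab):1, drop = FALSE]
    if (!is.null(roi)) roi <- roi[, ncol(roi):1, drop = FALSE]
  }
  angle <- if ("rotation" %in% augs) stats::runif(1, -config$max_rotation_deg, config$max_rotation_deg) else 0
  if ("shift" %in% augs) {
    m <- config$max_shift_px
    sh <- sample(seq(-m, m), 2L, replace = TRUE)
  } else sh <- c(0L, 0L)
  if (angle != 0 || any(sh != 0)) {
    w <- warp_affine(img, lab, roi, angle, sh[1L], sh[2L])
    img <- w$image; lab <- w$label; roi <- w$roi
  }
  if ("noise" %in% augs && config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd), nrow(img))
  segmentation_record(img, lab, roi, id = record$id,
                      provenance = record$provenance,
                      round_admitted = record$round_admitted)
}
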