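#' Texture class specification
#'
#' Parameters of one synthetic tissue-pattern class: a base intensity on the
#' normalized `[0, 1]` scale, a structured texture kind, pixel noise, and a
#' characteristic feature size. The shipped kinds loosely mimic CT lung
#' patterns: `"smooth"` (homogeneous, e.g. healthy parenchyma /
#' ground-glass), `"speckle"` (sparse bright dots), `"honeycomb"` (bright
#' cell-wall lattice), `"striation"` (oriented linear opacities), and
#' `"blobs"` (clustered patches).
#'
#' @param class_id Integer class label in `0..T-1`, unique per benchmark.
#' @param base_intensity Mean intensity of the class in `[0, 1]`.
#' @param texture_kind One of `"smooth"`, `"speckle"`, `"honeycomb"`,
#'   `"striation"`, `"blobs"`.
#' @param noise_sd Nonnegative per-pixel Gaussian noise standard deviation.
#' @param scale Characteristic texture feature size in pixels (`>= 1`).
#' @param amplitude Peak amplitude of the structured texture component
#'   (default 0.06). The texture is mean-centred within each class region so
#'   the region mean stays at `base_intensity`.
#' @return An object of class `texture_class_spec`.
#' @export
texture_class_spec <- function(class_id, base_intensity, texture_kind,
                               noise_sd = 0.07, scale = 6, amplitude = 0.06) {
  texture_kind <- match.arg(texture_kind,
                            c("smooth", "speckle", "honeycomb", "striation", "blobs"))
  if (!is_count(class_id, min = 0L)) stop("'class_id' must be a nonnegative integer")
  stopifnot_scalar_prob(base_intensity, "base_intensity")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (scale < 1) stop("'scale' must be >= 1 pixel")
  structure(list(class_id = as.integer(class_id), base_intensity = base_intensity,
                 texture_kind = texture_kind, noise_sd = noise_sd,
                 scale = scale, amplitude = amplitude),
            class = "texture_class_spec")
}

#' Default texture classes for the synthetic benchmark
#'
#' Four (or eight) texture classes with overlapping intensity ranges, so that
#' classes are separable only by combining intensity and local texture — the
#' regime in which dense labels are genuinely informative.
#'
#' @param n_classes 4 (default, fast test benchmark) or 8 (full mode).
#' @return A list of [texture_class_spec()] objects.
#' @export
default_class_specs <- function(n_classes = 4) {
  base <- list(
    texture_class_spec(0L, 0.30, "smooth"),
    texture_class_spec(1L, 0.44, "speckle", scale = 2, amplitude = 0.18),
    texture_class_spec(2L, 0.58, "honeycomb", scale = 8, amplitude = 0.16),
    texture_class_spec(3L, 0.50, "striation", scale = 6, amplitude = 0.12))
  if (n_classes == 4) return(base)
  if (n_classes == 8) {
    extra <- list(
      texture_class_spec(4L, 0.38, "blobs", scale = 7, amplitude = 0.14),
      texture_class_spec(5L, 0.62, "smooth"),
      texture_class_spec(6L, 0.46, "honeycomb", scale = 5, amplitude = 0.12),
      texture_class_spec(7L, 0.55, "speckle", scale = 3, amplitude = 0.12))
    return(c(base, extra))
  }
  stop("'n_classes' must be 4 or 8")
}

## Gaussian smoothing of a matrix by separable convolution with
## renormalized borders; kernel truncated at 3 sigma.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  smooth_1d <- function(n) {
    K <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n)
      src <- idx + d
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[d + r + 1L]
    }
    K / rowSums(K)
  }
  Kr <- smooth_1d(nrow(m))
  Kc <- smooth_1d(ncol(m))
  Kr %*% m %*% t(Kc)
}

## Lung-like ROI: two ellipse blobs with mild per-volume jitter.
make_roi <- function(H, W) {
  jit <- stats::runif(4, -0.02, 0.02)
  i <- rep(seq_len(H), W) / H
  j <- rep(seq_len(W), each = H) / W
  ell <- function(cy, cx, ry, rx) ((i - cy) / ry)^2 + ((j - cx) / rx)^2 <= 1
  roi <- ell(0.5 + jit[1], 0.27 + jit[2], 0.38, 0.19) |
    ell(0.5 + jit[3], 0.73 + jit[4], 0.38, 0.19)
  matrix(as.integer(roi), H, W)
}

## Structured texture field for one class over the whole slice; zero for
## "smooth".  Phases/orientations are drawn once per volume and passed in.
texture_field <- function(spec, H, W, pars) {
  s <- spec$scale
  i <- matrix(rep(seq_len(H), W), H, W)
  j <- matrix(rep(seq_len(W), each = H), H, W)
  switch(spec$texture_kind,
    smooth = matrix(0, H, W),
    speckle = {
      dots <- matrix(as.numeric(stats::runif(H * W) < 1 / (2 * s^2)), H, W)
      dots / max(1 / (2 * s^2), 1e-6) * 0.15  # sparse bright points, O(1) peak
    },
    honeycomb = {
      v <- pmax(abs(sin(pi * (i + pars$phase1) / s)), abs(sin(pi * (j + pars$phase2) / s)))^8
      v
    },
    striation = {
      sin(2 * pi * ((i * cos(pars$theta) + j * sin(pars$theta)) / s) + pars$phase1)
    },
    blobs = {
      b <- gaussian_smooth(matrix(stats::rnorm(H * W), H, W), s / 2)
      as.numeric(b > stats::quantile(b, 0.8)) * 1.0
    })
}

## Warp a matrix by a smooth displacement field (bilinear).
elastic_warp <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  ys <- pmin(pmax(i + as.vector(dy), 1), H)
  xs <- pmin(pmax(j + as.vector(dx), 1), W)
  y0 <- pmin(floor(ys), H - 1L); x0 <- pmin(floor(xs), W - 1L)
  fy <- ys - y0; fx <- xs - x0
  v <- (1 - fy) * (1 - fx) * m[cbind(y0, x0)] +
    (1 - fy) * fx * m[cbind(y0, x0 + 1)] +
    fy * (1 - fx) * m[cbind(y0 + 1, x0)] +
    fy * fx * m[cbind(y0 + 1, x0 + 1)]
  matrix(v, H, W)
}

#' Generate one synthetic annotated volume
#'
#' Produces a stack of correlated 2D texture slices inside a lung-like
#' two-blob ROI, with dense class labels on every slice and a sparse
#' annotation pattern: `n_labeled` evenly spaced slices are marked as
#' labeled, and the `neighbour_window` slices on either side of each labeled
#' slice form the unlabeled pool. Class regions evolve between slices by
#' small random elastic deformations, so adjacent slices are highly
#' correlated, as in consecutive CT sections.
#'
#' @param specs List of [texture_class_spec()]; class ids must be unique.
#' @param n_slices Number of slices in the volume.
#' @param shape Integer `(H, W)` slice shape.
#' @param n_labeled Number of labeled slices (`>= 1`).
#' @param neighbour_window Slices on each side of a labeled slice that enter
#'   the unlabeled pool (default 3).
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @return An object of class `synthetic_volume`: lists `slices`,
#'   `dense_labels` (with [ignore_label()] outside the ROI), `roi_masks`,
#'   plus `labeled_slice_indices` and `unlabeled_slice_indices`.
#' @export
generate_volume <- function(specs, n_slices = 28, shape = c(64, 64),
                            n_labeled = 4, neighbour_window = 3, seed = 1) {
  if (length(specs) == 0) stop("'specs' must be non-empty")
  ids <- vapply(specs, function(s) s$class_id, integer(1))
  if (anyDuplicated(ids)) stop("class ids must be unique")
  if (!all(sort(ids) == seq_along(ids) - 1L)) stop("class ids must be contiguous from 0")
  if (n_labeled < 1) stop("'n_labeled' must be >= 1")
  spacing <- floor(n_slices / n_labeled)
  if (spacing < 2 * neighbour_window + 1)
    stop("infeasible geometry: need n_labeled * (2 * neighbour_window + 1) <= n_slices")
  H <- shape[1]; W <- shape[2]
  set.seed(seed)

  labeled_idx <- as.integer(ceiling(spacing / 2) + (seq_len(n_labeled) - 1L) * spacing)
  unlabeled_idx <- sort(unique(unlist(lapply(labeled_idx, function(k)
    setdiff(seq(k - neighbour_window, k + neighbour_window), k)))))
  unlabeled_idx <- unlabeled_idx[unlabeled_idx >= 1 & unlabeled_idx <= n_slices]

  roi <- make_roi(H, W)
  K <- length(specs)
  ## per-volume texture parameters (orientation, phases) per class
  tex_pars <- lapply(specs, function(s)
    list(theta = stats::runif(1, 0, pi), phase1 = stats::runif(1, 0, 2 * pi),
         phase2 = stats::runif(1, 0, 2 * pi)))

  field_sigma <- 6
  fields <- lapply(seq_len(K), function(k) gaussian_smooth(matrix(stats::rnorm(H * W), H, W), field_sigma))
  slices <- vector("list", n_slices)
  labels <- vector("list", n_slices)
  rois <- vector("list", n_slices)
  xi <- 0.15  # innovation weight keeping the fields near-stationary

  for (s in seq_len(n_slices)) {
    if (s > 1) {
      dy <- gaussian_smooth(matrix(stats::rnorm(H * W, 0, 1), H, W), 8) * 8
      dx <- gaussian_smooth(matrix(stats::rnorm(H * W, 0, 1), H, W), 8) * 8
      fields <- lapply(fields, function(f)
        sqrt(1 - xi^2) * elastic_warp(f, dy, dx) +
          xi * gaussian_smooth(matrix(stats::rnorm(H * W), H, W), field_sigma))
    }
    Fm <- vapply(fields, as.vector, numeric(H * W))
    lab <- matrix(max.col(Fm, ties.method = "first") - 1L, H, W)
    img <- matrix(0, H, W)
    for (k in seq_len(K)) {
      spec <- specs[[k]]
      inside <- lab == spec$class_id & roi == 1
      n_in <- sum(inside)
      tex <- texture_field(spec, H, W, tex_pars[[k]]) * spec$amplitude
      if (n_in > 0) tex[inside] <- tex[inside] - mean(tex[inside])
      v <- spec$base_intensity + tex + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      img[inside] <- v[inside]
    }
    img <- pmin(pmax(img, 0), 1)
    img[roi == 0] <- 0
    lab[roi == 0] <- IGNORE_LABEL
    slices[[s]] <- img
    labels[[s]] <- lab
    rois[[s]] <- roi
  }

  structure(list(slices = slices, dense_labels = labels, roi_masks = rois,
                 labeled_slice_indices = labeled_idx,
                 unlabeled_slice_indices = unlabeled_idx,
                 shape = c(H, W), n_classes = K, seed = seed),
            class = "synthetic_volume")
}

#' @export
print.synthetic_volume <- function(x, ...) {
  cat(sprintf("synthetic_volume: %d slices of %dx%d, %d classes, %d labeled (seed %d)\n",
              length(x$slices), x$shape[1], x$shape[2], x$n_classes,
              length(x$labeled_slice_indices), x$seed))
  invisible(x)
}

## Build a segmentation_record from one slice of a volume.
slice_record <- function(vol, vol_id, s, with_label = TRUE) {
  lab <- if (with_label) vol$dense_labels[[s]] else NULL
  segmentation_record(vol$slices[[s]], lab, vol$roi_masks[[s]],
                      id = sprintf("v%02d_s%03d", vol_id, s))
}

#' Dataset state: labeled / unlabeled / validation / test partitions
#'
#' @param labeled,unlabeled,val,test Lists of [segmentation_record()]s. The
#'   labeled and unlabeled sets must be disjoint by id.
#' @return An object of class `dataset_state`.
#' @export
dataset_state <- function(labeled, unlabeled = list(), val = list(), test = list()) {
  idl <- vapply(labeled, `[[`, "", "id")
  idu <- vapply(unlabeled, `[[`, "", "id")
  if (length(intersect(idl, idu))) stop("labeled and unlabeled sets overlap")
  names(labeled) <- idl
  if (length(unlabeled)) names(unlabeled) <- idu
  structure(list(labeled = labeled, unlabeled = unlabeled, val = val, test = test),
            class = "dataset_state")
}

#' @export
print.dataset_state <- function(x, ...) {
  cat(sprintf("dataset_state: %d labeled (%d pseudo), %d unlabeled, %d val, %d test\n",
              length(x$labeled),
              sum(vapply(x$labeled, function(r) r$provenance == "pseudo", logical(1))),
              length(x$unlabeled), length(x$val), length(x$test)))
  invisible(x)
}

#' Volume-level train/validation/test split
#'
#' Partitions volumes (never individual slices) into train, validation and
#' test sets, then splits the training portion into the labeled set (the
#' annotated slices) and the unlabeled set (their neighbour slices).
#' Validation and test volumes contribute their annotated slices with labels
#' for evaluation. Assignment is deterministic in the order the volumes are
#' given.
#'
#' @param volumes List of at least 3 [generate_volume()] outputs (or
#'   compatible objects).
#' @param ratios Numeric `(train, val, test)` proportions (default 3/1/1).
#' @return A [dataset_state()].
#' @export
make_split <- function(volumes, ratios = c(3, 1, 1)) {
  n <- length(volumes)
  if (n < 3) stop("need at least 3 volumes to split")
  ratios <- ratios / sum(ratios)
  n_val <- max(1L, floor(n * ratios[2]))
  n_test <- max(1L, floor(n * ratios[3]))
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("split leaves no training volumes")
  part <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))

  labeled <- list(); unlabeled <- list(); val <- list(); test <- list()
  for (v in seq_len(n)) {
    vol <- volumes[[v]]
    if (part[v] == "train") {
      for (s in vol$labeled_slice_indices)
        labeled[[length(labeled) + 1L]] <- slice_record(vol, v, s, TRUE)
      for (s in vol$unlabeled_slice_indices)
        unlabeled[[length(unlabeled) + 1L]] <- slice_record(vol, v, s, FALSE)
    } else if (part[v] == "val") {
      for (s in vol$labeled_slice_indices)
        val[[length(val) + 1L]] <- slice_record(vol, v, s, TRUE)
    } else {
      for (s in vol$labeled_slice_indices)
        test[[length(test) + 1L]] <- slice_record(vol, v, s, TRUE)
    }
  }
  st <- dataset_state(labeled, unlabeled, val, test)
  attr(st, "volume_partition") <- part
  st
}

#' Default synthetic benchmark
#'
#' Nine 28-slice 64x64 volumes with the default 4-class textures, split
#' 5 train / 2 validation / 2 test. Each training volume contributes 4
#' labeled slices and their 24 neighbour slices, giving 20 labeled and 120
#' unlabeled training slices.
#'
#' @param seed Integer master seed; volume `k` uses `seed + k`.
#' @param n_volumes Number of volumes (default 9).
#' @param n_classes 4 or 8 texture classes.
#' @param n_slices,shape,n_labeled,neighbour_window Passed to
#'   [generate_volume()].
#' @return A [dataset_state()].
#' @export
default_benchmark <- function(seed = 1, n_volumes = 9, n_classes = 4,
                              n_slices = 28, shape = c(64, 64), n_labeled = 4,
                              neighbour_window = 3) {
  specs <- default_class_specs(n_classes)
  vols <- lapply(seq_len(n_volumes), function(k)
    generate_volume(specs, n_slices, shape, n_labeled, neighbour_window,
                    seed = seed + k))
  make_split(vols, ratios = c(5, 2, 2))
}
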