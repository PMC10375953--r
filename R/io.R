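#' Write a volume to disk
#'
#' Emits one NIfTI file each for the image stack (float64, lossless), the
#' dense label masks (uint8, ignore = 255) and the ROI masks (uint8), plus
#' optional per-slice 8-bit PNGs for quick inspection, and returns the
#' manifest entry describing the case.
#'
#' @param volume A `synthetic_volume` (or compatible object with `slices`,
#'   `dense_labels`, `roi_masks`, `labeled_slice_indices`).
#' @param dir Output directory (created if needed).
#' @param case_id Character case identifier.
#' @param split Optional split tag (`"train"`, `"val"`, `"test"`).
#' @param png Also write per-slice PNGs (default `FALSE`).
#' @return The manifest entry (a list), invisibly usable with
#'   [write_manifest()].
#' @export
write_case <- function(volume, dir, case_id, split = NA_character_, png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  H <- nrow(volume$slices[[1]]); W <- ncol(volume$slices[[1]])
  S <- length(volume$slices)
  img <- array(unlist(volume$slices), c(H, W, S))
  lab <- array(as.integer(unlist(volume$dense_labels)), c(H, W, S))
  roi <- array(as.integer(unlist(volume$roi_masks)), c(H, W, S))
  f_img <- file.path(dir, paste0(case_id, "_image.nii.gz"))
  f_lab <- file.path(dir, paste0(case_id, "_labels.nii.gz"))
  f_roi <- file.path(dir, paste0(case_id, "_roi.nii.gz"))
  RNifti::writeNifti(img, f_img, datatype = "double")
  RNifti::writeNifti(lab, f_lab, datatype = "uint8")
  RNifti::writeNifti(roi, f_roi, datatype = "uint8")
  if (png) {
    pdir <- file.path(dir, paste0(case_id, "_png"))
    dir.create(pdir, showWarnings = FALSE)
    for (s in seq_len(S)) {
      png::writePNG(volume$slices[[s]],
                    file.path(pdir, sprintf("slice_%03d.png", s)))
      png::writePNG(volume$dense_labels[[s]] / 255,
                    file.path(pdir, sprintf("mask_%03d.png", s)))
    }
  }
  list(case_id = case_id, image = basename(f_img), labels = basename(f_lab),
       roi = basename(f_roi),
       labeled_slice_indices = volume$labeled_slice_indices,
       unlabeled_slice_indices = volume$unlabeled_slice_indices,
       split = split, intensity = "normalized01")
}

#' Write / read a case manifest
#'
#' The manifest is a JSON list of case entries (paths, labeled slice
#' indices, split tags, intensity convention).
#'
#' @param entries List of entries from [write_case()].
#' @param file Path of the JSON manifest.
#' @export
write_manifest <- function(entries, file) {
  jsonlite::write_json(entries, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Read a case from disk
#'
#' Loads the NIfTI image/label/ROI files referenced by a manifest entry and
#' reconstructs a volume object. Intensities flagged as Hounsfield units
#' (`intensity = "hu"`, or detected by a value range far outside `[0, 1]`)
#' are routed through [hu_window_normalize()]; already-normalized inputs
#' pass through unchanged.
#'
#' @param entry One manifest entry ([read_manifest()] element).
#' @param dir Directory containing the files.
#' @param config A [preprocess_config()] for the HU window.
#' @return A `synthetic_volume`-compatible object.
#' @export
read_case <- function(entry, dir, config = preprocess_config()) {
  arr <- function(f) {
    a <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(a), dim(a))
  }
  img <- arr(entry$image)
  lab <- arr(entry$labels)
  roi <- arr(entry$roi)
  if (!all(dim(img) == dim(lab)) || !all(dim(img) == dim(roi)))
    stop("shape mismatch between image and masks in case ", entry$case_id)
  is_hu <- identical(entry$intensity, "hu") ||
    (is.null(entry$intensity) && (min(img) < -2 || max(img) > 2))
  if (is_hu) img <- hu_window_normalize(img, config)
  labv <- as.integer(lab)
  n_cls <- if (any(labv != IGNORE_LABEL)) max(labv[labv != IGNORE_LABEL]) + 1L else 0L
  if (any(labv != IGNORE_LABEL & (labv < 0L | labv > 254L)))
    stop("mask with out-of-range class id in case ", entry$case_id)
  S <- dim(img)[3]
  li <- as.integer(unlist(entry$labeled_slice_indices))
  if (any(li < 1L | li > S)) stop("labeled slice index out of range in case ", entry$case_id)
  structure(list(
    slices = lapply(seq_len(S), function(s) img[, , s]),
    dense_labels = lapply(seq_len(S), function(s) matrix(as.integer(lab[, , s]), dim(lab)[1])),
    roi_masks = lapply(seq_len(S), function(s) matrix(as.integer(roi[, , s]), dim(roi)[1])),
    labeled_slice_indices = li,
    unlabeled_slice_indices = as.integer(unlist(entry$unlabeled_slice_indices)),
    shape = dim(img)[1:2], n_classes = n_cls,
    seed = NA_integer_), class = "synthetic_volume")
}

#' Build a dataset from a manifest directory
#'
#' Reads every case of a manifest and assembles a [dataset_state()] from the
#' per-case split tags.
#'
#' @param dir Directory containing `manifest.json` and the case files.
#' @param config A [preprocess_config()].
#' @return A [dataset_state()].
#' @export
read_dataset <- function(dir, config = preprocess_config()) {
  entries <- read_manifest(file.path(dir, "manifest.json"))
  labeled <- list(); unlabeled <- list(); val <- list(); test <- list()
  for (v in seq_along(entries)) {
    e <- entries[[v]]
    vol <- read_case(e, dir, config)
    tag <- e$split %||% "train"
    if (tag == "train") {
      for (s in vol$labeled_slice_indices)
        labeled[[length(labeled) + 1L]] <- slice_record(vol, v, s, TRUE)
      for (s in vol$unlabeled_slice_indices)
        unlabeled[[length(unlabeled) + 1L]] <- slice_record(vol, v, s, FALSE)
    } else if (tag == "val") {
      for (s in vol$labeled_slice_indices)
        val[[length(val) + 1L]] <- slice_record(vol, v, s, TRUE)
    } else {
      for (s in vol$labeled_slice_indices)
        test[[length(test) + 1L]] <- slice_record(vol, v, s, TRUE)
    }
  }
  dataset_state(labeled, unlabeled, val, test)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose blocks mirror the configuration objects
#' (top-level pipeline fields plus `loss:`, `network:`, `ema:` and
#' `preprocess:` blocks) and builds a [run_config()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_args <- y[intersect(names(y), c("max_rounds", "epochs_per_round", "composition",
                                      "q_checkpoints", "selection_fraction", "seed",
                                      "lr", "perturb_noise_sd", "beta_mode"))]
  if (!is.null(y$loss)) cfg_args$loss <- do.call(loss_config, y$loss)
  if (!is.null(y$network)) cfg_args$network <- do.call(network_config, y$network)
  if (!is.null(y$ema)) cfg_args$ema <- do.call(ema_config, y$ema)
  if (!is.null(y$preprocess)) cfg_args$preprocess <- do.call(preprocess_config, y$preprocess)
  do.call(run_config, cfg_args)
}
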