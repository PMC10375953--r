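#' Dice coefficient for one class
#'
#' `2 |X ∩ Y| / (|X| + |Y|)` between the binary masks of `class_id` in the
#' predicted and reference label masks, with ignore pixels excluded.
#' Symmetric in its arguments. When the class is absent from both masks the
#' value is 1 by convention, flagged with attribute `skipped = TRUE` so
#' aggregations can drop it.
#'
#' @param pred_mask,truth Integer label masks of identical shape.
#' @param class_id Class to score.
#' @return A value in `[0, 1]` (possibly with attribute `skipped`).
#' @export
dice_coefficient <- function(pred_mask, truth, class_id) {
  p <- as_label_vector(pred_mask); y <- as_label_vector(truth)
  if (length(p) != length(y)) stop("masks must share a shape")
  keep <- p != IGNORE_LABEL & y != IGNORE_LABEL
  p <- p[keep]; y <- y[keep]
  X <- p == class_id; Y <- y == class_id
  nX <- sum(X); nY <- sum(Y)
  if (nX + nY == 0) return(structure(1, skipped = TRUE))
  2 * sum(X & Y) / (nX + nY)
}

#' Evaluate a model on a labeled split
#'
#' Runs unperturbed inference on every record, takes per-pixel argmax masks
#' and computes the per-class dice against the reference labels. Classes
#' absent from both the truth and the prediction of an image are skipped for
#' that image. Reported are the per-class mean and standard deviation across
#' images and their class-mean average — the layout used for segmentation
#' result tables (classes as columns, the average last).
#'
#' @param model A `seg_network` (by convention the teacher: reported
#'   segmentations come from the trained teacher).
#' @param records Non-empty list of [segmentation_record()]s with dense
#'   labels.
#' @param n_classes Number of classes `T`.
#' @return An object of class `dice_report`: list with `per_class` (a data
#'   frame with columns `class`, `mean`, `sd`, `n`) and `average`.
#' @export
evaluate_split <- function(model, records, n_classes) {
  if (length(records) == 0) stop("no labeled records to evaluate")
  per_image <- matrix(NA_real_, length(records), n_classes)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.null(rec$label)) stop("record ", rec$id, " has no dense label")
    pm <- net_predict_mask(model, rec)
    for (t in seq_len(n_classes) - 1L) {
      d <- dice_coefficient(pm, rec$label, t)
      if (!isTRUE(attr(d, "skipped"))) per_image[i, t + 1L] <- as.numeric(d)
    }
  }
  means <- colMeans(per_image, na.rm = TRUE)
  sds <- apply(per_image, 2L, stats::sd, na.rm = TRUE)
  ns <- colSums(!is.na(per_image))
  per_class <- data.frame(class = seq_len(n_classes) - 1L,
                          mean = means, sd = sds, n = ns)
  structure(list(per_class = per_class, average = mean(means, na.rm = TRUE),
                 per_image = per_image),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, digits = 4, ...) {
  cat("Per-class dice (mean ± sd over images):\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  class %d: %.*f ± %.*f (n = %d)\n", pc$class[i],
                digits, pc$mean[i], digits, pc$sd[i], pc$n[i]))
  cat(sprintf("  Avg: %.*f\n", digits, x$average))
  invisible(x)
}

#' Format a dice report as a one-row table
#'
#' Classes as columns, `Avg` last — the usual reporting layout.
#'
#' @param report A [evaluate_split()] result.
#' @param label Row label (e.g. the training condition).
#' @return A one-row data frame.
#' @export
dice_report_row <- function(report, label = "model") {
  vals <- c(report$per_class$mean, report$average)
  df <- as.data.frame(as.list(round(100 * vals, 2)))
  names(df) <- c(paste0("class", report$per_class$class), "Avg")
  cbind(data.frame(model = label), df)
}

#' Unlabeled-fraction ablation
#'
#' Re-runs the full pipeline with the unlabeled pool subsampled at each of
#' the given fractions (seeded), plus the supervised-only baseline for
#' fraction 0, and tabulates the test dice of each arm. Mirrors the usual
#' "how much does unlabeled data help" ablation; the expected pattern is an
#' improving trend with more unlabeled data, though at small benchmark sizes
#' the trend is stochastic and is reported rather than guaranteed.
#'
#' @param data A [dataset_state()].
#' @param config A [run_config()].
#' @param fractions Fractions of the unlabeled pool to keep (0 = supervised
#'   only).
#' @return A list with `table` (one row per fraction) and `reports`.
#' @export
ablation_unlabeled_fraction <- function(data, config, fractions = c(0, 0.25, 0.5, 0.75, 1)) {
  rows <- list(); reports <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    if (f == 0) {
      fit <- supervised_baseline(data, config)
      rep_i <- evaluate_split(fit$pair$teacher, data$test, config$network$n_classes)
      label <- "SupOnly"
    } else {
      sub <- data
      if (f < 1) {
        set.seed(config$seed + 7000 + i)
        keep <- sort(sample(length(sub$unlabeled), max(1L, floor(f * length(sub$unlabeled)))))
        sub$unlabeled <- sub$unlabeled[keep]
      }
      rounds <- run_pipeline(sub, config)
      final <- rounds[[length(rounds)]]
      rep_i <- evaluate_split(final$pair$teacher, data$test, config$network$n_classes)
      label <- sprintf("Labeled + %d%% Unlabeled", round(100 * f))
    }
    rows[[i]] <- dice_report_row(rep_i, label)
    reports[[i]] <- rep_i
  }
  list(table = do.call(rbind, rows), reports = reports)
}
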