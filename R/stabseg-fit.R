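#' Fit a semi-supervised segmentation model
#'
#' The main entry point: trains the full iterative Mean-Teacher +
#' stability-selection pipeline (or the supervised-only baseline) on a
#' dataset and returns a fitted model object with the usual methods
#' (`print`, `summary`, `predict`, `plot`).
#'
#' @param data A [dataset_state()], e.g. from [make_split()] or
#'   [default_benchmark()].
#' @param config A [run_config()].
#' @param method `"semi"` (default: the full pipeline) or `"supervised"`
#'   (the SupOnly baseline: labeled data only, no consistency term, one
#'   round).
#' @return An object of class `stabseg` with components `rounds` (the
#'   per-round states), `model` (the final teacher network), `val_history`,
#'   `config`, and `method`.
#' @examples
#' \donttest{
#' data <- default_benchmark(seed = 1, n_volumes = 3, n_slices = 14,
#'                           shape = c(32, 32), n_labeled = 2)
#' cfg <- run_config(max_rounds = 1, epochs_per_round = 1,
#'                   network = network_config(4, "tiny", base_width = 8))
#' fit <- stabseg(data, cfg)
#' print(fit)
#' }
#' @export
stabseg <- function(data, config = run_config(), method = c("semi", "supervised")) {
  method <- match.arg(method)
  if (method == "supervised") {
    base <- supervised_baseline(data, config)
    rounds <- list(round_state(1L, data, pair = base$pair,
                               metrics = list(val_dice = base$val_dice,
                                              loss_log = base$loss_log,
                                              supervised_mode = TRUE)))
  } else {
    rounds <- run_pipeline(data, config)
  }
  final <- rounds[[length(rounds)]]
  structure(list(rounds = rounds, model = final$pair$teacher,
                 pair = final$pair,
                 val_history = vapply(rounds, function(s) s$metrics$val_dice %||% NA_real_,
                                      numeric(1)),
                 config = config, method = method, call = match.call()),
            class = "stabseg")
}

#' @export
print.stabseg <- function(x, ...) {
  cat(sprintf("stabseg fit (%s): %d round(s), %s backbone, %d classes\n",
              if (x$method == "semi") "semi-supervised" else "supervised-only",
              length(x$rounds), x$config$network$variant,
              x$config$network$n_classes))
  vh <- x$val_history
  if (any(!is.na(vh)))
    cat("validation avg dice by round:",
        paste(sprintf("%.3f", vh), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.stabseg <- function(object, ...) {
  rows <- lapply(object$rounds, function(st) {
    data.frame(round = st$round_index,
               n_labeled = length(st$dataset$labeled),
               n_unlabeled = length(st$dataset$unlabeled),
               n_admitted = if (!is.null(st$selection)) st$selection$n_admitted else 0L,
               val_dice = st$metrics$val_dice %||% NA_real_,
               mean_sup_loss = mean(st$metrics$loss_log[, "sup"], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.stabseg", class(out))
  out
}

#' @export
print.summary.stabseg <- function(x, ...) {
  cat("Per-round summary:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict label masks or probability maps for new slices
#'
#' @param object A fitted `stabseg` model.
#' @param newdata A [segmentation_record()] or a list of them.
#' @param type `"mask"` (argmax label masks, ROI-restricted) or `"prob"`
#'   (probability arrays).
#' @param ... Unused.
#' @return A list (one element per record) of masks or probability maps.
#' @export
predict.stabseg <- function(object, newdata, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "segmentation_record")) newdata <- list(newdata)
  lapply(newdata, function(rec) {
    if (type == "mask") net_predict_mask(object$model, rec)
    else net_forward(object$model, rec$image)$probs
  })
}

#' Plot training diagnostics of a fitted model
#'
#' Left panel: per-step loss components across all rounds. Right panel:
#' validation average dice by round.
#'
#' @param x A `stabseg` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stabseg <- function(x, ...) {
  logs <- do.call(rbind, lapply(x$rounds, function(st) st$metrics$loss_log))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(logs[, "total"], type = "l", xlab = "step", ylab = "loss",
                 main = "training loss", col = "grey30", ...)
  graphics::lines(logs[, "sup"], col = "steelblue")
  graphics::legend("topright", legend = c("total", "supervised"),
                   col = c("grey30", "steelblue"), lty = 1, bty = "n")
  vh <- x$val_history
  graphics::plot(seq_along(vh), vh, type = "b", xlab = "round",
                 ylab = "validation avg dice", main = "round trend",
                 ylim = range(vh, na.rm = TRUE) + c(-0.02, 0.02))
  invisible(x)
}
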