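#' Mean intersection-over-union between two label masks
#'
#' Per-class IoU averaged over the classes appearing in either mask (so no
#' class contributes an undefined 0/0 term). Ignore pixels are excluded from
#' both masks before counting.
#'
#' @param mask_a,mask_b Integer label masks of identical shape.
#' @return A value in `[0, 1]`; 1 iff the masks agree on every non-ignore
#'   pixel.
#' @export
mean_iou <- function(mask_a, mask_b) {
  a <- as_label_vector(mask_a); b <- as_label_vector(mask_b)
  if (length(a) != length(b)) stop("masks must share a shape")
  keep <- a != IGNORE_LABEL & b != IGNORE_LABEL
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("both masks are entirely ignored")
  classes <- sort(unique(c(a, b)))
  ious <- vapply(classes, function(t) {
    ia <- a == t; ib <- b == t
    sum(ia & ib) / sum(ia | ib)
  }, numeric(1))
  mean(ious)
}

#' Checkpoint ensemble
#'
#' An ordered collection of `Q >= 2` teacher snapshots saved during a
#' training round; the last snapshot is the round's final teacher and serves
#' as the reference for stability scoring.
#'
#' @param checkpoints List of `seg_network` snapshots.
#' @param provenance Optional data frame or list of `(round, step)` per
#'   snapshot.
#' @return An object of class `checkpoint_ensemble`.
#' @export
checkpoint_ensemble <- function(checkpoints, provenance = NULL) {
  if (length(checkpoints) < 2) stop("need at least 2 checkpoints (Q >= 2)")
  structure(list(checkpoints = checkpoints, provenance = provenance),
            class = "checkpoint_ensemble")
}

#' Checkpoint-stability score of a pseudo-label
#'
#' Predicts an unlabeled slice with all `Q` checkpoints (unperturbed
#' inference) and sums, over the first `Q - 1` predictions, their mean IoU
#' against the final checkpoint's prediction:
#' \eqn{s_i = \sum_{j=1}^{Q-1} \mathrm{meanIOU}(Y^p_{ij}, Y^p_{iQ})}.
#' The score lies in `[0, Q - 1]`, reaching `Q - 1` iff all predictions
#' coincide; a high score marks a pseudo-mask that stayed stable over
#' training, which correlates with its reliability. The final checkpoint's
#' prediction is returned as the pseudo-mask.
#'
#' @param record An unlabeled [segmentation_record()].
#' @param ensemble A [checkpoint_ensemble()].
#' @return An object of class `stability_score`: list with `image_id`,
#'   `s`, and `pseudo_mask`.
#' @export
stability_score <- function(record, ensemble) {
  stopifnot(inherits(ensemble, "checkpoint_ensemble"))
  masks <- lapply(ensemble$checkpoints, net_predict_mask, record = record)
  Q <- length(masks)
  ref <- masks[[Q]]
  s <- sum(vapply(masks[seq_len(Q - 1L)], mean_iou, numeric(1), mask_b = ref))
  structure(list(image_id = record$id, s = s, pseudo_mask = ref),
            class = "stability_score")
}

#' Rank stability scores and select the most reliable fraction
#'
#' Sorts scores in descending order and returns the ids of the top
#' `floor(fraction * N)` images (at least 1). Ties are broken by ascending
#' image id, making the selection a deterministic function of its inputs.
#'
#' @param scores Non-empty list of [stability_score()] objects.
#' @param fraction Selection quota in `(0, 1]` (default 0.25, the top-25%
#'   rule).
#' @return Character vector of selected image ids, in descending score
#'   order.
#' @export
rank_and_select <- function(scores, fraction = 0.25) {
  if (length(scores) == 0) stop("'scores' is empty")
  if (!(fraction > 0 && fraction <= 1)) stop("'fraction' must be in (0, 1]")
  s <- vapply(scores, `[[`, numeric(1), "s")
  ids <- vapply(scores, `[[`, character(1), "image_id")
  k <- max(1L, floor(fraction * length(scores)))
  ord <- order(-s, ids)
  unname(ids[ord][seq_len(k)])
}

#' Admit selected pseudo-labels into the labeled set
#'
#' Moves the selected records from the unlabeled set to the labeled set,
#' attaching their pseudo-masks as labels and tagging them with pseudo
#' provenance and the admitting round. The total number of training records
#' is conserved and human labels are never overwritten.
#'
#' @param state A [dataset_state()].
#' @param selected Character vector of ids, all currently in the unlabeled
#'   set.
#' @param pseudo_masks Named list of label masks (names = ids), e.g. the
#'   `pseudo_mask` fields of the corresponding [stability_score()]s.
#' @param round_index Round at which admission happens.
#' @return The updated [dataset_state()].
#' @export
update_datasets <- function(state, selected, pseudo_masks, round_index = NA_integer_) {
  stopifnot(inherits(state, "dataset_state"))
  if (length(selected) == 0) return(state)
  missing <- setdiff(selected, names(state$unlabeled))
  if (length(missing))
    stop("ids not in the unlabeled set: ", paste(missing, collapse = ", "))
  for (id in selected) {
    rec <- state$unlabeled[[id]]
    mask <- pseudo_masks[[id]]
    if (is.null(mask)) stop("missing pseudo mask for id ", id)
    rec$label <- matrix(as.integer(mask), nrow(rec$image), ncol(rec$image))
    rec$provenance <- "pseudo"
    rec$round_admitted <- as.integer(round_index)
    state$labeled[[id]] <- rec
  }
  state$unlabeled[selected] <- NULL
  state
}
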