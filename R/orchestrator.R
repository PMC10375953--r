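#' Run configuration
#'
#' All knobs of the iterative semi-supervised training procedure. The
#' defaults follow the study conditions: 3 training rounds, batches of 1
#' labeled + 3 unlabeled slices, Q = 4 teacher checkpoints per round at
#' 25/50/75/100% of the round's steps, and admission of the top-25% most
#' stable pseudo-labels after each round. Epochs per round default to 20,
#' the desk-scale counterpart of full-scale training.
#'
#' @param max_rounds Number of training rounds (default 3).
#' @param epochs_per_round Epochs per round (default 20).
#' @param steps_per_round Optional fixed optimization-step budget per round.
#'   When set, each round runs the number of whole epochs closest to this
#'   budget instead of `epochs_per_round`, so later rounds do not grow in
#'   wall time as admitted pseudo-labels enlarge the labeled set. The
#'   shipped benchmark study uses 400 (equal to 20 epochs of the initial
#'   labeled set).
#' @param composition Integer `(labeled, unlabeled)` batch composition
#'   (default `c(1, 3)`).
#' @param q_checkpoints Number of teacher snapshots per round (default 4).
#' @param selection_fraction Fraction of the remaining unlabeled pool
#'   admitted after each round (default 0.25; 0 disables selection).
#' @param seed Master seed; round `r` trains under seed `seed + r`.
#' @param loss A [loss_config()].
#' @param network A [network_config()].
#' @param ema An [ema_config()]. The default uses desk-scale smoothing
#'   (0.95 ramp-up / 0.99 main) so the teacher's averaging window,
#'   roughly `1/(1 - alpha)` steps, stays a small fraction of a round's
#'   total steps; at full scale (hundreds of epochs) the canonical
#'   0.99/0.999 horizons play the same role.
#' @param preprocess A [preprocess_config()] used for train-time
#'   augmentation, or `NULL` for none.
#' @param lr Student learning rate (default 1e-3).
#' @param perturb_noise_sd Input-noise SD of the perturbed forwards
#'   (default 0.05).
#' @param beta_mode `"inverse_freq"` (focal class weights from the human
#'   labels of the current labeled set), `"uniform"`, or `"explicit"` (use
#'   `loss$beta` as given).
#' @param round_init How rounds after the first initialize the model pair:
#'   `"warm"` (default) continues from the previous round's student and
#'   teacher (step counter and consistency ramp restart), `"scratch"`
#'   re-initializes a fresh pair each round.
#' @return An object of class `run_config`.
#' @export
run_config <- function(max_rounds = 3, epochs_per_round = 20,
                       steps_per_round = NULL,
                       composition = c(labeled = 1, unlabeled = 3),
                       q_checkpoints = 4, selection_fraction = 0.25, seed = 1,
                       loss = loss_config(), network = network_config(4, "tiny"),
                       ema = ema_config(alpha_rampup = 0.95, alpha_main = 0.99),
                       preprocess = preprocess_config(),
                       lr = 1e-3, perturb_noise_sd = 0.05,
                       beta_mode = c("inverse_freq", "uniform", "explicit"),
                       round_init = c("warm", "scratch")) {
  if (!is_count(max_rounds)) stop("'max_rounds' must be a positive integer")
  if (!is_count(epochs_per_round, 0L)) stop("'epochs_per_round' must be >= 0")
  if (length(composition) != 2L || composition[1] < 1 || any(composition < 0))
    stop("'composition' must be (labeled >= 1, unlabeled >= 0)")
  if (!is_count(q_checkpoints, 2L)) stop("'q_checkpoints' must be >= 2")
  if (selection_fraction < 0 || selection_fraction > 1)
    stop("'selection_fraction' must be in [0, 1]")
  if (!is.null(steps_per_round) && !is_count(steps_per_round))
    stop("'steps_per_round' must be a positive integer")
  structure(list(max_rounds = as.integer(max_rounds),
                 epochs_per_round = as.integer(epochs_per_round),
                 steps_per_round = steps_per_round,
                 composition = as.integer(composition),
                 q_checkpoints = as.integer(q_checkpoints),
                 selection_fraction = selection_fraction,
                 seed = as.integer(seed), loss = loss, network = network,
                 ema = ema, preprocess = preprocess, lr = lr,
                 perturb_noise_sd = perturb_noise_sd,
                 beta_mode = match.arg(beta_mode),
                 round_init = match.arg(round_init)),
            class = "run_config")
}

#' Round state
#'
#' The evolving state of one training round: the dataset partition, the
#' checkpoint ensemble saved during the round, the trained model pair and
#' the round's metrics.
#'
#' @param round_index Round number (1-based).
#' @param dataset A [dataset_state()].
#' @param ensemble,pair,metrics Filled in by [run_round()].
#' @return An object of class `round_state`.
#' @export
round_state <- function(round_index, dataset, ensemble = NULL, pair = NULL,
                        metrics = NULL) {
  structure(list(round_index = as.integer(round_index), dataset = dataset,
                 ensemble = ensemble, pair = pair, metrics = metrics),
            class = "round_state")
}

#' Sample one epoch of mixed batches
#'
#' Produces the batch sequence for one epoch under the given composition.
#' Every batch contains exactly `composition[1]` labeled and
#' `composition[2]` unlabeled record ids; each labeled record is visited at
#' least once per epoch (the final batch is padded from the epoch's shuffled
#' order when the set size is not a multiple of the quota). The unlabeled
#' side cycles through reshuffled permutations of the pool. With an empty
#' unlabeled pool the composition falls back to all-labeled batches of the
#' same total size. Randomness comes from R's global stream.
#'
#' @param dataset A [dataset_state()].
#' @param composition Integer `(labeled, unlabeled)` counts per batch.
#' @return A list of batches, each a list with character `labeled` and
#'   `unlabeled` id vectors.
#' @export
batch_sampler <- function(dataset, composition = c(1L, 3L)) {
  M <- length(dataset$labeled)
  if (M == 0) stop("no labeled records")
  comp_l <- as.integer(composition[1]); comp_u <- as.integer(composition[2])
  if (comp_l < 1) stop("infeasible composition: need at least 1 labeled per batch")
  N <- length(dataset$unlabeled)
  if (N == 0 && comp_u > 0) { comp_l <- comp_l + comp_u; comp_u <- 0L }
  steps <- ceiling(M / comp_l)
  perm <- sample(M)
  lseq <- perm
  need_l <- steps * comp_l
  if (need_l > M) lseq <- c(lseq, perm[seq_len(need_l - M)])
  lab_ids <- names(dataset$labeled)[lseq]
  if (comp_u > 0) {
    need_u <- steps * comp_u
    useq <- integer(0)
    while (length(useq) < need_u) useq <- c(useq, sample(N))
    unl_ids <- names(dataset$unlabeled)[useq[seq_len(need_u)]]
  }
  lapply(seq_len(steps), function(s) {
    list(labeled = lab_ids[((s - 1L) * comp_l + 1L):(s * comp_l)],
         unlabeled = if (comp_u > 0)
           unl_ids[((s - 1L) * comp_u + 1L):(s * comp_u)] else character(0))
  })
}

## Number of whole epochs a round runs: either the configured epoch count
## or the closest whole-epoch approximation of the per-round step budget.
round_epochs <- function(config, steps_per_epoch) {
  if (is.null(config$steps_per_round)) return(config$epochs_per_round)
  max(1L, as.integer(round(config$steps_per_round / steps_per_epoch)))
}

## Effective per-round loss/EMA configs: resolve deferred lengths and the
## focal class weights (from human-provenance labels only).
resolve_round_configs <- function(config, dataset, total_steps) {
  loss_cfg <- config$loss
  loss_cfg$ramp_length <- loss_cfg$ramp_length %||% max(1L, round(0.3 * total_steps))
  if (config$beta_mode == "inverse_freq") {
    human <- Filter(function(r) r$provenance == "human", dataset$labeled)
    loss_cfg$beta <- class_weights(lapply(human, `[[`, "label"),
                                   config$network$n_classes)
  } else if (config$beta_mode == "uniform") {
    loss_cfg$beta <- NULL
  }
  ema_cfg <- config$ema
  ema_cfg$rampup_steps <- ema_cfg$rampup_steps %||% max(1L, round(0.1 * total_steps))
  list(loss = loss_cfg, ema = ema_cfg)
}

#' Run one training round
#'
#' Initializes the round's student/teacher pair (a fresh seeded pair, or —
#' for rounds after the first under `round_init = "warm"` — the previous
#' round's pair carried in `state`), trains it for the round's epoch or
#' step budget of mixed batches with [training_step()], saves
#' `q_checkpoints` teacher snapshots at evenly spaced fractions of the
#' round's steps, and evaluates the final teacher on the validation split.
#' The whole round runs under seed `config$seed + round_index`. When the consistency term is
#' disabled (`lambda_max == 0`) or the unlabeled pool is empty (a warning),
#' the round degrades to supervised-only training.
#'
#' @param state A [round_state()] holding the round index and dataset.
#' @param config A [run_config()].
#' @return The completed [round_state()] with `ensemble`, `pair` and
#'   `metrics` (validation dice, loss log, effective configs) filled in.
#' @export
run_round <- function(state, config) {
  stopifnot(inherits(state, "round_state"), inherits(config, "run_config"))
  dataset <- state$dataset
  M <- length(dataset$labeled)
  if (M == 0) stop("labeled set is empty")
  round_seed <- config$seed + state$round_index

  if (config$epochs_per_round == 0) {
    warning("epochs_per_round is 0: returning an untrained model")
    pair <- model_pair(net_build(config$network, seed = round_seed))
    state$pair <- pair
    state$metrics <- list(val_dice = NA_real_, error = "no_training")
    return(state)
  }

  supervised_mode <- config$loss$lambda_max == 0
  du_empty <- length(dataset$unlabeled) == 0
  if (du_empty && !supervised_mode) {
    warning("unlabeled pool is empty; round degrades to supervised-only training")
    supervised_mode <- TRUE
  }
  comp <- if (config$loss$lambda_max == 0) c(config$composition[1], 0L)
          else if (du_empty) c(sum(config$composition), 0L)
          else config$composition
  loss_eff <- config$loss
  if (supervised_mode) loss_eff$lambda_max <- 0

  steps_per_epoch <- ceiling(M / comp[1])
  n_epochs <- round_epochs(config, steps_per_epoch)
  total_steps <- n_epochs * steps_per_epoch
  cfgs <- resolve_round_configs(config, dataset, total_steps)
  loss_cfg <- cfgs$loss
  loss_cfg$lambda_max <- loss_eff$lambda_max
  ema_cfg <- cfgs$ema
  ckpt_steps <- pmax(1L, floor(seq_len(config$q_checkpoints) / config$q_checkpoints * total_steps))

  set.seed(round_seed)
  if (config$round_init == "warm" && !is.null(state$pair)) {
    pair <- state$pair
    pair$step <- 0L  # consistency ramp and EMA phases restart each round
  } else {
    pair <- model_pair(net_build(config$network))
  }
  opt <- rmsprop_init(pair$student$params, lr = config$lr)
  log <- matrix(NA_real_, total_steps, 6,
                dimnames = list(NULL, c("sup", "dice", "focal", "con", "lambda", "total")))
  ensemble_list <- list()
  prov <- list()
  step_global <- 0L

  for (epoch in seq_len(n_epochs)) {
    batches <- batch_sampler(dataset, comp)
    for (batch in batches) {
      res <- training_step(pair,
                           labeled_batch = dataset$labeled[batch$labeled],
                           unlabeled_batch = dataset$unlabeled[batch$unlabeled],
                           loss_cfg = loss_cfg, ema_cfg = ema_cfg,
                           opt_state = opt, pre_cfg = config$preprocess,
                           perturb_noise_sd = config$perturb_noise_sd)
      pair <- res$pair; opt <- res$opt_state
      step_global <- step_global + 1L
      log[step_global, ] <- res$losses
      hits <- sum(ckpt_steps == step_global)
      if (hits > 0) for (h in seq_len(hits)) {
        ensemble_list[[length(ensemble_list) + 1L]] <- pair$teacher
        prov[[length(prov) + 1L]] <- c(round = state$round_index, step = step_global)
      }
    }
  }

  state$pair <- pair
  state$ensemble <- if (length(ensemble_list) >= 2)
    checkpoint_ensemble(ensemble_list, do.call(rbind, prov)) else NULL
  val_dice <- if (length(dataset$val))
    evaluate_split(pair$teacher, dataset$val, config$network$n_classes)$average
    else NA_real_
  state$metrics <- list(val_dice = val_dice, loss_log = log,
                        supervised_mode = supervised_mode,
                        loss_config = loss_cfg, ema_config = ema_cfg)
  state
}

#' Run the full iterative semi-supervised pipeline
#'
#' Executes the five-step procedure: train a round on the current labeled
#' and unlabeled sets; pseudo-label the remaining unlabeled slices with the
#' round's teacher-checkpoint ensemble; rank them by stability score; admit
#' the top fraction into the labeled set; repeat on the updated sets up to
#' `max_rounds`. Selection operates on the pool remaining at each round, so
#' with a pool of 40 and fraction 0.25 the admissions are 10, 7, 5 over
#' three rounds. The total number of training records is conserved
#' throughout. If the unlabeled pool is exhausted, later rounds train
#' supervised-only with a warning.
#'
#' @param initial A [dataset_state()].
#' @param config A [run_config()].
#' @return A list of completed [round_state()]s, with a per-round
#'   `selection` report (scores, selected ids) attached to each element that
#'   performed one.
#' @export
run_pipeline <- function(initial, config) {
  stopifnot(inherits(initial, "dataset_state"), inherits(config, "run_config"))
  dataset <- initial
  states <- vector("list", config$max_rounds)
  prev_pair <- NULL
  for (r in seq_len(config$max_rounds)) {
    st <- run_round(round_state(r, dataset, pair = prev_pair), config)
    prev_pair <- st$pair
    do_select <- config$selection_fraction > 0 &&
      length(st$dataset$unlabeled) > 0 && !is.null(st$ensemble)
    if (do_select) {
      scores <- lapply(st$dataset$unlabeled, stability_score, ensemble = st$ensemble)
      selected <- rank_and_select(scores, config$selection_fraction)
      masks <- lapply(scores, `[[`, "pseudo_mask")
      dataset <- update_datasets(st$dataset, selected, masks, round_index = r)
      st$selection <- list(
        scores = data.frame(image_id = vapply(scores, `[[`, "", "image_id"),
                            s = vapply(scores, `[[`, numeric(1), "s"),
                            selected = vapply(scores, `[[`, "", "image_id") %in% selected,
                            row.names = NULL),
        selected = selected, n_admitted = length(selected))
    } else {
      dataset <- st$dataset
    }
    states[[r]] <- st
  }
  states
}

#' Supervised-only baseline
#'
#' Trains the same network with the same compound supervised loss on the
#' labeled set alone: a plain flat loop of augment / forward / supervised
#' gradient / RMSprop step / EMA update, with no consistency term, no
#' unlabeled batches and a single round. Uses seed `config$seed + 1`, the
#' same seed as round 1 of [run_pipeline()], so the two are directly
#' comparable (and exactly equal when the pipeline's consistency and
#' selection are switched off).
#'
#' @param data A [dataset_state()]; only its labeled and validation parts
#'   are used.
#' @param config A [run_config()].
#' @return A list with the trained `pair`, the per-step `loss_log`, and
#'   `val_dice`.
#' @export
supervised_baseline <- function(data, config) {
  stopifnot(inherits(data, "dataset_state"), inherits(config, "run_config"))
  M <- length(data$labeled)
  if (M == 0) stop("labeled set is empty")
  comp_l <- config$composition[1]
  steps_per_epoch <- ceiling(M / comp_l)
  n_epochs <- round_epochs(config, steps_per_epoch)
  total_steps <- n_epochs * steps_per_epoch
  cfgs <- resolve_round_configs(config, data, total_steps)
  loss_cfg <- cfgs$loss
  loss_cfg$lambda_max <- 0
  ema_cfg <- cfgs$ema

  set.seed(config$seed + 1L)
  pair <- model_pair(net_build(config$network))
  opt <- rmsprop_init(pair$student$params, lr = config$lr)
  log <- matrix(NA_real_, total_steps, 6,
                dimnames = list(NULL, c("sup", "dice", "focal", "con", "lambda", "total")))
  i <- 0L
  for (epoch in seq_len(n_epochs)) {
    for (batch in batch_sampler(data, c(comp_l, 0L))) {
      res <- training_step(pair, data$labeled[batch$labeled], list(),
                           loss_cfg, ema_cfg, opt, pre_cfg = config$preprocess,
                           perturb_noise_sd = config$perturb_noise_sd)
      pair <- res$pair; opt <- res$opt_state
      i <- i + 1L
      log[i, ] <- res$losses
    }
  }
  val_dice <- if (length(data$val))
    evaluate_split(pair$teacher, data$val, config$network$n_classes)$average
    else NA_real_
  list(pair = pair, loss_log = log, val_dice = val_dice)
}
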