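# Reproduction experiments at desk scale. Each function wires the modules
# into one seeded, self-contained run: the overfit sanity check of the
# dual-branch trainer, and the adaptation-benefit comparison of continual
# test-time adaptation against a frozen checkpoint on a corrupted stream.
# Problem sizes (48x48 scenes, 8/12-channel backbones, hundreds of steps) are
# chosen so a run takes CPU minutes; the vignette discusses the scaling.

toy_experiment_spec <- function(seed, ...) {
  scene_spec(image_height = 48L, image_width = 48L, num_classes = 3L,
             seed = seed, ...)
}

toy_experiment_model <- function(seed) {
  dual_branch_model(3L, image_size = 48L, stages = 2L,
                    channels = c(8L, 12L), head_hidden = 12L, seed = seed)
}

# decreasing cosine from 0.05 to 0.005 with momentum and norm clipping:
# fast early progress, a quiet tail, and no loss-spike blowups
toy_experiment_config <- function(seed, ...) {
  train_config(image_size = 48L, batch_size = 8L, lr_init = 0.05,
               lr_final = 0.005, schedule = "cosine", seed = seed, ...)
}

#' Overfit sanity experiment for the dual-branch trainer
#'
#' Trains the toy dual-branch model on one fixed 8-scene batch and reports
#' the final training losses on that batch: the detection loss (class BCE +
#' 1 - IoU + objectness BCE over the per-cell predictions, the quantity the
#' optimizer descends) and the Dice loss. A mechanism that can learn drives
#' both near zero. The decoded post-NMS detection loss is reported alongside
#' for reference; it additionally pays for the inference-time operating
#' point (confidence threshold, suppression) that training never optimizes.
#'
#' @param seed integer seed (scenes, init, training)
#' @param steps optimization steps (default 500)
#' @return tibble with `det_loss`, `dice`, `det_loss_decoded`, `steps`,
#'   `n_scenes`
#' @export
overfit_experiment <- function(seed = 1L, steps = 500L) {
  scenes <- generate_scenes(toy_experiment_spec(derive_seed(seed, "overfit")),
                            8L)
  model <- toy_experiment_model(derive_seed(seed, "overfit-model"))
  cfg <- toy_experiment_config(derive_seed(seed, "overfit-train"))
  opt <- NULL
  for (s in seq_len(steps)) {
    lr <- lr_at(cfg, if (steps > 1) (s - 1) / (steps - 1) else 0)
    res <- train_step(model, scenes, cfg, lr = lr, opt = opt)
    model <- res$model
    opt <- res$opt
  }
  final <- train_step(model, scenes, cfg, lr = 0, freeze_gates = TRUE)
  det_dec <- vapply(scenes, function(sc) {
    detection_train_loss(forward_fused(model, sc$image)$detections, sc)
  }, numeric(1))
  tibble::tibble(det_loss = final$det_loss, dice = final$seg_loss,
                 det_loss_decoded = mean(det_dec),
                 steps = steps, n_scenes = length(scenes))
}

#' Adaptation-benefit experiment on a corrupted stream
#'
#' Trains a toy checkpoint on clean scenes, then streams corrupted scenes
#' through (a) continual test-time adaptation and (b) the frozen checkpoint,
#' and compares mAP50 over the last quartile of the stream — where the
#' adapted model has had time to move.
#'
#' @param seed integer seed
#' @param kind corruption kind of the stream (default `"BR"`)
#' @param severity corruption severity
#' @param n_stream stream length (default 16)
#' @param train_steps training steps for the base checkpoint
#' @param eta online learning rate used during the streamed adaptation
#' @return tibble with `map50_tta`, `map50_frozen` (last-quartile values),
#'   plus whole-stream values `map50_tta_all`, `map50_frozen_all`
#' @export
adaptation_benefit_experiment <- function(seed = 1L, kind = "BR",
                                          severity = 0.5, n_stream = 16L,
                                          train_steps = 300L, eta = 1e-4) {
  train_scenes <- generate_scenes(
    toy_experiment_spec(derive_seed(seed, "benefit-train-data")), 24L)
  fit <- train_dual_branch(
    toy_experiment_model(derive_seed(seed, "benefit-model")),
    train_scenes,
    toy_experiment_config(derive_seed(seed, "benefit-train")),
    steps = train_steps)
  base <- fit$model
  clean <- generate_scenes(
    toy_experiment_spec(derive_seed(seed, "benefit-stream-data")), n_stream)
  cspec <- corruption_spec(kind, severity, derive_seed(seed, "benefit-corrupt"))
  stream <- lapply(clean, apply_corruption, spec = cspec)
  cfg <- tta_config(eta = eta, seed = derive_seed(seed, "benefit-tta"))
  model <- base
  adapted_preds <- vector("list", n_stream)
  for (i in seq_len(n_stream)) {
    res <- tta_step(model, stream[[i]]$image, cfg)
    model <- res$model
    adapted_preds[[i]] <- res$detections
  }
  frozen_preds <- lapply(stream, function(sc) {
    predict_scene(base, sc$image)$detections
  })
  lq <- (n_stream - floor(n_stream / 4) + 1L):n_stream
  tibble::tibble(
    map50_tta = map50(adapted_preds[lq], stream[lq]),
    map50_frozen = map50(frozen_preds[lq], stream[lq]),
    map50_tta_all = map50(adapted_preds, stream),
    map50_frozen_all = map50(frozen_preds, stream))
}

#' Continual seven-domain experiment
#'
#' Streams the full BR/DA/GN/FO/RA/SN/SP corruption sequence through a
#' trained checkpoint with and without continual adaptation and reports the
#' per-domain mAP50 matrix.
#'
#' @param seed integer seed
#' @param severity corruption severity shared by all domains
#' @param n_per_domain images per domain
#' @param train_steps training steps for the base checkpoint
#' @param eta online learning rate during adaptation
#' @return a `domain_report` (see [run_domain_sequence_report()])
#' @export
domain_sequence_experiment <- function(seed = 1L, severity = 0.5,
                                       n_per_domain = 6L, train_steps = 400L,
                                       eta = 1e-4) {
  train_scenes <- generate_scenes(
    toy_experiment_spec(derive_seed(seed, "seq-train-data")), 24L)
  fit <- train_dual_branch(
    toy_experiment_model(derive_seed(seed, "seq-model")),
    train_scenes,
    toy_experiment_config(derive_seed(seed, "seq-train")),
    steps = train_steps)
  clean <- generate_scenes(
    toy_experiment_spec(derive_seed(seed, "seq-stream-data")), n_per_domain)
  stream <- lapply(domain_sequence(severity, derive_seed(seed, "seq-dom")),
                   function(cs) {
                     list(domain = cs$kind,
                          scenes = lapply(clean, apply_corruption, spec = cs))
                   })
  cfg <- tta_config(eta = eta, seed = derive_seed(seed, "seq-tta"))
  run_domain_sequence_report(fit$model, stream, cfg)
}
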