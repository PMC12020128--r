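# Continual test-time adaptation. Each incoming test image is expanded into a
# set of photometric variants (noise, brightness, combined); every variant is
# run through the fused dual-branch model; the highest-confidence result
# becomes the pseudo-label; the losses of the ORIGINAL image's predictions
# against that pseudo-label update both branches online. No weights are reset
# between domains, so adaptation is continual across a drifting stream.

#' Test-time adaptation configuration
#'
#' @param num_variants number of photometric variants per image (default 16,
#'   allocated roughly 5 noise-only, 5 brightness-only, 6 combined)
#' @param noise_alpha standard deviation of the variant Gaussian noise on the
#'   `[0,1]` scale (default 8/255)
#' @param brightness_factor_range range of the multiplicative brightness
#'   factor L
#' @param offset_range range of the additive offset B for combined variants
#' @param eta online learning rate for both branches
#' @param lambda weight of the auxiliary (mask) loss in the total
#' @param adapt_dag also update the gate parameters during adaptation
#'   (default `FALSE`: gates stay frozen at test time, fusion remains active)
#' @param conf_thresh,nms_iou detection operating point used throughout
#' @param seed integer seed
#' @return an object of class `tta_config`
#' @export
tta_config <- function(num_variants = 16L, noise_alpha = 8 / 255,
                       brightness_factor_range = c(0.7, 1.3),
                       offset_range = c(-0.3, 0.3),
                       eta = 1e-4, lambda = 1, adapt_dag = FALSE,
                       conf_thresh = 0.25, nms_iou = 0.5, seed = 1L) {
  stopifnot(num_variants >= 1, eta >= 0, noise_alpha >= 0,
            brightness_factor_range[1] <= brightness_factor_range[2],
            offset_range[1] <= offset_range[2])
  structure(list(num_variants = as.integer(num_variants),
                 noise_alpha = noise_alpha,
                 brightness_factor_range = brightness_factor_range,
                 offset_range = offset_range,
                 eta = eta, lambda = lambda, adapt_dag = isTRUE(adapt_dag),
                 conf_thresh = conf_thresh, nms_iou = nms_iou,
                 seed = as.integer(seed)),
            class = "tta_config")
}

#' Generate photometric test-time variants of an image
#'
#' A deterministic allocation over three recipes: additive Gaussian noise,
#' multiplicative brightness (a factor grid over
#' `brightness_factor_range`), and offset-plus-noise (an offset grid over
#' `offset_range`). Geometry is untouched, so ground-truth-frame boxes remain
#' valid for every variant. All outputs are clipped to `[0,1]`.
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param cfg a [tta_config()]
#' @return list of `cfg$num_variants` images
#' @export
generate_variants <- function(image, cfg) {
  nv <- cfg$num_variants
  n_noise <- round(nv * 5 / 16)
  n_bright <- round(nv * 5 / 16)
  n_comb <- nv - n_noise - n_bright
  d <- dim(image)
  clip <- function(x) { x <- pmin(pmax(x, 0), 1); dim(x) <- d; x }
  add_noise <- function(img, tag) {
    with_seed(derive_seed(cfg$seed, "tta-variant", tag), {
      img + array(stats::rnorm(length(img), 0, cfg$noise_alpha), d)
    })
  }
  grid_over <- function(range, n) {
    if (n <= 1) rep(mean(range), n) else seq(range[1], range[2],
                                             length.out = n)
  }
  out <- vector("list", nv)
  i <- 0L
  for (k in seq_len(n_noise)) {
    i <- i + 1L
    out[[i]] <- clip(add_noise(image, paste0("n", k)))
  }
  for (L in grid_over(cfg$brightness_factor_range, n_bright)) {
    i <- i + 1L
    out[[i]] <- clip(L * image)
  }
  bs <- grid_over(cfg$offset_range, n_comb)
  for (k in seq_len(n_comb)) {
    i <- i + 1L
    out[[i]] <- clip(add_noise(image + bs[k], paste0("c", k)))
  }
  out
}

#' Confidence of a detection result
#'
#' Mean of the per-box confidences of a post-NMS detection set; 0 when there
#' are no boxes.
#' @param det a [detections()]
#' @return scalar in `[0,1]`
#' @export
image_confidence <- function(det) {
  if (length(det$confidence) == 0L) return(0)
  mean(det$confidence)
}

# decision-margin score of a mask probability map (how binary it is)
mask_confidence <- function(mask) {
  if (!length(mask)) return(0)
  mean(abs(2 * mask - 1))
}

#' Construct a pseudo-label
#'
#' @param boxes pixel boxes in the original image geometry
#' @param class_ids 0-based class ids
#' @param class_probs per-box K-vectors
#' @param conf per-box confidences in `[0,1]`
#' @param mask binary H x W pseudo segmentation mask
#' @param source_variant index of the winning variant
#' @param source_model `"main"` or `"aux"`
#' @return an object of class `pseudo_label`
#' @export
pseudo_label <- function(boxes, class_ids, class_probs, conf, mask,
                         source_variant = NA_integer_,
                         source_model = c("main", "aux")) {
  source_model <- match.arg(source_model)
  stopifnot(all(conf >= 0), all(conf <= 1))
  structure(list(boxes = matrix(as.numeric(boxes), ncol = 4L),
                 class_ids = as.integer(class_ids),
                 class_probs = matrix(as.numeric(class_probs),
                                      nrow = length(class_ids)),
                 conf = as.numeric(conf), mask = mask,
                 source_variant = as.integer(source_variant),
                 source_model = source_model),
            class = "pseudo_label")
}

#' Select the highest-confidence pseudo-label across variants and models
#'
#' Scans every (variant, model) result: main-branch results score by
#' [image_confidence()], auxiliary results by the mean pixel decision margin.
#' The winning variant's detections become the box/class/confidence
#' pseudo-labels and its mask, binarized at 0.5, becomes the segmentation
#' pseudo-label. Ties break toward the lowest variant index, main model
#' before aux.
#'
#' @param variant_results list of per-variant results, each a list with
#'   `detections` and `mask`
#' @return a [pseudo_label()]
#' @export
select_pseudo_label <- function(variant_results) {
  if (!length(variant_results)) stop("no variant results to select from")
  best <- -Inf; best_v <- 1L; best_m <- "main"
  for (v in seq_along(variant_results)) {
    for (m in c("main", "aux")) {
      sc <- if (m == "main") {
        image_confidence(variant_results[[v]]$detections)
      } else {
        mask_confidence(variant_results[[v]]$mask)
      }
      if (sc > best) {
        best <- sc; best_v <- v; best_m <- m
      }
    }
  }
  det <- variant_results[[best_v]]$detections
  pseudo_label(det$boxes, detection_classes(det), det$class_probs,
               det$confidence,
               (variant_results[[best_v]]$mask >= 0.5) * 1,
               source_variant = best_v - 1L, source_model = best_m)
}

# ---- pseudo-label losses (plain-numeric surface) ---------------------------

#' Main-branch test-time loss against a pseudo-label
#'
#' Cross-entropy of class probabilities against the pseudo-class one-hots
#' (matched pairs), plus the sum of squared differences of the four box
#' coordinates normalized by the image size, plus binary cross-entropy of
#' objectness against the pseudo-confidence binarized at 0.5 (all
#' predictions). All three terms are unnormalized sums.
#'
#' @param pred a [detections()]
#' @param pl a [pseudo_label()]
#' @param image_size normalizing size for box coordinates (default 1: boxes
#'   already normalized)
#' @param iou_threshold matching threshold
#' @return scalar loss
#' @export
tta_main_loss <- function(pred, pl, image_size = 1, iou_threshold = 0.5) {
  mt <- match_boxes(pred$boxes, pl$boxes, iou_threshold)
  l_cls <- 0; l_loc <- 0
  if (nrow(mt$pairs) > 0) {
    for (r in seq_len(nrow(mt$pairs))) {
      i <- mt$pairs[r, 1]; j <- mt$pairs[r, 2]
      p <- pmin(pmax(pred$class_probs[i, pl$class_ids[j] + 1L], BCE_EPS),
                1 - BCE_EPS)
      l_cls <- l_cls - log(p)
      l_loc <- l_loc +
        sum(((pred$boxes[i, ] - pl$boxes[j, ]) / image_size)^2)
    }
  }
  l_conf <- 0
  np <- nrow(pred$boxes)
  if (np > 0) {
    y <- numeric(np)
    if (nrow(mt$pairs) > 0) {
      y[mt$pairs[, 1]] <- as.numeric(pl$conf[mt$pairs[, 2]] >= 0.5)
    }
    p <- pmin(pmax(pred$confidence, BCE_EPS), 1 - BCE_EPS)
    l_conf <- -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  l_cls + l_loc + l_conf
}

#' Auxiliary-branch test-time loss against a pseudo-mask
#'
#' Mean over pixels of the squared difference between the predicted mask
#' probabilities and the binary pseudo-mask (the raw sum normalized by
#' `H * W` so the loss weight is resolution-independent).
#'
#' @param mask_probs H x W probability matrix
#' @param pseudo_mask H x W binary matrix
#' @return scalar loss
#' @export
tta_aux_loss <- function(mask_probs, pseudo_mask) {
  if (!all(dim(mask_probs) == dim(pseudo_mask))) stop("shape mismatch")
  mean((mask_probs - pseudo_mask)^2)
}

# ---- graph versions --------------------------------------------------------

tta_main_loss_graph <- function(det_node, pl, model) {
  G <- model$grid; S <- model$image_size; K <- model$num_classes
  asg <- assign_cells(pl$boxes, G, S)
  npos <- nrow(asg)
  # objectness over all cells (unnormalized sum)
  conf_p <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(
    rep(seq_len(G), G), rep(seq_len(G), each = G), 5L, G)), pestshift_conf_slope()))
  y_conf <- numeric(G * G)
  if (npos > 0) {
    y_conf[asg$row + (asg$col - 1L) * G] <-
      as.numeric(pl$conf[asg$idx] >= 0.5)
  }
  loss <- bce_sum_graph(conf_p, y_conf)
  if (npos == 0) return(loss)
  # cross-entropy against pseudo-class one-hots: only positive-class terms
  cls_ch <- 5L + pl$class_ids[asg$idx] + 1L
  cls_p <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col,
                                                         cls_ch, G)),
                             pestshift_cls_slope()))
  loss <- ag_add(loss, ag_neg(ag_sum(ag_log(ag_clamp(cls_p, BCE_EPS, 1)))))
  # squared differences of normalized box coordinates
  bs <- pestshift_box_slope()
  tx <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 1L, G)), bs))
  ty <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 2L, G)), bs))
  tw <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 3L, G)), bs))
  th <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 4L, G)), bs))
  cx <- ag_mul(ag_add(tx, asg$col - 1), 1 / G)
  cy <- ag_mul(ag_add(ty, asg$row - 1), 1 / G)
  x1 <- ag_sub(cx, ag_mul(tw, 0.5)); x2 <- ag_add(cx, ag_mul(tw, 0.5))
  y1 <- ag_sub(cy, ag_mul(th, 0.5)); y2 <- ag_add(cy, ag_mul(th, 0.5))
  tb <- pl$boxes[asg$idx, , drop = FALSE] / S
  sq <- function(a) ag_mul(a, a)
  l_loc <- ag_add(ag_add(sq(ag_sub(x1, tb[, 1])), sq(ag_sub(y1, tb[, 2]))),
                  ag_add(sq(ag_sub(x2, tb[, 3])), sq(ag_sub(y2, tb[, 4]))))
  ag_add(loss, ag_sum(l_loc))
}

tta_aux_loss_graph <- function(seg_node, pseudo_mask) {
  diff <- ag_sub(seg_node, array(pseudo_mask, dim(ag_value(seg_node))))
  ag_mean(ag_mul(diff, diff))
}

#' Total test-time loss of a model against a fixed pseudo-label
#'
#' Recomputes `L_main + lambda * L_aux` for the original image's current
#' predictions; used both inside [tta_step()] and to verify that an
#' adaptation step descends.
#'
#' @param model a [dual_branch_model()]
#' @param image original H x W x 3 image
#' @param pl a [pseudo_label()]
#' @param cfg a [tta_config()]
#' @return scalar loss
#' @export
tta_total_loss <- function(model, image, pl, cfg) {
  out <- model_forward_graph(model, wrap_model(model), image)
  l_main <- tta_main_loss_graph(out$det, pl, model)
  l_aux <- tta_aux_loss_graph(out$seg, pl$mask)
  ag_value(ag_add(l_main, ag_mul(l_aux, cfg$lambda)))
}

#' One continual test-time adaptation step on a single image
#'
#' Generates the photometric variants, forward-fuses each through both
#' branches, selects the highest-confidence pseudo-label, computes the total
#' pseudo-label loss on the ORIGINAL image's predictions, and updates the
#' main and auxiliary branches (and the gates only when `cfg$adapt_dag`).
#' Returns the post-update prediction on the original image.
#'
#' @param model a [dual_branch_model()]
#' @param image H x W x 3 array in `[0,1]`
#' @param cfg a [tta_config()]
#' @return list with the updated `model`, `detections`, `mask`,
#'   `pseudo_label` and the pre-update `loss`
#' @export
tta_step <- function(model, image, cfg) {
  variants <- generate_variants(image, cfg)
  results <- lapply(variants, function(v) {
    predict_scene(model, v, conf_thresh = cfg$conf_thresh,
                  nms_iou = cfg$nms_iou)
  })
  pl <- select_pseudo_label(results)
  wrapped <- wrap_model(model)
  out <- model_forward_graph(model, wrapped, image)
  l_main <- tta_main_loss_graph(out$det, pl, model)
  l_aux <- tta_aux_loss_graph(out$seg, pl$mask)
  total <- ag_add(l_main, ag_mul(l_aux, cfg$lambda))
  loss_v <- ag_value(total)
  if (is.finite(loss_v) && cfg$eta > 0) {
    ag_backward(total)
    g_main <- ag_grads(wrapped$main)
    g_aux <- ag_grads(wrapped$aux)
    if (params_finite(g_main) && params_finite(g_aux)) {
      model$main_backbone <- sgd_step(model$main_backbone, g_main$backbone,
                                      cfg$eta)
      model$main_head <- sgd_step(model$main_head, g_main$head, cfg$eta)
      model$aux_backbone <- sgd_step(model$aux_backbone, g_aux$backbone,
                                     cfg$eta)
      model$aux_head <- sgd_step(model$aux_head, g_aux$head, cfg$eta)
      if (cfg$adapt_dag) {
        for (k in seq_along(model$gates)) {
          gk <- ag_grads(wrapped$gates[[k]])
          cls <- class(model$gates[[k]]$am)
          model$gates[[k]]$am <- structure(
            sgd_step(unclass(model$gates[[k]]$am), gk$am, cfg$eta),
            class = cls)
          model$gates[[k]]$ma <- structure(
            sgd_step(unclass(model$gates[[k]]$ma), gk$ma, cfg$eta),
            class = cls)
        }
      }
    }
  }
  pred <- predict_scene(model, image, conf_thresh = cfg$conf_thresh,
                        nms_iou = cfg$nms_iou)
  list(model = model, detections = pred$detections, mask = pred$mask,
       pseudo_label = pl, loss = loss_v)
}

#' Continually adapt a model along a domain stream
#'
#' Processes the domains in order WITHOUT resetting weights between them,
#' adapting on every image and evaluating the post-update predictions against
#' the ground truth of each domain.
#'
#' @param model a trained [dual_branch_model()]
#' @param stream list of domain blocks, each a list with `domain` (a label)
#'   and `scenes` (list of [labeled_scene()])
#' @param cfg a [tta_config()]; `eta = 0` reduces to plain frozen evaluation
#' @return a `domain_sequence_result`: tibble of per-domain metrics with the
#'   running model attached (see [domain_sequence_result()])
#' @export
continual_adapt <- function(model, stream, cfg) {
  stopifnot(length(stream) >= 1)
  rows <- vector("list", length(stream))
  for (b in seq_along(stream)) {
    blk <- stream[[b]]
    preds <- vector("list", length(blk$scenes))
    for (i in seq_along(blk$scenes)) {
      if (cfg$eta > 0) {
        res <- tta_step(model, blk$scenes[[i]]$image, cfg)
        model <- res$model
        preds[[i]] <- res$detections
      } else {
        preds[[i]] <- predict_scene(model, blk$scenes[[i]]$image,
                                    conf_thresh = cfg$conf_thresh,
                                    nms_iou = cfg$nms_iou)$detections
      }
    }
    ms <- metric_set(preds, blk$scenes, conf_thresh = cfg$conf_thresh)
    rows[[b]] <- dplyr::mutate(ms, domain = blk$domain, .before = 1)
  }
  domain_sequence_result(dplyr::bind_rows(rows), model = model)
}
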