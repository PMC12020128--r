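# Dual-branch multi-task model: a detection main branch and a segmentation
# auxiliary branch with identical toy convolutional backbones, fused after
# every stage by gated cross-task message passing. The detection head is a
# minimal anchor-free design: each cell of the final feature grid predicts an
# objectness logit, K class logits and a box (sigmoid offsets within the cell
# plus sigmoid width/height as fractions of the image). The segmentation head
# is a 1x1 convolution to a foreground probability map, upsampled back to
# image resolution.

#' Toy convolutional backbone
#'
#' A stack of stages, each `3x3 conv -> ReLU -> 2x2 average pool`, with
#' deterministic seeded initialization. Stands in for a production detection
#' backbone so that the fusion and adaptation machinery can be exercised on a
#' CPU in seconds.
#'
#' @param stages number of stages (>= 2)
#' @param channels integer vector of output channels per stage
#' @param seed integer seed
#' @param in_channels channels of the input image (3 for RGB)
#' @return list of per-stage parameter lists (`w`, `b`)
#' @export
make_toy_backbone <- function(stages, channels, seed = 1L, in_channels = 3L) {
  stopifnot(stages >= 2, length(channels) == stages)
  with_seed(derive_seed(seed, "backbone-init"), {
    cin <- in_channels
    lapply(seq_len(stages), function(k) {
      w <- matrix(stats::rnorm(9 * cin * channels[k], 0,
                               sqrt(2 / (9 * cin))), 9 * cin, channels[k])
      p <- list(w = w, b = numeric(channels[k]))
      cin <<- channels[k]
      p
    })
  })
}

backbone_stage_forward <- function(x, sp) {
  ag_avgpool2(ag_relu(ag_conv3x3(x, sp$w, sp$b)))
}

# slopes on the detection-head logits: the objectness and box signals must
# traverse several logits within short training budgets while their loss
# terms are grid-averaged or gated through sigmoids; steeper activations
# compensate without touching the losses themselves
CONF_SLOPE <- 4
BOX_SLOPE <- 1
CLS_SLOPE <- 1

# constant coordinate channels in [-1, 1], cached per grid size
coord_grid <- function(G) {
  key <- paste0("coord_", G)
  cg <- .ag$conv_plans[[key]]
  if (is.null(cg)) {
    y <- matrix(rep(seq(-1, 1, length.out = G), G), G, G)
    x <- t(y)
    cg <- array(c(y, x), c(G, G, 2L))
    .ag$conv_plans[[key]] <- cg
  }
  cg
}

#' Construct a dual-branch detection + segmentation model
#'
#' @param num_classes number of pest classes K
#' @param image_size input image side length (square images)
#' @param stages number of backbone stages (each halves the resolution)
#' @param channels per-stage channel counts (shared by both branches)
#' @param head_hidden hidden channels of the detection head
#' @param seed integer seed for all parameter initialization
#' @return an object of class `dual_branch_model`
#' @export
dual_branch_model <- function(num_classes, image_size = 64L, stages = 2L,
                              channels = c(12L, 16L), head_hidden = 16L,
                              seed = 1L) {
  stopifnot(image_size %% (2^stages) == 0)
  grid <- image_size / 2^stages
  C <- channels[stages]
  nout <- 5L + num_classes
  heads <- with_seed(derive_seed(seed, "head-init"), list(
    # detection head sees two extra constant coordinate channels so cells can
    # specialize by position (helps precise box regression on small grids)
    main = list(
      w1 = matrix(stats::rnorm(9 * (C + 2) * head_hidden, 0,
                               sqrt(2 / (9 * (C + 2)))),
                  9 * (C + 2), head_hidden),
      b1 = numeric(head_hidden),
      w2 = matrix(stats::rnorm(head_hidden * nout, 0, 0.1), head_hidden, nout),
      # objectness bias starts at a background prior so the many negative
      # cells are near-satisfied from step one and positives dominate the
      # confidence gradient
      b2 = c(numeric(4L), -2 / CONF_SLOPE, numeric(num_classes))
    ),
    aux = list(
      # decoder: fused grid features upsampled to image resolution and
      # combined with a full-resolution image stem (skip) before the final
      # prediction conv -- mask boundaries need sub-grid detail
      w_up = matrix(stats::rnorm(C * 8, 0, sqrt(2 / C)), C, 8),
      b_up = numeric(8),
      w_stem = matrix(stats::rnorm(9 * 3 * 8, 0, sqrt(2 / 27)), 9 * 3, 8),
      b_stem = numeric(8),
      w1 = matrix(stats::rnorm(9 * 8 * 8, 0, sqrt(2 / 72)), 9 * 8, 8),
      b1 = numeric(8),
      w2 = matrix(stats::rnorm(8, 0, 0.2), 8, 1),
      b2 = numeric(1)
    )
  ))
  gates <- lapply(seq_len(stages), function(k) {
    list(am = gate_params(channels[k], seed = derive_seed(seed, "gate-am", k)),
         ma = gate_params(channels[k], seed = derive_seed(seed, "gate-ma", k)))
  })
  structure(list(
    main_backbone = make_toy_backbone(stages, channels,
                                      derive_seed(seed, "main")),
    aux_backbone = make_toy_backbone(stages, channels,
                                     derive_seed(seed, "aux")),
    gates = gates,
    main_head = heads$main,
    aux_head = heads$aux,
    num_classes = as.integer(num_classes),
    image_size = as.integer(image_size),
    stages = as.integer(stages),
    channels = as.integer(channels),
    grid = as.integer(grid)
  ), class = "dual_branch_model")
}

#' Zero and freeze all fusion transforms of a model
#'
#' With every gate's transform zeroed, each fusion point is an exact no-op and
#' the dual-branch forward equals two independent single-branch forwards.
#' @param model a [dual_branch_model()]
#' @return the model with all gate transforms zeroed
#' @export
zero_fusion <- function(model) {
  model$gates <- lapply(model$gates, function(g) {
    list(am = gate_zero_transform(g$am), ma = gate_zero_transform(g$ma))
  })
  model
}

# wrap all parameter groups as autodiff leaves
wrap_model <- function(model) {
  list(
    main = list(backbone = ag_wrap(model$main_backbone),
                head = ag_wrap(model$main_head)),
    aux = list(backbone = ag_wrap(model$aux_backbone),
               head = ag_wrap(model$aux_head)),
    gates = lapply(model$gates, function(g) {
      list(am = ag_wrap(unclass(g$am)), ma = ag_wrap(unclass(g$ma)))
    })
  )
}

# graph forward through both branches with bidirectional fusion after every
# stage; returns nodes for the detection map (G x G x (5+K)) and the mask
# probability map (H x W)
model_forward_graph <- function(model, wrapped, image, fused = TRUE) {
  x_main <- as_node(image)
  x_main0 <- x_main  # image-resolution input reused by the mask decoder skip
  x_aux <- x_main
  for (k in seq_len(model$stages)) {
    f_main <- backbone_stage_forward(x_main, wrapped$main$backbone[[k]])
    f_aux <- backbone_stage_forward(x_aux, wrapped$aux$backbone[[k]])
    if (!all(is.finite(ag_value(f_main))) ||
        !all(is.finite(ag_value(f_aux)))) {
      stop("non-finite activations at stage ", k)
    }
    if (fused) {
      # both directions read the PRE-fusion features (simultaneous update)
      x_main <- gate_fuse_graph(f_aux, f_main, wrapped$gates[[k]]$am)
      x_aux <- gate_fuse_graph(f_main, f_aux, wrapped$gates[[k]]$ma)
    } else {
      x_main <- f_main
      x_aux <- f_aux
    }
  }
  hp <- wrapped$main$head
  x_head <- ag_append_chan(x_main, coord_grid(model$grid))
  det <- ag_conv1x1(ag_relu(ag_conv3x3(x_head, hp$w1, hp$b1)), hp$w2, hp$b2)
  ap <- wrapped$aux$head
  up <- ag_conv1x1(x_aux, ap$w_up, ap$b_up)
  for (k in seq_len(model$stages)) up <- ag_upsample2(up)
  stem <- ag_conv3x3(x_main0, ap$w_stem, ap$b_stem)
  h <- ag_relu(ag_add(up, stem))
  # mask logits are tanh-bounded to +/-8: an all-background collapse is a
  # saturated dead zone of the Dice loss, and the bound keeps it escapable
  zseg <- ag_conv1x1(ag_relu(ag_conv3x3(h, ap$w1, ap$b1)), ap$w2, ap$b2)
  seg <- ag_sigmoid(ag_mul(ag_tanh(ag_mul(zseg, 1 / 8)), 8))
  list(det = det, seg = seg)
}

# ---- detections ------------------------------------------------------------

#' Construct a detection set
#'
#' @param boxes n x 4 pixel box matrix (`xmin, ymin, xmax, ymax`)
#' @param class_probs n x K matrix of per-class probabilities
#' @param confidence length-n vector of objectness scores in `[0,1]`
#' @return an object of class `detections`
#' @export
detections <- function(boxes, class_probs, confidence) {
  boxes <- matrix(as.numeric(boxes), ncol = 4L)
  class_probs <- matrix(as.numeric(class_probs), nrow = nrow(boxes))
  stopifnot(length(confidence) == nrow(boxes),
            all(confidence >= 0), all(confidence <= 1),
            all(class_probs >= 0), all(class_probs <= 1))
  structure(list(boxes = boxes, class_probs = class_probs,
                 confidence = as.numeric(confidence)),
            class = "detections")
}

detections_empty <- function(num_classes) {
  detections(matrix(numeric(0), 0L, 4L),
             matrix(numeric(0), 0L, num_classes), numeric(0))
}

detections_subset <- function(det, idx) {
  detections(det$boxes[idx, , drop = FALSE],
             det$class_probs[idx, , drop = FALSE],
             det$confidence[idx])
}

#' Predicted class ids (0-based) of a detection set
#' @param det a [detections()]
#' @return integer vector
#' @export
detection_classes <- function(det) {
  if (nrow(det$boxes) == 0L) return(integer(0))
  max.col(det$class_probs, ties.method = "first") - 1L
}

# ---- box geometry ----------------------------------------------------------

#' Intersection over union of two pixel boxes
#'
#' Boxes are half-open `(xmin, ymin, xmax, ymax)`; degenerate (zero-area)
#' boxes give 0.
#' @param box_a,box_b numeric length-4 vectors
#' @return scalar in `[0,1]`
#' @export
iou <- function(box_a, box_b) {
  aa <- max(0, box_a[3] - box_a[1]) * max(0, box_a[4] - box_a[2])
  ab <- max(0, box_b[3] - box_b[1]) * max(0, box_b[4] - box_b[2])
  if (aa <= 0 || ab <= 0) return(0)
  iw <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  ih <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- iw * ih
  inter / (aa + ab - inter)
}

iou_matrix <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(matrix(0, nrow(A), nrow(B)))
  outer(seq_len(nrow(A)), seq_len(nrow(B)),
        Vectorize(function(i, j) iou(A[i, ], B[j, ])))
}

#' Greedy one-to-one box matching
#'
#' Repeatedly pairs the highest-IoU (prediction, truth) couple above the
#' threshold; ties break toward the lower prediction index, then the lower
#' truth index. Unmatched predictions are confidence negatives; unmatched
#' truths are misses.
#'
#' @param pred_boxes m x 4 matrix of predicted pixel boxes
#' @param true_boxes n x 4 matrix of ground-truth pixel boxes
#' @param iou_threshold minimum IoU for a valid pair
#' @return list with `pairs` (matrix of columns `pred`, `truth`, `iou`),
#'   `unmatched_pred`, `unmatched_truth`
#' @export
match_boxes <- function(pred_boxes, true_boxes, iou_threshold = 0.5) {
  pred_boxes <- matrix(as.numeric(pred_boxes), ncol = 4L)
  true_boxes <- matrix(as.numeric(true_boxes), ncol = 4L)
  m <- nrow(pred_boxes); n <- nrow(true_boxes)
  pairs <- matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("pred", "truth", "iou")))
  if (m > 0 && n > 0) {
    M <- iou_matrix(pred_boxes, true_boxes)
    repeat {
      best <- max(M)
      if (best < iou_threshold || best <= 0) break
      hit <- which(M == best, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      pairs <- rbind(pairs, c(hit[1], hit[2], best))
      M[hit[1], ] <- -1
      M[, hit[2]] <- -1
    }
  }
  list(pairs = pairs,
       unmatched_pred = setdiff(seq_len(m), pairs[, 1]),
       unmatched_truth = setdiff(seq_len(n), pairs[, 2]))
}

# ---- losses (plain-numeric surface) ----------------------------------------

#' Detection training loss
#'
#' Class binary cross-entropy over matched positives, plus `1 - mean IoU` of
#' the matched pairs (1 when nothing matches), plus objectness binary
#' cross-entropy over all predictions (target 1 for matched, 0 otherwise).
#'
#' @param pred a [detections()]
#' @param target a [labeled_scene()]
#' @param iou_threshold matching threshold
#' @return scalar loss
#' @export
detection_train_loss <- function(pred, target, iou_threshold = 0.5) {
  mt <- match_boxes(pred$boxes, target$boxes, iou_threshold)
  np <- nrow(pred$boxes)
  K <- ncol(pred$class_probs)
  cls_term <- 0
  iou_term <- 1
  if (nrow(mt$pairs) > 0) {
    n_cls <- nrow(mt$pairs)
    tot <- 0
    for (r in seq_len(n_cls)) {
      p <- pmin(pmax(pred$class_probs[mt$pairs[r, 1], ], BCE_EPS), 1 - BCE_EPS)
      y <- as.numeric(seq_len(K) == target$class_ids[mt$pairs[r, 2]] + 1L)
      tot <- tot - sum(y * log(p) + (1 - y) * log(1 - p))
    }
    cls_term <- tot / n_cls
    iou_term <- 1 - mean(mt$pairs[, 3])
  }
  conf_term <- 0
  if (np > 0) {
    yc <- as.numeric(seq_len(np) %in% mt$pairs[, 1])
    pc <- pmin(pmax(pred$confidence, BCE_EPS), 1 - BCE_EPS)
    conf_term <- -mean(yc * log(pc) + (1 - yc) * log(1 - pc))
  }
  cls_term + iou_term + conf_term
}

#' Dice segmentation loss
#'
#' `1 - 2 sum(p t) / (sum(p^2) + sum(t^2))`; returns 0 when both prediction
#' and target are identically zero.
#' @param p H x W probability matrix (values in `[0,1]`)
#' @param t H x W binary matrix
#' @return scalar loss in `[0,1]`
#' @export
dice_loss <- function(p, t) {
  if (!all(dim(p) == dim(t))) stop("shape mismatch")
  denom <- sum(p^2) + sum(t^2)
  if (denom == 0) return(0)
  1 - 2 * sum(p * t) / denom
}

#' Combined dual-task training loss
#'
#' @param l_main detection branch loss
#' @param l_aux segmentation branch loss
#' @param lambda_train weight of the auxiliary loss
#' @return `l_main + lambda_train * l_aux`
#' @export
total_train_loss <- function(l_main, l_aux, lambda_train = 1) {
  stopifnot(is.finite(l_main), is.finite(l_aux))
  l_main + lambda_train * l_aux
}

# ---- decoding --------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# raw per-cell decode of a detection map value (no thresholding)
decode_cells <- function(det_map, image_size, num_classes) {
  G <- dim(det_map)[1]
  K <- num_classes
  tx <- sigmoid(BOX_SLOPE * det_map[, , 1])
  ty <- sigmoid(BOX_SLOPE * det_map[, , 2])
  tw <- sigmoid(BOX_SLOPE * det_map[, , 3])
  th <- sigmoid(BOX_SLOPE * det_map[, , 4])
  conf <- sigmoid(CONF_SLOPE * det_map[, , 5])
  cols <- matrix(rep(seq_len(G), each = G), G, G)  # cell col per entry
  rows <- matrix(rep(seq_len(G), G), G, G)
  cx <- (cols - 1 + tx) / G * image_size
  cy <- (rows - 1 + ty) / G * image_size
  w <- tw * image_size; h <- th * image_size
  boxes <- cbind(pmax(as.numeric(cx - w / 2), 0),
                 pmax(as.numeric(cy - h / 2), 0),
                 pmin(as.numeric(cx + w / 2), image_size),
                 pmin(as.numeric(cy + h / 2), image_size))
  probs <- matrix(sigmoid(CLS_SLOPE * det_map[, , 5 + seq_len(K)]), G * G, K)
  detections(boxes, probs, as.numeric(conf))
}

#' Non-maximum suppression
#'
#' Standard greedy NMS: keep the highest-confidence box, drop boxes
#' overlapping it above `nms_iou`, repeat.
#' @param det a [detections()]
#' @param nms_iou overlap threshold (default 0.5)
#' @param conf_thresh minimum confidence (default 0.25)
#' @return filtered [detections()]
#' @export
nms_filter <- function(det, nms_iou = 0.5, conf_thresh = 0.25) {
  keep0 <- which(det$confidence >= conf_thresh)
  if (!length(keep0)) return(detections_subset(det, integer(0)))
  det <- detections_subset(det, keep0)
  ord <- order(det$confidence, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    ious <- vapply(rest, function(j) iou(det$boxes[i, ], det$boxes[j, ]),
                   numeric(1))
    ord <- rest[ious <= nms_iou]
  }
  detections_subset(det, sort(keep))
}

#' Fused forward pass of the dual-branch model
#'
#' Runs both backbones stage by stage with bidirectional gated fusion after
#' each stage; the detection head consumes the fused main features and the
#' segmentation head the fused auxiliary features.
#'
#' @param model a [dual_branch_model()]
#' @param image H x W x 3 array, `H == W == model$image_size`
#' @param fused apply gated fusion (`FALSE` runs the branches independently)
#' @param nms apply confidence filtering and NMS to the decoded detections
#' @param conf_thresh,nms_iou NMS operating point
#' @return list with `detections` (a [detections()]), `mask` (H x W
#'   probability matrix), and `raw` (the undecoded per-cell detection map)
#' @export
forward_fused <- function(model, image, fused = TRUE, nms = TRUE,
                          conf_thresh = 0.25, nms_iou = 0.5) {
  stopifnot(all(dim(image)[1:2] == model$image_size))
  out <- model_forward_graph(model, wrap_model(model), image, fused = fused)
  det_map <- ag_value(out$det)
  mask <- ag_value(out$seg)[, , 1]
  det <- decode_cells(det_map, model$image_size, model$num_classes)
  if (nms) det <- nms_filter(det, nms_iou, conf_thresh)
  list(detections = det, mask = mask, raw = det_map)
}

# ---- graph losses (training) -----------------------------------------------

# assign each target box to the grid cell containing its center; at most one
# box per cell (first wins)
assign_cells <- function(boxes, grid, image_size) {
  if (nrow(boxes) == 0L) {
    return(data.frame(row = integer(0), col = integer(0), idx = integer(0)))
  }
  cx <- (boxes[, 1] + boxes[, 3]) / 2
  cy <- (boxes[, 2] + boxes[, 4]) / 2
  col <- pmin(pmax(floor(cx / image_size * grid), 0), grid - 1) + 1L
  row <- pmin(pmax(floor(cy / image_size * grid), 0), grid - 1) + 1L
  df <- data.frame(row = row, col = col, idx = seq_len(nrow(boxes)))
  df[!duplicated(df[, c("row", "col")]), , drop = FALSE]
}

flat_idx <- function(row, col, ch, G) row + (col - 1L) * G + (ch - 1L) * G * G

# graph BCE of a probability-node vector against constant targets (sum)
bce_sum_graph <- function(p, y) {
  p <- ag_clamp(p, BCE_EPS, 1 - BCE_EPS)
  ag_neg(ag_sum(ag_add(ag_mul(y, ag_log(p)),
                       ag_mul(1 - y, ag_log(ag_sub(1, p))))))
}

# detection training loss on the graph (center-cell assignment)
det_loss_graph <- function(det_node, scene, model) {
  G <- model$grid; S <- model$image_size; K <- model$num_classes
  asg <- assign_cells(scene$boxes, G, S)
  npos <- nrow(asg)
  # objectness over all cells
  conf_p <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(
    rep(seq_len(G), G), rep(seq_len(G), each = G), 5L, G)), CONF_SLOPE))
  y_conf <- numeric(G * G)
  if (npos > 0) {
    y_conf[asg$row + (asg$col - 1L) * G] <- 1
  }
  loss <- ag_mul(bce_sum_graph(conf_p, y_conf), 1 / (G * G))
  if (npos == 0) return(ag_add(loss, 1))  # worst-case IoU term
  # class BCE at positive cells
  cls_idx <- as.integer(outer(flat_idx(asg$row, asg$col, 5L, G), G * G *
                                seq_len(K), "+"))
  cls_p <- ag_sigmoid(ag_mul(ag_index(det_node, cls_idx), CLS_SLOPE))
  y_cls <- as.numeric(outer(scene$class_ids[asg$idx] + 1L, seq_len(K), "=="))
  loss <- ag_add(loss, ag_mul(bce_sum_graph(cls_p, y_cls), 1 / npos))
  # box IoU at positive cells
  tx <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 1L, G)), BOX_SLOPE))
  ty <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 2L, G)), BOX_SLOPE))
  tw <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 3L, G)), BOX_SLOPE))
  th <- ag_sigmoid(ag_mul(ag_index(det_node, flat_idx(asg$row, asg$col, 4L, G)), BOX_SLOPE))
  cx <- ag_mul(ag_add(tx, asg$col - 1), S / G)
  cy <- ag_mul(ag_add(ty, asg$row - 1), S / G)
  w <- ag_mul(tw, S); h <- ag_mul(th, S)
  x1 <- ag_sub(cx, ag_mul(w, 0.5)); x2 <- ag_add(cx, ag_mul(w, 0.5))
  y1 <- ag_sub(cy, ag_mul(h, 0.5)); y2 <- ag_add(cy, ag_mul(h, 0.5))
  tb <- scene$boxes[asg$idx, , drop = FALSE]
  iw <- ag_pmax(ag_sub(ag_pmin(x2, tb[, 3]), ag_pmax(x1, tb[, 1])), 0)
  ih <- ag_pmax(ag_sub(ag_pmin(y2, tb[, 4]), ag_pmax(y1, tb[, 2])), 0)
  inter <- ag_mul(iw, ih)
  area_p <- ag_mul(ag_sub(x2, x1), ag_sub(y2, y1))
  area_t <- (tb[, 3] - tb[, 1]) * (tb[, 4] - tb[, 2])
  iou_v <- ag_div(inter, ag_sub(ag_add(area_p, area_t), inter))
  ag_add(loss, ag_sub(1, ag_mean(iou_v)))
}

# Dice loss on the graph; seg_node is H x W x 1
dice_loss_graph <- function(seg_node, target_mask) {
  t <- as.numeric(target_mask > 0)
  p <- seg_node
  num <- ag_mul(ag_sum(ag_mul(p, array(t, dim(ag_value(p))))), 2)
  den <- ag_add(ag_sum(ag_mul(p, p)), sum(t^2))
  if (ag_value(den) == 0) return(new_ag_node(0))
  ag_sub(1, ag_div(num, den))
}

# ---- training --------------------------------------------------------------

#' Training configuration for the dual-branch model
#'
#' Defaults follow the reference training recipe: 50 epochs, input size 416,
#' batch size 32, learning rate interpolated from 0.05 to 0.1, gate module
#' learning rate 0.02, auxiliary-loss weight 1. The `schedule` switch selects
#' the as-printed increasing linear ramp or a conventional decreasing cosine.
#'
#' @param epochs training epochs
#' @param image_size input image side length
#' @param batch_size scenes per step
#' @param lr_init,lr_final learning-rate endpoints for both branches
#' @param dag_lr learning rate of the gate parameters
#' @param lambda_train auxiliary-loss weight
#' @param schedule `"linear"` (as printed, increasing) or `"cosine"`
#' @param momentum heavy-ball momentum coefficient of the shared optimizer
#'   (0 gives plain gradient descent)
#' @param clip_norm global gradient-norm ceiling per step (`Inf` disables);
#'   guards the shared optimizer against loss spikes
#' @param seed integer seed
#' @return an object of class `train_config`
#' @export
train_config <- function(epochs = 50L, image_size = 416L, batch_size = 32L,
                         lr_init = 0.05, lr_final = 0.1, dag_lr = 0.02,
                         lambda_train = 1, schedule = c("linear", "cosine"),
                         momentum = 0.9, clip_norm = 4, seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(lr_init > 0, lr_final > 0, dag_lr > 0, epochs >= 1,
            momentum >= 0, momentum < 1, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_final = lr_final, dag_lr = dag_lr,
                 lambda_train = lambda_train, schedule = schedule,
                 momentum = momentum, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# optimizer state: momentum velocities for every parameter group
init_opt_state <- function(model) {
  list(main_backbone = tree_zero(model$main_backbone),
       main_head = tree_zero(model$main_head),
       aux_backbone = tree_zero(model$aux_backbone),
       aux_head = tree_zero(model$aux_head),
       gates = lapply(model$gates, function(g) {
         list(am = tree_zero(unclass(g$am)), ma = tree_zero(unclass(g$ma)))
       }))
}

lr_at <- function(cfg, frac) {
  switch(cfg$schedule,
    linear = cfg$lr_init + (cfg$lr_final - cfg$lr_init) * frac,
    cosine = cfg$lr_final + (cfg$lr_init - cfg$lr_final) *
      (1 + cos(pi * frac)) / 2)
}

#' One joint optimization step on a batch of scenes
#'
#' Builds the fused forward graph for every scene, computes
#' `L_main + lambda_train * L_aux` averaged over the batch, and updates the
#' main branch, auxiliary branch and gate parameters from the shared total
#' loss — the branch groups with `lr`, the gates with `cfg$dag_lr`.
#'
#' @param model a [dual_branch_model()]
#' @param batch list of [labeled_scene()]
#' @param cfg a [train_config()]
#' @param lr branch learning rate for this step
#' @param freeze_gates if `TRUE` the gate parameters are left untouched
#' @param fused run with gated fusion (`FALSE` trains the branches
#'   independently)
#' @param opt optimizer state from the previous step (`NULL` starts with zero
#'   momentum)
#' @return list with the updated `model`, the batch `loss` components, and
#'   the updated optimizer state `opt`
#' @export
train_step <- function(model, batch, cfg, lr = cfg$lr_init,
                       freeze_gates = FALSE, fused = TRUE, opt = NULL) {
  if (is.null(opt)) opt <- init_opt_state(model)
  wrapped <- wrap_model(model)
  total <- NULL
  l_det_v <- 0; l_seg_v <- 0
  for (sc in batch) {
    out <- model_forward_graph(model, wrapped, sc$image, fused = fused)
    l_det <- det_loss_graph(out$det, sc, model)
    l_seg <- dice_loss_graph(out$seg, sc$mask)
    l_tot <- ag_add(l_det, ag_mul(l_seg, cfg$lambda_train))
    l_det_v <- l_det_v + ag_value(l_det)
    l_seg_v <- l_seg_v + ag_value(l_seg)
    total <- if (is.null(total)) l_tot else ag_add(total, l_tot)
  }
  total <- ag_mul(total, 1 / length(batch))
  if (!is.finite(ag_value(total))) {
    warning("non-finite training loss; step skipped")
    return(list(model = model, loss = NA_real_,
                det_loss = NA_real_, seg_loss = NA_real_, opt = opt))
  }
  ag_backward(total)
  g_main <- ag_grads(wrapped$main)
  g_aux <- ag_grads(wrapped$aux)
  ok <- params_finite(g_main) && params_finite(g_aux)
  if (ok) {
    mu <- cfg$momentum
    clip <- cfg$clip_norm %||% Inf
    if (is.finite(clip)) {
      gn <- sqrt(tree_sq_norm(g_main) + tree_sq_norm(g_aux))
      if (gn > clip) {
        g_main <- tree_scale(g_main, clip / gn)
        g_aux <- tree_scale(g_aux, clip / gn)
      }
    }
    up <- momentum_step(model$main_backbone, g_main$backbone,
                        opt$main_backbone, lr, mu)
    model$main_backbone <- up$params; opt$main_backbone <- up$vel
    up <- momentum_step(model$main_head, g_main$head, opt$main_head, lr, mu)
    model$main_head <- up$params; opt$main_head <- up$vel
    up <- momentum_step(model$aux_backbone, g_aux$backbone,
                        opt$aux_backbone, lr, mu)
    model$aux_backbone <- up$params; opt$aux_backbone <- up$vel
    up <- momentum_step(model$aux_head, g_aux$head, opt$aux_head, lr, mu)
    model$aux_head <- up$params; opt$aux_head <- up$vel
    if (!freeze_gates) {
      for (k in seq_along(model$gates)) {
        gk <- ag_grads(wrapped$gates[[k]])
        if (is.finite(clip)) {
          gkn <- sqrt(tree_sq_norm(gk))
          if (gkn > clip) gk <- tree_scale(gk, clip / gkn)
        }
        cls_am <- class(model$gates[[k]]$am)
        up <- momentum_step(unclass(model$gates[[k]]$am), gk$am,
                            opt$gates[[k]]$am, cfg$dag_lr, mu)
        model$gates[[k]]$am <- structure(up$params, class = cls_am)
        opt$gates[[k]]$am <- up$vel
        up <- momentum_step(unclass(model$gates[[k]]$ma), gk$ma,
                            opt$gates[[k]]$ma, cfg$dag_lr, mu)
        model$gates[[k]]$ma <- structure(up$params, class = cls_am)
        opt$gates[[k]]$ma <- up$vel
      }
    }
  } else {
    warning("non-finite gradients; step skipped")
  }
  list(model = model, loss = ag_value(total),
       det_loss = l_det_v / length(batch), seg_loss = l_seg_v / length(batch),
       opt = opt)
}

#' Train the dual-branch model
#'
#' Iterates [train_step()] over seeded random batches, following the
#' configured learning-rate schedule.
#'
#' @param model a [dual_branch_model()]
#' @param scenes list of [labeled_scene()] (typically [combined_scenes()])
#' @param cfg a [train_config()]
#' @param steps total optimization steps (defaults to
#'   `epochs * ceiling(n / batch_size)`)
#' @param fused train with gated fusion
#' @return an object of class `dual_branch_fit` with elements `model`,
#'   `history` (a tibble of per-step losses) and `cfg`
#' @export
train_dual_branch <- function(model, scenes, cfg, steps = NULL, fused = TRUE) {
  n <- length(scenes)
  if (is.null(steps)) steps <- cfg$epochs * ceiling(n / cfg$batch_size)
  hist <- vector("list", steps)
  opt <- NULL
  for (s in seq_len(steps)) {
    lr <- lr_at(cfg, if (steps > 1) (s - 1) / (steps - 1) else 0)
    idx <- with_seed(derive_seed(cfg$seed, "batch", s), {
      sample.int(n, min(cfg$batch_size, n))
    })
    res <- train_step(model, scenes[idx], cfg, lr = lr, fused = fused,
                      opt = opt)
    model <- res$model
    opt <- res$opt
    hist[[s]] <- tibble::tibble(step = s, lr = lr, loss = res$loss,
                                det_loss = res$det_loss,
                                seg_loss = res$seg_loss)
  }
  structure(list(model = model, history = dplyr::bind_rows(hist), cfg = cfg),
            class = "dual_branch_fit")
}

#' Predict detections and a segmentation mask for one image
#'
#' @param model a [dual_branch_model()]
#' @param image H x W x 3 array
#' @param conf_thresh,nms_iou NMS operating point
#' @return list with `detections` and `mask`
#' @export
predict_scene <- function(model, image, conf_thresh = 0.25, nms_iou = 0.5) {
  out <- forward_fused(model, image, conf_thresh = conf_thresh,
                       nms_iou = nms_iou)
  out[c("detections", "mask")]
}

# internal accessors used by the adaptation losses
pestshift_conf_slope <- function() CONF_SLOPE
pestshift_box_slope <- function() BOX_SLOPE
pestshift_cls_slope <- function() CLS_SLOPE
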