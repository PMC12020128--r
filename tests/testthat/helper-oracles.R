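# Independent loop-oracle implementations of the losses and metrics,
# written naively (explicit loops) so they share no code with the
# package's vectorized paths. Used by the per-module tests and by the
# acceptance suite.

oracle_bce <- function(probs, labels) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  n <- nrow(probs); K <- ncol(probs)
  tot <- 0
  for (i in seq_len(n)) for (k in seq_len(K)) {
    p <- min(max(probs[i, k], 1e-7), 1 - 1e-7)
    tot <- tot + labels[i, k] * log(p) + (1 - labels[i, k]) * log(1 - p)
  }
  -tot / (n * K)
}

oracle_dif <- function(oris, augs) {
  tot <- 0
  for (i in seq_along(oris)) {
    d <- dim(oris[[i]])
    acc <- 0
    for (m in seq_len(d[1])) for (nn in seq_len(d[2])) for (c in seq_len(d[3])) {
      acc <- acc + (oris[[i]][m, nn, c] - augs[[i]][m, nn, c])^2
    }
    tot <- tot + acc / prod(d)
  }
  tot
}

oracle_bdf <- function(augs) {
  n <- length(augs)
  if (n < 2) return(0)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean((augs[[i]] - augs[[j]])^2)
  }
  2 / (n * (n - 1)) * tot
}

oracle_det_loss <- function(pred, target, iou_threshold = 0.5) {
  mt <- match_boxes(pred$boxes, target$boxes, iou_threshold)
  K <- ncol(pred$class_probs)
  cls <- 0; iouv <- numeric(0)
  if (nrow(mt$pairs)) {
    for (r in seq_len(nrow(mt$pairs))) {
      for (k in seq_len(K)) {
        y <- as.numeric(target$class_ids[mt$pairs[r, 2]] + 1L == k)
        p <- min(max(pred$class_probs[mt$pairs[r, 1], k], 1e-7), 1 - 1e-7)
        cls <- cls - (y * log(p) + (1 - y) * log(1 - p))
      }
      iouv <- c(iouv, iou(pred$boxes[mt$pairs[r, 1], ],
                          target$boxes[mt$pairs[r, 2], ]))
    }
    cls <- cls / nrow(mt$pairs)
  }
  conf <- 0
  for (i in seq_len(nrow(pred$boxes))) {
    y <- as.numeric(i %in% mt$pairs[, 1])
    p <- min(max(pred$confidence[i], 1e-7), 1 - 1e-7)
    conf <- conf - (y * log(p) + (1 - y) * log(1 - p))
  }
  if (nrow(pred$boxes)) conf <- conf / nrow(pred$boxes)
  cls + (if (nrow(mt$pairs)) 1 - mean(iouv) else 1) + conf
}

random_target <- function(n, K = 3L, seed = 1L) {
  withr::with_seed(seed, {
    b <- cbind(runif(n, 0, 30), runif(n, 0, 30), 0, 0)
    b[, 3] <- b[, 1] + runif(n, 8, 14)
    b[, 4] <- b[, 2] + runif(n, 8, 14)
    img <- array(0.5, c(48, 48, 3))
    labeled_scene(img, pmin(pmax(b, 0), 48), sample(K, n, TRUE) - 1L,
                  matrix(0L, 48, 48))
  })
}

oracle_tta_main <- function(pred, pl, S = 1) {
  mt <- match_boxes(pred$boxes, pl$boxes, 0.5)
  cls <- 0; loc <- 0
  for (r in seq_len(nrow(mt$pairs))) {
    i <- mt$pairs[r, 1]; j <- mt$pairs[r, 2]
    cls <- cls - log(min(max(pred$class_probs[i, pl$class_ids[j] + 1], 1e-7),
                         1 - 1e-7))
    for (k in 1:4) {
      loc <- loc + ((pred$boxes[i, k] - pl$boxes[j, k]) / S)^2
    }
  }
  conf <- 0
  for (i in seq_len(nrow(pred$boxes))) {
    r <- which(mt$pairs[, 1] == i)
    y <- if (length(r)) as.numeric(pl$conf[mt$pairs[r, 2]] >= 0.5) else 0
    p <- min(max(pred$confidence[i], 1e-7), 1 - 1e-7)
    conf <- conf - (y * log(p) + (1 - y) * log(1 - p))
  }
  cls + loc + conf
}

brute_pr <- function(preds, truths, iou_thresh, conf_thresh) {
  tp <- 0; fp <- 0; nt <- 0
  for (i in seq_along(preds)) {
    det <- preds[[i]]
    keep <- order(det$confidence, decreasing = TRUE)
    keep <- keep[det$confidence[keep] >= conf_thresh]
    truth <- truths[[i]]
    nt <- nt + nrow(truth$boxes)
    taken <- rep(FALSE, nrow(truth$boxes))
    cls <- detection_classes(det)
    for (j in keep) {
      found <- FALSE
      cands <- which(!taken & truth$class_ids == cls[j])
      if (length(cands)) {
        io <- sapply(cands, function(t) iou(det$boxes[j, ], truth$boxes[t, ]))
        if (max(io) >= iou_thresh) {
          taken[cands[which.max(io)]] <- TRUE
          tp <- tp + 1
          found <- TRUE
        }
      }
      if (!found) fp <- fp + 1
    }
  }
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (nt > 0) tp / nt else 0)
}

random_eval_case <- function(seed, n_img = 3L, K = 2L) {
  withr::with_seed(seed, {
    truths <- lapply(seq_len(n_img), function(i) {
      n <- sample(0:5, 1)
      b <- matrix(0, n, 4)
      if (n > 0) {
        b[, 1] <- runif(n, 0, 30)
        b[, 2] <- runif(n, 0, 30)
        b[, 3] <- b[, 1] + runif(n, 6, 12)
        b[, 4] <- b[, 2] + runif(n, 6, 12)
      }
      labeled_scene(array(0.5, c(48, 48, 3)), pmin(b, 48),
                    sample(K, n, TRUE) - 1L, matrix(0L, 48, 48))
    })
    preds <- lapply(truths, function(tr) {
      n <- nrow(tr$boxes)
      # jittered truths plus occasional spurious boxes
      nb <- n + sample(0:2, 1)
      b <- matrix(0, nb, 4)
      cls <- integer(nb)
      if (n > 0) {
        b[seq_len(n), ] <- tr$boxes + matrix(runif(4 * n, -3, 3), n, 4)
        cls[seq_len(n)] <- tr$class_ids
      }
      if (nb > n) {
        for (j in (n + 1):nb) {
          x <- runif(1, 0, 30); y <- runif(1, 0, 30)
          b[j, ] <- c(x, y, x + runif(1, 6, 10), y + runif(1, 6, 10))
          cls[j] <- sample(K, 1) - 1L
        }
      }
      probs <- matrix(0.1, nb, K)
      probs[cbind(seq_len(nb), cls + 1L)] <- 0.9
      detections(pmin(pmax(b, 0), 48), probs, runif(nb, 0.3, 1))
    })
    list(preds = preds, truths = truths)
  })
}
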