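# Detection and segmentation evaluation: precision/recall at a fixed
# operating point, COCO-style mean average precision with 101-point
# interpolated precision-recall integration (mAP50 and mAP50-95), confusion
# matrices, and the continual-domain report.

conf_filter_sort <- function(det, conf_thresh) {
  keep <- which(det$confidence >= conf_thresh)
  keep <- keep[order(det$confidence[keep], decreasing = TRUE)]
  detections_subset(det, keep)
}

#' Precision and recall at a confidence threshold
#'
#' Predictions at or above `conf_thresh` are greedily matched (in confidence
#' order) to unmatched ground-truth boxes of the same class at IoU >=
#' `iou_thresh`. Precision is defined as 0 when there are no predictions.
#'
#' @param preds list of per-image [detections()]
#' @param truths list of per-image [labeled_scene()]
#' @param iou_thresh IoU threshold (default 0.5)
#' @param conf_thresh confidence threshold (default 0.25)
#' @return named numeric vector with `precision` and `recall`
#' @export
precision_recall <- function(preds, truths, iou_thresh = 0.5,
                             conf_thresh = 0.25) {
  tp <- 0L; fp <- 0L; nt <- 0L
  for (i in seq_along(preds)) {
    det <- conf_filter_sort(preds[[i]], conf_thresh)
    truth <- truths[[i]]
    nt <- nt + nrow(truth$boxes)
    cls <- detection_classes(det)
    used <- rep(FALSE, nrow(truth$boxes))
    for (j in seq_len(nrow(det$boxes))) {
      cand <- which(!used & truth$class_ids == cls[j])
      if (length(cand)) {
        ious <- vapply(cand, function(t) {
          iou(det$boxes[j, ], truth$boxes[t, ])
        }, numeric(1))
        best <- which.max(ious)
        if (ious[best] >= iou_thresh) {
          used[cand[best]] <- TRUE
          tp <- tp + 1L
          next
        }
      }
      fp <- fp + 1L
    }
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (nt > 0) tp / nt else 0
  c(precision = precision, recall = recall)
}

# per-class AP at one IoU threshold (101-point interpolation)
average_precision_class <- function(preds, truths, cls, iou_thresh) {
  n_true <- sum(vapply(truths, function(t) sum(t$class_ids == cls),
                       numeric(1)))
  if (n_true == 0) return(NA_real_)
  recs <- list()
  for (i in seq_along(preds)) {
    det <- preds[[i]]
    pc <- detection_classes(det)
    sel <- which(pc == cls)
    if (length(sel)) {
      recs[[length(recs) + 1L]] <- data.frame(
        image = i, idx = sel, conf = det$confidence[sel])
    }
  }
  if (!length(recs)) return(0)
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$conf, decreasing = TRUE), , drop = FALSE]
  used <- lapply(truths, function(t) rep(FALSE, nrow(t$boxes)))
  tp <- logical(nrow(recs))
  for (r in seq_len(nrow(recs))) {
    i <- recs$image[r]
    truth <- truths[[i]]
    cand <- which(!used[[i]] & truth$class_ids == cls)
    if (length(cand)) {
      ious <- vapply(cand, function(t) {
        iou(preds[[i]]$boxes[recs$idx[r], ], truth$boxes[t, ])
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_thresh) {
        used[[i]][cand[best]] <- TRUE
        tp[r] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_true
  # 101-point interpolated integration
  mean(vapply(seq(0, 1, by = 0.01), function(r0) {
    p <- prec[rec >= r0]
    if (length(p)) max(p) else 0
  }, numeric(1)))
}

#' Mean average precision over classes and IoU thresholds
#'
#' Per-class average precision via 101-point interpolated precision-recall
#' integration, averaged over the classes present in the ground truth and
#' then over the IoU thresholds.
#'
#' @param preds list of per-image [detections()]
#' @param truths list of per-image [labeled_scene()]
#' @param iou_thresholds vector of thresholds (0.5 for mAP50;
#'   `seq(0.5, 0.95, 0.05)` for mAP50-95)
#' @return scalar in `[0,1]`
#' @export
mean_average_precision <- function(preds, truths, iou_thresholds = 0.5) {
  classes <- sort(unique(unlist(lapply(truths, `[[`, "class_ids"))))
  if (!length(classes)) return(0)
  mean(vapply(iou_thresholds, function(th) {
    aps <- vapply(classes, function(cls) {
      average_precision_class(preds, truths, cls, th)
    }, numeric(1))
    mean(aps, na.rm = TRUE)
  }, numeric(1)))
}

#' @rdname mean_average_precision
#' @export
map50 <- function(preds, truths) mean_average_precision(preds, truths, 0.5)

#' @rdname mean_average_precision
#' @export
map50_95 <- function(preds, truths) {
  mean_average_precision(preds, truths, seq(0.5, 0.95, by = 0.05))
}

#' Detection confusion matrix
#'
#' Class-agnostic greedy IoU matching per image; matched pairs vote a
#' (true class, predicted class) cell, unmatched truths fall into the
#' background column, unmatched predictions into the background row.
#'
#' @param preds list of per-image [detections()]
#' @param truths list of per-image [labeled_scene()]
#' @param num_classes number of classes K
#' @param iou_thresh IoU threshold
#' @param conf_thresh confidence threshold applied to predictions
#' @return (K+1) x (K+1) integer matrix, rows = truth, cols = prediction,
#'   last row/column = background
#' @export
confusion_matrix <- function(preds, truths, num_classes, iou_thresh = 0.5,
                             conf_thresh = 0.25) {
  K <- num_classes
  labs <- c(paste0("class_", seq_len(K) - 1L), "background")
  cm <- matrix(0L, K + 1L, K + 1L, dimnames = list(truth = labs, pred = labs))
  for (i in seq_along(preds)) {
    det <- conf_filter_sort(preds[[i]], conf_thresh)
    truth <- truths[[i]]
    mt <- match_boxes(det$boxes, truth$boxes, iou_thresh)
    cls <- detection_classes(det)
    if (nrow(mt$pairs) > 0) {
      for (r in seq_len(nrow(mt$pairs))) {
        tc <- truth$class_ids[mt$pairs[r, 2]] + 1L
        pc <- cls[mt$pairs[r, 1]] + 1L
        cm[tc, pc] <- cm[tc, pc] + 1L
      }
    }
    for (t in mt$unmatched_truth) {
      tc <- truth$class_ids[t] + 1L
      cm[tc, K + 1L] <- cm[tc, K + 1L] + 1L
    }
    for (p in mt$unmatched_pred) {
      cm[K + 1L, cls[p] + 1L] <- cm[K + 1L, cls[p] + 1L] + 1L
    }
  }
  cm
}

#' Full metric set for a prediction list
#'
#' @param preds list of per-image [detections()]
#' @param truths list of per-image [labeled_scene()]
#' @param iou_thresh IoU threshold for precision/recall
#' @param conf_thresh confidence threshold for precision/recall
#' @return one-row tibble with `precision`, `recall`, `map50`, `map50_95`
#' @export
metric_set <- function(preds, truths, iou_thresh = 0.5, conf_thresh = 0.25) {
  pr <- precision_recall(preds, truths, iou_thresh, conf_thresh)
  tibble::tibble(precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 map50 = map50(preds, truths),
                 map50_95 = map50_95(preds, truths))
}

#' Per-domain result of a continual-adaptation run
#'
#' @param per_domain tibble with a `domain` column and the [metric_set()]
#'   columns, one row per domain in stream order
#' @param model the model state after the run (optional)
#' @return an object of class `domain_sequence_result`: the per-domain tibble
#'   plus an `average` row (arithmetic mean over domains)
#' @export
domain_sequence_result <- function(per_domain, model = NULL) {
  avg <- dplyr::summarise(per_domain, dplyr::across(
    c("precision", "recall", "map50", "map50_95"), mean))
  structure(list(per_domain = per_domain, average = avg, model = model),
            class = "domain_sequence_result")
}

#' @export
print.domain_sequence_result <- function(x, ...) {
  cat("Continual domain-sequence result\n")
  tab <- dplyr::bind_rows(
    x$per_domain,
    dplyr::mutate(x$average, domain = "Avg", .before = 1))
  print(as.data.frame(tab), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Continual-domain experiment report for several adaptation strategies
#'
#' Runs each named strategy over the same domain stream from the same
#' starting checkpoint and collects the per-domain metric matrices. The
#' `frozen` strategy evaluates the checkpoint without updates; the `tta`
#' strategy adapts continually with the supplied configuration.
#'
#' @param model a trained [dual_branch_model()]
#' @param stream list of domain blocks (`domain`, `scenes`)
#' @param cfg a [tta_config()]
#' @param strategies character vector among `"frozen"`, `"tta"`
#' @param out_json optional path: writes the mAP50 matrix and averages as JSON
#' @return named list of [domain_sequence_result()], class `domain_report`
#' @export
run_domain_sequence_report <- function(model, stream, cfg,
                                       strategies = c("frozen", "tta"),
                                       out_json = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  results <- list()
  for (s in strategies) {
    scfg <- cfg
    if (s == "frozen") scfg$eta <- 0
    results[[s]] <- continual_adapt(model, stream, scfg)
  }
  out <- structure(results, class = "domain_report")
  if (!is.null(out_json)) {
    payload <- lapply(results, function(r) {
      vals <- as.list(stats::setNames(r$per_domain$map50,
                                      r$per_domain$domain))
      vals$Avg <- r$average$map50
      vals
    })
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
format.domain_report <- function(x, ...) {
  domains <- x[[1]]$per_domain$domain
  header <- sprintf("%-10s %s %7s", "method",
                    paste(sprintf("%7s", domains), collapse = " "), "Avg")
  rows <- vapply(names(x), function(s) {
    sprintf("%-10s %s %7.3f", s,
            paste(sprintf("%7.3f", x[[s]]$per_domain$map50), collapse = " "),
            x[[s]]$average$map50)
  }, character(1))
  paste(c("mAP50 by domain (stream order)", header, rows), collapse = "\n")
}

#' @export
print.domain_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
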