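# Inference (decode + non-maximum suppression) and detection metrics:
# precision/recall at a fixed IoU threshold and interpolated average
# precision, via deterministic greedy matching.

# decode one head level of one batch into a detections tibble
decode_level <- function(head, anc, stride, conf_thresh) {
  d <- dim(head) # (H, W, C, N)
  nc_off <- d[3] / 3
  n_cls <- nc_off - 5
  out <- list()
  gi <- matrix(rep(0:(d[2] - 1), each = d[1]), d[1], d[2]) # column index
  gj <- matrix(rep(0:(d[1] - 1), times = d[2]), d[1], d[2]) # row index
  for (a in 1:3) {
    base <- (a - 1) * nc_off
    obj <- sigmoid(head[, , base + 5, , drop = FALSE])
    cls <- if (n_cls >= 1) {
      sigmoid(head[, , base + 6, , drop = FALSE])
    } else {
      array(1, dim = dim(obj))
    }
    score <- obj * cls
    keep <- which(score > conf_thresh, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    r <- keep[, 1]; cc <- keep[, 2]; img <- keep[, 4]
    at <- function(ch) {
      head[cbind(r, cc, ch, img)]
    }
    sx <- sigmoid(at(base + 1)); sy <- sigmoid(at(base + 2))
    sw <- sigmoid(at(base + 3)); sh <- sigmoid(at(base + 4))
    cand <- tibble::tibble(
      image = as.integer(img),
      cx = (2 * sx - 0.5 + (cc - 1)) * stride,
      cy = (2 * sy - 0.5 + (r - 1)) * stride,
      w = 4 * sw^2 * anc[a, 1],
      h = 4 * sh^2 * anc[a, 2],
      score = score[keep])
    # drop degenerate boxes (non-finite activations or underflowed sizes)
    ok <- is.finite(cand$cx) & is.finite(cand$cy) &
      is.finite(cand$w) & is.finite(cand$h) & cand$w > 0 & cand$h > 0
    out[[a]] <- cand[ok, , drop = FALSE]
  }
  dplyr::bind_rows(out)
}

# greedy IoU-based NMS on one image's detections (already score-sorted)
nms_one <- function(det, iou_thresh, max_det) {
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  n_kept <- 0
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    n_kept <- n_kept + 1
    if (n_kept >= max_det) break
    later <- which(alive & seq_len(nrow(det)) > i)
    if (length(later)) {
      ious <- box_iou(det[rep(i, length(later)), c("cx", "cy", "w", "h")],
                      det[later, c("cx", "cy", "w", "h")])
      alive[later[ious > iou_thresh]] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' Run inference on a batch of images
#'
#' Decodes all three head levels, thresholds on
#' `score = sigmoid(objectness) * sigmoid(class)`, and applies per-image
#' greedy non-maximum suppression. Evaluation-mode forward pass (running
#' batch-norm statistics).
#'
#' @param model A trained detector.
#' @param images List of `[0,1]` grayscale matrices (side must match the
#'   training size) or a `(H, W, 3, N)` array.
#' @param conf_thresh Minimum score to keep a raw box.
#' @param iou_thresh NMS IoU threshold.
#' @param max_det Maximum detections per image.
#' @param batch_size Inference batch size.
#' @return Tibble of detections: `image`, `cx`, `cy`, `w`, `h`, `score`.
#' @export
detect <- function(model, images, conf_thresh = 0.05, iou_thresh = 0.45,
                   max_det = 100, batch_size = 8) {
  if (inherits(model, "nodulite_fit")) model <- model$model
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[4]), function(i) images[, , 1, i])
  }
  n <- length(images)
  out <- list()
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- seq(b0, min(b0 + batch_size - 1, n))
    x <- dataset_to_batch(images, idx)
    fw <- detector_forward(model, x, train = FALSE)
    dets <- dplyr::bind_rows(lapply(seq_along(fw$heads), function(l) {
      decode_level(fw$heads[[l]], model$anchors[[l]], model$strides[l],
                   conf_thresh)
    }))
    if (nrow(dets)) dets$image <- idx[dets$image]
    out[[length(out) + 1]] <- dets
  }
  dets <- dplyr::bind_rows(out)
  if (nrow(dets) == 0) {
    return(tibble::tibble(image = integer(0), cx = numeric(0),
                          cy = numeric(0), w = numeric(0), h = numeric(0),
                          score = numeric(0)))
  }
  dets <- dets[order(dets$image, -dets$score, dets$cx, dets$cy), ]
  dplyr::bind_rows(lapply(split(dets, dets$image), nms_one,
                          iou_thresh = iou_thresh, max_det = max_det))
}

# Greedy matching of score-sorted detections to ground truth. Ties in
# score break by descending best-IoU then ascending image/gt id, so the
# result is invariant to the input permutation.
match_detections <- function(detections, truth, iou_thresh) {
  nd <- nrow(detections)
  det <- detections
  det$best_iou <- 0
  iou_lists <- vector("list", nd)
  truth$.gt <- seq_len(nrow(truth))
  for (i in seq_len(nd)) {
    g <- truth[truth$image == det$image[i], , drop = FALSE]
    if (nrow(g) == 0) next
    ious <- box_iou(det[rep(i, nrow(g)), c("cx", "cy", "w", "h")],
                    g[, c("cx", "cy", "w", "h")])
    iou_lists[[i]] <- tibble::tibble(gt = g$.gt, iou = ious)
    det$best_iou[i] <- max(ious)
  }
  ord <- order(-det$score, -det$best_iou, det$image, det$cx, det$cy)
  gt_taken <- logical(nrow(truth))
  tp <- logical(nd); matched_gt <- rep(NA_integer_, nd)
  for (i in ord) {
    cand <- iou_lists[[i]]
    if (is.null(cand)) next
    cand <- cand[cand$iou >= iou_thresh & !gt_taken[cand$gt], , drop = FALSE]
    if (nrow(cand) == 0) next
    cand <- cand[order(-cand$iou, cand$gt), , drop = FALSE]
    gt_taken[cand$gt[1]] <- TRUE
    tp[i] <- TRUE
    matched_gt[i] <- cand$gt[1]
  }
  list(order = ord, tp = tp, matched_gt = matched_gt)
}

interp_ap <- function(recall, precision, interpolation) {
  if (length(recall) == 0) return(0)
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    vapply(grid, function(r) {
      p <- precision[recall >= r - 1e-12]
      if (length(p)) max(p) else 0
    }, numeric(1)) |> mean()
  } else {
    # all-points: area under the precision envelope
    mrec <- c(0, recall, 1)
    mpre <- c(0, precision, 0)
    for (i in rev(seq_len(length(mpre) - 1))) {
      mpre[i] <- max(mpre[i], mpre[i + 1])
    }
    ii <- which(mrec[-1] != mrec[-length(mrec)])
    sum((mrec[ii + 1] - mrec[ii]) * mpre[ii + 1])
  }
}

#' Evaluate detections against ground truth
#'
#' Score-sorted greedy matching at a single IoU threshold (ties break by
#' descending IoU, then lowest ground-truth id, so results do not depend
#' on input row order). Reports precision and recall over all supplied
#' detections plus interpolated average precision (101-point by default;
#' for a single class this is the mAP).
#'
#' @param detections Tibble with `image`, `cx`, `cy`, `w`, `h`, `score`.
#' @param truth Tibble with `image`, `cx`, `cy`, `w`, `h`.
#' @param iou_thresh Matching IoU threshold (default 0.5).
#' @param interpolation `"101"` (COCO-style grid) or `"all"` (exact area
#'   under the precision envelope).
#' @return An object of class `nodulite_eval`: a list with `metrics`
#'   (one-row tibble: `precision`, `recall`, `ap`, `map`, counts) and
#'   `curve` (cumulative precision/recall per kept detection).
#' @export
evaluate <- function(detections, truth, iou_thresh = 0.5,
                     interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(truth)
  nd <- nrow(detections)
  if (n_gt == 0) {
    metrics <- tibble::tibble(precision = if (nd) 0 else NA_real_,
                              recall = NA_real_, ap = NA_real_,
                              map = NA_real_, tp = 0L, fp = nd,
                              fn = 0L, n_gt = 0L, n_det = nd)
    return(structure(list(metrics = metrics,
                          curve = tibble::tibble(score = numeric(0),
                                                 precision = numeric(0),
                                                 recall = numeric(0)),
                          iou_thresh = iou_thresh,
                          note = "no ground truth: recall/AP undefined"),
                     class = "nodulite_eval"))
  }
  if (nd == 0) {
    metrics <- tibble::tibble(precision = NA_real_, recall = 0, ap = 0,
                              map = 0, tp = 0L, fp = 0L, fn = n_gt,
                              n_gt = n_gt, n_det = 0L)
    return(structure(list(metrics = metrics,
                          curve = tibble::tibble(score = numeric(0),
                                                 precision = numeric(0),
                                                 recall = numeric(0)),
                          iou_thresh = iou_thresh, note = NULL),
                     class = "nodulite_eval"))
  }
  mm <- match_detections(detections, truth, iou_thresh)
  tp_sorted <- mm$tp[mm$order]
  cum_tp <- cumsum(tp_sorted)
  cum_fp <- cumsum(!tp_sorted)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  ap <- interp_ap(rec, prec, interpolation)
  tp_n <- sum(mm$tp)
  metrics <- tibble::tibble(
    precision = tp_n / nd, recall = tp_n / n_gt, ap = ap, map = ap,
    tp = as.integer(tp_n), fp = as.integer(nd - tp_n),
    fn = as.integer(n_gt - tp_n), n_gt = as.integer(n_gt),
    n_det = as.integer(nd))
  curve <- tibble::tibble(score = detections$score[mm$order],
                          precision = prec, recall = rec)
  structure(list(metrics = metrics, curve = curve, iou_thresh = iou_thresh,
                 note = NULL),
            class = "nodulite_eval")
}

#' @export
print.nodulite_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<nodulite_eval> IoU %.2f | P %.3f  R %.3f  mAP@0.5 %.3f | TP %d FP %d FN %d\n",
    x$iou_thresh, m$precision, m$recall, m$map, m$tp, m$fp, m$fn))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname evaluate
#' @param x A `nodulite_eval`.
#' @param ... Unused.
#' @export
tidy.nodulite_eval <- function(x, ...) x$curve

#' @rdname evaluate
#' @export
glance.nodulite_eval <- function(x, ...) x$metrics

#' Plot a precision-recall curve
#'
#' @param object A `nodulite_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nodulite_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Precision-recall (AP = %.3f @ IoU %.2f)",
                      object$metrics$ap, object$iou_thresh),
      x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot a training loss trace
#'
#' @param object A `nodulite_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nodulite_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, dplyr::any_of(c("loss", "val_loss")),
                            names_to = "series", values_to = "value")
  tr <- tr[is.finite(tr$value), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("Training trace (%s loss)",
                                  object$loss_mode),
                  x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a slice with ground-truth and predicted boxes
#'
#' @param image A `[0,1]` grayscale matrix.
#' @param truth,detections Optional box tibbles (`cx`, `cy`, `w`, `h`).
#' @return A ggplot object.
#' @export
plot_slice <- function(image, truth = NULL, detections = NULL) {
  H <- nrow(image); W <- ncol(image)
  df <- expand.grid(y = seq_len(H), x = seq_len(W))
  df$v <- as.vector(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  rect <- function(b, col) {
    ggplot2::geom_rect(data = b, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$cx - .data$w / 2,
                                    xmax = .data$cx + .data$w / 2,
                                    ymin = .data$cy - .data$h / 2,
                                    ymax = .data$cy + .data$h / 2),
                       colour = col, fill = NA, linewidth = 0.5)
  }
  if (!is.null(truth) && nrow(truth)) p <- p + rect(truth, "green")
  if (!is.null(detections) && nrow(detections)) {
    p <- p + rect(detections, "red")
  }
  p
}

#' ggplot2 autoplot generic (re-export shim)
#' @param object Object to plot.
#' @param ... Passed on.
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
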