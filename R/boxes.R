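#' Construct a tibble of axis-aligned bounding boxes
#'
#' Boxes are the unit of detection throughout the package: axis-aligned
#' rectangles in continuous pixel coordinates (origin top-left, x right,
#' y down), parameterised by center and size.
#'
#' @param cx,cy Box center coordinates (pixels).
#' @param w,h Box width and height (pixels); must be strictly positive.
#' @return A tibble with columns `cx`, `cy`, `w`, `h`, one row per box.
#' @examples
#' bbox(c(0, 5), c(0, 7), c(2, 4), c(2, 6))
#' @export
bbox <- function(cx, cy, w, h) {
  b <- tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                      w = as.numeric(w), h = as.numeric(h))
  validate_bbox(b)
  b
}

validate_bbox <- function(b) {
  stopifnot(is.data.frame(b), all(c("cx", "cy", "w", "h") %in% names(b)))
  if (any(!is.finite(b$w)) || any(!is.finite(b$h)) || any(b$w <= 0) || any(b$h <= 0)) {
    stop("invalid box: width and height must be finite and strictly positive",
         call. = FALSE)
  }
  invisible(b)
}

#' Model boxes as 2-D Gaussian distributions
#'
#' Each box is mapped to an axis-aligned Gaussian with mean at the box
#' center and diagonal covariance `diag((w/2)^2, (h/2)^2)`, so that the
#' inner pixels of a small box are weighted more heavily than its rim.
#' This is the representation under which the Wasserstein box distance
#' is computed.
#'
#' @param boxes A data frame of boxes as produced by [bbox()].
#' @return A tibble with columns `mean_x`, `mean_y`, `var_x`, `var_y`.
#' @seealso [gaussian_to_box()], [wasserstein2()]
#' @export
box_to_gaussian <- function(boxes) {
  validate_bbox(boxes)
  tibble::tibble(
    mean_x = boxes$cx, mean_y = boxes$cy,
    var_x = (boxes$w / 2)^2, var_y = (boxes$h / 2)^2
  )
}

#' Invert the Gaussian box model
#'
#' @param g A tibble as returned by [box_to_gaussian()].
#' @return A tibble of boxes (columns `cx`, `cy`, `w`, `h`).
#' @export
gaussian_to_box <- function(g) {
  stopifnot(all(c("mean_x", "mean_y", "var_x", "var_y") %in% names(g)))
  if (any(g$var_x <= 0) || any(g$var_y <= 0)) {
    stop("invalid Gaussian box: covariance entries must be strictly positive",
         call. = FALSE)
  }
  bbox(g$mean_x, g$mean_y, 2 * sqrt(g$var_x), 2 * sqrt(g$var_y))
}

#' Second-order Wasserstein distance between box Gaussians
#'
#' For two axis-aligned Gaussians the 2-Wasserstein distance has the
#' closed form `sqrt(||m1 - m2||^2 + ||S1^(1/2) - S2^(1/2)||_F^2)`, which
#' for box-derived Gaussians reduces to
#' `sqrt((cx1-cx2)^2 + (cy1-cy2)^2 + ((w1-w2)/2)^2 + ((h1-h2)/2)^2)`.
#' Vectorised over paired rows (rows are recycled if one input has a
#' single box).
#'
#' @param a,b Data frames of boxes ([bbox()]).
#' @return A numeric vector of nonnegative distances (pixels).
#' @export
wasserstein2 <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2 +
         ((a$w - b$w) / 2)^2 + ((a$h - b$h) / 2)^2)
}

#' Normalized Wasserstein distance (NWD) box similarity
#'
#' `exp(-W2(a, b) / C)`: a similarity in (0, 1] that, unlike IoU, degrades
#' smoothly with center offset for tiny boxes and does not collapse to 0
#' for non-overlapping pairs. `C` is a dataset-scale constant in the same
#' pixel units as the boxes; see [nwd_constant()] for the default rule.
#'
#' @param a,b Data frames of boxes ([bbox()]).
#' @param C Positive normalisation constant (pixels).
#' @return Numeric vector of similarities in (0, 1].
#' @export
nwd <- function(a, b, C) {
  if (!is.numeric(C) || length(C) != 1 || !is.finite(C) || C <= 0) {
    stop("NWD constant C must be a single positive number", call. = FALSE)
  }
  exp(-wasserstein2(a, b) / C)
}

#' Default NWD normalisation constant from a set of training boxes
#'
#' The mean of `(w + h) / 2` over the target boxes: the typical box
#' half-perimeter scale of the dataset.
#'
#' @param boxes Data frame of boxes.
#' @return A single positive number.
#' @export
nwd_constant <- function(boxes) {
  validate_bbox(boxes)
  mean((boxes$w + boxes$h) / 2)
}

box_corners <- function(b) {
  list(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
       x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

#' Intersection over union of paired boxes
#'
#' @param a,b Data frames of boxes; rows are paired (length-1 inputs recycle).
#' @return Numeric vector in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  ca <- box_corners(a); cb <- box_corners(b)
  iw <- pmax(0, pmin(ca$x2, cb$x2) - pmax(ca$x1, cb$x1))
  ih <- pmax(0, pmin(ca$y2, cb$y2) - pmax(ca$y1, cb$y1))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Complete-IoU (CIoU) regression loss
#'
#' The stock YOLOv5 box loss: `1 - IoU + rho^2/c^2 + alpha * v`, where
#' `rho` is the center distance, `c` the diagonal of the smallest
#' enclosing box, and `v` the aspect-ratio consistency term
#' `4/pi^2 (atan(w2/h2) - atan(w1/h1))^2` with trade-off
#' `alpha = v / (1 - IoU + v)`. Zero iff the boxes coincide.
#'
#' @param a Predicted boxes; `b` target boxes (paired rows).
#' @param b Target boxes.
#' @return Numeric vector of nonnegative losses.
#' @export
ciou_loss <- function(a, b) {
  validate_bbox(a); validate_bbox(b)
  iou <- box_iou(a, b)
  ca <- box_corners(a); cb <- box_corners(b)
  cw <- pmax(ca$x2, cb$x2) - pmin(ca$x1, cb$x1)
  ch <- pmax(ca$y2, cb$y2) - pmin(ca$y1, cb$y1)
  c2 <- cw^2 + ch^2
  rho2 <- (a$cx - b$cx)^2 + (a$cy - b$cy)^2
  v <- (4 / pi^2) * (atan(b$w / b$h) - atan(a$w / a$h))^2
  alpha <- v / (1 - iou + v + 1e-12)
  1 - iou + rho2 / pmax(c2, 1e-12) + alpha * v
}

#' Loss configuration for the combined Focal + NWD objective
#'
#' @param nwd_constant NWD scale `C` in pixels, or `NULL` to derive it from
#'   the training targets via [nwd_constant()]. A fixed override such as
#'   12.8 is accepted.
#' @param focal_gamma Focusing exponent of the focal term (>= 0); 0 recovers
#'   plain cross-entropy.
#' @param focal_alpha Class-balance weight in `[0, 1]`, or `NA` to disable.
#' @param weight_focal,weight_nwd Mixture weights of the classification and
#'   regression terms; defaults 0.1 / 0.9.
#' @param iou_exponent Exponent of the per-pair `IoU^lambda` sample weight
#'   on the regression term.
#' @return A list of class `nodulite_loss_config`.
#' @export
loss_config <- function(nwd_constant = NULL, focal_gamma = 2, focal_alpha = 0.25,
                        weight_focal = 0.1, weight_nwd = 0.9, iou_exponent = 0.5) {
  if (!is.null(nwd_constant) && (!is.finite(nwd_constant) || nwd_constant <= 0)) {
    stop("nwd_constant must be positive", call. = FALSE)
  }
  stopifnot(focal_gamma >= 0, iou_exponent >= 0,
            weight_focal >= 0, weight_nwd >= 0)
  structure(list(nwd_constant = nwd_constant, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, weight_focal = weight_focal,
                 weight_nwd = weight_nwd, iou_exponent = iou_exponent),
            class = "nodulite_loss_config")
}

#' Focal loss for binary classification
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives. With `gamma = 0` and `alpha` disabled it equals
#' binary cross-entropy. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` before the log.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1), recycled against `p`.
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Class-balance weight in `[0, 1]`; `NA` disables it.
#' @return Numeric vector of nonnegative per-sample losses.
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- if (is.null(alpha) || is.na(alpha)) 1 else ifelse(y == 1, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

#' Combined Focal + NWD (F-NWD) detection loss
#'
#' `weight_focal * mean(focal classification term)` plus
#' `weight_nwd * mean(IoU^lambda * (1 - NWD))` over matched box pairs.
#' The `IoU^lambda` sample weight damps the influence of poorly localised
#' (low-quality) anchors on the regression term. An empty match set
#' contributes a zero regression term; the classification term is always
#' computed from `p` and `y`.
#'
#' @param pred_boxes,target_boxes Matched predicted / target boxes (paired
#'   rows); may have zero rows.
#' @param p Predicted objectness/class probabilities (all anchors under
#'   consideration, not only matched ones).
#' @param y Binary labels aligned with `p`.
#' @param cfg A [loss_config()]. If `cfg$nwd_constant` is `NULL` it is
#'   derived from `target_boxes`.
#' @return A list with `total`, `focal`, and `nwd` components (scalars).
#' @export
f_nwd_loss <- function(pred_boxes, target_boxes, p = numeric(0), y = numeric(0),
                       cfg = loss_config()) {
  stopifnot(inherits(cfg, "nodulite_loss_config"))
  n_pairs <- nrow(pred_boxes)
  stopifnot(n_pairs == nrow(target_boxes))
  focal_term <- if (length(p)) {
    mean(focal_loss(p, y, cfg$focal_gamma, cfg$focal_alpha))
  } else 0
  if (n_pairs > 0) {
    C <- cfg$nwd_constant %||% nwd_constant(target_boxes)
    wts <- box_iou(pred_boxes, target_boxes)^cfg$iou_exponent
    reg_term <- sum(wts * (1 - nwd(pred_boxes, target_boxes, C))) / n_pairs
  } else {
    reg_term <- 0
  }
  total <- cfg$weight_focal * focal_term + cfg$weight_nwd * reg_term
  list(total = total, focal = focal_term, nwd = reg_term)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
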