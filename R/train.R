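# Target assignment (anchor-based, ratio-gated, 3-cell neighbourhood),
# the detection losses (stock CIoU objective and the combined Focal + NWD
# objective), and the SGD training loop. Box-regression gradients are
# obtained by central differences of the closed-form pair losses with
# respect to the four decoded box parameters, then chained analytically
# through the sigmoid decodes; classification gradients are analytic.

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: SGD with momentum 0.937
#' and weight decay 5e-4, batch size 8, initial learning rate 0.01, 200
#' epochs (pass a small `epochs` for desk-scale runs). The learning rate
#' follows a cosine decay to `final_lr_frac * lr`.
#'
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution/linear weights.
#' @param batch_size Images per step.
#' @param epochs Training epochs.
#' @param seed Integer seed fixing shuffling and initialisation.
#' @param final_lr_frac Final learning rate as a fraction of `lr`.
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param box_gain,obj_gain Gains on the box-regression and objectness
#'   terms. The defaults are the reference large-scale values; short CPU
#'   runs need `box_gain = 5, obj_gain = 100, clip_norm = 0` (the tiny-run
#'   recipe; see the methods vignette) because both terms are normalized
#'   over far more cells/steps than a desk run provides.
#' @return A list of class `nodulite_train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
                         batch_size = 8, epochs = 200, seed = 0,
                         final_lr_frac = 0.1, clip_norm = 10,
                         box_gain = 0.05, obj_gain = 1.0) {
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 1)
  structure(as.list(environment()), class = "nodulite_train_config")
}

#' Assign ground-truth boxes to anchors and grid cells
#'
#' Anchor-based assignment: a box matches an anchor when the
#' width/height ratio gate `max(w/aw, aw/w, h/ah, ah/h) < ratio_thresh`
#' passes; each match is placed in its center cell plus up to two
#' neighbouring cells (the nearer neighbour per axis when the fractional
#' offset is < 0.5 / > 0.5). Deterministic in the input order.
#'
#' @param boxes Tibble of target boxes (`cx`, `cy`, `w`, `h` in pixels)
#'   with an `image` column (1-based batch index).
#' @param anchors List of per-level anchor matrices (pixels).
#' @param strides Per-level strides (e.g. `c(8, 16, 32)`).
#' @param input_size Image size in pixels.
#' @param ratio_thresh Anchor/target size gate (default 4).
#' @return A tibble with `image`, `level`, `anchor`, `gi`, `gj` (0-based
#'   cell column/row), target box columns, and `gt` (row in `boxes`).
#' @export
assign_targets <- function(boxes, anchors, strides, input_size,
                           ratio_thresh = 4) {
  if (nrow(boxes) == 0) {
    return(tibble::tibble(image = integer(0), level = integer(0),
                          anchor = integer(0), gi = integer(0),
                          gj = integer(0), cx = numeric(0), cy = numeric(0),
                          w = numeric(0), h = numeric(0), gt = integer(0)))
  }
  if (!"image" %in% names(boxes)) boxes$image <- 1L
  out <- list()
  for (l in seq_along(strides)) {
    s <- strides[l]
    ngrid <- input_size / s
    anc <- anchors[[l]]
    for (a in seq_len(nrow(anc))) {
      r1 <- boxes$w / anc[a, 1]; r2 <- boxes$h / anc[a, 2]
      gate <- pmax(r1, 1 / r1, r2, 1 / r2) < ratio_thresh
      if (!any(gate)) next
      b <- boxes[gate, , drop = FALSE]
      b$gt <- which(gate)
      gx <- b$cx / s; gy <- b$cy / s
      ci <- floor(gx); cj <- floor(gy)
      cand <- list(cbind(ci, cj))
      fx <- gx - ci; fy <- gy - cj
      cand[[2]] <- cbind(ifelse(fx < 0.5, ci - 1, ci + 1), cj)
      cand[[3]] <- cbind(ci, ifelse(fy < 0.5, cj - 1, cj + 1))
      for (cc in cand) {
        ok <- cc[, 1] >= 0 & cc[, 1] < ngrid & cc[, 2] >= 0 & cc[, 2] < ngrid
        if (!any(ok)) next
        out[[length(out) + 1]] <- tibble::tibble(
          image = b$image[ok], level = l, anchor = a,
          gi = as.integer(cc[ok, 1]), gj = as.integer(cc[ok, 2]),
          cx = b$cx[ok], cy = b$cy[ok], w = b$w[ok], h = b$h[ok],
          gt = b$gt[ok])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res <- dplyr::distinct(res, .data$image, .data$level,
                                        .data$anchor, .data$gi, .data$gj,
                                        .data$gt, .keep_all = TRUE)
  res
}

# flat indices of (gj, gi, channel, image) cells in an (H, W, C, N) array
cell_index <- function(dimhw, gj, gi, ch, img) {
  H <- dimhw[1]; W <- dimhw[2]; C <- dimhw[3]
  1 + gj + gi * H + (ch - 1) * H * W + (img - 1) * H * W * C
}

# Decode matched raw head values into pixel boxes.
decode_matches <- function(head, m, anc, stride) {
  d <- dim(head)
  nc_off <- d[3] / 3 # channels per anchor
  base <- (m$anchor - 1) * nc_off
  tx <- head[cell_index(d, m$gj, m$gi, base + 1, m$image)]
  ty <- head[cell_index(d, m$gj, m$gi, base + 2, m$image)]
  tw <- head[cell_index(d, m$gj, m$gi, base + 3, m$image)]
  th <- head[cell_index(d, m$gj, m$gi, base + 4, m$image)]
  sx <- sigmoid(tx); sy <- sigmoid(ty); sw <- sigmoid(tw); sh <- sigmoid(th)
  list(
    # floor w/h: sigmoid^2 underflows to exactly 0 for very negative
    # logits and the box losses require strictly positive sizes
    box = tibble::tibble(cx = (2 * sx - 0.5 + m$gi) * stride,
                         cy = (2 * sy - 0.5 + m$gj) * stride,
                         w = pmax(4 * sw^2 * anc[m$anchor, 1], 1e-6),
                         h = pmax(4 * sh^2 * anc[m$anchor, 2], 1e-6)),
    # d(decoded)/d(logit) for the chain rule
    dbox = tibble::tibble(cx = 2 * sx * (1 - sx) * stride,
                          cy = 2 * sy * (1 - sy) * stride,
                          w = 8 * anc[m$anchor, 1] * sw^2 * (1 - sw),
                          h = 8 * anc[m$anchor, 2] * sh^2 * (1 - sh))
  )
}

# central-difference gradient of a pairwise box loss wrt the predicted box
numeric_box_grad <- function(lossfn, pred, tgt, eps = 1e-4) {
  g <- matrix(0, nrow(pred), 4)
  cols <- c("cx", "cy", "w", "h")
  for (j in 1:4) {
    pp <- pred; pm <- pred
    pp[[cols[j]]] <- pp[[cols[j]]] + eps
    pm[[cols[j]]] <- pmax(pm[[cols[j]]] - eps,
                          if (j >= 3) 1e-3 else -Inf)
    step <- pp[[cols[j]]] - pm[[cols[j]]]
    g[, j] <- (lossfn(pp, tgt) - lossfn(pm, tgt)) / step
  }
  g
}

# focal gradient wrt the logit (p = sigmoid(z))
focal_grad_logit <- function(p, y, gamma, alpha) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- if (is.null(alpha) || is.na(alpha)) 1 else ifelse(y == 1, alpha, 1 - alpha)
  # dL/dpt * dpt/dz, with dpt/dz = +/- pt (1 - pt) depending on y
  dl_dpt <- at * (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
                    (1 - pt)^gamma / pt)
  dpt_dz <- ifelse(y == 1, pt * (1 - pt), -pt * (1 - pt))
  dl_dpt * dpt_dz
}

# Compute the detection loss and the gradients wrt the raw head maps.
detection_loss <- function(heads, matches, model, mode, lcfg, tcfg,
                           nwd_C = NULL) {
  strides <- model$strides
  anchors <- model$anchors
  balance <- c(4, 1, 0.4)
  n_img <- dim(heads[[1]])[4]
  grads <- lapply(heads, function(h) array(0, dim = dim(h)))
  # a diverged model emits non-finite activations; report a non-finite loss
  # instead of crashing inside the decode
  if (!all(vapply(heads, function(h) all(is.finite(h)), logical(1)))) {
    return(list(total = NaN, box = NaN, obj = NaN, grads = grads,
                n_pairs = 0L))
  }
  lbox_sum <- 0; n_pairs <- 0; lobj <- 0
  nc_off <- dim(heads[[1]])[3] / 3
  for (l in seq_along(heads)) {
    h <- heads[[l]]
    d <- dim(h)
    m <- matches[matches$level == l, , drop = FALSE]
    # objectness target map
    obj_t <- array(0, dim = c(d[1], d[2], 3, d[4]))
    dec <- NULL
    if (nrow(m) > 0) {
      dec <- decode_matches(h, m, anchors[[l]], strides[l])
      tgt <- m[, c("cx", "cy", "w", "h")]
      if (mode == "ciou") {
        pl <- ciou_loss(dec$box, tgt)
        gbox <- numeric_box_grad(ciou_loss, dec$box, tgt)
        iou_det <- pmax(box_iou(dec$box, tgt), 0)
        oidx <- cell_index(dim(obj_t), m$gj, m$gi, m$anchor, m$image)
        obj_t[oidx] <- pmax(obj_t[oidx], iou_det)
        scale <- tcfg$box_gain
      } else {
        C <- nwd_C %||% nwd_constant(tgt)
        wts <- box_iou(dec$box, tgt)^lcfg$iou_exponent # detached weight
        fnwd <- function(p, t) wts * (1 - nwd(p, t, C))
        pl <- fnwd(dec$box, tgt)
        gbox <- numeric_box_grad(fnwd, dec$box, tgt)
        oidx <- cell_index(dim(obj_t), m$gj, m$gi, m$anchor, m$image)
        obj_t[oidx] <- 1
        scale <- lcfg$weight_nwd
      }
      lbox_sum <- lbox_sum + sum(pl)
      n_pairs <- n_pairs + nrow(m)
      # chain through decode; accumulate into the raw-head gradient
      gb <- gbox * as.matrix(dec$dbox[, c("cx", "cy", "w", "h")])
      base <- (m$anchor - 1) * nc_off
      for (j in 1:4) {
        idx <- cell_index(d, m$gj, m$gi, base + j, m$image)
        # duplicate cells (two targets in one cell) must accumulate
        agg <- rowsum(gb[, j] * scale, idx)
        aidx <- as.integer(rownames(agg))
        grads[[l]][aidx] <- grads[[l]][aidx] + agg[, 1]
      }
    }
    # objectness loss over the full map
    obase <- rep((0:2) * nc_off + 5, each = 1)
    zobj <- h[, , obase, , drop = FALSE]
    pobj <- sigmoid(zobj)
    ncell <- length(zobj)
    if (mode == "ciou") {
      eps <- 1e-12
      bce <- -(obj_t * log(pmax(pobj, eps)) +
                 (1 - obj_t) * log(pmax(1 - pobj, eps)))
      lobj <- lobj + balance[l] * mean(bce)
      gobj <- balance[l] * (pobj - obj_t) / ncell * tcfg$obj_gain
    } else {
      fl <- focal_loss(pobj, obj_t, lcfg$focal_gamma, lcfg$focal_alpha)
      lobj <- lobj + balance[l] * mean(fl)
      gobj <- balance[l] *
        focal_grad_logit(pobj, obj_t, lcfg$focal_gamma, lcfg$focal_alpha) /
        ncell * lcfg$weight_focal * tcfg$obj_gain
    }
    grads[[l]][, , obase, ] <- grads[[l]][, , obase, , drop = FALSE] + gobj
  }
  lbox <- if (n_pairs > 0) lbox_sum / n_pairs else 0
  if (mode == "ciou") {
    total <- tcfg$box_gain * lbox + tcfg$obj_gain * lobj
    box_scale <- 1 / max(n_pairs, 1)
  } else {
    total <- lcfg$weight_nwd * lbox + lcfg$weight_focal * tcfg$obj_gain * lobj
    box_scale <- 1 / max(n_pairs, 1)
  }
  # box-channel gradients were accumulated per pair; normalise by the count
  if (n_pairs > 0) {
    for (l in seq_along(grads)) {
      boxch <- as.vector(outer(1:4, (0:2) * nc_off, `+`))
      grads[[l]][, , boxch, ] <- grads[[l]][, , boxch, ] * box_scale
    }
  }
  list(total = total, box = lbox, obj = lobj, grads = grads,
       n_pairs = n_pairs)
}

clip_global_norm <- function(model, max_norm) {
  if (max_norm <= 0) return(1)
  ss <- 0
  for (nd in model$nodes) for (g in nd$ly$grad) ss <- ss + sum(g^2)
  nrm <- sqrt(ss)
  scale <- if (nrm > max_norm) max_norm / nrm else 1
  if (scale < 1) {
    for (nd in model$nodes) {
      ly <- nd$ly
      for (nm in names(ly$grad)) ly$grad[[nm]] <- ly$grad[[nm]] * scale
    }
  }
  scale
}

sgd_step <- function(model, lr, momentum, weight_decay) {
  for (nd in model$nodes) {
    ly <- nd$ly
    if (length(ly$par) == 0) next
    if (is.null(ly$opt)) ly$opt <- lapply(ly$par, function(p) p * 0)
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]]
      # gradients accumulated via rowSums()/aperm() may carry a stray dim
      # attribute; force them to the parameter's shape so the update never
      # reshapes the parameter (array addition in R is shape-strict)
      if (!identical(dim(g), dim(ly$par[[nm]]))) dim(g) <- dim(ly$par[[nm]])
      if (!is.null(ly$decay) && isTRUE(ly$decay[[nm]])) {
        g <- g + weight_decay * ly$par[[nm]]
      }
      ly$opt[[nm]] <- momentum * ly$opt[[nm]] + g
      ly$par[[nm]] <- ly$par[[nm]] - lr * ly$opt[[nm]]
    }
  }
}

dataset_to_batch <- function(images, idx) {
  H <- nrow(images[[idx[1]]]); W <- ncol(images[[idx[1]]])
  x <- array(0, dim = c(H, W, 3, length(idx)))
  for (i in seq_along(idx)) {
    x[, , 1, i] <- images[[idx[i]]]
    x[, , 2, i] <- images[[idx[i]]]
    x[, , 3, i] <- images[[idx[i]]]
  }
  x
}

#' Load an exported slice/label directory into memory
#'
#' @param dir Directory of PNG slices and YOLO label files (as written by
#'   [export_slices()]/[prep_dataset()]).
#' @return A list with `images` (list of `[0,1]` matrices) and `boxes`
#'   (list of tibbles in pixel units), plus `files`.
#' @export
load_dataset <- function(dir) {
  pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(pngs) == 0) stop("no PNG slices under ", dir, call. = FALSE)
  images <- vector("list", length(pngs))
  boxes <- vector("list", length(pngs))
  for (i in seq_along(pngs)) {
    img <- png::readPNG(pngs[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    images[[i]] <- img
    lbl <- sub("\\.png$", ".txt", pngs[i])
    boxes[[i]] <- read_yolo_labels(if (file.exists(lbl)) lbl else NA,
                                   ncol(img), nrow(img))
  }
  list(images = images, boxes = boxes, files = pngs)
}

#' Train a detector
#'
#' SGD training with momentum, weight decay, cosine learning-rate decay and
#' global gradient clipping. `loss_mode` selects the stock CIoU box loss +
#' binary cross-entropy objectness, or the combined Focal + NWD objective
#' (`"f_nwd"`). Fully deterministic given `cfg$seed`. After the last epoch
#' the batch-norm running statistics are recalibrated with one pass over
#' the training images.
#'
#' @param model A detector from [build_detector()] (modified in place and
#'   returned).
#' @param dataset A dataset as from [load_dataset()] (images must be square
#'   with side divisible by 32 and equal to the model's `input_size`).
#' @param loss_mode `"ciou"` or `"f_nwd"`; defaults to the model config.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()] for the F-NWD objective.
#' @param validation Optional held-out dataset for a per-epoch loss.
#' @param verbose Print per-epoch losses.
#' @return An object of class `nodulite_fit`: the trained model plus a
#'   per-epoch loss trace.
#' @export
train <- function(model, dataset, loss_mode = NULL, cfg = train_config(),
                  loss_cfg = loss_config(), validation = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "nodulite_detector"))
  loss_mode <- loss_mode %||% model$cfg$loss_mode
  n <- length(dataset$images)
  if (n == 0) stop("empty dataset", call. = FALSE)
  input_size <- nrow(dataset$images[[1]])
  all_t <- dplyr::bind_rows(dataset$boxes)
  nwd_C <- loss_cfg$nwd_constant %||%
    (if (nrow(all_t)) nwd_constant(all_t) else 8)
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  # per-image target assignment is static; precompute
  tgt_by_img <- vector("list", n)
  for (i in seq_len(n)) {
    b <- dataset$boxes[[i]]
    if (nrow(b)) b$image <- 1L
    tgt_by_img[[i]] <- assign_targets(b, model$anchors, model$strides,
                                      input_size)
  }
  trace <- list()
  for (ep in seq_len(cfg$epochs)) {
    lr <- cfg$final_lr_frac * cfg$lr +
      (1 - cfg$final_lr_frac) * cfg$lr *
        (1 + cos(pi * (ep - 1) / max(1, cfg$epochs - 1))) / 2
    ord <- sample(n)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      x <- dataset_to_batch(dataset$images, idx)
      fw <- detector_forward(model, x, train = TRUE)
      matches <- dplyr::bind_rows(lapply(seq_along(idx), function(i) {
        m <- tgt_by_img[[idx[i]]]
        if (nrow(m)) m$image <- i
        m
      }))
      ls <- detection_loss(fw$heads, matches, model, loss_mode, loss_cfg,
                           cfg, nwd_C)
      if (!is.finite(ls$total)) {
        stop("NaN/Inf loss at epoch ", ep, "; aborting (lr too high?)",
             call. = FALSE)
      }
      for (nd in model$nodes) zero_grads(nd$ly)
      detector_backward(model, fw$outs, ls$grads)
      clip_global_norm(model, cfg$clip_norm)
      sgd_step(model, lr, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + ls$total; nb <- nb + 1
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      val_loss <- dataset_loss(model, validation, loss_mode, cfg, loss_cfg,
                               nwd_C)
    }
    trace[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / nb,
                                  val_loss = val_loss, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e", ep,
                      ep_loss / nb, val_loss, lr))
    }
  }
  # recalibrate BN running stats on the training set
  for (b0 in seq(1, n, by = cfg$batch_size)) {
    idx <- seq(b0, min(b0 + cfg$batch_size - 1, n))
    invisible(detector_forward(model, dataset_to_batch(dataset$images, idx),
                               train = TRUE))
  }
  structure(list(model = model, trace = dplyr::bind_rows(trace),
                 loss_mode = loss_mode, cfg = cfg),
            class = "nodulite_fit")
}

# mean loss over a dataset without updating weights or BN state
dataset_loss <- function(model, dataset, loss_mode, cfg, loss_cfg, nwd_C) {
  n <- length(dataset$images)
  input_size <- nrow(dataset$images[[1]])
  tot <- 0; nb <- 0
  for (b0 in seq(1, n, by = cfg$batch_size)) {
    idx <- seq(b0, min(b0 + cfg$batch_size - 1, n))
    x <- dataset_to_batch(dataset$images, idx)
    fw <- detector_forward(model, x, train = FALSE)
    matches <- dplyr::bind_rows(lapply(seq_along(idx), function(i) {
      b <- dataset$boxes[[idx[i]]]
      if (nrow(b)) b$image <- 1L
      m <- assign_targets(b, model$anchors, model$strides, input_size)
      if (nrow(m)) m$image <- i
      m
    }))
    ls <- detection_loss(fw$heads, matches, model, loss_mode, loss_cfg, cfg,
                         nwd_C)
    tot <- tot + ls$total; nb <- nb + 1
  }
  tot / nb
}

#' @export
print.nodulite_fit <- function(x, ...) {
  cat(sprintf("<nodulite_fit> %s loss | %d epochs | final train loss %.4f\n",
              x$loss_mode, nrow(x$trace), x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @rdname train
#' @param x A `nodulite_fit`.
#' @export
tidy.nodulite_fit <- function(x, ...) x$trace

#' @rdname train
#' @export
glance.nodulite_fit <- function(x, ...) {
  tibble::tibble(loss_mode = x$loss_mode, epochs = nrow(x$trace),
                 initial_loss = x$trace$loss[1],
                 final_loss = x$trace$loss[nrow(x$trace)])
}

#' Broom-style generics
#' @param x Object to tidy.
#' @param ... Unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
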