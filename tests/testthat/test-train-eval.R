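# Target assignment, the training harness, inference and metrics.

test_that("assign_targets implements gate + neighbour-cell rules", {
  anchors <- default_anchors()
  strides <- c(8, 16, 32)
  # 12x12 box at (20.2, 24.8) on a 64px image
  b <- bbox(20.2, 24.8, 12, 12); b$image <- 1L
  m <- assign_targets(b, anchors, strides, 64)
  expect_true(all(m$gi >= 0 & m$gj >= 0))
  # P3 anchor (10, 13): ratios (1.2, 12/13...) pass; center cell (2, 3)
  m3 <- m[m$level == 1 & m$anchor == 1, ]
  expect_true(nrow(m3) >= 1)
  expect_true(any(m3$gi == 2 & m3$gj == 3))
  # fractional parts (0.525, 0.1): neighbours right-of? no: fx>0.5 -> gi+1,
  # fy<0.5 -> gj-1
  expect_true(any(m3$gi == 3 & m3$gj == 3))
  expect_true(any(m3$gi == 2 & m3$gj == 2))
  expect_equal(nrow(m3), 3)
  # anchor (116, 90) at level 3 fails the ratio-4 gate for a 12px box
  expect_false(any(m$level == 3 & m$anchor == 1))
  # a huge anchor ratio never matches: 1px box matches nothing
  tiny <- bbox(32, 32, 1, 1); tiny$image <- 1L
  expect_equal(nrow(assign_targets(tiny, anchors, strides, 64)), 0)
  # empty input
  expect_equal(nrow(assign_targets(b[0, ], anchors, strides, 64)), 0)
})

test_that("assign_targets matches a brute-force oracle on random scenes", {
  anchors <- default_anchors()
  strides <- c(8, 16, 32)
  set.seed(50)
  for (trial in 1:10) {
    n <- sample(1:5, 1)
    b <- tibble::tibble(cx = runif(n, 4, 124), cy = runif(n, 4, 124),
                        w = runif(n, 3, 60), h = runif(n, 3, 60),
                        image = sample(1:2, n, replace = TRUE))
    got <- assign_targets(b, anchors, strides, 128)
    # oracle: enumerate every (level, anchor, gt), apply gate and cells
    want <- 0
    for (l in 1:3) for (a in 1:3) for (i in seq_len(n)) {
      aw <- anchors[[l]][a, 1]; ah <- anchors[[l]][a, 2]
      r <- max(b$w[i] / aw, aw / b$w[i], b$h[i] / ah, ah / b$h[i])
      if (r >= 4) next
      ng <- 128 / strides[l]
      gx <- b$cx[i] / strides[l]; gy <- b$cy[i] / strides[l]
      cells <- list(c(floor(gx), floor(gy)))
      cells[[2]] <- c(floor(gx) + ifelse(gx - floor(gx) < 0.5, -1, 1),
                      floor(gy))
      cells[[3]] <- c(floor(gx),
                      floor(gy) + ifelse(gy - floor(gy) < 0.5, -1, 1))
      cells <- unique(Filter(function(cc) all(cc >= 0 & cc < ng), cells))
      want <- want + length(cells)
      for (cc in cells) {
        expect_true(any(got$level == l & got$anchor == a & got$gt == i &
                          got$gi == cc[1] & got$gj == cc[2] &
                          got$image == b$image[i]))
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("evaluate matches hand-computed precision/recall", {
  # 3 gt, 3 detections: 2 true matches and 1 localisation miss
  truth <- bbox(c(20, 60, 100), c(20, 60, 100), c(10, 10, 10),
                c(10, 10, 10))
  truth$image <- 1L
  det <- bbox(c(20, 61, 140), c(20, 60, 140), c(10, 10, 10), c(10, 10, 10))
  det$image <- 1L
  det$score <- c(0.9, 0.8, 0.7)
  ev <- evaluate(det, truth)
  expect_equal(ev$metrics$tp, 2L)
  expect_equal(ev$metrics$fp, 1L)
  expect_equal(ev$metrics$fn, 1L)
  expect_equal(ev$metrics$precision, 2 / 3)
  expect_equal(ev$metrics$recall, 2 / 3)
  # AP: precision envelope 1 up to recall 2/3, 0 beyond ->
  # 101-point mean over the grid: 67 of 101 points at 1
  expect_equal(ev$metrics$ap, 67 / 101)
  expect_equal(ev$metrics$map, ev$metrics$ap)
})

test_that("evaluate AP matches a brute-force threshold sweep", {
  set.seed(51)
  truth <- tibble::tibble(cx = runif(12, 20, 200), cy = runif(12, 20, 200),
                          w = 12, h = 12,
                          image = rep(1:3, each = 4))
  # detections: jittered copies + noise boxes with random scores
  jit <- truth
  jit$cx <- jit$cx + runif(12, -6, 6)
  jit$cy <- jit$cy + runif(12, -6, 6)
  noise <- tibble::tibble(cx = runif(8, 20, 200), cy = runif(8, 20, 200),
                          w = 12, h = 12, image = sample(1:3, 8, TRUE))
  det <- dplyr::bind_rows(jit, noise)
  det$score <- runif(nrow(det))
  ev <- evaluate(det, truth, interpolation = "all")
  # brute force: greedy-match once (same order), then integrate the
  # exact PR steps
  curve <- ev$curve
  ap_bf <- 0
  prev_r <- 0
  env <- rev(cummax(rev(curve$precision)))
  for (i in seq_len(nrow(curve))) {
    ap_bf <- ap_bf + (curve$recall[i] - prev_r) * env[i]
    prev_r <- curve$recall[i]
  }
  expect_equal(ev$metrics$ap, ap_bf, tolerance = 1e-9)
  # 101-point version is within a grid-quantisation step of the exact area
  ev101 <- evaluate(det, truth, interpolation = "101")
  expect_lt(abs(ev101$metrics$ap - ap_bf), 0.05)
})

test_that("evaluate is invariant to detection row order (score ties)", {
  set.seed(52)
  truth <- tibble::tibble(cx = c(30, 70, 110), cy = c(30, 70, 110),
                          w = 10, h = 10, image = 1L)
  det <- tibble::tibble(cx = c(30, 31, 70, 150), cy = c(30, 30, 70, 150),
                        w = 10, h = 10, image = 1L,
                        score = c(0.5, 0.5, 0.5, 0.5))  # all tied
  e1 <- evaluate(det, truth)
  for (perm in list(c(4, 3, 2, 1), c(2, 1, 4, 3), sample(4))) {
    e2 <- evaluate(det[perm, ], truth)
    expect_equal(e2$metrics, e1$metrics)
  }
  # the tied duplicate pair resolves to 1 TP + 1 FP by best-IoU
  expect_equal(e1$metrics$tp, 2L)
  expect_equal(e1$metrics$fp, 2L)
})

test_that("evaluate handles edge cases with flags", {
  det <- bbox(10, 10, 5, 5); det$image <- 1L; det$score <- 0.5
  none <- tibble::tibble(cx = numeric(0), cy = numeric(0), w = numeric(0),
                         h = numeric(0), image = integer(0))
  ev <- evaluate(det, none)
  expect_true(is.na(ev$metrics$recall))
  expect_match(ev$note, "no ground truth")
  truth <- bbox(10, 10, 5, 5); truth$image <- 1L
  ev2 <- evaluate(none %>% dplyr::mutate(score = numeric(0)), truth)
  expect_equal(ev2$metrics$recall, 0)
  expect_equal(ev2$metrics$ap, 0)
})

test_that("tidy/glance/autoplot methods work on evaluations", {
  truth <- bbox(c(20, 60), c(20, 60), 10, 10); truth$image <- 1L
  det <- truth; det$score <- c(0.9, 0.8)
  ev <- evaluate(det, truth)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_named(tidy(ev), c("score", "precision", "recall"))
  expect_equal(glance(ev), ev$metrics)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})

test_that("nms suppresses overlapping duplicates", {
  det <- tibble::tibble(cx = c(50, 52, 120), cy = c(50, 50, 120),
                        w = 20, h = 20, image = 1L,
                        score = c(0.9, 0.7, 0.8))
  kept <- nodulite:::nms_one(det[order(-det$score), ], iou_thresh = 0.45,
                             max_det = 10)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$cx, c(50, 120))
})

test_that("a tiny training run decreases the loss deterministically", {
  set.seed(60)
  img <- matrix(0.1, 64, 64)
  img[28:40, 20:32] <- 0.9
  img2 <- matrix(0.1, 64, 64)
  img2[10:22, 40:52] <- 0.9
  ds <- list(images = list(img, img2),
             boxes = list(bbox(26, 34, 13, 13), bbox(46, 16, 13, 13)))
  run <- function(seed) {
    m <- build_detector(tiny_config(), seed = seed)
    train(m, ds, cfg = train_config(epochs = 6, batch_size = 2,
                                    seed = seed, box_gain = 5,
                                    clip_norm = 0))
  }
  fit <- run(0)
  expect_s3_class(fit, "nodulite_fit")
  expect_equal(nrow(fit$trace), 6)
  expect_lt(fit$trace$loss[6], fit$trace$loss[1])
  expect_true(all(is.finite(fit$trace$loss)))
  # identical seeds reproduce the trace exactly
  fit2 <- run(0)
  expect_identical(fit$trace, fit2$trace)
  # different seed gives a different trajectory
  fit3 <- run(1)
  expect_false(identical(fit$trace$loss, fit3$trace$loss))
  # tidy/glance accessors
  expect_equal(tidy(fit), fit$trace)
  expect_equal(glance(fit)$final_loss, fit$trace$loss[6])
})

test_that("both loss modes train and detect end to end", {
  set.seed(61)
  img <- matrix(0.1, 64, 64)
  img[28:40, 20:32] <- 0.9
  ds <- list(images = list(img), boxes = list(bbox(26, 34, 13, 13)))
  for (lm in c("ciou", "f_nwd")) {
    m <- build_detector(tiny_config(loss_mode = lm), seed = 0)
    fit <- train(m, ds, cfg = train_config(epochs = 4, batch_size = 1,
                                           seed = 0, box_gain = 5,
                                           clip_norm = 0))
    expect_true(all(is.finite(fit$trace$loss)))
    dets <- detect(fit, ds$images, conf_thresh = 0.01)
    expect_true(is.data.frame(dets))
    if (nrow(dets)) {
      expect_true(all(dets$w > 0 & dets$h > 0))
      expect_true(all(dets$score > 0.01))
    }
  }
})

test_that("run_ablation covers all 8 combinations with correct counts", {
  set.seed(62)
  img <- matrix(0.1, 64, 64); img[28:40, 20:32] <- 0.9
  ds <- list(images = list(img), boxes = list(bbox(26, 34, 13, 13)))
  tab <- run_ablation(ds, ds,
                      model_args = list(input_size = 64,
                                        width_multiple = 0.25),
                      train_cfg = train_config(epochs = 1, batch_size = 1,
                                               seed = 0),
                      seed = 0)
  expect_equal(nrow(tab), 8)
  expect_equal(nrow(dplyr::distinct(tab, use_c3_odc, use_gs_bifpn,
                                    loss_mode)), 8)
  # params/flops agree with direct counting and ignore the loss mode
  for (i in seq_len(nrow(tab))) {
    m <- build_detector(model_config(input_size = 64, width_multiple = 0.25,
                                     use_c3_odc = tab$use_c3_odc[i],
                                     use_gs_bifpn = tab$use_gs_bifpn[i]),
                        seed = 0)
    expect_equal(tab$params[i], count_params(m))
    expect_equal(tab$flops[i], count_flops(m))
  }
  wide <- tidyr::pivot_wider(tab, names_from = loss_mode,
                             values_from = c(map, precision, recall))
  expect_equal(nrow(wide), 4)
})

test_that("train aborts cleanly when the loss goes non-finite", {
  # a NaN pixel propagates to the heads, so detection_loss must report a
  # non-finite total and train must stop with a clear message
  img <- matrix(0.5, 64, 64)
  img[1, 1] <- NaN
  ds <- list(images = list(img), boxes = list(bbox(32, 32, 10, 10)))
  m <- build_detector(tiny_config(), seed = 0)
  expect_error(
    train(m, ds, cfg = train_config(epochs = 3, batch_size = 1, seed = 0)),
    "NaN|Inf|aborting")
})
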