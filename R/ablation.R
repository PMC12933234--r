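# Ablation driver: trains and evaluates every combination of the three
# improvements (C3_ODC backbone blocks, GS-BiFPN neck, F-NWD loss) and
# tabulates mAP alongside analytic parameter/FLOP counts.

#' Run the full ablation grid
#'
#' Builds, trains and evaluates all 8 combinations of
#' `use_c3_odc` x `use_gs_bifpn` x loss (`ciou`/`f_nwd`) with a shared
#' seed and training budget, and returns one row per combination.
#'
#' @param train_data,test_data Datasets as from [load_dataset()].
#' @param model_args Named list of [model_config()] overrides shared by
#'   every run (e.g. `list(input_size = 128, width_multiple = 0.25)`).
#' @param train_cfg A [train_config()]. The default uses the package's
#'   tiny-run recipe (`box_gain = 5`, `obj_gain = 100`, `clip_norm = 0`),
#'   which is calibrated for short CPU runs; see the methods vignette.
#' @param seed Seed for model initialisation (training uses
#'   `train_cfg$seed`).
#' @param conf_thresh,iou_thresh Inference thresholds passed to [detect()].
#' @param verbose Print one line per combination.
#' @return A tibble with `use_c3_odc`, `use_gs_bifpn`, `loss_mode`,
#'   `params`, `flops`, `map`, `precision`, `recall`.
#' @export
run_ablation <- function(train_data, test_data, model_args = list(),
                         train_cfg = train_config(epochs = 5, box_gain = 5,
                                                  obj_gain = 100,
                                                  clip_norm = 0),
                         seed = 0,
                         conf_thresh = 0.05, iou_thresh = 0.45,
                         verbose = FALSE) {
  grid <- expand.grid(use_c3_odc = c(FALSE, TRUE),
                      use_gs_bifpn = c(FALSE, TRUE),
                      loss_mode = c("ciou", "f_nwd"),
                      stringsAsFactors = FALSE)
  truth <- boxes_with_image(test_data$boxes)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- utils::modifyList(model_args, list(
      use_c3_odc = grid$use_c3_odc[i],
      use_gs_bifpn = grid$use_gs_bifpn[i],
      loss_mode = grid$loss_mode[i]))
    cfg <- do.call(model_config, args)
    model <- build_detector(cfg, seed = seed)
    fit <- train(model, train_data, cfg = train_cfg)
    dets <- detect(fit, test_data$images, conf_thresh = conf_thresh,
                   iou_thresh = iou_thresh)
    ev <- evaluate(dets, truth)
    rows[[i]] <- tibble::tibble(
      use_c3_odc = grid$use_c3_odc[i],
      use_gs_bifpn = grid$use_gs_bifpn[i],
      loss_mode = grid$loss_mode[i],
      params = count_params(model),
      flops = count_flops(model),
      map = ev$metrics$map,
      precision = ev$metrics$precision,
      recall = ev$metrics$recall)
    if (verbose) {
      message(sprintf("odc=%d bifpn=%d %-5s | %.2fM params %.2fG FLOPs | mAP %.3f",
                      grid$use_c3_odc[i], grid$use_gs_bifpn[i],
                      grid$loss_mode[i], rows[[i]]$params / 1e6,
                      rows[[i]]$flops / 1e9, rows[[i]]$map))
    }
  }
  dplyr::bind_rows(rows)
}

# stack a list of per-image box tibbles into one tibble with `image` ids
boxes_with_image <- function(box_list) {
  dplyr::bind_rows(lapply(seq_along(box_list), function(i) {
    b <- box_list[[i]]
    if (nrow(b)) b$image <- i
    b
  }))
}
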