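# CT preprocessing: lung-parenchyma segmentation, world-coordinate nodule
# annotations to per-slice pixel boxes, and detector-ready slice/label
# export. Segmentation is slice-wise (the detector is slice-based):
# denoise -> HU window -> binarise -> drop border-touching air -> keep the
# two largest interior low-density components -> close + fill holes.

#' Segmentation configuration for [segment_parenchyma()]
#'
#' @param hu_window HU clipping window applied before thresholding.
#' @param threshold Binarisation threshold in HU separating air/lung from
#'   soft tissue (default -320).
#' @param median_radius Radius of the median denoising filter (voxels).
#' @param closing_radius Radius of the morphological closing brush
#'   (pixels). The default is deliberately generous so that dense nodules
#'   whose cross-section touches the in-plane lung boundary are sealed
#'   into the mask rather than cut out; it trades a slightly looser lung
#'   contour for full nodule retention.
#' @param max_components Number of interior low-density components to keep
#'   per slice (the two lung fields).
#' @return A list of settings.
#' @export
prep_config <- function(hu_window = c(-1000, 400), threshold = -320,
                        median_radius = 1, closing_radius = 9,
                        max_components = 2) {
  list(hu_window = hu_window, threshold = threshold,
       median_radius = median_radius, closing_radius = closing_radius,
       max_components = max_components)
}

#' Segment the lung parenchyma of a CT volume
#'
#' Slice-wise segmentation of the two low-density lung fields: median
#' denoise, clip to the HU window, threshold, discard low-density
#' components touching the image border (outside air), keep the largest
#' interior components, then morphological closing and hole filling. The
#' union over slices is the parenchyma mask.
#'
#' @param vol A [ct_volume()] in HU.
#' @param cfg A [prep_config()].
#' @return A binary array (0/1) with the volume's shape. If no interior
#'   component exists anywhere a warning is raised and an empty mask
#'   returned.
#' @export
segment_parenchyma <- function(vol, cfg = prep_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  mask <- array(0L, dim = d)
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  brush <- EBImage::makeBrush(2 * cfg$closing_radius + 1, shape = "disc")
  for (k in seq_len(d[1])) {
    sl <- vol$voxels[k, , ]
    img <- (pmin(pmax(sl, lo), hi) - lo) / (hi - lo)
    if (cfg$median_radius > 0) {
      img <- EBImage::medianFilter(img, cfg$median_radius)
    }
    hu <- img * (hi - lo) + lo
    low <- hu < cfg$threshold
    if (!any(low)) next
    lab <- EBImage::bwlabel(low)
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labels <- setdiff(border_labels, 0)
    interior <- lab
    interior[interior %in% border_labels] <- 0L
    if (!any(interior > 0)) next
    sizes <- table(interior[interior > 0])
    keep <- as.integer(names(sort(sizes, decreasing = TRUE)))
    keep <- keep[seq_len(min(cfg$max_components, length(keep)))]
    m <- matrix(as.integer(interior %in% keep), nrow(lab), ncol(lab))
    m <- EBImage::closing(m, brush)
    m <- EBImage::fillHull(m)
    mask[k, , ] <- as.integer(m > 0)
  }
  if (!any(mask > 0)) warning("no interior lung component found; empty mask")
  mask
}

#' Mask a volume, filling voxels outside the mask
#'
#' @param vol A [ct_volume()].
#' @param mask Binary array of the same shape (e.g. from
#'   [segment_parenchyma()]).
#' @param fill_value HU value for voxels outside the mask (default air).
#' @return A masked [ct_volume()].
#' @export
apply_mask <- function(vol, mask, fill_value = -1000) {
  if (!identical(dim(vol$voxels), dim(mask))) {
    stop("mask shape does not match volume", call. = FALSE)
  }
  v <- vol$voxels
  v[mask == 0] <- fill_value
  ct_volume(v, vol$spacing, vol$origin, vol$series_id)
}

#' Convert world-mm nodule annotations to per-slice pixel boxes
#'
#' The annotation center is mapped to continuous 0-based voxel coordinates
#' (`(world - origin) / spacing` per axis). A nodule of diameter `d` mm
#' spans the slices within `d / (2 sz)` of its center slice; on each
#' spanned slice the box is centered at `(vx, vy)` with width `d / sx` and
#' height `d / sy` pixels.
#'
#' @param ann Data frame with columns `world_x`, `world_y`, `world_z`,
#'   `diameter` (mm), and optionally `series_id`.
#' @param vol The matching [ct_volume()].
#' @return A tibble with columns `slice` (0-based z index), `cx`, `cy`,
#'   `w`, `h` (pixels), and `annotation` (row index into `ann`).
#'   Annotations outside the volume are skipped with a message.
#' @export
annotation_to_boxes <- function(ann, vol) {
  stopifnot(all(c("world_x", "world_y", "world_z", "diameter") %in% names(ann)))
  if (any(ann$diameter <= 0)) stop("annotation diameter must be positive", call. = FALSE)
  d <- dim(vol$voxels)
  vox <- world_to_voxel(vol, ann)
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (vox$vx[i] < 0 || vox$vx[i] > d[3] - 1 ||
        vox$vy[i] < 0 || vox$vy[i] > d[2] - 1 ||
        vox$vz[i] < 0 || vox$vz[i] > d[1] - 1) {
      message("annotation ", i, " outside volume bounds for ", vol$series_id,
              "; skipped")
      next
    }
    half_z <- ann$diameter[i] / (2 * vol$spacing[1])
    z0 <- max(0L, as.integer(ceiling(vox$vz[i] - half_z)))
    z1 <- min(d[1] - 1L, as.integer(floor(vox$vz[i] + half_z)))
    if (z1 < z0) next
    out[[i]] <- tibble::tibble(
      slice = z0:z1,
      cx = vox$vx[i], cy = vox$vy[i],
      w = ann$diameter[i] / vol$spacing[3],
      h = ann$diameter[i] / vol$spacing[2],
      annotation = i
    )
  }
  dplyr::bind_rows(out)
}

#' Export detector-ready slices and YOLO-format labels
#'
#' Writes one 8-bit grayscale PNG per exported slice (HU window mapped to
#' `[0, 255]`) and, for slices with boxes, a label text file with lines
#' `class cx cy w h` normalized to `[0, 1]`. File names are
#' `<series>_z<index>`. By default only nodule-bearing slices plus one
#' neighbour on each side are exported; `all_slices = TRUE` exports the
#' whole stack (empty slices become negatives without a label file).
#'
#' @param vol A [ct_volume()] (typically parenchyma-masked).
#' @param boxes Per-slice boxes from [annotation_to_boxes()] (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param hu_window HU display window for the PNG mapping.
#' @param all_slices Export every slice instead of nodule neighbourhoods.
#' @return A tibble with `slice`, `image`, `label` (label is `NA` for
#'   negative slices).
#' @export
export_slices <- function(vol, boxes, out_dir, hu_window = c(-1000, 400),
                          all_slices = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  if (all_slices) {
    keep <- 0:(d[1] - 1)
  } else {
    keep <- sort(unique(unlist(lapply(boxes$slice, function(s) s + (-1:1)))))
    keep <- keep[keep >= 0 & keep <= d[1] - 1]
  }
  lo <- hu_window[1]; hi <- hu_window[2]
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    img <- (pmin(pmax(vol$voxels[k + 1, , ], lo), hi) - lo) / (hi - lo)
    stem <- sprintf("%s_z%04d", vol$series_id, k)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    png::writePNG(img, img_path)
    b <- boxes[boxes$slice == k, , drop = FALSE]
    lbl_path <- NA_character_
    if (nrow(b) > 0) {
      lbl_path <- file.path(out_dir, paste0(stem, ".txt"))
      lines <- sprintf("%d %.8f %.8f %.8f %.8f", 0L,
                       b$cx / d[3], b$cy / d[2], b$w / d[3], b$h / d[2])
      writeLines(lines, lbl_path)
    }
    rows[[j]] <- tibble::tibble(slice = k, image = img_path, label = lbl_path)
  }
  dplyr::bind_rows(rows)
}

#' Parse a YOLO-format label file back into pixel boxes
#'
#' @param path Label file path (`class cx cy w h`, normalized).
#' @param width,height Image size in pixels for denormalisation.
#' @return A tibble of boxes with a `class` column; zero rows if the file
#'   is missing.
#' @export
read_yolo_labels <- function(path, width, height) {
  if (is.na(path) || !file.exists(path)) {
    return(tibble::tibble(class = integer(0), cx = numeric(0), cy = numeric(0),
                          w = numeric(0), h = numeric(0)))
  }
  m <- utils::read.table(path)
  tibble::tibble(class = as.integer(m[[1]]), cx = m[[2]] * width,
                 cy = m[[3]] * height, w = m[[4]] * width, h = m[[5]] * height)
}

#' Read a LUNA16-dialect annotation CSV
#'
#' Expects the header `seriesuid,coordX,coordY,coordZ,diameter_mm` and
#' returns tidy column names used throughout the package.
#'
#' @param path CSV path.
#' @return A tibble with `series_id`, `world_x`, `world_y`, `world_z`,
#'   `diameter`.
#' @export
read_annotations <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  if (!all(need %in% names(a))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::tibble(series_id = a$seriesuid, world_x = a$coordX,
                 world_y = a$coordY, world_z = a$coordZ,
                 diameter = a$diameter_mm)
}

#' Deterministic series-disjoint train/test split
#'
#' @param series_ids Character vector of scan identifiers.
#' @param ratio Fraction of series assigned to training (default 0.8).
#' @param seed Integer seed controlling the shuffle.
#' @return A tibble with `series_id` and `split` (`"train"`/`"test"`).
#' @export
series_split <- function(series_ids, ratio = 0.8, seed = 0) {
  ids <- sort(unique(series_ids))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(ids)
  n_train <- max(1L, floor(length(ids) * ratio))
  tibble::tibble(series_id = shuffled,
                 split = rep(c("train", "test"),
                             c(n_train, length(ids) - n_train))) |>
    dplyr::arrange(.data$series_id)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the full preprocessing pipeline over a directory of volumes
#'
#' Reads every `.mhd` volume under `input_dir`, segments and masks the lung
#' parenchyma, converts the matching annotations to per-slice boxes, and
#' exports slices/labels to `out_dir/<split>` with a deterministic
#' series-disjoint 8:2 split.
#'
#' @param input_dir Directory containing `.mhd`/`.raw` volumes.
#' @param annotations Annotation tibble ([read_annotations()]) or CSV path.
#' @param out_dir Output root.
#' @param seed Split seed.
#' @param cfg A [prep_config()].
#' @param mask_lungs Apply the parenchyma mask before export.
#' @return A tibble of exported files with `series_id` and `split`.
#' @export
prep_dataset <- function(input_dir, annotations, out_dir, seed = 0,
                         cfg = prep_config(), mask_lungs = TRUE) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  headers <- sort(list.files(input_dir, pattern = "\\.mhd$", full.names = TRUE))
  if (length(headers) == 0) stop("no .mhd volumes under ", input_dir, call. = FALSE)
  series <- sub("\\.mhd$", "", basename(headers))
  split <- series_split(series, 0.8, seed)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    vol <- read_mhd(headers[i])
    if (mask_lungs) {
      mask <- segment_parenchyma(vol, cfg)
      vol <- apply_mask(vol, mask)
    }
    ann <- annotations[annotations$series_id == vol$series_id, , drop = FALSE]
    boxes <- annotation_to_boxes(ann, vol)
    sp <- split$split[split$series_id == vol$series_id]
    files <- export_slices(vol, boxes, file.path(out_dir, sp),
                           hu_window = cfg$hu_window)
    if (nrow(files)) {
      files$series_id <- vol$series_id
      files$split <- sp
    }
    out[[i]] <- files
  }
  dplyr::bind_rows(out)
}
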