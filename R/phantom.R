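# Synthetic CT phantoms shaped like LUNA16 data: an elliptical body at soft
# tissue density over an air background, two low-density lung fields,
# bright tubular vessels, and bright spherical nodules annotated in world
# millimetres. Everything is reproducible from the spec seed.

#' Phantom specification
#'
#' Defaults model a desk-scale thorax: 24 x 128 x 128 voxels at
#' 5 x 1.25 x 1.25 mm, air -1000 HU, lung fields -800 HU, body +40 HU,
#' vessels +30 HU, nodules +60 HU, and 20 HU Gaussian noise — densities
#' chosen so the -320 HU parenchyma threshold is exercised realistically.
#' `difficulty = "tiny"` switches to 4-7 mm nodules (3-6 px in plane), the
#' hard small-object case.
#'
#' @param dims Volume shape `(z, y, x)` in voxels.
#' @param spacing Voxel spacing `(sz, sy, sx)` mm.
#' @param n_nodules Number of nodules to place.
#' @param diameter_range Nodule diameter range in mm.
#' @param nodule_hu,lung_hu,body_hu,vessel_hu,air_hu Tissue densities (HU).
#' @param vessel_count Number of tubular vessels per lung pair.
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param difficulty `"easy"` (default diameters) or `"tiny"` (3-6 px
#'   nodules).
#' @param seed Integer seed fixing all randomness of the phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(24, 128, 128), spacing = c(5, 1.25, 1.25),
                         n_nodules = 2, diameter_range = c(12, 22),
                         nodule_hu = 60, lung_hu = -800, body_hu = 40,
                         vessel_hu = 30, air_hu = -1000, vessel_count = 6,
                         noise_sd = 20, difficulty = c("easy", "tiny"),
                         seed = 0) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "tiny") diameter_range <- c(4, 7)
  stopifnot(length(dims) == 3, all(dims >= 1), all(spacing > 0),
            diameter_range[1] > 0, diameter_range[2] >= diameter_range[1])
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 n_nodules = n_nodules, diameter_range = diameter_range,
                 nodule_hu = nodule_hu, lung_hu = lung_hu, body_hu = body_hu,
                 vessel_hu = vessel_hu, air_hu = air_hu,
                 vessel_count = vessel_count, noise_sd = noise_sd,
                 difficulty = difficulty, seed = seed),
            class = "phantom_spec")
}

# ellipsoid membership field over the voxel grid; returns logical array
ellipsoid_mask <- function(dims, center, semi) {
  z <- ((seq_len(dims[1]) - 1) - center[1]) / semi[1]
  y <- ((seq_len(dims[2]) - 1) - center[2]) / semi[2]
  x <- ((seq_len(dims[3]) - 1) - center[3]) / semi[3]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= 1
}

#' Generate a synthetic CT phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [ct_volume()]), `annotations` (tibble
#'   in LUNA16 dialect columns: `series_id`, `world_x`, `world_y`,
#'   `world_z`, `diameter`), and `lung_mask` (ground-truth binary array of
#'   the two lung fields).
#' @export
generate_phantom <- function(spec = phantom_spec(), series_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  d <- spec$dims
  series_id <- series_id %||% sprintf("phantom_%06d", spec$seed)
  vox <- array(spec$air_hu, dim = d)
  center <- (d - 1) / 2
  body <- ellipsoid_mask(d, center, c(0.60 * d[1], 0.42 * d[2], 0.46 * d[3]))
  vox[body] <- spec$body_hu
  lungs <- vector("list", 2)
  lung_semi <- c(0.42 * d[1], 0.30 * d[2], 0.18 * d[3])
  offsets <- c(-0.21, 0.21) * d[3]
  lung_mask <- array(FALSE, dim = d)
  for (s in 1:2) {
    lc <- c(center[1], center[2], center[3] + offsets[s])
    lungs[[s]] <- list(center = lc, semi = lung_semi)
    m <- ellipsoid_mask(d, lc, lung_semi)
    vox[m] <- spec$lung_hu
    lung_mask <- lung_mask | m
  }
  # vessels: short tubes inside the lungs, mostly along z
  zc <- array(rep((seq_len(d[1]) - 1), times = d[2] * d[3]), dim = d)
  yc <- array(rep(rep((seq_len(d[2]) - 1), each = d[1]), times = d[3]), dim = d)
  xc <- array(rep((seq_len(d[3]) - 1), each = d[1] * d[2]), dim = d)
  in_lung <- which(lung_mask)
  for (v in seq_len(spec$vessel_count)) {
    side <- lungs[[1 + (v %% 2)]]
    u <- stats::runif(3, -0.5, 0.5) * side$semi
    p0 <- side$center + u
    dirv <- c(1, stats::runif(1, -0.15, 0.15), stats::runif(1, -0.15, 0.15))
    dirv <- dirv / sqrt(sum(dirv^2))
    len <- stats::runif(1, 0.4, 0.9) * d[1]
    radius <- stats::runif(1, 1.0, 1.8)
    rel <- cbind(zc[in_lung] - p0[1], yc[in_lung] - p0[2], xc[in_lung] - p0[3])
    t <- pmin(pmax(rel %*% dirv, -len / 2), len / 2)
    # anisotropic voxels: measure the tube radius in-plane (y, x)
    dy <- rel[, 2] - t * dirv[2]
    dx <- rel[, 3] - t * dirv[3]
    dz <- (rel[, 1] - t * dirv[1]) * spec$spacing[1] / spec$spacing[2]
    hit <- (dz^2 + dy^2 + dx^2) <= radius^2
    vox[in_lung[hit]] <- spec$vessel_hu
  }
  # nodules: spheres (in world mm) fully inside a lung field
  ann <- list()
  for (i in seq_len(spec$n_nodules)) {
    dia <- stats::runif(1, spec$diameter_range[1], spec$diameter_range[2])
    placed <- FALSE
    for (try in seq_len(200)) {
      side <- lungs[[1 + (i + try) %% 2]]
      u <- stats::runif(3, -1, 1)
      cand <- side$center + u * side$semi * 0.75
      rv <- dia / 2 / spec$spacing       # radius in voxels per axis
      # require the sphere to fit inside the lung ellipsoid with margin
      q <- sum(((cand - side$center) / (side$semi - rv - 0.5))^2)
      if (any(side$semi - rv - 0.5 <= 0) || q > 1) next
      sph <- ((zc - cand[1]) / rv[1])^2 + ((yc - cand[2]) / rv[2])^2 +
        ((xc - cand[3]) / rv[3])^2 <= 1
      vox[sph] <- spec$nodule_hu
      ann[[length(ann) + 1]] <- tibble::tibble(vz = cand[1], vy = cand[2],
                                               vx = cand[3], diameter = dia)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place nodule ", i, " after bounded retries",
                      call. = FALSE)
  }
  if (spec$noise_sd > 0) {
    vox <- vox + stats::rnorm(length(vox), sd = spec$noise_sd)
  }
  origin <- -(d - 1) * spec$spacing / 2   # centred world frame
  vol <- ct_volume(vox, spacing = spec$spacing, origin = origin,
                   series_id = series_id)
  annotations <- if (length(ann)) {
    a <- dplyr::bind_rows(ann)
    w <- voxel_to_world(vol, a)
    tibble::tibble(series_id = series_id, world_x = w$world_x,
                   world_y = w$world_y, world_z = w$world_z,
                   diameter = a$diameter)
  } else {
    tibble::tibble(series_id = character(0), world_x = numeric(0),
                   world_y = numeric(0), world_z = numeric(0),
                   diameter = numeric(0))
  }
  list(volume = vol, annotations = annotations,
       lung_mask = array(as.integer(lung_mask), dim = d))
}

#' Generate a LUNA16-shaped dataset of phantom volumes
#'
#' Writes `n_volumes` MetaImage volumes plus a single `annotations.csv`
#' (header `seriesuid,coordX,coordY,coordZ,diameter_mm`) under `out_dir`.
#' Per-volume seeds are derived from the template's seed so the dataset is
#' fully reproducible.
#'
#' @param n_volumes Number of volumes.
#' @param spec Template [phantom_spec()]; its `seed` is the master seed.
#' @param out_dir Output directory.
#' @return A tibble with `series_id`, `path`, and nodule counts.
#' @export
generate_dataset <- function(n_volumes, spec = phantom_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_volumes)
  anns <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    sp <- spec
    sp$seed <- (spec$seed * 1009L + i) %% .Machine$integer.max
    sid <- sprintf("phantom_%03d", i)
    ph <- generate_phantom(sp, series_id = sid)
    write_mhd(ph$volume, file.path(out_dir, sid))
    anns[[i]] <- ph$annotations
    rows[[i]] <- tibble::tibble(series_id = sid,
                                path = file.path(out_dir, paste0(sid, ".mhd")),
                                n_nodules = nrow(ph$annotations))
  }
  all_ann <- dplyr::bind_rows(anns)
  utils::write.csv(
    data.frame(seriesuid = all_ann$series_id, coordX = all_ann$world_x,
               coordY = all_ann$world_y, coordZ = all_ann$world_z,
               diameter_mm = all_ann$diameter),
    file.path(out_dir, "annotations.csv"), row.names = FALSE)
  dplyr::bind_rows(rows)
}
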