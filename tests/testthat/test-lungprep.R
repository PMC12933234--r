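# MetaImage I/O, coordinate transforms, parenchyma segmentation, and the
# annotation -> slice/label export pipeline.

test_that("MetaImage volumes round-trip losslessly", {
  set.seed(40)
  vox <- array(round(runif(6 * 8 * 10, -1000, 400)), dim = c(6, 8, 10))
  vol <- ct_volume(vox, spacing = c(2.5, 0.7, 0.7),
                   origin = c(-100, -195, -198), series_id = "rt")
  path <- file.path(tempdir(), "rt")
  write_mhd(vol, path)
  back <- read_mhd(paste0(path, ".mhd"))
  expect_equal(back$voxels, vox)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
  expect_equal(back$series_id, "rt")
  # float element type preserves fractions
  volf <- ct_volume(vox + 0.25, spacing = c(1, 1, 1))
  write_mhd(volf, file.path(tempdir(), "rtf"), element_type = "MET_FLOAT")
  backf <- read_mhd(file.path(tempdir(), "rtf.mhd"))
  expect_equal(backf$voxels, vox + 0.25, tolerance = 1e-6)
})

test_that("MHD header stores x,y,z order while volumes use z,y,x", {
  vox <- array(0, dim = c(4, 6, 8))  # z=4, y=6, x=8
  vol <- ct_volume(vox, spacing = c(3, 2, 1), origin = c(30, 20, 10))
  path <- file.path(tempdir(), "ord")
  write_mhd(vol, path)
  hdr <- readLines(paste0(path, ".mhd"))
  expect_true(any(grepl("^DimSize = 8 6 4$", hdr)))
  expect_true(any(grepl("^ElementSpacing = 1 2 3$", hdr)))
  expect_true(any(grepl("^Offset = 10 20 30$", hdr)))
  # raw block: x varies fastest -> one x-row is contiguous
  vol2 <- ct_volume(array(seq_len(4 * 6 * 8), dim = c(4, 6, 8)))
  write_mhd(vol2, file.path(tempdir(), "ord2"))
  con <- file(file.path(tempdir(), "ord2.raw"), "rb")
  first_row <- readBin(con, integer(), 8, size = 2)
  close(con)
  expect_equal(first_row, vol2$voxels[1, 1, ])
})

test_that("read_mhd agrees with the SimpleITK oracle when available", {
  has_sitk <- nzchar(Sys.which("python3")) &&
    system2("python3", c("-c", shQuote("import SimpleITK")),
            stdout = FALSE, stderr = FALSE) == 0
  skip_if_not(has_sitk, "python3 + SimpleITK not available")
  set.seed(41)
  vox <- array(round(runif(5 * 7 * 9, -1000, 400)), dim = c(5, 7, 9))
  vol <- ct_volume(vox, spacing = c(2, 0.8, 0.6), origin = c(-5, -2, -1))
  path <- file.path(tempdir(), "sitk")
  write_mhd(vol, path)
  script <- sprintf(paste0(
    "import SimpleITK as sitk, json\n",
    "img = sitk.ReadImage('%s.mhd')\n",
    "a = sitk.GetArrayFromImage(img)\n",  # numpy order (z, y, x)
    "print(json.dumps({'shape': list(a.shape),",
    " 'spacing': list(img.GetSpacing()),",
    " 'origin': list(img.GetOrigin()),",
    " 'sum': int(a.sum()), 'v000': int(a[0,0,0]),",
    " 'v123': int(a[1,2,3])}))"), path)
  out <- system2("python3", c("-c", shQuote(script)), stdout = TRUE)
  ref <- jsonlite::fromJSON(out[length(out)])
  expect_equal(ref$shape, c(5, 7, 9))
  expect_equal(ref$spacing, c(0.6, 0.8, 2))  # sitk reports (x, y, z)
  expect_equal(ref$origin, c(-1, -2, -5))
  expect_equal(ref$sum, sum(vox))
  expect_equal(ref$v000, vox[1, 1, 1])
  expect_equal(ref$v123, vox[2, 3, 4])
})

test_that("world/voxel transforms invert each other and use spacing", {
  vol <- ct_volume(array(0, dim = c(4, 6, 8)), spacing = c(5, 1.25, 2),
                   origin = c(-10, -20, -30))
  w <- tibble::tibble(world_x = c(-30, -26), world_y = c(-20, -17.5),
                      world_z = c(-10, 0))
  v <- world_to_voxel(vol, w)
  expect_equal(v$vx, c(0, 2))
  expect_equal(v$vy, c(0, 2))
  expect_equal(v$vz, c(0, 2))
  expect_equal(voxel_to_world(vol, v), w)
})

test_that("segment_parenchyma recovers the phantom lung fields (Dice)", {
  ph <- generate_phantom(phantom_spec(seed = 3, n_nodules = 2))
  mask <- segment_parenchyma(ph$volume)
  inter <- sum(mask == 1 & ph$lung_mask == 1)
  dice <- 2 * inter / (sum(mask) + sum(ph$lung_mask))
  expect_gt(dice, 0.90)
  # masking fills everything outside with the fill value
  masked <- apply_mask(ph$volume, mask)
  expect_true(all(masked$voxels[mask == 0] == -1000))
  expect_equal(masked$voxels[mask == 1], ph$volume$voxels[mask == 1])
  expect_error(apply_mask(ph$volume, mask[1:2, , ]), "shape")
})

test_that("annotation_to_boxes implements the slice-extent formula", {
  vol <- ct_volume(array(0, dim = c(10, 64, 64)), spacing = c(5, 1, 2),
                   origin = c(0, 0, 0))
  # center at voxel (vz=4, vy=10, vx=5), diameter 12mm
  ann <- tibble::tibble(world_x = 10, world_y = 10, world_z = 20,
                        diameter = 12)
  b <- annotation_to_boxes(ann, vol)
  # half_z = 12 / (2*5) = 1.2 -> slices ceil(2.8)..floor(5.2) = 3..5
  expect_equal(b$slice, 3:5)
  expect_equal(unique(b$cx), 5)   # 10mm / 2mm spacing
  expect_equal(unique(b$cy), 10)
  expect_equal(unique(b$w), 6)    # 12mm / 2mm
  expect_equal(unique(b$h), 12)   # 12mm / 1mm
  # out-of-bounds annotations are skipped with a message
  bad <- tibble::tibble(world_x = 500, world_y = 10, world_z = 20,
                        diameter = 5)
  expect_message(b2 <- annotation_to_boxes(bad, vol), "outside")
  expect_equal(nrow(b2), 0)
  expect_error(annotation_to_boxes(
    tibble::tibble(world_x = 1, world_y = 1, world_z = 1, diameter = 0),
    vol), "positive")
})

test_that("exported slices and labels round-trip the boxes", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  boxes <- annotation_to_boxes(ph$annotations, ph$volume)
  out <- file.path(tempdir(), "exp")
  files <- export_slices(ph$volume, boxes, out)
  expect_true(all(file.exists(files$image)))
  pos <- files[!is.na(files$label), ]
  expect_gt(nrow(pos), 0)
  d <- dim(ph$volume$voxels)
  for (i in seq_len(nrow(pos))) {
    back <- read_yolo_labels(pos$label[i], d[3], d[2])
    want <- boxes[boxes$slice == pos$slice[i], ]
    expect_equal(back$cx, want$cx, tolerance = 1e-6)
    expect_equal(back$cy, want$cy, tolerance = 1e-6)
    expect_equal(back$w, want$w, tolerance = 1e-6)
    expect_equal(back$h, want$h, tolerance = 1e-6)
    expect_true(all(back$class == 0))
  }
  # neighbours of nodule slices are exported as negatives
  expect_gt(sum(is.na(files$label)), 0)
  # PNG values encode the HU window
  img <- png::readPNG(pos$image[1])
  expect_true(all(img >= 0 & img <= 1))
})

test_that("segmentation keeps >= 0.95 of nodule-containing lung voxels", {
  # nodules are dense holes in the low-density lung field; the mask must
  # not cut them out (voxel-level recall over the annotation spheres)
  tot <- 0; hit <- 0
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(seed = 100 + s))
    mask <- segment_parenchyma(ph$volume)
    d <- dim(ph$volume$voxels)
    v <- world_to_voxel(ph$volume, ph$annotations)
    zc <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d)
    yc <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d)
    xc <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d)
    for (i in seq_len(nrow(v))) {
      rv <- ph$annotations$diameter[i] / 2 / ph$volume$spacing
      sph <- ((zc - v$vz[i]) / rv[1])^2 + ((yc - v$vy[i]) / rv[2])^2 +
        ((xc - v$vx[i]) / rv[3])^2 <= 1
      tot <- tot + sum(sph)
      hit <- hit + sum(sph & mask == 1)
    }
  }
  expect_gte(hit / tot, 0.95)
})

test_that("series_split is deterministic, disjoint and ~8:2", {
  ids <- sprintf("s%02d", 1:10)
  sp1 <- series_split(ids, 0.8, seed = 1)
  sp2 <- series_split(ids, 0.8, seed = 1)
  expect_identical(sp1, sp2)
  expect_setequal(sp1$series_id, ids)
  expect_equal(sum(sp1$split == "train"), 8)
  expect_equal(sum(sp1$split == "test"), 2)
  sp3 <- series_split(ids, 0.8, seed = 2)
  expect_false(identical(sp1$split, sp3$split))
  # duplicated inputs collapse to unique ids
  expect_equal(nrow(series_split(c(ids, ids), 0.8, 1)), 10)
  # the split leaves the global RNG state untouched
  set.seed(99); before <- .Random.seed
  series_split(ids, 0.8, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("read_annotations validates the LUNA16 header", {
  f <- file.path(tempdir(), "ann.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,1.5,-2,3,8.2"), f)
  a <- read_annotations(f)
  expect_named(a, c("series_id", "world_x", "world_y", "world_z",
                    "diameter"))
  expect_equal(a$diameter, 8.2)
  writeLines("foo,bar\n1,2", f)
  expect_error(read_annotations(f), "columns")
})
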