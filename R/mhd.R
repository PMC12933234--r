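# MetaImage (.mhd/.raw) I/O. The header is a small "Key = value" text file;
# voxel data live in a sidecar raw file, x varying fastest. Volumes are held
# in (z, y, x) order internally, with spacing/origin vectors in the same
# axis order.

#' Construct a CT volume
#'
#' @param voxels 3-D numeric array in `(z, y, x)` order, values in
#'   Hounsfield units.
#' @param spacing Voxel spacing `(sz, sy, sx)` in mm/voxel, all positive.
#' @param origin World-coordinate offset `(oz, oy, ox)` in mm.
#' @param series_id Identifier string for the scan.
#' @return A list of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      series_id = "volume") {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing entries must be positive", call. = FALSE)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), series_id = series_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s: %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g mm, HU [%d, %d]\n",
              x$series_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2],
              x$spacing[3], round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

mhd_element_types <- c(MET_SHORT = "short", MET_FLOAT = "float",
                       MET_DOUBLE = "double", MET_UCHAR = "uchar")

#' Read a MetaImage volume
#'
#' Parses the `.mhd` ASCII header and loads the referenced `.raw` voxel
#' block. Supported element types: `MET_SHORT`, `MET_FLOAT`, `MET_DOUBLE`,
#' `MET_UCHAR`. Header `DimSize`/`ElementSpacing`/`Offset` are in (x, y, z)
#' order per the format; the returned volume uses (z, y, x).
#'
#' @param path Path to the `.mhd` header.
#' @return A [ct_volume()].
#' @export
read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(kv$CompressedData) && tolower(kv$CompressedData) == "true") {
    stop("compressed MetaImage data is not supported", call. = FALSE)
  }
  et <- kv$ElementType %||% "MET_SHORT"
  if (!et %in% names(mhd_element_types)) {
    stop("unsupported ElementType: ", et, call. = FALSE)
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])          # (x, y, z)
  spacing <- as.numeric(strsplit(kv$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(kv$Offset %||% kv$Origin %||% "0 0 0", "\\s+")[[1]])
  raw_file <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_file)) {
    stop("raw data file not found: ", raw_file, call. = FALSE)
  }
  msb <- !is.null(kv$ElementByteOrderMSB) && tolower(kv$ElementByteOrderMSB) == "true"
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  con <- file(raw_file, "rb"); on.exit(close(con))
  v <- switch(et,
    MET_SHORT = readBin(con, integer(), n, size = 2, signed = TRUE, endian = endian),
    MET_UCHAR = readBin(con, integer(), n, size = 1, signed = FALSE, endian = endian),
    MET_FLOAT = readBin(con, numeric(), n, size = 4, endian = endian),
    MET_DOUBLE = readBin(con, numeric(), n, size = 8, endian = endian))
  if (length(v) != n) stop("raw file truncated: ", raw_file, call. = FALSE)
  a <- array(as.numeric(v), dim = dims)       # (x, y, z), x fastest
  ct_volume(aperm(a, c(3, 2, 1)), spacing = rev(spacing), origin = rev(origin),
            series_id = sub("\\.mhd$", "", basename(path)))
}

#' Write a MetaImage volume
#'
#' Writes `<path>.mhd` plus the sidecar `<path>.raw`. Round-trips with
#' [read_mhd()] losslessly for the supported element types.
#'
#' @param vol A [ct_volume()].
#' @param path Output path; the `.mhd` extension is added if absent.
#' @param element_type `MET_SHORT` (default; values are rounded) or
#'   `MET_FLOAT`/`MET_DOUBLE`.
#' @return The header path, invisibly.
#' @export
write_mhd <- function(vol, path, element_type = "MET_SHORT") {
  stopifnot(inherits(vol, "ct_volume"))
  if (!element_type %in% names(mhd_element_types)) {
    stop("unsupported ElementType: ", element_type, call. = FALSE)
  }
  path <- sub("\\.mhd$", "", path)
  hdr <- paste0(path, ".mhd"); raw_path <- paste0(path, ".raw")
  d <- dim(vol$voxels)                          # (z, y, x)
  a <- aperm(vol$voxels, c(3, 2, 1))            # back to x fastest
  con <- file(raw_path, "wb")
  switch(element_type,
    MET_SHORT = writeBin(as.integer(round(a)), con, size = 2, endian = "little"),
    MET_UCHAR = writeBin(as.integer(round(a)), con, size = 1, endian = "little"),
    MET_FLOAT = writeBin(as.numeric(a), con, size = 4, endian = "little"),
    MET_DOUBLE = writeBin(as.numeric(a), con, size = 8, endian = "little"))
  close(con)
  writeLines(c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", d[3], d[2], d[1]),
    paste("ElementSpacing =", vol$spacing[3], vol$spacing[2], vol$spacing[1]),
    paste("Offset =", vol$origin[3], vol$origin[2], vol$origin[1]),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", basename(raw_path))
  ), hdr)
  invisible(hdr)
}

#' Convert world coordinates (mm) to 0-based voxel indices
#'
#' @param vol A [ct_volume()].
#' @param world Data frame with `world_x`, `world_y`, `world_z` columns (mm).
#' @return A tibble with continuous 0-based voxel coordinates `vx`, `vy`, `vz`.
#' @export
world_to_voxel <- function(vol, world) {
  tibble::tibble(
    vx = (world$world_x - vol$origin[3]) / vol$spacing[3],
    vy = (world$world_y - vol$origin[2]) / vol$spacing[2],
    vz = (world$world_z - vol$origin[1]) / vol$spacing[1]
  )
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param vol A [ct_volume()].
#' @param voxel Data frame with `vx`, `vy`, `vz` columns.
#' @return A tibble with `world_x`, `world_y`, `world_z` (mm).
#' @export
voxel_to_world <- function(vol, voxel) {
  tibble::tibble(
    world_x = vol$origin[3] + voxel$vx * vol$spacing[3],
    world_y = vol$origin[2] + voxel$vy * vol$spacing[2],
    world_z = vol$origin[1] + voxel$vz * vol$spacing[1]
  )
}
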