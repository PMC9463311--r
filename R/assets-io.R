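#' Camera intrinsics of a pinhole model
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels (0-based image coordinates).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  stopifnot(is.numeric(fx), is.numeric(fy), is.numeric(cx), is.numeric(cy))
  if (fx <= 0 || fy <= 0) stop("focal lengths fx, fy must be positive")
  if (cx < 0 || cy < 0) stop("principal point cx, cy must be non-negative")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Surgical instrument class registry
#'
#' The 18-instrument set for wisdom teeth extraction, in class-index order.
#' Each instrument belongs to one of five shape families; similar-looking
#' instruments share a family, which is what makes inter-class confusion
#' analysis meaningful.
#'
#' @return A data frame with columns `class_index` (0-17), `name`, and
#'   `shape_type` (one of `"Unique"`, `"Stick-like"`, `"Forceps"`,
#'   `"Retractor"`, `"Scissors-like"`).
#' @export
load_class_registry <- function() {
  data.frame(
    class_index = 0:17,
    name = c(
      "Root elevator", "Dental pliers", "Raspatory", "Scalpel holder",
      "Dental mirror", "Freer raspatory", "Dental sharp spoon",
      "Luniatschek gauze packer",
      "Anatomical forceps", "Surgical forceps", "Dental forceps",
      "Long retractor", "Short retractor",
      "Big needle holder", "Small needle holder", "Surgical Scissors",
      "Surgical clamp", "Backhaus towel clamp"
    ),
    shape_type = c(
      rep("Unique", 4), rep("Stick-like", 4), rep("Forceps", 3),
      rep("Retractor", 2), rep("Scissors-like", 5)
    ),
    stringsAsFactors = FALSE
  )
}

#' Single-instrument asset
#'
#' Bundles the raw material of one insertion source: an RGB image, its binary
#' segmentation mask, the per-pixel depth map in meters, the camera intrinsics,
#' and the instrument class.
#'
#' @param class_index Integer class index (0-based registry index).
#' @param rgb Numeric `h x w x 3` array in `[0, 1]`.
#' @param mask Logical `h x w` matrix; must contain at least one `TRUE` pixel.
#' @param depth Numeric `h x w` matrix, meters, `0` = invalid.
#' @param intrinsics A [camera_intrinsics()] object.
#' @param meta Optional named list of extra metadata (e.g. analytic ground
#'   truth for fixture assets).
#' @return An object of class `si_asset`.
#' @export
si_asset <- function(class_index, rgb, mask, depth, intrinsics, meta = list()) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"), is.list(meta))
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be an h x w x 3 array")
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("mask must be a logical matrix matching the rgb dimensions")
  if (!identical(dim(depth), d[1:2]))
    stop("depth must be a matrix matching the rgb dimensions")
  if (any(depth < 0)) stop("depth values must be non-negative")
  if (!any(mask)) stop("mask is empty: the asset contains no instrument")
  structure(list(class_index = as.integer(class_index), rgb = rgb, mask = mask,
                 depth = depth, intrinsics = intrinsics, meta = meta),
            class = "si_asset")
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return Numeric `(x, y, w, h)`: 0-based column/row of the top-left corner
#'   and the box extent in pixels; every `TRUE` pixel lies inside and each edge
#'   is touched by at least one.
#' @export
bbox_from_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute a bounding box of an empty mask")
  r <- range(idx[, 1L]); cc <- range(idx[, 2L])
  c(x = cc[1L] - 1, y = r[1L] - 1, w = cc[2L] - cc[1L] + 1,
    h = r[2L] - r[1L] + 1)
}

# --- run-length encoding (COCO uncompressed RLE, column-major) ---------------

#' Encode a binary mask as COCO-style uncompressed RLE
#'
#' Counts alternate runs of `FALSE` and `TRUE` over the column-major (Fortran
#' order) flattening of the mask, starting with the `FALSE` run (possibly of
#' length zero).
#'
#' @param mask Logical matrix.
#' @return A list with `size = c(h, w)` and an integer `counts` vector.
#' @export
rle_encode <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  v <- as.vector(mask)  # column-major
  r <- rle(v)
  counts <- r$lengths
  if (length(counts) > 0L && r$values[1L]) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

#' Decode COCO-style uncompressed RLE into a logical mask
#'
#' @param rle A list with `size` and `counts` as produced by [rle_encode()].
#' @return A logical `size[1] x size[2]` matrix.
#' @export
rle_decode <- function(rle) {
  size <- as.integer(rle$size); counts <- as.integer(rle$counts)
  n <- prod(size)
  if (sum(counts) != n)
    stop("RLE counts sum to ", sum(counts), " but the mask has ", n, " pixels")
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  matrix(vals, nrow = size[1L], ncol = size[2L])
}

# --- COCO-instances dataset --------------------------------------------------

#' Construct an annotated dataset (COCO-instances dialect)
#'
#' @param images Data frame with columns `id`, `file_name`, `width`, `height`.
#' @param annotations List of annotation records; each is a list with `id`,
#'   `image_id`, `category_id` (`class_index + 1`), `bbox` (0-based
#'   `(x, y, w, h)`), `area`, `segmentation` (RLE as from [rle_encode()]), and
#'   `iscrowd`.
#' @param categories Data frame with `id`, `name`, `supercategory`; defaults to
#'   the projection of [load_class_registry()].
#' @return An object of class `coco_dataset`.
#' @export
coco_dataset <- function(images, annotations, categories = coco_categories()) {
  ds <- structure(list(images = images, annotations = annotations,
                       categories = categories),
                  class = "coco_dataset")
  validate_coco(ds)
  ds
}

#' @rdname coco_dataset
#' @export
coco_categories <- function() {
  reg <- load_class_registry()
  data.frame(id = reg$class_index + 1L,
             name = sprintf("Class %02d", reg$class_index),
             supercategory = reg$name, stringsAsFactors = FALSE)
}

validate_coco <- function(ds) {
  imgs <- ds$images
  stopifnot(is.data.frame(imgs),
            all(c("id", "file_name", "width", "height") %in% names(imgs)))
  if (anyDuplicated(imgs$id)) stop("duplicate image ids")
  ann_ids <- vapply(ds$annotations, function(a) a$id, numeric(1))
  if (anyDuplicated(ann_ids)) stop("duplicate annotation ids")
  for (a in ds$annotations) {
    i <- match(a$image_id, imgs$id)
    if (is.na(i))
      stop("annotation ", a$id, " references missing image id ", a$image_id)
    bb <- a$bbox
    if (bb[1] < 0 || bb[2] < 0 || bb[1] + bb[3] > imgs$width[i] ||
        bb[2] + bb[4] > imgs$height[i])
      stop("annotation ", a$id, " has an out-of-bounds bbox")
  }
  invisible(ds)
}

#' Write / read a COCO-instances JSON file
#'
#' The on-disk dialect uses `category_id = class_index + 1`, 0-based
#' `(x, y, w, h)` boxes, and uncompressed column-major RLE segmentations.
#' `read_coco(write_coco(d))` is the identity on images, categories, boxes and
#' masks.
#'
#' @param dataset A [coco_dataset()].
#' @param path Output / input JSON file path.
#' @return `read_coco` returns a `coco_dataset`; `write_coco` returns `path`
#'   invisibly.
#' @export
write_coco <- function(dataset, path) {
  validate_coco(dataset)
  anns <- lapply(dataset$annotations, function(a) {
    list(id = a$id, image_id = a$image_id, category_id = a$category_id,
         bbox = as.numeric(a$bbox), area = a$area,
         segmentation = list(size = as.integer(a$segmentation$size),
                             counts = as.integer(a$segmentation$counts)),
         iscrowd = if (is.null(a$iscrowd)) 0L else a$iscrowd)
  })
  obj <- list(
    images = lapply(seq_len(nrow(dataset$images)), function(i)
      list(id = dataset$images$id[i], file_name = dataset$images$file_name[i],
           width = dataset$images$width[i], height = dataset$images$height[i])),
    annotations = anns,
    categories = lapply(seq_len(nrow(dataset$categories)), function(i)
      list(id = dataset$categories$id[i], name = dataset$categories$name[i],
           supercategory = dataset$categories$supercategory[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed COCO JSON in '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("images", "annotations", "categories"))
    if (is.null(obj[[f]])) stop("COCO file lacks the '", f, "' field")
  images <- data.frame(
    id = vapply(obj$images, function(x) as.numeric(x$id), numeric(1)),
    file_name = vapply(obj$images, function(x) as.character(x$file_name),
                       character(1)),
    width = vapply(obj$images, function(x) as.numeric(x$width), numeric(1)),
    height = vapply(obj$images, function(x) as.numeric(x$height), numeric(1)),
    stringsAsFactors = FALSE
  )
  categories <- data.frame(
    id = vapply(obj$categories, function(x) as.integer(x$id), integer(1)),
    name = vapply(obj$categories, function(x) as.character(x$name),
                  character(1)),
    supercategory = vapply(obj$categories, function(x)
      if (is.null(x$supercategory)) NA_character_
      else as.character(x$supercategory), character(1)),
    stringsAsFactors = FALSE
  )
  annotations <- lapply(obj$annotations, function(a) {
    list(id = as.numeric(a$id), image_id = as.numeric(a$image_id),
         category_id = as.integer(a$category_id),
         bbox = as.numeric(unlist(a$bbox)),
         area = as.numeric(a$area),
         segmentation = list(size = as.integer(unlist(a$segmentation$size)),
                             counts = as.integer(unlist(a$segmentation$counts))),
         iscrowd = as.integer(a$iscrowd))
  })
  coco_dataset(images, annotations, categories)
}

# --- depth map I/O -----------------------------------------------------------

#' Read / write a depth map as a 16-bit grayscale PNG
#'
#' On disk, depth is stored as a single-channel 16-bit PNG whose integer values
#' are millimeters (`0` = no measurement), the convention of consumer RGB-D
#' cameras. In memory, depth is always a numeric matrix in meters, so the
#' round trip is exact up to the 1 mm quantization.
#'
#' @param path PNG file path.
#' @param depth Numeric matrix, meters; values must fit in `[0, 65.535]` m.
#' @return `read_depth_png` returns the depth matrix in meters;
#'   `write_depth_png` returns `path` invisibly.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  if (length(dim(img)) != 2L)
    stop("depth PNG must be single-channel, got ", dim(img)[3], " channels")
  meta <- attr(img, "info")
  if (!identical(as.integer(meta$bit.depth), 16L))
    stop("depth PNG must be 16-bit, got bit depth ", meta$bit.depth)
  # png::readPNG scales to [0,1] by 65535; recover millimeters, then meters
  out <- round(img * 65535) / 1000
  attributes(out) <- list(dim = dim(img))
  out
}

#' @rdname read_depth_png
#' @export
write_depth_png <- function(depth, path) {
  stopifnot(is.matrix(depth), all(depth >= 0))
  mm <- round(depth * 1000)
  if (any(mm > 65535)) stop("depth exceeds the 65.535 m range of 16-bit mm")
  write_png16(matrix(as.integer(mm), nrow(depth), ncol(depth)), path)
  invisible(path)
}

# Minimal 16-bit grayscale PNG encoder: IHDR + IDAT (zlib via memCompress,
# filter 0 per scanline, big-endian uint16) + IEND. Values in [0, 65535].
write_png16 <- function(values, path) {
  h <- nrow(values); w <- ncol(values)
  v <- t(values)                              # row-major scanlines
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  bytes <- as.vector(rbind(hi, lo))           # big-endian pairs
  scan <- matrix(bytes, nrow = 2L * w)        # one column per scanline
  raw_stream <- as.raw(rbind(rep(0L, h), matrix(as.integer(scan), 2L * w)))
  idat <- memCompress(raw_stream, "gzip")     # RFC 1950 zlib stream
  u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(png_crc32(body)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             chunk("IHDR", ihdr), chunk("IDAT", idat),
             chunk("IEND", raw(0))), con)
}

png_crc32 <- local({
  tab <- NULL
  function(bytes) {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c_ <- i
        for (k in 1:8)
          c_ <- if (bitwAnd(c_, 1L)) bitwXor(-306674912L, bitwShiftR(bitwAnd(c_, -2L), 1)) else bitwShiftR(bitwAnd(c_, -2L), 1)
        t[i + 1] <- c_
      }
      tab <<- t
    }
    crc <- -1L
    for (b in as.integer(bytes))
      crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                     bitwShiftR(bitwAnd(crc, -256L), 8))
    crc <- bitwXor(crc, -1L)
    if (crc < 0) crc + 4294967296 else as.numeric(crc)
  }
})

# --- asset directory layout --------------------------------------------------

#' Write / read a single-instrument asset directory entry
#'
#' Each asset is stored as four sibling files sharing a stem:
#' `<stem>_rgb.png` (8-bit RGB), `<stem>_mask.png` (8-bit gray, 255 = TRUE),
#' `<stem>_depth.png` (16-bit mm), and `<stem>_meta.json` (intrinsics, class
#' index, optional metadata such as fixture ground truth).
#'
#' @param asset An [si_asset()].
#' @param stem File path stem (directory + base name, no suffix).
#' @return `read_asset` returns an `si_asset`; `write_asset` the stem,
#'   invisibly.
#' @export
write_asset <- function(asset, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(asset$rgb, paste0(stem, "_rgb.png"))
  png::writePNG(matrix(as.numeric(asset$mask), nrow(asset$mask)),
                paste0(stem, "_mask.png"))
  write_depth_png(asset$depth, paste0(stem, "_depth.png"))
  meta <- c(list(class_index = asset$class_index,
                 intrinsics = unclass(asset$intrinsics)), asset$meta)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_asset
#' @export
read_asset <- function(stem) {
  rgb <- png::readPNG(paste0(stem, "_rgb.png"))
  if (length(dim(rgb)) == 3L && dim(rgb)[3] == 4L) rgb <- rgb[, , 1:3]
  maskimg <- png::readPNG(paste0(stem, "_mask.png"))
  if (length(dim(maskimg)) == 3L) maskimg <- maskimg[, , 1L]
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"))
  intr <- camera_intrinsics(meta$intrinsics$fx, meta$intrinsics$fy,
                            meta$intrinsics$cx, meta$intrinsics$cy)
  extra <- meta[setdiff(names(meta), c("class_index", "intrinsics"))]
  si_asset(meta$class_index, rgb, maskimg > 0.5,
           read_depth_png(paste0(stem, "_depth.png")), intr, extra)
}

#' Read a directory of per-class asset collections
#'
#' Expects `dir/class_00`, `dir/class_01`, ... subdirectories, each holding
#' assets written by [write_asset()].
#'
#' @param dir Root asset directory.
#' @return A named list (one element per class subdirectory, in class order) of
#'   lists of `si_asset` objects.
#' @export
read_asset_collections <- function(dir) {
  sub <- sort(list.dirs(dir, recursive = FALSE))
  if (length(sub) == 0L) stop("no class subdirectories found under '", dir, "'")
  out <- lapply(sub, function(d) {
    stems <- sort(unique(sub("_rgb\\.png$", "",
                             list.files(d, pattern = "_rgb\\.png$",
                                        full.names = TRUE))))
    if (length(stems) == 0L) stop("no assets found for class directory '", d,
                                  "'")
    lapply(stems, read_asset)
  })
  names(out) <- basename(sub)
  out
}
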