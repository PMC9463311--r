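#' Generation configuration for mask-based object insertion
#'
#' Defaults are the reference operating point of the method: 1000 annotated
#' instances per class, 3 to 12 instruments per composed image, a cap of 20
#' placement attempts per instrument before it is omitted, and the rule that an
#' instrument missing at least 50 % of its pixels after insertion is pasted but
#' not annotated.
#'
#' @param instances_per_class Per-class quota of annotated instances.
#' @param min_per_image,max_per_image Range of the per-image instrument count.
#' @param max_resample_iters Total placement attempts (first attempt included)
#'   before an instrument is omitted from the scene.
#' @param out_of_frame_drop_fraction Missing-pixel fraction at or above which a
#'   pasted instrument is not annotated.
#' @param preserve_relative_size `TRUE` for relative-size-preserving insertion
#'   (depth-derived scales); `FALSE` for the pseudo variant that pastes every
#'   instrument at its raw image scale.
#' @param keep_unannotated_paste Keep the visible pixels of
#'   mostly-out-of-frame instruments in the image (without annotation); if
#'   `FALSE` such instruments are omitted entirely.
#' @param overlap_margin Safety margin in pixels around occupied pixels when
#'   testing candidate placements for overlap.
#' @param output_size `(width, height)` of the composed images.
#' @param seed Integer seed controlling the whole generation run.
#' @param max_images Image budget after which generation aborts with an error
#'   if quotas are still unmet; `NULL` picks a generous bound from the quotas.
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(instances_per_class = 1000L,
                              min_per_image = 3L, max_per_image = 12L,
                              max_resample_iters = 20L,
                              out_of_frame_drop_fraction = 0.5,
                              preserve_relative_size = TRUE,
                              keep_unannotated_paste = TRUE,
                              overlap_margin = 0L,
                              output_size = c(640L, 480L),
                              seed = 1L, max_images = NULL) {
  if (min_per_image < 1L || min_per_image > max_per_image)
    stop("need 1 <= min_per_image <= max_per_image")
  if (instances_per_class < 0L) stop("instances_per_class must be >= 0")
  if (out_of_frame_drop_fraction <= 0 || out_of_frame_drop_fraction > 1)
    stop("out_of_frame_drop_fraction must lie in (0, 1]")
  if (max_resample_iters < 1L) stop("max_resample_iters must be >= 1")
  if (overlap_margin < 0L) stop("overlap_margin must be >= 0")
  structure(list(instances_per_class = as.integer(instances_per_class),
                 min_per_image = as.integer(min_per_image),
                 max_per_image = as.integer(max_per_image),
                 max_resample_iters = as.integer(max_resample_iters),
                 out_of_frame_drop_fraction = out_of_frame_drop_fraction,
                 preserve_relative_size = isTRUE(preserve_relative_size),
                 keep_unannotated_paste = isTRUE(keep_unannotated_paste),
                 overlap_margin = as.integer(overlap_margin),
                 output_size = as.integer(output_size),
                 seed = as.integer(seed), max_images = max_images),
            class = "generation_config")
}

#' Select classes for the next scene, largest deficit first
#'
#' Classes with remaining quota are ranked by remaining count (descending,
#' uniform random tie-breaking) and the top `k` distinct classes are taken, so
#' the per-class annotated counts stay balanced throughout a run.
#'
#' @param remaining Non-negative integer vector of per-class remaining quotas.
#' @param k Number of classes wanted.
#' @return Integer vector of 0-based class indices, of length
#'   `min(k, number of classes with remaining quota)`; empty when all quotas
#'   are exhausted.
#' @export
select_classes <- function(remaining, k) {
  stopifnot(k >= 1, all(remaining >= 0))
  avail <- which(remaining > 0L)
  if (length(avail) == 0L) return(integer(0))
  ord <- avail[order(-remaining[avail], runif(length(avail)))]
  ord[seq_len(min(k, length(ord)))] - 1L
}

dilate_mask <- function(mask, margin) {
  if (margin <= 0L || !any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dx in -margin:margin) for (dy in -margin:margin) {
    if (dx == 0L && dy == 0L) next
    if (dx * dx + dy * dy > margin * margin) next
    sr <- max(1L, 1L - dy):min(h, h - dy)
    sc <- max(1L, 1L - dx):min(w, w - dx)
    out[sr + dy, sc + dx] <- out[sr + dy, sc + dx] | mask[sr, sc]
  }
  out
}

#' Test a candidate placement for overlap with occupied pixels
#'
#' @param candidate Logical matrix: the warped instrument mask.
#' @param occupied Logical matrix: union of already placed instrument masks.
#' @param margin Dilation radius in pixels applied to `occupied`; `0` means a
#'   literal shared pixel.
#' @return `TRUE` iff the candidate intersects the (dilated) occupied mask.
#' @export
occlusion_check <- function(candidate, occupied, margin = 0L) {
  if (!identical(dim(candidate), dim(occupied)))
    stop("candidate and occupied masks have different dimensions")
  any(candidate & dilate_mask(occupied, margin))
}

new_scene_draft <- function(background) {
  d <- dim(background)
  list(canvas = background, occupied = matrix(FALSE, d[1], d[2]),
       w = d[2], h = d[1], placements = list(), annotations = list())
}

#' Place one instrument into a scene draft
#'
#' Samples the flip/rotation/translation parameters (the scale is fixed to
#' `s_target`), warps the asset, and tests the warped mask against the
#' occupied pixels. On overlap the random parameters are redrawn, up to
#' `config$max_resample_iters` total attempts, after which the instrument is
#' omitted. A successfully placed instrument is pasted by pixel substitution;
#' if at least `config$out_of_frame_drop_fraction` of its warped pixels fall
#' outside the frame it is pasted without annotation (or omitted when
#' `keep_unannotated_paste` is `FALSE`).
#'
#' @param draft Scene draft as built by [compose_scene()] internals: a list
#'   with `canvas`, `occupied`, `w`, `h`, `placements`, `annotations`.
#' @param asset An [si_asset()].
#' @param s_target Scale factor to apply (from [insertion_scale()], or 1).
#' @param config A [generation_config()].
#' @param forced_transform Optional `spatial_transform` used for every attempt
#'   instead of random sampling (deterministic placement for testing and
#'   inspection); its `s` is overridden by `s_target`.
#' @return The updated draft, with fields `outcome` (one of `"annotated"`,
#'   `"pasted_unannotated"`, `"omitted"`), `attempts`, `missing_fraction`, and
#'   `last_annotation` describing the placement just made.
#' @export
place_instrument <- function(draft, asset, s_target, config,
                             forced_transform = NULL) {
  stopifnot(inherits(asset, "si_asset"), s_target > 0,
            inherits(config, "generation_config"))
  attempts <- 0L
  placed <- NULL
  while (attempts < config$max_resample_iters) {
    attempts <- attempts + 1L
    tr <- if (is.null(forced_transform)) sample_transform(draft$w, draft$h)
          else forced_transform
    tr$s <- s_target
    warped <- apply_transform(asset$rgb, asset$mask, tr, draft$w, draft$h)
    if (!occlusion_check(warped$mask, draft$occupied,
                         config$overlap_margin)) {
      placed <- list(transform = tr, warped = warped)
      break
    }
  }
  draft$attempts <- attempts
  if (is.null(placed)) {
    draft$outcome <- "omitted"
    draft$missing_fraction <- NA_real_
    draft$last_annotation <- NULL
    return(draft)
  }
  warped <- placed$warped
  in_frame <- sum(warped$mask)
  missing <- 1 - in_frame / max(warped$total_px, 1)
  draft$missing_fraction <- missing
  annotate <- missing < config$out_of_frame_drop_fraction && in_frame > 0L
  if (!annotate && !config$keep_unannotated_paste) {
    draft$outcome <- "omitted"
    draft$last_annotation <- NULL
    return(draft)
  }
  if (in_frame > 0L) {
    sel <- which(warped$mask)
    plane <- draft$h * draft$w
    for (k in 0:2)
      draft$canvas[sel + k * plane] <- warped$rgb[sel + k * plane]
    draft$occupied <- draft$occupied | warped$mask
  }
  draft$placements <- c(draft$placements,
                        list(list(class_index = asset$class_index,
                                  transform = placed$transform,
                                  annotated = annotate,
                                  missing_fraction = missing)))
  if (annotate) {
    draft$outcome <- "annotated"
    draft$last_annotation <- list(class_index = asset$class_index,
                                  mask = warped$mask,
                                  bbox = bbox_from_mask(warped$mask),
                                  area = in_frame,
                                  missing_fraction = missing)
    draft$annotations <- c(draft$annotations, list(draft$last_annotation))
  } else {
    draft$outcome <- "pasted_unannotated"
    draft$last_annotation <- NULL
  }
  draft
}

asset_scale_info <- function(asset) {
  if (!is.null(asset$meta$l_px) && !is.null(asset$meta$l_m))
    return(list(l_px = asset$meta$l_px, l_m = asset$meta$l_m))
  l_px <- as.numeric(mask_diameter(asset$mask))
  list(l_px = l_px, l_m = physical_length(asset))
}

#' Compose one multi-instrument scene
#'
#' Inserts the given assets one by one onto a copy of the background by pixel
#' substitution at mask-true positions. The first asset is inserted at its raw
#' image scale (`s = 1`) and its pixels-per-meter scale becomes the scene
#' reference `s0`; every subsequent asset is resized by [insertion_scale()] so
#' its scale matches `s0` (when `preserve_relative_size` is set) or pasted at
#' `s = 1` otherwise. `s0` is computed analytically from the raw mask diameter
#' and depth-derived physical length, not re-measured on the warped raster.
#'
#' @param background Numeric `h x w x 3` array matching the configured output
#'   size.
#' @param assets Ordered list of [si_asset()] objects, one per instrument to
#'   insert (the first defines the reference scale).
#' @param config A [generation_config()].
#' @return `NULL` if the first asset could not be placed (callers retry with a
#'   fresh draw); otherwise a list with `image`, `annotations` (each with
#'   `class_index`, `mask`, `bbox`, `area`, `missing_fraction`), `placements`,
#'   `s0`, and `outcomes` (per-asset placement outcome).
#' @export
compose_scene <- function(background, assets, config) {
  stopifnot(length(assets) >= 1L)
  d <- dim(background)
  if (d[2] != config$output_size[1] || d[1] != config$output_size[2])
    stop("background size does not match config$output_size")
  draft <- new_scene_draft(background)
  outcomes <- character(length(assets))
  info0 <- asset_scale_info(assets[[1L]])
  s0 <- scale_of(info0$l_px, info0$l_m)   # reference: first asset at s = 1
  draft <- place_instrument(draft, assets[[1L]], 1, config)
  outcomes[1L] <- draft$outcome
  if (draft$outcome == "omitted") return(NULL)
  for (i in seq_along(assets)[-1L]) {
    s_i <- if (config$preserve_relative_size) {
      info <- asset_scale_info(assets[[i]])
      insertion_scale(s0, info$l_m, info$l_px)
    } else 1
    draft <- place_instrument(draft, assets[[i]], s_i, config)
    outcomes[i] <- draft$outcome
  }
  list(image = draft$canvas, annotations = draft$annotations,
       placements = draft$placements, s0 = s0, outcomes = outcomes)
}

#' Generate a class-balanced annotated dataset by object insertion
#'
#' Repeatedly draws a background, a per-image instrument count
#' `k ~ U{min_per_image, ..., max_per_image}` (capped at the number of classes
#' still under quota), a set of classes (largest deficit first), and one
#' single-instrument asset per class, then composes a scene. Only annotated
#' instances count toward the per-class quota; generation stops when every
#' class has exactly `instances_per_class` annotated instances.
#'
#' @param assets_by_class List (length = number of classes, in class-index
#'   order) of lists of [si_asset()] objects.
#' @param backgrounds List of numeric `h x w x 3` arrays matching the
#'   configured output size.
#' @param config A [generation_config()]; `config$seed` seeds the run.
#' @param out_dir Optional directory; when given, each composed image is
#'   written there as `mboi_<id>.png` and pixels are not retained in memory.
#' @param keep_images Retain composed images in the returned object (only
#'   sensible for small runs); default `is.null(out_dir)`.
#' @return A list with `dataset` (a [coco_dataset()]), `images` (list of
#'   pixel arrays, or `NULL`), and `log`: seed and config echo, per-class
#'   annotated counts, omission/unannotated tallies, and one record per
#'   annotation (image id, class, asset index, applied scale, the scene
#'   reference `s0`, missing fraction).
#' @export
generate_dataset <- function(assets_by_class, backgrounds, config,
                             out_dir = NULL, keep_images = is.null(out_dir)) {
  stopifnot(inherits(config, "generation_config"),
            length(assets_by_class) >= 1L, length(backgrounds) >= 1L)
  if (config$min_per_image > length(assets_by_class))
    stop("min_per_image exceeds the number of classes")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n_class <- length(assets_by_class)
  # cache each asset's image/physical length once; compose_scene reuses them
  assets_by_class <- lapply(assets_by_class, function(lst)
    lapply(lst, function(a) {
      info <- asset_scale_info(a)
      a$meta$l_px <- info$l_px; a$meta$l_m <- info$l_m
      a
    }))
  remaining <- rep(config$instances_per_class, n_class)
  budget <- if (is.null(config$max_images)) {
    200L + 40L * ceiling(n_class * config$instances_per_class /
                           config$min_per_image)
  } else config$max_images
  images <- list(); pixels <- list(); anns <- list(); ann_log <- list()
  image_id <- 0L; ann_id <- 0L
  tally <- c(annotated = 0L, pasted_unannotated = 0L, omitted = 0L,
             aborted_scenes = 0L)
  while (any(remaining > 0L)) {
    if (image_id + tally[["aborted_scenes"]] >= budget)
      stop("image budget (", budget, ") exhausted with unmet quotas; ",
           "remaining: ", paste(remaining, collapse = ","))
    bg_i <- sample.int(length(backgrounds), 1L)
    kk <- seq.int(config$min_per_image, config$max_per_image)
    k <- if (length(kk) == 1L) kk else sample(kk, 1L)
    k <- min(k, sum(remaining > 0L))
    classes <- select_classes(remaining, k)
    asset_idx <- vapply(classes, function(cl)
      sample.int(length(assets_by_class[[cl + 1L]]), 1L), integer(1))
    assets <- mapply(function(cl, ai) assets_by_class[[cl + 1L]][[ai]],
                     classes, asset_idx, SIMPLIFY = FALSE)
    scene <- compose_scene(backgrounds[[bg_i]], assets, config)
    if (is.null(scene)) {
      tally[["aborted_scenes"]] <- tally[["aborted_scenes"]] + 1L
      next
    }
    image_id <- image_id + 1L
    fn <- sprintf("mboi_%05d.png", image_id)
    images[[image_id]] <- list(id = image_id, file_name = fn,
                               width = config$output_size[1],
                               height = config$output_size[2])
    if (!is.null(out_dir))
      png::writePNG(scene$image, file.path(out_dir, fn))
    if (keep_images) pixels[[image_id]] <- scene$image
    for (o in scene$outcomes)
      tally[[o]] <- tally[[o]] + 1L
    placed_classes <- vapply(scene$placements, function(p) p$class_index,
                             integer(1))
    for (a in scene$annotations) {
      ann_id <- ann_id + 1L
      anns[[ann_id]] <- list(id = ann_id, image_id = image_id,
                             category_id = a$class_index + 1L,
                             bbox = as.numeric(a$bbox), area = a$area,
                             segmentation = rle_encode(a$mask), iscrowd = 0L)
      remaining[a$class_index + 1L] <- remaining[a$class_index + 1L] - 1L
      pi_ <- match(a$class_index, placed_classes)
      ann_log[[ann_id]] <- list(
        annotation_id = ann_id, image_id = image_id,
        class_index = a$class_index,
        asset_index = asset_idx[match(a$class_index, classes)],
        applied_scale = scene$placements[[pi_]]$transform$s,
        s0 = scene$s0, missing_fraction = a$missing_fraction)
    }
  }
  images_df <- do.call(rbind, lapply(images, function(x)
    data.frame(id = x$id, file_name = x$file_name, width = x$width,
               height = x$height, stringsAsFactors = FALSE)))
  if (is.null(images_df))
    images_df <- data.frame(id = numeric(0), file_name = character(0),
                            width = numeric(0), height = numeric(0))
  categories <- if (n_class == 18L) coco_categories() else
    data.frame(id = seq_len(n_class),
               name = sprintf("Class %02d", seq_len(n_class) - 1L),
               supercategory = sprintf("Class %02d", seq_len(n_class) - 1L),
               stringsAsFactors = FALSE)
  dataset <- coco_dataset(images_df, anns, categories)
  counts <- integer(n_class)
  for (a in anns) counts[a$category_id] <- counts[a$category_id] + 1L
  log <- list(seed = config$seed, config = unclass(config),
              mode = if (config$preserve_relative_size) "mboi" else "pmboi",
              per_class_annotated = counts, tally = as.list(tally),
              n_images = image_id, annotations = ann_log)
  list(dataset = dataset, images = if (keep_images) pixels else NULL,
       log = log)
}
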