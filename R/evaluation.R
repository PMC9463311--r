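#' Construct a detection record
#'
#' @param image_id Image the detection belongs to.
#' @param class_index 0-based predicted class.
#' @param score Confidence in `[0, 1]`.
#' @param bbox `(x, y, w, h)` box, 0-based pixels.
#' @param mask Optional logical matrix (instance mask).
#' @return A list of class `detection`.
#' @export
detection <- function(image_id, class_index, score, bbox, mask = NULL) {
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  structure(list(image_id = image_id, class_index = as.integer(class_index),
                 score = score, bbox = as.numeric(bbox), mask = mask),
            class = "detection")
}

#' Discard detections below a class-score threshold
#'
#' Detections with scores strictly below the threshold are discarded; a score
#' exactly at the threshold is kept. The operation is idempotent and preserves
#' input order.
#'
#' @param dets List of [detection()] records.
#' @param threshold Score threshold in `[0, 1]`; default 0.7.
#' @return The filtered list.
#' @export
filter_by_score <- function(dets, threshold = 0.7) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  dets[vapply(dets, function(d) d$score >= threshold, logical(1))]
}

#' Intersection over union of two boxes or masks
#'
#' Boxes are `(x, y, w, h)` with half-open pixel extent; the IoU is the ratio
#' of intersection to union area. Degenerate (zero-area) inputs yield 0 with a
#' warning.
#'
#' @param a,b Boxes (`iou_bbox`) or logical matrices (`iou_mask`).
#' @return IoU in `[0, 1]`; 0 for disjoint inputs.
#' @export
iou_bbox <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0) {
    warning("degenerate zero-area box; IoU set to 0")
    return(0)
  }
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  inter <- max(0, ix) * max(0, iy)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' @rdname iou_bbox
#' @export
iou_mask <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks have different dimensions")
  un <- sum(a | b)
  if (un == 0L) {
    warning("both masks empty; IoU set to 0")
    return(0)
  }
  sum(a & b) / un
}

# Greedy one-to-one assignment by descending IoU over an n_gt x n_det matrix.
# Returns, per GT row, the matched det column (NA if none above min_iou) and
# the matched IoU (0 if unmatched).
greedy_match <- function(iou, min_iou = 0) {
  n_gt <- nrow(iou); n_det <- ncol(iou)
  match_det <- rep(NA_integer_, n_gt); match_iou <- numeric(n_gt)
  if (n_gt == 0L || n_det == 0L) return(list(det = match_det, iou = match_iou))
  work <- iou
  repeat {
    best <- which.max(work)
    if (length(best) == 0L || work[best] < min_iou || work[best] <= 0) break
    k <- arrayInd(best, dim(work))
    g <- k[1L]; d <- k[2L]
    match_det[g] <- d; match_iou[g] <- iou[g, d]
    work[g, ] <- -1; work[, d] <- -1
    if (all(work < min_iou)) break
  }
  list(det = match_det, iou = match_iou)
}

#' Match detections to ground-truth instances within one image
#'
#' Greedy one-to-one, class-agnostic assignment by descending bounding-box
#' IoU; ground-truth instances left unmatched are scored 0.
#'
#' @param gts List of ground-truth records (each with `class_index`, `bbox`,
#'   optionally `mask`).
#' @param dets List of [detection()] records (already score-filtered).
#' @param min_iou Minimum IoU for a pair to be considered at all; default 0
#'   (any positive overlap).
#' @return A list with `det` (per-GT matched detection index or `NA`), `iou`
#'   (per-GT matched bbox IoU, 0 if unmatched), and `iou_matrix`.
#' @export
match_instances <- function(gts, dets, min_iou = 0) {
  iou <- matrix(0, length(gts), length(dets))
  for (g in seq_along(gts)) for (d in seq_along(dets))
    iou[g, d] <- iou_bbox(gts[[g]]$bbox, dets[[d]]$bbox)
  c(greedy_match(iou, min_iou), list(iou_matrix = iou))
}

split_by_image <- function(records) {
  ids <- vapply(records, function(r) as.numeric(r$image_id), numeric(1))
  split(records, ids)
}

#' Per-class and overall IoU report
#'
#' Detections are matched to ground truth per image (class-agnostic greedy
#' matching on bounding-box IoU); each ground-truth instance contributes its
#' matched bounding-box IoU and, when masks are available, the mask IoU of the
#' same matched pair, or 0 when unmatched. Means are taken per ground-truth
#' class and over all instances (mIoU).
#'
#' @param gts List of ground-truth records with `image_id`, `class_index`,
#'   `bbox`, optionally `mask`.
#' @param dets List of [detection()] records (apply [filter_by_score()]
#'   first).
#' @param n_classes Number of classes; default 18.
#' @return A list with `per_instance` (data frame: image_id, class_index,
#'   iou_bbox, iou_mask, matched), `per_class` (data frame of per-class means
#'   and counts), `miou_bbox`, and `miou_mask`.
#' @export
iou_report <- function(gts, dets, n_classes = 18L) {
  if (length(gts) == 0L) stop("cannot build an IoU report without ground truth")
  det_groups <- split_by_image(dets)
  rows <- list()
  for (grp in split_by_image(gts)) {
    img <- as.character(grp[[1L]]$image_id)
    dimg <- if (img %in% names(det_groups)) det_groups[[img]] else list()
    m <- match_instances(grp, dimg)
    for (g in seq_along(grp)) {
      mi <- 0
      if (!is.na(m$det[g]) && !is.null(grp[[g]]$mask) &&
          !is.null(dimg[[m$det[g]]]$mask))
        mi <- iou_mask(grp[[g]]$mask, dimg[[m$det[g]]]$mask)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = grp[[g]]$image_id, class_index = grp[[g]]$class_index,
        iou_bbox = m$iou[g], iou_mask = mi, matched = !is.na(m$det[g]))
    }
  }
  per_instance <- do.call(rbind, rows)
  per_class <- do.call(rbind, lapply(0:(n_classes - 1L), function(cl) {
    sub <- per_instance[per_instance$class_index == cl, , drop = FALSE]
    data.frame(class_index = cl, n = nrow(sub),
               mean_iou_bbox = if (nrow(sub)) mean(sub$iou_bbox) else NA_real_,
               mean_iou_mask = if (nrow(sub)) mean(sub$iou_mask) else NA_real_)
  }))
  list(per_instance = per_instance, per_class = per_class,
       miou_bbox = mean(per_instance$iou_bbox),
       miou_mask = mean(per_instance$iou_mask))
}

#' Normalized confusion matrix with IoU-gated matching
#'
#' Candidate (ground truth, detection) pairs are those whose bounding-box IoU
#' is greater than or equal to `iou_threshold`, regardless of predicted label
#' (otherwise cross-class confusion could never be tallied). Pairs are matched
#' greedily one-to-one by descending IoU; a matched pair increments cell
#' `(true class, predicted class)` and an unmatched ground-truth instance the
#' `missed` column. Rows are normalized by the per-class ground-truth count.
#'
#' @param gts,dets As in [iou_report()] (filter detections first).
#' @param iou_threshold Matching gate, inclusive; default 0.5.
#' @param n_classes Number of classes; default 18.
#' @return An `n_classes x (n_classes + 1)` matrix (last column `missed`) of
#'   row-normalized rates; raw counts in attribute `counts`, unmatched
#'   detection (false positive) count in attribute `false_positives`. Rows
#'   with no ground truth are left at 0.
#' @export
confusion_matrix <- function(gts, dets, iou_threshold = 0.5, n_classes = 18L) {
  counts <- matrix(0L, n_classes, n_classes + 1L)
  dimnames(counts) <- list(sprintf("true_%02d", 0:(n_classes - 1L)),
                           c(sprintf("pred_%02d", 0:(n_classes - 1L)),
                             "missed"))
  fp <- 0L
  det_groups <- split_by_image(dets)
  for (grp in split_by_image(gts)) {
    img <- as.character(grp[[1L]]$image_id)
    dimg <- if (img %in% names(det_groups)) det_groups[[img]] else list()
    m <- match_instances(grp, dimg, min_iou = iou_threshold)
    for (g in seq_along(grp)) {
      row <- grp[[g]]$class_index + 1L
      if (is.na(m$det[g])) {
        counts[row, n_classes + 1L] <- counts[row, n_classes + 1L] + 1L
      } else {
        col <- dimg[[m$det[g]]]$class_index + 1L
        counts[row, col] <- counts[row, col] + 1L
      }
    }
    fp <- fp + length(dimg) - sum(!is.na(m$det))
  }
  norm <- counts
  totals <- rowSums(counts)
  nz <- totals > 0
  norm[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  structure(norm, counts = counts, false_positives = fp,
            class = c("confusion_matrix", "matrix", "array"))
}

#' Write a detection list as COCO-results-style JSON
#'
#' Each record carries `image_id`, `category_id` (`class_index + 1`),
#' `score`, `bbox`, and, when the detection has a mask, an uncompressed RLE
#' `segmentation`; the format [cmd_evaluate()] consumes.
#'
#' @param dets List of [detection()] records.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  obj <- lapply(dets, function(d) {
    rec <- list(image_id = d$image_id, category_id = d$class_index + 1L,
                score = d$score, bbox = as.numeric(d$bbox))
    if (!is.null(d$mask)) rec$segmentation <- rle_encode(d$mask)
    rec
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ground-truth records from a COCO dataset
#'
#' Flattens a [coco_dataset()] into the record list consumed by
#' [iou_report()] and [confusion_matrix()], decoding RLE masks.
#'
#' @param dataset A [coco_dataset()].
#' @param decode_masks Decode RLE segmentations into logical matrices.
#' @return List of records with `image_id`, `class_index`, `bbox`, `mask`.
#' @export
coco_ground_truth <- function(dataset, decode_masks = TRUE) {
  lapply(dataset$annotations, function(a)
    list(image_id = a$image_id, class_index = a$category_id - 1L,
         bbox = a$bbox,
         mask = if (decode_masks) rle_decode(a$segmentation) else NULL))
}
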