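#' Construct a spatial transform
#'
#' The randomized similarity transform applied to a single-instrument image
#' before insertion: two flip bits, a rotation, a translation, and a uniform
#' scale factor.
#'
#' @param n,m Flip bits in `{0, 1}` (horizontal-axis and vertical-axis sign
#'   flips of the x and y coordinates respectively).
#' @param theta Rotation in radians, in `[-pi/2, pi/2]`.
#' @param tx,ty Translation in pixels (displacement of the mask centroid from
#'   the output-frame center).
#' @param s Uniform scale factor, positive.
#' @return An object of class `spatial_transform`.
#' @export
spatial_transform <- function(n = 0L, m = 0L, theta = 0, tx = 0, ty = 0,
                              s = 1) {
  if (!n %in% c(0, 1) || !m %in% c(0, 1)) stop("flip bits n, m must be 0 or 1")
  if (theta < -pi / 2 || theta > pi / 2)
    stop("theta must lie in [-pi/2, pi/2]")
  if (s <= 0) stop("scale factor s must be positive")
  structure(list(n = as.integer(n), m = as.integer(m), theta = theta,
                 tx = tx, ty = ty, s = s),
            class = "spatial_transform")
}

#' Sample a random spatial transform
#'
#' Draws `n, m ~ Bernoulli(0.5)`, `theta ~ U(-pi/2, pi/2)`,
#' `tx ~ U(-w/2, w/2)`, `ty ~ U(-h/2, h/2)` from R's global RNG, with the
#' scale factor initialized to 1 (the scale is set deterministically by the
#' relative-size logic, never sampled).
#'
#' @param w,h Output frame width and height in pixels.
#' @return A `spatial_transform`.
#' @export
sample_transform <- function(w, h) {
  stopifnot(w > 0, h > 0)
  spatial_transform(n = as.integer(runif(1) < 0.5),
                    m = as.integer(runif(1) < 0.5),
                    theta = runif(1, -pi / 2, pi / 2),
                    tx = runif(1, -w / 2, w / 2),
                    ty = runif(1, -h / 2, h / 2), s = 1)
}

#' Homogeneous matrix of a spatial transform
#'
#' Composes `Translate(tx, ty) %*% Scale(s) %*% Rotate(theta) %*% Flip(n, m)`
#' with `Flip(n, m) = diag((-1)^n, (-1)^m)`. For `n = m = 0` and `s = 1` this
#' is the plain rotation-plus-translation matrix; for all parameters it is a
#' similarity transform (the linear block divided by `s` is orthogonal and
#' `|det| = s^2`), which is what a scalar pixels-per-meter scale requires.
#'
#' @param t A `spatial_transform`.
#' @return A 3x3 numeric matrix acting on homogeneous `(x, y, 1)` columns.
#' @export
transform_matrix <- function(t) {
  stopifnot(inherits(t, "spatial_transform"))
  rot <- matrix(c(cos(t$theta), sin(t$theta),
                  -sin(t$theta), cos(t$theta)), 2, 2)
  lin <- t$s * rot %*% diag(c((-1)^t$n, (-1)^t$m))
  rbind(cbind(lin, c(t$tx, t$ty)), c(0, 0, 1))
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot locate the centroid of an empty mask")
  c(x = mean(idx[, 2L]) - 0.5, y = mean(idx[, 1L]) - 0.5)
}

#' Warp an RGB image and mask with a spatial transform
#'
#' The rotation, scale, and flips act about the mask centroid; the centroid is
#' then placed at `(out_w/2 + tx, out_h/2 + ty)` in the output frame. RGB is
#' interpolated bilinearly, the mask by nearest neighbor, and the returned
#' mask is clipped to the output frame. The unclipped warped pixel count is
#' returned alongside so callers can apply the out-of-frame annotation rule.
#'
#' @param rgb Numeric `h x w x 3` array.
#' @param mask Logical matrix matching `rgb`; must be non-empty.
#' @param trans A `spatial_transform`.
#' @param out_w,out_h Output frame size in pixels.
#' @return A list with `rgb` (warped foreground, zero outside the mask),
#'   `mask` (clipped logical matrix), and `total_px` (unclipped warped mask
#'   pixel count).
#' @export
apply_transform <- function(rgb, mask, trans, out_w, out_h) {
  stopifnot(inherits(trans, "spatial_transform"), out_w > 0, out_h > 0)
  if (!any(mask)) stop("cannot warp an asset with an empty mask")
  ctr <- mask_centroid(mask)
  M <- transform_matrix(trans)
  A <- M[1:2, 1:2]
  offset <- c(out_w / 2 + trans$tx, out_h / 2 + trans$ty)
  # bounding box of the warped mask support (forward-map the mask bbox corners)
  bb <- bbox_from_mask(mask)
  corners <- rbind(c(bb[1], bb[2]), c(bb[1] + bb[3], bb[2]),
                   c(bb[1], bb[2] + bb[4]), c(bb[1] + bb[3], bb[2] + bb[4]))
  warped <- t(A %*% (t(corners) - ctr) + offset)
  res <- warp_asset_cpp(rgb, mask, solve(A), ctr[1], ctr[2],
                        offset[1], offset[2], as.integer(out_w),
                        as.integer(out_h),
                        min(warped[, 1]), min(warped[, 2]),
                        max(warped[, 1]), max(warped[, 2]))
  res
}

#' Maximal extent (diameter) of a binary mask
#'
#' The image length of an instrument: the largest Euclidean distance between
#' centers of any two `TRUE` pixels. Computed over the convex hull of the
#' pixel centers, which gives the exact all-pairs maximum.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return The diameter in pixels (`0` for a single pixel). The two pixel
#'   centers realizing it are attached as attribute `endpoints`, a 2x2 matrix
#'   of 0-based `(x, y)` rows.
#' @export
mask_diameter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot measure the diameter of an empty mask")
  pts <- cbind(x = idx[, 2L] - 0.5, y = idx[, 1L] - 0.5)
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- as.matrix(stats::dist(pts))^2
  k <- arrayInd(which.max(d2), dim(d2))
  structure(sqrt(d2[k]), endpoints = pts[as.vector(k), , drop = FALSE])
}

#' Metric length of an instrument from its depth map
#'
#' Deprojects the two mask pixels realizing [mask_diameter()] through the
#' pinhole model `X = (u - cx) z / fx`, `Y = (v - cy) z / fy`, `Z = z`, taking
#' `z` as the median of valid (non-zero) depths in a square window around each
#' endpoint, and returns the Euclidean distance of the two 3D points.
#'
#' @param asset An [si_asset()].
#' @param window Odd window side length in pixels for the robust depth lookup
#'   (depth maps from consumer RGB-D sensors have holes); default 5.
#' @return Physical length in meters.
#' @export
physical_length <- function(asset, window = 5L) {
  stopifnot(inherits(asset, "si_asset"), window >= 1L, window %% 2L == 1L)
  diam <- mask_diameter(asset$mask)
  ep <- attr(diam, "endpoints")
  intr <- asset$intrinsics
  half <- (window - 1L) %/% 2L
  h <- nrow(asset$depth); w <- ncol(asset$depth)
  deproject <- function(pt) {
    r1 <- as.integer(floor(pt[2])) + 1L  # 1-based row of the endpoint pixel
    c1 <- as.integer(floor(pt[1])) + 1L
    rows <- max(1L, r1 - half):min(h, r1 + half)
    cols <- max(1L, c1 - half):min(w, c1 + half)
    vals <- asset$depth[rows, cols]
    vals <- vals[vals > 0]
    if (length(vals) == 0L)
      stop("no valid depth near endpoint (x=", pt[1], ", y=", pt[2], ")")
    z <- median(vals)
    c((pt[1] - intr$cx) * z / intr$fx, (pt[2] - intr$cy) * z / intr$fy, z)
  }
  p1 <- deproject(ep[1, ]); p2 <- deproject(ep[2, ])
  sqrt(sum((p1 - p2)^2))
}

#' Pixels-per-meter scale of an instrument in an image
#'
#' The scale of an instrument is the quotient of its image length (mask
#' diameter, pixels) and its physical length (meters).
#'
#' @param l_px Image length in pixels, positive.
#' @param l_m Physical length in meters, positive.
#' @return The scale `s = l_px / l_m` in pixels per meter.
#' @export
scale_of <- function(l_px, l_m) {
  if (l_px <= 0 || l_m <= 0) stop("lengths must be positive")
  l_px / l_m
}

#' Scale factor that brings an instrument to a reference scale
#'
#' For an instrument with physical length `l_m_i` and image length `l_px_i`,
#' resizing by `s_i = (l_m_i / l_px_i) * s0` makes its pixels-per-meter scale
#' equal to the reference `s0`, which is how the relative physical size of the
#' instruments is preserved across a composed scene.
#'
#' @param s0 Reference scale in pixels per meter, positive.
#' @param l_m_i Physical length of instrument `i`, meters.
#' @param l_px_i Image length of instrument `i`, pixels.
#' @return The dimensionless resize factor `s_i`.
#' @export
insertion_scale <- function(s0, l_m_i, l_px_i) {
  if (s0 <= 0 || l_m_i <= 0 || l_px_i <= 0) stop("inputs must be positive")
  (l_m_i / l_px_i) * s0
}

# --- flip augmentation -------------------------------------------------------

#' Flip an image, mask, or bounding box
#'
#' Modes: `"h"` mirrors columns, `"v"` mirrors rows, `"d"` is their
#' composition (a 180-degree rotation). Each mode is an involution.
#'
#' @param x Numeric `h x w x 3` array (`flip_rgb`), logical matrix
#'   (`flip_mask`), or `(x, y, w, h)` box (`flip_bbox`).
#' @param mode One of `"h"`, `"v"`, `"d"`.
#' @param w,h Image width and height (for `flip_bbox`).
#' @return The flipped object.
#' @export
flip_rgb <- function(x, mode) {
  switch(match.arg(mode, c("h", "v", "d")),
         h = x[, ncol(x):1, , drop = FALSE],
         v = x[nrow(x):1, , , drop = FALSE],
         d = x[nrow(x):1, ncol(x):1, , drop = FALSE])
}

#' @rdname flip_rgb
#' @export
flip_mask <- function(x, mode) {
  switch(match.arg(mode, c("h", "v", "d")),
         h = x[, ncol(x):1, drop = FALSE],
         v = x[nrow(x):1, , drop = FALSE],
         d = x[nrow(x):1, ncol(x):1, drop = FALSE])
}

#' @rdname flip_rgb
#' @export
flip_bbox <- function(x, mode, w, h) {
  mode <- match.arg(mode, c("h", "v", "d"))
  out <- x
  if (mode %in% c("h", "d")) out[1] <- w - x[1] - x[3]
  if (mode %in% c("v", "d")) out[2] <- h - x[2] - x[4]
  out
}

#' Quadruple a set of annotated scenes by flipping
#'
#' Emits, for every input scene, the original plus its horizontal, vertical,
#' and diagonal (180-degree) flips, with masks and boxes transformed
#' consistently; 225 annotated images become 900.
#'
#' @param scenes A list of scenes; each scene is a list with `image` (numeric
#'   `h x w x 3` array) and `annotations`, a list of records each holding
#'   `class_index` and `mask` (logical matrix).
#' @return A list of `4 * length(scenes)` scenes in input order, original
#'   first, each tagged with a `flip` field in `c("none", "h", "v", "d")`.
#' @export
flip_augment <- function(scenes) {
  out <- vector("list", 4L * length(scenes))
  j <- 0L
  for (sc in scenes) {
    for (mode in c("none", "h", "v", "d")) {
      j <- j + 1L
      if (mode == "none") {
        new <- sc
      } else {
        new <- sc
        new$image <- flip_rgb(sc$image, mode)
        new$annotations <- lapply(sc$annotations, function(a) {
          a$mask <- flip_mask(a$mask, mode)
          a
        })
      }
      new$flip <- mode
      out[[j]] <- new
    }
  }
  out
}
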