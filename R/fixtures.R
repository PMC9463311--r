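#' Fixture specification for a procedural instrument asset
#'
#' Describes an instrument-like object of known physical length rendered onto
#' a flat (fronto-parallel) depth plane with known camera intrinsics, so that
#' every geometric quantity the package estimates has an analytic ground
#' truth.
#'
#' @param class_index 0-based class index.
#' @param shape_family One of `"Unique"`, `"Stick-like"`, `"Forceps"`,
#'   `"Retractor"`, `"Scissors-like"`.
#' @param physical_length_m True tip-to-tip length in meters.
#' @param camera_distance_m Depth-plane distance in meters.
#' @param intrinsics A [camera_intrinsics()].
#' @param frame `(width, height)` of the rendered asset image in pixels.
#' @param tilt Depth-plane slope in meters per pixel along x (0 = flat).
#' @return A `fixture_spec` object. The projected diameter
#'   `f * L / z` must be at least 8 px and fit the frame.
#' @export
fixture_spec <- function(class_index, shape_family, physical_length_m,
                         camera_distance_m, intrinsics,
                         frame = c(320L, 240L), tilt = 0) {
  shape_family <- match.arg(shape_family, c("Unique", "Stick-like", "Forceps",
                                            "Retractor", "Scissors-like"))
  stopifnot(physical_length_m > 0, camera_distance_m > 0,
            inherits(intrinsics, "camera_intrinsics"))
  d_px <- intrinsics$fx * physical_length_m / camera_distance_m
  if (d_px < 8) stop("projected diameter ", round(d_px, 1), " px is below 8 px")
  if (d_px > frame[1] - 8)
    stop("projected diameter ", round(d_px, 1), " px does not fit the ",
         frame[1], " px frame")
  structure(list(class_index = as.integer(class_index),
                 shape_family = shape_family,
                 physical_length_m = physical_length_m,
                 camera_distance_m = camera_distance_m,
                 intrinsics = intrinsics, frame = as.integer(frame),
                 tilt = tilt),
            class = "fixture_spec")
}

#' Synthesize a background image
#'
#' A low-frequency texture in a surgical-cloth blue-green hue with randomized
#' overall brightness, emulating pictures of the cloth under different
#' illumination conditions.
#'
#' @param w,h Image size in pixels.
#' @return Numeric `h x w x 3` array in `[0, 1]`.
#' @export
make_background <- function(w, h) {
  stopifnot(w > 0, h > 0)
  gw <- 9L; gh <- 7L
  coarse <- matrix(runif(gw * gh, -0.08, 0.08), gh, gw)
  up <- bilinear_upsample(coarse, h, w)
  brightness <- runif(1, 0.35, 0.65)
  base <- c(0.55, 1.0, 0.95) * brightness  # cloth hue: muted blue-green
  px <- array(0, c(h, w, 3))
  noise <- matrix(rnorm(h * w, 0, 0.01), h, w)
  for (k in 1:3) px[, , k] <- pmin(pmax(base[k] + up + noise, 0), 1)
  px
}

bilinear_upsample <- function(m, h, w) {
  gy <- seq(1, nrow(m), length.out = h)
  gx <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(gy), nrow(m) - 1L); x0 <- pmin(floor(gx), ncol(m) - 1L)
  fy <- gy - y0; fx <- gx - x0
  m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0, x0 + 1] * outer(1 - fy, fx) +
    m[y0 + 1, x0] * outer(fy, 1 - fx) + m[y0 + 1, x0 + 1] * outer(fy, fx)
}

# Distance from pixel centers to a segment (x1,y1)-(x2,y2); vectorized over a
# grid. Used to rasterize capsule (stadium) strokes.
segment_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx * vx + vy * vy
  tt <- if (L2 == 0) 0 else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2,
                                      0), 1)
  sqrt((px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2)
}

# Family silhouettes, all with exact horizontal tip-to-tip extent D about
# (x0, y0): a spine capsule whose cap tips sit at x0 +- D/2 guarantees the
# diameter; decorations stay strictly inside the disc of radius D/2.
draw_family_mask <- function(family, w, h, x0, y0, D) {
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  r <- max(D / 24, 1.5)                      # spine half-thickness
  eps <- 1e-9                                # keep boundary pixel centers in
  spine <- segment_dist(cx, cy, x0 - D / 2 + r, y0, x0 + D / 2 - r, y0) <=
    r + eps
  deco <- rep(FALSE, length(cx))
  inner <- D / 2 - max(2, r)                 # decoration containment radius
  if (family == "Stick-like") {
    # bare capsule
  } else if (family == "Forceps") {
    off <- max(2.5, D / 16)
    deco <- segment_dist(cx, cy, x0, y0 - off, x0 + inner * 0.8, y0 - off) <= r |
            segment_dist(cx, cy, x0, y0 + off, x0 + inner * 0.8, y0 + off) <= r
  } else if (family == "Retractor") {
    ro <- D / 5; ri <- D / 8
    rr <- sqrt((cx - x0)^2 + (cy - y0)^2)
    deco <- rr <= ro & rr >= ri
  } else if (family == "Scissors-like") {
    ang <- pi / 7; len <- inner * 0.85
    deco <- segment_dist(cx, cy, x0 - len * cos(ang), y0 - len * sin(ang),
                         x0 + len * cos(ang), y0 + len * sin(ang)) <= r
  } else {                                   # Unique: lumpy blob on the spine
    for (i in 1:3) {
      bx <- x0 + (i - 2) * inner * 0.45
      br <- D / 10 + (i %% 2) * D / 24
      deco <- deco | (sqrt((cx - bx)^2 + (cy - y0)^2) <= br)
    }
  }
  matrix(spine | deco, h, w)
}

#' Synthesize a single-instrument asset with analytic ground truth
#'
#' Renders a shape-family silhouette whose mask diameter equals the pinhole
#' projection `round(f * L / z)` of the specified physical length onto the
#' (by default fronto-parallel) depth plane at distance `z`, textures it, and
#' attaches the flat depth map and intrinsics. The true length is retained in
#' the asset metadata as `true_length_m`.
#'
#' @param spec A [fixture_spec()].
#' @return An [si_asset()]; `asset$meta$true_length_m` holds the ground truth.
#' @export
make_asset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  w <- spec$frame[1]; h <- spec$frame[2]
  f <- spec$intrinsics$fx; z <- spec$camera_distance_m
  D <- f * spec$physical_length_m / z
  # center the shape on a pixel center or a pixel corner, whichever makes the
  # realized extent (an even vs odd integer) closest to D
  even_ext <- 2 * floor(D / 2)
  odd_ext <- 2 * floor((D + 1) / 2) - 1
  on_center <- abs(even_ext - D) <= abs(odd_ext - D)
  x0 <- w / 2 + if (on_center) 0.5 else 0
  y0 <- h / 2 + 0.5
  mask <- draw_family_mask(spec$shape_family, w, h, x0, y0, D)
  tone <- runif(1, 0.55, 0.8)                 # metallic gray, varied per asset
  tex <- matrix(pmin(pmax(tone + rnorm(h * w, 0, 0.03), 0), 1), h, w)
  rgb <- array(0, c(h, w, 3))
  bgcol <- c(0.28, 0.5, 0.48) * runif(1, 0.8, 1.1)
  for (k in 1:3) {
    plane <- matrix(bgcol[k], h, w)
    plane[mask] <- tex[mask] * c(1, 0.98, 0.95)[k]
    rgb[, , k] <- pmin(plane, 1)
  }
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  depth <- z + spec$tilt * (xs - w / 2)
  si_asset(spec$class_index, rgb, mask, depth, spec$intrinsics,
           meta = list(true_length_m = spec$physical_length_m,
                       camera_distance_m = z,
                       shape_family = spec$shape_family))
}

# Realistic tip-to-tip lengths (meters) for the 18-instrument wisdom-teeth
# extraction set; big vs small needle holder differ mainly in size.
fixture_class_lengths <- function() {
  c(0.16, 0.17, 0.15, 0.13,     # Unique: elevator, pliers, raspatory, scalpel
    0.18, 0.16, 0.17, 0.15,     # Stick-like
    0.14, 0.145, 0.17,          # Forceps
    0.22, 0.16,                 # Retractors: long vs short
    0.20, 0.125, 0.145, 0.14, 0.13)  # Scissors-like; big/small needle holder
}

#' Build full fixture collections: per-class assets and backgrounds
#'
#' Emulates the raw material of the method: `n_per_class` annotated
#' single-instrument images per registry class, rendered at camera distances
#' spread over the working range of a table-mounted RGB-D camera (so the
#' instrument size differs in every image), plus a set of background pictures.
#'
#' @param n_per_class Assets per class; default 12.
#' @param registry Class registry data frame; default [load_class_registry()].
#' @param n_backgrounds Number of backgrounds; default 20.
#' @param frame `(width, height)` of asset and background frames in pixels.
#' @param fx Focal length in pixels (fx = fy); principal point at the frame
#'   center. `NULL` (default) scales with the frame as `1.4 * frame[1]`, which
#'   keeps every instrument's projection inside the frame at all configured
#'   distances.
#' @param z_range Camera distance range in meters, spanned per class.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `assets` (list of per-class asset lists, in class
#'   order) and `backgrounds` (list of `h x w x 3` arrays).
#' @export
make_collections <- function(n_per_class = 12L,
                             registry = load_class_registry(),
                             n_backgrounds = 20L, frame = c(320L, 240L),
                             fx = NULL, z_range = c(0.35, 0.6), seed = NULL) {
  stopifnot(n_per_class >= 1L, n_backgrounds >= 1L)
  if (is.null(fx)) fx <- round(1.4 * frame[1])
  if (!is.null(seed)) set.seed(seed)
  intr <- camera_intrinsics(fx, fx, frame[1] / 2, frame[2] / 2)
  lengths <- fixture_class_lengths()[seq_len(nrow(registry))]
  zs_base <- seq(z_range[1], z_range[2], length.out = max(n_per_class, 2L))
  assets <- lapply(seq_len(nrow(registry)), function(i) {
    lapply(seq_len(n_per_class), function(j) {
      z <- zs_base[j] * runif(1, 0.98, 1.02)
      make_asset(fixture_spec(registry$class_index[i],
                              registry$shape_type[i], lengths[i], z, intr,
                              frame = frame))
    })
  })
  backgrounds <- lapply(seq_len(n_backgrounds), function(i)
    make_background(frame[1], frame[2]))
  list(assets = assets, backgrounds = backgrounds)
}

#' Synthesize a detection list from ground-truth annotations
#'
#' Produces one detection per annotation with controllable degradation:
#' box/mask translation jitter, a score range, per-class label confusion, and
#' drop/extra rates; with the defaults the detections reproduce the ground
#' truth exactly (IoU 1).
#'
#' @param gts Ground-truth records as from [coco_ground_truth()].
#' @param jitter_px Standard deviation of the integer translation jitter.
#' @param score_range Detections draw scores uniformly from this range.
#' @param confusion Optional `n_classes x n_classes` row-stochastic matrix;
#'   row `i` gives the probability of reporting each label for true class
#'   `i - 1`. `NULL` = identity.
#' @param drop_rate Probability of dropping a ground-truth instance.
#' @param extra_rate Expected number of spurious detections per image, drawn
#'   as shifted copies of real instances with random labels.
#' @param image_size `(width, height)`, needed to keep jittered boxes inside
#'   the frame.
#' @param n_classes Number of classes; default 18.
#' @return A list of [detection()] records.
#' @export
make_detections <- function(gts, jitter_px = 0, score_range = c(0.75, 1),
                            confusion = NULL, drop_rate = 0, extra_rate = 0,
                            image_size = c(320L, 240L), n_classes = 18L) {
  out <- list()
  for (g in gts) {
    if (drop_rate > 0 && runif(1) < drop_rate) next
    lab <- g$class_index
    if (!is.null(confusion))
      lab <- sample.int(n_classes, 1L, prob = confusion[g$class_index + 1L, ]) - 1L
    dx <- if (jitter_px > 0) round(rnorm(1, 0, jitter_px)) else 0
    dy <- if (jitter_px > 0) round(rnorm(1, 0, jitter_px)) else 0
    bb <- g$bbox
    dx <- min(max(dx, -bb[1]), image_size[1] - bb[1] - bb[3])
    dy <- min(max(dy, -bb[2]), image_size[2] - bb[2] - bb[4])
    bb[1] <- bb[1] + dx; bb[2] <- bb[2] + dy
    mk <- if (!is.null(g$mask)) shift_mask(g$mask, dx, dy) else NULL
    out[[length(out) + 1L]] <-
      detection(g$image_id, lab, runif(1, score_range[1], score_range[2]),
                bb, mk)
    if (extra_rate > 0 && runif(1) < extra_rate) {
      eb <- g$bbox
      eb[1] <- max(0, min(eb[1] + eb[3], image_size[1] - eb[3]))
      out[[length(out) + 1L]] <-
        detection(g$image_id, sample.int(n_classes, 1L) - 1L,
                  runif(1, score_range[1], score_range[2]), eb, NULL)
    }
  }
  out
}

shift_mask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  sr <- max(1L, 1L - dy):min(h, h - dy)
  sc <- max(1L, 1L - dx):min(w, w - dx)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr + dy, sc + dx] <- mask[sr, sc]
  out
}

#' Hu's seven moment invariants of a binary mask
#'
#' Rotation-, translation-, and scale-invariant shape descriptors; used to
#' verify that the fixture shape families are mutually distinguishable.
#'
#' @param mask Logical matrix.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no moments")
  x <- idx[, 2L] - 0.5; y <- idx[, 1L] - 0.5
  xb <- mean(x); yb <- mean(y)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  m00 <- nrow(idx)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}
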