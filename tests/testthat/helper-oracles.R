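# Independent brute-force oracles, deliberately naive.

bf_diameter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 2L] - 0.5, idx[, 1L] - 0.5)
  best <- 0
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
    best <- max(best, sum((pts[i, ] - pts[j, ])^2))
  sqrt(best)
}

bf_bbox <- function(mask) {
  xs <- integer(0); ys <- integer(0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) { xs <- c(xs, c); ys <- c(ys, r) }
  c(min(xs) - 1, min(ys) - 1, max(xs) - min(xs) + 1, max(ys) - min(ys) + 1)
}

# IoU of two boxes by counting cells on an integer pixel grid (boxes must have
# integer coordinates)
bf_iou_box_pixels <- function(a, b, w = 64L, h = 64L) {
  grid_a <- matrix(FALSE, h, w); grid_b <- matrix(FALSE, h, w)
  if (a[3] > 0 && a[4] > 0)
    grid_a[(a[2] + 1):(a[2] + a[4]), (a[1] + 1):(a[1] + a[3])] <- TRUE
  if (b[3] > 0 && b[4] > 0)
    grid_b[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] <- TRUE
  un <- sum(grid_a | grid_b)
  if (un == 0) 0 else sum(grid_a & grid_b) / un
}

random_blob_mask <- function(h, w, n_seeds = 3L, grow = 8L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_seeds))
    m[sample.int(h, 1L), sample.int(w, 1L)] <- TRUE
  for (g in seq_len(grow)) {
    idx <- which(m, arr.ind = TRUE)
    k <- idx[sample.int(nrow(idx), 1L), ]
    r <- min(max(k[1] + sample(c(-1L, 1L), 1L), 1L), h)
    c_ <- min(max(k[2] + sample(c(-1L, 1L), 1L), 1L), w)
    m[r, c_] <- TRUE
  }
  m
}
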