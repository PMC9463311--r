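test_that("transform_matrix reproduces the printed rotation matrix and its factors", {
  expect_equal(transform_matrix(spatial_transform()), diag(3))
  expect_equal(transform_matrix(spatial_transform(0, 0, pi / 2, 0, 0, 1)),
               rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_equal(transform_matrix(spatial_transform(1, 0, 0, 3, 4, 2)),
               rbind(c(-2, 0, 3), c(0, 2, 4), c(0, 0, 1)))
  # unflipped unit-scale case matches the plain rotation+translation form
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, -pi / 2, pi / 2); tx <- runif(1, -50, 50)
    ty <- runif(1, -50, 50)
    M <- transform_matrix(spatial_transform(0, 0, th, tx, ty, 1))
    expect_equal(M, rbind(c(cos(th), -sin(th), tx),
                          c(sin(th), cos(th), ty),
                          c(0, 0, 1)))
  }
})

test_that("the linear block is a similarity: |det| = s^2 and A/s orthogonal", {
  set.seed(32)
  for (i in 1:50) {
    t <- spatial_transform(sample(0:1, 1), sample(0:1, 1),
                           runif(1, -pi / 2, pi / 2), runif(1, -80, 80),
                           runif(1, -60, 60), runif(1, 0.2, 3))
    A <- transform_matrix(t)[1:2, 1:2]
    expect_equal(abs(det(A)), t$s^2)
    expect_equal(crossprod(A / t$s), diag(2))
  }
})

test_that("sample_transform respects its distribution supports and is seed-stable", {
  set.seed(33)
  draws <- replicate(10000, sample_transform(640, 480), simplify = FALSE)
  n <- vapply(draws, `[[`, numeric(1), "n")
  th <- vapply(draws, `[[`, numeric(1), "theta")
  tx <- vapply(draws, `[[`, numeric(1), "tx")
  ty <- vapply(draws, `[[`, numeric(1), "ty")
  expect_gte(mean(n), 0.48); expect_lte(mean(n), 0.52)
  expect_true(all(th >= -pi / 2 & th <= pi / 2))
  expect_true(all(abs(tx) <= 320) && all(abs(ty) <= 240))
  expect_true(all(vapply(draws, `[[`, numeric(1), "s") == 1))
  set.seed(99); a <- replicate(5, sample_transform(100, 80), simplify = FALSE)
  set.seed(99); b <- replicate(5, sample_transform(100, 80), simplify = FALSE)
  expect_identical(a, b)
})

test_that("apply_transform preserves area up to rasterization", {
  set.seed(34)
  a <- tiny_asset(L = 0.09, z = 0.45)
  n0 <- sum(a$mask)
  ident <- apply_transform(a$rgb, a$mask, spatial_transform(), 80, 60)
  expect_equal(sum(ident$mask), n0)
  expect_equal(ident$total_px, n0)
  for (th in c(-1.2, -0.4, 0.7, 1.5)) {
    w <- apply_transform(a$rgb, a$mask, spatial_transform(0, 0, th), 80, 60)
    expect_lt(abs(w$total_px / n0 - 1), 0.05)
  }
  big <- apply_transform(a$rgb, a$mask, spatial_transform(0, 0, 0.4, 0, 0, 2),
                         200, 160)
  expect_lt(abs(big$total_px / (4 * n0) - 1), 0.05)
  expect_error(apply_transform(a$rgb, matrix(FALSE, 60, 80),
                               spatial_transform(), 80, 60), "empty")
})

test_that("warped foreground differs from zero only on the warped mask", {
  set.seed(35)
  a <- tiny_asset()
  w <- apply_transform(a$rgb, a$mask, spatial_transform(0, 0, 0.3, 5, -4), 80,
                       60)
  outside <- !w$mask
  for (k in 1:3) expect_true(all(w$rgb[, , k][outside] == 0))
  expect_true(all(w$rgb[, , 1][w$mask] > 0))
})

test_that("mask_diameter matches the all-pairs brute force", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(as.numeric(mask_diameter(single)), 0)
  run3 <- matrix(FALSE, 3, 5); run3[2, 2:4] <- TRUE
  expect_equal(as.numeric(mask_diameter(run3)), 2)
  rect <- matrix(FALSE, 6, 8); rect[2:4, 3:6] <- TRUE   # 3 x 4 block
  expect_equal(as.numeric(mask_diameter(rect)), sqrt(13))
  expect_error(mask_diameter(matrix(FALSE, 2, 2)), "empty")
  set.seed(36)
  for (i in 1:60) {
    m <- random_blob_mask(14, 18, n_seeds = sample(1:4, 1))
    expect_equal(as.numeric(mask_diameter(m)), bf_diameter(m))
  }
})

test_that("physical_length recovers metric length by pinhole deprojection", {
  set.seed(37)
  a <- tiny_asset(L = 0.1, z = 0.5, f = 150)
  l_px <- as.numeric(mask_diameter(a$mask))
  expect_equal(physical_length(a), l_px * 0.5 / 150, tolerance = 1e-9)
  # doubling depth doubles the recovered length
  a2 <- a; a2$depth <- a$depth * 2
  expect_equal(physical_length(a2), 2 * physical_length(a), tolerance = 1e-9)
  # no valid depth near an endpoint is an error naming the endpoint
  a3 <- a; a3$depth <- matrix(0, nrow(a$depth), ncol(a$depth))
  expect_error(physical_length(a3), "no valid depth")
})

test_that("physical_length tolerates depth holes via the median window", {
  set.seed(38)
  a <- tiny_asset(L = 0.1, z = 0.5)
  ref <- physical_length(a)
  holes <- a
  idx <- which(holes$depth > 0)
  kill <- sample(idx, length(idx) %/% 3)
  holes$depth[kill] <- 0
  expect_equal(physical_length(holes), ref, tolerance = 1e-6)
})

test_that("scale arithmetic follows the pixels-per-meter definition", {
  expect_equal(scale_of(400, 0.2), 2000)
  expect_equal(insertion_scale(2000, 0.1, 300), 2 / 3)
  expect_equal(insertion_scale(1234, 0.25, 1234 * 0.25), 1)
  expect_error(scale_of(0, 0.1), "positive")
  expect_error(insertion_scale(-1, 0.1, 10), "positive")
})

test_that("rescaling by the insertion scale lands on the reference scale", {
  set.seed(39)
  s0 <- 450 / 0.45   # pixels per meter of a reference view
  for (L in c(0.12, 0.16, 0.2)) {
    a <- tiny_asset(L = L, z = 0.5, frame = c(320L, 240L), f = 450)
    l_px <- as.numeric(mask_diameter(a$mask))
    l_m <- physical_length(a)
    s_i <- insertion_scale(s0, l_m, l_px)
    w <- apply_transform(a$rgb, a$mask, spatial_transform(0, 0, 0, 0, 0, s_i),
                         260, 140)
    expect_equal(as.numeric(mask_diameter(w$mask)) / l_m, s0,
                 tolerance = 0.02)
  }
})

test_that("flips are involutions and transform boxes by reflection", {
  set.seed(40)
  img <- array(runif(5 * 7 * 3), c(5, 7, 3))
  msk <- random_blob_mask(5, 7)
  for (mode in c("h", "v", "d")) {
    expect_identical(flip_rgb(flip_rgb(img, mode), mode), img)
    expect_identical(flip_mask(flip_mask(msk, mode), mode), msk)
    expect_equal(flip_bbox(flip_bbox(c(1, 2, 3, 2), mode, 7, 5), mode, 7, 5),
                 c(1, 2, 3, 2))
    # flipped bbox equals bbox of the flipped mask
    expect_equal(unname(flip_bbox(unname(bbox_from_mask(msk)), mode, 7, 5)),
                 unname(bbox_from_mask(flip_mask(msk, mode))))
  }
  expect_equal(flip_bbox(c(1, 2, 3, 2), "h", 10, 8), c(10 - 1 - 3, 2, 3, 2))
})

test_that("flip augmentation quadruples an annotated image set", {
  set.seed(41)
  scenes <- lapply(1:225, function(i) {
    m <- matrix(FALSE, 6, 8); m[2:3, 3:5] <- TRUE
    list(image = array(runif(6 * 8 * 3), c(6, 8, 3)),
         annotations = list(list(class_index = i %% 18L, mask = m)))
  })
  out <- flip_augment(scenes)
  expect_length(out, 900L)
  expect_equal(vapply(out[1:4], `[[`, character(1), "flip"),
               c("none", "h", "v", "d"))
  # each flip keeps the annotation count and classes
  expect_true(all(vapply(out, function(s) length(s$annotations), integer(1)) ==
                    1L))
  one <- flip_augment(scenes[1])
  expect_length(one, 4L)
  # the diagonal flip equals horizontal-then-vertical
  expect_identical(one[[4]]$image, flip_rgb(flip_rgb(one[[1]]$image, "h"), "v"))
})
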