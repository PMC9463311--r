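test_that("select_classes picks distinct classes, largest deficit first", {
  set.seed(50)
  expect_setequal(select_classes(c(5, 5, 5), 3), 0:2)
  expect_setequal(select_classes(c(2, 0, 7), 2), c(2L, 0L))
  expect_equal(select_classes(c(0, 0, 0), 4), integer(0))
  expect_equal(select_classes(c(0, 3, 0), 2), 1L)
  # equal quotas: pairs drawn uniformly (3 classes -> 3 pairs)
  picks <- replicate(9000, paste(sort(select_classes(c(4, 4, 4), 2)),
                                 collapse = "-"))
  tab <- table(picks)
  expect_length(tab, 3L)
  expected <- 9000 / 3
  sigma <- sqrt(9000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(tab - expected) < 3 * sigma))
})

test_that("occlusion_check detects shared pixels and margin violations", {
  a <- matrix(FALSE, 20, 20); a[5:8, 5:8] <- TRUE
  b <- matrix(FALSE, 20, 20); b[10:12, 10:12] <- TRUE
  expect_false(occlusion_check(a, b, 0))
  shared <- b; shared[8, 8] <- TRUE
  expect_true(occlusion_check(a, shared, 0))
  # masks two pixels apart: margin 3 bridges the gap, margin 1 does not
  c1 <- matrix(FALSE, 20, 20); c1[5, 5] <- TRUE
  c2 <- matrix(FALSE, 20, 20); c2[5, 8] <- TRUE
  expect_false(occlusion_check(c1, c2, 0))
  expect_false(occlusion_check(c1, c2, 1))
  expect_true(occlusion_check(c1, c2, 3))
  expect_error(occlusion_check(a, matrix(FALSE, 5, 5)), "dimensions")
})

empty_draft <- function(w = 80L, h = 60L)
  list(canvas = array(0.5, c(h, w, 3)), occupied = matrix(FALSE, h, w),
       w = w, h = h, placements = list(), annotations = list())

test_that("place_instrument annotates a clean in-frame placement on attempt 1", {
  set.seed(51)
  a <- tiny_asset()
  cfg <- tiny_config()
  d <- place_instrument(empty_draft(), a, 1,
                        cfg, forced_transform = spatial_transform())
  expect_equal(d$outcome, "annotated")
  expect_equal(d$attempts, 1L)
  expect_equal(d$missing_fraction, 0)
  expect_equal(d$last_annotation$area, sum(a$mask))
  expect_equal(unname(d$last_annotation$bbox),
               unname(bbox_from_mask(d$last_annotation$mask)))
})

test_that("a fully occupied frame forces exactly the attempt cap, then omission", {
  set.seed(52)
  a <- tiny_asset()
  cfg <- tiny_config()
  d <- empty_draft()
  d$occupied[] <- TRUE
  out <- place_instrument(d, a, 1, cfg)
  expect_equal(out$outcome, "omitted")
  expect_equal(out$attempts, 20L)
  expect_length(out$placements, 0L)
  # the cap is configurable
  cfg5 <- tiny_config(max_resample_iters = 5L)
  out5 <- place_instrument(d, a, 1, cfg5)
  expect_equal(out5$attempts, 5L)
})

# A 1 x 1000 horizontal bar asset: shifting it across the left frame edge
# gives exact control over the missing-pixel fraction.
bar_asset <- function(n_px = 1000L, frame_w = 1100L) {
  h <- 21L
  mask <- matrix(FALSE, h, frame_w)
  mask[11L, 51L:(50L + n_px)] <- TRUE
  rgb <- array(0.8, c(h, frame_w, 3))
  depth <- matrix(0.5, h, frame_w)
  si_asset(0L, rgb, mask, depth,
           camera_intrinsics(600, 600, frame_w / 2, h / 2))
}

test_that("the out-of-frame rule is exact at the 50 % boundary", {
  a <- bar_asset()
  cfg <- tiny_config(output_size = c(1100L, 21L))
  draft <- empty_draft(1100L, 21L)
  # centroid sits at frame center + tx; tx = -550 puts 500/1000 px off frame
  half_out <- spatial_transform(0, 0, 0, -550, 0, 1)
  d1 <- place_instrument(draft, a, 1, cfg, forced_transform = half_out)
  expect_equal(d1$missing_fraction, 0.5)
  expect_equal(d1$outcome, "pasted_unannotated")
  expect_length(d1$annotations, 0L)
  expect_gt(sum(d1$occupied), 0L)        # visible half still pasted
  # one pixel less off frame: 499/1000 = 0.499 -> annotated
  d2 <- place_instrument(draft, a, 1, cfg,
                         forced_transform = spatial_transform(0, 0, 0, -549,
                                                              0, 1))
  expect_equal(d2$missing_fraction, 0.499)
  expect_equal(d2$outcome, "annotated")
  # keep_unannotated_paste = FALSE drops the mostly-out instrument entirely
  cfg_drop <- tiny_config(output_size = c(1100L, 21L),
                          keep_unannotated_paste = FALSE)
  d3 <- place_instrument(draft, a, 1, cfg_drop, forced_transform = half_out)
  expect_equal(d3$outcome, "omitted")
  expect_equal(sum(d3$occupied), 0L)
})

test_that("compose_scene substitutes pixels exactly on the inserted masks", {
  set.seed(53)
  coll <- tiny_collections(n_classes = 2L)
  cfg <- tiny_config()
  bg <- coll$backgrounds[[1]]
  scene <- NULL
  for (seed in 1:50) {
    set.seed(seed)
    scene <- compose_scene(bg, list(coll$assets[[1]][[1]]), cfg)
    if (!is.null(scene) && length(scene$annotations) == 1L &&
        scene$annotations[[1]]$missing_fraction == 0) break
  }
  m <- scene$annotations[[1]]$mask
  for (k in 1:3) {
    ch_out <- scene$image[, , k]; ch_bg <- bg[, , k]
    expect_identical(ch_out[!m], ch_bg[!m])
  }
  expect_false(isTRUE(all.equal(scene$image[, , 1][m], bg[, , 1][m])))
})

test_that("relative physical size is preserved across a composed scene", {
  # two instruments of physical length 0.20 m and 0.10 m: their annotated
  # diameters must come out 2:1 regardless of the raw image scales
  intr <- camera_intrinsics(300, 300, 160, 120)
  big <- make_asset(fixture_spec(0L, "Stick-like", 0.20, 0.45, intr))
  small <- make_asset(fixture_spec(1L, "Stick-like", 0.10, 0.35, intr))
  cfg <- generation_config(instances_per_class = 2L, min_per_image = 2L,
                           max_per_image = 2L, output_size = c(320L, 240L),
                           seed = 1L)
  found <- FALSE
  for (seed in 1:200) {
    set.seed(seed)
    scene <- compose_scene(make_background(320, 240), list(big, small), cfg)
    if (is.null(scene) || length(scene$annotations) != 2L) next
    mf <- vapply(scene$annotations, `[[`, numeric(1), "missing_fraction")
    if (any(mf > 0)) next
    found <- TRUE
    diams <- vapply(scene$annotations, function(a)
      as.numeric(mask_diameter(a$mask)), numeric(1))
    cls <- vapply(scene$annotations, `[[`, integer(1), "class_index")
    ratio <- diams[cls == 0L] / diams[cls == 1L]
    expect_equal(ratio, 2, tolerance = 0.02)
    break
  }
  expect_true(found)
})

test_that("the pseudo mode pastes at raw image scale instead", {
  intr <- camera_intrinsics(300, 300, 160, 120)
  big <- make_asset(fixture_spec(0L, "Stick-like", 0.20, 0.45, intr))
  small <- make_asset(fixture_spec(1L, "Stick-like", 0.10, 0.35, intr))
  raw_ratio <- as.numeric(mask_diameter(big$mask)) /
    as.numeric(mask_diameter(small$mask))
  cfg <- generation_config(instances_per_class = 2L, min_per_image = 2L,
                           max_per_image = 2L, output_size = c(320L, 240L),
                           preserve_relative_size = FALSE, seed = 1L)
  for (seed in 1:200) {
    set.seed(seed)
    scene <- compose_scene(make_background(320, 240), list(big, small), cfg)
    if (is.null(scene) || length(scene$annotations) != 2L) next
    mf <- vapply(scene$annotations, `[[`, numeric(1), "missing_fraction")
    if (any(mf > 0)) next
    diams <- vapply(scene$annotations, function(a)
      as.numeric(mask_diameter(a$mask)), numeric(1))
    cls <- vapply(scene$annotations, `[[`, integer(1), "class_index")
    expect_equal(diams[cls == 0L] / diams[cls == 1L], raw_ratio,
                 tolerance = 0.02)
    return(invisible(NULL))
  }
  fail("no fully in-frame two-instrument scene found")
})

test_that("generate_dataset hits every quota exactly and stays disjoint", {
  coll <- tiny_collections(n_classes = 3L)
  cfg <- tiny_config(instances_per_class = 5L, min_per_image = 3L,
                     max_per_image = 3L)
  res <- generate_dataset(coll$assets, coll$backgrounds, cfg)
  expect_equal(res$log$per_class_annotated, c(5L, 5L, 5L))
  expect_length(res$dataset$annotations, 15L)
  # pairwise disjoint instance masks within every image
  for (img in res$dataset$images$id) {
    masks <- lapply(Filter(function(a) a$image_id == img,
                           res$dataset$annotations),
                    function(a) rle_decode(a$segmentation))
    if (length(masks) < 2L) next
    for (i in seq_along(masks)[-1]) for (j in seq_len(i - 1))
      expect_equal(sum(masks[[i]] & masks[[j]]), 0L)
  }
  # annotations carry tight boxes consistent with their masks
  for (a in res$dataset$annotations) {
    m <- rle_decode(a$segmentation)
    expect_equal(a$bbox, unname(bbox_from_mask(m)))
    expect_equal(a$area, sum(m))
  }
})

test_that("zero quota produces an empty dataset", {
  coll <- tiny_collections(n_classes = 2L)
  cfg <- tiny_config(instances_per_class = 0L, min_per_image = 2L,
                     max_per_image = 2L)
  res <- generate_dataset(coll$assets, coll$backgrounds, cfg)
  expect_equal(nrow(res$dataset$images), 0L)
  expect_length(res$dataset$annotations, 0L)
})

test_that("identical seeds reproduce the dataset; different seeds do not", {
  coll <- tiny_collections(n_classes = 3L)
  cfg <- tiny_config(instances_per_class = 3L)
  r1 <- generate_dataset(coll$assets, coll$backgrounds, cfg)
  r2 <- generate_dataset(coll$assets, coll$backgrounds, cfg)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_coco(r1$dataset, p1); write_coco(r2$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
  cfg2 <- tiny_config(instances_per_class = 3L, seed = 8L)
  r3 <- generate_dataset(coll$assets, coll$backgrounds, cfg2)
  expect_false(identical(jsonlite::toJSON(r1$dataset$annotations),
                         jsonlite::toJSON(r3$dataset$annotations)))
})

test_that("an unreachable quota aborts at the image budget", {
  coll <- tiny_collections(n_classes = 2L)
  cfg <- tiny_config(instances_per_class = 50L, min_per_image = 2L,
                     max_per_image = 2L, max_images = 3L)
  expect_error(generate_dataset(coll$assets, coll$backgrounds, cfg),
               "image budget")
})
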