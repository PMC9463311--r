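# Small fixture collections used across tests: instrument-like assets rendered
# in an 80x60 frame, with analytic lengths scaled so projections fit.

tiny_intrinsics <- function(frame = c(80L, 60L), f = 150)
  camera_intrinsics(f, f, frame[1] / 2, frame[2] / 2)

tiny_asset <- function(class_index = 0L, family = "Stick-like", L = 0.1,
                       z = 0.5, frame = c(80L, 60L), f = 150) {
  make_asset(fixture_spec(class_index, family, L, z,
                          tiny_intrinsics(frame, f), frame = frame))
}

tiny_collections <- function(n_classes = 3L, n_per_class = 2L,
                             n_backgrounds = 2L, frame = c(80L, 60L),
                             f = 150) {
  fams <- rep(c("Stick-like", "Forceps", "Unique", "Retractor",
                "Scissors-like"), length.out = n_classes)
  lengths <- seq(0.07, 0.11, length.out = n_classes)
  zs <- seq(0.4, 0.6, length.out = max(n_per_class, 2L))
  assets <- lapply(seq_len(n_classes), function(i)
    lapply(seq_len(n_per_class), function(j)
      tiny_asset(i - 1L, fams[i], lengths[i], zs[j], frame, f)))
  backgrounds <- lapply(seq_len(n_backgrounds), function(i)
    make_background(frame[1], frame[2]))
  list(assets = assets, backgrounds = backgrounds)
}

tiny_config <- function(...) {
  defaults <- list(instances_per_class = 4L, min_per_image = 2L,
                   max_per_image = 3L, output_size = c(80L, 60L), seed = 7L)
  do.call(generation_config, modifyList(defaults, list(...)))
}

# Memoized medium-scale generated dataset shared by the acceptance checks:
# full 18-class fixture collections at 320x240, a reduced per-class quota.
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coll <- make_collections(n_per_class = 4L, n_backgrounds = 6L,
                               seed = 303L)
      cfg <- generation_config(instances_per_class = 12L, min_per_image = 3L,
                               max_per_image = 12L,
                               output_size = c(320L, 240L), seed = 904L)
      res <- generate_dataset(coll$assets, coll$backgrounds, cfg)
      cache <<- list(coll = coll, cfg = cfg, res = res)
    }
    cache
  }
})
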