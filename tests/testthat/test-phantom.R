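test_that("phantom generation is reproducible from the seed", {
  cfg <- phantom_config(n_frames = 8, image_size = 48, seed = 21)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a, b)
  c <- generate_phantom(phantom_config(n_frames = 8, image_size = 48,
                                       seed = 22))
  expect_false(identical(a, c))
})

test_that("annotations are unchanged whether or not images are rendered", {
  cfg <- phantom_config(n_frames = 10, image_size = 48, seed = 5)
  with_img <- generate_phantom(cfg)
  without <- generate_phantom(cfg, render = FALSE)
  for (i in seq_len(10)) {
    expect_equal(without[[i]]$keypoints, with_img[[i]]$keypoints)
    expect_null(without[[i]]$image)
  }
})

test_that("visibility rules hold on every generated frame", {
  frames <- small_phantom(300, seed = 31, render = FALSE)
  anat <- c("AA1", "AA2", "STJ1", "STJ2")
  for (f in frames) {
    labs <- f$keypoints$label
    if (!f$contrast_on) expect_length(intersect(labs, anat), 0L)
    if (f$stage != "deployment") {
      expect_length(intersect(labs, c("FE1", "FE2")), 0L)
    }
    expect_true(all(c(f$keypoints$x, f$keypoints$y) >= 0))
    expect_true(all(c(f$keypoints$x, f$keypoints$y) <= 1))
    expect_gte(nrow(f$keypoints), 1L)
    expect_lte(nrow(f$keypoints), 11L)
    expect_true("CT" %in% labs)
  }
})

test_that("contrast and stage gates are forced off when configured off", {
  frames <- generate_phantom(
    phantom_config(n_frames = 60, seed = 13,
                   contrast_prob = c(positioning = 0, retraction = 0,
                                     deployment = 0)),
    render = FALSE)
  labs <- unlist(lapply(frames, function(f) f$keypoints$label))
  expect_length(intersect(labs, c("AA1", "AA2", "STJ1", "STJ2")), 0L)

  frames2 <- generate_phantom(
    phantom_config(n_frames = 60, seed = 14,
                   stage_mix = c(positioning = 1, retraction = 0,
                                 deployment = 0)),
    render = FALSE)
  labs2 <- unlist(lapply(frames2, function(f) f$keypoints$label))
  expect_length(intersect(labs2, c("FE1", "FE2")), 0L)
})

test_that("sampled geometry respects the annulus and catheter layout", {
  cfg <- phantom_config(n_frames = 1, seed = 1)
  set.seed(77)
  for (i in 1:50) {
    g <- sample_geometry(cfg)
    pts <- g$points
    xy <- function(l) unlist(pts[pts$label == l, c("x", "y")])
    expect_lt(xy("AA1")[1], xy("AA2")[1])
    # stent edges sit between the capsule marker (CD) and the tip
    expect_gt(g$arc[["CD"]], g$fe_arc)
    expect_gt(g$fe_arc, 0)
    expect_true(all(pts$x >= 0 & pts$x <= 1 & pts$y >= 0 & pts$y <= 1))
  }
})

test_that("rendered images stay in 8-bit range and are deterministic", {
  cfg <- phantom_config(n_frames = 3, image_size = 48, seed = 9,
                        jitter_sd = 0, pixel_noise_sd = 0)
  set.seed(3)
  g <- sample_geometry(cfg)
  f1 <- render_frame(g, cfg)
  f2 <- render_frame(g, cfg)
  expect_identical(f1$image, f2$image)
  expect_gte(min(f1$image), 0)
  expect_lte(max(f1$image), 255)
  expect_equal(dim(f1$image), c(48L, 48L))
  if (!g$contrast_on) {
    expect_length(intersect(f1$keypoints$label,
                            c("AA1", "AA2", "STJ1", "STJ2")), 0L)
  }
})

test_that("configuration validation catches impossible settings", {
  expect_error(phantom_config(n_frames = 0), "n_frames")
  expect_error(phantom_config(stage_mix = c(positioning = 0.5,
                                            retraction = 0.5,
                                            deployment = 0.5)),
               "sum to 1")
  expect_error(phantom_config(contrast_prob = c(positioning = 1.5,
                                                retraction = 0,
                                                deployment = 0)),
               "probabilities")
})

test_that("delivery-system labels dominate and counts are bell-shaped", {
  frames <- generate_phantom(phantom_config(n_frames = 400, seed = 17),
                             render = FALSE)
  s <- summarize_dataset(frames)
  device <- c("PT", "CD", "CM", "CT", "CP")
  other <- c("AA1", "AA2", "STJ1", "STJ2", "FE1", "FE2")
  expect_gt(min(s$per_label_totals[device]), max(s$per_label_totals[other]))
  h <- s$count_histogram
  mode_bin <- which.max(h)
  expect_gt(mode_bin, 1L)
  expect_lt(mode_bin, 11L)
})
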