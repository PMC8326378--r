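test_that("the annulus frame follows the axis conventions", {
  fr <- build_annulus_frame(c(0.4, 0.6), c(0.6, 0.6))
  expect_equal(fr$origin, c(0.5, 0.6))
  expect_equal(fr$x_axis, c(1, 0))
  expect_equal(fr$y_axis, c(0, 1))
  fr2 <- build_annulus_frame(c(0.5, 0.4), c(0.5, 0.8))
  expect_equal(fr2$x_axis, c(0, 1))
  expect_equal(fr2$y_axis, c(-1, 0))
  expect_equal(sum(fr2$x_axis * fr2$y_axis), 0, tolerance = 1e-12)
  expect_error(build_annulus_frame(c(0.5, 0.5), c(0.5, 0.5)), "degenerate")
})

test_that("pigtail binding stores offsets and round-trips exactly", {
  aa1 <- c(0.4, 0.6); aa2 <- c(0.62, 0.58); pt <- c(0.35, 0.64)
  b <- bind_to_pigtail(aa1, aa2, pt)
  expect_equal(b$offset_AA1, aa1 - pt)
  b0 <- bind_to_pigtail(aa1, aa2, aa1)
  expect_equal(b0$offset_AA1, c(0, 0))
  orig <- build_annulus_frame(aa1, aa2)
  rec <- reconstruct_frame(b, pt)
  expect_equal(rec$origin, orig$origin, tolerance = 1e-12)
  expect_equal(rec$x_axis, orig$x_axis, tolerance = 1e-12)
  expect_equal(rec$y_axis, orig$y_axis, tolerance = 1e-12)
  expect_equal(rec$source, "pigtail_reconstructed")
  # offsets are translation-covariant
  d <- c(0.07, -0.03)
  b2 <- bind_to_pigtail(aa1 + d, aa2 + d, pt + d)
  expect_equal(b2$offset_AA1, b$offset_AA1, tolerance = 1e-12)
  # a pure pigtail shift translates the frame without rotating it
  rec2 <- reconstruct_frame(b, pt + c(0.1, 0))
  expect_equal(rec2$origin, orig$origin + c(0.1, 0), tolerance = 1e-12)
  expect_equal(rec2$x_axis, orig$x_axis)
})

test_that("guidance errors match hand dot products", {
  fr <- build_annulus_frame(c(0.4, 0.6), c(0.6, 0.6))
  g <- guidance_report(fr, CT = c(0.55, 0.6), CP = c(0.7, 0.2),
                       CD = c(0.6, 0.4),
                       FE1 = c(0.45, 0.7), FE2 = c(0.55, 0.7))
  expect_equal(g$annulus_catheter_error, 0, tolerance = 1e-12)
  expect_equal(g$annulus_stent_error, 0.1, tolerance = 1e-12)
  expect_equal(g$stent_tilt_deg, 0, tolerance = 1e-9)
  expect_equal(g$extraction_degree, sqrt(0.1^2 + 0.2^2), tolerance = 1e-12)
  g2 <- guidance_report(fr, CT = c(0.5, 0.5), CP = c(0.5, 0.5),
                        CD = c(0.5, 0.5))
  expect_equal(g2$extraction_degree, 0)
  expect_true(is.na(g2$annulus_stent_error))
  expect_error(guidance_report(fr, CT = NULL, CP = c(0, 0), CD = c(0, 0)),
               "required")
})

test_that("points on opposite sides of the annulus have opposite signs", {
  fr <- build_annulus_frame(c(0.3, 0.5), c(0.7, 0.5))
  below <- guidance_report(fr, CT = c(0.5, 0.7), CP = c(0, 0), CD = c(1, 1))
  above <- guidance_report(fr, CT = c(0.5, 0.3), CP = c(0, 0), CD = c(1, 1))
  expect_gt(below$annulus_catheter_error, 0)
  expect_lt(above$annulus_catheter_error, 0)
  expect_equal(below$annulus_catheter_error, -above$annulus_catheter_error,
               tolerance = 1e-12)
})

test_that("guidance magnitudes are invariant under rigid transforms", {
  set.seed(19)
  rot <- function(p, th, d) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    as.numeric(R %*% p) + d
  }
  for (i in 1:200) {
    pts <- lapply(1:7, function(j) runif(2, 0.2, 0.8))
    names(pts) <- c("AA1", "AA2", "CT", "CP", "CD", "FE1", "FE2")
    if (sqrt(sum((pts$AA1 - pts$AA2)^2)) < 0.05) next
    g0 <- guidance_report(build_annulus_frame(pts$AA1, pts$AA2),
                          pts$CT, pts$CP, pts$CD, pts$FE1, pts$FE2)
    th <- runif(1, -pi, pi); d <- runif(2, -0.3, 0.3)
    ptsT <- lapply(pts, rot, th = th, d = d)
    g1 <- guidance_report(build_annulus_frame(ptsT$AA1, ptsT$AA2),
                          ptsT$CT, ptsT$CP, ptsT$CD, ptsT$FE1, ptsT$FE2)
    expect_equal(abs(g1$annulus_catheter_error),
                 abs(g0$annulus_catheter_error), tolerance = 1e-9)
    expect_equal(abs(g1$annulus_stent_error), abs(g0$annulus_stent_error),
                 tolerance = 1e-9)
    expect_equal(g1$stent_tilt_deg, g0$stent_tilt_deg, tolerance = 1e-6)
    expect_equal(g1$extraction_degree, g0$extraction_degree,
                 tolerance = 1e-9)
  }
})

test_that("tracking a frame stream reconstructs contrast-free frames", {
  contrast <- make_frame(c("AA1", "AA2", "PT", "CP", "CD", "CT"),
                         xs = c(0.4, 0.6, 0.35, 0.7, 0.6, 0.52),
                         ys = c(0.6, 0.6, 0.64, 0.2, 0.4, 0.58),
                         contrast_on = TRUE, frame_index = 0L)
  plain <- make_frame(c("PT", "CP", "CD", "CT"),
                      xs = c(0.35, 0.7, 0.6, 0.52) + 0.05,
                      ys = c(0.64, 0.2, 0.4, 0.58),
                      frame_index = 1L)
  orphan <- make_frame(c("CP", "CD", "CT"),
                       xs = c(0.7, 0.6, 0.52), ys = c(0.2, 0.4, 0.58),
                       frame_index = 2L)
  tr <- track_frames(list(contrast, plain, orphan))
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$frame_source, c("contrast", "pigtail_reconstructed", NA))
  # the whole scene translated rigidly: identical signed errors
  expect_equal(tr$annulus_catheter_error[2], tr$annulus_catheter_error[1],
               tolerance = 1e-12)
  expect_true(is.na(tr$extraction_degree[3]))
})
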