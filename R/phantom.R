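#' Configuration of the synthetic aortography phantom
#'
#' Parameters governing generation of aortography-like grayscale frames
#' with ground-truth keypoints. The defaults emulate the structure of
#' clinical TAVI series: three procedure stages, contrast-dependent
#' visibility of the four anatomical landmarks (most frames are
#' acquired without contrast), stent edges visible only at deployment,
#' per-frame keypoint counts spanning 1-11 driven by the insertion
#' depth of the delivery system, and spatially clustered landmark
#' locations.
#'
#' @param n_frames Number of frames to generate (>= 1).
#' @param image_size Side length of the square frame in pixels
#'   (default 256; coordinates are normalized so the model is agnostic
#'   to this).
#' @param stage_mix Named probabilities over
#'   \code{positioning}/\code{retraction}/\code{deployment}, summing
#'   to 1.
#' @param contrast_prob Named per-stage probability that a frame is
#'   contrast-enhanced.
#' @param geometry Named list of geometric priors in normalized units;
#'   see Details.
#' @param jitter_sd Gaussian annotation noise sd applied to the stored
#'   keypoint coordinates (normalized units), emulating labeling error.
#' @param pixel_noise_sd Additive Gaussian image noise sd (8-bit
#'   units).
#' @param pt_prob Probability the pigtail catheter is present (and
#'   rendered) on a frame.
#' @param seed Integer seed; the full dataset is reproducible from it.
#'
#' @details Geometry priors (means/spreads, normalized units): annulus
#' center and width, sinotubular-junction vertical offset, the
#' delivery-catheter path (entry point on the upper border, tip
#' position near the annulus, quadratic bow), the arc distances of the
#' CD/CM/CP landmarks behind the tip, stage-dependent insertion
#' advance, pigtail loop center offset and radius, and the stent edge
#' arc position and half-width. A catheter landmark is visible only
#' while its arc position lies inside the frame, so presence is always
#' consistent with the rendered image.
#'
#' @return List with class \code{"phantom_config"}.
#' @export
phantom_config <- function(n_frames = 500L,
                           image_size = 256L,
                           stage_mix = c(positioning = 0.4,
                                         retraction = 0.3,
                                         deployment = 0.3),
                           contrast_prob = c(positioning = 0.45,
                                             retraction = 0.30,
                                             deployment = 0.30),
                           geometry = list(),
                           jitter_sd = 0.01,
                           pixel_noise_sd = 6,
                           pt_prob = 0.9,
                           seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 1) stop("n_frames must be >= 1")
  stopifnot(image_size >= 16)
  stage_mix <- stage_mix[.kp_stages]
  contrast_prob <- contrast_prob[.kp_stages]
  if (anyNA(stage_mix) || abs(sum(stage_mix) - 1) > 1e-9) {
    stop("stage_mix must cover the three stages and sum to 1")
  }
  if (anyNA(contrast_prob) || any(contrast_prob < 0 | contrast_prob > 1)) {
    stop("contrast_prob must be per-stage probabilities in [0, 1]")
  }
  if (pt_prob < 0 || pt_prob > 1) stop("pt_prob must lie in [0, 1]")
  g <- list(
    annulus_center = c(0.48, 0.58), annulus_center_sd = 0.025,
    annulus_width = 0.24, annulus_width_sd = 0.02,
    stj_offset = 0.14, stj_offset_sd = 0.015, stj_inset = 0.02,
    entry_x = 0.82, entry_x_sd = 0.08,
    tip_offset = c(0.03, -0.02), tip_offset_sd = 0.02,
    bow = 0.07, bow_sd = 0.02,
    d_cd = 0.16, d_cd_sd = 0.010,
    d_cm = 0.34, d_cm_sd = 0.015,
    d_cp = 0.50, d_cp_sd = 0.020,
    advance_max_positioning = 0.38, advance_max_late = 0.20,
    pigtail_offset = c(-0.10, 0.03), pigtail_offset_sd = 0.02,
    pigtail_radius = 0.035, pigtail_radius_sd = 0.004,
    fe_arc = 0.085, fe_arc_sd = 0.015,
    fe_halfwidth = 0.035, fe_halfwidth_sd = 0.004,
    anat_prob = c(AA1 = 1, AA2 = 0.85, STJ1 = 0.9, STJ2 = 0.75),
    fe_prob = 0.9)
  g[names(geometry)] <- geometry
  structure(list(n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 stage_mix = stage_mix, contrast_prob = contrast_prob,
                 geometry = g, jitter_sd = jitter_sd,
                 pixel_noise_sd = pixel_noise_sd, pt_prob = pt_prob,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

.clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Quadratic Bezier from tip to entry, sampled densely; returns the
# sample coordinates and cumulative arc length from the tip.
.catheter_curve <- function(tip, entry, bow, n = 101L) {
  mid <- (tip + entry) / 2
  d <- entry - tip
  len <- sqrt(sum(d^2))
  nrm <- c(-d[2], d[1]) / max(len, 1e-9)
  ctrl <- mid + bow * nrm
  t <- seq(0, 1, length.out = n)
  bx <- (1 - t)^2 * tip[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * entry[1]
  by <- (1 - t)^2 * tip[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * entry[2]
  arc <- c(0, cumsum(sqrt(diff(bx)^2 + diff(by)^2)))
  list(x = bx, y = by, arc = arc, length = arc[n])
}

# Point on the curve at arc distance d from the tip (clamped to the
# curve extent).
.curve_at <- function(curve, d) {
  d <- .clamp(d, 0, curve$length)
  c(stats::approx(curve$arc, curve$x, xout = d)$y,
    stats::approx(curve$arc, curve$y, xout = d)$y)
}

#' Sample one phantom frame geometry
#'
#' Draws the stage, contrast state, full 11-point ground-truth
#' configuration and per-label visibility for one frame, consuming the
#' global RNG stream. Visibility rules: the anatomical landmarks
#' (AA1/AA2/STJ1/STJ2) are visible only on contrast-enhanced frames
#' (and then with graded per-label probabilities, since the downstream
#' annulus points are the hardest to see); FE1/FE2 only at the
#' deployment stage; CT always; CD/CM/CP only while their arc position
#' along the delivery catheter lies inside the frame; PT with
#' probability \code{pt_prob}. The graded rules keep per-frame counts
#' spanning 1-11 with a roughly bell-shaped distribution.
#'
#' @param config A \code{\link{phantom_config}}.
#' @return List with class \code{"phantom_geometry"}: \code{points}
#'   (data frame of all 11 labels), \code{visible} (named logical),
#'   \code{stage}, \code{contrast_on}, plus the internal curve and
#'   marker parameters used by \code{\link{render_frame}}.
#' @export
sample_geometry <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$geometry
  stage <- sample(.kp_stages, 1L, prob = config$stage_mix)
  contrast_on <- stats::runif(1) < config$contrast_prob[[stage]]
  for (try in seq_len(20L)) {
    ac <- g$annulus_center + stats::rnorm(2, 0, g$annulus_center_sd)
    aw <- stats::rnorm(1, g$annulus_width, g$annulus_width_sd)
    if (aw < 0.10) next
    aa1 <- c(ac[1] - aw / 2, ac[2] + stats::rnorm(1, 0, 0.01))
    aa2 <- c(ac[1] + aw / 2, ac[2] + stats::rnorm(1, 0, 0.01))
    if (aa1[1] >= aa2[1]) next
    soff <- stats::rnorm(1, g$stj_offset, g$stj_offset_sd)
    stj1 <- c(aa1[1] + g$stj_inset, aa1[2] - soff) + stats::rnorm(2, 0, 0.008)
    stj2 <- c(aa2[1] - g$stj_inset, aa2[2] - soff) + stats::rnorm(2, 0, 0.008)
    entry <- c(.clamp(stats::rnorm(1, g$entry_x, g$entry_x_sd), 0.55, 0.98), 0)
    base_tip <- ac + g$tip_offset + stats::rnorm(2, 0, g$tip_offset_sd)
    adv_max <- if (stage == "positioning") g$advance_max_positioning else g$advance_max_late
    adv <- stats::runif(1, 0, adv_max)
    dir <- entry - base_tip
    dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
    tip <- base_tip + adv * dir
    bow <- stats::rnorm(1, g$bow, g$bow_sd)
    curve <- .catheter_curve(tip, entry, bow)
    if (curve$length < 0.08) next
    d_cd <- stats::rnorm(1, g$d_cd, g$d_cd_sd)
    d_cm <- stats::rnorm(1, g$d_cm, g$d_cm_sd)
    d_cp <- stats::rnorm(1, g$d_cp, g$d_cp_sd)
    if (!(0.02 < d_cd && d_cd < d_cm && d_cm < d_cp)) next
    cd <- .curve_at(curve, d_cd)
    cm <- .curve_at(curve, d_cm)
    cp <- .curve_at(curve, d_cp)
    ptc <- ac + g$pigtail_offset + stats::rnorm(2, 0, g$pigtail_offset_sd)
    ptr <- max(stats::rnorm(1, g$pigtail_radius, g$pigtail_radius_sd), 0.02)
    fe_arc <- .clamp(stats::rnorm(1, g$fe_arc, g$fe_arc_sd), 0.03, d_cd - 0.02)
    fe_hw <- max(stats::rnorm(1, g$fe_halfwidth, g$fe_halfwidth_sd), 0.015)
    fe_mid <- .curve_at(curve, fe_arc)
    fe_ahead <- .curve_at(curve, fe_arc + 0.01)
    tang <- fe_ahead - fe_mid
    tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
    perp <- c(-tang[2], tang[1])
    fe1 <- fe_mid - fe_hw * perp
    fe2 <- fe_mid + fe_hw * perp
    pts <- rbind(AA1 = aa1, AA2 = aa2, STJ1 = stj1, STJ2 = stj2,
                 CP = cp, CM = cm, CD = cd, CT = tip, PT = ptc,
                 FE1 = fe1, FE2 = fe2)
    pts <- .clamp(pts)
    margin <- 0.02
    anat_vis <- contrast_on & stats::runif(4) < g$anat_prob
    fe_vis <- (stage == "deployment") & stats::runif(2) < g$fe_prob
    visible <- c(AA1 = anat_vis[[1]], AA2 = anat_vis[[2]],
                 STJ1 = anat_vis[[3]], STJ2 = anat_vis[[4]],
                 CP = d_cp <= curve$length - margin,
                 CM = d_cm <= curve$length - margin,
                 CD = d_cd <= curve$length - margin,
                 CT = TRUE,
                 PT = stats::runif(1) < config$pt_prob,
                 FE1 = fe_vis[[1]], FE2 = fe_vis[[2]])
    if (any(pts[visible, ] < 0.01 | pts[visible, ] > 0.99)) next
    return(structure(list(
      points = data.frame(label = rownames(pts), x = pts[, 1], y = pts[, 2],
                          row.names = NULL),
      visible = visible, stage = stage, contrast_on = contrast_on,
      curve = curve, pigtail_radius = ptr, fe_arc = fe_arc,
      arc = c(CD = d_cd, CM = d_cm, CP = d_cp)),
      class = "phantom_geometry"))
  }
  stop("failed to sample a non-degenerate phantom geometry in 20 tries")
}

# Pixel-center grids per image size, cached.
.grid_cache <- new.env(parent = emptyenv())
.pixel_grid <- function(S) {
  key <- as.character(S)
  if (is.null(.grid_cache[[key]])) {
    row <- rep(seq_len(S), times = S)
    col <- rep(seq_len(S), each = S)
    .grid_cache[[key]] <- list(px = (col - 0.5) / S, py = (row - 0.5) / S)
  }
  .grid_cache[[key]]
}

# Minimum squared distance from each grid pixel to a set of points.
.min_dist2 <- function(px, py, xs, ys) {
  d2 <- rep(Inf, length(px))
  for (i in seq_along(xs)) {
    d2 <- pmin(d2, (px - xs[i])^2 + (py - ys[i])^2)
  }
  d2
}

# Subtract a Gaussian-profile dark stamp around a point set.
.stamp <- function(img, grid, xs, ys, depth, sigma) {
  d2 <- .min_dist2(grid$px, grid$py, xs, ys)
  img - depth * exp(-d2 / sigma^2)
}

.segment_points <- function(a, b, n = 20L) {
  t <- seq(0, 1, length.out = n)
  list(x = a[1] + t * (b[1] - a[1]), y = a[2] + t * (b[2] - a[2]))
}

#' Render one phantom frame
#'
#' Draws the dark delivery-catheter curve (with radiopaque marker
#' bands at CD/CP and the tip), the pigtail loop, the stent edge marks
#' at deployment, and a contrast silhouette of the aortic root on
#' contrast-enhanced frames, on a bright fluoroscopy background with
#' additive Gaussian noise clipped to [0, 255]. The annotation lists
#' exactly the visible keypoints, each perturbed by the configured
#' labeling jitter.
#'
#' @param geometry A \code{\link{sample_geometry}} result.
#' @param config The \code{\link{phantom_config}}.
#' @param series_id,frame_index Metadata stored on the frame.
#' @param render If \code{FALSE}, skip the image (annotation-only
#'   frame); the annotation is identical either way because pixel noise
#'   is drawn after all geometric quantities.
#' @return An \code{\link{annotated_frame}}.
#' @export
render_frame <- function(geometry, config, series_id = "ph00",
                         frame_index = 0L, render = TRUE,
                         noise_seed = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  pts <- geometry$points
  vis <- geometry$visible
  kdf <- pts[vis[pts$label], , drop = FALSE]
  kdf$x <- .clamp(kdf$x + stats::rnorm(nrow(kdf), 0, config$jitter_sd))
  kdf$y <- .clamp(kdf$y + stats::rnorm(nrow(kdf), 0, config$jitter_sd))
  img <- NULL
  if (render) {
    S <- config$image_size
    grid <- .pixel_grid(S)
    img <- rep(215, S * S)
    p <- function(lbl) unlist(pts[pts$label == lbl, c("x", "y")], use.names = FALSE)
    if (geometry$contrast_on) {
      corners <- rbind(p("STJ1"), p("STJ2"),
                       p("AA2") + c(0, 0.05), p("AA1") + c(0, 0.05))
      ctr <- colMeans(corners)
      corners <- sweep(sweep(corners, 2, ctr), 1, 1.25, "*")
      corners <- sweep(corners, 2, ctr, "+")
      inside <- rep(TRUE, length(grid$px))
      for (i in 1:4) {
        a <- corners[i, ]; b <- corners[if (i == 4) 1 else i + 1, ]
        cr <- (b[1] - a[1]) * (grid$py - a[2]) - (b[2] - a[2]) * (grid$px - a[1])
        inside <- inside & cr >= 0
      }
      img <- img - 55 * inside
    }
    cur <- geometry$curve
    keep <- seq(1, length(cur$x), length.out = 120L)
    img <- .stamp(img, grid, cur$x[keep], cur$y[keep], 130, 0.010)
    img <- .stamp(img, grid, p("CT")[1], p("CT")[2], 120, 0.014)
    if (vis[["CD"]]) img <- .stamp(img, grid, p("CD")[1], p("CD")[2], 90, 0.011)
    if (vis[["CP"]]) img <- .stamp(img, grid, p("CP")[1], p("CP")[2], 70, 0.011)
    if (vis[["PT"]]) {
      ptc <- p("PT")
      d <- abs(sqrt((grid$px - ptc[1])^2 + (grid$py - ptc[2])^2) -
                 geometry$pigtail_radius)
      img <- img - 120 * exp(-(d / 0.008)^2)
    }
    if (geometry$stage == "deployment") {
      sp <- .segment_points(p("FE1"), p("FE2"))
      img <- .stamp(img, grid, sp$x, sp$y, 110, 0.010)
      crown <- .curve_at(cur, 0.02)
      for (fe in list(p("FE1"), p("FE2"))) {
        sp <- .segment_points(fe, crown, 15L)
        img <- .stamp(img, grid, sp$x, sp$y, 100, 0.008)
      }
    }
    if (config$pixel_noise_sd > 0) {
      noise <- if (is.null(noise_seed)) {
        stats::rnorm(S * S, 0, config$pixel_noise_sd)
      } else {
        with_seed(noise_seed, stats::rnorm(S * S, 0, config$pixel_noise_sd))
      }
      img <- img + noise
    }
    img <- matrix(round(.clamp(img, 0, 255)), S, S)
  }
  annotated_frame(image = img, keypoints = kdf, stage = geometry$stage,
                  contrast_on = geometry$contrast_on, series_id = series_id,
                  frame_index = frame_index)
}

#' Generate a synthetic phantom dataset
#'
#' Fully reproducible from the seed in the configuration: the same
#' configuration yields a byte-identical dataset.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param render If \code{FALSE}, frames carry annotations only (much
#'   faster; annotations are identical to the rendered run).
#' @return List of \code{\link{annotated_frame}}s of length
#'   \code{config$n_frames}.
#' @export
generate_phantom <- function(config, render = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_frames), function(i) {
      geom <- sample_geometry(config)
      # image noise uses a per-frame derived seed so that rendering
      # does not shift the geometry stream (annotations are identical
      # with render = FALSE)
      noise_seed <- sample.int(2147483646L, 1L)
      render_frame(geom, config,
                   series_id = sprintf("ph%02d", 1L + (i - 1L) %/% 50L),
                   frame_index = i - 1L, render = render,
                   noise_seed = noise_seed)
    })
  })
}
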