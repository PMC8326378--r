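# Intraoperative guidance geometry: a local orthogonal 2-D frame
# anchored on the aortic annulus (AA1-AA2), pigtail binding for
# contrast-free reconstruction, and the positioning/deployment error
# measures derived from it.

.as_xy <- function(p) {
  if (inherits(p, "keypoint")) return(c(p$x, p$y))
  if (is.numeric(p) && length(p) == 2L) return(as.numeric(p))
  stop("expected a keypoint or a length-2 numeric (x, y)")
}

#' Build the annulus coordinate frame
#'
#' The aortic annulus points AA1 and AA2 define the X-axis (the
#' annulus plane); the Y-axis is the X-axis rotated +90 degrees in
#' image coordinates, which points image-downward (toward the
#' ventricle) in the canonical AA1-left-of-AA2 orientation. The origin
#' is the AA1-AA2 midpoint.
#'
#' @param AA1,AA2 Keypoints or (x, y) vectors; must be distinct.
#' @param source \code{"contrast"} (measured during contrast
#'   injection) or \code{"pigtail_reconstructed"}.
#' @return List with class \code{"annulus_frame"}: \code{origin},
#'   \code{x_axis}, \code{y_axis} (unit vectors), \code{source}.
#' @export
build_annulus_frame <- function(AA1, AA2, source = "contrast") {
  a1 <- .as_xy(AA1)
  a2 <- .as_xy(AA2)
  d <- a2 - a1
  len <- sqrt(sum(d^2))
  if (len <= 1e-6) stop("degenerate annulus: AA1 and AA2 coincide")
  x_axis <- d / len
  y_axis <- c(-x_axis[2], x_axis[1])
  structure(list(origin = (a1 + a2) / 2, x_axis = x_axis, y_axis = y_axis,
                 source = source),
            class = "annulus_frame")
}

#' Bind the annulus to the pigtail catheter
#'
#' Captures the offsets from the pigtail landmark to AA1 and AA2 on a
#' contrast-enhanced frame, so the annulus frame can be reconstructed
#' from the pigtail alone once contrast has washed out.
#'
#' @param AA1,AA2,PT Keypoints or (x, y) vectors from the same
#'   contrast-enhanced image.
#' @return List with class \code{"pigtail_binding"}:
#'   \code{offset_AA1}, \code{offset_AA2}.
#' @export
bind_to_pigtail <- function(AA1, AA2, PT) {
  a1 <- .as_xy(AA1); a2 <- .as_xy(AA2); pt <- .as_xy(PT)
  o1 <- a1 - pt
  o2 <- a2 - pt
  if (sqrt(sum((o1 - o2)^2)) <= 1e-6) {
    stop("binding would reconstruct a degenerate annulus")
  }
  structure(list(offset_AA1 = o1, offset_AA2 = o2),
            class = "pigtail_binding")
}

#' Reconstruct the annulus frame from the pigtail
#'
#' Applies the stored offsets to a newly tracked pigtail position:
#' virtual annulus points \code{PT + offset} rebuild the frame, marked
#' \code{pigtail_reconstructed}.
#'
#' @param binding A \code{\link{bind_to_pigtail}} result.
#' @param PT_new Current pigtail keypoint or (x, y).
#' @return An \code{annulus_frame}.
#' @export
reconstruct_frame <- function(binding, PT_new) {
  stopifnot(inherits(binding, "pigtail_binding"))
  pt <- .as_xy(PT_new)
  build_annulus_frame(pt + binding$offset_AA1, pt + binding$offset_AA2,
                      source = "pigtail_reconstructed")
}

#' Positioning and deployment error measures
#'
#' In the annulus frame: the annulus-catheter error is the signed
#' Y-coordinate of the catheter tip (its distance from the annulus
#' plane); the annulus-stent error is the signed Y-coordinate of the
#' FE1-FE2 midpoint; the stent tilt is the angle (degrees, in
#' [0, 90]) between the stent edge line and the annulus plane; the
#' extraction degree is the Euclidean CP-CD distance, which grows as
#' the prosthesis is extracted from the capsule.
#'
#' @param frame An \code{annulus_frame}.
#' @param CT,CP,CD Required keypoints or (x, y) vectors.
#' @param FE1,FE2 Optional stent edge keypoints; stent fields are
#'   \code{NA} when not deployed.
#' @return List with class \code{"guidance_report"}:
#'   \code{annulus_catheter_error}, \code{annulus_stent_error},
#'   \code{stent_tilt_deg}, \code{extraction_degree},
#'   \code{frame_source}.
#' @export
guidance_report <- function(frame, CT, CP, CD, FE1 = NULL, FE2 = NULL) {
  stopifnot(inherits(frame, "annulus_frame"))
  if (missing(CT) || missing(CP) || missing(CD) ||
      is.null(CT) || is.null(CP) || is.null(CD)) {
    stop("CT, CP and CD are required for a guidance report")
  }
  ct <- .as_xy(CT); cp <- .as_xy(CP); cd <- .as_xy(CD)
  cat_err <- sum((ct - frame$origin) * frame$y_axis)
  stent_err <- NA_real_
  tilt <- NA_real_
  if (!is.null(FE1) && !is.null(FE2)) {
    f1 <- .as_xy(FE1); f2 <- .as_xy(FE2)
    mid <- (f1 + f2) / 2
    stent_err <- sum((mid - frame$origin) * frame$y_axis)
    d <- f2 - f1
    len <- sqrt(sum(d^2))
    if (len > 1e-9) {
      cosang <- min(1, abs(sum(d / len * frame$x_axis)))
      tilt <- acos(cosang) * 180 / pi
    }
  }
  structure(list(annulus_catheter_error = cat_err,
                 annulus_stent_error = stent_err,
                 stent_tilt_deg = tilt,
                 extraction_degree = sqrt(sum((cp - cd)^2)),
                 frame_source = frame$source),
            class = "guidance_report")
}

#' Track a sequence of keypoint frames
#'
#' Streams per-frame keypoint sets through the guidance geometry. On
#' contrast-enhanced frames carrying AA1 and AA2 the annulus frame is
#' measured directly (and re-bound to the pigtail when PT is present);
#' on contrast-free frames it is reconstructed from the most recent
#' binding and the current PT. Frames without enough information give
#' \code{NA} rows.
#'
#' @param frames List of \code{aort_frame}s (annotations or decoded
#'   predictions; images not needed).
#' @return Data frame, one row per input frame: \code{series_id},
#'   \code{frame_index}, \code{frame_source},
#'   \code{annulus_catheter_error}, \code{annulus_stent_error},
#'   \code{stent_tilt_deg}, \code{extraction_degree}.
#' @export
track_frames <- function(frames) {
  binding <- NULL
  rows <- lapply(frames, function(f) {
    kp <- f$keypoints
    get <- function(lbl) {
      i <- match(lbl, kp$label)
      if (is.na(i)) NULL else c(kp$x[i], kp$y[i])
    }
    aa1 <- get("AA1"); aa2 <- get("AA2"); pt <- get("PT")
    fr <- NULL
    if (!is.null(aa1) && !is.null(aa2)) {
      fr <- tryCatch(build_annulus_frame(aa1, aa2), error = function(e) NULL)
      if (!is.null(fr) && !is.null(pt)) {
        binding <<- bind_to_pigtail(aa1, aa2, pt)
      }
    } else if (!is.null(binding) && !is.null(pt)) {
      fr <- tryCatch(reconstruct_frame(binding, pt),
                     error = function(e) NULL)
    }
    ct <- get("CT"); cp <- get("CP"); cd <- get("CD")
    rep_row <- data.frame(series_id = f$series_id,
                          frame_index = f$frame_index,
                          frame_source = NA_character_,
                          annulus_catheter_error = NA_real_,
                          annulus_stent_error = NA_real_,
                          stent_tilt_deg = NA_real_,
                          extraction_degree = NA_real_)
    if (!is.null(fr) && !is.null(ct) && !is.null(cp) && !is.null(cd)) {
      g <- guidance_report(fr, ct, cp, cd, get("FE1"), get("FE2"))
      rep_row$frame_source <- g$frame_source
      rep_row$annulus_catheter_error <- g$annulus_catheter_error
      rep_row$annulus_stent_error <- g$annulus_stent_error
      rep_row$stent_tilt_deg <- g$stent_tilt_deg
      rep_row$extraction_degree <- g$extraction_degree
    }
    rep_row
  })
  do.call(rbind, rows)
}

#' @export
print.guidance_report <- function(x, digits = 4, ...) {
  cat(sprintf(paste0("Guidance (%s frame): annulus-catheter %.*f, ",
                     "annulus-stent %s, tilt %s deg, extraction %.*f\n"),
              x$frame_source, digits, x$annulus_catheter_error,
              if (is.na(x$annulus_stent_error)) "NA" else
                format(round(x$annulus_stent_error, digits)),
              if (is.na(x$stent_tilt_deg)) "NA" else
                format(round(x$stent_tilt_deg, digits)),
              digits, x$extraction_degree))
  invisible(x)
}
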