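#' Read keypoint annotations
#'
#' Reads an annotation file in the package's Supervisely-like JSON
#' dialect: a top-level list of objects
#' \code{{"image": name, "size": {"width", "height"},
#' "points": [{"label", "x_px", "y_px"}], "meta": {...}}}.
#' Pixel coordinates are normalized by the image width/height into
#' [0, 1]. Frames with zero points are skipped with a warning; unknown
#' point names and out-of-bounds coordinates are errors.
#'
#' @param path Path to the JSON annotation file.
#' @param image_dir Directory holding the referenced 8-bit grayscale
#'   PNG images, or \code{NULL} to load annotations only.
#' @return List of \code{\link{annotated_frame}} objects.
#' @export
read_annotations <- function(path, image_dir = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(entries)) stop("malformed annotation file: expected a JSON array")
  frames <- list()
  for (e in entries) {
    if (is.null(e$image) || is.null(e$size)) {
      stop("malformed annotation entry: missing image/size")
    }
    w <- as.numeric(e$size$width)
    h <- as.numeric(e$size$height)
    pts <- e$points
    if (length(pts) == 0L) {
      warning("skipping frame with zero keypoints: ", e$image)
      next
    }
    kdf <- do.call(rbind, lapply(pts, function(p) {
      kp_index(p$label)
      xp <- as.numeric(p$x_px); yp <- as.numeric(p$y_px)
      if (xp < 0 || xp > w || yp < 0 || yp > h) {
        stop("coordinate outside image bounds for ", p$label, " in ", e$image)
      }
      data.frame(label = p$label, x = xp / w, y = yp / h)
    }))
    img <- NULL
    if (!is.null(image_dir)) {
      img <- read_frame_png(file.path(image_dir, e$image))
    }
    meta <- e$meta
    frames[[length(frames) + 1L]] <- annotated_frame(
      image = img, keypoints = kdf,
      stage = if (!is.null(meta$stage)) meta$stage else "positioning",
      contrast_on = isTRUE(meta$contrast_on),
      series_id = if (!is.null(meta$series_id)) meta$series_id else "s0",
      frame_index = if (!is.null(meta$frame_index)) meta$frame_index else 0L)
  }
  frames
}

#' Write keypoint annotations (and images)
#'
#' Writes the JSON dialect read by \code{\link{read_annotations}} and,
#' when frames carry images, one grayscale PNG per frame named
#' \code{<series>_<index>.png}.
#'
#' @param frames List of \code{aort_frame}s.
#' @param dir Output directory (created if missing); the annotation
#'   file is \code{annotations.json} inside it, images go to
#'   \code{images/}.
#' @return Invisibly, the annotation file path.
#' @export
write_annotations <- function(frames, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(frames, function(f) {
    sz <- if (is.null(f$image)) c(1000L, 1000L) else rev(dim(f$image))
    name <- sprintf("%s_%05d.png", f$series_id, f$frame_index)
    if (!is.null(f$image)) {
      write_frame_png(f$image, file.path(dir, "images", name))
    }
    list(image = name,
         size = list(width = sz[1], height = sz[2]),
         points = lapply(seq_len(nrow(f$keypoints)), function(i) {
           list(label = f$keypoints$label[i],
                x_px = f$keypoints$x[i] * sz[1],
                y_px = f$keypoints$y[i] * sz[2])
         }),
         meta = list(stage = f$stage, contrast_on = f$contrast_on,
                     series_id = f$series_id, frame_index = f$frame_index))
  })
  path <- file.path(dir, "annotations.json")
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a 0-255 matrix
#' @param path PNG file path.
#' @return Numeric matrix, rows = image rows.
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  round(a * 255)
}

#' Write a 0-255 matrix as an 8-bit grayscale PNG
#' @param image Numeric matrix with values in [0, 255].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_frame_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}
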