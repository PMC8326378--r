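#' The 11-keypoint vocabulary
#'
#' Canonical landmark labels for TAVI aortography, in fixed order:
#' the aortic annulus pair (\code{AA1}, \code{AA2}), the sinotubular
#' junction pair (\code{STJ1}, \code{STJ2}), the delivery-catheter
#' landmarks (\code{CP} proximal, \code{CM} middle, \code{CD} distal,
#' \code{CT} tip), the pigtail reference catheter (\code{PT}) and the
#' stent frame edges (\code{FE1}, \code{FE2}). Every 11- or 22-long
#' vector in the package uses this order; coordinate vectors interleave
#' as \code{[x1, y1, x2, y2, ...]}.
#'
#' @return Character vector of length 11.
#' @export
kp_labels <- function() {
  c("AA1", "AA2", "STJ1", "STJ2", "CP", "CM", "CD", "CT", "PT", "FE1", "FE2")
}

#' Zero-based canonical index of a keypoint label
#'
#' @param label Character vector of labels.
#' @return Integer vector in 0..10.
#' @export
kp_index <- function(label) {
  idx <- match(label, kp_labels())
  if (anyNA(idx)) {
    stop("unknown keypoint label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

.kp_stages <- c("positioning", "retraction", "deployment")

#' Construct a single keypoint
#'
#' @param label One of \code{kp_labels()}.
#' @param x,y Normalized coordinates in [0, 1] (origin top-left, x
#'   rightward, y downward).
#' @return A list with class \code{"keypoint"}.
#' @export
keypoint <- function(label, x, y) {
  kp_index(label)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (x < 0 || x > 1 || y < 0 || y > 1) {
    stop("keypoint coordinates must lie in [0, 1]; got (", x, ", ", y, ")")
  }
  structure(list(label = label, x = as.numeric(x), y = as.numeric(y)),
            class = "keypoint")
}

#' Construct an annotated frame
#'
#' One grayscale image together with its visible keypoints and
#' acquisition metadata.
#'
#' @param image Numeric matrix (rows = image rows), values in [0, 255],
#'   or \code{NULL} for annotation-only frames.
#' @param keypoints A data frame with columns \code{label}, \code{x},
#'   \code{y} (normalized), distinct labels, or a list of
#'   \code{keypoint} objects.
#' @param stage One of \code{"positioning"}, \code{"retraction"},
#'   \code{"deployment"}.
#' @param contrast_on Logical: was this frame contrast-enhanced?
#' @param series_id Identifier of the imaging series.
#' @param frame_index Non-negative integer index within the series.
#' @return A list with class \code{"aort_frame"}.
#' @export
annotated_frame <- function(image, keypoints, stage = "positioning",
                            contrast_on = FALSE, series_id = "s0",
                            frame_index = 0L) {
  if (is.list(keypoints) && !is.data.frame(keypoints)) {
    keypoints <- do.call(rbind, lapply(keypoints, function(k) {
      data.frame(label = k$label, x = k$x, y = k$y)
    }))
  }
  stopifnot(is.data.frame(keypoints),
            all(c("label", "x", "y") %in% names(keypoints)))
  keypoints$label <- as.character(keypoints$label)
  kp_index(keypoints$label)
  if (anyDuplicated(keypoints$label)) stop("duplicate keypoint labels in frame")
  n <- nrow(keypoints)
  if (n < 1L || n > 11L) stop("a frame must carry between 1 and 11 keypoints")
  if (any(keypoints$x < 0 | keypoints$x > 1 | keypoints$y < 0 | keypoints$y > 1)) {
    stop("normalized keypoint coordinates must lie in [0, 1]")
  }
  if (!is.null(image)) {
    stopifnot(is.matrix(image))
    if (min(image) < 0 || max(image) > 255) stop("pixel values must lie in [0, 255]")
  }
  stage <- match.arg(stage, .kp_stages)
  structure(list(image = image,
                 keypoints = keypoints[order(kp_index(keypoints$label)),
                                       c("label", "x", "y"), drop = FALSE],
                 stage = stage, contrast_on = isTRUE(contrast_on),
                 series_id = as.character(series_id),
                 frame_index = as.integer(frame_index)),
            class = "aort_frame")
}

#' @export
print.aort_frame <- function(x, ...) {
  sz <- if (is.null(x$image)) "no image" else paste(dim(x$image), collapse = "x")
  cat(sprintf("<aort_frame %s/%d: %s, stage %s, contrast %s, %d keypoint(s): %s>\n",
              x$series_id, x$frame_index, sz, x$stage, x$contrast_on,
              nrow(x$keypoints), paste(x$keypoints$label, collapse = " ")))
  invisible(x)
}

#' Encode a frame into supervised targets
#'
#' Produces the presence vector (length 11), the interleaved coordinate
#' vector (length 22) and the coordinate mask (length 22). Slots of
#' absent keypoints hold the placeholder 0 and a mask of 0 so that they
#' can never leak into the regression loss or metrics.
#'
#' @param frame An \code{aort_frame}.
#' @return List with class \code{"target_encoding"}: \code{presence},
#'   \code{coords}, \code{mask}.
#' @export
encode_targets <- function(frame) {
  stopifnot(inherits(frame, "aort_frame"))
  presence <- numeric(11L)
  coords <- numeric(22L)
  idx <- kp_index(frame$keypoints$label) + 1L
  presence[idx] <- 1
  coords[2L * idx - 1L] <- frame$keypoints$x
  coords[2L * idx] <- frame$keypoints$y
  mask <- rep(presence, each = 2L)
  structure(list(presence = presence, coords = coords, mask = mask),
            class = "target_encoding")
}

#' Decode a target encoding back into a keypoint table
#'
#' Inverse of \code{\link{encode_targets}} on the keypoint set.
#'
#' @param encoding A \code{target_encoding}.
#' @return Data frame with columns \code{label}, \code{x}, \code{y}.
#' @export
decode_targets <- function(encoding) {
  idx <- which(encoding$presence >= 0.5)
  data.frame(label = kp_labels()[idx],
             x = encoding$coords[2L * idx - 1L],
             y = encoding$coords[2L * idx])
}

#' Split a dataset into training and validation parts
#'
#' Seeded uniform shuffle at frame level; the training size is
#' \code{floor(train_fraction * n + 0.5)}, which reproduces the
#' 2,984 / 746 partition of 3,730 frames at 80 percent. Grouped
#' splitting (all frames of a series on the same side) is available for
#' leakage-free evaluation of sequence data.
#'
#' @param frames List of frames (or any list).
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param by_series Logical; if \code{TRUE}, shuffle and split whole
#'   series (requires elements with a \code{series_id}).
#' @return List with elements \code{train} and \code{valid}.
#' @export
split_dataset <- function(frames, train_fraction = 0.8, seed = 1L,
                          by_series = FALSE) {
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  if (by_series) {
    sids <- vapply(frames, function(f) f$series_id, character(1))
    u <- unique(sids)
    perm <- with_seed(seed, sample.int(length(u)))
    n_tr_series <- floor(train_fraction * length(u) + 0.5)
    tr_sids <- u[perm[seq_len(n_tr_series)]]
    take <- sids %in% tr_sids
    return(list(train = frames[take], valid = frames[!take]))
  }
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(train_fraction * n + 0.5)
  list(train = frames[perm[seq_len(n_train)]],
       valid = frames[perm[seq.int(n_train + 1L, n)]])
}

#' Summarize a keypoint dataset
#'
#' The exploratory summaries of an annotated set: the per-frame
#' keypoint-count histogram, the number of frames containing each label,
#' and per-label coordinate scatter.
#'
#' @param frames Non-empty list of \code{aort_frame}s.
#' @return List with class \code{"dataset_summary"}:
#'   \code{count_histogram} (named vector over 1..11),
#'   \code{per_label_totals} (named vector over the 11 labels),
#'   \code{scatter} (data frame label/x/y).
#' @export
summarize_dataset <- function(frames) {
  if (length(frames) == 0L) stop("cannot summarize an empty dataset")
  counts <- vapply(frames, function(f) nrow(f$keypoints), integer(1))
  hist <- table(factor(counts, levels = 1:11))
  totals <- stats::setNames(integer(11L), kp_labels())
  for (f in frames) totals[f$keypoints$label] <- totals[f$keypoints$label] + 1L
  scatter <- do.call(rbind, lapply(frames, function(f) f$keypoints))
  structure(list(count_histogram = stats::setNames(as.integer(hist), 1:11),
                 per_label_totals = totals,
                 scatter = scatter),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Dataset summary over", sum(x$count_histogram), "frames\n")
  cat("Keypoints per frame:\n")
  print(x$count_histogram)
  cat("Frames containing each label:\n")
  print(x$per_label_totals)
  invisible(x)
}

#' Export a dataset summary as CSV files
#'
#' Writes \code{counts.csv} (one row per per-frame count bin),
#' \code{labels.csv} (one row per label) and \code{scatter.csv}.
#'
#' @param summary A \code{dataset_summary}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_summary_csv <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "counts.csv")
  p2 <- file.path(dir, "labels.csv")
  p3 <- file.path(dir, "scatter.csv")
  utils::write.csv(data.frame(keypoints_per_frame = 1:11,
                              frames = summary$count_histogram),
                   p1, row.names = FALSE)
  utils::write.csv(data.frame(label = names(summary$per_label_totals),
                              frames = summary$per_label_totals),
                   p2, row.names = FALSE)
  utils::write.csv(summary$scatter, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

# Run code under a temporary RNG state; restores .Random.seed afterwards
# so library calls never disturb the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
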