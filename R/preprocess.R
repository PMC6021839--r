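## Minimal stand-in for the acquisition chain of an overhead depth camera:
## depth interpolation, foreground extraction by background differencing, and
## the size gate that declares a connected component a touching pair.
## Depth frames are numeric matrices; undefined depth is NA internally and the
## sentinel 0 on disk.

#' Gate configuration
#'
#' @param size_threshold components with strictly more pixels are treated as a
#'   touching pair (default 500, the published operating point for weaning
#'   pigs at 256 x 212 resolution).
#' @param single_pig_size reference size of a single animal (default 350,
#'   roughly length 35 x width 10).
#' @return list of class `ts_gate_config`.
#' @export
gate_config <- function(size_threshold = 500L, single_pig_size = 350L) {
  stopifnot(size_threshold > 0)
  structure(list(size_threshold = as.integer(size_threshold),
                 single_pig_size = as.integer(single_pig_size)),
            class = "ts_gate_config")
}

#' Halve resolution with a 2 x 2 mean window
#'
#' Each output pixel is the mean of the valid (non-NA) pixels of its 2 x 2
#' block; a block with no valid pixel stays NA. Odd dimensions are padded by
#' edge replication first. A 512 x 424 frame becomes 256 x 212.
#'
#' @param frame numeric matrix, NA = undefined depth.
#' @return numeric matrix with halved dimensions.
#' @export
spatial_interpolate_2x2 <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr %% 2L == 1L) { frame <- rbind(frame, frame[nr, ]); nr <- nr + 1L }
  if (nc %% 2L == 1L) { frame <- cbind(frame, frame[, nc]); nc <- nc + 1L }
  a <- frame[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE]
  b <- frame[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE]
  c_ <- frame[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]
  d <- frame[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]
  tot <- ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b) +
    ifelse(is.na(c_), 0, c_) + ifelse(is.na(d), 0, d)
  cnt <- (!is.na(a)) + (!is.na(b)) + (!is.na(c_)) + (!is.na(d))
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Average a pixel across three consecutive frames
#'
#' Per pixel, the mean of the valid values among the current frame and the two
#' following frames; NA only where all three are undefined. Values are kept as
#' reals internally and quantized only on export.
#'
#' @param current,next1,next2 numeric matrices of identical dimensions.
#' @return numeric matrix.
#' @export
temporal_interpolate <- function(current, next1, next2) {
  if (!all(dim(current) == dim(next1)) || !all(dim(current) == dim(next2))) {
    ts_error("DIM_MISMATCH", "frames must share dimensions")
  }
  tot <- ifelse(is.na(current), 0, current) + ifelse(is.na(next1), 0, next1) +
    ifelse(is.na(next2), 0, next2)
  cnt <- (!is.na(current)) + (!is.na(next1)) + (!is.na(next2))
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Foreground by depth differencing against a background frame
#'
#' A pixel is foreground iff both depths are valid and the scene point is at
#' least `depth_delta` nearer the overhead camera than the background floor
#' (background - current >= depth_delta). Undefined depth is background.
#'
#' @param frame,background numeric matrices of identical dimensions.
#' @param depth_delta positive height threshold in depth units.
#' @return binary mask matrix.
#' @export
foreground_mask <- function(frame, background, depth_delta) {
  if (!all(dim(frame) == dim(background))) {
    ts_error("DIM_MISMATCH", "frame and background must share dimensions")
  }
  stopifnot(depth_delta > 0)
  fg <- !is.na(frame) & !is.na(background) & (background - frame >= depth_delta)
  matrix(as.integer(fg), nrow(frame), ncol(frame))
}

#' Extract touching-pair blobs from a component label map
#'
#' Components whose pixel count strictly exceeds `cfg$size_threshold` are
#' returned as individual masks, each cropped to the component bounding box
#' plus a 2-pixel margin.
#'
#' @param labels integer matrix from [label_components()].
#' @param cfg a [gate_config()].
#' @return list of masks (possibly empty); each has attributes `offset`
#'   (row, col of the crop origin in the source frame).
#' @export
gate_touching <- function(labels, cfg = gate_config()) {
  out <- list()
  if (max(labels) == 0L) return(out)
  nr <- nrow(labels); nc <- ncol(labels)
  for (k in seq_len(max(labels))) {
    idx <- which(labels == k)
    if (length(idx) <= cfg$size_threshold) next
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    top <- max(1L, min(r) - 2L); bottom <- min(nr, max(r) + 2L)
    left <- max(1L, min(c) - 2L); right <- min(nc, max(c) + 2L)
    m <- matrix(0L, bottom - top + 1L, right - left + 1L)
    m[cbind(r - top + 1L, c - left + 1L)] <- 1L
    attr(m, "offset") <- c(row = top, col = left)
    out[[length(out) + 1L]] <- m
  }
  out
}
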