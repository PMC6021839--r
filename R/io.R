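## Text raster I/O. Masks, label maps and depth frames travel as plain-text
## NetPBM PGM (P2): masks 0/255, label maps {0,1,2}, depth frames 16-bit with
## sentinel 0 = undefined depth. Candidate boxes travel as JSON.

#' Read a plain (P2) PGM file
#' @param path file path.
#' @return numeric matrix; attribute `maxval` carries the stated maximum.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) ts_error("FILE_NOT_FOUND", paste("no such file:", path))
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") ts_error("BAD_FORMAT", "only plain P2 PGM is supported")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  maxv <- as.integer(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) ts_error("BAD_FORMAT", "pixel count mismatch")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  attr(m, "maxval") <- maxv
  m
}

#' Write a plain (P2) PGM file
#' @param mat numeric matrix of non-negative integers.
#' @param path file path.
#' @param maxval stated maximum pixel value.
#' @export
write_pgm <- function(mat, path, maxval = 255L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  writeLines(apply(mat, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname read_pgm
#' @export
read_mask <- function(path) as_mask(read_pgm(path))

#' Write a binary mask (0/255) PGM
#' @param mask binary matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) write_pgm(as_mask(mask) * 255L, path, 255L)

#' Write a label map as PGM
#'
#' `path` gets raw values `{0, 1, 2}` (maxval 2); if `preview` is given a
#' human-viewable version with levels 0/128/255 is written there.
#'
#' @param labels 0/1/2 matrix.
#' @param path file path.
#' @param preview optional path for the preview rendering.
#' @export
write_labels <- function(labels, path, preview = NULL) {
  write_pgm(labels, path, 2L)
  if (!is.null(preview)) write_pgm(labels * 127L + (labels > 0L), preview, 255L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- read_pgm(path)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Depth-frame PGM I/O (sentinel 0 = undefined depth)
#' @param path file path.
#' @export
read_depth <- function(path) {
  m <- read_pgm(path)
  m[m == 0] <- NA_real_
  m
}

#' @rdname read_depth
#' @param frame numeric matrix, NA = undefined; values are rounded on export.
#' @export
write_depth <- function(frame, path) {
  q <- round(frame)
  q[is.na(q)] <- 0
  write_pgm(q, path, 65535L)
}

#' Read candidate boxes from JSON
#'
#' Accepts a list of objects with either `top/left/bottom/right` (inclusive,
#' 1-based) or `x/y/w/h` (x = leftmost column, y = topmost row, so
#' left = x, top = y, right = x + w - 1, bottom = y + h - 1), each with an
#' optional `probability` (default 1).
#'
#' @param path JSON file path.
#' @return list of [bbox()].
#' @export
read_bbs_json <- function(path) {
  if (!file.exists(path)) ts_error("FILE_NOT_FOUND", paste("no such file:", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(b) {
    p <- if (is.null(b$probability)) 1 else b$probability
    if (!is.null(b$top)) {
      bbox(b$top, b$left, b$bottom, b$right, p)
    } else if (!is.null(b$x)) {
      bbox(b$y, b$x, b$y + b$h - 1L, b$x + b$w - 1L, p)
    } else {
      ts_error("BAD_FORMAT", "box needs top/left/bottom/right or x/y/w/h")
    }
  })
}

#' @rdname read_bbs_json
#' @param bbs list of [bbox()].
#' @export
write_bbs_json <- function(bbs, path) {
  jsonlite::write_json(lapply(bbs, function(b) {
    list(top = b$top, left = b$left, bottom = b$bottom, right = b$right,
         probability = b$probability)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
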