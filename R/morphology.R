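## Binary morphology on 0/1 matrices with a full 3x3 structuring element.
## Pixels outside the grid are background.

pad0 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask != 0)
  p
}

shift_views <- function(p, nr, nc) {
  lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
              c(1, -1), c(1, 0), c(1, 1)),
         function(d) p[(2 + d[1]):(nr + 1 + d[1]), (2 + d[2]):(nc + 1 + d[2]), drop = FALSE])
}

#' Morphological erosion, 3x3 square element
#' @param mask binary matrix.
#' @param times number of repetitions.
#' @return binary integer matrix.
#' @export
erode3 <- function(mask, times = 1L) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  for (t in seq_len(times)) {
    p <- pad0(m)
    acc <- p[2:(nr + 1L), 2:(nc + 1L)]
    for (v in shift_views(p, nr, nc)) acc <- acc & v
    m <- matrix(as.integer(acc), nr, nc)
    if (!any(m != 0)) break
  }
  m
}

#' Morphological dilation, 3x3 square element
#' @inheritParams erode3
#' @param within optional binary matrix; the dilation is clipped to it after
#'   every step (geodesic/conditional dilation).
#' @return binary integer matrix.
#' @export
dilate3 <- function(mask, times = 1L, within = NULL) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  for (t in seq_len(times)) {
    p <- pad0(m)
    acc <- p[2:(nr + 1L), 2:(nc + 1L)] == 1L
    for (v in shift_views(p, nr, nc)) acc <- acc | (v == 1L)
    m <- matrix(as.integer(acc), nr, nc)
    if (!is.null(within)) m <- m * as_mask(within)
  }
  m
}

#' Skeleton by Zhang-Suen thinning
#'
#' Iterative thinning down to a 1-pixel-wide 8-connected skeleton, the
#' discrete stand-in for the medial-axis transform used by the last-resort
#' hole generator.
#'
#' @param mask binary matrix.
#' @return binary integer matrix containing the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad0(m)
      ## neighbours in the conventional order P2..P9 = N, NE, E, SE, S, SW, W, NW
      N  <- p[1:nr, 2:(nc + 1L)]
      NE <- p[1:nr, 3:(nc + 2L)]
      E  <- p[2:(nr + 1L), 3:(nc + 2L)]
      SE <- p[3:(nr + 2L), 3:(nc + 2L)]
      S  <- p[3:(nr + 2L), 2:(nc + 1L)]
      SW <- p[3:(nr + 2L), 1:nc]
      W  <- p[2:(nr + 1L), 1:nc]
      NW <- p[1:nr, 1:nc]
      B <- N + NE + E + SE + S + SW + W + NW
      A <- (N == 0 & NE == 1) + (NE == 0 & E == 1) + (E == 0 & SE == 1) +
        (SE == 0 & S == 1) + (S == 0 & SW == 1) + (SW == 0 & W == 1) +
        (W == 0 & NW == 1) + (NW == 0 & N == 1)
      if (phase == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          (N * E * S == 0) & (E * S * W == 0)
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          (N * E * W == 0) & (N * S * W == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
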