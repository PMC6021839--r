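## Detector-box route: ingest candidate boxes from any external detector,
## keep the ones that are "useful" under the size / boundary / coverage
## conditions, cut the blob with one or two of them, and gate the cut quality.
## Quantities follow the field's naming: PP_* = pig-pixel counts, BP_* =
## boundary-pixel counts, L_BL = boundary-line length.

#' Candidate bounding box
#'
#' Inclusive 1-based pixel bounds plus the detector's objectness probability.
#'
#' @param top,left,bottom,right inclusive bounds.
#' @param probability objectness in `[0, 1]`.
#' @return object of class `ts_bbox`.
#' @export
bbox <- function(top, left, bottom, right, probability = 1) {
  if (top > bottom || left > right) ts_error("BAD_BOX", "degenerate box bounds")
  structure(list(top = as.integer(top), left = as.integer(left),
                 bottom = as.integer(bottom), right = as.integer(right),
                 probability = as.numeric(probability)),
            class = "ts_bbox")
}

clip_bbox <- function(box, nr, nc) {
  bbox(max(1L, box$top), max(1L, box$left),
       min(nr, box$bottom), min(nc, box$right), box$probability)
}

#' Box-evaluation configuration
#'
#' Defaults are the published operating points: a useful box holds between 40%
#' and 60% of the blob pixels, reaches at least 20% of the blob's outer
#' boundary, and a box cut is accepted only if the boundary line is at most
#' 20 pixels long and the size ratio of the two halves is at most 1.5.
#'
#' @param size_lo,size_hi bounds of the size condition (0.4, 0.6).
#' @param boundary_frac boundary condition fraction (0.2).
#' @param probability_th objectness threshold for ingest (1.0).
#' @param near_band width in pixels of the band around a box perimeter within
#'   which blob border pixels count as "near" (2).
#' @param seg_length_th segmentation length threshold (20).
#' @param seg_size_th segmentation size-ratio threshold (1.5).
#' @return list of class `ts_bb_config`.
#' @export
bb_config <- function(size_lo = 0.4, size_hi = 0.6, boundary_frac = 0.2,
                      probability_th = 1.0, near_band = 2L,
                      seg_length_th = 20L, seg_size_th = 1.5) {
  stopifnot(0 < size_lo, size_lo < size_hi, size_hi < 1,
            boundary_frac > 0, boundary_frac < 1,
            seg_length_th > 0, seg_size_th >= 1)
  structure(list(size_lo = size_lo, size_hi = size_hi,
                 boundary_frac = boundary_frac,
                 probability_th = probability_th,
                 near_band = as.integer(near_band),
                 seg_length_th = as.integer(seg_length_th),
                 seg_size_th = seg_size_th),
            class = "ts_bb_config")
}

## distance of pixels to the perimeter ring of a box: inside the box it is the
## distance to the nearest side, outside the Chebyshev distance to the box
ring_dist <- function(r, c, box) {
  inside <- r >= box$top & r <= box$bottom & c >= box$left & c <= box$right
  d_in <- pmin(r - box$top, box$bottom - r, c - box$left, box$right - c)
  d_out <- pmax(box$top - r, r - box$bottom, 0L)
  d_out <- pmax(d_out, pmax(box$left - c, c - box$right, 0L))
  ifelse(inside, d_in, d_out)
}

#' Region of interest of a touching blob
#'
#' The RoI is the tight enclosing box of the blob; `pp_roi` is the blob pixel
#' count (PP_RoI) and `bp_roi` the count of blob border pixels lying within
#' `near_band` of the RoI perimeter (BP_RoI).
#'
#' @param mask single-component binary matrix.
#' @param cfg a [bb_config()].
#' @return object of class `ts_roi` with fields `box`, `pp_roi`, `bp_roi`,
#'   and `border` (the blob border pixels, cached for box scoring).
#' @export
build_roi <- function(mask, cfg = bb_config()) {
  mask <- as_mask(mask)
  idx <- which(mask != 0)
  if (!length(idx)) ts_error("EMPTY_MASK", "no foreground pixel")
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  box <- bbox(min(r), min(c), max(r), max(c), 1)
  border <- border_pixels(mask)
  bp <- sum(ring_dist(border[, 1], border[, 2], box) <= cfg$near_band)
  structure(list(box = box, pp_roi = length(idx), bp_roi = bp, border = border),
            class = "ts_roi")
}

#' Drop candidate boxes outside the RoI or below the probability threshold
#'
#' Keeps boxes with `probability >= probability_th` that lie inside the RoI
#' box up to a tolerance of `near_band` pixels per side; kept boxes are
#' clipped to the RoI.
#'
#' @param bbs list of [bbox()].
#' @param roi a `ts_roi`.
#' @param cfg a [bb_config()].
#' @return list of clipped `ts_bbox`.
#' @export
filter_candidates <- function(bbs, roi, cfg = bb_config()) {
  keep <- list()
  rb <- roi$box
  for (b in bbs) {
    if (b$probability < cfg$probability_th) next
    if (b$top < rb$top - cfg$near_band || b$bottom > rb$bottom + cfg$near_band ||
        b$left < rb$left - cfg$near_band || b$right > rb$right + cfg$near_band) next
    keep[[length(keep) + 1L]] <-
      bbox(max(b$top, rb$top), max(b$left, rb$left),
           min(b$bottom, rb$bottom), min(b$right, rb$right), b$probability)
  }
  keep
}

#' Score one candidate box against the blob
#'
#' Computes PP_BB (blob pixels inside the box) and BP_BB (blob border pixels
#' within `near_band` of both the box perimeter and the RoI perimeter), sets
#' the size condition `size_lo * PP_RoI <= PP_BB <= size_hi * PP_RoI` and the
#' boundary condition `boundary_frac * BP_RoI <= BP_BB`, and the confidence
#' value
#' \deqn{(BP_{BB} - 0.2\,BP_{RoI}) / |PP_{BB} - 0.5\,PP_{RoI}|}
#' with a half-pixel denominator floor when the box holds exactly half the
#' blob (the formula diverges there by construction). Confidence is NA unless
#' both conditions hold.
#'
#' @param bb a `ts_bbox` (already clipped inside the RoI).
#' @param mask the blob mask.
#' @param roi a `ts_roi`.
#' @param cfg a [bb_config()].
#' @return object of class `ts_usefulbb`.
#' @export
evaluate_bb <- function(bb, mask, roi, cfg = bb_config()) {
  mask <- as_mask(mask)
  nr <- nrow(mask)
  idx <- which(mask != 0)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  pp_bb <- sum(r >= bb$top & r <= bb$bottom & c >= bb$left & c <= bb$right)
  bd <- roi$border
  near_bb <- ring_dist(bd[, 1], bd[, 2], bb) <= cfg$near_band
  near_roi <- ring_dist(bd[, 1], bd[, 2], roi$box) <= cfg$near_band
  bp_bb <- sum(near_bb & near_roi)
  size_ok <- cfg$size_lo * roi$pp_roi <= pp_bb && pp_bb <= cfg$size_hi * roi$pp_roi
  boundary_ok <- cfg$boundary_frac * roi$bp_roi <= bp_bb
  conf <- NA_real_
  if (size_ok && boundary_ok) {
    den <- abs(pp_bb - 0.5 * roi$pp_roi)
    if (den == 0) den <- 0.5
    conf <- (bp_bb - cfg$boundary_frac * roi$bp_roi) / den
  }
  structure(list(box = bb, pp_bb = pp_bb, bp_bb = bp_bb,
                 size_ok = size_ok, boundary_ok = boundary_ok,
                 confidence = conf),
            class = "ts_usefulbb")
}

#' Select the first and (optionally) second useful box
#'
#' Candidates are scored boxes passing both the size and boundary conditions.
#' The first useful box is the confidence argmax (ties: larger PP_BB, then
#' top-left-most box). The second is the highest-confidence remaining
#' candidate whose blob pixels outside the first box cover at least half of
#' the blob pixels the first box leaves uncovered (the coverage condition).
#'
#' @param ubbs list of `ts_usefulbb` from [evaluate_bb()].
#' @param roi a `ts_roi`.
#' @param mask the blob mask (needed to count pixels outside the first box).
#' @return list of 0, 1 or 2 `ts_usefulbb`, confidence non-increasing.
#' @export
select_useful_bbs <- function(ubbs, roi, mask) {
  cand <- Filter(function(u) isTRUE(u$size_ok) && isTRUE(u$boundary_ok), ubbs)
  if (!length(cand)) return(list())
  conf <- vapply(cand, function(u) u$confidence, 0)
  pp <- vapply(cand, function(u) u$pp_bb, 0)
  tops <- vapply(cand, function(u) u$box$top, 0L)
  lefts <- vapply(cand, function(u) u$box$left, 0L)
  ord <- order(-conf, -pp, tops, lefts)
  cand <- cand[ord]
  first <- cand[[1]]
  if (length(cand) == 1L) return(list(first))
  mask <- as_mask(mask)
  nr <- nrow(mask)
  idx <- which(mask != 0)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  in_first <- r >= first$box$top & r <= first$box$bottom &
    c >= first$box$left & c <= first$box$right
  remaining <- roi$pp_roi - first$pp_bb
  for (u in cand[-1]) {
    in_u <- r >= u$box$top & r <= u$box$bottom & c >= u$box$left & c <= u$box$right
    outside_cover <- sum(in_u & !in_first)
    if (outside_cover >= 0.5 * remaining) return(list(first, u))
  }
  list(first)
}

## ordered pixels of a box perimeter, clockwise starting at the top-left corner
box_ring <- function(box) {
  t <- box$top; b <- box$bottom; l <- box$left; r <- box$right
  if (t == b && l == r) return(pt_mat(t, l))
  if (t == b) return(pt_mat(rep(t, r - l + 1L), l:r))
  if (l == r) return(pt_mat(t:b, rep(l, b - t + 1L)))
  ring <- rbind(pt_mat(rep(t, r - l + 1L), l:r),
                pt_mat((t + 1L):b, rep(r, b - t)),
                pt_mat(rep(b, r - l), (r - 1L):l))
  if (b - t >= 2L) {
    ring <- rbind(ring, pt_mat((b - 1L):(t + 1L), rep(l, b - t - 1L)))
  }
  ring
}

## extend a path endpoint along direction d while staying on foreground
extend_on_fg <- function(mask, p, d, maxsteps = 1024L) {
  out <- list()
  q <- p + d
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(maxsteps)) {
    if (q[1] < 1L || q[1] > nr || q[2] < 1L || q[2] > nc || mask[q[1], q[2]] == 0L) break
    out[[length(out) + 1L]] <- q
    q <- q + d
  }
  if (length(out)) do.call(rbind, lapply(out, function(z) pt_mat(z[1], z[2]))) else NULL
}

## build a cut line from segment a--b: rasterize, make 4-connected, extend
## both ends along the segment direction while on foreground, keep the
## contiguous foreground run containing the segment midpoint
line_through_blob <- function(mask, a, b) {
  seg <- thicken_path4(rasterize_segment(a, b))
  dvec <- c(b[1] - a[1], b[2] - a[2])
  if (all(dvec == 0)) dvec <- c(1, 0)
  step <- c(sign(dvec[1]), sign(dvec[2]))
  n <- sqrt(sum(dvec^2))
  u <- dvec / n
  ## unit-ish integer steps: extend using the dominant direction rasterized
  far_a <- c(round(a[1] - u[1] * 4096), round(a[2] - u[2] * 4096))
  far_b <- c(round(b[1] + u[1] * 4096), round(b[2] + u[2] * 4096))
  full <- thicken_path4(rasterize_segment(far_a, far_b))
  nr <- nrow(mask); nc <- ncol(mask)
  inb <- full[, 1] >= 1L & full[, 1] <= nr & full[, 2] >= 1L & full[, 2] <= nc
  full <- full[inb, , drop = FALSE]
  if (!nrow(full)) return(NULL)
  on_fg <- mask[cbind(full[, 1], full[, 2])] != 0L
  mid <- c(round((a[1] + b[1]) / 2), round((a[2] + b[2]) / 2))
  d2 <- (full[, 1] - mid[1])^2 + (full[, 2] - mid[2])^2
  anchor <- which(on_fg)[which.min(d2[on_fg])]
  if (!length(anchor) || is.na(anchor)) return(NULL)
  lo <- anchor
  while (lo > 1L && on_fg[lo - 1L]) lo <- lo - 1L
  hi <- anchor
  while (hi < nrow(full) && on_fg[hi + 1L]) hi <- hi + 1L
  full[lo:hi, , drop = FALSE]
}

#' Cut the blob with a single useful box
#'
#' The box perimeter is intersected with the blob; contiguous runs of blob
#' pixels along the perimeter ring (with wrap-around) are candidate boundary
#' lines. Exactly one run: it is returned, each end extended straight along
#' its local direction to the blob border. Zero or two-plus runs: the blob is
#' handed to the shape route.
#'
#' @param ubb a `ts_usefulbb`.
#' @param mask the blob mask.
#' @return a `ts_boundary`, or a [fallback()] signal.
#' @export
cut_with_one_bb <- function(ubb, mask) {
  mask <- as_mask(mask)
  ring <- box_ring(clip_bbox(ubb$box, nrow(mask), ncol(mask)))
  on <- mask[cbind(ring[, 1], ring[, 2])] != 0L
  n <- length(on)
  if (!any(on)) return(fallback("box perimeter misses the blob"))
  if (all(on)) return(fallback("box perimeter fully inside the blob"))
  ## count runs on the circular sequence
  runs <- 0L
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    if (on[i] && !on[prev]) runs <- runs + 1L
  }
  if (runs != 1L) return(fallback(sprintf("%d boundary runs from one box", runs)))
  ## rotate the ring so the single run sits at the front, then take its prefix
  start <- which(vapply(seq_len(n), function(i) {
    prev <- if (i == 1L) n else i - 1L
    on[i] && !on[prev]
  }, TRUE))[1]
  idxs <- ((start - 1L) + seq_len(n) - 1L) %% n + 1L
  len <- 0L
  for (i in idxs) {
    if (!on[i]) break
    len <- len + 1L
  }
  pts <- ring[idxs[seq_len(len)], , drop = FALSE]
  ## extend both ends straight while still on the blob
  if (nrow(pts) >= 2L) {
    d_head <- pts[1, ] - pts[2, ]
    d_tail <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]
    head_ext <- extend_on_fg(mask, pts[1, ], d_head)
    tail_ext <- extend_on_fg(mask, pts[nrow(pts), ], d_tail)
    if (!is.null(head_ext)) pts <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], pts)
    if (!is.null(tail_ext)) pts <- rbind(pts, tail_ext)
  }
  boundary_line(thicken_path4(pts))
}

#' Cut the blob with two useful boxes
#'
#' Three geometric cases by the boxes' relative position: an overlap rectangle
#' (cut along the overlap diagonal more orthogonal to the axis joining the box
#' centres), a degenerate 1-pixel overlap line (cut along it), or disjoint
#' boxes (cut along the midline of the gap between the nearest parallel
#' edges). The cut is clipped/extended to the blob border and validated.
#'
#' @param a,b `ts_usefulbb`, `a` the first useful box.
#' @param mask the blob mask.
#' @return a `ts_boundary`, or a [fallback()] signal when no valid cut exists.
#' @export
cut_with_two_bbs <- function(a, b, mask) {
  mask <- as_mask(mask)
  A <- a$box; B <- b$box
  it <- max(A$top, B$top); ib <- min(A$bottom, B$bottom)
  il <- max(A$left, B$left); ir <- min(A$right, B$right)
  pts <- NULL
  if (it <= ib && il <= ir && (ib - it) >= 1L && (ir - il) >= 1L) {
    ## Case 1: overlap rectangle; pick the diagonal more orthogonal to the
    ## centre-centre axis (the cut should be transverse to the two-animal axis)
    ctr <- c((A$top + A$bottom) / 2 - (B$top + B$bottom) / 2,
             (A$left + A$right) / 2 - (B$left + B$right) / 2)
    d1 <- c(ib - it, ir - il)       # (top,left) -> (bottom,right)
    d2 <- c(ib - it, il - ir)       # (top,right) -> (bottom,left)
    a1 <- abs(sum(ctr * d1)) / max(sqrt(sum(d1^2)), 1e-9)
    a2 <- abs(sum(ctr * d2)) / max(sqrt(sum(d2^2)), 1e-9)
    if (a1 <= a2) {
      p1 <- c(it, il); p2 <- c(ib, ir)
    } else {
      p1 <- c(it, ir); p2 <- c(ib, il)
    }
    pts <- line_through_blob(mask, p1, p2)
  } else if (it <= ib && il <= ir) {
    ## Case 2: overlap degenerates to a 1-pixel line
    pts <- line_through_blob(mask, c(it, il), c(ib, ir))
  } else {
    ## Case 3: disjoint; midline of the larger gap between facing edges
    row_gap <- max(B$top - A$bottom, A$top - B$bottom) - 1L
    col_gap <- max(B$left - A$right, A$left - B$right) - 1L
    if (col_gap >= row_gap) {
      mid <- if (B$left > A$right) A$right + (B$left - A$right) %/% 2L
             else B$right + (A$left - B$right) %/% 2L
      pts <- line_through_blob(mask, c(max(min(A$top, B$top), 1L), mid),
                               c(min(max(A$bottom, B$bottom), nrow(mask)), mid))
    } else {
      mid <- if (B$top > A$bottom) A$bottom + (B$top - A$bottom) %/% 2L
             else B$bottom + (A$top - B$bottom) %/% 2L
      pts <- line_through_blob(mask, c(mid, max(min(A$left, B$left), 1L)),
                               c(mid, min(max(A$right, B$right), ncol(mask))))
    }
  }
  if (is.null(pts) || !nrow(pts)) return(fallback("two-box cut misses the blob"))
  line <- boundary_line(pts)
  ok <- tryCatch({ split_by_line(mask, line); TRUE },
                 touchsplit_error_BAD_CUT = function(e) FALSE)
  if (!ok) return(fallback("two-box cut does not sever the blob"))
  line
}

#' Segmentation quality gate
#'
#' A box cut is accepted only if the boundary line has at most
#' `seg_length_th` pixels and the larger/smaller size ratio of the two
#' resulting parts is at most `seg_size_th`.
#'
#' @param line a `ts_boundary`.
#' @param labels label matrix from [split_by_line()].
#' @param cfg a [bb_config()].
#' @return logical.
#' @export
quality_gate <- function(line, labels, cfg = bb_config()) {
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  ratio <- max(n1, n2) / min(n1, n2)
  line$length <= cfg$seg_length_th && ratio <= cfg$seg_size_th
}
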