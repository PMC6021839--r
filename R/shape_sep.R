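## Shape route: when detector boxes cannot cut the blob, the boundary line is
## drawn from the blob's own geometry. Hole sources are tried in a fixed
## order: natural holes (enclosed background), erosion-generated holes, and a
## last-resort hole built on the medial-axis skeleton. The hole yields a
## guideline; concave points extracted from the outline/convex-hull time
## series anchor the guideline to the outline.

#' Shape-route configuration
#'
#' @param erosion_repeat_th erosion repetitions for artificial hole
#'   generation (default 8, matched to an animal half-width of about 5 px
#'   at the working resolution).
#' @param skeleton_scale downsampling factor applied before skeletonization
#'   (default 0.5).
#' @param cp_band half-width of the concave-section interval on the global
#'   time series, as a fraction of the candidate's value (default 0.1).
#' @param cp_ratio_th minimum fold ratio (arc length over straight-line
#'   distance, maximized over outline point pairs straddling the candidate
#'   within its hull-defect run) for a candidate concave point to be kept
#'   (default 1.3: a straight or gently bent outline stays near 1, a shallow
#'   broad depression reaches ~1.2, a genuine touching notch exceeds 1.4).
#' @param min_depth minimum hull-defect depth in pixels for a candidate to
#'   count as concave at all (default 1.0: a digitized convex outline sags
#'   up to one pixel below its own hull chords, so sub-pixel defects are
#'   raster noise, not concavity).
#' @param max_cps fixed at 2: at most two concave points bound one touching
#'   region.
#' @return list of class `ts_shape_config`.
#' @export
shape_config <- function(erosion_repeat_th = 8L, skeleton_scale = 0.5,
                         cp_band = 0.1, cp_ratio_th = 1.3, min_depth = 1.0,
                         max_cps = 2L) {
  stopifnot(erosion_repeat_th >= 1, cp_band > 0, cp_band < 1,
            skeleton_scale > 0, skeleton_scale <= 1, min_depth >= 0)
  structure(list(erosion_repeat_th = as.integer(erosion_repeat_th),
                 skeleton_scale = skeleton_scale,
                 cp_band = cp_band, cp_ratio_th = cp_ratio_th,
                 min_depth = min_depth,
                 max_cps = as.integer(max_cps)),
            class = "ts_shape_config")
}

new_hole <- function(pixels, kind) {
  structure(list(pixels = pixels, kind = kind), class = "ts_hole")
}

#' Natural holes: enclosed background inside the blob
#'
#' Each 4-connected background component that touches no grid border is one
#' natural hole.
#'
#' @param mask binary matrix.
#' @return list of `ts_hole` (kind "natural"), possibly empty.
#' @export
find_natural_holes <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- 1L - mask
  lab <- label_components(bg, 4L)
  if (max(lab) == 0L) return(list())
  ## labels present on the grid border are outside background
  outside <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  holes <- list()
  for (k in setdiff(seq_len(max(lab)), outside)) {
    idx <- which(lab == k)
    holes[[length(holes) + 1L]] <-
      new_hole(pt_mat((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L), "natural")
  }
  holes
}

#' Artificial holes by repeated erosion
#'
#' The blob is eroded `erosion_repeat_th` times with a 3 x 3 element. Holes
#' are (a) enclosed background components of the eroded shape, else (b) when
#' the eroded shape splits, the neck region between the two largest remnants:
#' eroded-away blob pixels reached by the geodesic dilation
#' (`erosion_repeat_th` steps inside the original blob) of both remnants.
#' An emptied mask or no detectable void yields an empty list, and the
#' caller proceeds to the skeleton generator.
#'
#' @param mask binary matrix.
#' @param cfg a [shape_config()].
#' @return list of `ts_hole` (kind "erosion"), possibly empty.
#' @export
holes_by_erosion <- function(mask, cfg = shape_config()) {
  mask <- as_mask(mask)
  e <- erode3(mask, cfg$erosion_repeat_th)
  if (!any(e != 0)) return(list())
  nat <- find_natural_holes(e)
  if (length(nat)) {
    return(lapply(nat, function(h) new_hole(h$pixels, "erosion")))
  }
  lab <- label_components(e, 8L)
  if (max(lab) < 2L) return(list())
  sizes <- tabulate(lab[lab > 0])
  big <- order(sizes, decreasing = TRUE)[1:2]
  ## geodesic reconstruction of the two largest remnants inside the blob,
  ## stopped at the first step where they meet: their meeting zone is the
  ## vanished neck
  d1 <- matrix(as.integer(lab == big[1]), nrow(e), ncol(e))
  d2 <- matrix(as.integer(lab == big[2]), nrow(e), ncol(e))
  for (k in seq_len(2L * cfg$erosion_repeat_th)) {
    d1 <- dilate3(d1, 1L, within = mask)
    d2 <- dilate3(d2, 1L, within = mask)
    if (any(d1 & d2)) break
  }
  h <- d1 & d2 & (mask == 1L) & (e == 0L)
  idx <- which(h)
  if (!length(idx)) return(list())
  nr <- nrow(mask)
  list(new_hole(pt_mat((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L), "erosion"))
}

## breadth-first distances (and parents) over skeleton pixels, 8-connected
sk_bfs <- function(idx, nr, from) {
  pos <- match(idx, idx)
  names(pos) <- idx
  dist <- rep(NA_integer_, length(idx))
  parent <- rep(NA_integer_, length(idx))
  lut <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lut)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  s <- get(as.character(from), envir = lut)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (p in frontier) {
      lin <- idx[p]
      r <- (lin - 1L) %% nr + 1L; c <- (lin - 1L) %/% nr + 1L
      for (k in 1:8) {
        q <- (c + dc[k] - 1L) * nr + (r + dr[k])
        j <- mget(as.character(q), envir = lut, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && is.na(dist[j])) {
          dist[j] <- dist[p] + 1L
          parent[j] <- p
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  list(dist = dist, parent = parent)
}

#' Last-resort hole from the medial-axis skeleton
#'
#' The blob is downsampled, skeletonized, and the midpoint of the longest
#' skeleton path is taken as the skeleton centroid. The nearest outline point
#' to the centroid (P1) and the nearest outline point on the opposite side
#' (angular separation from the centroid of at least 90 degrees, P2) span the
#' touching region; the hole is the short transversal P1 -> centroid -> P2
#' restricted to a radius-2 neighbourhood of the centroid (a hole of length
#' about 4).
#'
#' @param mask binary matrix.
#' @param cfg a [shape_config()].
#' @param outline optionally a precomputed [extract_outline()] result.
#' @return one `ts_hole` (kind "skeleton").
#' @export
hole_by_skeleton <- function(mask, cfg = shape_config(), outline = NULL) {
  mask <- as_mask(mask)
  step <- max(1L, as.integer(round(1 / cfg$skeleton_scale)))
  nr <- nrow(mask); nc <- ncol(mask)
  srows <- seq(1L, nr, step); scols <- seq(1L, nc, step)
  small <- matrix(0L, length(srows), length(scols))
  ## block-OR downsampling preserves connectivity of thin shapes
  for (dr in 0:(step - 1L)) for (dc in 0:(step - 1L)) {
    rr <- pmin(srows + dr, nr); cc <- pmin(scols + dc, nc)
    small <- small | mask[rr, cc, drop = FALSE]
  }
  small <- matrix(as.integer(small), length(srows), length(scols))
  sk <- skeletonize(small)
  idx <- which(sk != 0)
  if (length(idx) < 2L) ts_error("DEGENERATE_SHAPE", "skeleton too small")
  snr <- nrow(sk)
  ## longest path: double BFS (tree-diameter heuristic)
  b1 <- sk_bfs(idx, snr, idx[1])
  u <- idx[which.max(replace(b1$dist, is.na(b1$dist), -1L))]
  b2 <- sk_bfs(idx, snr, u)
  v <- which.max(replace(b2$dist, is.na(b2$dist), -1L))
  path <- integer(0)
  j <- v
  while (!is.na(j)) {
    path <- c(idx[j], path)
    j <- b2$parent[j]
  }
  mid <- path[ceiling(length(path) / 2)]
  cr <- ((mid - 1L) %% snr) * step + 1L + step %/% 2L
  cc_ <- ((mid - 1L) %/% snr) * step + 1L + step %/% 2L
  ## snap the centroid to the nearest blob pixel at full resolution
  fgi <- which(mask != 0)
  fr <- (fgi - 1L) %% nr + 1L; fc <- (fgi - 1L) %/% nr + 1L
  s <- which.min((fr - cr)^2 + (fc - cc_)^2)
  ctr <- c(fr[s], fc[s])
  if (is.null(outline)) outline <- extract_outline(mask)
  op <- outline$points
  d2 <- (op[, 1] - ctr[1])^2 + (op[, 2] - ctr[2])^2
  p1 <- op[which.min(d2), ]
  v1 <- p1 - ctr
  dots <- (op[, 1] - ctr[1]) * v1[1] + (op[, 2] - ctr[2]) * v1[2]
  opp <- which(dots <= 0 & d2 > 0)
  if (!length(opp)) ts_error("DEGENERATE_SHAPE", "no opposite outline point")
  p2 <- op[opp[which.min(d2[opp])], ]
  seg <- rbind(rasterize_segment(p1, ctr), rasterize_segment(ctr, p2))
  keep <- (seg[, 1] - ctr[1])^2 + (seg[, 2] - ctr[2])^2 <= 4 &
    mask[cbind(seg[, 1], seg[, 2])] != 0L
  px <- seg[keep, , drop = FALSE]
  px <- px[!duplicated(px), , drop = FALSE]
  if (!nrow(px)) ts_error("DEGENERATE_SHAPE", "skeleton hole empty")
  new_hole(px, "skeleton")
}

## farthest pixel pair of a hole, ties to the lexicographically smallest pair
hole_diameter <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(list(a = pixels[1, ], b = pixels[1, ]))
  o <- order(pixels[, 1], pixels[, 2])
  p <- pixels[o, , drop = FALSE]
  best <- -1
  ba <- bb <- 1L
  for (i in seq_len(n - 1L)) {
    d2 <- (p[(i + 1L):n, 1] - p[i, 1])^2 + (p[(i + 1L):n, 2] - p[i, 2])^2
    j <- which.max(d2)
    if (d2[j] > best) {
      best <- d2[j]
      ba <- i; bb <- i + j
    }
  }
  list(a = p[ba, ], b = p[bb, ])
}

#' Guideline from one or more holes
#'
#' Each hole contributes a semi-guideline: the rasterized segment between its
#' two farthest pixels. Multiple semi-guidelines are ordered along the
#' principal axis of the union of hole pixels and chained nearest-endpoint to
#' nearest-endpoint into one polyline.
#'
#' @param holes non-empty list of `ts_hole`.
#' @return object of class `ts_guideline`: `points` (ordered polyline),
#'   `end_a`, `end_b` (free ends).
#' @export
guideline_from_holes <- function(holes) {
  if (!length(holes)) ts_error("EMPTY_HOLES", "no hole to build a guideline from")
  semis <- lapply(holes, function(h) {
    d <- hole_diameter(h$pixels)
    list(a = d$a, b = d$b, pts = rasterize_segment(d$a, d$b))
  })
  if (length(semis) == 1L) {
    s <- semis[[1]]
    return(structure(list(points = s$pts, end_a = s$a, end_b = s$b),
                     class = "ts_guideline"))
  }
  allpx <- do.call(rbind, lapply(holes, function(h) h$pixels))
  ctr <- colMeans(allpx)
  cv <- stats::cov(sweep(allpx, 2, ctr))
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- vapply(semis, function(s) sum(((s$a + s$b) / 2 - ctr) * ax), 0)
  semis <- semis[order(proj)]
  ## orient the first semi so its chaining end faces the second
  mid2 <- (semis[[2]]$a + semis[[2]]$b) / 2
  s1 <- semis[[1]]
  if (sum((s1$a - mid2)^2) < sum((s1$b - mid2)^2)) {
    s1 <- list(a = s1$b, b = s1$a, pts = s1$pts[rev(seq_len(nrow(s1$pts))), , drop = FALSE])
  }
  pts <- s1$pts
  free_a <- s1$a
  tail_pt <- s1$b
  for (i in 2:length(semis)) {
    s <- semis[[i]]
    if (sum((s$b - tail_pt)^2) < sum((s$a - tail_pt)^2)) {
      s <- list(a = s$b, b = s$a, pts = s$pts[rev(seq_len(nrow(s$pts))), , drop = FALSE])
    }
    pts <- rbind(pts, rasterize_segment(tail_pt, s$a), s$pts)
    tail_pt <- s$b
  }
  pts <- pts[!duplicated(pts), , drop = FALSE]
  structure(list(points = pts, end_a = free_a, end_b = tail_pt),
            class = "ts_guideline")
}

#' Concavity time series of an outline against its convex hull
#'
#' The convex hull of the outline is computed; hull segments are stored
#' counterclockwise and the end of the last stored segment defines the start
#' of the series; the outline is then traversed clockwise from that start.
#' `L[i]` is the perpendicular distance of outline point `i` to its covering
#' hull chord (zero on the hull, the local-curvature series); `G[i]` is the
#' Euclidean distance from the start point (the global-curvature series).
#'
#' @param outline a `ts_outline`.
#' @return object of class `ts_series`: `L`, `G`, `hull_segments` (list of
#'   `range` in series positions, `chord` endpoints, `chord_len`), `points`
#'   (outline points reordered to series positions), `start_index` (position
#'   of the start in the original outline).
#' @export
build_series <- function(outline) {
  pts <- outline$points
  n <- nrow(pts)
  if (n < 3L) ts_error("DEGENERATE_HULL", "outline too short")
  hv <- grDevices::chull(pts[, 2], pts[, 1])   # x = col, y = row
  if (length(hv) < 3L) ts_error("DEGENERATE_HULL", "collinear outline")
  hx <- pts[hv, 2]; hy <- pts[hv, 1]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area == 0) ts_error("DEGENERATE_HULL", "zero-area hull")
  start <- hv[1]                       # end of the last stored hull segment
  ordseq <- ((start - 1L) + seq_len(n) - 1L) %% n + 1L
  p <- pts[ordseq, , drop = FALSE]
  hpos <- sort(unique(((hv - start) %% n) + 1L))
  G <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
  L <- numeric(n)
  segs <- list()
  bounds <- c(hpos, n + 1L)            # wrap: last segment closes at start
  for (si in seq_len(length(bounds) - 1L)) {
    from <- bounds[si]
    to <- bounds[si + 1L]
    q1 <- p[from, ]
    q2 <- if (to == n + 1L) p[1, ] else p[to, ]
    tt <- from:min(to, n)
    dv <- q2 - q1
    len <- sqrt(sum(dv^2))
    if (len == 0) {
      L[tt] <- sqrt((p[tt, 1] - q1[1])^2 + (p[tt, 2] - q1[2])^2)
    } else {
      L[tt] <- abs(dv[1] * (p[tt, 2] - q1[2]) - dv[2] * (p[tt, 1] - q1[1])) / len
    }
    segs[[si]] <- list(range = c(from, min(to, n)), chord = rbind(q1, q2),
                       chord_len = len)
  }
  structure(list(L = L, G = G, hull_segments = segs, points = p,
                 start_index = start),
            class = "ts_series")
}

#' Candidate concave points
#'
#' One candidate per hull segment whose covered outline run departs from the
#' chord: the position of maximum `L` (ties to the smallest position).
#'
#' @param series a `ts_series`.
#' @return list of candidates (`index` series position, `point`, `depth`,
#'   `segment` id, `ratio` NA until [final_cps()]).
#' @export
candidate_cps <- function(series) {
  out <- list()
  for (si in seq_along(series$hull_segments)) {
    rg <- series$hull_segments[[si]]$range
    tt <- rg[1]:rg[2]
    Lv <- series$L[tt]
    m <- max(Lv)
    if (m <= 0) next
    t0 <- tt[which.max(Lv)]
    out[[length(out) + 1L]] <- list(index = t0, point = series$points[t0, ],
                                    depth = m, segment = si, ratio = NA_real_)
  }
  out
}

## arc length between consecutive series positions lo..hi (1 axial, sqrt(2)
## diagonal)
arc_length <- function(points, lo, hi) {
  if (hi <= lo) return(0)
  dr <- abs(diff(points[lo:hi, 1]))
  dc <- abs(diff(points[lo:hi, 2]))
  sum(ifelse(dr == 1 & dc == 1, sqrt(2), pmax(dr, dc)))
}

#' Final concave points
#'
#' Each candidate's degree of concavity is a fold ratio: over all pairs of
#' outline points straddling the candidate within its hull-defect run, the
#' maximum of (arc length walked between them) / (their straight-line
#' distance). A touching notch folds the outline back on itself (walls far
#' apart along the outline, close in the plane, ratio >> 1); a straight or
#' gently bent back does not (ratio near 1). Candidates with sub-pixel
#' defect depth (`min_depth`) are raster noise and dropped first; candidates
#' below `cp_ratio_th` are dropped; of more than two survivors only the two
#' deepest (largest `L`) are kept. The reported `section` is the contiguous
#' run around the candidate whose distance-from-origin values stay within
#' candidate value +- `cp_band`.
#'
#' @param candidates from [candidate_cps()].
#' @param series a `ts_series`.
#' @param cfg a [shape_config()].
#' @return list of at most two concave points with `ratio` and `section`
#'   filled in.
#' @export
final_cps <- function(candidates, series, cfg = shape_config()) {
  if (!length(candidates)) return(list())
  n <- length(series$G)
  kept <- list()
  for (cp in candidates) {
    if (cp$depth <= cfg$min_depth) next      # sub-pixel defect: raster noise
    rg <- series$hull_segments[[cp$segment]]$range
    tt <- rg[1]:rg[2]
    p <- series$points[tt, , drop = FALSE]
    t0 <- which(tt == cp$index)
    np <- nrow(p)
    step <- ifelse(abs(diff(p[, 1])) == 1 & abs(diff(p[, 2])) == 1,
                   sqrt(2), pmax(abs(diff(p[, 1])), abs(diff(p[, 2]))))
    ca <- c(0, cumsum(step))
    best <- 1
    for (i in seq_len(t0)) {
      j <- t0:np
      arc <- ca[j] - ca[i]
      ok <- arc >= 2
      if (!any(ok)) next
      d <- pmax(sqrt((p[j, 1] - p[i, 1])^2 + (p[j, 2] - p[i, 2])^2), 1)
      best <- max(best, max(arc[ok] / d[ok]))
    }
    cp$ratio <- best
    ## reported concave section: distance-from-origin band around the candidate
    g <- series$G[cp$index]
    lob <- g * (1 - cfg$cp_band); hib <- g * (1 + cfg$cp_band)
    lo <- cp$index
    while (lo > 1L && series$G[lo - 1L] >= lob && series$G[lo - 1L] <= hib) lo <- lo - 1L
    hi <- cp$index
    while (hi < n && series$G[hi + 1L] >= lob && series$G[hi + 1L] <= hib) hi <- hi + 1L
    cp$section <- c(lo, hi)
    if (cp$ratio >= cfg$cp_ratio_th) kept[[length(kept) + 1L]] <- cp
  }
  if (length(kept) > cfg$max_cps) {
    depths <- vapply(kept, function(cp) cp$depth, 0)
    idxs <- vapply(kept, function(cp) cp$index, 0L)
    kept <- kept[order(-depths, idxs)][seq_len(cfg$max_cps)]
  }
  kept
}

## signed side of point p relative to the oriented line a -> b
line_side <- function(a, b, p) {
  (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
}

## assemble candidate cut pixels, keep foreground only, validate by splitting
try_cut <- function(mask, segs) {
  pts <- do.call(rbind, segs)
  pts <- thicken_path4(pts)
  on <- mask[cbind(pts[, 1], pts[, 2])] != 0L
  pts <- pts[on, , drop = FALSE]
  if (!nrow(pts)) return(NULL)
  line <- boundary_line(pts)
  ok <- tryCatch({ split_by_line(mask, line); TRUE },
                 touchsplit_error_BAD_CUT = function(e) FALSE)
  if (ok) line else NULL
}

#' Boundary line from guideline and concave points
#'
#' Case 1 (two CPs): CP -> nearer guideline end -> guideline -> other end ->
#' other CP, with the CP-to-end assignment minimizing total connector
#' length. Case 2 (one CP): the CP joins its nearer end; the remaining end
#' joins the nearest outline point in the search region (the outline arc on
#' the opposite side of the guideline's supporting line from the CP).
#' Case 3 (no CP): one end joins its globally nearest outline point, the
#' search region is defined relative to that attachment, and the other end
#' joins the nearest region point. Invalid cuts retry with the next-nearest
#' region point (at most 5 retries).
#'
#' @param guideline a `ts_guideline`.
#' @param cps list of 0-2 concave points.
#' @param outline a `ts_outline`.
#' @param mask the blob mask (for validity checking).
#' @return a `ts_boundary`.
#' @export
boundary_from_shape <- function(guideline, cps, outline, mask) {
  mask <- as_mask(mask)
  ea <- guideline$end_a; eb <- guideline$end_b
  gpts <- guideline$points
  gpts_rev <- gpts[rev(seq_len(nrow(gpts))), , drop = FALSE]
  op <- outline$points
  if (length(cps) >= 2L) {
    c1 <- cps[[1]]$point; c2 <- cps[[2]]$point
    straight <- sqrt(sum((c1 - ea)^2)) + sqrt(sum((c2 - eb)^2))
    crossed <- sqrt(sum((c1 - eb)^2)) + sqrt(sum((c2 - ea)^2))
    if (straight <= crossed) {
      line <- try_cut(mask, list(rasterize_segment(c1, ea), gpts,
                                 rasterize_segment(eb, c2)))
    } else {
      line <- try_cut(mask, list(rasterize_segment(c1, eb), gpts_rev,
                                 rasterize_segment(ea, c2)))
    }
    if (!is.null(line)) return(line)
    ts_error("NO_VALID_CUT", "two-CP cut does not sever the blob")
  }
  degenerate <- sum((ea - eb)^2) == 0
  if (length(cps) == 1L) {
    cp <- cps[[1]]$point
    if (sqrt(sum((cp - ea)^2)) <= sqrt(sum((cp - eb)^2))) {
      e1 <- ea; e2 <- eb; gdir <- gpts
    } else {
      e1 <- eb; e2 <- ea; gdir <- gpts_rev
    }
    anchor <- cp
  } else {
    ## no CP: attach the end nearest to the outline first
    da <- sqrt((op[, 1] - ea[1])^2 + (op[, 2] - ea[2])^2)
    db <- sqrt((op[, 1] - eb[1])^2 + (op[, 2] - eb[2])^2)
    if (min(da) <= min(db)) {
      e1 <- ea; e2 <- eb; gdir <- gpts
      anchor <- op[which.min(da), ]
    } else {
      e1 <- eb; e2 <- ea; gdir <- gpts_rev
      anchor <- op[which.min(db), ]
    }
  }
  ## search region: outline points strictly on the opposite side of the
  ## guideline's supporting line from the anchor; when the anchor is nearly
  ## collinear with that line (typical for a transversal guideline), fall
  ## back to the half relative to the guideline midpoint
  gm <- (ea + eb) / 2
  s_anchor <- if (degenerate) 0 else line_side(ea, eb, anchor)
  sides <- if (degenerate) rep(0, nrow(op)) else
    apply(op, 1, function(q) line_side(ea, eb, q))
  region <- which(sides * s_anchor < 0)
  if (!length(region) || abs(s_anchor) < 0.5) {
    va <- anchor - gm
    region <- which((op[, 1] - gm[1]) * va[1] + (op[, 2] - gm[2]) * va[2] <= 0)
    region <- region[(op[region, 1] != anchor[1]) | (op[region, 2] != anchor[2])]
  }
  if (!length(region)) ts_error("NO_VALID_CUT", "empty search region")
  d2 <- (op[region, 1] - e2[1])^2 + (op[region, 2] - e2[2])^2
  region <- region[order(d2)]
  head_seg <- rasterize_segment(anchor, e1)
  for (q_i in region[seq_len(min(6L, length(region)))]) {
    q <- op[q_i, ]
    line <- try_cut(mask, list(head_seg, gdir, rasterize_segment(e2, q)))
    if (!is.null(line)) return(line)
  }
  ts_error("NO_VALID_CUT", "no valid cut after retries")
}
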