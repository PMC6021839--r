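## Grid conventions used everywhere in this package:
##   * a mask is an integer (or logical) matrix, 0 = background, 1 = foreground,
##     indexed (row, col), 1-based, row increasing downward;
##   * foreground is 8-connected, background 4-connected (standard duality);
##   * a point is a length-2 integer vector c(row, col); point sets are
##     n x 2 matrices with columns "row", "col";
##   * box bounds are inclusive.

#' Coerce and validate a binary mask
#'
#' @param x numeric/logical matrix; any nonzero entry is foreground.
#' @return integer matrix of 0/1 with class unchanged (plain matrix).
#' @export
as_mask <- function(x) {
  if (!is.matrix(x)) ts_error("EMPTY_MASK", "mask must be a matrix")
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

pt_mat <- function(row, col) {
  m <- cbind(row = as.integer(row), col = as.integer(col))
  m
}

#' Label connected components
#'
#' Breadth-first labelling of the nonzero pixels of `mask`.
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default, foreground convention) or 4
#'   (background convention).
#' @return integer matrix; 0 background, components numbered from 1 in
#'   raster-scan order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  fg <- which(mask != 0)
  ## raster-scan order = column-major in R; reorder to row-major so labels are
  ## deterministic "first seen scanning rows top to bottom"
  if (length(fg)) {
    r <- (fg - 1L) %% nr + 1L; c <- (fg - 1L) %/% nr + 1L
    fg <- fg[order(r, c)]
  }
  nlab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nlab <- nlab + 1L
    lab[seed] <- nlab
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr_r <- rep(r, each = length(dr)) + dr
      nbr_c <- rep(c, each = length(dc)) + dc
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      idx <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      idx <- unique(idx[mask[idx] != 0 & lab[idx] == 0L])
      lab[idx] <- nlab
      frontier <- idx
    }
  }
  lab
}

## foreground pixels with at least one 4-neighbour that is background
## (outside the grid counts as background)
border_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask != 0)
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  nb <- p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
  border <- core == 1L & !nb
  idx <- which(border)
  pt_mat((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
}

#' Trace the outer contour of a single-component blob
#'
#' Moore-neighbour tracing with Jacob's stopping criterion, clockwise when
#' viewed with rows increasing downward. Interior hole borders are not
#' traced.
#'
#' @param mask binary matrix whose foreground is one 8-connected component.
#' @return An object of class `ts_outline`: list with `points` (n x 2 matrix,
#'   closed 8-connected contour) and `start_index` (origin used by the
#'   concavity time series; 1 until [build_series()] sets it).
#' @export
extract_outline <- function(mask) {
  mask <- as_mask(mask)
  fg <- which(mask != 0)
  if (length(fg) == 0L) ts_error("EMPTY_MASK", "no foreground pixel")
  lab <- label_components(mask, 8L)
  if (max(lab) > 1L) ts_error("MULTI_COMPONENT", "mask has more than one component")
  nr <- nrow(mask); nc <- ncol(mask)
  if (length(fg) == 1L) {
    p <- c((fg - 1L) %% nr + 1L, (fg - 1L) %/% nr + 1L)
    return(structure(list(points = pt_mat(p[1], p[2]), start_index = 1L),
                     class = "ts_outline"))
  }
  r <- (fg - 1L) %% nr + 1L; c <- (fg - 1L) %/% nr + 1L
  o <- order(r, c)
  start <- c(r[o[1]], c[o[1]])
  ## clockwise cycle of 8 neighbours starting at West (screen orientation,
  ## row down): W, NW, N, NE, E, SE, S, SW
  cyc <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  is_fg <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc &&
    mask[p[1], p[2]] != 0L
  cyc_index <- function(d) which(cyc[, 1] == d[1] & cyc[, 2] == d[2])
  ## deterministic tracing over states (pixel, backtrack direction): the walk
  ## must eventually revisit a state; the contour is the cycle between the
  ## two visits (any pre-cycle tail, possible on one-pixel spurs at the
  ## start, is dropped)
  pts <- list(start)
  p <- start
  b_idx <- 1L           # backtrack at West of the start pixel (background)
  seen <- new.env(hash = TRUE)
  assign(paste(start[1], start[2], b_idx), 1L, envir = seen)
  maxit <- 32L * length(fg) + 16L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) ts_error("MULTI_COMPONENT", "contour tracing did not close")
    found <- FALSE
    for (k in 1:8) {
      j <- (b_idx - 1L + k) %% 8L + 1L
      q <- p + cyc[j, ]
      if (is_fg(q)) {
        jprev <- (b_idx - 1L + k - 1L) %% 8L + 1L
        prev <- p + cyc[jprev, ]
        nb_idx <- cyc_index(prev - q)
        key <- paste(q[1], q[2], nb_idx)
        first <- mget(key, envir = seen, ifnotfound = list(NULL))[[1]]
        if (!is.null(first)) {
          keep <- pts[first:length(pts)]
          return(structure(list(points = do.call(rbind, lapply(keep, function(z) pt_mat(z[1], z[2]))),
                                start_index = 1L), class = "ts_outline"))
        }
        pts[[length(pts) + 1L]] <- q
        assign(key, length(pts), envir = seen)
        p <- q
        b_idx <- nb_idx
        found <- TRUE
        break
      }
    }
    if (!found) {  # isolated pixel cannot happen here (single multi-pixel comp)
      ts_error("MULTI_COMPONENT", "contour tracing stalled")
    }
  }
}

#' Digital straight segment between two pixels
#'
#' Bresenham rasterization; the result is an 8-connected path including both
#' endpoints. `rasterize_segment(a, b)` and `rasterize_segment(b, a)` are
#' both valid 8-paths of equal length but are not guaranteed to be
#' point-for-point reverses of each other (documented contract).
#'
#' @param a,b length-2 integer vectors `c(row, col)`.
#' @return n x 2 matrix of points from `a` to `b`.
#' @export
rasterize_segment <- function(a, b) {
  r0 <- as.integer(a[1]); c0 <- as.integer(a[2])
  r1 <- as.integer(b[1]); c1 <- as.integer(b[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  rows <- integer(n); cols <- integer(n)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) { rows <- rows[1:i]; cols <- cols[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pt_mat(rows, cols)
}

## Insert one pixel at every diagonal step so the path becomes 4-connected.
## Needed because removing an 8-connected diagonal does not disconnect an
## 8-connected foreground (connectivity duality); cut paths must be
## 4-connected to actually sever the blob.
thicken_path4 <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  out <- vector("list", 2L * nrow(pts))
  k <- 0L
  for (i in seq_len(nrow(pts) - 1L)) {
    k <- k + 1L; out[[k]] <- pts[i, , drop = FALSE]
    dr <- pts[i + 1L, 1] - pts[i, 1]; dc <- pts[i + 1L, 2] - pts[i, 2]
    if (dr != 0L && dc != 0L) {
      k <- k + 1L
      out[[k]] <- pt_mat(pts[i + 1L, 1], pts[i, 2])
    }
  }
  k <- k + 1L; out[[k]] <- pts[nrow(pts), , drop = FALSE]
  m <- do.call(rbind, out[seq_len(k)])
  m[!duplicated(m), , drop = FALSE]
}

#' Construct a boundary line
#'
#' @param points n x 2 matrix of pixels (ordered path).
#' @return object of class `ts_boundary` with fields `points` and `length`
#'   (pixel count, the quantity gated by the segmentation length condition).
#' @export
boundary_line <- function(points) {
  points <- points[!duplicated(points), , drop = FALSE]
  structure(list(points = points, length = nrow(points)), class = "ts_boundary")
}

#' Split a blob by removing a boundary line
#'
#' Removes the line's pixels, requires exactly two 8-connected remnants, then
#' gives each line pixel the label of its nearest remnant pixel (Euclidean;
#' ties to the lower label). Labels are ordered so that component 1 has the
#' smaller centroid row (ties: smaller centroid column).
#'
#' @param mask binary matrix (one blob).
#' @param line a `ts_boundary`.
#' @return integer label matrix with values 0/1/2 partitioning the foreground.
#' @export
split_by_line <- function(mask, line) {
  mask <- as_mask(mask)
  nr <- nrow(mask)
  li <- (line$points[, 2] - 1L) * nr + line$points[, 1]
  li <- li[mask[li] != 0]           # only pixels actually on the blob cut
  m2 <- mask
  m2[li] <- 0L
  lab <- label_components(m2, 8L)
  if (max(lab) != 2L) {
    ts_error("BAD_CUT", sprintf("cut leaves %d component(s), need 2", max(lab)))
  }
  ## nearest-component re-assignment of the line pixels
  if (length(li)) {
    lr <- (li - 1L) %% nr + 1L; lc <- (li - 1L) %/% nr + 1L
    w1 <- which(lab == 1L); w2 <- which(lab == 2L)
    r1 <- (w1 - 1L) %% nr + 1L; c1 <- (w1 - 1L) %/% nr + 1L
    r2 <- (w2 - 1L) %% nr + 1L; c2 <- (w2 - 1L) %/% nr + 1L
    for (k in seq_along(li)) {
      d1 <- min((r1 - lr[k])^2 + (c1 - lc[k])^2)
      d2 <- min((r2 - lr[k])^2 + (c2 - lc[k])^2)
      lab[li[k]] <- if (d2 < d1) 2L else 1L
    }
  }
  relabel_by_centroid(lab)
}

## deterministic label ordering: label 1 = smaller centroid row, then col
relabel_by_centroid <- function(lab) {
  nr <- nrow(lab)
  w1 <- which(lab == 1L); w2 <- which(lab == 2L)
  cr <- c(mean((w1 - 1L) %% nr + 1L), mean((w2 - 1L) %% nr + 1L))
  cc <- c(mean((w1 - 1L) %/% nr + 1L), mean((w2 - 1L) %/% nr + 1L))
  swap <- cr[2] < cr[1] || (cr[2] == cr[1] && cc[2] < cc[1])
  if (swap) {
    lab[w1] <- 2L
    lab[w2] <- 1L
  }
  lab
}
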