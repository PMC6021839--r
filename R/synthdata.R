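## Synthetic touching-ellipse fixtures with per-pixel ground truth and
## simulated detector boxes. The default animal is a weaning pig seen
## top-down at the working resolution: length about 35 px (semi-major 17),
## width about 10 px (semi-minor 5); a pair blob therefore comfortably
## exceeds the 500-pixel touching gate.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a touching-ellipse pair
#'
#' @param axes_a,axes_b semi-major/semi-minor axes in pixels.
#' @param angle_a,angle_b major-axis rotations in radians (0 = horizontal).
#' @param contact_width target neck width in pixels (0 = a separated,
#'   non-touching pair, the negative control).
#' @param hole_prob probability of carving a small enclosed hole at the
#'   contact.
#' @param noise_rate fraction of boundary pixels flipped (then repaired to
#'   keep one component).
#' @param seed integer RNG seed.
#' @return list of class `ts_pair_spec`.
#' @export
pair_spec <- function(axes_a = c(17.5, 5.5), axes_b = c(17.5, 5.5),
                      angle_a = 0, angle_b = 0, contact_width = 8,
                      hole_prob = 0, noise_rate = 0, seed = 1L) {
  stopifnot(axes_a[2] >= 3, axes_b[2] >= 3, contact_width >= 0,
            hole_prob >= 0, hole_prob <= 1, noise_rate >= 0, noise_rate <= 1)
  structure(list(axes_a = axes_a, axes_b = axes_b,
                 angle_a = angle_a, angle_b = angle_b,
                 contact_width = contact_width,
                 hole_prob = hole_prob, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "ts_pair_spec")
}

## raster a two-ellipse scene at centre distance d; returns membership masks
raster_pair <- function(spec, d, margin = 6L) {
  half_h <- function(ax, th) sqrt((ax[1] * sin(th))^2 + (ax[2] * cos(th))^2)
  half_w <- function(ax, th) sqrt((ax[1] * cos(th))^2 + (ax[2] * sin(th))^2)
  hmax <- ceiling(max(half_h(spec$axes_a, spec$angle_a),
                      half_h(spec$axes_b, spec$angle_b)))
  wmax <- ceiling(max(half_w(spec$axes_a, spec$angle_a),
                      half_w(spec$axes_b, spec$angle_b)))
  cy <- hmax + margin + 1
  c1x <- wmax + margin + 1
  c2x <- c1x + d
  nr <- 2L * hmax + 2L * margin + 2L
  nc <- as.integer(ceiling(c2x + wmax + margin))
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), nc), nr, nc)
  inside <- function(cx, ax, th) {
    dx <- X - cx; dy <- Y - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / ax[1])^2 + (v / ax[2])^2 <= 1
  }
  inA <- inside(c1x, spec$axes_a, spec$angle_a)
  inB <- inside(c2x, spec$axes_b, spec$angle_b)
  list(inA = inA, inB = inB, mask = matrix(as.integer(inA | inB), nr, nc),
       c1 = c(cy, c1x), c2 = c(cy, c2x))
}

## ground-truth partition of the union: overlap pixels go to the nearer
## ellipse centre (ties to label 1)
truth_partition <- function(rp) {
  nr <- nrow(rp$mask)
  truth <- matrix(0L, nr, ncol(rp$mask))
  truth[rp$inA & !rp$inB] <- 1L
  truth[rp$inB & !rp$inA] <- 2L
  both <- rp$inA & rp$inB
  if (any(both)) {
    idx <- which(both)
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    dA <- (r - rp$c1[1])^2 + (c - rp$c1[2])^2
    dB <- (r - rp$c2[1])^2 + (c - rp$c2[2])^2
    truth[idx] <- ifelse(dB < dA, 2L, 1L)
  }
  truth
}

## interface between the two truth regions: label-1 pixels 8-adjacent to
## label 2; the neck width is the interface's spatial extent (diameter + 1),
## i.e. the length of the cut a perfect separation would need
measure_neck <- function(rp) {
  truth <- truth_partition(rp)
  iface <- interface_pixels(truth)
  if (!nrow(iface)) return(0)
  if (nrow(iface) == 1L) return(1)
  d <- hole_diameter(iface)
  sqrt(sum((d$a - d$b)^2)) + 1
}

interface_pixels <- function(truth) {
  nr <- nrow(truth)
  d2 <- dilate3(matrix(as.integer(truth == 2L), nr, ncol(truth)))
  idx <- which(truth == 1L & d2 == 1L)
  pt_mat((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
}

#' Generate one touching-ellipse fixture
#'
#' The centre distance is found by bisection so that the neck width matches
#' `contact_width` (within raster discretization of about 2 px); disputed
#' overlap pixels go to the nearer ellipse centre (ties to label 1);
#' optionally a 1-4 px enclosed hole is carved at the contact and boundary
#' noise applied with connectivity-preserving repair. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [pair_spec()].
#' @return object of class `ts_fixture`: `mask`, `truth` (0/1/2), `bbs`
#'   (simulated detector boxes, jitter 2), `spec`, and `meta` (ellipse
#'   centres and centre distance actually used, for analytic checks).
#' @export
gen_pair <- function(spec) {
  with_seed(spec$seed, {
    cw <- spec$contact_width
    wa <- sqrt((spec$axes_a[1] * cos(spec$angle_a))^2 + (spec$axes_a[2] * sin(spec$angle_a))^2)
    wb <- sqrt((spec$axes_b[1] * cos(spec$angle_b))^2 + (spec$axes_b[2] * sin(spec$angle_b))^2)
    if (cw == 0) {
      d <- wa + wb + 4
      rp <- raster_pair(spec, d)
    } else {
      ## neck width is unimodal in the centre distance (tiny at heavy overlap
      ## and past separation, peaking at moderate overlap); a real touching
      ## pair sits on the light-overlap branch, so take the LARGEST distance
      ## whose neck reaches the target: coarse descending scan, then refine
      f <- function(d) measure_neck(raster_pair(spec, d))
      hi <- (wa + wb) * 1.2 + 4
      while (f(hi) > 0) hi <- hi * 1.3
      d <- NA_real_
      for (dd in seq(hi, 2, by = -1)) {
        if (f(dd) >= cw) { d <- dd; break }
      }
      if (is.na(d)) {
        ts_error("UNATTAINABLE_CONTACT",
                 sprintf("contact width %g not attainable", cw))
      }
      for (dd in seq(d + 1, d, by = -0.0625)) {
        if (f(dd) >= cw) { d <- dd; break }
      }
      rp <- raster_pair(spec, d)
      ## the interface extent quantizes in diagonal-pixel steps (~1.4 px per
      ## end), so one raster step can overshoot by up to ~2.8 px
      if (abs(measure_neck(rp) - cw) > 3) {
        ts_error("UNATTAINABLE_CONTACT",
                 sprintf("contact width %g missed by more than 3 px", cw))
      }
    }
    mask <- rp$mask
    nr <- nrow(mask)
    truth <- truth_partition(rp)
    ## optional enclosed hole carved at the middle of the contact interface
    if (cw > 0 && stats::runif(1) < spec$hole_prob) {
      iface <- interface_pixels(truth)
      if (nrow(iface) >= 7L) {
        ctr <- colMeans(iface)
        ord <- order((iface[, 1] - ctr[1])^2 + (iface[, 2] - ctr[2])^2)
        k <- sample(1:4, 1)
        cand <- iface[ord[seq_len(min(k, nrow(iface)))], , drop = FALSE]
        bp <- border_pixels(mask)
        interior <- !(paste(cand[, 1], cand[, 2]) %in% paste(bp[, 1], bp[, 2]))
        cand <- cand[interior, , drop = FALSE]
        if (nrow(cand)) {
          mask[cbind(cand[, 1], cand[, 2])] <- 0L
          if (max(label_components(mask)) != 1L) {
            mask[cbind(cand[, 1], cand[, 2])] <- 1L   # carving broke the blob
          } else {
            truth[cbind(cand[, 1], cand[, 2])] <- 0L
          }
        }
      }
    }
    ## boundary noise with connectivity-preserving repair
    if (spec$noise_rate > 0) {
      bp <- border_pixels(mask)
      nflip <- round(spec$noise_rate * nrow(bp))
      holes0 <- length(find_natural_holes(mask))
      for (k in seq_len(nflip)) {
        if (stats::runif(1) < 0.5) {
          ## remove a border pixel if the blob stays one component
          p <- bp[sample(nrow(bp), 1), ]
          if (mask[p[1], p[2]] == 0L) next
          mask[p[1], p[2]] <- 0L
          if (max(label_components(mask)) != 1L) {
            mask[p[1], p[2]] <- 1L
          } else {
            truth[p[1], p[2]] <- 0L
          }
        } else {
          ## grow a background pixel 4-adjacent to the blob
          p <- bp[sample(nrow(bp), 1), ]
          dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          q <- p + dirs[sample(4, 1), ]
          if (q[1] < 2 || q[1] > nrow(mask) - 1 || q[2] < 2 || q[2] > ncol(mask) - 1) next
          if (mask[q[1], q[2]] != 0L) next
          mask[q[1], q[2]] <- 1L
          if (length(find_natural_holes(mask)) != holes0) {
            mask[q[1], q[2]] <- 0L
          } else {
            ## inherit the identity of the nearest labelled pixel
            idx <- which(truth != 0L)
            r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
            j <- which.min((r - q[1])^2 + (c - q[2])^2)
            truth[q[1], q[2]] <- truth[idx[j]]
          }
        }
      }
    }
    fx <- structure(list(mask = mask, truth = truth, bbs = list(), spec = spec,
                         meta = list(centre_a = rp$c1, centre_b = rp$c2,
                                     distance = d)),
                    class = "ts_fixture")
    fx$bbs <- gen_bbs(fx, jitter = 2L, drop_prob = 0,
                      seed = (spec$seed + 1L) %% 2147483647L)
    fx
  })
}

#' Simulated detector boxes for a fixture
#'
#' Each ground-truth object contributes its tight box with every side
#' jittered by up to `jitter` pixels and an objectness drawn in `[0.8, 1]`;
#' each box is dropped with probability `drop_prob`; 0-2 small distractor
#' boxes are placed outside the blob's RoI when the grid margin allows.
#'
#' @param fixture a `ts_fixture` (needs `mask`, `truth`).
#' @param jitter maximum per-side perturbation in pixels.
#' @param drop_prob per-box drop probability.
#' @param seed integer RNG seed.
#' @return list of [bbox()].
#' @export
gen_bbs <- function(fixture, jitter = 2L, drop_prob = 0, seed = 1L) {
  with_seed(seed, {
    nr <- nrow(fixture$mask); nc <- ncol(fixture$mask)
    out <- list()
    for (k in 1:2) {
      idx <- which(fixture$truth == k)
      if (!length(idx)) next
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      j <- if (jitter > 0) sample(seq(-jitter, jitter), 4, replace = TRUE) else rep(0L, 4)
      top <- max(1L, min(r) + j[1]); bottom <- min(nr, max(r) + j[2])
      left <- max(1L, min(c) + j[3]); right <- min(nc, max(c) + j[4])
      if (top > bottom) { top <- min(r); bottom <- max(r) }
      if (left > right) { left <- min(c); right <- max(c) }
      p <- stats::runif(1, 0.8, 1)
      dropped <- stats::runif(1) < drop_prob
      if (!dropped) out[[length(out) + 1L]] <- bbox(top, left, bottom, right, p)
    }
    ## distractors strictly outside the blob's enclosing box
    fg <- which(fixture$mask != 0)
    r <- (fg - 1L) %% nr + 1L; c <- (fg - 1L) %/% nr + 1L
    roi_top <- min(r); roi_left <- min(c)
    ndis <- sample(0:2, 1)
    for (k in seq_len(ndis)) {
      sz <- sample(3:5, 1)
      p <- stats::runif(1, 0.8, 1)
      dropped <- stats::runif(1) < drop_prob
      if (dropped) next
      if (roi_top - 2L >= sz) {
        l0 <- sample(seq_len(max(1L, nc - sz)), 1)
        out[[length(out) + 1L]] <- bbox(1L, l0, sz, min(nc, l0 + sz - 1L), p)
      } else if (roi_left - 2L >= sz) {
        t0 <- sample(seq_len(max(1L, nr - sz)), 1)
        out[[length(out) + 1L]] <- bbox(t0, 1L, min(nr, t0 + sz - 1L), sz, p)
      }
    }
    out
  })
}

#' Generate a stratified fixture suite
#'
#' Fixtures cycle deterministically through contact widths 4-24 px, tilt
#' angles (larger tilts make wide contacts attainable for the default
#' 35 x 10 animal), enclosed-hole carving (every 5th fixture), and boundary
#' noise rates 0 / 0.02 / 0.05.
#'
#' @param n number of fixtures.
#' @param seed master seed; fixture i uses seed `(seed * 100000 + i)` modulo
#'   2^31 - 1.
#' @return list of `ts_fixture`.
#' @export
gen_suite <- function(n, seed = 0L) {
  stopifnot(n > 0)
  cws <- seq(4, 24, 2)
  noises <- c(0, 0.02, 0.05)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cw <- cws[(i - 1L) %% length(cws) + 1L]
    noise <- noises[(i - 1L) %% length(noises) + 1L]
    hole <- as.numeric(i %% 5L == 0L)
    seed_i <- as.integer((seed * 100000 + i) %% 2147483647)
    ## minimum tilt that makes the contact width attainable: the transversal
    ## half-thickness sqrt((a sin t)^2 + (b cos t)^2) must exceed cw/2 + 3
    a <- 17.5; b <- 5.5
    req <- cw / 2 + 3
    tmin <- if (req <= b) 0 else asin(min(1, sqrt((req^2 - b^2) / (a^2 - b^2))))
    th <- min(tmin + 0.05 + 0.1 * ((i * 7L) %% 3L) / 2, 1.25)
    ## contact width 10 ~ the full animal width: untilted heavy side overlap,
    ## a smooth near-convex blob (the 0-CP stratum); narrower contacts use a
    ## chevron pose (opposed tilts); wider ones a parallel side-by-side pose
    if (cw == 10) th <- 0
    ang_b <- if (cw <= 10) -th else th
    out[[i]] <- gen_pair(pair_spec(axes_a = c(a, b), axes_b = c(a, b),
                                   angle_a = th, angle_b = ang_b,
                                   contact_width = cw, hole_prob = hole,
                                   noise_rate = noise, seed = seed_i))
  }
  out
}
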