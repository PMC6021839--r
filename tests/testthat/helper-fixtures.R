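# Shared fixture builders and a per-session cache for the expensive suite
# runs, so the acceptance criteria can reuse one 200-fixture evaluation.

mk_disc <- function(r = 12, pad = 3) {
  n <- 2 * r + 2 * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  idx <- which((row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2)
  m[idx] <- 1L
  m
}

mk_ellipse <- function(nr, nc, a, b, ctr = c(nr / 2 + 0.5, nc / 2 + 0.5)) {
  m <- matrix(0L, nr, nc)
  idx <- which(((col(m) - ctr[2]) / a)^2 + ((row(m) - ctr[1]) / b)^2 <= 1)
  m[idx] <- 1L
  m
}

# two discs overlapping with a given neck width (circle chord geometry)
mk_two_discs <- function(r = 12, neckw = 6, pad = 5) {
  d <- 2 * sqrt(r^2 - (neckw / 2)^2)
  nr <- 2 * r + 2 * pad
  nc <- ceiling(d) + 2 * r + 2 * pad
  c1 <- c(nr / 2, r + pad)
  c2 <- c(nr / 2, r + pad + d)
  m <- matrix(0L, nr, nc)
  idx <- which((row(m) - c1[1])^2 + (col(m) - c1[2])^2 <= r^2 |
                 (row(m) - c2[1])^2 + (col(m) - c2[2])^2 <= r^2)
  m[idx] <- 1L
  m
}

# axis-aligned rectangle blob with optional rectangular notches cut into the
# top edge; each notch is list(left, width, depth)
mk_rect <- function(nr = 20, nc = 40, pad = 3, notches = list()) {
  m <- matrix(0L, nr + 2 * pad, nc + 2 * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- 1L
  for (no in notches) {
    rows <- pad + seq_len(no$depth)
    cols <- pad + no$left + seq_len(no$width) - 1L
    m[rows, cols] <- 0L
  }
  m
}

# dumbbell: two square lobes joined by a thin neck
mk_dumbbell <- function(lobe = 20, neck_h = 4, neck_w = 10, pad = 4) {
  nr <- lobe + 2 * pad
  nc <- 2 * lobe + neck_w + 2 * pad
  m <- matrix(0L, nr, nc)
  m[pad + seq_len(lobe), pad + seq_len(lobe)] <- 1L
  m[pad + seq_len(lobe), pad + lobe + neck_w + seq_len(lobe)] <- 1L
  nr0 <- pad + (lobe - neck_h) %/% 2
  m[nr0 + seq_len(neck_h), pad + lobe + seq_len(neck_w)] <- 1L
  m
}

mk_ring <- function(router = 12, rinner = 6, pad = 3) {
  n <- 2 * router + 2 * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  d2 <- (row(m) - ctr)^2 + (col(m) - ctr)^2
  m[d2 <= router^2 & d2 > rinner^2] <- 1L
  m
}

# deterministic random blob: union of 1-3 random discs, largest component
mk_random_blob <- function(seed, n = 15) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  for (k in seq_len(sample(1:3, 1))) {
    ctr <- runif(2, 4, n - 3)
    r <- runif(1, 2, n / 3)
    m[(row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= r^2] <- 1L
  }
  lab <- label_components(m)
  if (max(lab) == 0L) {
    m[n %/% 2, n %/% 2] <- 1L
    return(m)
  }
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), n, n)
}

# suite/evaluation cache shared across test files (test_dir runs all files in
# one process; generation and the three 200-fixture evaluations are reused)
.ts_test_cache <- new.env(parent = emptyenv())

suite_200 <- function() {
  if (is.null(.ts_test_cache$suite)) .ts_test_cache$suite <- gen_suite(200, 0)
  .ts_test_cache$suite
}

suite_bb_cfg <- function() bb_config(probability_th = 0.8)

suite_results <- function(mode = "hybrid") {
  key <- paste0("res_", mode)
  if (is.null(.ts_test_cache[[key]])) {
    .ts_test_cache[[key]] <-
      run_batch(suite_200(), bb_cfg = suite_bb_cfg(), mode = mode)
  }
  .ts_test_cache[[key]]
}

# per-fixture segmentation results of the hybrid route (for partition checks)
suite_segmentations <- function() {
  if (is.null(.ts_test_cache$segs)) {
    .ts_test_cache$segs <- lapply(suite_200(), function(fx) {
      tryCatch(separate(fx$mask, fx$bbs, bb_cfg = suite_bb_cfg()),
               error = function(e) e)
    })
  }
  .ts_test_cache$segs
}

# independent pixel-counting oracle for box scoring: plain scalar loops,
# no shared code with evaluate_bb
oracle_eval_bb <- function(box, mask, cfg = bb_config()) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- integer(0); cs <- integer(0)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (mask[r, c] != 0) { rs <- c(rs, r); cs <- c(cs, c) }
  }
  top <- min(rs); bottom <- max(rs); left <- min(cs); right <- max(cs)
  pp_roi <- length(rs)
  is_border <- function(r, c) {          # only ever called on foreground
    (r == 1 || mask[r - 1, c] == 0) ||
      (r == nr || mask[r + 1, c] == 0) ||
      (c == 1 || mask[r, c - 1] == 0) ||
      (c == nc || mask[r, c + 1] == 0)
  }
  ringd <- function(r, c, t, l, b, rg) {
    if (r >= t && r <= b && c >= l && c <= rg) {
      min(r - t, b - r, c - l, rg - c)
    } else {
      max(t - r, r - b, l - c, c - rg, 0)
    }
  }
  bp_roi <- 0L; bp_bb <- 0L; pp_bb <- 0L
  for (k in seq_along(rs)) {
    r <- rs[k]; c <- cs[k]
    if (r >= box$top && r <= box$bottom && c >= box$left && c <= box$right) {
      pp_bb <- pp_bb + 1L
    }
    if (is_border(r, c)) {
      near_roi <- ringd(r, c, top, left, bottom, right) <= cfg$near_band
      if (near_roi) bp_roi <- bp_roi + 1L
      if (near_roi &&
          ringd(r, c, box$top, box$left, box$bottom, box$right) <= cfg$near_band) {
        bp_bb <- bp_bb + 1L
      }
    }
  }
  size_ok <- cfg$size_lo * pp_roi <= pp_bb && pp_bb <= cfg$size_hi * pp_roi
  boundary_ok <- cfg$boundary_frac * bp_roi <= bp_bb
  conf <- NA_real_
  if (size_ok && boundary_ok) {
    den <- abs(pp_bb - 0.5 * pp_roi)
    if (den == 0) den <- 0.5
    conf <- (bp_bb - cfg$boundary_frac * bp_roi) / den
  }
  list(pp_bb = pp_bb, bp_bb = bp_bb, size_ok = size_ok,
       boundary_ok = boundary_ok, confidence = conf)
}
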