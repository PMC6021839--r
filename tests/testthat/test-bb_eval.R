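test_that("build_roi measures blob pixels and near-perimeter border pixels", {
  m <- matrix(0L, 14, 14)
  m[3:12, 3:12] <- 1L
  roi <- build_roi(m)
  expect_equal(roi$pp_roi, 100L)
  expect_equal(roi$box$top, 3L)
  expect_equal(roi$box$right, 12L)
  # every border pixel of a filled square lies on the RoI perimeter
  expect_equal(roi$bp_roi, 36L)

  m1 <- matrix(0L, 5, 5); m1[3, 3] <- 1L
  roi1 <- build_roi(m1)
  expect_equal(roi1$pp_roi, 1L)
  expect_equal(roi1$bp_roi, 1L)

  expect_error(build_roi(matrix(0L, 3, 3)), class = "touchsplit_error_EMPTY_MASK")
})

test_that("filter_candidates keeps in-RoI boxes above the probability threshold", {
  m <- matrix(0L, 20, 30)
  m[5:15, 5:25] <- 1L
  cfg <- bb_config(probability_th = 0.8)
  roi <- build_roi(m, cfg)
  outside <- bbox(1, 1, 3, 3, 1)
  same <- bbox(5, 5, 15, 25, 0.9)
  over1 <- bbox(4, 4, 16, 26, 0.9)          # exceeds RoI by 1 < near_band
  weak <- bbox(6, 6, 14, 24, 0.5)           # below threshold
  kept <- filter_candidates(list(outside, same, over1, weak), roi, cfg)
  expect_length(kept, 2L)
  # the oversized box is clipped back to the RoI
  expect_equal(kept[[2]]$top, 5L)
  expect_equal(kept[[2]]$right, 25L)
})

test_that("size condition brackets 40-60% of blob pixels", {
  # 20x50 rectangle: a full-height box over k columns holds 20k pixels,
  # so the size condition is 20 <= k <= 30
  m <- matrix(0L, 26, 56)
  m[4:23, 4:53] <- 1L
  roi <- build_roi(m)
  for (k in c(19, 20, 30, 31)) {
    u <- evaluate_bb(bbox(4, 4, 23, 3 + k, 1), m, roi)
    expect_equal(u$pp_bb, 20L * k)
    expect_equal(u$size_ok, k >= 20 && k <= 30,
                 info = sprintf("k = %d", k))
  }
})

test_that("evaluate_bb agrees with the pixel-counting oracle on structured cases", {
  m <- mk_two_discs(r = 10, neckw = 6)
  roi <- build_roi(m)
  boxes <- list(bbox(roi$box$top, roi$box$left, roi$box$bottom,
                     (roi$box$left + roi$box$right) %/% 2, 1),
                bbox(roi$box$top, roi$box$left, roi$box$bottom, roi$box$right, 1),
                bbox(roi$box$top + 3, roi$box$left + 3, roi$box$bottom - 3,
                     roi$box$right - 3, 1))
  for (b in boxes) {
    u <- evaluate_bb(b, m, roi)
    o <- oracle_eval_bb(b, m)
    expect_equal(u$pp_bb, o$pp_bb)
    expect_equal(u$bp_bb, o$bp_bb)
    expect_equal(u$size_ok, o$size_ok)
    expect_equal(u$boundary_ok, o$boundary_ok)
    expect_equal(u$confidence, o$confidence)
  }
})

test_that("select_useful_bbs applies the coverage condition", {
  m <- matrix(0L, 26, 66)
  m[4:23, 4:63] <- 1L                        # 20 x 60 rectangle
  roi <- build_roi(m)
  left <- evaluate_bb(bbox(4, 4, 23, 33, 1), m, roi)    # half each
  right <- evaluate_bb(bbox(4, 34, 23, 63, 1), m, roi)
  expect_true(left$size_ok && left$boundary_ok)
  sel <- select_useful_bbs(list(left, right), roi, m)
  expect_length(sel, 2L)
  expect_true(sel[[1]]$confidence >= sel[[2]]$confidence)

  # no candidate passes -> empty; single candidate -> itself
  bad <- evaluate_bb(bbox(4, 4, 23, 10, 1), m, roi)     # far too small
  expect_length(select_useful_bbs(list(bad), roi, m), 0L)
  expect_length(select_useful_bbs(list(left), roi, m), 1L)

  # second box failing coverage: nearly coincident with the first
  twin <- evaluate_bb(bbox(4, 5, 23, 34, 1), m, roi)
  sel2 <- select_useful_bbs(list(left, twin), roi, m)
  expect_length(sel2, 1L)

  # brute-force check of the pairing actually returned
  cand <- list(left, right, twin)
  sel3 <- select_useful_bbs(cand, roi, m)
  expect_length(sel3, 2L)
  first <- sel3[[1]]; second <- sel3[[2]]
  idx <- which(m != 0); nr <- nrow(m)
  r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
  inb <- function(b) r >= b$box$top & r <= b$box$bottom & c >= b$box$left & c <= b$box$right
  outside_cover <- sum(inb(second) & !inb(first))
  expect_true(outside_cover >= 0.5 * (roi$pp_roi - first$pp_bb))
})

test_that("cut_with_one_bb yields one line on a dumbbell and falls back otherwise", {
  m <- mk_dumbbell()
  # box enclosing the left lobe with margin; only its right edge crosses the neck
  u <- evaluate_bb(bbox(2, 2, nrow(m) - 1, 29, 1), m, build_roi(m))
  line <- cut_with_one_bb(u, m)
  expect_s3_class(line, "ts_boundary")
  lab <- split_by_line(m, line)
  expect_equal(max(lab), 2L)

  # box strictly inside a convex blob: every edge crosses -> fallback
  big <- mk_rect(30, 30)
  u2 <- evaluate_bb(bbox(10, 10, 20, 20, 1), big, build_roi(big))
  expect_true(is_fallback(cut_with_one_bb(u2, big)))

  # box entirely off the blob -> fallback
  u3 <- evaluate_bb(bbox(1, 1, 2, 2, 1), big, build_roi(big))
  expect_true(is_fallback(cut_with_one_bb(u3, big)))
})

test_that("cut_with_two_bbs handles the three overlap cases", {
  # Case 2: boxes sharing one column over a rectangle -> cut along that edge
  m <- mk_rect(20, 40)                       # blob rows 4..23, cols 4..43
  a <- evaluate_bb(bbox(4, 4, 23, 23, 1), m, build_roi(m))
  b <- evaluate_bb(bbox(4, 23, 23, 43, 1), m, build_roi(m))
  line <- cut_with_two_bbs(a, b, m)
  expect_s3_class(line, "ts_boundary")
  expect_true(all(line$points[, 2] == 23L))
  lab <- split_by_line(m, line)
  expect_equal(sum(lab > 0), sum(m))

  # Case 1: overlapping boxes across a dumbbell neck -> valid split
  db <- mk_dumbbell()
  ra <- bbox(2, 2, nrow(db) - 1, 31, 1)
  rb <- bbox(2, 27, nrow(db) - 1, ncol(db) - 1, 1)
  ua <- evaluate_bb(ra, db, build_roi(db))
  ub <- evaluate_bb(rb, db, build_roi(db))
  line2 <- cut_with_two_bbs(ua, ub, db)
  expect_s3_class(line2, "ts_boundary")
  expect_equal(max(split_by_line(db, line2)), 2L)

  # Case 3: disjoint boxes with a 6-pixel gap -> midline at offset 3
  m3 <- mk_rect(20, 40)
  a3 <- evaluate_bb(bbox(4, 4, 23, 20, 1), m3, build_roi(m3))
  b3 <- evaluate_bb(bbox(4, 27, 23, 43, 1), m3, build_roi(m3))
  line3 <- cut_with_two_bbs(a3, b3, m3)
  expect_s3_class(line3, "ts_boundary")
  expect_true(all(line3$points[, 2] == 23L))  # 20 + 6 %/% 2
})

test_that("quality gate enforces the printed length and size thresholds", {
  cfg <- bb_config()
  mkline <- function(n) boundary_line(cbind(row = seq_len(n), col = rep(1L, n)))
  mklab <- function(n1, n2) {
    lab <- matrix(0L, 20, 20)
    lab[seq_len(n1)] <- 1L
    lab[n1 + seq_len(n2)] <- 2L
    lab
  }
  expect_true(quality_gate(mkline(20), mklab(50, 50), cfg))
  expect_false(quality_gate(mkline(21), mklab(50, 50), cfg))
  expect_true(quality_gate(mkline(10), mklab(60, 40), cfg))   # ratio exactly 1.5
  expect_false(quality_gate(mkline(10), mklab(61, 39), cfg))  # ratio ~ 1.564
})

test_that("box scoring is deterministic", {
  m <- mk_two_discs(r = 10, neckw = 6)
  roi <- build_roi(m)
  b <- bbox(roi$box$top, roi$box$left, roi$box$bottom,
            (roi$box$left + roi$box$right) %/% 2, 1)
  u1 <- evaluate_bb(b, m, roi)
  u2 <- evaluate_bb(b, m, roi)
  expect_identical(u1, u2)
})
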