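test_that("extract_outline matches the border-pixel oracle on canonical shapes", {
  # 3x3 all-foreground: the 8 border pixels, closed
  m <- matrix(1L, 3, 3)
  o <- extract_outline(m)
  expect_equal(nrow(o$points), 8L)
  expect_setequal(paste(o$points[, 1], o$points[, 2]),
                  paste(rep(1:3, 3), rep(1:3, each = 3))[-5])

  # single pixel
  m <- matrix(0L, 4, 4); m[2, 3] <- 1L
  expect_equal(extract_outline(m)$points, cbind(row = 2L, col = 3L))

  # filled ellipse in a 50x30 grid: outline length equals the brute-force
  # count of foreground pixels with a background 4-neighbour
  m <- mk_ellipse(50, 30, a = 13, b = 23)
  o <- extract_outline(m)
  oracle <- 0L
  for (r in 1:50) for (c in 1:30) {
    if (m[r, c] == 0) next
    up <- if (r == 1) 0L else m[r - 1, c]
    dn <- if (r == 50) 0L else m[r + 1, c]
    lf <- if (c == 1) 0L else m[r, c - 1]
    rt <- if (c == 30) 0L else m[r, c + 1]
    if (up == 0 || dn == 0 || lf == 0 || rt == 0) oracle <- oracle + 1L
  }
  expect_equal(nrow(o$points), oracle)
})

test_that("extract_outline rejects empty and multi-component masks", {
  expect_error(extract_outline(matrix(0L, 5, 5)), class = "touchsplit_error_EMPTY_MASK")
  m <- matrix(0L, 5, 5); m[1, 1] <- 1L; m[5, 5] <- 1L
  expect_error(extract_outline(m), class = "touchsplit_error_MULTI_COMPONENT")
})

test_that("outline invariants hold on 1000 random blobs", {
  for (seed in 1:1000) {
    m <- mk_random_blob(seed)
    o <- extract_outline(m)
    p <- o$points
    n <- nrow(p)
    # closed 8-connected contour
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    steps_ok <- all(abs(nxt - p) <= 1L)
    # every point is on the blob border (has a background 4-neighbour,
    # off-grid counting as background)
    pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
    pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    on_border <- all(vapply(seq_len(n), function(i) {
      r <- p[i, 1] + 1L; c <- p[i, 2] + 1L
      pad[r, c] == 1L &&
        (pad[r - 1, c] == 0L || pad[r + 1, c] == 0L ||
           pad[r, c - 1] == 0L || pad[r, c + 1] == 0L)
    }, TRUE))
    if (!steps_ok || !on_border) {
      fail(sprintf("outline invariant violated at seed %d", seed))
    }
  }
  succeed()
})

test_that("rasterize_segment produces valid digital segments", {
  expect_equal(nrow(rasterize_segment(c(1, 1), c(1, 4))), 4L)
  expect_equal(rasterize_segment(c(1, 1), c(1, 4))[, 1], rep(1L, 4))
  expect_equal(nrow(rasterize_segment(c(1, 1), c(4, 4))), 4L)

  # documented contract: forward and reverse are both valid 8-paths of
  # equal length (not necessarily point-for-point reverses)
  set.seed(7)
  for (k in 1:50) {
    a <- c(sample(1:30, 1), sample(1:30, 1))
    b <- c(sample(1:30, 1), sample(1:30, 1))
    fw <- rasterize_segment(a, b)
    bw <- rasterize_segment(b, a)
    expect_equal(nrow(fw), nrow(bw))
    for (p in list(fw, bw)) {
      if (nrow(p) > 1) expect_true(all(abs(diff(p[, 1])) <= 1 & abs(diff(p[, 2])) <= 1))
    }
    expect_equal(unname(fw[1, ]), a)
    expect_equal(unname(fw[nrow(fw), ]), b)
  }
})

test_that("split_by_line partitions a square along a vertical cut", {
  m <- matrix(1L, 10, 10)
  line <- boundary_line(cbind(row = 1:10, col = rep(5L, 10)))
  lab <- split_by_line(m, line)
  # components before re-assignment are 40 (left) and 50 (right); the 10
  # equidistant line pixels tie to the lower label, giving 50/50
  expect_equal(sum(lab == 1L), 50L)
  expect_equal(sum(lab == 2L), 50L)
  # label 1 is the left component (smaller centroid column at equal rows)
  expect_true(all(lab[, 1:4] == 1L))
  expect_true(all(lab[, 6:10] == 2L))
  # conservation
  expect_equal(sum(lab > 0L), sum(m))
})

test_that("split_by_line signals BAD_CUT for degenerate lines", {
  m <- matrix(1L, 4, 4)
  all_px <- cbind(row = rep(1:4, 4), col = rep(1:4, each = 4))
  expect_error(split_by_line(m, boundary_line(all_px)),
               class = "touchsplit_error_BAD_CUT")
  # a line that does not reach the border on both ends leaves one component
  short <- boundary_line(cbind(row = 2:3, col = c(2L, 2L)))
  expect_error(split_by_line(matrix(1L, 6, 6), short),
               class = "touchsplit_error_BAD_CUT")
})

test_that("split_by_line conserves foreground over random vertical cuts", {
  for (seed in 1:40) {
    m <- mk_random_blob(seed, n = 21)
    idx <- which(m != 0)
    cols <- (idx - 1L) %/% 21L + 1L
    cc <- round(mean(range(cols)))
    line <- boundary_line(cbind(row = 1:21, col = rep(cc, 21)))
    lab <- tryCatch(split_by_line(m, line),
                    touchsplit_error_BAD_CUT = function(e) NULL)
    if (is.null(lab)) next
    expect_equal(sum(lab > 0L), sum(m))
    expect_identical(unname(which(lab > 0L)), unname(which(m != 0L)))
  }
})

test_that("label_components honours 4- vs 8-connectivity", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L     # diagonal touch
  expect_equal(max(label_components(m, 8L)), 1L)
  expect_equal(max(label_components(m, 4L)), 2L)
})
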