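test_that("natural holes are enclosed background components", {
  expect_length(find_natural_holes(mk_ellipse(30, 50, 22, 12)), 0L)

  ring <- mk_ring(12, 6)
  holes <- find_natural_holes(ring)
  expect_length(holes, 1L)
  # the hole is the interior disc
  expect_equal(nrow(holes[[1]]$pixels), sum(mk_disc(6, 9) == 1L & ring == 0L))

  m <- mk_rect(14, 30)
  m[10, 10:12] <- 0L                 # two 3-pixel enclosed gaps
  m[12, 20:22] <- 0L
  holes2 <- find_natural_holes(m)
  expect_length(holes2, 2L)
  expect_setequal(vapply(holes2, function(h) nrow(h$pixels), 0L), c(3L, 3L))
})

test_that("erosion holes appear only for blobs that survive eight erosions", {
  # two r=12 discs with a 6-wide neck: the neck vanishes, remnants survive
  holes <- holes_by_erosion(mk_two_discs(12, 6))
  expect_gte(length(holes), 1L)
  expect_equal(holes[[1]]$kind, "erosion")

  # thin blob (width <= 16 everywhere) erodes away entirely
  thin <- mk_rect(12, 60)
  expect_true(all(erode3(thin, 8) == 0L))
  expect_length(holes_by_erosion(thin), 0L)

  # solid square: survives but produces no void
  expect_length(holes_by_erosion(mk_rect(100, 100, pad = 2)), 0L)
})

test_that("skeleton hole spans a bar transversally at its centre", {
  bar <- mk_rect(10, 60)                   # 60x10 bar, rows 4..13, cols 4..63
  h <- hole_by_skeleton(bar)
  expect_equal(h$kind, "skeleton")
  ctr <- c(mean(c(4, 13)), mean(c(4, 63)))
  # hole pixels cluster around the bar centre
  expect_true(all(abs(h$pixels[, 2] - ctr[2]) <= 4))
  expect_true(all(abs(h$pixels[, 1] - ctr[1]) <= 4))
  # and span rows (transversal), not columns
  expect_gte(diff(range(h$pixels[, 1])), diff(range(h$pixels[, 2])))

  expect_error(hole_by_skeleton(matrix(1L, 3, 3)),
               class = "touchsplit_error_DEGENERATE_SHAPE")
})

test_that("skeleton hole sits on the neck of a symmetric pair", {
  fx <- gen_pair(pair_spec(contact_width = 8, seed = 5))
  h <- hole_by_skeleton(fx$mask)
  iface <- which(fx$truth == 1L & dilate3(matrix(as.integer(fx$truth == 2L),
                                                nrow(fx$truth), ncol(fx$truth))) == 1L)
  icols <- (iface - 1L) %/% nrow(fx$truth) + 1L
  expect_lte(min(abs(mean(h$pixels[, 2]) - icols)), 4)
})

test_that("guidelines join hole extremal points", {
  g1 <- guideline_from_holes(list(structure(
    list(pixels = cbind(row = 5L, col = 7L), kind = "natural"), class = "ts_hole")))
  expect_equal(nrow(g1$points), 1L)

  # 5 collinear pixels: the diameter spans the extremes
  px <- cbind(row = rep(4L, 5), col = 3:7)
  g2 <- guideline_from_holes(list(structure(list(pixels = px, kind = "natural"),
                                            class = "ts_hole")))
  expect_equal(nrow(g2$points), 5L)
  expect_setequal(c(g2$end_a[2], g2$end_b[2]), c(3L, 7L))

  # two holes 10 px apart: chained polyline contains both diameters
  h1 <- structure(list(pixels = cbind(row = rep(4L, 3), col = 3:5), kind = "natural"),
                  class = "ts_hole")
  h2 <- structure(list(pixels = cbind(row = rep(4L, 3), col = 15:17), kind = "natural"),
                  class = "ts_hole")
  g3 <- guideline_from_holes(list(h1, h2))
  expect_setequal(c(g3$end_a[2], g3$end_b[2]), c(3L, 17L))
  expect_true(all(paste(4, 3:17) %in% paste(g3$points[, 1], g3$points[, 2])))
})

test_that("concavity series is zero on the hull and measures notch depth", {
  # convex rectangle: L identically zero
  s <- build_series(extract_outline(mk_rect(15, 30)))
  expect_true(all(s$L == 0))
  expect_equal(s$G[1], 0)
  expect_length(candidate_cps(s), 0L)

  # rectangle with one 5-deep notch: max L is 5 on the notch floor
  m <- mk_rect(15, 30, notches = list(list(left = 12, width = 4, depth = 5)))
  s2 <- build_series(extract_outline(m))
  expect_equal(max(s2$L), 5)
  cands <- candidate_cps(s2)
  expect_gte(length(cands), 1L)
  deepest <- cands[[which.max(vapply(cands, function(x) x$depth, 0))]]
  expect_equal(deepest$depth, 5)
  expect_equal(deepest$point[[1]], 9L)   # pad 3 + depth 5 + 1

  # per-segment runs cover the outline exactly once
  covered <- unlist(lapply(s2$hull_segments, function(sg) sg$range[1]:sg$range[2]))
  expect_setequal(covered, seq_along(s2$L))

  # collinear outline degenerates
  bar <- matrix(0L, 5, 10); bar[3, 2:9] <- 1L
  expect_error(build_series(extract_outline(bar)),
               class = "touchsplit_error_DEGENERATE_HULL")
})

test_that("final_cps keeps deep narrow notches and rejects shallow broad bends", {
  # deep narrow notch: kept
  m <- mk_rect(20, 40, notches = list(list(left = 18, width = 3, depth = 8)))
  s <- build_series(extract_outline(m))
  fc <- final_cps(candidate_cps(s), s)
  expect_length(fc, 1L)
  expect_equal(fc[[1]]$depth, 8)
  expect_gte(fc[[1]]$ratio, 1.3)

  # shallow broad depression: discarded
  m2 <- mk_rect(20, 40, notches = list(list(left = 6, width = 28, depth = 2)))
  s2 <- build_series(extract_outline(m2))
  fc2 <- final_cps(candidate_cps(s2), s2)
  expect_length(fc2, 0L)

  # more than two survivors (one notch per side, since collinear rim points
  # are not hull vertices): the two deepest win
  m3 <- mk_rect(30, 50)                  # rows 4..33, cols 4..53
  m3[4:13, 24:26] <- 0L                  # top notch, depth 10
  m3[26:33, 38:40] <- 0L                 # bottom notch, depth 8
  m3[17:19, 4:9] <- 0L                   # left notch, depth 6
  s3 <- build_series(extract_outline(m3))
  fc3 <- final_cps(candidate_cps(s3), s3)
  expect_length(fc3, 2L)
  expect_setequal(vapply(fc3, function(x) x$depth, 0), c(10, 8))

  expect_length(final_cps(list(), s3), 0L)
})

test_that("boundary_from_shape covers the two-, one- and zero-CP cases", {
  # two CPs: symmetric pair, cut sizes within 5%
  fx <- gen_pair(pair_spec(contact_width = 6, seed = 11))
  res <- separate(fx$mask, list(), mode = "shape")
  n1 <- sum(res$labels == 1L); n2 <- sum(res$labels == 2L)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.05)

  # one CP: rectangle with a single deep notch and a hole beneath it
  m <- mk_rect(20, 40, notches = list(list(left = 18, width = 3, depth = 6)))
  m[14:15, 19] <- 0L                     # enclosed hole under the notch
  o <- extract_outline(m)
  s <- build_series(o)
  cps <- final_cps(candidate_cps(s), s)
  expect_length(cps, 1L)
  gl <- guideline_from_holes(find_natural_holes(m))
  line <- boundary_from_shape(gl, cps, o, m)
  expect_equal(max(split_by_line(m, line)), 2L)

  # zero CPs: annulus, guideline from its natural hole
  ring <- mk_ring(12, 5)
  o2 <- extract_outline(ring)
  s2 <- build_series(o2)
  cps2 <- final_cps(candidate_cps(s2), s2)
  expect_length(cps2, 0L)
  gl2 <- guideline_from_holes(find_natural_holes(ring))
  line2 <- boundary_from_shape(gl2, cps2, o2, ring)
  lab2 <- split_by_line(ring, line2)
  expect_equal(max(lab2), 2L)
  expect_equal(sum(lab2 > 0), sum(ring))
})

test_that("hole-source precedence is natural, then erosion, then skeleton", {
  # natural: carved hole at the contact
  fx <- gen_pair(pair_spec(contact_width = 8, hole_prob = 1, seed = 21))
  expect_gte(length(find_natural_holes(fx$mask)), 1L)
  expect_equal(separate(fx$mask, list(), mode = "shape")$module_used, "shape_natural")

  # erosion: fat blob that splits under erosion
  m <- mk_two_discs(12, 6)
  expect_length(find_natural_holes(m), 0L)
  expect_equal(separate(m, list(), mode = "shape")$module_used, "shape_erosion")

  # skeleton: thin pair, erosion empties the blob
  fx2 <- gen_pair(pair_spec(contact_width = 8, seed = 22))
  expect_length(find_natural_holes(fx2$mask), 0L)
  expect_length(holes_by_erosion(fx2$mask), 0L)
  expect_equal(separate(fx2$mask, list(), mode = "shape")$module_used, "shape_skeleton")
})
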