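test_that("co-occurrence accumulation matches brute-force pair counting", {
  # constant 2x2 patch: one gray level, all mass in (1,1)
  p <- toy_patch(matrix(0.5, 2, 2))
  g <- compute_glcm(p, 1, 0, levels = 8)
  expect_equal(sum(g$p), 1)
  expect_equal(g$p[1, 1], 1)

  # masked 4x4 two-level patch vs exhaustive enumeration of horizontal pairs
  set.seed(4)
  px <- matrix(sample(c(0.2, 0.8), 16, replace = TRUE), 4, 4)
  mask <- matrix(TRUE, 4, 4); mask[1, 4] <- FALSE; mask[3, 2] <- FALSE
  p2 <- toy_patch(px, mask)
  g2 <- compute_glcm(p2, 1, 0, levels = 2)
  cnt <- matrix(0, 2, 2)
  lev <- ifelse(px > 0.5, 2, 1)
  for (r in 1:4) for (c in 1:3)
    if (mask[r, c] && mask[r, c + 1]) {
      cnt[lev[r, c], lev[r, c + 1]] <- cnt[lev[r, c], lev[r, c + 1]] + 1
      cnt[lev[r, c + 1], lev[r, c]] <- cnt[lev[r, c + 1], lev[r, c]] + 1
    }
  expect_equal(g2$p, cnt / sum(cnt))

  # symmetric accumulation for arbitrary patches and directions
  set.seed(9)
  p3 <- toy_patch(matrix(runif(64), 8, 8))
  for (th in c(0, 45, 90, 135)) {
    g3 <- compute_glcm(p3, 2, th, levels = 8)
    expect_equal(g3$p, t(g3$p))
  }
  expect_error(compute_glcm(p3, 1, 30), "direction")
})

test_that("Haralick statistics agree with the definition oracle", {
  # point mass: entropy 0, energy 1
  pm <- matrix(0, 4, 4); pm[2, 2] <- 1
  h <- haralick_stats(pm)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["energy"]), 1)
  expect_true(all(is.finite(h)))

  # uniform GxG: entropy 2*log2(G), energy 1/G^2
  G <- 8
  hu <- haralick_stats(matrix(1 / G^2, G, G))
  expect_equal(unname(hu["entropy"]), 2 * log2(G))
  expect_equal(unname(hu["energy"]), 1 / G^2)

  # random normalized 8x8 vs straight-from-definition loops
  set.seed(21)
  m <- matrix(runif(64), 8, 8); m <- (m + t(m)); m <- m / sum(m)
  expect_equal(unname(haralick_stats(m)), haralick_oracle(m), tolerance = 1e-12)
})

test_that("feature blocks have the documented lengths and layout", {
  fb <- feature_block_index()
  expect_equal(fb$length,
               c(354L, 312L, 20L, 96L, 5L, 5L, 20L))
  expect_equal(feature_dim(), 812L)
  expect_equal(fb$offset, cumsum(c(0L, head(fb$length, -1))))

  p <- gen_roi(phantom_spec("ill_defined", image_size = 64,
                            core_radius = 12, seed = 2))
  for (i in seq_len(nrow(fb)))
    expect_length(extract_block(p, fb$block[i]), fb$length[i])
  expect_error(extract_block(p, "wavelet"), "unknown feature block")

  f <- extract_features(p)
  expect_length(f, 812)
  expect_true(all(is.finite(f)))
  expect_identical(as.numeric(f), as.numeric(extract_features(p)))
})

test_that("degenerate constant patches obey the zero-variance conventions", {
  p <- toy_patch(matrix(0.4, 24, 24))
  iv <- extract_block(p, "intensity")
  expect_equal(unname(iv[2]), 0.4)   # mean gray
  expect_equal(unname(iv[3:5]), c(0, 0, 0))  # sd, skewness, kurtosis
  expect_true(all(is.finite(extract_block(p, "sgld"))))
  expect_true(all(is.finite(extract_block(p, "glds"))))
})

test_that("each 59-bin LBP sub-histogram is l1-normalized", {
  p <- gen_roi(phantom_spec("micro_lobulated", image_size = 64,
                            core_radius = 12, seed = 6))
  v <- extract_block(p, "lbp")
  sums <- vapply(0:5, function(k) sum(v[k * 59 + 1:59]), numeric(1))
  expect_equal(sums, rep(1, 6))
})

test_that("rotating a patch by 90 degrees swaps the 0/90 GLCM directions", {
  set.seed(13)
  px <- matrix(runif(100), 10, 10)
  mask <- matrix(TRUE, 10, 10); mask[1, 1] <- FALSE
  p <- toy_patch(px, mask)
  # counter-clockwise rotation: rows become reversed columns
  rot <- toy_patch(t(px)[ncol(px):1, ], t(mask)[ncol(mask):1, ])
  g0 <- compute_glcm(p, 2, 0, levels = 8)
  g90 <- compute_glcm(rot, 2, 90, levels = 8)
  expect_equal(g0$p, g90$p)
})

test_that("radial length descriptors match a boundary-walk oracle on a disk", {
  n <- 160
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ctr <- (n + 1) / 2
  mask <- sqrt((rows - ctr)^2 + (cols - ctr)^2) <= 64
  p <- toy_patch(matrix(0.5, n, n) + 0.01 * rows / n, mask)
  v <- extract_block(p, "nrl")
  expect_lt(v[2], 0.05)     # near-constant radius
  expect_gt(v[1], 0.9)      # normalized mean close to 1

  # independent zero-crossing count: walk the 4-boundary ordered by angle
  idx <- which(mask, arr.ind = TRUE)
  on_bd <- apply(idx, 1, function(rc) {
    r <- rc[1]; c <- rc[2]
    !(mask[r - 1, c] && mask[r + 1, c] && mask[r, c - 1] && mask[r, c + 1])
  })
  bd <- idx[on_bd, ]
  ang <- atan2(bd[, 1] - mean(idx[, 1]), bd[, 2] - mean(idx[, 2]))
  d <- sqrt((bd[, 1] - mean(idx[, 1]))^2 + (bd[, 2] - mean(idx[, 2]))^2)
  d <- d[order(ang)] / max(d)
  s <- sign(d - mean(d)); s <- s[s != 0]
  zc <- sum(s != c(s[-1], s[1]))
  expect_equal(unname(v[4]), zc)
})

test_that("all features stay finite across margin types and seeds", {
  for (mt in c(margin_types(), "normal")) {
    p <- gen_roi(phantom_spec(mt, image_size = 64, core_radius = 11,
                              seed = match(mt, c(margin_types(), "normal"))))
    f <- extract_features(p)
    expect_true(all(is.finite(f)), label = paste("finite features:", mt))
  }
})
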