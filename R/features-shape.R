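mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# boundary = foreground pixels with a 4-neighbour outside the mask (or on
# the image edge), ordered by polar angle around the centroid
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  bd <- mask & !inner
  idx <- which(bd, arr.ind = TRUE)
  ctr <- mask_centroid(mask)
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  idx[order(ang), , drop = FALSE]
}

# circular sign changes of x, zeros inheriting the previous sign
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s != c(s[-1], s[1]))
}

# normalized radial length: mean, sd, area ratio, zero-crossing count,
# 10-bin entropy of centroid-to-boundary distances scaled by their maximum
nrl_block <- function(patch) {
  bd <- boundary_pixels(patch$mask)
  ctr <- mask_centroid(patch$mask)
  d <- sqrt((bd[, 1] - ctr[1])^2 + (bd[, 2] - ctr[2])^2)
  nd <- d / max(d)
  m <- mean(nd)
  n <- length(nd)
  area_ratio <- sum(pmax(nd - m, 0)) / (n * m)
  zc <- zero_crossings(nd - m)
  h <- tabulate(pmin(10L, floor(nd * 10) + 1L), 10L)
  p <- h / sum(h)
  ent <- -sum(p * log2z(p))
  c(nrl_mean = m, nrl_sd = stats::sd(nd), nrl_area_ratio = area_ratio,
    nrl_zero_crossings = as.numeric(zc), nrl_entropy = ent)
}

# contrast measure, mean, sd, skewness, excess kurtosis of in-mask
# intensities; the contrast measure compares the in-mask mean against a
# 5-pixel-wide band just outside the mask; zero-variance patches report
# 0 skewness/kurtosis
intensity_block <- function(patch) {
  v <- patch$pixels[patch$mask]
  mu <- mean(v)
  band <- dilate_mask(patch$mask, 5L) & !patch$mask
  mu_band <- if (any(band)) mean(patch$pixels[band]) else mu
  contrast <- if (mu + mu_band > 0) (mu - mu_band) / (mu + mu_band) else 0
  s <- stats::sd(v)
  if (is.na(s)) s <- 0
  m2 <- mean((v - mu)^2)
  if (m2 > .Machine$double.eps) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  c(contrast_measure = contrast, mean_gray = mu, sd_gray = s,
    skewness = skew, kurtosis = kurt)
}

region_mean_sd <- function(map, region) {
  v <- map[region]
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(c(0, 0))
  s <- if (length(v) > 1L) stats::sd(v) else 0
  c(mean(v), s)
}

# region-based stellate features (20): two pixel-wise maps -- (a) absolute
# cosine alignment of the local gradient with the direction toward the mask
# centroid and (b) magnitude of the radial gradient component -- summarised
# over core (inner third of the radial extent), inner (rest of the mask)
# and outer (5-pixel band outside the mask) regions by per-region means
# (6), per-region standard deviations (6) and pairwise differences of the
# per-region means (6), plus the global mean and standard deviation of the
# alignment map (2)
stellate_block <- function(patch) {
  img <- patch$pixels
  nr <- nrow(img); nc <- ncol(img)
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  ctr <- mask_centroid(patch$mask)
  ry <- ctr[1] - matrix(seq_len(nr), nr, nc)
  rx <- ctr[2] - matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rn <- sqrt(ry^2 + rx^2)
  gn <- sqrt(gy^2 + gx^2)
  dotp <- gy * ry + gx * rx
  align <- ifelse(gn * rn > 0, abs(dotp) / (gn * rn), 0)
  radial <- ifelse(rn > 0, abs(dotp) / rn, 0)

  dist <- sqrt((matrix(seq_len(nr), nr, nc) - ctr[1])^2 +
                 (matrix(seq_len(nc), nr, nc, byrow = TRUE) - ctr[2])^2)
  extent <- max(dist[patch$mask])
  core <- patch$mask & dist < extent / 3
  inner <- patch$mask & dist >= extent / 3
  outer <- dilate_mask(patch$mask, 5L) & !patch$mask
  regions <- list(core = core, inner = inner, outer = outer)

  ms_a <- vapply(regions, function(r) region_mean_sd(align, r), numeric(2))
  ms_b <- vapply(regions, function(r) region_mean_sd(radial, r), numeric(2))
  glob <- region_mean_sd(align, core | inner | outer)
  diffs <- function(m) c(m[1] - m[2], m[1] - m[3], m[2] - m[3])
  unname(c(ms_a[1, ], ms_b[1, ],          # per-region means (6)
           ms_a[2, ], ms_b[2, ],          # per-region sds (6)
           diffs(ms_a[1, ]), diffs(ms_b[1, ]),  # mean differences (6)
           glob))                          # global mean/sd of alignment (2)
}
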