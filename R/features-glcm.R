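# displacement (drow, dcol) for a co-occurrence direction in degrees;
# row index grows downward, so 45 degrees points up-right
direction_offset <- function(direction, distance) {
  switch(as.character(direction),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stopf("'direction' must be one of 0, 45, 90, 135, got %s",
               format(direction)))
}

# uniform quantization of in-mask intensities to 1..levels (NA outside mask)
quantize_patch <- function(patch, levels) {
  v <- patch$pixels[patch$mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(patch$pixels), ncol(patch$pixels))
  if (diff(rng) < .Machine$double.eps) {
    q[patch$mask] <- 1L
  } else {
    q[patch$mask] <- pmin(levels,
                          floor((patch$pixels[patch$mask] - rng[1]) /
                                  diff(rng) * levels) + 1L)
  }
  q
}

# pairs of quantized values at a displacement, both endpoints in mask
displaced_pairs <- function(q, off) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) == 0L || length(c1) == 0L)
    return(cbind(integer(0), integer(0)))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a[ok], b[ok])
}

#' Masked gray-level co-occurrence matrix
#'
#' Accumulates co-occurrences of quantized gray levels at one displacement,
#' counting only pixel pairs with both endpoints inside the mask, with
#' symmetric accumulation (each pair counted in both orders), normalized to
#' sum 1. Quantization is uniform over the in-mask intensity range.
#'
#' @param patch An [roi_patch()].
#' @param distance Inter-pixel distance in pixels (>= 1).
#' @param direction Direction in degrees: 0, 45, 90 or 135.
#' @param levels Number of gray levels (>= 2; default 64).
#' @return A `cooccurrence_matrix`: list with the normalized `p` matrix and
#'   the displacement parameters. `p` is all-zero if the mask admits no
#'   valid pair at this displacement.
#' @export
compute_glcm <- function(patch, distance, direction, levels = 64L) {
  if (!inherits(patch, "roi_patch")) stopf("'patch' must be an roi_patch")
  check_number(distance, "distance", min = 1, integer = TRUE)
  check_number(levels, "levels", min = 2, integer = TRUE)
  off <- direction_offset(direction, as.integer(distance))
  q <- quantize_patch(patch, levels)
  pr <- displaced_pairs(q, off)
  p <- matrix(0, levels, levels)
  if (nrow(pr) > 0L) {
    counts <- tabulate(pr[, 1] + (pr[, 2] - 1L) * levels, levels * levels)
    p <- matrix(counts, levels, levels)
    p <- p + t(p)
    p <- p / sum(p)
  }
  structure(list(p = p, levels = as.integer(levels),
                 distance = as.integer(distance), direction = direction),
            class = "cooccurrence_matrix")
}

log2z <- function(x) ifelse(x > 0, log2(x), 0)

#' Haralick statistics of a co-occurrence matrix
#'
#' The 13 classical co-occurrence statistics in fixed order: correlation,
#' energy, entropy, inertia, inverse difference moment, sum average, sum
#' variance, sum entropy, difference energy, difference variance, difference
#' entropy, and the two information measures of correlation. Logarithms are
#' base 2 with `0*log(0) = 0`. Degenerate matrices never yield non-finite
#' values: correlation is 0 when a marginal variance is 0, and the first
#' information measure is 0 when both marginal entropies are 0.
#'
#' @param glcm A `cooccurrence_matrix` from [compute_glcm()] (normalized).
#' @return Named numeric vector of length 13.
#' @export
haralick_stats <- function(glcm) {
  p <- if (inherits(glcm, "cooccurrence_matrix")) glcm$p else as.matrix(glcm)
  G <- nrow(p)
  if (sum(p) > 0) p <- p / sum(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(G) * px)
  muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  correlation <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  energy <- sum(p^2)
  entropy <- -sum(p * log2z(p))
  inertia <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))

  # p_{x+y} over k = 2..2G and p_{x-y} over k = 0..G-1
  psum <- as.numeric(tapply(p, i + j, sum))
  ks <- sort(unique(as.integer(i + j)))
  pdif <- as.numeric(tapply(p, abs(i - j), sum))
  kd <- sort(unique(as.integer(abs(i - j))))

  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * log2z(psum))
  difference_energy <- sum(pdif^2)
  dmean <- sum(kd * pdif)
  difference_variance <- sum((kd - dmean)^2 * pdif)
  difference_entropy <- -sum(pdif * log2z(pdif))

  hx <- -sum(px * log2z(px))
  hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(correlation = correlation, energy = energy, entropy = entropy,
    inertia = inertia, inverse_difference_moment = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_energy = difference_energy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

glcm_distances <- function() c(1L, 2L, 4L, 6L, 8L, 10L)
glcm_directions <- function() c(0, 45, 90, 135)

# 24 co-occurrence matrices (6 distances x 4 directions) x 13 stats = 312
sgld_block <- function(patch, levels = 64L) {
  out <- numeric(0)
  for (d in glcm_distances())
    for (th in glcm_directions())
      out <- c(out, haralick_stats(compute_glcm(patch, d, th, levels)))
  unname(out)
}

# gray-level difference statistics: histogram of |level difference| per
# displacement; 4 stats (contrast, ASM, entropy, mean) x 24 = 96
glds_block <- function(patch, levels = 64L) {
  q <- quantize_patch(patch, levels)
  out <- numeric(0)
  for (d in glcm_distances()) {
    for (th in glcm_directions()) {
      off <- direction_offset(th, d)
      pr <- displaced_pairs(q, off)
      p <- rep(0, levels)                      # diffs 0 .. levels-1
      if (nrow(pr) > 0L) {
        cnt <- tabulate(abs(pr[, 1] - pr[, 2]) + 1L, levels)
        p <- cnt / sum(cnt)
      }
      k <- 0:(levels - 1L)
      out <- c(out, sum(k^2 * p), sum(p^2), -sum(p * log2z(p)), sum(k * p))
    }
  }
  unname(out)
}
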