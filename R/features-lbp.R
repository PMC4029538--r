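# map 8-bit patterns to uniform-LBP (u2) bins 1..59: the 58 uniform
# patterns (<= 2 circular 0/1 transitions) in increasing numeric order,
# then one catch-all bin for non-uniform patterns
lbp_u2_map <- local({
  map <- integer(256)
  bits <- function(v) as.integer(intToBits(v))[1:8]
  uniform <- vapply(0:255, function(v) {
    b <- bits(v)
    sum(b != c(b[-1], b[1])) <= 2L
  }, logical(1))
  map[uniform] <- seq_len(sum(uniform))
  map[!uniform] <- sum(uniform) + 1L
  function() map
})

# bilinear interpolation of img at a constant fractional offset (dy, dx);
# NA where the sample point leaves the image
shift_interp <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  r <- seq_len(nr) + dy
  c <- seq_len(nc) + dx
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  okr <- which(r0 >= 1 & r0 + 1 <= nr | (fr == 0 & r0 >= 1 & r0 <= nr))
  okc <- which(c0 >= 1 & c0 + 1 <= nc | (fc == 0 & c0 >= 1 & c0 <= nc))
  if (length(okr) == 0L || length(okc) == 0L) return(out)
  r0c <- pmin(r0[okr], nr); r1c <- pmin(r0[okr] + 1L, nr)
  c0c <- pmin(c0[okc], nc); c1c <- pmin(c0[okc] + 1L, nc)
  wr <- fr[okr]; wc <- fc[okc]
  a00 <- img[r0c, c0c, drop = FALSE]; a01 <- img[r0c, c1c, drop = FALSE]
  a10 <- img[r1c, c0c, drop = FALSE]; a11 <- img[r1c, c1c, drop = FALSE]
  wrm <- matrix(wr, length(okr), length(okc))
  wcm <- matrix(wc, length(okr), length(okc), byrow = TRUE)
  out[okr, okc] <- a00 * (1 - wrm) * (1 - wcm) + a01 * (1 - wrm) * wcm +
    a10 * wrm * (1 - wcm) + a11 * wrm * wcm
  out
}

# LBP codes (0..255) for P=8 neighbours on a circle of radius R;
# NA where any neighbour leaves the image
lbp_codes <- function(img, R, P = 8L) {
  code <- matrix(0, nrow(img), ncol(img))
  valid <- matrix(TRUE, nrow(img), ncol(img))
  for (p in seq_len(P) - 1L) {
    ang <- 2 * pi * p / P
    nb <- shift_interp(img, -R * sin(ang), R * cos(ang))
    valid <- valid & !is.na(nb)
    ge <- nb >= img
    ge[is.na(ge)] <- FALSE
    code <- code + 2^p * ge
  }
  code[!valid] <- NA_real_
  code
}

lbp_histogram <- function(codes, region) {
  map <- lbp_u2_map()
  sel <- region & !is.na(codes)
  h <- rep(0, 59)
  if (any(sel)) {
    bins <- map[codes[sel] + 1L]
    h <- tabulate(bins, 59L)
    h <- h / sum(h)
  }
  h
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

erode_mask <- function(mask, r) {
  EBImage::erode(matrix(as.numeric(mask), nrow(mask)), disc_brush(r)) > 0.5
}

dilate_mask <- function(mask, r) {
  EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), disc_brush(r)) > 0.5
}

# uniform LBP histograms at (P,R) in {(8,1),(8,2),(8,3)} over two regions:
# the mask interior (eroded by R+2) and a margin band (dilated by R+2 minus
# the interior), emphasising border texture; 59 x 3 x 2 = 354. A region
# that erodes/dilates to nothing falls back to the full mask so every
# 59-bin histogram still sums to 1.
lbp_block <- function(patch) {
  out <- numeric(0)
  for (R in c(1L, 2L, 3L)) {
    codes <- lbp_codes(patch$pixels, R)
    interior <- erode_mask(patch$mask, R + 2L)
    band <- dilate_mask(patch$mask, R + 2L) & !interior
    for (region in list(interior, band)) {
      if (!any(region & !is.na(codes))) region <- patch$mask
      if (!any(region & !is.na(codes))) region <- !is.na(codes)
      out <- c(out, lbp_histogram(codes, region))
    }
  }
  unname(out)
}
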