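# extract scan lines of a matrix along a direction; each line is a vector
# of quantized levels with NA outside the mask
direction_lines <- function(q, direction) {
  nr <- nrow(q); nc <- ncol(q)
  switch(as.character(direction),
    "0" = lapply(seq_len(nr), function(r) q[r, ]),
    "90" = lapply(seq_len(nc), function(c) q[, c]),
    "45" = lapply(seq_len(nr + nc - 1L), function(s) {
      # anti-diagonals: r + c = s + 1, traversed up-right
      r <- min(s, nr):max(1L, s - nc + 1L)
      c <- (s + 1L) - r
      q[cbind(r, c)]
    }),
    "135" = lapply(seq_len(nr + nc - 1L), function(s) {
      # diagonals: c - r = s - nr, traversed down-right
      r <- max(1L, nr - s + 1L):min(nr, nr + nc - s)
      c <- r + (s - nr)
      q[cbind(r, c)]
    }),
    stopf("'direction' must be one of 0, 45, 90, 135"))
}

# maximal runs of equal gray level along one direction, broken at mask gaps
run_length_matrix <- function(q, direction, levels, max_len) {
  rlm <- matrix(0, levels, max_len)
  for (line in direction_lines(q, direction)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    len <- pmin(r$lengths[keep], max_len)
    val <- r$values[keep]
    for (k in seq_along(val)) rlm[val[k], len[k]] <- rlm[val[k], len[k]] + 1
  }
  rlm
}

galloway_stats <- function(rlm, n_pixels) {
  nr_runs <- sum(rlm)
  if (nr_runs == 0) return(rep(0, 5))
  jl <- matrix(seq_len(ncol(rlm)), nrow(rlm), ncol(rlm), byrow = TRUE)
  c(sre = sum(rlm / jl^2) / nr_runs,
    lre = sum(rlm * jl^2) / nr_runs,
    gln = sum(rowSums(rlm)^2) / nr_runs,
    rln = sum(colSums(rlm)^2) / nr_runs,
    rp = nr_runs / n_pixels)
}

# Galloway's 5 run-length statistics per direction (4 directions x 5 = 20);
# 16 gray levels, runs are maximal within the mask
rls_block <- function(patch, levels = 16L) {
  q <- quantize_patch(patch, levels)
  n_px <- sum(patch$mask)
  max_len <- max(dim(q))
  out <- numeric(0)
  for (th in glcm_directions())
    out <- c(out, galloway_stats(run_length_matrix(q, th, levels, max_len),
                                 n_px))
  unname(out)
}
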