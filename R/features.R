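#' Feature block layout
#'
#' The 812-dimensional feature vector is the concatenation of seven named
#' blocks in fixed order: uniform local binary pattern histograms (`lbp`,
#' 354), co-occurrence texture statistics (`sgld`, 312), run-length
#' statistics (`rls`, 20), gray-level difference statistics (`glds`, 96),
#' normalized radial length shape descriptors (`nrl`, 5), intensity moments
#' (`intensity`, 5) and region-based stellate spiculation measures
#' (`stellate`, 20).
#'
#' @return A data.frame with columns `block`, `offset` (0-based) and
#'   `length`; offsets are contiguous and non-overlapping.
#' @export
feature_block_index <- function() {
  len <- c(lbp = 354L, sgld = 312L, rls = 20L, glds = 96L,
           nrl = 5L, intensity = 5L, stellate = 20L)
  data.frame(block = names(len),
             offset = c(0L, cumsum(unname(len))[-length(len)]),
             length = unname(len), stringsAsFactors = FALSE)
}

#' Total feature dimension
#' @return 812, the sum of the block lengths.
#' @export
feature_dim <- function() sum(feature_block_index()$length)

feature_names <- function() {
  fb <- feature_block_index()
  unlist(lapply(seq_len(nrow(fb)), function(i)
    paste0(fb$block[i], ".", seq_len(fb$length[i]))), use.names = FALSE)
}

#' Compute one feature block
#'
#' @param patch An [roi_patch()].
#' @param block Block name, one of `lbp`, `sgld`, `rls`, `glds`, `nrl`,
#'   `intensity`, `stellate` (see [feature_block_index()]).
#' @return Numeric vector of the block's length.
#' @export
extract_block <- function(patch, block) {
  if (!inherits(patch, "roi_patch")) stopf("'patch' must be an roi_patch")
  fb <- feature_block_index()
  if (!is.character(block) || length(block) != 1L || !block %in% fb$block)
    stopf("unknown feature block '%s'", paste(block, collapse = ","))
  v <- switch(block,
              lbp = lbp_block(patch),
              sgld = sgld_block(patch),
              rls = rls_block(patch),
              glds = glds_block(patch),
              nrl = nrl_block(patch),
              intensity = intensity_block(patch),
              stellate = stellate_block(patch))
  v <- as.numeric(v)
  stopifnot(length(v) == fb$length[fb$block == block])
  v
}

#' Compute the full 812-dimensional feature vector
#'
#' Concatenates the seven feature blocks in the fixed order of
#' [feature_block_index()]. Deterministic: the same patch always yields a
#' bit-identical vector.
#'
#' @param patch An [roi_patch()].
#' @return Named numeric vector of length 812 (names `block.k`), with the
#'   block layout attached as attribute `block_index`.
#' @export
extract_features <- function(patch) {
  fb <- feature_block_index()
  v <- unlist(lapply(fb$block, function(b) extract_block(patch, b)),
              use.names = FALSE)
  names(v) <- feature_names()
  attr(v, "block_index") <- fb
  v
}

#' Extract features for a list of patches
#'
#' @param patches List of [roi_patch()] objects (e.g. from
#'   [gen_dataset()]).
#' @param id Optional ids, defaults to `roi1, roi2, ...`.
#' @return A [feature_set()] with one row per patch; labels and margins are
#'   taken from the patches.
#' @export
extract_feature_set <- function(patches, id = NULL) {
  if (!length(patches)) stopf("'patches' must be a non-empty list")
  x <- t(vapply(patches, function(p) as.numeric(extract_features(p)),
                numeric(feature_dim())))
  colnames(x) <- feature_names()
  feature_set(x,
              label = vapply(patches, function(p) p$label %||% "normal", ""),
              margin = vapply(patches, function(p) p$margin %||% "none", ""),
              id = id %||% paste0("roi", seq_along(patches)))
}
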