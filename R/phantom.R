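#' Construct a region-of-interest patch
#'
#' Bundles a grayscale pixel grid with its aligned binary segmentation mask
#' and optional class/margin labels. This is the unit of classification: all
#' feature extraction operates on the in-mask pixels (and narrow bands just
#' outside the mask).
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param mask Logical (or 0/1 numeric) matrix of the same shape; foreground
#'   is `TRUE`/`> 0`. Must contain at least 16 foreground pixels.
#' @param label Optional `"mass"` or `"normal"`.
#' @param margin Optional margin type (see [margin_types()]), or `"none"`.
#' @return An object of class `roi_patch`.
#' @export
roi_patch <- function(pixels, mask, label = NULL, margin = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stopf("'pixels' must be finite")
  if (is.null(dim(mask)) || !all(dim(mask) == dim(pixels)))
    stopf("'mask' shape must equal 'pixels' shape")
  mask <- matrix(as.logical(mask > 0), nrow(pixels), ncol(pixels))
  if (sum(mask) < 16L)
    stopf("'mask' must contain at least 16 foreground pixels, got %d", sum(mask))
  if (!is.null(label) && !label %in% c("mass", "normal"))
    stopf("'label' must be \"mass\" or \"normal\"")
  if (!is.null(margin) && !margin %in% c(margin_types(), "none", "all"))
    stopf("'margin' must be one of the margin types, \"all\" or \"none\"")
  structure(list(pixels = pixels, mask = mask, label = label, margin = margin),
            class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> %dx%d px, %d in mask, label=%s, margin=%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              x$label %||% "?", x$margin %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a phantom mass or normal-tissue patch
#'
#' Parameters of the phantom generator. Each margin type is rendered by one
#' controllable mechanism matched to its radiological description:
#' circumscribed masses are smooth radial blobs with a sharp edge; obscured
#' masses are the same blob alpha-blended into the background texture at
#' reduced contrast; micro-lobulated masses modulate the blob boundary with
#' a high-frequency, low-amplitude angular sinusoid; ill-defined masses have
#' a wide, blurred boundary; spiculated masses carry 6--14 thin radial
#' spikes. Normal patches are pure background texture with a pseudo-mask
#' over the central region so that the feature battery stays computable.
#'
#' @param margin_type One of [margin_types()] or `"normal"`.
#' @param image_size Pixels per side of the square patch (>= 32).
#' @param core_radius Radius of the mass core in pixels, in
#'   `[4, image_size/3]`.
#' @param contrast Peak mass-to-background intensity difference as a
#'   fraction of the dynamic range, in `(0, 1]`.
#' @param background_texture_scale Correlation length (pixels) of the
#'   parenchyma-like background texture.
#' @param seed Integer seed; phantoms are pure functions of their spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(margin_type, image_size = 96L, core_radius = 18,
                         contrast = 0.5, background_texture_scale = 6,
                         seed = 1L) {
  if (!is.character(margin_type) || length(margin_type) != 1L ||
      !margin_type %in% c(margin_types(), "normal"))
    stopf("'margin_type' must be one of %s or \"normal\"",
          paste(dQuote(margin_types(), '"'), collapse = ", "))
  check_number(image_size, "image_size", min = 32, integer = TRUE)
  check_number(core_radius, "core_radius", min = 4, max = image_size / 3)
  check_number(contrast, "contrast", min = 1e-12, max = 1)
  check_number(background_texture_scale, "background_texture_scale", min = 0.5)
  check_number(seed, "seed", integer = TRUE)
  structure(list(margin_type = margin_type,
                 image_size = as.integer(image_size),
                 core_radius = core_radius, contrast = contrast,
                 background_texture_scale = background_texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# band-limited correlated noise emulating parenchymal texture
phantom_background <- function(size, scale) {
  noise <- matrix(stats::rnorm(size * size), size, size)
  sm <- EBImage::gblur(noise, sigma = scale)
  sm <- sm / max(stats::sd(sm), 1e-12)
  0.35 + 0.08 * sm
}

smoothstep <- function(u) {
  t <- pmin(pmax(u, 0), 1)
  t * t * (3 - 2 * t)
}

#' Generate a phantom region-of-interest patch
#'
#' Renders the patch described by a [phantom_spec()]: correlated background
#' texture plus, for mass types, a central blob whose boundary follows the
#' margin-type mechanism. The returned mask is the rasterised blob (blob
#' plus spikes for spiculated masses); normal patches get a pseudo-mask over
#' the central blob-like region. Identical specs give bit-identical patches.
#'
#' @param spec A [phantom_spec()].
#' @return An [roi_patch()] with label `"mass"` (margin set) or `"normal"`
#'   (margin `"none"`).
#' @export
gen_roi <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  with_seed(spec$seed, gen_roi_impl(spec))
}

gen_roi_impl <- function(spec) {
  s <- spec$image_size
  R <- spec$core_radius
  bg <- phantom_background(s, spec$background_texture_scale)

  ctr <- (s + 1) / 2 + stats::runif(2, -1.5, 1.5)
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  dy <- rows - ctr[1]
  dx <- cols - ctr[2]
  dist <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)

  if (spec$margin_type == "normal") {
    ph <- stats::runif(1, 0, 2 * pi)
    rb <- R * (1 + 0.05 * sin(3 * theta + ph))
    mask <- dist <= rb
    return(roi_patch(pmin(pmax(bg, 0), 1), mask,
                     label = "normal", margin = "none"))
  }

  ph <- stats::runif(3, 0, 2 * pi)
  base <- R * (1 + 0.03 * sin(2 * theta + ph[1]) + 0.02 * sin(3 * theta + ph[2]))
  rb <- switch(spec$margin_type,
    circumscribed = base,
    obscured = base,
    ill_defined = base,
    spiculated = base,
    micro_lobulated = {
      k <- sample(8:14, 1)
      base * (1 + 0.08 * sin(k * theta + ph[3]))
    })

  # edge width (px) controls boundary sharpness per margin mechanism
  w <- switch(spec$margin_type,
    circumscribed = 1.5, micro_lobulated = 1.5, spiculated = 1.5,
    obscured = 2.5, ill_defined = 6)
  amp <- if (spec$margin_type == "obscured") 0.4 * spec$contrast else spec$contrast
  blob <- amp * smoothstep((rb - dist) / w + 0.5)
  mask <- dist <= rb

  if (spec$margin_type == "spiculated") {
    n_sp <- sample(6:14, 1)
    psi <- stats::runif(n_sp, 0, 2 * pi)
    len <- stats::runif(n_sp, 0.5, 1.2) * R
    for (j in seq_len(n_sp)) {
      a <- theta - psi[j]
      perp <- abs(dist * sin(a))
      along <- cos(a) > 0
      sp <- along & perp <= 1.8 & dist <= rb + len[j]
      taper <- pmax(0, 1 - pmax(dist - rb, 0) / (len[j] + 1e-9))
      blob <- pmax(blob, 0.8 * amp * sp * taper)
      mask <- mask | sp
    }
  }

  roi_patch(pmin(pmax(bg + blob, 0), 1), mask,
            label = "mass", margin = spec$margin_type)
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_mass_per_margin` phantom masses for each of the five margin
#' types plus `n_normal` normal-tissue patches, each rendered from a
#' deterministic per-patch seed derived from `seed`.
#'
#' @param n_mass_per_margin Non-negative count of masses per margin type.
#' @param n_normal Non-negative count of normal patches.
#' @param base_spec A [phantom_spec()] providing size/contrast/texture
#'   parameters (its `margin_type` and `seed` are overridden per patch).
#' @param seed Integer master seed.
#' @return A list of [roi_patch()] objects: masses first (margin types in
#'   canonical order), then normals.
#' @export
gen_dataset <- function(n_mass_per_margin, n_normal,
                        base_spec = phantom_spec("circumscribed"),
                        seed = 1L) {
  check_number(n_mass_per_margin, "n_mass_per_margin", min = 0, integer = TRUE)
  check_number(n_normal, "n_normal", min = 0, integer = TRUE)
  types <- c(rep(margin_types(), each = n_mass_per_margin),
             rep("normal", n_normal))
  seeds <- derive_seeds(seed, max(length(types), 1L))
  lapply(seq_along(types), function(i) {
    sp <- base_spec
    sp$margin_type <- types[i]
    sp$seed <- seeds[i]
    gen_roi(sp)
  })
}
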