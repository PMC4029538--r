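#' A labelled set of feature vectors
#'
#' Container used throughout the classification stages: a samples-by-features
#' numeric matrix plus per-sample class labels, margin annotations and ids.
#'
#' @param x Numeric matrix, one row per sample.
#' @param label Character vector in `{"mass", "normal"}`, one per row.
#' @param margin Optional margin annotation per row (`"none"` for normals).
#' @param id Optional unique sample ids; defaults to `s1, s2, ...`.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(x, label, margin = NULL, id = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x))) stopf("'x' must be finite numeric")
  n <- nrow(x)
  if (length(label) != n) stopf("'label' length must equal nrow(x)")
  if (!all(label %in% c("mass", "normal")))
    stopf("'label' entries must be \"mass\" or \"normal\"")
  if (is.null(margin)) margin <- ifelse(label == "mass", "none", "none")
  if (length(margin) != n) stopf("'margin' length must equal nrow(x)")
  if (!all(margin %in% c(margin_types(), "none", "all")))
    stopf("'margin' entries must be margin types, \"all\" or \"none\"")
  if (is.null(id)) id <- paste0("s", seq_len(n))
  if (anyDuplicated(id)) stopf("'id' must be unique")
  structure(list(x = x, label = as.character(label),
                 margin = as.character(margin), id = as.character(id)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d samples x %d features (%d mass, %d normal)\n",
              nrow(x$x), ncol(x$x), sum(x$label == "mass"),
              sum(x$label == "normal")))
  invisible(x)
}

#' Subset a feature set by row index
#' @param x A [feature_set()].
#' @param i Row indices (integer or logical).
#' @param ... Unused.
#' @return A [feature_set()] with the selected rows.
#' @export
`[.feature_set` <- function(x, i, ...) {
  feature_set(x$x[i, , drop = FALSE], x$label[i], x$margin[i], x$id[i])
}

#' Specify feature-space Gaussian clusters
#'
#' Direct feature-space stand-in for extracted mass/normal features: one
#' isotropic Gaussian cluster per margin type plus one for normal tissue.
#' By default the normal cluster sits at the origin and every margin mean
#' lies at distance `separation * margin_scale` from it, decomposed into a
#' dominant shared "mass-like" direction (80% of the separation, the same
#' for all margins -- masses of any margin share intensity and shape
#' character) and a smaller margin-specific component (60%, along a
#' distinct coordinate axis per margin -- the margin texture). A single
#' knob therefore controls mass-vs-normal separability while margins stay
#' mutually closer than either is to normal tissue. The default dimension
#' (200) keeps per-margin dictionaries undercomplete (atoms < dimension),
#' the regime the real 812-dimensional feature battery operates in.
#'
#' @param dimension Feature dimension (>= 2; >= 6 when default means are
#'   used).
#' @param n_mass_per_margin Samples drawn per margin type (>= 1).
#' @param n_normal Normal samples (>= 1).
#' @param separation Distance from each default margin mean to the normal
#'   mean, in units of `margin_scale`.
#' @param margin_means Optional 5 x `dimension` matrix of margin means
#'   (rows in canonical [margin_types()] order).
#' @param margin_scale Isotropic standard deviation of every margin cluster
#'   (> 0).
#' @param normal_mean Optional length-`dimension` normal-class mean.
#' @param normal_scale Standard deviation of the normal cluster (> 0).
#' @param seed Integer seed.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(dimension = 200L, n_mass_per_margin = 100L,
                         n_normal = 500L, separation = 6,
                         margin_means = NULL, margin_scale = 1,
                         normal_mean = NULL, normal_scale = 1, seed = 1L) {
  check_number(dimension, "dimension", min = 2, integer = TRUE)
  check_number(n_mass_per_margin, "n_mass_per_margin", min = 1, integer = TRUE)
  check_number(n_normal, "n_normal", min = 1, integer = TRUE)
  check_number(margin_scale, "margin_scale", min = 1e-12)
  check_number(normal_scale, "normal_scale", min = 1e-12)
  check_number(separation, "separation", min = 0)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(margin_means)) {
    if (dimension < 6)
      stopf("'dimension' must be >= 6 when default margin means are used")
    margin_means <- matrix(0, 5, dimension)
    for (t in 1:5) {
      margin_means[t, t] <- 0.6 * separation * margin_scale
      margin_means[t, dimension] <- 0.8 * separation * margin_scale
    }
  } else {
    margin_means <- as.matrix(margin_means)
    if (!all(dim(margin_means) == c(5, dimension)))
      stopf("'margin_means' must be a 5 x dimension matrix")
  }
  if (is.null(normal_mean)) normal_mean <- rep(0, dimension)
  if (length(normal_mean) != dimension)
    stopf("'normal_mean' must have length 'dimension'")
  structure(list(dimension = as.integer(dimension),
                 n_mass_per_margin = as.integer(n_mass_per_margin),
                 n_normal = as.integer(n_normal),
                 margin_means = margin_means, margin_scale = margin_scale,
                 normal_mean = as.numeric(normal_mean),
                 normal_scale = normal_scale, seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Draw feature-space clusters
#'
#' Samples the Gaussian clusters configured in a [cluster_spec()]:
#' `n_mass_per_margin` vectors per margin type and `n_normal` normal
#' vectors, labels attached. Deterministic given the spec.
#'
#' @param spec A [cluster_spec()].
#' @return A [feature_set()] (masses first, margin types in canonical
#'   order, then normals).
#' @export
gen_feature_clusters <- function(spec) {
  if (!inherits(spec, "cluster_spec")) stopf("'spec' must be a cluster_spec")
  d <- spec$dimension
  nm <- spec$n_mass_per_margin
  with_seed(spec$seed, {
    mass <- do.call(rbind, lapply(1:5, function(t) {
      matrix(stats::rnorm(nm * d, sd = spec$margin_scale), nm, d,
             byrow = TRUE) +
        matrix(spec$margin_means[t, ], nm, d, byrow = TRUE)
    }))
    norm <- matrix(stats::rnorm(spec$n_normal * d, sd = spec$normal_scale),
                   spec$n_normal, d, byrow = TRUE) +
      matrix(spec$normal_mean, spec$n_normal, d, byrow = TRUE)
    feature_set(rbind(mass, norm),
                label = c(rep("mass", 5L * nm), rep("normal", spec$n_normal)),
                margin = c(rep(margin_types(), each = nm),
                           rep("none", spec$n_normal)))
  })
}
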