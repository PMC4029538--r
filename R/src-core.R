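#' Sparse coding solver configuration
#'
#' The l1 coding problem is solved in Lagrangian form,
#' `min 0.5*||Ax - y||^2 + lambda*||x||_1`, by accelerated proximal
#' gradient (FISTA) with soft-thresholding. When `lambda` is `NULL` it is
#' set per query to `lambda_factor * max|A'y|`, which is self-scaling: the
#' threshold at which the all-zero solution becomes optimal is
#' `max|A'y|`, so `lambda_factor` expresses the penalty as a fraction of
#' that critical value. The default 0.1 keeps the codes genuinely sparse
#' (the point of the method) and the iteration well conditioned; much
#' smaller values drift toward a dense least-squares fit.
#'
#' @param lambda Fixed l1 weight (> 0), or `NULL` for the self-scaling
#'   default.
#' @param lambda_factor Fraction of `max|A'y|` used when `lambda` is
#'   `NULL`.
#' @param max_iter Maximum FISTA iterations (>= 1).
#' @param tol Relative objective-change convergence tolerance.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(lambda = NULL, lambda_factor = 0.1,
                          max_iter = 1000L, tol = 1e-6) {
  if (!is.null(lambda)) check_number(lambda, "lambda", min = 1e-300)
  check_number(lambda_factor, "lambda_factor", min = 0)
  check_number(max_iter, "max_iter", min = 1, integer = TRUE)
  check_number(tol, "tol", min = 0)
  structure(list(lambda = lambda, lambda_factor = lambda_factor,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "solver_config")
}

new_dictionary <- function(atoms, atom_class, center, scale) {
  atom_class <- as.character(atom_class)
  if (ncol(atoms) != length(atom_class))
    stopf("atom_class length must equal number of atoms")
  structure(list(atoms = atoms, atom_class = atom_class,
                 center = center, scale = scale,
                 n_mass = sum(atom_class == "mass"),
                 n_normal = sum(atom_class == "normal"),
                 lipschitz = spectral_norm_sq(atoms)),
            class = "src_dictionary")
}

#' @export
print.src_dictionary <- function(x, ...) {
  cat(sprintf("<src_dictionary> %d x %d (%d mass + %d normal atoms)\n",
              nrow(x$atoms), ncol(x$atoms), x$n_mass, x$n_normal))
  invisible(x)
}

# per-feature scale = sd over the normal-class training samples (the
# reference population); falls back to the overall sd for degenerate
# features and to 1 where even that is zero
feature_scale_stats <- function(x, label) {
  s <- apply(x[label == "normal", , drop = FALSE], 2, stats::sd)
  bad <- !is.finite(s) | s < 1e-12
  if (any(bad)) {
    s_all <- apply(x[, bad, drop = FALSE], 2, stats::sd)
    s[bad] <- ifelse(is.finite(s_all) & s_all >= 1e-12, s_all, 1)
  }
  s
}

unit_columns <- function(m) {
  nrm <- sqrt(colSums(m^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    # degenerate atom (sample equal to the training mean): replace by the
    # uniform unit vector so the unit-norm invariant holds
    m[, zero] <- 1 / sqrt(nrow(m))
    nrm[zero] <- 1
  }
  sweep(m, 2, nrm, "/")
}

#' Assemble an SRC dictionary from training samples
#'
#' Training feature vectors become dictionary atoms: features are divided
#' by their training-set standard deviation (statistics retained for
#' test-time normalization), samples become columns (mass class first,
#' then normal), and every column is scaled to unit l2 norm.
#'
#' @param features A [feature_set()] or a samples-by-features matrix.
#' @param label Class labels when `features` is a matrix.
#' @return An `src_dictionary` with fields `atoms` (d x n), `atom_class`,
#'   and the stored `center`/`scale` statistics.
#' @export
build_dictionary <- function(features, label = NULL) {
  if (inherits(features, "feature_set")) {
    x <- features$x; label <- features$label
  } else {
    x <- as.matrix(features)
  }
  if (is.null(label) || length(label) != nrow(x))
    stopf("'label' must give one class per sample")
  if (sum(label == "mass") < 1L || sum(label == "normal") < 1L)
    stopf("both classes must be present (got %d mass, %d normal)",
          sum(label == "mass"), sum(label == "normal"))
  # scale-only standardization: dividing by the normal-class sd equalises
  # the wildly different block scales against the reference-tissue
  # variability without shrinking the case-control contrast, and keeping
  # the origin fixed avoids mean-centering's sign-flip artefact (centred
  # normal atoms reconstruct mass queries through negative coefficients,
  # destroying the residual contrast)
  center <- rep(0, ncol(x))
  scale <- feature_scale_stats(x, label)
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  ord <- order(factor(label, levels = c("mass", "normal")))
  new_dictionary(unit_columns(t(xs[ord, , drop = FALSE])),
                 label[ord], center, scale)
}

# apply the dictionary's stored feature statistics to raw query vectors;
# y may be a vector or a samples-in-columns matrix
normalize_query <- function(D, y) {
  y <- as.matrix(y)
  if (nrow(y) != nrow(D$atoms))
    stopf("query dimension %d does not match dictionary dimension %d",
          nrow(y), nrow(D$atoms))
  (y - D$center) / D$scale
}

spectral_norm_sq <- function(A) {
  # largest eigenvalue of A'A (or AA', whichever is smaller) via eigen
  G <- if (ncol(A) <= nrow(A)) crossprod(A) else tcrossprod(A)
  max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# Batched FISTA on 0.5||Ax - y||^2 + lambda||x||_1, columns of y solved
# jointly (the objective is separable across columns; lambda is
# per-column). Convergence is tracked per column: a query whose relative
# objective change drops below tol is frozen and leaves the active set,
# so a few slow queries do not force full-batch iterations for all. The
# iteration itself runs in compiled code (src/solvers.cpp).
fista_lasso <- function(A, y, lambda, max_iter, tol, L = NULL) {
  L <- max(L %||% spectral_norm_sq(A), 1e-12)
  lam <- rep_len(lambda, ncol(y))
  fit <- fista_lasso_cpp(A, y, lam, as.integer(max_iter), tol, L)
  list(x = fit$x, iterations = fit$iterations, converged = fit$converged)
}

#' Solve the l1 sparse coding problem against a dictionary
#'
#' Codes one or more query vectors as sparse linear combinations of the
#' dictionary atoms by minimizing
#' `0.5*||Ax - y||^2 + lambda*||x||_1` with FISTA. Queries are normalized
#' with the dictionary's stored feature statistics before coding. On
#' non-convergence within `max_iter` the best iterate is returned with
#' `converged = FALSE` rather than an error.
#'
#' @param D An `src_dictionary`.
#' @param y Raw query vector (length d) or d x m matrix of queries in
#'   columns.
#' @param cfg A [solver_config()].
#' @return A `sparse_solution`: `coefficients` (n x m), `lambda` (per
#'   query), `iterations`, `residual` (l2 per query), `converged`.
#' @export
sparse_code <- function(D, y, cfg = solver_config()) {
  if (!inherits(D, "src_dictionary")) stopf("'D' must be an src_dictionary")
  ys <- normalize_query(D, y)
  lam <- cfg$lambda %||%
    pmax(cfg$lambda_factor * apply(abs(crossprod(D$atoms, ys)), 2, max), 0)
  fit <- fista_lasso(D$atoms, ys, lam, cfg$max_iter, cfg$tol, L = D$lipschitz)
  res <- sqrt(colSums((D$atoms %*% fit$x - ys)^2))
  structure(list(coefficients = fit$x, lambda = lam,
                 iterations = fit$iterations, residual = res,
                 converged = fit$converged),
            class = "sparse_solution")
}

#' Class-restricted reconstruction residual
#'
#' Reconstruction error of a query using only the coefficients of one
#' class block: `||y - A * delta_class(x)||_2`, where `delta_class` zeroes
#' all coefficients outside the class.
#'
#' @param D An `src_dictionary`.
#' @param y Raw query vector or matrix (columns).
#' @param sol A `sparse_solution` from [sparse_code()].
#' @param class `"mass"` or `"normal"`.
#' @return Numeric residual (one per query column).
#' @export
class_residual <- function(D, y, sol, class) {
  if (!class %in% c("mass", "normal")) stopf("'class' must be mass or normal")
  ys <- normalize_query(D, y)
  x <- as.matrix(sol$coefficients)
  x[D$atom_class != class, ] <- 0
  sqrt(colSums((ys - D$atoms %*% x)^2))
}

#' Classify a query with a single dictionary
#'
#' Sparse-codes the query and assigns it to the class whose atoms give the
#' smaller class-restricted residual; ties go to `"normal"`.
#'
#' @inheritParams sparse_code
#' @return `"mass"` or `"normal"` (vector for matrix input).
#' @export
classify_single <- function(D, y, cfg = solver_config()) {
  sol <- sparse_code(D, y, cfg)
  rm <- class_residual(D, y, sol, "mass")
  rn <- class_residual(D, y, sol, "normal")
  ifelse(rm < rn, "mass", "normal")
}
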