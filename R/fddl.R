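#' Fisher discrimination dictionary learning parameters
#'
#' @param n_atoms Atoms per class sub-dictionary; `NULL` means
#'   `min(n_class, 40)` per class.
#' @param lambda1 l1 sparsity weight on the codes (>= 0).
#' @param lambda2 Fisher discrimination weight (>= 0).
#' @param eta Elastic weight on `||X||_F^2` inside the Fisher term (> 0),
#'   keeping that term convex.
#' @param max_iter Maximum outer (coding + dictionary) iterations.
#' @param tol Relative objective-decrease stopping tolerance.
#' @return An object of class `fddl_params`.
#' @export
fddl_params <- function(n_atoms = NULL, lambda1 = 0.01, lambda2 = 0.01,
                        eta = 1, max_iter = 30L, tol = 1e-4) {
  if (!is.null(n_atoms)) check_number(n_atoms, "n_atoms", min = 1, integer = TRUE)
  check_number(lambda1, "lambda1", min = 0)
  check_number(lambda2, "lambda2", min = 0)
  check_number(eta, "eta", min = 1e-12)
  check_number(max_iter, "max_iter", min = 1, integer = TRUE)
  check_number(tol, "tol", min = 0)
  if (!is.null(n_atoms)) n_atoms <- as.integer(n_atoms)
  structure(list(n_atoms = n_atoms, lambda1 = lambda1, lambda2 = lambda2,
                 eta = eta, max_iter = as.integer(max_iter), tol = tol),
            class = "fddl_params")
}

# row blocks of the code matrix belonging to each class sub-dictionary
fddl_blocks <- function(m_per_class) {
  ends <- cumsum(m_per_class)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(m_per_class), function(i) starts[i]:ends[i])
}

# Fisher scatter penalty: tr S_W - tr S_B + eta*||X||_F^2, where scatter
# is computed over code columns grouped by class
fisher_penalty <- function(X_list, eta) {
  ns <- vapply(X_list, ncol, integer(1))
  means <- lapply(X_list, rowMeans)
  gmean <- Reduce(`+`, Map(`*`, means, ns)) / sum(ns)
  sw <- sum(vapply(seq_along(X_list), function(i)
    sum((X_list[[i]] - means[[i]])^2), numeric(1)))
  sb <- sum(vapply(seq_along(X_list), function(i)
    ns[i] * sum((means[[i]] - gmean)^2), numeric(1)))
  fro <- sum(vapply(X_list, function(x) sum(x^2), numeric(1)))
  sw - sb + eta * fro
}

#' Fisher discrimination dictionary learning objective
#'
#' The learned dictionary `D = [D_1, D_2]` (class sub-dictionaries) and
#' codes `X = [X_1, X_2]` (columns grouped by the class of the coded
#' sample) are scored by a discriminative fidelity term -- each class must
#' be represented by the whole dictionary and by its own sub-dictionary,
#' while other classes' sub-dictionaries should contribute nothing -- plus
#' an l1 sparsity penalty and a Fisher term that shrinks within-class
#' scatter of the codes while growing between-class scatter:
#' \deqn{\sum_i \{ \|A_i - D X_i\|_F^2 + \|A_i - D_i X_i^i\|_F^2 +
#'   \sum_{j \ne i} \|D_j X_i^j\|_F^2 \} + \lambda_1 \|X\|_1 +
#'   \lambda_2 ( \mathrm{tr}\,S_W - \mathrm{tr}\,S_B + \eta \|X\|_F^2 )}
#'
#' @param D Dictionary matrix (d x m), class sub-dictionaries side by side.
#' @param X_list List of per-class code matrices (m x n_i).
#' @param data_list List of per-class data matrices (d x n_i).
#' @param m_per_class Integer vector of atoms per class sub-dictionary.
#' @param params An [fddl_params()].
#' @return The objective value (a single number).
#' @export
fddl_objective <- function(D, X_list, data_list, m_per_class, params) {
  if (sum(m_per_class) != ncol(D))
    stopf("'m_per_class' must sum to ncol(D)")
  if (length(X_list) != length(data_list))
    stopf("'X_list' and 'data_list' must have the same length")
  blocks <- fddl_blocks(m_per_class)
  fid <- 0
  for (i in seq_along(data_list)) {
    Ai <- data_list[[i]]; Xi <- X_list[[i]]
    if (nrow(Xi) != ncol(D) || ncol(Xi) != ncol(Ai) || nrow(Ai) != nrow(D))
      stopf("shape mismatch between D, X_list and data_list for class %d", i)
    fid <- fid + sum((Ai - D %*% Xi)^2)
    for (j in seq_along(blocks)) {
      Dj <- D[, blocks[[j]], drop = FALSE]
      Xij <- Xi[blocks[[j]], , drop = FALSE]
      fid <- fid + if (j == i) sum((Ai - Dj %*% Xij)^2) else sum((Dj %*% Xij)^2)
    }
  }
  l1 <- sum(vapply(X_list, function(x) sum(abs(x)), numeric(1)))
  fid + params$lambda1 * l1 + params$lambda2 * fisher_penalty(X_list, params$eta)
}

# class-i coding subproblem in precomputed Gram form: smooth fidelity,
# its gradient, and the Fisher coupling to the (fixed) other classes'
# code means; constant terms of the fixed classes are dropped, which is
# safe because monotonicity is checked on differences only
fddl_code_ctx <- function(D, i, data_list, X_list, blocks, params) {
  Ai <- data_list[[i]]
  G0 <- crossprod(D)
  DtAi <- crossprod(D, Ai)
  cAi <- sum(Ai^2)
  sub <- lapply(blocks, function(b) G0[b, b, drop = FALSE])
  ns <- vapply(X_list, ncol, integer(1))
  fixed_means <- lapply(X_list, rowMeans)
  list(i = i, G0 = G0, DtAi = DtAi, cAi = cAi, sub = sub, blocks = blocks,
       ns = ns, fixed_means = fixed_means, params = params,
       lip = 4 * max(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) +
         params$lambda2 * (4 + 2 * params$eta))
}

fddl_code_obj <- function(ctx, Xi) {
  p <- ctx$params
  f <- ctx$cAi - 2 * sum(ctx$DtAi * Xi) + sum(Xi * (ctx$G0 %*% Xi))
  for (j in seq_along(ctx$blocks)) {
    b <- ctx$blocks[[j]]
    Xb <- Xi[b, , drop = FALSE]
    q <- sum(Xb * (ctx$sub[[j]] %*% Xb))
    f <- f + if (j == ctx$i)
      ctx$cAi - 2 * sum(ctx$DtAi[b, , drop = FALSE] * Xb) + q else q
  }
  if (p$lambda2 > 0) {
    means <- ctx$fixed_means
    means[[ctx$i]] <- rowMeans(Xi)
    gmean <- Reduce(`+`, Map(`*`, means, ctx$ns)) / sum(ctx$ns)
    sw_i <- sum((Xi - means[[ctx$i]])^2)
    sb <- sum(vapply(seq_along(means), function(c)
      ctx$ns[c] * sum((means[[c]] - gmean)^2), numeric(1)))
    f <- f + p$lambda2 * (sw_i - sb + p$eta * sum(Xi^2))
  }
  f + p$lambda1 * sum(abs(Xi))
}

# monotone proximal-gradient update of class i's codes: fixed step 1/L
# with L a Lipschitz bound of the smooth part (descent guaranteed by
# majorization); the whole step is reverted if rounding ever broke
# monotonicity. The inner iteration runs in compiled code.
fddl_code_step <- function(D, i, data_list, X_list, blocks, params,
                           inner_iter = 15L) {
  ctx <- fddl_code_ctx(D, i, data_list, X_list, blocks, params)
  Xi <- X_list[[i]]
  f0 <- fddl_code_obj(ctx, Xi)
  t <- 1 / max(ctx$lip, 1e-12)
  Xn <- fddl_code_ista_cpp(ctx$G0, ctx$DtAi, ctx$sub,
                           lapply(blocks, function(b) b - 1L), i - 1L,
                           do.call(cbind, ctx$fixed_means),
                           as.numeric(ctx$ns), params$lambda1,
                           params$lambda2, params$eta, t,
                           as.integer(inner_iter), Xi)
  if (fddl_code_obj(ctx, Xn) <= f0) Xn else Xi
}

# exact unit-norm atom updates for class j's sub-dictionary: stacking the
# data-fidelity targets for all classes, each atom's constrained least
# squares minimizer is E*c / ||E*c||
fddl_dict_step <- function(D, j, data_list, X_list, blocks, params) {
  C <- length(data_list)
  Ms <- vector("list", 2L * C)
  Ns <- vector("list", 2L * C)
  for (i in seq_len(C)) {
    Ri <- data_list[[i]] - D %*% X_list[[i]] +
      D[, blocks[[j]], drop = FALSE] %*% X_list[[i]][blocks[[j]], , drop = FALSE]
    Ms[[i]] <- Ri
    Ns[[i]] <- X_list[[i]][blocks[[j]], , drop = FALSE]
    Ms[[C + i]] <- if (i == j) data_list[[i]] else
      matrix(0, nrow(D), ncol(data_list[[i]]))
    Ns[[C + i]] <- X_list[[i]][blocks[[j]], , drop = FALSE]
  }
  M <- do.call(cbind, Ms)
  N <- do.call(cbind, Ns)
  Dj <- D[, blocks[[j]], drop = FALSE]
  # E_k c_k = (M - sum_{l != k} d_l n_l') n_k = P[,k] - Dj Q[,k] + d_k Q[k,k]
  # with P = M N' and Q = N N' fixed across the atom sweep
  P <- M %*% t(N)
  Q <- tcrossprod(N)
  for (k in seq_len(ncol(Dj))) {
    Ek_c <- P[, k] - as.numeric(Dj %*% Q[, k]) + Dj[, k] * Q[k, k]
    nrm <- sqrt(sum(Ek_c^2))
    if (nrm > 1e-12) Dj[, k] <- Ek_c / nrm
  }
  D[, blocks[[j]]] <- Dj
  D
}

#' Learn a class-structured dictionary by FDDL
#'
#' Alternates (a) class-wise sparse coding of the training data with the
#' dictionary fixed and (b) atom-wise unit-norm dictionary updates with the
#' codes fixed, each step monotone in the joint objective
#' ([fddl_objective()]). Sub-dictionaries are initialized from seeded
#' random subsets of each class's samples.
#'
#' @param data_list List of per-class data matrices (d x n_i), features in
#'   rows; order defines the class blocks (mass first, normal second in
#'   this package).
#' @param params An [fddl_params()].
#' @param seed Integer seed for the initialization.
#' @return A `fddl_dictionary`: `D` (d x m), `m_per_class`, `X_list`
#'   (final codes), `objective` (final value), `trace` (objective after
#'   every outer iteration, non-increasing), `params`, `converged`.
#' @export
fddl_learn <- function(data_list, params = fddl_params(), seed = 1L) {
  if (!is.list(data_list) || length(data_list) < 1L)
    stopf("'data_list' must be a non-empty list of class matrices")
  ns <- vapply(data_list, ncol, integer(1))
  if (any(ns == 0L)) stopf("every class must have at least one sample")
  m_per_class <- vapply(ns, function(n)
    as.integer(min(n, params$n_atoms %||% min(n, 40L))), integer(1))
  if (!is.null(params$n_atoms) && any(params$n_atoms > ns))
    warning("fewer samples than requested atoms in a class; using all samples",
            call. = FALSE)
  blocks <- fddl_blocks(m_per_class)

  D <- with_seed(seed, {
    do.call(cbind, lapply(seq_along(data_list), function(i) {
      idx <- sample(ns[i], m_per_class[i])
      unit_columns(data_list[[i]][, idx, drop = FALSE])
    }))
  })
  X_list <- lapply(ns, function(n) matrix(0, sum(m_per_class), n))

  trace <- numeric(0)
  obj <- fddl_objective(D, X_list, data_list, m_per_class, params)
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    for (i in seq_along(data_list))
      X_list[[i]] <- fddl_code_step(D, i, data_list, X_list, blocks, params)
    for (j in seq_along(blocks))
      D <- fddl_dict_step(D, j, data_list, X_list, blocks, params)
    new_obj <- fddl_objective(D, X_list, data_list, m_per_class, params)
    trace <- c(trace, new_obj)
    if ((obj - new_obj) <= params$tol * max(abs(obj), 1e-12)) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  structure(list(D = D, m_per_class = m_per_class, X_list = X_list,
                 objective = obj, trace = trace, params = params,
                 seed = as.integer(seed), converged = converged),
            class = "fddl_dictionary")
}

#' @export
print.fddl_dictionary <- function(x, ...) {
  cat(sprintf("<fddl_dictionary> %d x %d (%s atoms/class), objective %.6g after %d iterations\n",
              nrow(x$D), ncol(x$D), paste(x$m_per_class, collapse = "+"),
              x$objective, length(x$trace)))
  invisible(x)
}
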