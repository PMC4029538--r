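test_that("dictionary assembly, ordering and normalization", {
  set.seed(1)
  x <- matrix(runif(8 * 10, 1, 2), 8, 10)
  lab <- c("normal", "mass", "normal", "mass", "mass",
           "normal", "normal", "normal")
  D <- build_dictionary(x, lab)
  expect_equal(dim(D$atoms), c(10, 8))
  expect_equal(D$atom_class, c(rep("mass", 3), rep("normal", 5)))
  expect_equal(sqrt(colSums(D$atoms^2)), rep(1, 8), tolerance = 1e-12)

  # duplicated training sample => duplicated atom
  x2 <- rbind(x, x[2, ])
  D2 <- build_dictionary(x2, c(lab, "mass"))
  expect_equal(D2$n_mass, 4)
  expect_equal(sum(duplicated(t(D2$atoms))), 1)

  expect_error(build_dictionary(x, rep("mass", 8)), "both classes")
})

test_that("sparse coding recovers an identity atom and maps zero to zero", {
  # orthogonal dictionary: atoms are coordinate directions
  D <- mammosrc:::new_dictionary(diag(6), c(rep("mass", 3), rep("normal", 3)),
                                 rep(0, 6), rep(1, 6))
  y <- c(0, 0, 1, 0, 0, 0)  # equals mass atom 3
  sol <- sparse_code(D, y, solver_config(lambda_factor = 0.05))
  expect_equal(which(abs(sol$coefficients) > 1e-9), 3L)
  expect_lte(sol$residual, 0.05 + 1e-9)  # soft-threshold shrinkage bound

  sol0 <- sparse_code(D, rep(0, 6))
  expect_equal(as.numeric(sol0$coefficients), rep(0, 6))
  expect_equal(as.numeric(sol0$residual), 0)
})

test_that("the l1 objective matches the glmnet oracle on small instances", {
  skip_if_not_installed("glmnet")
  for (s in 1:10) {
    set.seed(300 + s)
    d <- sample(3:8, 1); n <- sample(4:12, 1)
    A <- matrix(rnorm(d * n), d)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    y <- rnorm(d)
    lam <- 0.1 * max(abs(crossprod(A, y)))
    D <- mammosrc:::new_dictionary(A, rep(c("mass", "normal"),
                                          length.out = n),
                                   rep(0, d), rep(1, d))
    sol <- sparse_code(D, y, solver_config(lambda = lam, tol = 1e-12,
                                           max_iter = 20000))
    obj_pkg <- lasso_objective(A, as.numeric(sol$coefficients), y, lam)
    obj_ora <- lasso_objective(A, glmnet_lasso_oracle(A, y, lam), y, lam)
    expect_lt(abs(obj_pkg - obj_ora), 1e-4)
  }
})

test_that("class residuals obey their bounds and hand computations", {
  set.seed(7)
  A <- qr.Q(qr(matrix(rnorm(36), 6)))  # orthonormal atoms
  D <- mammosrc:::new_dictionary(A, c(rep("mass", 3), rep("normal", 3)),
                                 rep(0, 6), rep(1, 6))
  y <- rnorm(6)
  sol <- sparse_code(D, y)
  for (cl in c("mass", "normal")) {
    r <- class_residual(D, y, sol, cl)
    expect_gte(r, 0)
    xm <- as.numeric(sol$coefficients)
    xm[D$atom_class != cl] <- 0
    expect_equal(r, sqrt(sum((y - A %*% xm)^2)))  # direct matrix-vector
    expect_lte(r, sqrt(sum(y^2)) + sqrt(sum((A %*% xm)^2)) + 1e-12)
  }
  # empty selection reduces to ||y||
  sol0 <- list(coefficients = rep(0, 6))
  expect_equal(class_residual(D, y, sol0, "mass"), sqrt(sum(y^2)))

  # exact reconstruction from mass atoms only
  ym <- A[, 1:3] %*% c(1, -2, 0.5)
  solm <- list(coefficients = c(1, -2, 0.5, 0, 0, 0))
  expect_equal(class_residual(D, ym, solm, "mass"), 0)
})

test_that("single-dictionary classification matches the subspace oracle", {
  # two clusters 10 sigma apart; oracle = least squares onto each class
  # (atoms per class < dimension so the class subspaces are proper)
  tr <- two_cluster_set(8, 20, 10, seed = 41)
  te <- two_cluster_set(25, 20, 10, seed = 42)
  D <- build_dictionary(tr)
  pred <- classify_single(D, t(te$x))
  ys <- mammosrc:::normalize_query(D, t(te$x))
  Am <- D$atoms[, D$atom_class == "mass"]
  An <- D$atoms[, D$atom_class == "normal"]
  rss <- function(B, y) sum(stats::lsfit(B, y, intercept = FALSE)$residuals^2)
  oracle <- apply(ys, 2, function(y)
    if (rss(Am, y) < rss(An, y)) "mass" else "normal")
  expect_equal(mean(pred == oracle), 1)
})

test_that("residual ties classify as normal", {
  D <- mammosrc:::new_dictionary(diag(4), c("mass", "mass", "normal", "normal"),
                                 rep(0, 4), rep(1, 4))
  expect_equal(classify_single(D, rep(0, 4)), "normal")
})

test_that("solution sparsity does not decrease as lambda grows", {
  set.seed(17)
  A <- matrix(rnorm(20 * 40), 20)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  D <- mammosrc:::new_dictionary(A, rep(c("mass", "normal"), each = 20),
                                 rep(0, 20), rep(1, 20))
  Y <- matrix(rnorm(20 * 10), 20)
  nnz <- sapply(c(0.01, 0.1, 0.3, 0.6), function(lf) {
    sol <- sparse_code(D, Y, solver_config(lambda_factor = lf))
    mean(colSums(abs(sol$coefficients) > 1e-8))
  })
  expect_true(all(diff(nnz) <= 0))
})
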