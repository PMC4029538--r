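small_margin_set <- function(seed, n_per_margin = 8, n_normal = 40, d = 30) {
  gen_feature_clusters(cluster_spec(dimension = d,
                                    n_mass_per_margin = n_per_margin,
                                    n_normal = n_normal, seed = seed))
}

test_that("one dictionary is built per margin type present, balanced", {
  fs <- small_margin_set(1)
  keep <- fs$margin %in% c("circumscribed", "obscured", "spiculated") |
    fs$label == "normal"
  tr <- fs[keep]
  expect_warning(m <- build_margin_model(tr, learn = FALSE, seed = 3),
                 "micro_lobulated")
  expect_equal(length(m$dictionaries), 3)
  expect_setequal(m$margins, c("circumscribed", "obscured", "spiculated"))
  for (mt in m$margins) {
    D <- m$dictionaries[[mt]]
    expect_equal(D$n_mass, 8)       # all masses of the margin
    expect_equal(D$n_normal, 8)     # balanced negative sample
  }
  expect_error(build_margin_model(fs[fs$label == "normal"]), "no mass samples")
})

test_that("negative sampling is seeded and reproducible", {
  fs <- small_margin_set(2)
  m1 <- build_margin_model(fs, learn = FALSE, seed = 11)
  m2 <- build_margin_model(fs, learn = FALSE, seed = 11)
  m3 <- build_margin_model(fs, learn = FALSE, seed = 12)
  expect_identical(m1$sampled_negatives, m2$sampled_negatives)
  expect_false(identical(m1$sampled_negatives, m3$sampled_negatives))
  expect_identical(m1$dictionaries[[1]]$atoms, m2$dictionaries[[1]]$atoms)
})

test_that("with one dictionary, fusion reduces to plain class residuals", {
  tr <- two_cluster_set(12, 20, 6, seed = 31)
  m <- build_single_model(tr, seed = 1)
  te <- two_cluster_set(5, 20, 6, seed = 32)
  fr <- fused_residuals(m, te)

  D <- build_dictionary(tr)
  sol <- sparse_code(D, t(te$x), m$solver)
  expect_equal(fr$res_mass, class_residual(D, t(te$x), sol, "mass"))
  expect_equal(fr$res_normal, class_residual(D, t(te$x), sol, "normal"))
})

test_that("fused residuals are additive over dictionaries", {
  fs <- small_margin_set(3)
  m <- build_margin_model(fs, learn = FALSE, seed = 5)
  te <- small_margin_set(99, n_per_margin = 2, n_normal = 5)
  fr <- fused_residuals(m, te)
  rm_sum <- rn_sum <- 0
  for (mt in m$margins) {
    mt_model <- m
    mt_model$dictionaries <- m$dictionaries[mt]
    mt_model$margins <- mt
    fr1 <- fused_residuals(mt_model, te)
    rm_sum <- rm_sum + fr1$res_mass
    rn_sum <- rn_sum + fr1$res_normal
  }
  expect_equal(fr$res_mass, rm_sum, tolerance = 1e-10)
  expect_equal(fr$res_normal, rn_sum, tolerance = 1e-10)

  # and equal hand-summed per-dictionary class residuals (T = 2 sub-model)
  m2 <- m; m2$dictionaries <- m$dictionaries[1:2]; m2$margins <- m$margins[1:2]
  fr2 <- fused_residuals(m2, te)
  by_hand_m <- by_hand_n <- 0
  for (mt in m2$margins) {
    D <- m2$dictionaries[[mt]]
    sol <- sparse_code(D, t(te$x), m2$solver)
    by_hand_m <- by_hand_m + class_residual(D, t(te$x), sol, "mass")
    by_hand_n <- by_hand_n + class_residual(D, t(te$x), sol, "normal")
  }
  expect_equal(fr2$res_mass, by_hand_m)
  expect_equal(fr2$res_normal, by_hand_n)
})

test_that("classification fills its contract: argmin, tie, confidence sign", {
  fs <- small_margin_set(4)
  m <- build_margin_model(fs, learn = FALSE, seed = 2)

  # a zero query has zero residuals everywhere: tie => normal, confidence 0
  res0 <- classify(m, rep(0, 30))
  expect_equal(res0$predicted, "normal")
  expect_equal(res0$confidence, 0)

  te <- small_margin_set(77, n_per_margin = 4, n_normal = 20)
  res <- classify(m, te)
  expect_equal(res$predicted, ifelse(res$confidence > 0, "mass", "normal"))
  expect_equal(res$confidence, res$res_normal - res$res_mass)
  expect_true(all(res$res_mass >= 0 & res$res_normal >= 0))
  expect_equal(res$id, te$id)
})

test_that("a query spanned by mass atoms in every dictionary has ~zero mass residual", {
  fs <- small_margin_set(5)
  m <- build_margin_model(fs, learn = FALSE, seed = 2,
                          solver = solver_config(lambda = 1e-10,
                                                 max_iter = 5000,
                                                 tol = 1e-12))
  # a scaled common mass atom: present (up to scale) in every dictionary?
  # use a query equal to one circumscribed training mass; it is an atom of
  # the circumscribed dictionary only, so check that dictionary alone
  q <- fs$x[which(fs$margin == "circumscribed")[1], ]
  D <- m$dictionaries[["circumscribed"]]
  sol <- sparse_code(D, q, m$solver)
  expect_lt(class_residual(D, q, sol, "mass") /
              sqrt(sum(mammosrc:::normalize_query(D, q)^2)), 1e-4)
})

test_that("margin-specific fusion is not worse than a single dictionary on average", {
  acc_m <- acc_s <- numeric(10)
  for (s in 1:10) {
    tr <- gen_feature_clusters(cluster_spec(n_mass_per_margin = 20,
                                            n_normal = 100, seed = 400 + s))
    te <- gen_feature_clusters(cluster_spec(n_mass_per_margin = 20,
                                            n_normal = 100, seed = 500 + s))
    mm <- build_margin_model(tr, seed = s)
    sm <- build_single_model(tr, seed = s)
    acc_m[s] <- mean(classify(mm, te)$predicted == te$label)
    acc_s[s] <- mean(classify(sm, te)$predicted == te$label)
  }
  expect_gte(mean(acc_m), mean(acc_s))
})
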