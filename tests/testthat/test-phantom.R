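test_that("phantom generation is a pure function of its spec", {
  for (mt in c("circumscribed", "spiculated", "normal")) {
    a <- gen_roi(phantom_spec(mt, seed = 7))
    b <- gen_roi(phantom_spec(mt, seed = 7))
    expect_identical(a$pixels, b$pixels)
    expect_identical(a$mask, b$mask)
    c <- gen_roi(phantom_spec(mt, seed = 8))
    expect_false(identical(a$pixels, c$pixels))
  }
})

test_that("invalid phantom specs are rejected with the field named", {
  expect_error(phantom_spec("circumscribed", core_radius = 96, image_size = 96),
               "core_radius")
  expect_error(phantom_spec("circumscribed", contrast = 0), "contrast")
  expect_error(phantom_spec("circumscribed", contrast = 1.5), "contrast")
  expect_error(phantom_spec("circumscribed", image_size = 16), "image_size")
  expect_error(phantom_spec("lobular"), "margin_type")
})

test_that("spiculated masses have rougher boundaries than circumscribed", {
  roughness <- function(mask) {
    # perimeter^2 / (4 pi area), perimeter ~ boundary pixel count
    idx <- which(mask, arr.ind = TRUE)
    nbr <- function(r, c) !(r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)) |
      !mask[cbind(pmin(pmax(r, 1), nrow(mask)), pmin(pmax(c, 1), ncol(mask)))]
    bd <- nbr(idx[, 1] - 1, idx[, 2]) | nbr(idx[, 1] + 1, idx[, 2]) |
      nbr(idx[, 1], idx[, 2] - 1) | nbr(idx[, 1], idx[, 2] + 1)
    sum(bd)^2 / (4 * pi * nrow(idx))
  }
  r_spic <- r_circ <- numeric(20)
  for (s in 1:20) {
    r_spic[s] <- roughness(gen_roi(phantom_spec("spiculated", seed = s))$mask)
    r_circ[s] <- roughness(gen_roi(phantom_spec("circumscribed", seed = s))$mask)
  }
  expect_gt(mean(r_spic), mean(r_circ))
})

test_that("every generated mass mask is 8-connected and non-trivial", {
  for (mt in c(margin_types(), "normal")) {
    p <- gen_roi(phantom_spec(mt, seed = 11))
    expect_true(mask_is_connected8(p$mask), label = paste("connected:", mt))
    expect_gte(sum(p$mask), 16)
    expect_true(all(p$pixels >= 0 & p$pixels <= 1))
  }
})

test_that("dataset composition, degenerate counts and determinism hold", {
  ds <- gen_dataset(2, 10, seed = 5)
  expect_length(ds, 20)
  margins <- vapply(ds, function(p) p$margin, "")
  expect_equal(unname(table(margins[margins != "none"])),
               rep(2L, 5), ignore_attr = TRUE)
  expect_equal(sum(vapply(ds, function(p) p$label, "") == "normal"), 10)

  ds0 <- gen_dataset(0, 5, seed = 5)
  expect_length(ds0, 5)
  expect_true(all(vapply(ds0, function(p) p$label, "") == "normal"))

  ds2 <- gen_dataset(2, 10, seed = 5)
  expect_identical(lapply(ds, `[[`, "pixels"), lapply(ds2, `[[`, "pixels"))
  expect_identical(vapply(ds, function(p) p$margin, ""),
                   vapply(ds2, function(p) p$margin, ""))
})

test_that("feature clusters have the configured shape and means", {
  spec <- cluster_spec(dimension = 10, n_mass_per_margin = 50, n_normal = 100,
                       margin_means = matrix(rep(c(3, rep(0, 9)), 5), 5,
                                             byrow = TRUE),
                       seed = 2)
  fs <- gen_feature_clusters(spec)
  expect_equal(dim(fs$x), c(350, 10))
  expect_identical(gen_feature_clusters(spec)$x, fs$x)

  # Monte-Carlo mean recovery at n = 500 per class
  spec2 <- cluster_spec(dimension = 8, n_mass_per_margin = 500,
                        n_normal = 500, seed = 3)
  fs2 <- gen_feature_clusters(spec2)
  for (t in seq_along(margin_types())) {
    sm <- colMeans(fs2$x[fs2$margin == margin_types()[t], ])
    expect_lt(max(abs(sm - spec2$margin_means[t, ])),
              3 * spec2$margin_scale / sqrt(500) * 3)
  }
  expect_lt(max(abs(colMeans(fs2$x[fs2$label == "normal", ]))),
            3 * spec2$normal_scale / sqrt(500) * 3)
})

test_that("invalid cluster specs are rejected", {
  expect_error(cluster_spec(margin_scale = 0), "margin_scale")
  expect_error(cluster_spec(normal_scale = -1), "normal_scale")
  expect_error(cluster_spec(dimension = 1), "dimension")
  expect_error(cluster_spec(n_mass_per_margin = 0), "n_mass_per_margin")
})

test_that("cluster separation knob raises downstream separability", {
  # wider inter-mean distance => higher single-dictionary AUC on average
  auc_at <- function(sep) {
    aucs <- numeric(3)
    for (s in 1:3) {
      tr <- gen_feature_clusters(cluster_spec(dimension = 40,
                                              n_mass_per_margin = 15,
                                              n_normal = 75,
                                              separation = sep, seed = s))
      te <- gen_feature_clusters(cluster_spec(dimension = 40,
                                              n_mass_per_margin = 5,
                                              n_normal = 25,
                                              separation = sep, seed = 50 + s))
      m <- build_single_model(tr, seed = 1)
      aucs[s] <- roc_auc(classify(m, te)$confidence, te$label)
    }
    mean(aucs)
  }
  expect_gt(auc_at(8), auc_at(1))
})
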