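# Independent oracle implementations used to check the package's fast
# paths. These deliberately use naive loops / enumeration and share no
# code with the implementation.

# 8-connectivity check by flood fill from the first foreground pixel
mask_is_connected8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  stack <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  count <- 1L
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          mask[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        count <- count + 1L
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  count == sum(mask)
}

# straight-from-definition Haralick statistics (base-2 logs, 0*log0 = 0)
haralick_oracle <- function(p) {
  G <- nrow(p)
  p <- p / sum(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum((1:G - mux)^2 * px)); sy <- sqrt(sum((1:G - muy)^2 * py))
  cor <- 0; ene <- 0; ent <- 0; ine <- 0; idm <- 0
  psum <- rep(0, 2 * G); pdif <- rep(0, G)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    ene <- ene + v^2
    ent <- ent - v * lg(v)
    ine <- ine + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
  }
  if (sx > 0 && sy > 0) {
    for (i in 1:G) for (j in 1:G) cor <- cor + i * j * p[i, j]
    cor <- (cor - mux * muy) / (sx * sy)
  }
  sa <- sum((2:(2 * G)) * psum[2:(2 * G)])
  sv <- sum(((2:(2 * G)) - sa)^2 * psum[2:(2 * G)])
  se <- -sum(sapply(2:(2 * G), function(k) psum[k] * lg(psum[k])))
  de <- sum(pdif^2)
  dm <- sum((0:(G - 1)) * pdif)
  dv <- sum(((0:(G - 1)) - dm)^2 * pdif)
  dent <- -sum(sapply(1:G, function(k) pdif[k] * lg(pdif[k])))
  hx <- -sum(sapply(px, function(v) v * lg(v)))
  hy <- -sum(sapply(py, function(v) v * lg(v)))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(cor, ene, ent, ine, idm, sa, sv, se, de, dv, dent, imc1, imc2)
}

# exhaustive pairwise-concordance AUC (ties count half)
pairwise_auc_oracle <- function(conf, labels) {
  pos <- conf[labels == "mass"]; neg <- conf[labels == "normal"]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# lasso objective 0.5||Ax-y||^2 + lambda||x||_1
lasso_objective <- function(A, x, y, lambda) {
  0.5 * sum((A %*% x - y)^2) + lambda * sum(abs(x))
}

# high-accuracy lasso solution via glmnet (coordinate descent on a
# lambda path, thresh 1e-14); objective mapping lambda_glmnet = lambda/d
glmnet_lasso_oracle <- function(A, y, lambda) {
  d <- nrow(A)
  lmax <- max(abs(crossprod(A, y))) / d
  target <- lambda / d
  lseq <- exp(seq(log(max(lmax, target * 1.01)), log(target), length.out = 60))
  fit <- glmnet::glmnet(A, y, lambda = lseq, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  as.numeric(glmnet::coef.glmnet(fit, s = target))[-1]
}

# small labelled feature set of two well-separated Gaussian clusters,
# centred on distinct coordinate axes (inter-mean distance = sep * sqrt(2)
# in units of the noise sd) so both classes carry subspace structure
two_cluster_set <- function(n_per_class, d, sep, seed) {
  set.seed(seed)
  mu1 <- c(sep, rep(0, d - 1))
  mu2 <- c(0, sep, rep(0, d - 2))
  x <- rbind(matrix(rnorm(n_per_class * d), n_per_class) +
               matrix(mu1, n_per_class, d, byrow = TRUE),
             matrix(rnorm(n_per_class * d), n_per_class) +
               matrix(mu2, n_per_class, d, byrow = TRUE))
  feature_set(x, rep(c("mass", "normal"), each = n_per_class),
              rep(c("all", "none"), each = n_per_class))
}

# tiny deterministic patch with a centred rectangular mask
toy_patch <- function(values, mask = NULL) {
  v <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  structure(list(pixels = v, mask = mask, label = NULL, margin = NULL),
            class = "roi_patch")
}

# random per-class data for small FDDL instances
fddl_toy_data <- function(d, n, seed, sep = 3) {
  set.seed(seed)
  list(mass = matrix(rnorm(d * n), d) + sep,
       normal = matrix(rnorm(d * n), d))
}
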