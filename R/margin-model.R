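#' Build the margin-specific dictionary model
#'
#' The package's central classifier. For every margin type present in the
#' training data a balanced dictionary is assembled -- all masses of that
#' margin plus an equal number of normal samples drawn once, without
#' replacement, under the model seed -- and refined by Fisher
#' discrimination dictionary learning ([fddl_learn()]). Feature scaling
#' statistics are computed once from the whole training set and shared by
#' all dictionaries. Margin types absent from the training data are
#' skipped with a warning.
#'
#' @param train A [feature_set()] with labels, and margin annotations on
#'   the mass samples.
#' @param fddl An [fddl_params()].
#' @param solver A [solver_config()] used at classification time.
#' @param seed Integer seed driving negative sampling and FDDL
#'   initialization.
#' @param learn If `FALSE`, skip FDDL and use the raw (sd-scaled,
#'   unit-norm) samples as atoms; used for the conventional
#'   single-dictionary configuration.
#' @return A `margin_model`: list of per-margin `src_dictionary` objects
#'   sharing one set of normalization statistics, plus the configuration.
#' @export
build_margin_model <- function(train, fddl = fddl_params(),
                               solver = solver_config(), seed = 1L,
                               learn = TRUE) {
  if (!inherits(train, "feature_set")) stopf("'train' must be a feature_set")
  is_mass <- train$label == "mass"
  if (!any(is_mass)) stopf("training data contains no mass samples")
  if (!any(!is_mass)) stopf("training data contains no normal samples")

  # scale-only feature standardization shared by all dictionaries (see
  # build_dictionary for why features are scaled by the normal-class sd
  # and not mean-centered)
  center <- rep(0, ncol(train$x))
  scale <- feature_scale_stats(train$x, train$label)
  xs <- sweep(sweep(train$x, 2, center), 2, scale, "/")

  present <- intersect(c(margin_types(), "all"), unique(train$margin[is_mass]))
  missing <- setdiff(margin_types(),
                     unique(train$margin[is_mass]))
  if (length(missing) && !"all" %in% present)
    warning(sprintf("no training masses for margin type(s): %s; skipped",
                    paste(missing, collapse = ", ")), call. = FALSE)
  if (!length(present))
    stopf("mass samples carry no usable margin annotation")

  normal_idx <- which(!is_mass)
  seeds <- derive_seeds(seed, 2L * length(present))
  dictionaries <- list()
  sampled_negatives <- list()
  for (t in seq_along(present)) {
    mt <- present[t]
    mass_idx <- which(is_mass & train$margin == mt)
    n_neg <- min(length(normal_idx), length(mass_idx))
    neg_idx <- with_seed(seeds[2L * t - 1L],
                         sort(sample(normal_idx, n_neg)))
    sampled_negatives[[mt]] <- neg_idx
    mass_m <- t(xs[mass_idx, , drop = FALSE])
    norm_m <- t(xs[neg_idx, , drop = FALSE])
    if (learn) {
      fit <- fddl_learn(list(mass = mass_m, normal = norm_m), fddl,
                        seed = seeds[2L * t])
      atoms <- fit$D
      cls <- rep(c("mass", "normal"), fit$m_per_class)
      dict <- new_dictionary(atoms, cls, center, scale)
      dict$fddl <- fit[c("objective", "trace", "m_per_class", "converged")]
    } else {
      atoms <- unit_columns(cbind(mass_m, norm_m))
      dict <- new_dictionary(atoms,
                             rep(c("mass", "normal"),
                                 c(ncol(mass_m), ncol(norm_m))),
                             center, scale)
    }
    dictionaries[[mt]] <- dict
  }
  structure(list(dictionaries = dictionaries, margins = present,
                 center = center, scale = scale, solver = solver,
                 fddl = if (learn) fddl else NULL, learn = learn,
                 seed = as.integer(seed),
                 sampled_negatives = sampled_negatives),
            class = "margin_model")
}

#' Conventional single-dictionary configuration
#'
#' Baseline configuration: one pooled dictionary holding all training
#' masses (margins mixed) plus an equal-sized seeded sample of normals,
#' without dictionary learning. Returned as a `margin_model` with a single
#' pseudo-margin `"all"`, so that fusion reduces exactly to plain
#' single-dictionary SRC.
#'
#' @inheritParams build_margin_model
#' @return A `margin_model` with one dictionary.
#' @export
build_single_model <- function(train, solver = solver_config(), seed = 1L,
                               learn = FALSE, fddl = fddl_params()) {
  pooled <- train
  pooled$margin <- ifelse(train$label == "mass", "all", "none")
  build_margin_model(pooled, fddl = fddl, solver = solver, seed = seed,
                     learn = learn)
}

#' @export
print.margin_model <- function(x, ...) {
  cat(sprintf("<margin_model> T=%d dictionaries (%s), d=%d, %s\n",
              length(x$dictionaries), paste(x$margins, collapse = ", "),
              length(x$center),
              if (x$learn) "FDDL-learned" else "raw atoms"))
  invisible(x)
}

#' Score-level fused class residuals
#'
#' Codes the query against every margin dictionary and sums the
#' class-restricted residuals over dictionaries:
#' `Res_i = sum_t ||y - D_t delta_i(x_t)||_2` for `i` in mass, normal.
#' With a single dictionary this reduces to the plain class residuals.
#'
#' @param model A `margin_model`.
#' @param y Raw query vector (length d) or d x m matrix of queries in
#'   columns.
#' @return List with `res_mass`, `res_normal` (one value per query) and
#'   `solutions` (per-margin `sparse_solution` objects).
#' @export
fused_residuals <- function(model, y) {
  if (!inherits(model, "margin_model")) stopf("'model' must be a margin_model")
  if (inherits(y, "feature_set")) y <- t(y$x)
  y <- as.matrix(y)
  m <- ncol(y)
  res_mass <- numeric(m)
  res_normal <- numeric(m)
  sols <- list()
  for (mt in model$margins) {
    D <- model$dictionaries[[mt]]
    sol <- sparse_code(D, y, model$solver)
    res_mass <- res_mass + class_residual(D, y, sol, "mass")
    res_normal <- res_normal + class_residual(D, y, sol, "normal")
    sols[[mt]] <- sol
  }
  list(res_mass = res_mass, res_normal = res_normal, solutions = sols)
}

#' Classify queries with the margin-dictionary model
#'
#' Computes the fused residuals and assigns each query to the class with
#' the smaller fused residual (ties go to `"normal"`). The confidence is
#' `Res_normal - Res_mass`, so larger values mean more mass-like; it is
#' the score thresholded by the ROC analysis.
#'
#' @inheritParams fused_residuals
#' @param id Optional query ids for the result table.
#' @return A `classification_result`: data.frame with columns `id`,
#'   `res_mass`, `res_normal`, `confidence`, `predicted`, carrying the
#'   per-dictionary sparse solutions as attribute `solutions`.
#' @export
classify <- function(model, y, id = NULL) {
  if (inherits(y, "feature_set")) {
    if (is.null(id)) id <- y$id
    y <- t(y$x)
  }
  y <- as.matrix(y)
  fr <- fused_residuals(model, y)
  predicted <- ifelse(fr$res_mass < fr$res_normal, "mass", "normal")
  out <- data.frame(id = id %||% paste0("q", seq_len(ncol(y))),
                    res_mass = fr$res_mass, res_normal = fr$res_normal,
                    confidence = fr$res_normal - fr$res_mass,
                    predicted = predicted, stringsAsFactors = FALSE)
  attr(out, "solutions") <- fr$solutions
  class(out) <- c("classification_result", class(out))
  out
}
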