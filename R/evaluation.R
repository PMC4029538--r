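#' Sparsity concentration in the true class
#'
#' Fraction of a sparse code's l1 mass carried by the coefficients of the
#' sample's true class: `||delta_true(x)||_1 / ||x||_1`, always in
#' `[0, 1]`. A code with zero l1 norm returns 0 by convention.
#'
#' @param coefficients Sparse coefficient vector (or a `sparse_solution`,
#'   whose single-column coefficients are used).
#' @param selector Logical vector marking the coefficients of the true
#'   class.
#' @return A number in `[0, 1]`.
#' @export
sctc <- function(coefficients, selector) {
  if (inherits(coefficients, "sparse_solution"))
    coefficients <- as.numeric(coefficients$coefficients)
  coefficients <- as.numeric(coefficients)
  if (length(selector) != length(coefficients))
    stopf("'selector' length must match the coefficient vector")
  tot <- sum(abs(coefficients))
  if (tot == 0) return(0)
  sum(abs(coefficients[selector])) / tot
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC of mass-vs-normal confidences: the probability that a
#' random mass sample scores above a random normal sample, ties counted
#' half (equivalently, the trapezoidal area over all thresholds).
#'
#' @param confidences Numeric scores; larger means more mass-like.
#' @param labels `"mass"`/`"normal"` per score; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(confidences, labels) {
  if (length(confidences) != length(labels))
    stopf("'confidences' and 'labels' must have equal length")
  is_mass <- labels == "mass"
  n1 <- sum(is_mass); n0 <- sum(!is_mass)
  if (n1 == 0L || n0 == 0L)
    stopf("both classes must be present to compute AUC")
  r <- rank(confidences)
  (sum(r[is_mass]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: every label x margin stratum is spread
# evenly over the k folds
stratified_folds <- function(label, margin, k) {
  stratum <- paste(label, margin, sep = "|")
  fold <- integer(length(label))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Multi-run stratified k-fold cross-validation of both configurations
#'
#' For each run: a stratified k-fold split (by class and margin type); on
#' every fold both configurations are trained on the k-1 training folds --
#' the margin-specific model ([build_margin_model()]) and the conventional
#' single-dictionary model ([build_single_model()]) -- and the held-out
#' fold is scored by fused-residual confidence. Every sample is scored
#' exactly once per run. Per run the pooled out-of-fold confidences give
#' one AUC per configuration; for every mass test sample the sparsity
#' concentration in the true class is measured against its own margin's
#' dictionary (margin-specific configuration) and against the pooled
#' dictionary (single configuration), then averaged per margin over folds
#' and runs.
#'
#' @param dataset A [feature_set()] with both classes and margin
#'   annotations on the masses.
#' @param k Number of folds (>= 2).
#' @param runs Number of independent repetitions (fresh folds and fresh
#'   negative sampling per run).
#' @param seed Master seed; all run/fold/sampling randomness derives from
#'   it.
#' @param fddl An [fddl_params()] for the margin-specific configuration.
#' @param solver A [solver_config()].
#' @return An `eval_report`: `per_run` data.frame (run, auc_single,
#'   auc_margin), `mean_auc_single`, `mean_auc_margin`, `sctc` data.frame
#'   (margin, sctc_single, sctc_margin, n), plus the protocol parameters.
#' @export
cross_validate <- function(dataset, k = 10L, runs = 30L, seed = 1L,
                           fddl = fddl_params(), solver = solver_config()) {
  if (!inherits(dataset, "feature_set")) stopf("'dataset' must be a feature_set")
  check_number(k, "k", min = 2, integer = TRUE)
  check_number(runs, "runs", min = 1, integer = TRUE)
  if (!all(c("mass", "normal") %in% dataset$label))
    stopf("'dataset' must contain both classes")
  if (min(table(dataset$label)) < k)
    stopf("each class needs at least k samples for %d-fold splitting", k)

  run_seeds <- derive_seeds(seed, runs)
  per_run <- data.frame(run = seq_len(runs), auc_single = NA_real_,
                        auc_margin = NA_real_)
  sctc_acc <- list()

  for (run in seq_len(runs)) {
    fold_seeds <- derive_seeds(run_seeds[run], k + 1L)
    fold <- with_seed(fold_seeds[k + 1L],
                      stratified_folds(dataset$label, dataset$margin, k))
    conf_single <- conf_margin <- numeric(nrow(dataset$x))
    for (f in seq_len(k)) {
      tr <- dataset[fold != f]
      te <- dataset[fold == f]
      m_margin <- build_margin_model(tr, fddl = fddl, solver = solver,
                                     seed = fold_seeds[f], learn = TRUE)
      m_single <- build_single_model(tr, solver = solver,
                                     seed = fold_seeds[f])
      yte <- t(te$x)
      fr_m <- fused_residuals(m_margin, yte)
      fr_s <- fused_residuals(m_single, yte)
      conf_margin[fold == f] <- fr_m$res_normal - fr_m$res_mass
      conf_single[fold == f] <- fr_s$res_normal - fr_s$res_mass

      mass_te <- which(te$label == "mass")
      for (q in mass_te) {
        mt <- te$margin[q]
        sc_s <- sctc(fr_s$solutions[["all"]]$coefficients[, q],
                     m_single$dictionaries[["all"]]$atom_class == "mass")
        sc_m <- if (mt %in% m_margin$margins)
          sctc(fr_m$solutions[[mt]]$coefficients[, q],
               m_margin$dictionaries[[mt]]$atom_class == "mass")
        else NA_real_
        sctc_acc[[length(sctc_acc) + 1L]] <-
          data.frame(margin = mt, single = sc_s, margin_specific = sc_m)
      }
    }
    per_run$auc_single[run] <- roc_auc(conf_single, dataset$label)
    per_run$auc_margin[run] <- roc_auc(conf_margin, dataset$label)
  }

  sc <- do.call(rbind, sctc_acc)
  sctc_tab <- do.call(rbind, lapply(split(sc, sc$margin), function(g)
    data.frame(margin = g$margin[1],
               sctc_single = mean(g$single),
               sctc_margin = mean(g$margin_specific, na.rm = TRUE),
               n = nrow(g))))
  sctc_tab <- sctc_tab[order(match(sctc_tab$margin, margin_types())), ]
  rownames(sctc_tab) <- NULL

  structure(list(per_run = per_run,
                 mean_auc_single = mean(per_run$auc_single),
                 mean_auc_margin = mean(per_run$auc_margin),
                 sctc = sctc_tab, k = as.integer(k), runs = as.integer(runs),
                 seed = as.integer(seed), n = nrow(dataset$x)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d runs x %d-fold CV on %d samples (seed %d)\n",
              x$runs, x$k, x$n, x$seed))
  cat(sprintf("  mean AUC: single %.4f, margin-specific %.4f\n",
              x$mean_auc_single, x$mean_auc_margin))
  cat("  mean SCTC per margin:\n")
  print(x$sctc, row.names = FALSE)
  invisible(x)
}
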