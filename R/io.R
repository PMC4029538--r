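MODEL_FORMAT_VERSION <- "1.0"

read_gray_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read image file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stopf("unsupported image format '%s' for '%s'", ext, path))
  if (length(dim(img)) == 3L) {
    warning(sprintf("'%s' has %d channels; converted to luminance",
                    path, dim(img)[3]), call. = FALSE)
    ch <- dim(img)[3]
    w <- if (ch >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / ch, ch)
    img <- Reduce(`+`, lapply(seq_len(min(ch, 3L)),
                              function(k) w[k] * img[, , k]))
  }
  img
}

#' Load a region of interest from image and mask files
#'
#' Reads an 8- or 16-bit grayscale image (PNG or TIFF) rescaled to
#' `[0, 1]` and a mask image binarized at `> 0`. RGB inputs are converted
#' to luminance with a warning.
#'
#' @param image_path Path to the grayscale ROI image.
#' @param mask_path Path to the mask image (same shape).
#' @param label,margin Optional annotations attached to the patch.
#' @return An [roi_patch()].
#' @export
load_roi <- function(image_path, mask_path, label = NULL, margin = NULL) {
  px <- read_gray_image(image_path)
  mk <- read_gray_image(mask_path)
  if (!all(dim(px) == dim(mk)))
    stopf("mask shape (%s) does not match image shape (%s) for '%s'",
          paste(dim(mk), collapse = "x"), paste(dim(px), collapse = "x"),
          mask_path)
  roi_patch(pmin(pmax(px, 0), 1), mk > 0, label = label, margin = margin)
}

#' Write a region of interest to image and mask files
#'
#' The pixel grid is quantized to 16-bit grayscale TIFF (or 8-bit PNG when
#' `image_path` ends in `.png`); the mask is written as an 8-bit 0/255
#' PNG.
#'
#' @param patch An [roi_patch()].
#' @param image_path Output image path (`.tif`/`.tiff` or `.png`).
#' @param mask_path Output mask path (`.png`).
#' @return Invisibly, the two paths.
#' @export
write_roi <- function(patch, image_path, mask_path) {
  if (!inherits(patch, "roi_patch")) stopf("'patch' must be an roi_patch")
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(patch$pixels, image_path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(patch$pixels, image_path)
  } else stopf("unsupported image format '%s'", ext)
  png::writePNG(matrix(as.numeric(patch$mask), nrow(patch$mask)), mask_path)
  invisible(c(image_path, mask_path))
}

margin_abbrev <- c(circumscribed = "circ", obscured = "obsc",
                   micro_lobulated = "mlob", ill_defined = "ill",
                   spiculated = "spic", none = "none", all = "all")

#' Write a phantom dataset plus manifest to a directory
#'
#' Writes each patch's image (16-bit TIFF) and mask (PNG) and a manifest
#' CSV with columns `id, image_path, mask_path, label, margin, seed`.
#'
#' @param patches List of [roi_patch()] objects.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return The manifest as a data.frame (invisibly); the CSV is
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_dataset <- function(patches, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    id <- sprintf("roi%04d", i)
    ip <- file.path(dir, paste0(id, ".tif"))
    mp <- file.path(dir, paste0(id, "_mask.png"))
    write_roi(p, ip, mp)
    data.frame(id = id, image_path = ip, mask_path = mp,
               label = p$label %||% "normal",
               margin = margin_abbrev[[p$margin %||% "none"]],
               seed = seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a dataset manifest and load its patches
#'
#' @param path Manifest CSV path (columns `id, image_path, mask_path,
#'   label, margin, seed`); relative image paths are resolved against the
#'   manifest's directory.
#' @return List of [roi_patch()] objects, names set to the ids.
#' @export
read_dataset <- function(path) {
  man <- data.table::fread(path, data.table = FALSE)
  need <- c("id", "image_path", "mask_path", "label", "margin")
  if (!all(need %in% names(man)))
    stopf("manifest '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  if (anyDuplicated(man$id)) stopf("manifest ids must be unique")
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  long <- names(margin_abbrev)
  names(long) <- margin_abbrev
  patches <- lapply(seq_len(nrow(man)), function(i)
    load_roi(resolve(man$image_path[i]), resolve(man$mask_path[i]),
             label = man$label[i],
             margin = long[[as.character(man$margin[i])]]))
  names(patches) <- man$id
  patches
}

#' Write a feature table to CSV
#'
#' One row per sample: `id`, `label`, `margin`, then the named feature
#' columns. Values round-trip at full double precision.
#'
#' @param fs A [feature_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fs, path) {
  if (!inherits(fs, "feature_set")) stopf("'fs' must be a feature_set")
  x <- fs$x
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  # 17 significant digits so every double survives the round trip exactly
  xc <- matrix(formatC(x, digits = 17, format = "g"), nrow(x),
               dimnames = dimnames(x))
  df <- data.frame(id = fs$id, label = fs$label, margin = fs$margin,
                   xc, check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' Validates the `id`/`label`/`margin` header. If the feature columns use
#' the full 812-column block naming of [extract_features()], their order
#' and count are checked against [feature_block_index()]; otherwise any
#' set of numeric columns is accepted (e.g. cluster phantoms).
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A [feature_set()].
#' @export
read_feature_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("id", "label", "margin")
  if (!all(need %in% names(df)))
    stopf("feature table '%s' must start with columns id, label, margin", path)
  feat_cols <- setdiff(names(df), need)
  if (length(feat_cols) == 0L) stopf("feature table '%s' has no feature columns", path)
  if (any(grepl("^(lbp|sgld|rls|glds|nrl|intensity|stellate)\\.", feat_cols)) &&
      !identical(feat_cols, feature_names()))
    stopf("feature table '%s' does not match the %d-column block schema",
          path, feature_dim())
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(x)) stopf("feature columns in '%s' must be numeric", path)
  feature_set(x, df$label, df$margin, df$id)
}

# whitespace-delimited text matrix with a "rows cols" header line;
# 17 significant digits so doubles reload bit-identically
write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  apply(m, 1, function(r)
    writeLines(paste(formatC(r, digits = 17, format = "g"), collapse = " "),
               con))
  invisible(path)
}

read_matrix_txt <- function(path) {
  if (!file.exists(path)) stopf("missing matrix file '%s'", path)
  hdr <- scan(path, what = integer(), n = 2, quiet = TRUE)
  vals <- scan(path, what = double(), skip = 1, quiet = TRUE)
  if (length(vals) != hdr[1] * hdr[2])
    stopf("matrix file '%s' is truncated", path)
  matrix(vals, hdr[1], hdr[2], byrow = TRUE)
}

#' Save a margin model to a directory
#'
#' Writes `model.json` (format version, margins, seed, solver and FDDL
#' parameters, normalization statistics) plus one subdirectory per
#' dictionary with the atom matrix as whitespace-delimited text, the atom
#' class labels, and (for learned dictionaries) the objective trace CSV.
#'
#' @param model A `margin_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_margin_model <- function(model, dir) {
  if (!inherits(model, "margin_model")) stopf("'model' must be a margin_model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = MODEL_FORMAT_VERSION,
               margins = model$margins, seed = model$seed,
               learn = model$learn,
               solver = unclass(model$solver),
               fddl = if (!is.null(model$fddl)) unclass(model$fddl),
               dimension = length(model$center))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_matrix_txt(rbind(model$center, model$scale),
                   file.path(dir, "normalization.txt"))
  for (mt in model$margins) {
    d <- file.path(dir, paste0("dict_", mt))
    dir.create(d, showWarnings = FALSE)
    D <- model$dictionaries[[mt]]
    write_matrix_txt(D$atoms, file.path(d, "atoms.txt"))
    writeLines(D$atom_class, file.path(d, "atom_class.txt"))
    if (!is.null(D$fddl))
      data.table::fwrite(data.frame(iteration = seq_along(D$fddl$trace),
                                    objective = D$fddl$trace),
                         file.path(d, "trace.csv"))
  }
  invisible(dir)
}

#' Load a margin model saved by [save_margin_model()]
#'
#' @param dir Model directory.
#' @return A `margin_model` whose classifications are identical to the
#'   saved model's.
#' @export
load_margin_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stopf("missing model metadata '%s'", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, MODEL_FORMAT_VERSION))
    stopf("model format version '%s' is incompatible with '%s'",
          meta$format_version %||% "<missing>", MODEL_FORMAT_VERSION)
  ns <- read_matrix_txt(file.path(dir, "normalization.txt"))
  center <- ns[1, ]; scale <- ns[2, ]
  dicts <- list()
  for (mt in meta$margins) {
    d <- file.path(dir, paste0("dict_", mt))
    atoms <- read_matrix_txt(file.path(d, "atoms.txt"))
    cls <- readLines(file.path(d, "atom_class.txt"))
    dicts[[mt]] <- new_dictionary(atoms, cls, center, scale)
  }
  solver <- do.call(solver_config, meta$solver[c("lambda", "lambda_factor",
                                                "max_iter", "tol")])
  fddl <- if (!is.null(meta$fddl) && length(meta$fddl))
    do.call(fddl_params, meta$fddl[c("n_atoms", "lambda1", "lambda2", "eta",
                                     "max_iter", "tol")])
  structure(list(dictionaries = dicts, margins = meta$margins,
                 center = center, scale = scale, solver = solver,
                 fddl = fddl, learn = isTRUE(meta$learn),
                 seed = as.integer(meta$seed), sampled_negatives = NULL),
            class = "margin_model")
}
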