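#' Read an observations-by-features matrix from delimited text or Matrix Market
#'
#' Reads a numeric matrix in file order (one observation per row).  CSV and
#' TSV files may carry a header line of feature names; Matrix Market (`.mtx`)
#' files are read sparsely and only densified when a downstream consumer
#' needs dense input.  Any non-finite entry is an error — see
#' [arcsinh_transform()] for the rationale.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (guess from the file extension), `"csv"`,
#'   `"tsv"`, or `"mtx"`.
#' @param has_header Logical; does the first line name the columns?  Ignored
#'   for `mtx`.
#' @return A numeric matrix (dense for `csv`/`tsv`, a sparse
#'   [Matrix::sparseMatrix] for `mtx`) with `n_obs` rows in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("1,2", "3,4", "5,6"), f)
#' read_matrix(f)
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        has_header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", tab = "tsv", txt = "tsv", mtx = "mtx",
      abort(sprintf("Cannot guess format from extension '.%s'; pass `format`.", ext))
    )
  }
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      abort(sprintf("Failed to parse Matrix Market file '%s': %s", path, conditionMessage(e)))
    })
    if (any(!is.finite(m@x))) {
      abort(sprintf("'%s' contains non-finite values; refusing to impute.", path))
    }
    return(m)
  }
  if (file.size(path) == 0) {
    abort(sprintf("File '%s' is empty.", path))
  }
  delim <- if (format == "csv") "," else "\t"
  # parse problems are escalated to errors below, so readr's own warning is
  # redundant noise
  df <- suppressWarnings(readr::read_delim(
    path,
    delim = delim,
    col_names = has_header,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE,
    show_col_types = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "Malformed %s file '%s': line %d (%s, expected %s, got %s).",
      format, path, p$row + has_header, "parse problem",
      as.character(p$expected), as.character(p$actual)
    ))
  }
  if (nrow(df) == 0 || ncol(df) == 0) {
    abort(sprintf("File '%s' parsed to an empty matrix.", path))
  }
  as_feature_matrix(df, arg = path)
}

#' Inverse-hyperbolic-sine transform for mass-cytometry intensities
#'
#' Applies `asinh(x / cofactor)` elementwise — the standard variance-
#' stabilising transform for CyTOF marker intensities, with the conventional
#' cofactor (scale factor) of 5.  The transform is monotone and invertible
#' (`sinh(y) * cofactor`); shape, dimnames and column order are preserved.
#'
#' @param x Numeric matrix or data frame (observations x features).
#' @param cofactor Positive scale factor; intensities are divided by it
#'   before `asinh`.  Default 5, the usual CyTOF choice.
#' @return Object of the same shape as `x` (a tibble when `x` was a data
#'   frame, otherwise a matrix).
#' @export
#' @examples
#' arcsinh_transform(matrix(c(0, 5, -5), 1), cofactor = 5)
arcsinh_transform <- function(x, cofactor = 5) {
  check_positive_number(cofactor, "cofactor")
  was_df <- is.data.frame(x)
  m <- as_feature_matrix(x, arg = "x")
  out <- asinh(m / cofactor)
  if (was_df) as_tibble(out) else out
}

# Fit-side PCA used both by `pca_reduce()` and by the preprocessing recorded
# inside a fitted embedding model (out-of-sample rows must be projected with
# the training loadings, never refit).  Exact SVD for moderate n; truncated
# Lanczos SVD (irlba) for very tall matrices, where full decomposition is a
# waste for a noise-reduction step.
pca_fit <- function(m, n_components, exact_limit = 1e5, seed = NULL) {
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(m))) {
    abort(sprintf(
      "`n_components` (%d) exceeds min(n_obs, n_feat) = %d.",
      n_components, min(dim(m))
    ))
  }
  center <- colMeans(m)
  if (nrow(m) <= exact_limit) {
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
    rotation <- p$rotation
    sdev <- p$sdev
  } else {
    p <- with_seed(seed %||% 1L, irlba::prcomp_irlba(m, n = n_components, center = center, scale. = FALSE))
    rotation <- p$rotation
    sdev <- p$sdev
  }
  list(rotation = rotation[, seq_len(n_components), drop = FALSE],
       center = center,
       sdev = sdev)
}

pca_project <- function(m, fit) {
  sweep(m, 2, fit$center) %*% fit$rotation
}

#' Project observations onto their top principal components
#'
#' Mean-centres the data and returns coordinates on the leading
#' `n_components` principal axes, ordered by decreasing explained variance.
#' This is the conventional noise-reduction step before embedding scRNA-seq
#' data, where cells are projected into a 50-dimensional PC space.
#' Deterministic up to per-axis sign.
#'
#' @param x Numeric matrix or data frame (observations x features).
#' @param n_components Number of components to keep; must not exceed
#'   `min(n_obs, n_feat)`.  Default 50.
#' @param seed Seed for the truncated solver used on very tall matrices
#'   (> 1e5 rows); ignored otherwise.
#' @return Tibble of PC scores (`PC1`, `PC2`, ...) when `x` is a data frame,
#'   otherwise a matrix.  The attribute `"explained_variance"` carries the
#'   per-component variance fractions.
#' @export
pca_reduce <- function(x, n_components = 50, seed = NULL) {
  was_df <- is.data.frame(x)
  m <- as_feature_matrix(x, arg = "x")
  fit <- pca_fit(m, n_components, seed = seed)
  scores <- pca_project(m, fit)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  out <- if (was_df) as_tibble(scores) else scores
  attr(out, "explained_variance") <- ev[seq_len(n_components)]
  out
}

#' Write an embedding to delimited text
#'
#' One row per observation, one column per embedding coordinate, optionally
#' preceded by an identifier column.  Values are written at full double
#' precision so the file round-trips through [read_matrix()] losslessly.
#'
#' @param embedding Numeric matrix or data frame with one row per observation.
#' @param path Output path (CSV).
#' @param row_ids Optional character vector of per-observation identifiers;
#'   must match the number of rows.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, row_ids = NULL) {
  m <- as_feature_matrix(embedding, arg = "embedding")
  d <- ncol(m)
  df <- as_tibble(m, .name_repair = ~ paste0("dim", seq_len(d)))
  if (!is.null(row_ids)) {
    if (length(row_ids) != nrow(m)) {
      abort(sprintf(
        "`row_ids` has length %d but `embedding` has %d rows.",
        length(row_ids), nrow(m)
      ))
    }
    df <- dplyr::bind_cols(tibble(id = as.character(row_ids)), df)
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
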