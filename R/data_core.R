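# Data model, file I/O, preprocessing and semi-supervised label masking.

#' Expression dataset container
#'
#' Holds a cells x genes expression matrix together with cell and gene
#' identifiers and a layer flag recording whether values are raw counts or
#' depth-normalized log1p values. Cells are rows, genes are columns.
#'
#' @param matrix Numeric matrix, cells in rows, genes in columns. No negative
#'   entries; a `raw_counts` layer must be integral.
#' @param cell_ids Character vector of unique cell identifiers (row names).
#' @param gene_ids Character vector of unique gene identifiers (column names).
#' @param layer One of `"raw_counts"` or `"lognorm"`. If `NULL`, inferred as
#'   `raw_counts` when all entries are integral, `lognorm` otherwise.
#' @return An object of class `expression_dataset` with fields `matrix`,
#'   `cell_ids`, `gene_ids`, `layer`.
#' @export
expression_dataset <- function(matrix, cell_ids = NULL, gene_ids = NULL,
                               layer = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (any(matrix < 0)) stop("expression matrix has negative entries")
  cell_ids <- as.character(cell_ids %||% rownames(matrix) %||%
                             paste0("cell_", seq_len(nrow(matrix))))
  gene_ids <- as.character(gene_ids %||% colnames(matrix) %||%
                             paste0("gene_", seq_len(ncol(matrix))))
  if (length(cell_ids) != nrow(matrix))
    stop("length(cell_ids) must equal the number of rows")
  if (length(gene_ids) != ncol(matrix))
    stop("length(gene_ids) must equal the number of columns")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be duplicate-free")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be duplicate-free")
  if (is.null(layer)) {
    layer <- if (is_wholenumber(matrix)) "raw_counts" else "lognorm"
  }
  layer <- match.arg(layer, c("raw_counts", "lognorm"))
  if (layer == "raw_counts" && !is_wholenumber(matrix))
    stop("raw_counts layer must contain only integral values")
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(list(matrix = matrix, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes [%s]\n",
              nrow(x$matrix), ncol(x$matrix), x$layer))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Factor specification
#'
#' Ordered list of named categorical factors (for example batch, condition,
#' cell type), each with a category vocabulary and the dimension of the latent
#' code block that the model reserves for it, plus the dimension of the
#' residual latent block.
#'
#' By default a factor with at most 4 categories gets a 2-dimensional code and
#' larger factors (such as cell type) an 8-dimensional one, so a batch /
#' condition1 / condition2 / cell-type design with a 10-dimensional residual
#' yields a 24-column latent space.
#'
#' @param factors Named list: each element is a character vector of category
#'   names (at least two per factor), list names are the factor names.
#' @param code_dims Optional integer vector of per-factor code dimensions
#'   (recycled rules: default 2 for factors with <= 4 categories, 8 otherwise).
#' @param residual_dim Dimension of the residual latent block (default 10).
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(factors, code_dims = NULL, residual_dim = 10L) {
  if (is.null(names(factors)) || anyDuplicated(names(factors)) ||
      any(!nzchar(names(factors))))
    stop("factors must be a named list with unique non-empty names")
  k <- length(factors)
  if (k < 1L) stop("need at least one factor")
  factors <- lapply(factors, as.character)
  if (any(vapply(factors, length, 1L) < 2L))
    stop("every factor needs at least 2 categories")
  if (any(vapply(factors, anyDuplicated, 1L) > 0L))
    stop("factor categories must be unique")
  if (is.null(code_dims)) {
    code_dims <- ifelse(vapply(factors, length, 1L) <= 4L, 2L, 8L)
  }
  code_dims <- as.integer(rep(code_dims, length.out = k))
  if (any(code_dims < 1L)) stop("code_dims must be >= 1")
  residual_dim <- as.integer(residual_dim)
  if (residual_dim < 1L) stop("residual_dim must be >= 1")
  names(code_dims) <- names(factors)
  structure(list(factors = factors, code_dims = code_dims,
                 residual_dim = residual_dim),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("factor_spec: %d factors + residual(%d)\n",
              length(x$factors), x$residual_dim))
  for (nm in names(x$factors))
    cat(sprintf("  %s: %d categories, code_dim %d\n",
                nm, length(x$factors[[nm]]), x$code_dims[[nm]]))
  invisible(x)
}

n_categories <- function(spec) vapply(spec$factors, length, 1L)

#' Per-cell factor label table
#'
#' Integer category labels (0-based) for every cell and factor together with
#' the availability indicator: `mask[i, j] = 1` when the label of factor j is
#' known for cell i, 0 otherwise. Missing labels carry the sentinel -1.
#'
#' @param labels Integer matrix, n cells x k factors; -1 marks a missing label.
#' @param mask Optional binary matrix of the same shape; derived from `labels`
#'   (`labels >= 0`) when omitted.
#' @param factor_names Optional factor names (column names).
#' @param cell_ids Optional cell identifiers (row names).
#' @param n_cats Optional integer vector of category counts per factor, used to
#'   range-check labels.
#' @return An object of class `label_table`.
#' @export
label_table <- function(labels, mask = NULL, factor_names = NULL,
                        cell_ids = NULL, n_cats = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(mask)) mask <- (labels >= 0L) * 1L
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!identical(dim(labels), dim(mask)))
    stop("labels and mask must have identical dimensions")
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary")
  if (any(labels[mask == 0L] != -1L))
    stop("unmasked labels must carry the sentinel -1")
  if (any(labels[mask == 1L] < 0L))
    stop("masked-available labels must be >= 0")
  factor_names <- factor_names %||% colnames(labels) %||%
    paste0("factor_", seq_len(ncol(labels)))
  cell_ids <- cell_ids %||% rownames(labels)
  if (!is.null(n_cats)) {
    n_cats <- as.integer(rep(n_cats, length.out = ncol(labels)))
    for (j in seq_len(ncol(labels))) {
      bad <- labels[, j] >= n_cats[j]
      if (any(bad))
        stop(sprintf("labels for factor '%s' exceed its category count",
                     factor_names[j]))
    }
  }
  dimnames(labels) <- dimnames(mask) <- list(cell_ids, factor_names)
  structure(list(labels = labels, mask = mask, factor_names = factor_names),
            class = "label_table")
}

#' @export
print.label_table <- function(x, ...) {
  cat(sprintf("label_table: %d cells x %d factors (%.1f%% labeled entries)\n",
              nrow(x$labels), ncol(x$labels), 100 * mean(x$mask)))
  invisible(x)
}

#' Read an expression dataset from disk
#'
#' Supported dialects: a dense CSV (header row = gene ids, first column = cell
#' ids) and a MatrixMarket triplet directory in the CellRanger layout
#' (`matrix.mtx` with genes in rows and cells in columns, plus `barcodes.tsv`
#' and `features.tsv`). The layer is inferred: `raw_counts` iff every entry is
#' integral.
#'
#' @param path File (csv) or directory (mtx_dir) to read.
#' @param format `"csv"`, `"mtx_dir"`, or `"auto"` (directory implies mtx_dir).
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path, format = c("auto", "csv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx_dir" else "csv"
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    return(expression_dataset(m))
  }
  # CellRanger-style triplet directory
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  ft <- file.path(path, "features.tsv")
  for (f in c(mtx, bc, ft)) if (!file.exists(f)) stop("file not found: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  feats <- utils::read.delim(ft, header = FALSE)
  gene_ids <- as.character(feats[[1]])
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
    stop("dimension mismatch between matrix.mtx and barcodes/features files")
  m <- t(m)  # stored genes x cells; we keep cells x genes
  expression_dataset(m, cell_ids = barcodes, gene_ids = gene_ids)
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_dataset()] for both supported dialects; a round-trip
#' preserves the matrix and both identifier vectors.
#'
#' @param ds An [expression_dataset()].
#' @param path Target file (csv) or directory (mtx_dir, created if absent).
#' @param format `"csv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "mtx_dir")) {
  stopifnot(inherits(ds, "expression_dataset"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell_id = ds$cell_ids, ds$matrix, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(ds$matrix), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  writeLines(ds$cell_ids, file.path(path, "barcodes.tsv"))
  utils::write.table(data.frame(ds$gene_ids, ds$gene_ids, "Gene Expression"),
                     file.path(path, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Depth-normalize and log-transform raw counts
#'
#' Scales every cell to a common total count and applies log1p, the standard
#' preprocessing for mean-squared-error reconstruction. The default target is
#' the median cell depth of the dataset.
#'
#' @param ds An [expression_dataset()] with `layer == "raw_counts"`.
#' @param target_sum Positive total count each cell is scaled to before log1p;
#'   defaults to the median per-cell depth.
#' @return An [expression_dataset()] with `layer == "lognorm"`.
#' @export
normalize_counts <- function(ds, target_sum = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$layer != "raw_counts")
    stop("normalize_counts expects a raw_counts layer")
  depth <- rowSums(ds$matrix)
  if (any(depth == 0))
    stop("all-zero cell(s): ", paste(ds$cell_ids[depth == 0], collapse = ", "))
  target_sum <- target_sum %||% stats::median(depth)
  if (target_sum <= 0) stop("target_sum must be positive")
  m <- log1p(ds$matrix * (target_sum / depth))
  expression_dataset(m, ds$cell_ids, ds$gene_ids, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Optional feature selection: keeps the `n` genes with the largest variance on
#' the lognorm layer.
#'
#' @param ds An [expression_dataset()] with `layer == "lognorm"`.
#' @param n Number of genes to keep.
#' @return The subsetted [expression_dataset()].
#' @export
select_hvg <- function(ds, n) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$layer != "lognorm") stop("select_hvg expects a lognorm layer")
  n <- min(as.integer(n), ncol(ds$matrix))
  v <- apply(ds$matrix, 2, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n)])
  expression_dataset(ds$matrix[, keep, drop = FALSE],
                     ds$cell_ids, ds$gene_ids[keep], layer = "lognorm")
}

#' Mask labels for semi-supervised training
#'
#' Starting from a fully observed label table, keeps the labels of a simple
#' random sample of `round(n * fraction)` cells (rounding half up) and hides
#' everything else. A labeled cell keeps all its factor labels (all-or-none by
#' default); `per_factor = TRUE` instead samples each (cell, factor) entry
#' independently, matching the per-entry availability indicator.
#'
#' @param full A [label_table()] whose mask is all ones.
#' @param fraction Fraction of cells (or entries) to keep labeled, in [0, 1].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param per_factor Sample availability per (cell, factor) entry instead of
#'   per cell.
#' @return A [label_table()] with the reduced mask and -1 sentinels.
#' @export
mask_labels <- function(full, fraction, seed = 0L, per_factor = FALSE) {
  stopifnot(inherits(full, "label_table"))
  if (!all(full$mask == 1L)) stop("mask_labels expects a fully observed table")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  labels <- full$labels
  mask <- full$mask
  n <- nrow(labels)
  k <- ncol(labels)
  if (per_factor) {
    keep <- with_seed(seed, {
      m <- round_half_up(n * k * fraction)
      sample.int(n * k, m)
    })
    mask[] <- 0L
    mask[keep] <- 1L
  } else {
    keep <- with_seed(seed, sample.int(n, round_half_up(n * fraction)))
    mask[] <- 0L
    mask[keep, ] <- 1L
  }
  labels[mask == 0L] <- -1L
  label_table(labels, mask, full$factor_names, rownames(full$labels))
}

#' Read / write per-cell factor labels as CSV
#'
#' Label files have one row per cell, an optional `cell_id` first column, and
#' one column per factor holding category names; empty strings or NA mark
#' missing labels. Categories are mapped to 0-based indices via `spec`.
#'
#' @param path CSV file path.
#' @param spec A [factor_spec()] giving factor order and vocabularies.
#' @return A [label_table()].
#' @export
read_label_table <- function(path, spec) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  cell_ids <- NULL
  if ("cell_id" %in% names(df)) {
    cell_ids <- df[["cell_id"]]
    df[["cell_id"]] <- NULL
  }
  missing_f <- setdiff(names(spec$factors), names(df))
  if (length(missing_f))
    stop("label file lacks factor column(s): ",
         paste(missing_f, collapse = ", "))
  labels <- sapply(names(spec$factors), function(nm) {
    idx <- match(df[[nm]], spec$factors[[nm]]) - 1L
    bad <- !is.na(df[[nm]]) & is.na(idx)
    if (any(bad))
      stop(sprintf("unknown category '%s' for factor '%s'",
                   df[[nm]][bad][1], nm))
    idx[is.na(idx)] <- -1L
    idx
  })
  labels <- matrix(as.integer(labels), nrow = nrow(df),
                   dimnames = list(cell_ids, names(spec$factors)))
  label_table(labels, factor_names = names(spec$factors),
              cell_ids = cell_ids, n_cats = n_categories(spec))
}

#' @rdname read_label_table
#' @param lt A [label_table()] to write.
#' @export
write_label_table <- function(lt, path, spec) {
  stopifnot(inherits(lt, "label_table"))
  cols <- lapply(seq_along(spec$factors), function(j) {
    v <- rep(NA_character_, nrow(lt$labels))
    sel <- lt$mask[, j] == 1L
    v[sel] <- spec$factors[[j]][lt$labels[sel, j] + 1L]
    v
  })
  names(cols) <- names(spec$factors)
  df <- data.frame(cell_id = rownames(lt$labels) %||%
                     paste0("cell_", seq_len(nrow(lt$labels))),
                   cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
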