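#' Read single-cell counts with cell and gene metadata
#'
#' Reads a genes x cells counts matrix in MatrixMarket sparse format (with
#' companion gene and cell metadata TSVs) or as a dense TSV with gene symbols
#' in the first column and cell ids as header. Duplicate gene symbols are
#' collapsed by summing their rows.
#'
#' The cell metadata must carry `cell_id`, `sample_id`, `cell_type` and
#' `class` columns; `class` is the per-sample binary label (1 = target /
#' disease, 0 = base / control) and must be constant within a sample.
#'
#' @param counts_path Path to `.mtx` or dense `.tsv` counts.
#' @param cells_meta_path Path to the cell metadata TSV. Required for `.mtx`;
#'   for dense TSV it may be omitted if not needed downstream.
#' @param genes_meta_path Path to a one-column (or first-column) TSV of gene
#'   symbols aligned with matrix rows. Required for `.mtx`.
#' @return A list with `counts` (a `dgCMatrix`, genes x cells) and `cells`
#'   (a tibble of cell annotations in matrix column order).
#' @export
read_counts <- function(counts_path, cells_meta_path = NULL, genes_meta_path = NULL) {
  is_mtx <- grepl("\\.mtx$", counts_path, ignore.case = TRUE)
  if (is_mtx) {
    if (is.null(cells_meta_path) || is.null(genes_meta_path)) {
      abort("MatrixMarket input requires `cells_meta_path` and `genes_meta_path`.")
    }
    m <- methods::as(Matrix::readMM(counts_path), "CsparseMatrix")
    genes <- readr::read_tsv(genes_meta_path, col_types = readr::cols(), progress = FALSE)
    cells <- readr::read_tsv(cells_meta_path, col_types = readr::cols(), progress = FALSE)
    if (nrow(genes) != nrow(m)) {
      abort(paste0(
        "Gene metadata (", genes_meta_path, ") has ", nrow(genes),
        " rows but the matrix has ", nrow(m), " rows."
      ))
    }
    if (nrow(cells) != ncol(m)) {
      abort(paste0(
        "Cell metadata (", cells_meta_path, ") has ", nrow(cells),
        " rows but the matrix has ", ncol(m), " columns."
      ))
    }
    rownames(m) <- toupper(genes[[1]])
    colnames(m) <- as.character(cells[[1]])
    if (Matrix::nnzero(m) == 0) {
      warn("Counts matrix has no nonzero entries.")
    }
  } else {
    dense <- readr::read_tsv(counts_path, col_types = readr::cols(), progress = FALSE)
    m <- as.matrix(dense[, -1, drop = FALSE])
    rownames(m) <- toupper(as.character(dense[[1]]))
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    cells <- if (!is.null(cells_meta_path)) {
      readr::read_tsv(cells_meta_path, col_types = readr::cols(), progress = FALSE)
    } else {
      tibble(cell_id = colnames(m))
    }
    if (nrow(cells) != ncol(m)) {
      abort(paste0(
        "Cell metadata (", cells_meta_path %||% "<none>", ") has ", nrow(cells),
        " rows but the matrix has ", ncol(m), " columns."
      ))
    }
  }
  m <- collapse_duplicate_genes(m)
  cells <- validate_cell_annotation(cells)
  list(counts = m, cells = cells)
}

collapse_duplicate_genes <- function(m) {
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    inform(paste0(
      "Collapsing ", length(dups), " duplicated gene symbol(s) by sum: ",
      paste(head(dups, 5), collapse = ", ")
    ))
    groups <- factor(rownames(m), levels = unique(rownames(m)))
    agg <- Matrix::sparseMatrix(
      i = as.integer(groups), j = seq_along(groups), x = 1,
      dims = c(nlevels(groups), length(groups))
    )
    m2 <- agg %*% m
    rownames(m2) <- levels(groups)
    colnames(m2) <- colnames(m)
    m <- methods::as(m2, "CsparseMatrix")
  }
  m
}

validate_cell_annotation <- function(cells) {
  cells <- as_tibble(cells)
  names(cells)[1] <- "cell_id"
  needed <- c("cell_id", "sample_id", "cell_type", "class")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("Cell metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(cells$class %in% c(0, 1))) {
    bad <- unique(cells$class[!cells$class %in% c(0, 1)])
    abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", "), "; expected 0/1."))
  }
  per_sample <- cells |>
    distinct(.data$sample_id, .data$class) |>
    count(.data$sample_id)
  if (any(per_sample$n > 1)) {
    abort("A sample carries more than one class label.")
  }
  cells$class <- as.integer(cells$class)
  cells
}

#' Read a one-to-one ortholog map
#'
#' Three-column TSV: `human_symbol`, `model_symbol`, `one_to_one` (0/1). Human
#' symbols are uppercased; model symbols kept as-is. Rows flagged one-to-one
#' must be unique in both symbol columns.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `human_symbol`, `model_symbol`, `one_to_one`
#'   (logical).
#' @export
read_ortholog_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(x)[1:3] <- c("human_symbol", "model_symbol", "one_to_one")
  x <- x |>
    mutate(
      human_symbol = toupper(.data$human_symbol),
      one_to_one = as.logical(as.integer(.data$one_to_one))
    )
  oo <- x |> filter(.data$one_to_one)
  if (anyDuplicated(oo$human_symbol) || anyDuplicated(oo$model_symbol)) {
    abort("Ortholog map flags a symbol one-to-one in more than one record.")
  }
  x
}

#' Read a human-to-model cell-type map
#'
#' Two-column TSV: `human_cell_type`, `model_cell_type`; the keyword `ABSENT`
#' (or an empty field) marks a human cell type with no counterpart in the
#' disease model.
#'
#' @param path Path to the TSV.
#' @return Tibble with `human_cell_type` and `model_cell_type` (`NA` when
#'   absent).
#' @export
read_celltype_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(x)[1:2] <- c("human_cell_type", "model_cell_type")
  if (anyDuplicated(x$human_cell_type)) {
    abort("Cell-type map lists a human cell type more than once.")
  }
  x |>
    mutate(
      model_cell_type = ifelse(
        is.na(.data$model_cell_type) | .data$model_cell_type %in% c("ABSENT", ""),
        NA_character_, .data$model_cell_type
      )
    )
}

#' Read a precomputed fold-change table
#'
#' Alternative to computing fold changes from model counts: a TSV with
#' columns `cell_type` (model nomenclature), `model_gene`, `log2FC`, `adj_p`.
#' The significance gate is applied on read.
#'
#' @param path Path to the TSV.
#' @param gate Adjusted p-value threshold below/at which the fold change is
#'   kept; above it the gated value `r` is 0.
#' @return A fold-change tibble with columns `cell_type`, `gene`, `log2fc`,
#'   `adj_p`, `r`, `reason`.
#' @export
read_fc_table <- function(path, gate = 0.05) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(x)[1:4] <- c("cell_type", "gene", "log2fc", "adj_p")
  gate_fold_changes(as_tibble(x[, 1:4]), gate = gate)
}

# Shared gating step (Eq.-style rule): r = log2fc iff adj_p <= gate else 0.
gate_fold_changes <- function(fc, gate = 0.05) {
  fc |>
    mutate(
      r = ifelse(!is.na(.data$adj_p) & .data$adj_p <= gate, .data$log2fc, 0),
      reason = case_when(
        is.na(.data$adj_p) ~ "untested",
        .data$adj_p <= gate ~ "significant",
        TRUE ~ "not_significant"
      )
    )
}

#' Write and read pseudobulk blocks as plain TSV
#'
#' Serializes a block container to a directory of full-precision TSVs (one
#' per cell type plus a sample table) and reads it back. Round-tripping
#' reproduces values exactly.
#'
#' @param blocks A `pb_blocks` object.
#' @param dir Directory to write into (created if needed).
#' @return `write_blocks` returns `dir` invisibly; `read_blocks` returns a
#'   `pb_blocks` object.
#' @export
write_blocks <- function(blocks, dir) {
  stopifnot(inherits(blocks, "pb_blocks"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(blocks$samples, file.path(dir, "samples.tsv"))
  for (ct in names(blocks$blocks)) {
    m <- blocks$blocks[[ct]]
    # %.17g guarantees binary round-trip of doubles through text
    df <- as_tibble(
      `dimnames<-`(matrix(sprintf("%.17g", m), nrow(m)), dimnames(m)),
      rownames = "sample_id"
    )
    readr::write_tsv(df, file.path(dir, paste0("block_", ct, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(dir) {
  samples <- readr::read_tsv(
    file.path(dir, "samples.tsv"),
    col_types = readr::cols(sample_id = readr::col_character()), progress = FALSE
  )
  files <- list.files(dir, pattern = "^block_.*\\.tsv$", full.names = TRUE)
  cts <- sub("^block_(.*)\\.tsv$", "\\1", basename(files))
  blocks <- map(files, function(f) {
    df <- readr::read_tsv(
      f, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    # parse through strtod (correctly rounded) so %.17g output round-trips
    m <- vapply(df[-1], as.numeric, numeric(nrow(df)))
    rownames(m) <- df$sample_id
    m[samples$sample_id, , drop = FALSE]
  })
  names(blocks) <- cts
  pb_blocks(blocks, samples)
}
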