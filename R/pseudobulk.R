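#' Pseudobulk block container
#'
#' Low-level constructor for the per-cell-type pseudobulk matrices consumed
#' by the multi-block model. All blocks share one sample order; values are
#' log2 of library-size-normalized pooled counts (unitless).
#'
#' @param blocks Named list of numeric matrices (samples x genes) with
#'   identical rownames in identical order.
#' @param samples Tibble with `sample_id` and `class` (0/1) in block row
#'   order.
#' @return An object of class `pb_blocks`.
#' @export
pb_blocks <- function(blocks, samples) {
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "class") %in% names(samples)))
  if (length(blocks) == 0) {
    abort("No blocks supplied.")
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("`blocks` must be a named list keyed by cell type.")
  }
  for (ct in names(blocks)) {
    m <- blocks[[ct]]
    if (!is.matrix(m) || !is.numeric(m)) {
      abort(paste0("Block '", ct, "' is not a numeric matrix."))
    }
    if (!identical(rownames(m), samples$sample_id)) {
      abort(paste0("Block '", ct, "' rows do not match the sample table order."))
    }
    if (anyNA(m)) {
      abort(paste0("Block '", ct, "' contains missing values."))
    }
  }
  structure(
    list(blocks = blocks, samples = samples),
    class = "pb_blocks"
  )
}

#' @export
print.pb_blocks <- function(x, ...) {
  cat(
    "<pb_blocks> ", nrow(x$samples), " samples, ", length(x$blocks),
    " cell-type blocks\n",
    sep = ""
  )
  for (ct in names(x$blocks)) {
    cat("  ", ct, ": ", ncol(x$blocks[[ct]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method as_tibble pb_blocks
as_tibble.pb_blocks <- function(x, ...) {
  imap(x$blocks, function(m, ct) {
    as_tibble(m, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "gene", values_to = "value") |>
      mutate(cell_type = ct, .after = "sample_id")
  }) |>
    bind_rows() |>
    left_join(x$samples, by = "sample_id")
}

# Subset a pb_blocks to a sample subset (order preserved).
subset_samples <- function(blocks, keep) {
  idx <- which(blocks$samples$sample_id %in% keep)
  pb_blocks(
    map(blocks$blocks, ~ .x[idx, , drop = FALSE]),
    blocks$samples[idx, ]
  )
}

#' Aggregate single-cell counts to pseudobulk blocks
#'
#' For each (sample, cell type) pair: sum raw counts over cells, library-size
#' normalize the pooled profile to `norm_target`, then transform to
#' `log2(1 + x)`. One block per cell type, samples x genes, shared sample
#' order. A cell type with fewer than `min_cells` cells in any sample is
#' dropped for the whole dataset (too unstable to aggregate); a cell type
#' absent from all samples is dropped with a warning.
#'
#' @param counts Genes x cells counts (`dgCMatrix` or dense matrix) with gene
#'   symbols as rownames and cell ids as colnames.
#' @param cells Cell annotation tibble with `cell_id`, `sample_id`,
#'   `cell_type`, `class` (see [read_counts()]).
#' @param norm_target Library size each pooled profile is scaled to before
#'   the log transform (counts; default 1e4).
#' @param min_cells Minimum cells per (sample, cell type); default 10.
#' @return A [pb_blocks] object over all measured genes.
#' @export
build_pseudobulk <- function(counts, cells, norm_target = 1e4, min_cells = 10) {
  cells <- validate_cell_annotation(cells)
  if (!all(cells$cell_id %in% colnames(counts))) {
    abort("Some annotated cells are missing from the counts matrix.")
  }
  counts <- counts[, cells$cell_id, drop = FALSE]
  samples <- cells |>
    distinct(.data$sample_id, .data$class) |>
    arrange(.data$sample_id)
  cts <- sort(unique(cells$cell_type))

  tally <- cells |> count(.data$sample_id, .data$cell_type)
  keep_ct <- character(0)
  for (ct in cts) {
    n_by_sample <- tally |> filter(.data$cell_type == ct)
    present <- samples$sample_id %in% n_by_sample$sample_id
    if (!any(present)) {
      warn(paste0("Cell type '", ct, "' absent from all samples; dropped."))
      next
    }
    counts_per_sample <- samples |>
      left_join(n_by_sample, by = "sample_id") |>
      mutate(n = tidyr::replace_na(.data$n, 0L))
    if (any(counts_per_sample$n < min_cells)) {
      warn(paste0(
        "Cell type '", ct, "' has fewer than ", min_cells,
        " cells in at least one sample; dropped."
      ))
      next
    }
    keep_ct <- c(keep_ct, ct)
  }
  if (length(keep_ct) == 0) {
    abort("No cell type passes the minimum-cells filter.")
  }

  blocks <- map(setNames(keep_ct, keep_ct), function(ct) {
    cell_sub <- cells |> filter(.data$cell_type == ct)
    # pooled counts per sample: genes x samples
    groups <- factor(cell_sub$sample_id, levels = samples$sample_id)
    agg <- Matrix::sparseMatrix(
      i = seq_len(nrow(cell_sub)), j = as.integer(groups), x = 1,
      dims = c(nrow(cell_sub), nrow(samples))
    )
    pooled <- as.matrix(counts[, cell_sub$cell_id, drop = FALSE] %*% agg)
    colnames(pooled) <- samples$sample_id
    libs <- colSums(pooled)
    libs[libs == 0] <- 1  # all-zero profile stays all-zero after scaling
    normalized <- sweep(pooled, 2, norm_target / libs, `*`)
    t(log2(1 + normalized))
  })
  pb_blocks(blocks, samples)
}

#' Restrict pseudobulk blocks to a superpathway
#'
#' Keeps, per cell type, exactly the genes of the superpathway subset that
#' were measured; unmeasured genes are dropped from the subset (not
#' zero-filled) with a message. Blocks whose entire gene subset is unmeasured
#' are dropped with a warning; if no block survives, that is an error.
#'
#' @param blocks [pb_blocks] over all measured genes.
#' @param sp A [superpathway].
#' @return A [pb_blocks] restricted to the superpathway, block per cell type
#'   of `sp` present in `blocks`.
#' @export
assemble_superpathway_blocks <- function(blocks, sp) {
  stopifnot(inherits(blocks, "pb_blocks"), inherits(sp, "superpathway"))
  out <- list()
  for (ct in names(sp$gene_sets)) {
    if (!ct %in% names(blocks$blocks)) {
      warn(paste0("Cell type '", ct, "' not present in pseudobulk; block dropped."))
      next
    }
    measured <- colnames(blocks$blocks[[ct]])
    wanted <- sp$gene_sets[[ct]]
    have <- wanted[wanted %in% measured]
    dropped <- setdiff(wanted, have)
    if (length(dropped) > 0) {
      inform(paste0(
        "Block '", ct, "': dropping ", length(dropped),
        " unmeasured gene(s): ", paste(head(dropped, 5), collapse = ", ")
      ))
    }
    if (length(have) == 0) {
      warn(paste0("Block '", ct, "': no superpathway gene measured; block dropped."))
      next
    }
    out[[ct]] <- blocks$blocks[[ct]][, have, drop = FALSE]
  }
  if (length(out) == 0) {
    abort("All superpathway blocks are empty after intersecting with measured genes.")
  }
  pb_blocks(out, blocks$samples)
}
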