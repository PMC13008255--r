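#' Per-gene, per-cell-type disease-model fold changes
#'
#' For each mapped model cell type and each gene of its pathway subset,
#' computes the log2 fold change between target- and base-class cells as the
#' difference of mean `log2(count + 1)` (the log2 ratio of geometric means of
#' counts + 1), a two-sided Wilcoxon rank-sum p-value on the per-cell
#' `log2(count + 1)` values, and a Benjamini-Hochberg adjustment within each
#' cell type. Fold changes with adjusted p-value above `gate` are gated to
#' zero; a cell type with fewer than 3 cells per class in a gene's data has
#' all its genes gated with a reason code.
#'
#' @param counts Genes x cells counts of the disease model (model gene
#'   symbols as rownames).
#' @param cells Model cell annotation tibble (`cell_id`, `sample_id`,
#'   `cell_type`, `class`).
#' @param gene_sets Named list: model cell type -> character vector of model
#'   gene symbols to test.
#' @param gate Adjusted p-value threshold (default 0.05).
#' @return A fold-change tibble: `cell_type`, `gene`, `log2fc`, `p_value`,
#'   `adj_p`, `r` (gated value), `reason`.
#' @export
compute_fold_changes <- function(counts, cells, gene_sets, gate = 0.05) {
  cells <- validate_cell_annotation(cells)
  out <- imap(gene_sets, function(genes, ct) {
    ct_cells <- cells |> filter(.data$cell_type == ct)
    genes <- genes[genes %in% rownames(counts)]
    missing <- setdiff(gene_sets[[ct]], genes)
    rows <- list()
    if (length(missing) > 0) {
      rows$missing <- tibble(
        cell_type = ct, gene = missing, log2fc = NA_real_, p_value = NA_real_,
        adj_p = NA_real_, r = 0, reason = "not_sequenced"
      )
    }
    if (length(genes) == 0) {
      return(bind_rows(rows))
    }
    tgt <- ct_cells$cell_id[ct_cells$class == 1]
    base <- ct_cells$cell_id[ct_cells$class == 0]
    if (length(tgt) < 3 || length(base) < 3) {
      warn(paste0(
        "Cell type '", ct, "' has fewer than 3 cells in a class; ",
        "all fold changes gated to 0."
      ))
      rows$tested <- tibble(
        cell_type = ct, gene = genes, log2fc = NA_real_, p_value = NA_real_,
        adj_p = NA_real_, r = 0, reason = "insufficient_cells"
      )
      return(bind_rows(rows))
    }
    lt <- log2(1 + as.matrix(counts[genes, tgt, drop = FALSE]))
    lb <- log2(1 + as.matrix(counts[genes, base, drop = FALSE]))
    log2fc <- rowMeans(lt) - rowMeans(lb)
    p <- vapply(seq_along(genes), function(k) {
      if (all(lt[k, ] == lt[k, 1]) && all(lb[k, ] == lb[k, 1]) &&
        lt[k, 1] == lb[k, 1]) {
        return(1)
      }
      suppressWarnings(wilcox.test(lt[k, ], lb[k, ], exact = FALSE)$p.value)
    }, numeric(1))
    rows$tested <- tibble(
      cell_type = ct, gene = genes, log2fc = unname(log2fc),
      p_value = p, adj_p = bh_adjust(p)
    ) |>
      gate_fold_changes(gate = gate)
    bind_rows(rows)
  })
  bind_rows(out)
}

#' In-silico treatment of base-class samples
#'
#' Injects the gated disease-model fold changes into the human base-class
#' pseudobulk: `x' = x + r` where the human cell type maps to a model cell
#' type AND the gene has a one-to-one ortholog observed in the model;
#' everywhere else `x' = x` (the no-op case covers unmapped cell types,
#' missing orthologs, unsequenced genes and non-significant fold changes,
#' whose gated `r` is zero).
#'
#' @param base_blocks [pb_blocks] holding base-class samples only.
#' @param fc Fold-change tibble (model space) from [compute_fold_changes()]
#'   or [read_fc_table()].
#' @param orthology Ortholog map tibble (see [read_ortholog_map()]).
#' @param celltype_map Cell-type map tibble (see [read_celltype_map()]).
#' @return A list: `blocks` (treated [pb_blocks], human symbols and sample
#'   order preserved) and `log` (tibble per human (cell_type, gene):
#'   `model_cell_type`, `model_gene`, `r`, `reason`).
#' @export
apply_treatment <- function(base_blocks, fc, orthology, celltype_map) {
  stopifnot(inherits(base_blocks, "pb_blocks"))
  if (any(base_blocks$samples$class != 0)) {
    abort("`base_blocks` must contain base-class (class 0) samples only.")
  }
  oo <- orthology |> filter(.data$one_to_one)
  log_rows <- list()
  treated <- base_blocks$blocks
  for (ct in names(treated)) {
    model_ct <- celltype_map$model_cell_type[celltype_map$human_cell_type == ct]
    model_ct <- if (length(model_ct) == 1) model_ct else NA_character_
    genes <- colnames(treated[[ct]])
    entry <- tibble(
      cell_type = ct, gene = genes,
      model_cell_type = model_ct,
      model_gene = oo$model_symbol[match(genes, oo$human_symbol)],
      r = 0, reason = NA_character_
    )
    if (is.na(model_ct)) {
      entry$reason <- "unmapped_cell_type"
    } else {
      entry$reason <- ifelse(is.na(entry$model_gene), "no_ortholog", NA)
      fc_ct <- fc |> filter(.data$cell_type == model_ct)
      hit <- match(entry$model_gene, fc_ct$gene)
      found <- !is.na(entry$model_gene) & !is.na(hit)
      entry$r[found] <- fc_ct$r[hit[found]]
      entry$reason[found] <- fc_ct$reason[hit[found]]
      entry$reason[!is.na(entry$model_gene) & is.na(hit)] <- "not_sequenced"
    }
    treated[[ct]] <- sweep(treated[[ct]], 2, entry$r, `+`)
    log_rows[[ct]] <- entry
  }
  list(
    blocks = pb_blocks(treated, base_blocks$samples),
    log = bind_rows(log_rows)
  )
}

#' Human reference recapitulation
#'
#' The reference shift of the superpathway: the median predicted score of
#' target-class samples minus the median of base-class samples, and the
#' analogous per-cell-type shifts on the gamma contributions.
#'
#' @param decomp A [decompose()] result over all human samples.
#' @param y Binary class labels aligned with the decomposition's samples.
#' @param eps Magnitudes below `eps` flag the reference as degenerate (its
#'   fractions are meaningless).
#' @return List with `omega` (scalar), `gamma` (tibble `cell_type`,
#'   `gamma_ref`, `degenerate`), `degenerate` (flag on omega).
#' @export
reference_recapitulation <- function(decomp, y, eps = 1e-8) {
  stopifnot(inherits(decomp, "score_decomposition"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  ids <- decomp$scores$sample_id
  omega <- median(decomp$scores$score[y == 1]) -
    median(decomp$scores$score[y == 0])
  cls <- tibble(sample_id = ids, .y = y)
  gamma <- decomp$gamma |>
    left_join(cls, by = "sample_id") |>
    group_by(.data$cell_type) |>
    summarise(
      gamma_ref = median(.data$gamma[.data$.y == 1]) -
        median(.data$gamma[.data$.y == 0]),
      .groups = "drop"
    ) |>
    mutate(degenerate = abs(.data$gamma_ref) < eps)
  list(omega = omega, gamma = gamma, degenerate = abs(omega) < eps)
}

#' Predicted recapitulation of the in-silico-treated samples
#'
#' Scores treated and untreated base-class samples under the same fitted
#' model and takes median differences: the superpathway-level predicted
#' shift, the per-cell-type shifts, and the per-gene delta contributions of
#' both states.
#'
#' @param model The fitted `asmbplsda` (unmodified step-1 fit).
#' @param base_blocks Untreated base-class [pb_blocks].
#' @param treated_blocks Treated [pb_blocks] from [apply_treatment()].
#' @return List with `omega_pred`, `gamma` (tibble `cell_type`,
#'   `gamma_pred`), `delta_base`, `delta_treated` (decomposition tibbles).
#' @export
predicted_recapitulation <- function(model, base_blocks, treated_blocks) {
  d0 <- decompose(model, base_blocks)
  d1 <- decompose(model, treated_blocks)
  omega_pred <- median(d1$scores$score) - median(d0$scores$score)
  gamma <- d0$gamma |>
    rename(gamma0 = "gamma") |>
    left_join(d1$gamma |> rename(gamma1 = "gamma"),
      by = c("sample_id", "cell_type")
    ) |>
    group_by(.data$cell_type) |>
    summarise(
      gamma_pred = median(.data$gamma1) - median(.data$gamma0),
      .groups = "drop"
    )
  list(
    omega_pred = omega_pred, gamma = gamma,
    delta_base = d0$delta, delta_treated = d1$delta
  )
}

#' Assemble the recapitulation report
#'
#' Joins reference and predicted recapitulation into the fraction form:
#' superpathway fraction `100 * omega_pred / omega_ref`, cell-type fractions
#' `100 * gamma_pred_b / gamma_ref_b`, and signed per-gene contributions
#' `100 * delta_gb / gamma_ref_b`, where `delta_gb` is the (sample-constant)
#' difference between treated and untreated gene contributions. Degenerate
#' references yield `NA` fractions, never infinities. Fractions may exceed
#' +/-100 when the disease model overshoots the human shift.
#'
#' @param ref Result of [reference_recapitulation()].
#' @param pred Result of [predicted_recapitulation()].
#' @param treatment_log The `log` tibble from [apply_treatment()].
#' @param pathway_id Pathway label carried into the report.
#' @param tol Maximum allowed across-sample variation of `delta_gb` (a
#'   consistency guard; exceeding it is an error).
#' @return An object of class `recap_report`: list of tibbles `pathway`
#'   (one row: reference, predicted, fraction, degenerate flag, orthology
#'   coverage), `cell_types`, `genes` (with reason codes).
#' @export
recapitulation_report <- function(ref, pred, treatment_log, pathway_id = "pathway",
                                  tol = 1e-10) {
  delta <- pred$delta_base |>
    rename(delta0 = "delta") |>
    left_join(
      pred$delta_treated |> rename(delta1 = "delta"),
      by = c("sample_id", "cell_type", "gene")
    ) |>
    mutate(d = .data$delta1 - .data$delta0) |>
    group_by(.data$cell_type, .data$gene) |>
    summarise(
      delta_gb = .data$d[1],
      spread = max(.data$d) - min(.data$d),
      .groups = "drop"
    )
  if (any(delta$spread > tol)) {
    abort("Per-gene treatment increments vary across samples beyond tolerance.")
  }
  gamma <- ref$gamma |>
    left_join(pred$gamma, by = "cell_type") |>
    mutate(
      fraction = ifelse(.data$degenerate, NA_real_,
        100 * .data$gamma_pred / .data$gamma_ref
      )
    )
  genes <- delta |>
    select(-"spread") |>
    left_join(ref$gamma, by = "cell_type") |>
    mutate(
      fraction = ifelse(.data$degenerate, NA_real_,
        100 * .data$delta_gb / .data$gamma_ref
      )
    ) |>
    select(-"degenerate") |>
    left_join(
      treatment_log |>
        select("cell_type", "gene", "model_cell_type", "model_gene", "r", "reason"),
      by = c("cell_type", "gene")
    )
  coverage <- treatment_log |>
    group_by(.data$cell_type) |>
    summarise(
      orthology_coverage = 100 * mean(!is.na(.data$model_gene)),
      .groups = "drop"
    )
  pathway <- tibble(
    pathway_id = pathway_id,
    omega_ref = ref$omega,
    omega_pred = pred$omega_pred,
    fraction = ifelse(ref$degenerate, NA_real_, 100 * pred$omega_pred / ref$omega),
    degenerate = ref$degenerate,
    orthology_coverage = mean(coverage$orthology_coverage)
  )
  structure(
    list(
      pathway = pathway,
      cell_types = gamma |> left_join(coverage, by = "cell_type"),
      genes = genes
    ),
    class = "recap_report"
  )
}

#' @export
print.recap_report <- function(x, ...) {
  p <- x$pathway
  cat(
    "<recap_report> ", p$pathway_id, ": superpathway recapitulation ",
    ifelse(is.na(p$fraction), "undefined (degenerate reference)",
      paste0(round(p$fraction, 1), "%")
    ),
    "\n",
    sep = ""
  )
  print(x$cell_types |> select("cell_type", "gamma_ref", "gamma_pred", "fraction"))
  invisible(x)
}

#' @export
#' @method tidy recap_report
tidy.recap_report <- function(x, ...) {
  bind_rows(
    x$pathway |>
      transmute(
        level = "superpathway", pathway_id = .data$pathway_id,
        cell_type = NA_character_, gene = NA_character_,
        reference = .data$omega_ref, predicted = .data$omega_pred,
        fraction = .data$fraction, reason = NA_character_
      ),
    x$cell_types |>
      transmute(
        level = "cell_type", pathway_id = x$pathway$pathway_id,
        cell_type = .data$cell_type, gene = NA_character_,
        reference = .data$gamma_ref, predicted = .data$gamma_pred,
        fraction = .data$fraction, reason = NA_character_
      ),
    x$genes |>
      transmute(
        level = "gene", pathway_id = x$pathway$pathway_id,
        cell_type = .data$cell_type, gene = .data$gene,
        reference = .data$gamma_ref, predicted = .data$delta_gb,
        fraction = .data$fraction, reason = .data$reason
      )
  )
}

#' @export
#' @method glance recap_report
glance.recap_report <- function(x, ...) {
  x$pathway
}

#' @export
#' @method autoplot recap_report
autoplot.recap_report <- function(object, ...) {
  df <- object$cell_types |>
    mutate(fraction = tidyr::replace_na(.data$fraction, 0))
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$cell_type, y = .data$fraction, fill = .data$fraction > 0)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = c("solid", "dashed")) +
    ggplot2::labs(
      x = NULL, y = "cell-type recapitulation (%)",
      title = object$pathway$pathway_id,
      subtitle = paste0(
        "superpathway: ",
        ifelse(is.na(object$pathway$fraction), "undefined",
          paste0(round(object$pathway$fraction, 1), "%")
        )
      )
    ) +
    ggplot2::theme_minimal()
}

#' Gene-contribution plot for one report
#'
#' Horizontal bars of signed per-gene percentage contributions to each
#' cell-type recapitulation, faceted by cell type; the top `n` genes by
#' absolute contribution are shown.
#'
#' @param report A `recap_report`.
#' @param n Genes per cell type to display.
#' @return A ggplot object.
#' @export
plot_gene_contributions <- function(report, n = 10) {
  df <- report$genes |>
    filter(!is.na(.data$fraction), .data$fraction != 0) |>
    group_by(.data$cell_type) |>
    slice_max(abs(.data$fraction), n = n) |>
    ungroup()
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$fraction, y = stats::reorder(.data$gene, .data$fraction),
      fill = .data$fraction > 0
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = "gene contribution to cell-type recapitulation (%)", y = NULL) +
    ggplot2::theme_minimal()
}
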