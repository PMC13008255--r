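#' End-to-end recapitulation run
#'
#' Wires the full pipeline for every (superpathway, disease model) pair:
#' assemble superpathway blocks, tune the multi-block sparse PLS-DA by
#' leave-one-out cross-validation, run the permutation validity test,
#' compute importance projections, apply each model's in-silico treatment to
#' the base-class samples and report recapitulation fractions. Pathway
#' p-values are adjusted across superpathways by Benjamini-Hochberg;
#' fractions of pathways failing the validity gate are suppressed (set to
#' `NA`) in the headline table but all raw results are retained. A hard
#' failure in one pair aborts only that pair.
#'
#' @param pseudobulk [pb_blocks] over all measured human genes (or an
#'   already-restricted block set if `superpathways` gene sets match it).
#' @param superpathways List of [superpathway] objects.
#' @param models Named list of disease models, each a list with elements
#'   `fc`, `orthology`, `celltype_map` (as from [simulate_model()] or the
#'   readers).
#' @param J_grid,lambda_values,expand Tuning grids (see [tune_asmbplsda()]).
#' @param n_perm Permutations for the validity test.
#' @param alpha Confidence threshold of the validity test.
#' @param fdr False discovery rate for the across-pathway gate.
#' @param seed Integer seed for permutation draws.
#' @param gip Also run the (slower) per-gene importance significance test.
#' @param outdir Optional directory for TSV reports and a JSON manifest.
#' @return Object of class `recap_run`: list with `headline` (tibble pathway
#'   x model), `validity` (tibble with p, adjusted p, pass), `pathways`
#'   (per-pathway details: cv fit, permutation test, importance, reports per
#'   model), `failures` (tibble) and `manifest`.
#' @export
run_recapitulation <- function(pseudobulk, superpathways, models,
                               J_grid = 1:3,
                               lambda_values = c(0, 0.5, 0.9),
                               expand = FALSE,
                               n_perm = 1000, alpha = 0.05, fdr = 0.1,
                               seed = 1, gip = FALSE, outdir = NULL) {
  stopifnot(inherits(pseudobulk, "pb_blocks"))
  if (inherits(superpathways, "superpathway")) superpathways <- list(superpathways)
  names(superpathways) <- map_chr(superpathways, "pathway_id")
  if (is.null(names(models))) {
    names(models) <- paste0("model", seq_along(models))
  }
  failures <- list()
  pathways <- list()
  for (sp in superpathways) {
    pid <- sp$pathway_id
    res <- tryCatch(
      run_one_pathway(
        pseudobulk, sp, models, J_grid, lambda_values, expand,
        n_perm, alpha, seed, gip
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[pid]] <- tibble(
        pathway_id = pid, model = NA_character_,
        message = conditionMessage(res)
      )
      next
    }
    failures <- c(failures, res$failures)
    res$failures <- NULL
    pathways[[pid]] <- res
  }
  if (length(pathways) == 0) {
    abort("Every superpathway failed; nothing to report.")
  }
  validity <- map(pathways, function(res) {
    tibble(
      pathway_id = res$pathway_id,
      observed_error = res$perm$observed_error,
      p_value = res$perm$p_value,
      better_than_null = res$perm$better_than_null
    )
  }) |>
    bind_rows() |>
    mutate(
      adj_p = bh_adjust(.data$p_value),
      pass = .data$adj_p <= fdr & .data$better_than_null
    )
  headline <- map(pathways, function(res) {
    map(names(res$reports), function(mod) {
      rep <- res$reports[[mod]]
      tibble(
        pathway_id = res$pathway_id, model = mod,
        omega_ref = rep$pathway$omega_ref,
        omega_pred = rep$pathway$omega_pred,
        fraction = rep$pathway$fraction,
        orthology_coverage = rep$pathway$orthology_coverage
      )
    }) |>
      bind_rows()
  }) |>
    bind_rows() |>
    left_join(validity |> select("pathway_id", "adj_p", "pass"), by = "pathway_id") |>
    mutate(fraction = ifelse(.data$pass, .data$fraction, NA_real_))
  manifest <- list(
    package_version = as.character(utils::packageVersion("screcap")),
    seed = seed, n_perm = n_perm, alpha = alpha, fdr = fdr,
    J_grid = J_grid, lambda_values = lambda_values,
    n_pathways = length(pathways), models = names(models),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- structure(
    list(
      headline = headline, validity = validity, pathways = pathways,
      failures = bind_rows(failures), manifest = manifest
    ),
    class = "recap_run"
  )
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

run_one_pathway <- function(pseudobulk, sp, models, J_grid, lambda_values,
                            expand, n_perm, alpha, seed, gip) {
  blocks <- assemble_superpathway_blocks(pseudobulk, sp)
  y <- blocks$samples$class
  cv <- tune_asmbplsda(
    blocks, y,
    J_grid = J_grid, lambda_values = lambda_values, expand = expand
  )
  perm <- permutation_validity_test(
    blocks, y,
    J = cv$best$J, lambda = cv$best$lambda,
    n_perm = n_perm, seed = seed, alpha = alpha
  )
  importance <- compute_cip_gip(cv$model)
  gip_sig <- if (gip) {
    gip_significance(blocks, y, cv$model, n_perm = max(50, n_perm %/% 10), seed = seed)
  } else {
    NULL
  }
  decomp <- decompose(cv$model, blocks)
  ref <- reference_recapitulation(decomp, y)
  base_blocks <- subset_samples(blocks, blocks$samples$sample_id[y == 0])
  reports <- list()
  failures <- list()
  for (mod in names(models)) {
    res <- tryCatch(
      {
        trt <- apply_treatment(
          base_blocks, models[[mod]]$fc,
          models[[mod]]$orthology, models[[mod]]$celltype_map
        )
        pred <- predicted_recapitulation(cv$model, base_blocks, trt$blocks)
        recapitulation_report(ref, pred, trt$log, pathway_id = sp$pathway_id)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[paste(sp$pathway_id, mod)]] <- tibble(
        pathway_id = sp$pathway_id, model = mod,
        message = conditionMessage(res)
      )
    } else {
      reports[[mod]] <- res
    }
  }
  list(
    pathway_id = sp$pathway_id, cv = cv, perm = perm,
    importance = importance, gip_significance = gip_sig,
    reference = ref, reports = reports, failures = failures
  )
}

write_run <- function(run, outdir) {
  dir.create(file.path(outdir, "reports"), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$headline, file.path(outdir, "reports", "headline.tsv"))
  readr::write_tsv(run$validity, file.path(outdir, "reports", "validity.tsv"))
  for (pid in names(run$pathways)) {
    res <- run$pathways[[pid]]
    for (mod in names(res$reports)) {
      readr::write_tsv(
        tidy(res$reports[[mod]]),
        file.path(outdir, "reports", paste0(pid, "__", mod, ".tsv"))
      )
    }
    readr::write_tsv(
      tidy(res$importance),
      file.path(outdir, "reports", paste0(pid, "__importance.tsv"))
    )
  }
  if (nrow(run$failures) > 0) {
    readr::write_tsv(run$failures, file.path(outdir, "reports", "failures.tsv"))
  }
  jsonlite::write_json(
    run$manifest, file.path(outdir, "manifest.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(outdir)
}

#' @export
print.recap_run <- function(x, ...) {
  cat("<recap_run> ", length(x$pathways), " pathway(s)\n", sep = "")
  print(x$headline)
  invisible(x)
}

#' @export
#' @method tidy recap_run
tidy.recap_run <- function(x, ...) {
  x$headline
}

#' @export
#' @method autoplot recap_run
autoplot.recap_run <- function(object, ...) {
  df <- object$headline |>
    mutate(fraction = tidyr::replace_na(.data$fraction, 0))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$model, y = .data$fraction, fill = .data$model)
  ) +
    ggplot2::geom_col(position = "dodge", show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = c("solid", "dashed")) +
    ggplot2::facet_wrap(~pathway_id) +
    ggplot2::labs(x = NULL, y = "superpathway recapitulation (%)") +
    ggplot2::theme_minimal()
}
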