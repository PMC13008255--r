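#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the paired human / disease-model simulation. The
#' defaults describe a small two-class study: 5 samples per class, 3 cell
#' types, 60 cells per (sample, cell type), one 50-gene pathway with 10
#' signal genes per cell type shifted by 1.5 log2 units in the target class.
#'
#' Two injection modes are available. `"counts"` draws negative-binomial
#' per-cell counts (the standard scRNA-seq marginal) and multiplies the mean
#' of target-class signal genes by `2^shift`, so the pseudobulk log2 shift
#' approximates `shift`. `"pseudobulk"` bypasses count noise and writes the
#' shift directly into the target-class pseudobulk, reusing the base-class
#' noise profiles so the class shift is exactly constant per gene - the
#' regime in which the recapitulation identities are exact.
#'
#' @param n_per_class Samples per class.
#' @param cell_types Character vector of human cell-type names.
#' @param cells_per_type Cells per (sample, cell type) in counts mode.
#' @param n_genes Pathway gene-set size.
#' @param n_signal Signal genes per cell type.
#' @param shift Log2 shift of signal genes (target minus base).
#' @param mode Model concordance: `"perfect"` (model FC equals the human
#'   shift), `"sign_flipped"` (negated), `"partial"` (`rho * shift` plus
#'   noise) or `"null"` (no significant FC).
#' @param rho Attenuation for `"partial"` mode.
#' @param coverage Fraction of pathway genes with a one-to-one ortholog.
#' @param unmapped_cell_types Human cell types absent from the model.
#' @param deg_frac Fraction of signal genes reported significant by the
#'   model.
#' @param dispersion Negative-binomial size parameter (counts mode).
#' @param noise_sd Gaussian pseudobulk noise sd (pseudobulk mode).
#' @param norm_target Pseudobulk library-size target.
#' @param injection `"pseudobulk"` (default) or `"counts"`.
#' @param paired In pseudobulk mode, reuse the base-class noise profiles for
#'   the target class (default), making the planted shift exactly constant
#'   per gene; set `FALSE` for independent target noise (e.g. to study null
#'   behaviour, where pairing would make classes linearly indistinguishable).
#' @param n_background Extra non-pathway genes drawn in counts mode so
#'   library-size normalization is not distorted by the planted pathway
#'   signal (as in real data, where a pathway is a sliver of the
#'   transcriptome).
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_per_class = 5,
                              cell_types = c("TC", "KC", "DC"),
                              cells_per_type = 60,
                              n_genes = 50,
                              n_signal = 10,
                              shift = 1.5,
                              mode = c("perfect", "sign_flipped", "partial", "null"),
                              rho = 0.5,
                              coverage = 1,
                              unmapped_cell_types = character(0),
                              deg_frac = 1,
                              dispersion = 20,
                              noise_sd = 0.25,
                              norm_target = 1e4,
                              injection = c("pseudobulk", "counts"),
                              paired = TRUE,
                              n_background = 500,
                              seed) {
  mode <- match.arg(mode)
  injection <- match.arg(injection)
  if (missing(seed)) abort("`seed` is mandatory for reproducible simulation.")
  if (coverage < 0 || coverage > 1) abort("`coverage` must lie in [0, 1].")
  if (!is.finite(shift)) abort("`shift` must be finite.")
  if (n_per_class < 2 || cells_per_type < 1 || n_genes < 1) {
    abort("Impossible configuration: need >= 2 samples/class, >= 1 cell and gene.")
  }
  structure(
    list(
      n_per_class = n_per_class, cell_types = cell_types,
      cells_per_type = cells_per_type, n_genes = n_genes,
      n_signal = min(n_signal, n_genes), shift = shift, mode = mode,
      rho = rho, coverage = coverage,
      unmapped_cell_types = unmapped_cell_types, deg_frac = deg_frac,
      dispersion = dispersion, noise_sd = noise_sd,
      norm_target = norm_target, injection = injection,
      paired = paired, n_background = n_background,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate the human two-class single-cell study
#'
#' Generates the human side of a synthetic study under `config` (see
#' [simulation_config()]): a superpathway, sample annotations, the ground
#' truth of planted signal, and either per-cell counts plus pseudobulk
#' (counts mode) or directly injected pseudobulk blocks.
#'
#' @param config A [simulation_config()].
#' @return Object of class `sc_sim`: list with `config`, `superpathway`,
#'   `samples` (tibble), `truth` (tibble `cell_type`, `gene`, `shift`),
#'   `blocks` (superpathway-restricted [pb_blocks]), and in counts mode also
#'   `counts` (`dgCMatrix`) and `cells`.
#' @export
simulate_human <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  n <- config$n_per_class
  samples <- tibble(
    sample_id = c(sprintf("BASE%02d", seq_len(n)), sprintf("TGT%02d", seq_len(n))),
    class = rep(c(0L, 1L), each = n)
  )
  sp <- superpathway(
    "SYNTHETIC_PATHWAY",
    setNames(rep(list(genes), length(config$cell_types)), config$cell_types)
  )
  truth <- map(setNames(config$cell_types, config$cell_types), function(ct) {
    tibble(
      cell_type = ct,
      gene = sort(sample(genes, config$n_signal)),
      shift = config$shift
    )
  }) |>
    bind_rows()

  base_mean <- exp(rnorm(config$n_genes, mean = log(5), sd = 0.6))
  names(base_mean) <- genes

  if (config$injection == "pseudobulk") {
    blocks <- map(setNames(config$cell_types, config$cell_types), function(ct) {
      mu <- log2(1 + base_mean * config$norm_target / sum(base_mean))
      noise <- matrix(
        rnorm(n * config$n_genes, sd = config$noise_sd),
        n, config$n_genes
      )
      shift_vec <- numeric(config$n_genes)
      sig <- truth$gene[truth$cell_type == ct]
      shift_vec[match(sig, genes)] <- truth$shift[truth$cell_type == ct]
      base <- sweep(noise, 2, mu, `+`)
      tgt_noise <- if (config$paired) {
        base # reused profiles: class shift exactly constant per gene
      } else {
        sweep(
          matrix(rnorm(n * config$n_genes, sd = config$noise_sd), n),
          2, mu, `+`
        )
      }
      target <- sweep(tgt_noise, 2, shift_vec, `+`)
      m <- rbind(base, target)
      dimnames(m) <- list(samples$sample_id, genes)
      m
    })
    out <- list(
      config = config, superpathway = sp, samples = samples,
      truth = truth, blocks = pb_blocks(blocks, samples)
    )
  } else {
    bg_genes <- if (config$n_background > 0) {
      sprintf("BG%04d", seq_len(config$n_background))
    } else {
      character(0)
    }
    bg_mean <- exp(rnorm(length(bg_genes), mean = log(5), sd = 0.6))
    all_genes <- c(genes, bg_genes)
    n_all <- length(all_genes)
    cells_list <- list()
    counts_cols <- list()
    for (ct in config$cell_types) {
      sig <- truth$gene[truth$cell_type == ct]
      mu_base <- c(base_mean, bg_mean)
      mu_target <- mu_base
      mu_target[match(sig, all_genes)] <- mu_target[match(sig, all_genes)] * 2^config$shift
      for (si in seq_len(nrow(samples))) {
        mu <- if (samples$class[si] == 1) mu_target else mu_base
        cnt <- matrix(
          rnbinom(
            n_all * config$cells_per_type,
            mu = rep(mu, config$cells_per_type), size = config$dispersion
          ),
          nrow = n_all
        )
        ids <- paste0(samples$sample_id[si], "_", ct, "_", seq_len(config$cells_per_type))
        counts_cols[[length(counts_cols) + 1]] <- cnt
        cells_list[[length(cells_list) + 1]] <- tibble(
          cell_id = ids, sample_id = samples$sample_id[si],
          cell_type = ct, class = samples$class[si]
        )
      }
    }
    counts <- do.call(cbind, counts_cols)
    cells <- bind_rows(cells_list)
    rownames(counts) <- all_genes
    colnames(counts) <- cells$cell_id
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    pb <- build_pseudobulk(counts, cells, norm_target = config$norm_target)
    out <- list(
      config = config, superpathway = sp, samples = samples, truth = truth,
      counts = counts, cells = cells,
      blocks = assemble_superpathway_blocks(pb, sp)
    )
  }
  structure(out, class = "sc_sim")
}

#' Simulate the disease-model side
#'
#' Emits a precomputed fold-change table, an ortholog map and a cell-type
#' map consistent with the human simulation's ground truth, under the
#' concordance mode, orthology coverage and cell-type mapping of `config`.
#' Model gene symbols are the lowercased human symbols; model cell types are
#' the human ones prefixed with `"m"`.
#'
#' @param config The same [simulation_config()] used for the human side.
#' @param human The [simulate_human()] result.
#' @return List with `fc` (gated fold-change tibble in model space),
#'   `orthology`, `celltype_map` and `truth` (model-side ground truth).
#' @export
simulate_model <- function(config, human) {
  stopifnot(inherits(config, "sim_config"), inherits(human, "sc_sim"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed + 1000003L)

  genes <- human$superpathway$genes
  n_cov <- round(config$coverage * length(genes))
  covered <- sort(sample(genes, n_cov))
  orthology <- tibble(
    human_symbol = genes,
    model_symbol = tolower(genes),
    one_to_one = genes %in% covered
  )
  celltype_map <- tibble(
    human_cell_type = config$cell_types,
    model_cell_type = ifelse(
      config$cell_types %in% config$unmapped_cell_types,
      NA_character_, paste0("m", config$cell_types)
    )
  )
  mapped <- celltype_map |> filter(!is.na(.data$model_cell_type))
  fc <- pmap(mapped, function(human_cell_type, model_cell_type) {
    sig <- human$truth |> filter(.data$cell_type == human_cell_type)
    is_sig <- genes %in% sig$gene
    s <- numeric(length(genes))
    s[match(sig$gene, genes)] <- sig$shift
    log2fc <- switch(config$mode,
      perfect = s,
      sign_flipped = -s,
      partial = config$rho * s +
        ifelse(is_sig, rnorm(length(genes), sd = 0.1 * max(abs(s), 1e-6)), 0),
      null = numeric(length(genes))
    )
    significant <- is_sig & config$mode != "null" &
      (runif(length(genes)) <= config$deg_frac)
    tibble(
      cell_type = model_cell_type,
      gene = tolower(genes),
      log2fc = log2fc,
      adj_p = ifelse(significant, 0.001, 1)
    )
  }) |>
    bind_rows() |>
    gate_fold_changes(gate = 0.05)
  list(
    fc = fc, orthology = orthology, celltype_map = celltype_map,
    truth = list(mode = config$mode, covered = covered)
  )
}

#' Write a simulated study to disk in interchange formats
#'
#' Emits exactly the formats the readers consume: MatrixMarket counts with
#' gene/cell metadata TSVs (counts mode) or pseudobulk block TSVs, a GMT
#' line for the pathway, ortholog and cell-type map TSVs, the fold-change
#' TSV, and a `ground_truth.json` manifest of the planted signal.
#'
#' @param human A [simulate_human()] result.
#' @param model A [simulate_model()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_sim_files <- function(human, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(human$counts)) {
    Matrix::writeMM(human$counts, file.path(dir, "counts.mtx"))
    readr::write_tsv(
      tibble(gene = rownames(human$counts)),
      file.path(dir, "genes.tsv")
    )
    readr::write_tsv(human$cells, file.path(dir, "cells.tsv"))
  }
  write_blocks(human$blocks, file.path(dir, "pseudobulk"))
  gmt_line <- paste(
    c(human$superpathway$pathway_id, "synthetic", human$superpathway$genes),
    collapse = "\t"
  )
  writeLines(gmt_line, file.path(dir, "pathways.gmt"))
  readr::write_tsv(
    model$orthology |> mutate(one_to_one = as.integer(.data$one_to_one)),
    file.path(dir, "orthologs.tsv")
  )
  readr::write_tsv(
    model$celltype_map |>
      mutate(model_cell_type = tidyr::replace_na(.data$model_cell_type, "ABSENT")),
    file.path(dir, "celltype_map.tsv")
  )
  readr::write_tsv(
    model$fc |> select("cell_type", "gene", "log2fc", "adj_p"),
    file.path(dir, "fold_changes.tsv")
  )
  jsonlite::write_json(
    list(
      config = unclass(human$config),
      signal = human$truth,
      model_mode = model$truth$mode,
      covered_genes = model$truth$covered
    ),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
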