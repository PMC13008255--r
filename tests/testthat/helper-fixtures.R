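# Shared fixture builders. Everything is generated in code; no stored data.

# Random multi-block pseudobulk with a controllable class shift.
make_blocks <- function(n_per_class = 3, p = c(A = 4, B = 5), shift = 0,
                        seed = 1, sd = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    class = rep(c(0L, 1L), each = n_per_class)
  )
  blocks <- lapply(seq_along(p), function(b) {
    m <- matrix(rnorm(n * p[b], sd = sd), n, p[b])
    m[samples$class == 1, ] <- m[samples$class == 1, ] + shift
    dimnames(m) <- list(samples$sample_id, sprintf("%s_G%d", names(p)[b], seq_len(p[b])))
    m
  })
  names(blocks) <- names(p)
  pb_blocks(blocks, samples)
}

# Paired location-shift blocks: target rows are exactly base rows + per-gene
# shift, so median equivariance is exact.
make_paired_blocks <- function(n_per_class = 4, p = c(A = 5, B = 6),
                               shift = 1.5, seed = 1) {
  set.seed(seed)
  samples <- tibble::tibble(
    sample_id = c(sprintf("b%02d", seq_len(n_per_class)),
                  sprintf("t%02d", seq_len(n_per_class))),
    class = rep(c(0L, 1L), each = n_per_class)
  )
  shifts <- lapply(p, function(pb) rep(shift, pb))
  blocks <- lapply(seq_along(p), function(b) {
    base <- matrix(rnorm(n_per_class * p[b]), n_per_class, p[b])
    m <- rbind(base, sweep(base, 2, shifts[[b]], `+`))
    dimnames(m) <- list(samples$sample_id, sprintf("%s_G%d", names(p)[b], seq_len(p[b])))
    m
  })
  names(blocks) <- names(p)
  list(blocks = pb_blocks(blocks, samples), shifts = shifts)
}

# Identity mappings for treatment of human blocks named like make_* output:
# model symbols are lowercased human ones, model cell types prefixed "m".
identity_maps <- function(blocks) {
  genes <- unique(unlist(lapply(blocks$blocks, colnames)))
  list(
    orthology = tibble::tibble(
      human_symbol = genes, model_symbol = tolower(genes), one_to_one = TRUE
    ),
    celltype_map = tibble::tibble(
      human_cell_type = names(blocks$blocks),
      model_cell_type = paste0("m", names(blocks$blocks))
    )
  )
}

# Significant fold-change table assigning r = shift to every gene of every
# mapped block.
fc_from_shifts <- function(blocks, shifts) {
  purrr::imap(blocks$blocks, function(m, ct) {
    tibble::tibble(
      cell_type = paste0("m", ct),
      gene = tolower(colnames(m)),
      log2fc = shifts[[ct]],
      adj_p = 1e-4
    )
  }) |>
    dplyr::bind_rows() |>
    screcap:::gate_fold_changes()
}

base_class_blocks <- function(blocks) {
  screcap:::subset_samples(blocks, blocks$samples$sample_id[blocks$samples$class == 0])
}

run_report <- function(blocks, fit, fc, maps) {
  d <- decompose(fit, blocks)
  ref <- reference_recapitulation(d, blocks$samples$class)
  base <- base_class_blocks(blocks)
  trt <- apply_treatment(base, fc, maps$orthology, maps$celltype_map)
  pred <- predicted_recapitulation(fit, base, trt$blocks)
  recapitulation_report(ref, pred, trt$log)
}
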