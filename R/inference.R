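#' Permutation validity test of the tuned model
#'
#' Checks that the tuned model's class separation is not a false positive.
#' The observed statistic is the leave-one-out F1 error of the model at its
#' optimal hyperparameters. A null distribution is built by permuting the
#' class labels: each permutation is scored by the same leave-one-out
#' procedure at the same hyperparameters (every prediction out-of-fold, so
#' the null cannot profit from in-sample interpolation of the permuted
#' labels), recording the F1 the model can manufacture once the
#' label-expression relationship is destroyed while the dependence structure
#' of the blocks is preserved. The p-value is the plus-one
#' estimate `(k + 1) / (n_perm + 1)` with `k` the number of null fits at
#' least as good (error at most the observed error). When several pathways
#' are tested, adjust the p-values with [bh_adjust()]; the pass rule is
#' adjusted p at or below the FDR and observed error below the `alpha/2`
#' null quantile.
#'
#' @param blocks A [pb_blocks].
#' @param y Binary response; defaults to block sample classes.
#' @param J,lambda Optimal hyperparameters (fixed; no re-tuning under the
#'   null).
#' @param n_perm Number of permutations (100 or more recommended).
#' @param seed Integer seed for the permutation draws.
#' @param alpha Confidence threshold for the null-quantile comparison.
#' @param threshold Thresholding mode of the fit.
#' @return Object of class `perm_test`: list with `observed_error`,
#'   `null_f1`, `null_error`, `p_value`, `alpha`, `null_quantile` (the
#'   `alpha/2` quantile of the null error) and `better_than_null` (observed
#'   error strictly below it).
#' @export
permutation_validity_test <- function(blocks, y = NULL, J, lambda,
                                      n_perm = 1000, seed = 1, alpha = 0.05,
                                      threshold = "soft") {
  stopifnot(inherits(blocks, "pb_blocks"))
  if (is.null(y)) y <- blocks$samples$class
  n <- length(y)
  observed <- loocv_error(blocks, y, J, lambda, threshold)
  if (observed$degenerate) {
    abort("The optimal model is degenerate under leave-one-out refits.")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_f1 <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    null_f1[k] <- one_null_f1(blocks, y, J, lambda, threshold)
  }
  null_error <- 1 - null_f1
  p <- (sum(null_error <= observed$error) + 1) / (n_perm + 1)
  qa <- unname(quantile(null_error, alpha / 2, type = 7))
  structure(
    list(
      observed_error = observed$error,
      null_f1 = null_f1,
      null_error = null_error,
      p_value = p,
      alpha = alpha,
      null_quantile = qa,
      better_than_null = observed$error < qa,
      n_perm = n_perm,
      seed = seed
    ),
    class = "perm_test"
  )
}

# One permutation replicate: permute the labels, score by the identical
# out-of-fold leave-one-out procedure used for the observed statistic
# (scoring against the original labels would reward permutations that
# happen to resemble the identity, and in-sample predictions would let a
# wide model interpolate the permuted labels). A degenerate replicate is
# resampled once, then counted as F1 = 0.
one_null_f1 <- function(blocks, y, J, lambda, threshold, retry = TRUE) {
  y_perm <- sample(y)
  res <- loocv_error(blocks, y_perm, J, lambda, threshold)
  if (res$degenerate) {
    return(if (retry) one_null_f1(blocks, y, J, lambda, threshold, FALSE) else 0)
  }
  1 - res$error
}

#' @export
print.perm_test <- function(x, ...) {
  cat(
    "<perm_test> observed LOOCV F1 error = ", signif(x$observed_error, 4),
    "; p = ", signif(x$p_value, 4), " (", x$n_perm, " permutations)\n",
    "null ", signif(x$alpha / 2, 3), "-quantile of error = ",
    signif(x$null_quantile, 4),
    "; better than null: ", x$better_than_null, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @method glance perm_test
glance.perm_test <- function(x, ...) {
  tibble(
    observed_error = x$observed_error,
    p_value = x$p_value,
    null_quantile = x$null_quantile,
    better_than_null = x$better_than_null,
    n_perm = x$n_perm
  )
}

#' Cell and gene importance projections
#'
#' Importance of each cell-type block and of each gene within its block as
#' the component-importance-weighted average of squared PLS weights. The
#' component weights are the fractions of response variance captured per
#' component during fitting. Super weights are unit-normalized across blocks
#' per component, and block weight vectors are unit within block, so the
#' indices sum to one: across blocks for the cell importance, and across a
#' block's genes for the gene importance (over the components in which the
#' block is active). A block zeroed in every component (sparsity quantile 1)
#' is flagged uninformative with importance 0. Signs follow the
#' component-weighted sign of the raw weights.
#'
#' @param model Fitted `asmbplsda`.
#' @return Object of class `importance_report`: list of tibbles `cip`
#'   (`cell_type`, `cip`, `sign`, `informative`) and `gip` (`cell_type`,
#'   `gene`, `gip`, `sign`), plus `q` (component importances).
#' @export
compute_cip_gip <- function(model) {
  stopifnot(inherits(model, "asmbplsda"))
  q <- model$component_importance
  if (sum(q) <= 0) abort("Degenerate model: no component explains any response variance.")
  J <- model$n_components
  B <- length(model$block_names)
  sw <- model$super_weights # J x B, unit rows by construction
  cip_val <- colSums(sw^2 * q) / sum(q)
  cip_sign <- sign(colSums(sw * q))
  cip <- tibble(
    cell_type = model$block_names,
    cip = unname(cip_val),
    sign = unname(cip_sign),
    informative = unname(cip_val > 0)
  )
  gip <- map(setNames(model$block_names, model$block_names), function(b) {
    W <- vapply(
      seq_len(J), function(j) model$weights[[j]][[b]],
      numeric(model$p_b[[b]])
    )
    W <- matrix(W, nrow = model$p_b[[b]])
    active <- colSums(W != 0) > 0
    if (!any(active)) {
      return(tibble(
        cell_type = b, gene = model$genes[[b]], gip = 0, sign = 0
      ))
    }
    qa <- q[active]
    Wa <- W[, active, drop = FALSE]
    tibble(
      cell_type = b,
      gene = model$genes[[b]],
      gip = as.numeric((Wa^2 %*% qa) / sum(qa)),
      sign = sign(as.numeric(Wa %*% qa))
    )
  }) |>
    bind_rows()
  structure(
    list(cip = cip, gip = gip, q = q),
    class = "importance_report"
  )
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report>\n")
  print(x$cip)
  invisible(x)
}

#' @export
#' @method tidy importance_report
tidy.importance_report <- function(x, ...) {
  bind_rows(
    x$cip |>
      transmute(
        level = "cell_type", cell_type = .data$cell_type, gene = NA_character_,
        importance = .data$cip, sign = .data$sign
      ),
    x$gip |>
      transmute(
        level = "gene", cell_type = .data$cell_type, gene = .data$gene,
        importance = .data$gip, sign = .data$sign
      )
  )
}

#' @export
#' @method autoplot importance_report
autoplot.importance_report <- function(object, ...) {
  ggplot2::ggplot(
    object$cip,
    ggplot2::aes(
      x = stats::reorder(.data$cell_type, .data$cip),
      y = .data$cip * .data$sign, fill = .data$sign > 0
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signed cell importance projection") +
    ggplot2::theme_minimal()
}

#' Significance of gene importance projections
#'
#' Compares, per gene, a jackknife distribution of its importance projection
#' (leave-one-sample-out refits at the fixed optimal hyperparameters)
#' against a block-level null distribution obtained by refitting on data
#' whose entries are permuted within each block (samples and genes scrambled
#' jointly within a block, never across blocks, which would break
#' exchangeability since the importance distribution depends on the block's
#' sparsity). A one-sided Mann-Whitney U test asks whether the jackknife
#' values are stochastically greater than the block null; p-values are
#' Bonferroni-adjusted with the block-specific factor
#' `m0 = max(1, floor(prod_j(lambda_jb) * p_b))`, a lower bound on the
#' expected number of true null genes in the block.
#'
#' @param blocks A [pb_blocks].
#' @param y Binary response; defaults to block sample classes.
#' @param model The tuned fit whose hyperparameters are reused.
#' @param n_perm Number of null refits.
#' @param seed Integer seed.
#' @return Tibble: `cell_type`, `gene`, `gip`, `sign`, `jack_median`,
#'   `null_median`, `p_value`, `adj_p`, `m0`.
#' @export
gip_significance <- function(blocks, y = NULL, model, n_perm = 100, seed = 1) {
  stopifnot(inherits(blocks, "pb_blocks"), inherits(model, "asmbplsda"))
  if (is.null(y)) y <- blocks$samples$class
  n <- length(y)
  if (n < 4) abort("Jackknife needs at least 4 samples.")
  refit_gip <- function(bl, yy) {
    fit <- tryCatch(
      suppressWarnings(asmbplsda(
        bl, yy,
        n_components = model$n_components, lambda = model$lambda,
        threshold = model$threshold, compute_coef = FALSE
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(NULL)
    }
    compute_cip_gip(fit)$gip
  }
  jack <- map(seq_len(n), function(i) {
    bl <- pb_blocks(
      map(blocks$blocks, ~ .x[-i, , drop = FALSE]),
      blocks$samples[-i, ]
    )
    refit_gip(bl, y[-i])
  }) |>
    keep(~ !is.null(.x)) |>
    bind_rows()
  if (nrow(jack) == 0) abort("All jackknife refits failed.")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_gip <- map(seq_len(n_perm), function(k) {
    scrambled <- map(blocks$blocks, function(m) {
      out <- matrix(sample(as.numeric(m)), nrow(m), ncol(m),
        dimnames = dimnames(m)
      )
      out
    })
    refit_gip(pb_blocks(scrambled, blocks$samples), y)
  }) |>
    keep(~ !is.null(.x)) |>
    bind_rows()
  if (nrow(null_gip) == 0) abort("All null refits failed; check the model grid.")

  observed <- compute_cip_gip(model)$gip
  m0 <- tibble(
    cell_type = model$block_names,
    m0 = pmax(1, floor(apply(model$lambda, 2, prod) * model$p_b))
  )
  null_by_block <- split(null_gip$gip, null_gip$cell_type)
  jack_by <- split(jack, list(jack$cell_type, jack$gene), drop = TRUE)

  res <- observed |>
    rowwise() |>
    mutate(
      jack_vals = list(jack_by[[paste(.data$cell_type, .data$gene, sep = ".")]]$gip),
      null_vals = list(null_by_block[[.data$cell_type]])
    ) |>
    ungroup() |>
    mutate(
      jack_median = map_dbl(.data$jack_vals, ~ if (length(.x)) median(.x) else NA_real_),
      null_median = map_dbl(.data$null_vals, ~ if (length(.x)) median(.x) else NA_real_),
      p_value = purrr::map2_dbl(.data$jack_vals, .data$null_vals, function(a, b) {
        if (length(a) == 0 || length(b) == 0) {
          return(NA_real_)
        }
        suppressWarnings(wilcox.test(
          a, b,
          alternative = "greater",
          exact = length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
        )$p.value)
      })
    ) |>
    select(-"jack_vals", -"null_vals") |>
    left_join(m0, by = "cell_type") |>
    mutate(adj_p = pmin(1, .data$p_value * .data$m0))
  res
}
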