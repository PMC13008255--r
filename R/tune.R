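#' Leave-one-out tuning of component count and sparsity quantiles
#'
#' Grid search over the number of PLS components and per-block sparsity
#' quantiles. Each candidate is scored by leave-one-out cross-validation:
#' fit on n-1 samples, predict the held-out sample, classify at 0.5 on the
#' 0/1 response scale, and take `1 - F1` against the true labels as the
#' error. The minimal-error candidate wins; ties break toward fewer
#' components, then toward larger total sparsity (the more parsimonious
#' model). Candidates whose fit is degenerate on any training fold (all
#' block weights zeroed) are excluded; if every candidate is degenerate that
#' is an error suggesting a different grid.
#'
#' @param blocks A [pb_blocks] object.
#' @param y Binary response; defaults to the block sample classes.
#' @param J_grid Integer vector of component counts to try.
#' @param lambda_values Sparsity quantiles to try per block. The candidate
#'   set is the full cross-product across blocks (shared across components)
#'   unless `expand = FALSE`, which ties all blocks to one shared value.
#' @param expand Cross all per-block combinations (default) or tie blocks.
#' @param threshold Thresholding mode passed to [asmbplsda()].
#' @return An object of class `asmbplsda_cv`: list with `grid` (one row per
#'   candidate with its LOOCV error), `best` (selected J and lambda vector)
#'   and `model` (refit on all samples at the optimum).
#' @export
tune_asmbplsda <- function(blocks, y = NULL, J_grid = 1:3,
                           lambda_values = c(0, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99, 1),
                           expand = TRUE, threshold = "soft") {
  stopifnot(inherits(blocks, "pb_blocks"))
  if (is.null(y)) y <- blocks$samples$class
  if (length(J_grid) == 0 || length(lambda_values) == 0) {
    abort("Tuning grids must be non-empty.")
  }
  B <- length(blocks$blocks)
  block_names <- names(blocks$blocks)

  lambda_combos <- if (expand) {
    as.matrix(expand.grid(rep(list(lambda_values), B)))
  } else {
    matrix(rep(lambda_values, each = B), ncol = B, byrow = TRUE)
  }
  colnames(lambda_combos) <- block_names

  candidates <- tidyr::crossing(J = J_grid, .combo = seq_len(nrow(lambda_combos)))
  errors <- numeric(nrow(candidates))
  degenerate <- logical(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    J <- candidates$J[k]
    lam <- lambda_combos[candidates$.combo[k], ]
    res <- loocv_error(blocks, y, J, lam, threshold)
    errors[k] <- res$error
    degenerate[k] <- res$degenerate
  }
  grid <- bind_cols(
    tibble(J = candidates$J),
    as_tibble(lambda_combos[candidates$.combo, , drop = FALSE]) |>
      rename_with(~ paste0("lambda_", .x)),
    tibble(error = errors, degenerate = degenerate)
  )

  ok <- which(!degenerate)
  if (length(ok) == 0) {
    abort("Every candidate fit is degenerate; widen `lambda_values` (include values < 1).")
  }
  lam_sum <- rowSums(lambda_combos[candidates$.combo, , drop = FALSE])
  ord <- ok[order(errors[ok], candidates$J[ok], -lam_sum[ok])]
  best_k <- ord[1]
  best_lambda <- lambda_combos[candidates$.combo[best_k], ]
  best <- list(
    J = candidates$J[best_k],
    lambda = best_lambda,
    error = errors[best_k]
  )
  model <- asmbplsda(
    blocks, y,
    n_components = best$J, lambda = best$lambda, threshold = threshold
  )
  structure(
    list(grid = grid, best = best, model = model, threshold = threshold),
    class = "asmbplsda_cv"
  )
}

# LOOCV error for one (J, lambda) candidate. Returns 1 - F1 plus a
# degeneracy flag (any fold failing to fit a first component).
loocv_error <- function(blocks, y, J, lambda, threshold = "soft") {
  n <- length(y)
  X <- if (inherits(blocks, "pb_blocks")) blocks$blocks else blocks
  pred <- integer(n)
  for (i in seq_len(n)) {
    train <- lapply(X, function(m) m[-i, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(asmbplsda(
        train, y[-i],
        n_components = J, lambda = lambda,
        threshold = threshold, compute_coef = FALSE
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(list(error = Inf, degenerate = TRUE))
    }
    held <- lapply(X, function(m) m[i, , drop = FALSE])
    pred[i] <- predict(fit, held, type = "class")
  }
  list(error = 1 - f1_score(y, pred), degenerate = FALSE)
}

#' @export
print.asmbplsda_cv <- function(x, ...) {
  cat(
    "<asmbplsda_cv> ", nrow(x$grid), " candidates; best: J = ", x$best$J,
    ", lambda = (", paste(signif(x$best$lambda, 3), collapse = ", "),
    "), LOOCV F1 error = ", signif(x$best$error, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @method tidy asmbplsda_cv
tidy.asmbplsda_cv <- function(x, ...) {
  x$grid
}

#' @export
#' @method glance asmbplsda_cv
glance.asmbplsda_cv <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$grid),
    best_J = x$best$J,
    best_error = x$best$error
  )
}

#' @export
#' @method autoplot asmbplsda_cv
autoplot.asmbplsda_cv <- function(object, ...) {
  grid <- object$grid |>
    mutate(mean_lambda = rowMeans(across(starts_with("lambda_"))))
  ggplot2::ggplot(
    grid,
    ggplot2::aes(x = .data$mean_lambda, y = .data$error,
                 colour = factor(.data$J))
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "mean sparsity quantile across blocks",
      y = "LOOCV F1 error",
      colour = "components"
    ) +
    ggplot2::theme_minimal()
}
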