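#' Fit an adaptive sparse multi-block PLS-DA model
#'
#' Multi-block partial least squares discriminant analysis with quantile-based
#' adaptive sparsity per block and component. The response is the binary
#' sample class (base class 0 as reference); predictor blocks are the
#' per-cell-type pseudobulk matrices, centered and scaled internally.
#'
#' Per component: each block weight vector is the covariance of the scaled
#' block with the current response residual, thresholded at the
#' `lambda[j, b]` quantile of its absolute entries (entries at or below the
#' threshold become exactly zero; survivors are soft-shrunk by default) and
#' renormalized to unit length. Block scores are scaled by `1/sqrt(p_b)` so
#' wide blocks do not dominate the superblock; super weights are the
#' unit-normalized covariances of block scores with the residual; blocks and
#' response are deflated by the super score. `lambda = 0` disables sparsity,
#' `lambda = 1` removes a block from a component entirely.
#'
#' @param blocks A [pb_blocks] object (or bare named list of sample-aligned
#'   matrices plus `y`).
#' @param y Binary response vector (0/1) per sample; defaults to the class
#'   column of `blocks$samples`.
#' @param n_components Number of PLS components to fit. Truncated with a
#'   warning if the data cannot support that many.
#' @param lambda Sparsity quantiles in `[0, 1]`: scalar, per-block vector, or
#'   `n_components` x B matrix.
#' @param threshold `"soft"` (default) or `"hard"` thresholding of block
#'   weights.
#' @param compute_coef Keep the accumulated per-gene linear coefficients
#'   (needed for [decompose()] and fast prediction); disable only inside
#'   tight cross-validation loops.
#' @return An object of class `asmbplsda`.
#' @export
asmbplsda <- function(blocks, y = NULL, n_components = 1, lambda = 0,
                      threshold = c("soft", "hard"), compute_coef = TRUE) {
  threshold <- match.arg(threshold)
  if (inherits(blocks, "pb_blocks")) {
    X <- blocks$blocks
    if (is.null(y)) y <- blocks$samples$class
  } else {
    X <- blocks
    if (is.null(y)) abort("`y` is required when `blocks` is a bare list.")
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4) abort("At least 4 samples are required.")
  if (length(unique(y)) < 2) abort("Both classes must be present in `y`.")
  B <- length(X)
  block_names <- names(X)
  p_b <- map_dbl(X, ncol)

  lambda <- expand_lambda(lambda, n_components, block_names)

  # center/scale; constant columns get scale 1 (their centered values are 0,
  # so they can never earn weight)
  centers <- map(X, colMeans)
  scales <- map(X, function(m) {
    s <- apply(m, 2, sd)
    s[s == 0] <- 1
    s
  })
  Z <- map2(X, seq_len(B), function(m, b) {
    scale(m, center = centers[[b]], scale = scales[[b]])[, , drop = FALSE]
  })
  Z <- map(Z, function(m) {
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    m
  })
  y_mean <- mean(y)
  f <- y - y_mean

  weights <- vector("list", n_components)
  super_weights <- matrix(0, n_components, B, dimnames = list(NULL, block_names))
  loadings <- vector("list", n_components)
  q <- numeric(n_components)
  expl <- numeric(n_components)
  scores <- matrix(0, n, n_components)

  j_done <- 0
  for (j in seq_len(n_components)) {
    w_j <- vector("list", B)
    names(w_j) <- block_names
    T_mat <- matrix(0, n, B)
    for (b in seq_len(B)) {
      w_raw <- as.numeric(crossprod(Z[[b]], f))
      names(w_raw) <- colnames(X[[b]])
      w <- unitize(threshold_weights(w_raw, lambda[j, b], mode = threshold))
      w_j[[b]] <- w
      T_mat[, b] <- (Z[[b]] %*% w) / sqrt(p_b[b])
    }
    a_raw <- as.numeric(crossprod(T_mat, f))
    if (sqrt(sum(a_raw^2)) < 1e-12) {
      if (j == 1) {
        abort(paste0(
          "Degenerate fit: every block weight vector is zero at component 1. ",
          "Relax the sparsity quantiles (lambda)."
        ))
      }
      warn(paste0(
        "Component ", j, " is degenerate; truncating model at ", j_done,
        " component(s)."
      ))
      break
    }
    a <- unitize(a_raw)
    t_super <- as.numeric(T_mat %*% a)
    tt <- sum(t_super^2)
    if (tt < 1e-12) {
      if (j == 1) abort("Degenerate fit: the first super score has no variance.")
      warn(paste0(
        "Component ", j, " has a null super score; truncating at ", j_done, "."
      ))
      break
    }
    q_j <- sum(f * t_super) / tt
    p_load <- map(Z, ~ as.numeric(crossprod(.x, t_super)) / tt)
    for (b in seq_len(B)) {
      Z[[b]] <- Z[[b]] - tcrossprod(t_super, p_load[[b]])
    }
    f <- f - q_j * t_super

    weights[[j]] <- w_j
    super_weights[j, ] <- a
    loadings[[j]] <- p_load
    q[j] <- q_j
    expl[j] <- q_j^2 * tt
    scores[, j] <- t_super
    j_done <- j
  }
  if (j_done < n_components) {
    weights <- weights[seq_len(j_done)]
    loadings <- loadings[seq_len(j_done)]
    super_weights <- super_weights[seq_len(j_done), , drop = FALSE]
    q <- q[seq_len(j_done)]
    expl <- expl[seq_len(j_done)]
    scores <- scores[, seq_len(j_done), drop = FALSE]
    lambda <- lambda[seq_len(j_done), , drop = FALSE]
  }

  model <- structure(
    list(
      n_components = j_done,
      block_names = block_names,
      genes = map(X, colnames),
      p_b = p_b,
      lambda = lambda,
      threshold = threshold,
      weights = weights,
      super_weights = super_weights,
      loadings = loadings,
      q = q,
      component_importance = if (sum(expl) > 0) expl / sum(expl) else expl,
      centers = centers,
      scales = scales,
      y_mean = y_mean,
      super_scores = scores,
      coef = NULL
    ),
    class = "asmbplsda"
  )
  if (compute_coef) {
    model$coef <- accumulate_coefficients(model)
  }
  model
}

expand_lambda <- function(lambda, n_components, block_names) {
  B <- length(block_names)
  if (is.matrix(lambda)) {
    if (ncol(lambda) != B) abort("`lambda` matrix must have one column per block.")
    if (nrow(lambda) == 1) lambda <- lambda[rep(1, n_components), , drop = FALSE]
    if (nrow(lambda) != n_components) {
      abort("`lambda` matrix must have one row per component.")
    }
  } else if (length(lambda) == 1) {
    lambda <- matrix(lambda, n_components, B)
  } else if (length(lambda) == B) {
    lambda <- matrix(lambda, n_components, B, byrow = TRUE)
  } else {
    abort("`lambda` must be a scalar, a per-block vector, or a J x B matrix.")
  }
  if (any(lambda < 0 | lambda > 1)) abort("Sparsity quantiles must lie in [0, 1].")
  colnames(lambda) <- block_names
  lambda
}

# The fitted prediction map is linear in the scaled inputs; running the
# component recursion over block-partitioned unit vectors yields the exact
# accumulated per-gene coefficients (scaled space, centered response).
accumulate_coefficients <- function(model) {
  p_total <- sum(model$p_b)
  offsets <- cumsum(c(0, model$p_b))
  Z <- map(seq_along(model$block_names), function(b) {
    m <- matrix(0, p_total, model$p_b[b])
    idx <- offsets[b] + seq_len(model$p_b[b])
    m[cbind(idx, seq_len(model$p_b[b]))] <- 1
    m
  })
  beta <- forward_recursion(model, Z)
  map(seq_along(model$block_names), function(b) {
    idx <- offsets[b] + seq_len(model$p_b[b])
    setNames(beta[idx], model$genes[[b]])
  }) |>
    setNames(model$block_names)
}

# Centered predicted response for already-scaled blocks.
forward_recursion <- function(model, Z) {
  n <- nrow(Z[[1]])
  f_hat <- numeric(n)
  for (j in seq_len(model$n_components)) {
    T_mat <- matrix(0, n, length(Z))
    for (b in seq_along(Z)) {
      T_mat[, b] <- (Z[[b]] %*% model$weights[[j]][[b]]) / sqrt(model$p_b[b])
    }
    t_super <- as.numeric(T_mat %*% model$super_weights[j, ])
    f_hat <- f_hat + model$q[j] * t_super
    for (b in seq_along(Z)) {
      Z[[b]] <- Z[[b]] - tcrossprod(t_super, model$loadings[[j]][[b]])
    }
  }
  f_hat
}

# Scale new blocks with the stored centering/scaling, verifying gene columns.
scale_newdata <- function(model, blocks) {
  X <- if (inherits(blocks, "pb_blocks")) blocks$blocks else blocks
  missing_blocks <- setdiff(model$block_names, names(X))
  if (length(missing_blocks) > 0) {
    abort(paste0("Missing block(s): ", paste(missing_blocks, collapse = ", ")))
  }
  map(setNames(model$block_names, model$block_names), function(b) {
    m <- X[[b]]
    missing_genes <- setdiff(model$genes[[b]], colnames(m))
    if (length(missing_genes) > 0) {
      abort(paste0(
        "Block '", b, "' lacks gene column(s): ",
        paste(head(missing_genes, 10), collapse = ", ")
      ))
    }
    m <- m[, model$genes[[b]], drop = FALSE]
    sweep(sweep(m, 2, model$centers[[b]]), 2, model$scales[[b]], `/`)
  })
}

#' Predict from a fitted multi-block sparse PLS-DA model
#'
#' @param object A fitted `asmbplsda` model.
#' @param newdata A [pb_blocks] (or named list of matrices) with the model's
#'   gene columns; unseen samples are allowed.
#' @param type `"response"` (default; intercept plus linear predictor on the
#'   0/1 class scale), `"score"` (centered scale, intercept excluded) or
#'   `"class"` (response thresholded at 0.5).
#' @param ... Unused.
#' @return Named numeric (or integer for `"class"`) vector per sample.
#' @export
predict.asmbplsda <- function(object, newdata,
                              type = c("response", "score", "class"), ...) {
  type <- match.arg(type)
  Z <- scale_newdata(object, newdata)
  score <- if (!is.null(object$coef)) {
    Reduce(`+`, map2(Z, object$coef[names(Z)], function(m, beta) {
      as.numeric(m %*% beta)
    }))
  } else {
    forward_recursion(object, Z)
  }
  names(score) <- rownames(Z[[1]])
  switch(type,
    score = score,
    response = score + object$y_mean,
    class = as.integer(score + object$y_mean >= 0.5)
  )
}

#' Additive cell-type and gene decomposition of predicted scores
#'
#' Splits each sample's predicted score into per-cell-type contributions
#' (gamma) and per-gene contributions (delta) such that
#' `score_i = sum_b gamma_ib = sum_b sum_g delta_igb` holds exactly. Scores
#' here are on the centered scale (the response-mean intercept is stored
#' separately; it cancels in every downstream reference/predicted difference).
#'
#' @param model A fitted `asmbplsda` model with coefficients.
#' @param blocks A [pb_blocks] compatible with the model.
#' @return An object of class `score_decomposition`: list with tibbles
#'   `scores` (`sample_id`, `score`, `response`), `gamma` (`sample_id`,
#'   `cell_type`, `gamma`), `delta` (`sample_id`, `cell_type`, `gene`,
#'   `delta`) and the scalar `intercept`.
#' @export
decompose <- function(model, blocks) {
  stopifnot(inherits(model, "asmbplsda"))
  if (is.null(model$coef)) {
    abort("Model was fitted with `compute_coef = FALSE`; refit to decompose.")
  }
  Z <- scale_newdata(model, blocks)
  sample_ids <- rownames(Z[[1]])
  delta <- imap(Z, function(m, ct) {
    d <- sweep(m, 2, model$coef[[ct]], `*`)
    as_tibble(d, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "gene", values_to = "delta") |>
      mutate(cell_type = ct, .after = "sample_id")
  }) |>
    bind_rows()
  gamma <- delta |>
    group_by(.data$sample_id, .data$cell_type) |>
    summarise(gamma = sum(.data$delta), .groups = "drop")
  scores <- gamma |>
    group_by(.data$sample_id) |>
    summarise(score = sum(.data$gamma), .groups = "drop") |>
    mutate(response = .data$score + model$y_mean)
  # restore block sample order
  ord <- tibble(sample_id = sample_ids, .ord = seq_along(sample_ids))
  scores <- scores |> left_join(ord, by = "sample_id") |>
    arrange(.data$.ord) |> select(-".ord")
  structure(
    list(
      scores = scores, gamma = gamma, delta = delta,
      intercept = model$y_mean
    ),
    class = "score_decomposition"
  )
}

#' @export
print.asmbplsda <- function(x, ...) {
  cat(
    "<asmbplsda> ", x$n_components, " component(s), ",
    length(x$block_names), " block(s)\n",
    sep = ""
  )
  nz <- map_dbl(x$block_names, function(b) {
    sum(map_dbl(x$weights, ~ sum(.x[[b]] != 0)))
  })
  for (i in seq_along(x$block_names)) {
    cat(
      "  ", x$block_names[i], ": ", x$p_b[i], " genes, ",
      nz[i], " nonzero weight entries across components\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
#' @method tidy asmbplsda
tidy.asmbplsda <- function(x, ...) {
  out <- list()
  for (j in seq_len(x$n_components)) {
    for (b in x$block_names) {
      w <- x$weights[[j]][[b]]
      out[[length(out) + 1]] <- tibble(
        component = j, cell_type = b, gene = names(w), weight = unname(w),
        super_weight = x$super_weights[j, b], lambda = x$lambda[j, b]
      )
    }
  }
  bind_rows(out)
}

#' @export
#' @method glance asmbplsda
glance.asmbplsda <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_blocks = length(x$block_names),
    n_genes = sum(x$p_b),
    nonzero_weights = sum(map_dbl(x$weights, function(wj) {
      sum(map_dbl(wj, ~ sum(.x != 0)))
    })),
    intercept = x$y_mean
  )
}

#' Serialize a fitted model to JSON (and back)
#'
#' Plain-text archive of everything needed to reuse a fit on later treatment
#' runs: weights, loadings, super weights, response loadings, sparsity
#' quantiles, centering/scaling and coefficients.
#'
#' @param model A fitted `asmbplsda`.
#' @param path File to write / read.
#' @return `write_asmbplsda` returns `path` invisibly; `read_asmbplsda`
#'   returns the model.
#' @export
write_asmbplsda <- function(model, path) {
  payload <- model
  payload$super_weights <- as.data.frame(model$super_weights)
  payload$lambda <- as.data.frame(model$lambda)
  payload$super_scores <- as.data.frame(model$super_scores)
  class(payload) <- NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_asmbplsda
#' @export
read_asmbplsda <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- raw
  model$block_names <- as.character(raw$block_names)
  model$super_weights <- as.matrix(raw$super_weights)
  colnames(model$super_weights) <- model$block_names
  model$lambda <- as.matrix(raw$lambda)
  colnames(model$lambda) <- model$block_names
  model$super_scores <- as.matrix(raw$super_scores)
  model$p_b <- setNames(as.numeric(raw$p_b), model$block_names)
  relist_block <- function(x) map(x, ~ unlist(.x))
  model$weights <- map(raw$weights, relist_block)
  model$loadings <- map(raw$loadings, function(l) map(l, unlist))
  model$centers <- relist_block(raw$centers)
  model$scales <- relist_block(raw$scales)
  model$coef <- relist_block(raw$coef)
  model$genes <- map(raw$genes, unlist)
  structure(model, class = "asmbplsda")
}
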