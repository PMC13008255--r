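test_that("single-block dense model matches the analytic PLS1 first component", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(12), 4, 3,
      dimnames = list(paste0("s", 1:4), paste0("G", 1:3))
    )
    y <- c(0, 1, 0, 1)
    bl <- pb_blocks(list(A = X), tibble::tibble(sample_id = rownames(X), class = y))
    fit <- asmbplsda(bl, n_components = 1, lambda = 0)
    w_oracle <- crossprod(scale(X), y - mean(y))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    cosine <- abs(sum(fit$weights[[1]]$A * w_oracle))
    expect_equal(cosine, 1, tolerance = 1e-8)
  }
})

test_that("sparsity quantile 1 zeroes a block; quantile is monotone", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 6, B = 7), shift = 1, seed = 3)
  fit <- asmbplsda(bl, n_components = 1, lambda = c(1, 0))
  expect_true(all(fit$weights[[1]]$A == 0))
  expect_true(any(fit$weights[[1]]$B != 0))

  # nonzero support shrinks as lambda grows (first component)
  lambdas <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
  supports <- lapply(lambdas, function(l) {
    f <- asmbplsda(bl, n_components = 1, lambda = c(l, 0), compute_coef = FALSE)
    which(f$weights[[1]]$A != 0)
  })
  for (k in seq_len(length(lambdas) - 1)) {
    expect_true(all(supports[[k + 1]] %in% supports[[k]]))
  }
})

test_that("duplicated blocks receive symmetric super weights", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5), shift = 1, seed = 4)
  twin <- pb_blocks(
    list(A = bl$blocks$A, B = `colnames<-`(bl$blocks$A, paste0("B_", 1:5))),
    bl$samples
  )
  fit <- asmbplsda(twin, n_components = 1, lambda = 0)
  expect_equal(unname(fit$super_weights[1, "A"]), unname(fit$super_weights[1, "B"]),
    tolerance = 1e-10
  )
})

test_that("score decomposition is additive at all levels", {
  for (seed in 1:10) {
    shift <- runif(1, 0, 2)
    bl <- make_blocks(
      n_per_class = sample(3:5, 1),
      p = c(A = sample(3:8, 1), B = sample(3:8, 1), C = sample(3:8, 1)),
      shift = shift, seed = 100 + seed
    )
    J <- sample(1:2, 1)
    fit <- asmbplsda(bl, n_components = J, lambda = runif(1, 0, 0.5))
    d <- decompose(fit, bl)
    by_gamma <- d$gamma |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(s = sum(gamma))
    by_delta <- d$delta |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(s = sum(delta))
    scores <- d$scores |> dplyr::arrange(sample_id)
    expect_lt(max(abs(scores$score - by_gamma$s)), 1e-10)
    expect_lt(max(abs(scores$score - by_delta$s)), 1e-10)
    # response = intercept + score
    expect_equal(d$scores$response, d$scores$score + d$intercept)
  }
})

test_that("prediction is affine in the inputs", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5, B = 4), shift = 1, seed = 9)
  fit <- asmbplsda(bl, n_components = 2, lambda = 0.25)
  y0 <- predict(fit, bl)
  # perturb one gene by a constant c: every prediction shifts by coef*c/scale
  g <- "A_G2"
  cshift <- 0.7
  pert <- bl$blocks
  pert$A[, g] <- pert$A[, g] + cshift
  y1 <- predict(fit, pert)
  expected <- cshift * fit$coef$A[g] / fit$scales$A[g]
  expect_equal(unname(y1 - y0), rep(unname(expected), length(y0)), tolerance = 1e-12)

  # arbitrary perturbation E: difference equals coefficient-weighted E
  set.seed(1)
  E <- lapply(bl$blocks, function(m) matrix(rnorm(length(m)), nrow(m)))
  pert2 <- purrr::map2(bl$blocks, E, `+`)
  for (ct in names(pert2)) dimnames(pert2[[ct]]) <- dimnames(bl$blocks[[ct]])
  y2 <- predict(fit, pert2)
  lin <- Reduce(`+`, purrr::imap(E, function(e, ct) {
    sweep(e, 2, fit$coef[[ct]] / fit$scales[[ct]], `*`) |> rowSums()
  }))
  expect_equal(unname(y2 - y0), unname(lin), tolerance = 1e-10)
})

test_that("a sample at the gene means predicts the response mean", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5), shift = 1, seed = 10)
  fit <- asmbplsda(bl, n_components = 1, lambda = 0)
  centered <- list(A = matrix(fit$centers$A, 1, dimnames = list("new", names(fit$centers$A))))
  expect_equal(unname(predict(fit, centered)), fit$y_mean, tolerance = 1e-12)
})

test_that("fitting is deterministic and in-sample prediction matches stored scores", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 6, B = 3), shift = 0.5, seed = 12)
  f1 <- asmbplsda(bl, n_components = 2, lambda = 0.5)
  f2 <- asmbplsda(bl, n_components = 2, lambda = 0.5)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$coef, f2$coef)
  # coefficient path equals the component recursion
  recursion <- screcap:::forward_recursion(f1, screcap:::scale_newdata(f1, bl))
  expect_equal(unname(predict(f1, bl, type = "score")), recursion, tolerance = 1e-12)
})

test_that("degenerate requests fail or truncate loudly", {
  bl <- make_blocks(n_per_class = 3, p = c(A = 4), shift = 0.5, seed = 13)
  expect_error(asmbplsda(bl, y = rep(1, 6)), "Both classes")
  expect_error(asmbplsda(bl, n_components = 1, lambda = 1), "Degenerate")
  expect_warning(asmbplsda(bl, n_components = 6, lambda = 0), "truncat")
  small <- screcap:::subset_samples(bl, bl$samples$sample_id[1:3])
  expect_error(asmbplsda(small), "4 samples")
})

test_that("gene column permutation leaves contributions unchanged", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5, B = 4), shift = 1, seed = 14)
  fit <- asmbplsda(bl, n_components = 1, lambda = 0)
  shuffled <- bl$blocks
  shuffled$A <- shuffled$A[, c(3, 1, 5, 2, 4)]
  d1 <- decompose(fit, bl)
  d2 <- decompose(fit, shuffled)
  expect_equal(d1$gamma, d2$gamma, tolerance = 1e-12)
})

test_that("models serialize to JSON and reload with identical predictions", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5, B = 4), shift = 1, seed = 15)
  fit <- asmbplsda(bl, n_components = 2, lambda = c(0.5, 0.25))
  path <- withr::local_tempfile(fileext = ".json")
  write_asmbplsda(fit, path)
  fit2 <- read_asmbplsda(path)
  expect_equal(predict(fit2, bl), predict(fit, bl), tolerance = 1e-12)
  expect_equal(unname(fit2$lambda), unname(fit$lambda), ignore_attr = TRUE)
})
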