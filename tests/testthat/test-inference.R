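test_that("importance projections sum to one across blocks and within blocks", {
  for (seed in 1:10) {
    bl <- make_blocks(
      n_per_class = 4,
      p = c(A = sample(3:8, 1), B = sample(3:8, 1), C = sample(3:8, 1)),
      shift = runif(1, 0.5, 2), seed = 400 + seed
    )
    J <- sample(1:3, 1)
    fit <- suppressWarnings(
      asmbplsda(bl, n_components = J, lambda = runif(3, 0, 0.6))
    )
    imp <- compute_cip_gip(fit)
    expect_equal(sum(imp$cip$cip), 1, tolerance = 1e-10)
    gip_sums <- tapply(imp$gip$gip, imp$gip$cell_type, sum)
    expect_equal(as.vector(gip_sums), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("single-component cell importance is the squared normalized super weight", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 4, B = 4), shift = 1, seed = 41)
  fit <- asmbplsda(bl, n_components = 1, lambda = 0)
  imp <- compute_cip_gip(fit)
  sw <- fit$super_weights[1, ]
  expect_equal(imp$cip$cip, unname(sw^2 / sum(sw^2)), tolerance = 1e-12)
})

test_that("identical blocks have equal importance; a lambda-1 block has none", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 5), shift = 1, seed = 42)
  twin <- pb_blocks(
    list(A = bl$blocks$A, B = `colnames<-`(bl$blocks$A, paste0("B_", 1:5))),
    bl$samples
  )
  imp <- compute_cip_gip(asmbplsda(twin, n_components = 1, lambda = 0))
  expect_equal(imp$cip$cip[1], imp$cip$cip[2], tolerance = 1e-10)

  fit2 <- asmbplsda(twin, n_components = 1, lambda = c(1, 0))
  imp2 <- compute_cip_gip(fit2)
  expect_equal(imp2$cip$cip[imp2$cip$cell_type == "A"], 0)
  expect_false(imp2$cip$informative[imp2$cip$cell_type == "A"])
  # gene importance of weight-zeroed genes is exactly zero
  expect_true(all(imp2$gip$gip[imp2$gip$cell_type == "A"] == 0))
  zeroed <- fit2$weights[[1]]$B == 0
  if (any(zeroed)) {
    expect_true(all(imp2$gip$gip[imp2$gip$cell_type == "B"][zeroed] == 0))
  }
})

test_that("the true-null Bonferroni factor follows its closed form", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 10, B = 10), shift = 1, seed = 43)
  fit <- asmbplsda(bl, n_components = 2, lambda = matrix(c(0.5, 0.5, 1, 1), 2, 2))
  m0 <- pmax(1, floor(apply(fit$lambda, 2, prod) * fit$p_b))
  expect_equal(unname(m0), c(floor(0.25 * 10), floor(1 * 10)))
  # lambda = 1 throughout presumes every gene null
  expect_equal(unname(pmax(1, floor(prod(c(1, 1)) * 10))), 10)
})

test_that("Benjamini-Hochberg wrapper matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(44)
  p <- runif(25)
  # brute-force step-up oracle
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[ord[k]] * m / k)
    adj[ord[k]] <- prev
  }
  expect_equal(bh_adjust(p), adj, tolerance = 1e-12)
})

test_that("permutation test: strong signal reaches the smallest possible p", {
  bl <- make_blocks(n_per_class = 4, p = c(A = 6, B = 6), shift = 4, seed = 45)
  pt <- permutation_validity_test(bl, J = 1, lambda = 0, n_perm = 99, seed = 46)
  expect_equal(pt$observed_error, 0)
  expect_lte(pt$p_value, 2 / (99 + 1)) # near 1/(n_perm+1), allow one tie
  expect_true(pt$better_than_null)
})

test_that("permutation p-values are reproducible and respect the estimator", {
  bl <- make_blocks(n_per_class = 3, p = c(A = 5), shift = 1, seed = 47)
  p1 <- permutation_validity_test(bl, J = 1, lambda = 0, n_perm = 30, seed = 48)
  p2 <- permutation_validity_test(bl, J = 1, lambda = 0, n_perm = 30, seed = 48)
  expect_identical(p1$null_f1, p2$null_f1)
  expect_identical(p1$p_value, p2$p_value)
  # single permutation: (k+1)/2 forces p into {0.5, 1}
  p3 <- permutation_validity_test(bl, J = 1, lambda = 0, n_perm = 1, seed = 49)
  expect_true(p3$p_value %in% c(0.5, 1))
})

test_that("a planted informative gene earns the smallest adjusted p in its block", {
  hits <- vapply(1:5, function(rep_i) {
    set.seed(500 + rep_i)
    n <- 8
    samples <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:n), class = rep(0:1, each = 4)
    )
    m <- matrix(rnorm(n * 6), n, 6,
      dimnames = list(samples$sample_id, paste0("A_G", 1:6))
    )
    m[samples$class == 1, 1] <- m[samples$class == 1, 1] + 5 # planted gene
    bl <- pb_blocks(list(A = m), samples)
    fit <- asmbplsda(bl, n_components = 1, lambda = 0.5)
    sig <- gip_significance(bl, model = fit, n_perm = 30, seed = 501)
    sig$gene[which.min(sig$adj_p)] == "A_G1"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
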