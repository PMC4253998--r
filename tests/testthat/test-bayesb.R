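test_that("with pi = 0 and fixed variances the sampler matches the ridge posterior", {
  toy <- conj_toy
  spec <- bayesb_spec(pi = 0, n_iter = 12000, burn_in = 2000, seed = 42)
  fit <- bayesb(toy$y, matrix(1, length(toy$y), 1), toy$Z, spec = spec,
                fixed_sigma2_alpha = toy$sigma2_alpha,
                fixed_sigma2_e = toy$sigma2_e, store_effects = TRUE)
  ridge <- ridge_posterior_mean(toy$y, toy$Z, toy$sigma2_alpha, toy$sigma2_e)
  # Monte-Carlo s.e. by batch means (20 batches of the stored chain)
  nb <- 20
  batches <- matrix(NA_real_, nb, ncol(toy$Z))
  idx <- split(seq_len(fit$n_saved),
               rep(seq_len(nb), each = fit$n_saved / nb))
  for (b in seq_len(nb))
    batches[b, ] <- colMeans(fit$effect_samples[idx[[b]], ])
  mcse <- apply(batches, 2, sd) / sqrt(nb)
  expect_true(all(abs(tidy(fit)$effect_mean - ridge) <= 2.5 * mcse + 1e-3))
})

test_that("single-marker conjugate mean matches the scalar closed form", {
  set.seed(50)
  n <- 5
  z <- matrix(c(-1, 0, 0, 1, 0), n, 1, dimnames = list(NULL, "m1"))
  y <- c(0.2, -0.1, 0.4, 1.1, 0.3)
  s2a <- 0.5; s2e <- 0.2
  spec <- bayesb_spec(pi = 0, n_iter = 22000, burn_in = 2000, seed = 3)
  fit <- bayesb(y, matrix(1, n, 1), z, spec = spec,
                fixed_sigma2_alpha = s2a, fixed_sigma2_e = s2e)
  # z is orthogonal to the intercept, so the marker mean is z'y/(z'z + s2e/s2a)
  expect_equal(tidy(fit)$effect_mean,
               sum(z * y) / (sum(z^2) + s2e / s2a), tolerance = 0.02)
})

test_that("chains are bit-for-bit reproducible under the spec seed", {
  toy <- conj_toy
  spec <- bayesb_spec(pi = 0.5, n_iter = 500, burn_in = 100, seed = 77)
  f1 <- bayesb(toy$y, matrix(1, 20, 1), toy$Z, spec = spec,
               store_effects = TRUE)
  f2 <- bayesb(toy$y, matrix(1, 20, 1), toy$Z, spec = spec,
               store_effects = TRUE)
  expect_identical(f1$effect_samples, f2$effect_samples)
  expect_identical(f1$samples, f2$samples)
  expect_identical(glance(f1), glance(f2))
})

test_that("exclusion is consistent: indicator false means effect exactly zero", {
  toy <- conj_toy
  spec <- bayesb_spec(pi = 0.8, n_iter = 600, burn_in = 100, seed = 8)
  fit <- bayesb(toy$y, matrix(1, 20, 1), toy$Z, spec = spec,
                store_effects = TRUE)
  # stored effect samples are exactly 0 whenever excluded; sPPI equals the
  # fraction of nonzero samples
  nz <- colMeans(fit$effect_samples != 0)
  expect_equal(unname(nz), fit$effects$sppi)
})

test_that("null data give near-zero heritability and pi controls model size", {
  set.seed(60)
  cfg <- sim_config(seed = 61, n_sires = 25, progeny_mean = 20,
                    n_chrom = 2, mb_per_chrom = 5, snps_per_mb = 100,
                    n_cg = 4)
  g <- simulate_genotypes(cfg)
  Z <- impute_and_center(g$geno)$Z
  y <- rnorm(nrow(Z))
  spec <- bayesb_spec(pi = 0.995, n_iter = 1500, burn_in = 500, seed = 62)
  fit <- bayesb(y, matrix(1, nrow(Z), 1), Z, map = g$map, spec = spec)
  expect_lt(fit$h2, 0.05)
  # about (1-pi)*M markers fitted per iteration on null data
  expect_lt(abs(mean(fit$samples$n_included) - 0.005 * ncol(Z)),
            0.5 * 0.005 * ncol(Z))
})

test_that("genomic variance identities hold", {
  toy <- conj_toy
  expect_equal(genomic_variance(rep(0, 5), toy$Z), 0)
  a <- c(0.7, 0, 0, 0, 0)
  expect_equal(genomic_variance(a, toy$Z), 0.49 * var(toy$Z[, 1]))
  set.seed(70)
  a2 <- rnorm(5)
  expect_equal(genomic_variance(a2, toy$Z),
               var(as.vector(toy$Z %*% a2)))
})

test_that("heritability worked examples and guards", {
  expect_equal(round(heritability(0.85, 1.55), 2), 0.35)
  expect_equal(round(heritability(24.02, 23.79), 2), 0.50)
  expect_equal(heritability(0, 1), 0)
  expect_error(heritability(0, 0), "positive")
  expect_error(heritability(-1, 1), "non-negative")
})

test_that("window variance partitioning obeys its algebraic structure", {
  set.seed(80)
  n <- 80
  # two blocks of mutually independent markers with equal planted variance
  Z1 <- scale(matrix(rnorm(n * 10), n), scale = FALSE)
  Z2 <- scale(matrix(rnorm(n * 10), n), scale = FALSE)
  # orthogonalise the second block so cross-window sample covariance is 0
  Z2 <- Z2 - Z1 %*% solve(crossprod(Z1), crossprod(Z1, Z2))
  Z <- cbind(Z1, Z2)
  colnames(Z) <- sprintf("s%02d", 1:20)
  map <- tibble::tibble(marker_id = colnames(Z),
                        chrom = "1",
                        bp = round(c(seq(1e5, 9e5, length.out = 10),
                                     seq(1.1e6, 1.9e6, length.out = 10))),
                        allele_a = "A", allele_b = "B")
  a <- c(rnorm(10, 0, 0.3), rnorm(10, 0, 0.3))
  g1 <- as.vector(Z1 %*% a[1:10]); g2 <- as.vector(Z2 %*% a[11:20])
  y <- g1 + g2 + rnorm(n, 0, 0.3)
  spec <- bayesb_spec(pi = 0, n_iter = 2000, burn_in = 500, seed = 81)
  fit <- bayesb(y, matrix(1, n, 1), Z, map = map, spec = spec)
  ws <- window_shares(fit)
  expect_equal(ws$window, c("1_0", "1_1"))
  # equal planted variance -> roughly equal shares, summing to ~100
  expect_equal(sum(ws$pct_va), 100, tolerance = 1e-6)
  share_truth <- 100 * var(g1) / (var(g1) + var(g2))
  expect_equal(ws$pct_va[1], share_truth, tolerance = 12)
  # all markers in one window -> always 100%
  fit1 <- bayesb(y, matrix(1, n, 1), Z, map = NULL, spec = spec)
  expect_equal(window_shares(fit1)$pct_va, 100, tolerance = 1e-8)
})

test_that("sppi lookups behave and errors name unknown markers", {
  toy <- conj_toy
  spec <- bayesb_spec(pi = 0.5, n_iter = 400, burn_in = 100, seed = 90)
  fit <- bayesb(toy$y, matrix(1, 20, 1), toy$Z, spec = spec)
  expect_equal(sppi(fit, "m01"), fit$effects$sppi[1])
  expect_true(all(fit$effects$sppi >= 0 & fit$effects$sppi <= 1))
  expect_error(sppi(fit, "mX"), "unknown marker")
})

test_that("spec validation rejects impossible configurations", {
  expect_error(bayesb_spec(pi = 1), "\\[0, 1\\)")
  expect_error(bayesb_spec(n_iter = 100, burn_in = 100), "burn_in")
  toy <- conj_toy
  expect_error(bayesb(c(toy$y[-1], NA), matrix(1, 20, 1), toy$Z), "finite")
  X_bad <- cbind(1, 1) # rank deficient
  expect_error(bayesb(toy$y, matrix(X_bad[rep(1, 20), ], 20, 2), toy$Z),
               "rank deficient")
})
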