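test_that("window labels use half-open 1-based megabase bins", {
  expect_equal(window_of("7", 23456789), "7_23")
  expect_equal(window_of("7", 1), "7_0")
  expect_equal(window_of("7", 1000000), "7_0")
  expect_equal(window_of("7", 1000001), "7_1")
  expect_equal(window_of(c("X", "MT"), c(115e6 + 5, 300)), c("X_115", "MT_0"))
  expect_error(window_of("chr7", 100), "unknown chromosome")
  expect_error(window_of("7", 0), ">= 1")
})

test_that("phenotype permutation preserves the trait multiset and is seeded", {
  set.seed(20)
  y <- rnorm(30)
  X <- cbind(1, rbinom(30, 1, 0.5))
  p1 <- permute_phenotypes(y, X, seed = 5)
  p2 <- permute_phenotypes(y, X, seed = 5)
  expect_identical(p1$perm, p2$perm)
  expect_equal(sort(p1$y), sort(y))
  expect_equal(p1$X, X[p1$perm, ])
  # planted genotype-phenotype correlation is destroyed
  set.seed(21)
  z <- rnorm(400)
  y2 <- 0.8 * z + rnorm(400, 0, 0.5)
  expect_gt(cor(z, y2), 0.5)
  p3 <- permute_phenotypes(y2, matrix(1, 400), seed = 9)
  expect_lt(abs(cor(z, p3$y)), 3 / sqrt(400))
})

test_that("Johnson Su distribution functions satisfy their identities", {
  p <- johnson_su_params(-1.019, 0.924, 0.018, 0.009)
  # values frozen from independent numerical evaluation of the JS law
  expect_equal(js_sf(0.018, p), pnorm(1.019), tolerance = 1e-6)
  expect_equal(js_sf(0.043, p), 0.2762383, tolerance = 1e-6)
  x <- c(-0.5, 0.01, 0.018, 0.05, 0.2, 2, 50)
  expect_true(all(diff(js_sf(x, p)) < 0))
  expect_equal(js_cdf(x, p) + js_sf(x, p), rep(1, length(x)),
               tolerance = 1e-12)
  # quantile round trip where the cdf is representable in double precision
  xr <- c(-0.5, 0.01, 0.018, 0.05, 0.2, 2)
  expect_equal(js_quantile(js_cdf(xr, p), p), xr, tolerance = 1e-8)
  # density integrates to the cdf differences
  igr <- integrate(js_density, lower = -1, upper = 0.1, params = p,
                   rel.tol = 1e-10)
  expect_equal(igr$value, js_cdf(0.1, p) - js_cdf(-1, p), tolerance = 1e-6)
  expect_error(johnson_su_params(0, -1, 0, 1), "positive")
})

test_that("Johnson Su ML fit recovers known parameters and near-normal shapes", {
  p <- johnson_su_params(-1.019, 0.924, 0.018, 0.009)
  x <- js_sample(1e5, p, seed = 31)
  f <- fit_johnson_su(x)
  expect_lt(abs(f$params$gamma - p$gamma) / abs(p$gamma), 0.05)
  expect_lt(abs(f$params$delta - p$delta) / p$delta, 0.05)
  expect_lt(abs(f$params$theta - p$theta) / p$theta, 0.10)
  expect_lt(abs(f$params$sigma - p$sigma) / p$sigma, 0.10)
  expect_equal(f$n, 1e5)
  # the JS family contains near-normal members
  set.seed(32)
  z <- rnorm(5e4)
  fn <- fit_johnson_su(z)
  q <- quantile(z, 0.95)
  expect_lt(abs(js_sf(q, fn$params) - pnorm(q, lower.tail = FALSE)), 0.005)
  expect_error(fit_johnson_su(rnorm(50)), "at least 100")
})

test_that("tidy and glance report the fitted null parameters", {
  x <- js_sample(5000, johnson_su_params(0.5, 1.2, 1, 2), seed = 33)
  f <- fit_johnson_su(x)
  td <- tidy(f)
  expect_equal(td$term, c("gamma", "delta", "theta", "sigma"))
  gl <- glance(f)
  expect_true(all(c("gamma", "delta", "theta", "sigma", "n",
                    "neg2loglik") %in% names(gl)))
  expect_equal(gl$n, 5000)
})

test_that("Bonferroni correction caps at one, matches p.adjust and is monotone", {
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1e-4, 100), 0.01)
  p <- c(1e-6, 1e-4, 0.02, 0.9)
  expect_equal(bonferroni(p, length(p)), p.adjust(p, "bonferroni"))
  expect_true(all(diff(bonferroni(sort(p), 2684)) >= 0))
  expect_true(all(bonferroni(p, 50) <= bonferroni(p, 500)))
  expect_error(bonferroni(1.2, 10), "\\[0, 1\\]")
})

test_that("QTL calling computes p-values, flags significance and picks lead-SNPs", {
  p <- johnson_su_params(-1.0, 1.0, 0.02, 0.01)
  windows <- tibble::tibble(window = c("1_0", "1_1", "2_5"),
                            n_snps = c(3L, 2L, 2L),
                            pct_va = c(6.0, 0.01, 0.04))
  effects <- tibble::tibble(
    marker_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    window = c("1_0", "1_0", "1_0", "1_1", "1_1", "2_5", "2_5"),
    bp = c(100, 200, 300, 1e6 + 10, 1e6 + 20, 5e6 + 1, 5e6 + 2),
    sppi = c(0.1, 0.9, 0.3, 0.2, 0.2, 0.5, 0.5))
  qt <- call_qtl(windows, p, effects = effects)
  expect_equal(qt$window, c("1_0", "1_1", "2_5")) # sorted by chrom, Mb
  expect_equal(qt$nominal_p, js_sf(qt$pct_va, p))
  expect_equal(qt$bonferroni_p, pmin(1, 3 * qt$nominal_p))
  expect_true(qt$significant[qt$window == "1_0"])
  expect_false(any(qt$significant[qt$window != "1_0"]))
  # below the null median is never significant
  expect_gt(qt$nominal_p[qt$window == "1_1"], 0.5)
  expect_equal(qt$lead_snp[qt$window == "1_0"], "s2")  # highest sPPI
  expect_equal(qt$lead_snp[qt$window == "1_1"], "s4")  # tie -> smaller bp
  expect_equal(qt$lead_sppi[qt$window == "1_0"], 0.9)
  # alpha = 0 yields no significant windows
  qt0 <- call_qtl(windows, p, effects = effects, alpha = 0)
  expect_false(any(qt0$significant))
  # per-trait parameter maps, with one trait reusing another's null
  qmap <- list(RFI = p)
  expect_error(call_qtl(windows, qmap, trait = "MBW"), "no null parameters")
  qt2 <- call_qtl(windows, qmap, trait = "RFI")
  expect_equal(qt2$nominal_p, qt$nominal_p)
})

test_that("null sample layout pools windows across replicates", {
  set.seed(40)
  n <- 60
  Z <- matrix(rnorm(n * 40), n)
  colnames(Z) <- sprintf("s%02d", 1:40)
  Z <- scale(Z, scale = FALSE)
  map <- tibble::tibble(marker_id = colnames(Z),
                        chrom = rep(c("1", "2"), each = 20),
                        bp = round(rep(c(seq(1e5, 9e5, length.out = 10),
                                         seq(11e5, 19e5, length.out = 10)), 2)),
                        allele_a = "A", allele_b = "B")
  y <- rnorm(n)
  spec <- bayesb_spec(pi = 0.5, n_iter = 300, burn_in = 100, seed = 2)
  n1 <- build_null(y, matrix(1, n), Z, map, spec, n_replicates = 1, seed = 7)
  expect_equal(nrow(n1), 4) # 4 windows, one replicate
  n5 <- build_null(y, matrix(1, n), Z, map, spec, n_replicates = 5, seed = 7)
  expect_equal(nrow(n5), 20)
  expect_equal(attr(n5, "n_windows"), 4)
  # replicate 1 of the pooled run reproduces the single-replicate run
  expect_equal(n5$share[n5$replicate == 1], n1$share)
})
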