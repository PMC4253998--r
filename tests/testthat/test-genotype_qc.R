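test_that("animal call rate counts non-missing genotypes", {
  tg <- tiny_geno()
  cr <- animal_call_rate(tg$geno)
  expect_equal(unname(cr[c("a1", "a2", "a3")]), c(5 / 6, 5 / 6, 1))
  g10 <- matrix(c(rep(0L, 9), NA), 1, 10,
                dimnames = list("z", paste0("m", 1:10)))
  expect_equal(unname(animal_call_rate(g10)), 0.9)
  g10[] <- NA_integer_
  expect_equal(unname(animal_call_rate(g10)), 0)
  expect_error(animal_call_rate(tg$geno, "nope"), "unknown animal")
})

test_that("heterozygosity uses the non-missing denominator per chromosome class", {
  geno <- matrix(c(0L, 1L, 1L, 2L,  1L, NA,  0L, 0L, 2L),
                 nrow = 1, dimnames = list("a", paste0("m", 1:9)))
  map <- tibble::tibble(marker_id = paste0("m", 1:9),
                        chrom = c("1", "1", "2", "3", "X", "X",
                                  "MT", "MT", "MT"),
                        bp = 1:9, allele_a = "A", allele_b = "B")
  expect_equal(unname(heterozygosity(geno, map, "autosomes")), 0.5)
  expect_equal(unname(heterozygosity(geno, map, "x")), 1) # 1 het of 1 called
  expect_equal(unname(heterozygosity(geno, map, "mt")), 0)
  expect_true(is.na(heterozygosity(geno, map, "y"))) # empty subset
  geno[1, 5:6] <- NA_integer_
  expect_true(is.na(heterozygosity(geno, map, "x"))) # all missing
})

test_that("sex assignment reproduces the full decision table", {
  # HD quadrants
  expect_equal(assign_sex(0.01, 0.9, "assayHD"), "male")
  expect_equal(assign_sex(0.20, 0.9, "assayHD"), "klinefelter")
  expect_equal(assign_sex(0.20, 0.1, "assayHD"), "female")
  expect_warning(lowlow <- assign_sex(0.01, 0.1, "assayHD"), "low Y")
  expect_equal(lowlow, "male")
  # 50K branches ignore Y entirely
  expect_equal(assign_sex(0.20, NA, "assay50K"), "female")
  expect_equal(assign_sex(0.01, NA, "assay50K"), "male")
  # boundary: threshold is strict <
  expect_equal(assign_sex(0.03, 0.5, "assayHD"), "klinefelter")
  expect_error(assign_sex(1.2, 0.5, "assayHD"), "\\[0, 1\\]")
})

test_that("chi-square HWE p-values match direct computation and handle edge cases", {
  expect_equal(hwe_pvalue(25, 50, 25), 1)
  # 50/0/50: statistic is exactly 100
  expect_equal(hwe_pvalue(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_pvalue(50, 0, 50), 3e-9)
  expect_equal(hwe_pvalue(100, 0, 0), 1) # monomorphic
  expect_error(hwe_pvalue(0, 0, 0), "zero")
  # exact test agrees to the decision deep in the tail
  expect_lt(hwe_pvalue(50, 0, 50, method = "exact"), 3e-9)
  expect_gt(hwe_pvalue(25, 50, 25, method = "exact"), 0.5)
})

test_that("chi-square HWE agrees with a Monte-Carlo oracle when cells are large", {
  cases <- list(c(30, 45, 25), c(40, 40, 20), c(55, 30, 15))
  set.seed(42)
  # the oracle re-estimates the allele frequency in every resample, as the
  # test itself does
  stat_of <- function(m) {
    n <- colSums(m)
    p <- (2 * m[1, ] + m[2, ]) / (2 * n)
    e <- rbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    colSums((m - e)^2 / pmax(e, 1e-300))
  }
  for (cts in cases) {
    n <- sum(cts)
    p <- (2 * cts[1] + cts[2]) / (2 * n)
    probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    obs <- stat_of(matrix(cts, 3))
    sim <- stat_of(rmultinom(1e5, n, probs))
    mc_p <- mean(sim >= obs - 1e-9)
    chi_p <- hwe_pvalue(cts[1], cts[2], cts[3])
    expect_lt(abs(chi_p - mc_p) / mc_p, 0.10)
  }
})

test_that("marker and animal filters remove exactly the planted violations", {
  fa <- filter_animals(qc_panel$geno, qc_panel$map, qc_panel$platform)
  bad_a <- fa$report[!fa$report$kept, ]
  expect_equal(setNames(bad_a$reason, bad_a$animal_id),
               qc_panel$planted$animals)
  fm <- filter_markers(fa$geno, qc_panel$map, fa$sex)
  bad_m <- fm$report[!fm$report$kept, ]
  expect_equal(setNames(bad_m$reason, bad_m$marker_id),
               qc_panel$planted$markers)
  # kept-set sizes
  expect_equal(nrow(fa$geno), nrow(qc_panel$geno) - 3)
  expect_equal(ncol(fm$geno), ncol(qc_panel$geno) - 5)
})

test_that("filtering is idempotent", {
  fa <- filter_animals(qc_panel$geno, qc_panel$map, qc_panel$platform)
  fm <- filter_markers(fa$geno, qc_panel$map, fa$sex)
  fa2 <- filter_animals(fm$geno, fm$map, qc_panel$platform[rownames(fm$geno)])
  expect_true(all(fa2$report$kept))
  fm2 <- filter_markers(fa2$geno, fm$map, fa2$sex)
  expect_true(all(fm2$report$kept))
})

test_that("thresholds behave as strict boundaries on worked examples", {
  rep_a <- qc_animals(qc_panel$geno, qc_panel$map, qc_panel$platform)
  expect_lt(rep_a$call_rate[rep_a$animal_id == "an01"], 0.90)
  expect_gt(rep_a$autosomal_het[rep_a$animal_id == "an02"], 0.45)
  expect_equal(rep_a$sex[rep_a$animal_id == "an03"], "klinefelter")
  # a clean marker is kept
  fa <- filter_animals(qc_panel$geno, qc_panel$map, qc_panel$platform)
  rep_m <- qc_markers(fa$geno, qc_panel$map, fa$sex)
  clean <- rep_m[rep_m$marker_id == "a010", ]
  expect_true(clean$kept)
  expect_gt(clean$call_rate, 0.85)
  expect_gt(clean$maf, 0.001)
  expect_gt(clean$hwe_p, 3e-9)
})

test_that("mean imputation and centering reconstructs and centers exactly", {
  col <- matrix(c(0L, 2L, NA), 3, 1, dimnames = list(letters[1:3], "m"))
  ic <- impute_and_center(col)
  expect_equal(ic$means[["m"]], 1)
  expect_equal(as.vector(ic$Z), c(-1, 1, 0))
  const <- matrix(1L, 3, 1, dimnames = list(letters[1:3], "m"))
  expect_equal(as.vector(impute_and_center(const)$Z), c(0, 0, 0))
  ic2 <- impute_and_center(qc_panel$geno)
  expect_true(all(abs(colMeans(ic2$Z)) < 1e-12))
  allna <- matrix(NA_integer_, 2, 1, dimnames = list(c("a", "b"), "m"))
  expect_error(impute_and_center(allna), "all genotypes missing")
})
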