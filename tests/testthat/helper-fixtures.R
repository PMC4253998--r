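# Shared small fixtures, built once per test run.

qc_panel <- fixture_suite("qc_panel")
conj_toy <- fixture_suite("conjugate_toy")

# tiny deterministic genotype matrix + map for unit tests
tiny_geno <- function() {
  geno <- matrix(
    c(0L, 1L, 2L, NA, 1L, 0L,
      2L, 2L, 0L, 1L, NA, 1L,
      0L, 0L, 0L, 0L, 1L, 2L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("a1", "a2", "a3"),
                    c("m1", "m2", "m3", "m4", "m5", "m6")))
  map <- tibble::tibble(
    marker_id = paste0("m", 1:6),
    chrom = c("1", "1", "2", "X", "paX", "MT"),
    bp = c(100L, 500000L, 1500000L, 200L, 300L, 50L),
    allele_a = "A", allele_b = "B")
  list(geno = geno, map = map)
}

ridge_posterior_mean <- function(y, Z, s2a, s2e) {
  A <- crossprod(Z) + diag(s2e / s2a, ncol(Z))
  as.vector(solve(A, crossprod(Z, y - mean(y))))
}
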