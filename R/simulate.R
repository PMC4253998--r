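# Half-sib feeding-trial simulator. Generates LD-structured biallelic SNP
# genotypes for sire half-sib families, breeding values with planted 1-Mb
# window QTL and a polygenic background, and the raw records (serial
# weights, daily intakes, contemporary groups) that the trait-derivation
# stage consumes. Everything is seed-determined.
#
# Default scale follows a single-herd national-test design: 40 sires with
# half-sib groups averaging 21.2 progeny and 10 contemporary groups;
# default heritabilities and variance components sit in the ranges reported
# for feedlot ADG / DMI / MBW / RFI (e.g. h2 0.27 / 0.41 / 0.50 / 0.45).
# LD comes from blockwise copying out of a small haplotype pool: gametes
# copy a whole 1-Mb block from one pool haplotype, giving strong
# within-window correlation and negligible cross-window correlation.

#' Simulation configuration
#'
#' @param seed Master seed; all outputs are byte-identical given the seed.
#' @param n_sires Number of sires.
#' @param progeny_mean Mean half-sib family size (Poisson, minimum 1).
#' @param n_chrom,mb_per_chrom,snps_per_mb Marker layout: chromosomes
#'   labelled "1", "2", ... each spanning `mb_per_chrom` 1-Mb windows with
#'   `snps_per_mb` SNPs per window.
#' @param pool_size Number of haplotypes in the founder pool (smaller =
#'   stronger LD).
#' @param freq_range Range of pool allele frequencies.
#' @param n_cg Number of contemporary groups.
#' @param cg_sd Standard deviation of contemporary-group effects, per trait
#'   (named: ADG, MBW, RFI; the RFI entry acts on the DMI deviation).
#' @param qtl Tibble of planted QTL: columns `window`, `trait` (one of
#'   ADG, MBW, RFI), `frac_va` (fraction of that trait's additive variance),
#'   `n_snps` (causal SNPs per window, default 5). `NULL` for none.
#' @param h2,va Named per-trait heritabilities and additive variances for
#'   the latent traits ADG (kg/d), MBW (kg^0.75) and RFI (the DMI deviation,
#'   kg/d).
#' @param gen_cor 3x3 genetic correlation matrix over (ADG, MBW, RFI)
#'   breeding values (positive definite).
#' @param mu Named trait means (ADG kg/d, MBW kg^0.75; RFI deviation is
#'   centred at `mu["RFI"]`).
#' @param dmi_on_adg,dmi_on_mbw Partial-regression coefficients composing
#'   DMI from ADG and MBW phenotypes plus the deviation.
#' @param bg_per_window Number of polygenic background markers per 1-Mb
#'   window (`NULL`: every marker carries background effect).
#' @param test_days,weigh_every Feeding-test length (d) and weighing
#'   interval (d).
#' @param weight_noise_sd Weighing error s.d. (kg).
#' @param intake_noise_sd Day-to-day as-fed intake s.d. (kg).
#' @param dm_fraction Ration dry-matter fraction.
#' @param missing_rate Fraction of genotypes set missing.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sires = 40, progeny_mean = 21.2,
                       n_chrom = 3, mb_per_chrom = 10, snps_per_mb = 100,
                       pool_size = 30, freq_range = c(0.1, 0.9),
                       n_cg = 10,
                       cg_sd = c(ADG = 0.1, MBW = 3, RFI = 0.3),
                       qtl = NULL,
                       h2 = c(ADG = 0.27, MBW = 0.50, RFI = 0.45),
                       va = c(ADG = 0.02, MBW = 24.0, RFI = 0.32),
                       gen_cor = matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3, 3,
                                        dimnames = list(c("ADG", "MBW", "RFI"),
                                                        c("ADG", "MBW", "RFI"))),
                       mu = c(ADG = 1.5, MBW = 92.8, RFI = 0),
                       dmi_on_adg = 1.5, dmi_on_mbw = 0.09,
                       bg_per_window = NULL,
                       test_days = 70, weigh_every = 10,
                       weight_noise_sd = 3, intake_noise_sd = 1,
                       dm_fraction = 0.85, missing_rate = 0) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0,1)", call. = FALSE)
  ev <- eigen(gen_cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("genetic correlation matrix must be positive definite",
         call. = FALSE)
  if (!is.null(qtl)) {
    qtl <- tibble::as_tibble(qtl)
    if (!"n_snps" %in% names(qtl)) qtl$n_snps <- 5L
    sums <- tapply(qtl$frac_va, qtl$trait, sum)
    if (any(sums >= 1))
      stop("planted QTL fractions must sum to < 1 per trait", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# one gamete: per 1-Mb block, copy that block from a random pool haplotype
.gamete_from_pool <- function(pool, block_of) {
  pick <- sample.int(nrow(pool), max(block_of), replace = TRUE)
  pool[cbind(pick[block_of], seq_along(block_of))]
}

#' Simulate half-sib genotypes with within-window LD
#'
#' Founder haplotypes are drawn from a `pool_size`-haplotype pool by
#' blockwise (1-Mb) copying; each sire carries two pooled gametes; each
#' progeny receives one recombination-free-within-block gamete from its
#' sire (one of the sire's two haplotypes chosen per block) and one fresh
#' pool gamete for the unobserved dam.
#'
#' @param config A [sim_config()].
#' @return List: `geno` (animals x markers 0/1/2 matrix), `map`
#'   (marker-map tibble), `pedigree` (tibble `animal_id`, `sire`),
#'   `pool_freq` (founder-pool allele frequencies per marker).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    M_mb <- config$n_chrom * config$mb_per_chrom
    M <- M_mb * config$snps_per_mb
    chrom <- rep(as.character(seq_len(config$n_chrom)),
                 each = config$mb_per_chrom * config$snps_per_mb)
    mb_in_chrom <- rep(rep(seq_len(config$mb_per_chrom) - 1L,
                           each = config$snps_per_mb), config$n_chrom)
    pos_in_mb <- rep(round(seq(5000, 995000,
                               length.out = config$snps_per_mb)), M_mb)
    bp <- mb_in_chrom * 1e6 + pos_in_mb
    map <- tibble::tibble(
      marker_id = sprintf("snp%05d", seq_len(M)),
      chrom = chrom, bp = as.integer(bp),
      allele_a = "A", allele_b = "B")
    block_of <- rep(seq_len(M_mb), each = config$snps_per_mb)

    freq <- runif(M, config$freq_range[1], config$freq_range[2])
    pool <- matrix(rbinom(config$pool_size * M, 1L,
                          rep(freq, each = config$pool_size)),
                   nrow = config$pool_size)

    sire_h1 <- t(replicate(config$n_sires, .gamete_from_pool(pool, block_of)))
    sire_h2 <- t(replicate(config$n_sires, .gamete_from_pool(pool, block_of)))

    fam <- pmax(1L, rpois(config$n_sires, config$progeny_mean))
    n <- sum(fam)
    sire_of <- rep(seq_len(config$n_sires), fam)
    geno <- matrix(0L, n, M)
    for (i in seq_len(n)) {
      s <- sire_of[i]
      use2 <- sample(c(TRUE, FALSE), M_mb, replace = TRUE)[block_of]
      pat <- ifelse(use2, sire_h2[s, ], sire_h1[s, ])
      mat <- .gamete_from_pool(pool, block_of)
      geno[i, ] <- pat + mat
    }
    if (config$missing_rate > 0)
      geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
    ids <- sprintf("an%04d", seq_len(n))
    dimnames(geno) <- list(ids, map$marker_id)
    list(geno = geno, map = map,
         pedigree = tibble::tibble(animal_id = ids,
                                   sire = sprintf("sire%02d", sire_of)),
         pool_freq = setNames(colMeans(pool), map$marker_id))
  })
}

# scale a genomic-value vector to an exact target variance
.scale_to_var <- function(g, target) {
  v <- var(g)
  if (v <= 0 || target <= 0) return(list(g = g * 0, k = 0))
  k <- sqrt(target / v)
  list(g = g * k, k = k)
}

#' Simulate correlated traits and feeding-trial records
#'
#' Breeding values are the sum of planted window-QTL effects (scaled so
#' each window explains its configured fraction of the trait's additive
#' variance) and a polygenic background on markers outside the QTL windows
#' (correlated across traits via the configured genetic correlations, and
#' scaled so total additive variance hits the target). Phenotypes add
#' contemporary-group effects and normal residuals sized for the target
#' heritabilities. DMI is composed as partial regressions on the ADG and
#' MBW phenotypes plus its own deviation, so the deviation carries the true
#' RFI signal. Weight series follow the linear growth line implied by ADG
#' and mid-test weight plus weighing error; daily intakes are consistent
#' with DMI and the dry-matter fraction.
#'
#' @param sim_geno Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List: `weights`, `intakes`, `groups` (record tibbles in the
#'   reader formats) and `truth` (tibble of true breeding values and
#'   phenotype components, with attributes `qtl` — planted and realised
#'   window fractions — and `h2`, `va`).
#' @export
simulate_traits <- function(sim_geno, config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed + 1L, {
    geno <- sim_geno$geno
    map <- sim_geno$map
    n <- nrow(geno); M <- ncol(geno)
    Z <- impute_and_center(geno)$Z
    win <- window_of(map$chrom, map$bp)
    traits <- c("ADG", "MBW", "RFI")

    qtl <- config$qtl
    # Polygenic background on every marker, balanced across windows: each
    # window's background component is scaled to an equal share of the
    # background variance and made orthogonal to any planted QTL component
    # in the same window. Realized window variance fractions then match
    # their nominal values (planted windows: QTL fraction + one background
    # share; other windows: one background share), mirroring the
    # infinitesimal-model picture of evenly spread polygenic variance.
    L <- chol(config$gen_cor[traits, traits])
    raw <- matrix(rnorm(M * 3), ncol = 3) %*% L
    colnames(raw) <- traits
    win_idx <- split(seq_len(M), win)
    W <- length(win_idx)
    # optional background concentration: a fixed subset per window carries
    # the polygenic effects (the same subset for every trait)
    bg_keep <- NULL
    if (!is.null(config$bg_per_window))
      bg_keep <- lapply(win_idx, function(ix)
        sort(sample(ix, min(config$bg_per_window, length(ix)))))

    bv <- matrix(0, n, 3, dimnames = list(rownames(geno), traits))
    eff_true <- matrix(0, M, 3, dimnames = list(colnames(geno), traits))
    qtl_real <- NULL
    for (tr in traits) {
      va_t <- config$va[[tr]]
      eff_t <- rep(0, M)
      q_rows <- if (is.null(qtl)) NULL else qtl[qtl$trait == tr, ]
      frac_q <- if (is.null(q_rows)) 0 else sum(q_rows$frac_va)
      qtl_g <- list() # per planted window, the QTL genomic-value vector
      if (!is.null(q_rows) && nrow(q_rows)) {
        for (k in seq_len(nrow(q_rows))) {
          widx <- which(win == q_rows$window[k])
          if (!length(widx))
            stop("planted QTL window ", q_rows$window[k],
                 " has no markers", call. = FALSE)
          cau <- sample(widx, min(q_rows$n_snps[k], length(widx)))
          eff <- rnorm(length(cau))
          gk <- as.vector(Z[, cau, drop = FALSE] %*% eff)
          sc <- .scale_to_var(gk, q_rows$frac_va[k] * va_t)
          eff_t[cau] <- eff_t[cau] + eff * sc$k
          qtl_g[[q_rows$window[k]]] <- sc$g
        }
      }
      bg_target <- (1 - frac_q) * va_t / W
      for (w in names(win_idx)) {
        ix <- win_idx[[w]]
        e_w <- raw[ix, tr]
        if (!is.null(config$bg_per_window) &&
            config$bg_per_window < length(ix)) {
          keep <- bg_keep[[w]]
          e_w[!(ix %in% keep)] <- 0
        }
        g_w <- as.vector(Z[, ix, drop = FALSE] %*% e_w)
        gq <- qtl_g[[w]]
        if (!is.null(gq) && var(gq) > 0) {
          # orthogonalise the window background against its QTL component
          beta <- cov(g_w, gq) / var(gq)
          g_w <- g_w - beta * gq
          e_w <- e_w - beta * eff_t[ix]
        }
        sc <- .scale_to_var(g_w, bg_target)
        eff_t[ix] <- eff_t[ix] + e_w * sc$k
      }
      g_t <- as.vector(Z %*% eff_t)
      sc <- .scale_to_var(g_t, va_t) # exact total additive variance
      eff_t <- eff_t * sc$k
      bv[, tr] <- sc$g
      eff_true[, tr] <- eff_t
      if (!is.null(q_rows) && nrow(q_rows)) {
        qtl_real <- rbind(qtl_real, tibble::tibble(
          window = q_rows$window, trait = tr,
          frac_planted = q_rows$frac_va,
          frac_realized = vapply(q_rows$window, function(w) {
            ix <- win_idx[[w]]
            var(as.vector(Z[, ix, drop = FALSE] %*% eff_t[ix])) /
              var(bv[, tr])
          }, numeric(1)) - (1 - frac_q) / W))
      }
    }

    cg <- sample(sprintf("cg%02d", seq_len(config$n_cg)), n, replace = TRUE)
    cg_eff <- sapply(traits, function(tr)
      setNames(rnorm(config$n_cg, 0, config$cg_sd[[tr]]),
               sprintf("cg%02d", seq_len(config$n_cg))))
    ve <- config$va[traits] * (1 - config$h2[traits]) / config$h2[traits]
    e <- sapply(traits, function(tr) rnorm(n, 0, sqrt(ve[[tr]])))

    adg <- unname(config$mu[["ADG"]] + cg_eff[cg, "ADG"] + bv[, "ADG"] +
                    e[, "ADG"])
    mbw <- unname(config$mu[["MBW"]] + cg_eff[cg, "MBW"] + bv[, "MBW"] +
                    e[, "MBW"])
    dev <- unname(config$mu[["RFI"]] + cg_eff[cg, "RFI"] + bv[, "RFI"] +
                    e[, "RFI"])
    dmi_true <- config$dmi_on_adg * adg + config$dmi_on_mbw * mbw + dev
    adg <- pmax(adg, 0.05)
    mbw <- pmax(mbw, 1)
    dmi_true <- pmax(dmi_true, 0.1)
    midwt <- mbw^(4 / 3)

    days <- seq(0, config$test_days, by = config$weigh_every)
    ids <- rownames(geno)
    weights <- tidyr::expand_grid(animal_id = ids, day = days) |>
      dplyr::mutate(weight_kg = midwt[match(.data$animal_id, ids)] +
                      adg[match(.data$animal_id, ids)] *
                      (.data$day - config$test_days / 2) +
                      rnorm(dplyr::n(), 0, config$weight_noise_sd))
    feed_days <- seq_len(config$test_days)
    intakes <- tidyr::expand_grid(animal_id = ids, day = feed_days) |>
      dplyr::mutate(intake_asfed_kg = pmax(0,
        dmi_true[match(.data$animal_id, ids)] / config$dm_fraction +
          rnorm(dplyr::n(), 0, config$intake_noise_sd)),
        dm_fraction = config$dm_fraction)
    groups <- tibble::tibble(animal_id = ids, cg = cg)

    truth <- tibble::tibble(
      animal_id = ids, sire = sim_geno$pedigree$sire, cg = cg,
      bv_adg = bv[, "ADG"], bv_mbw = bv[, "MBW"], bv_rfi = bv[, "RFI"],
      bv_dmi = config$dmi_on_adg * bv[, "ADG"] +
        config$dmi_on_mbw * bv[, "MBW"] + bv[, "RFI"],
      adg = adg, mbw = mbw, dmi = dmi_true)
    attr(truth, "qtl") <- qtl_real
    attr(truth, "h2") <- config$h2
    attr(truth, "va") <- config$va
    attr(truth, "effects") <- eff_true
    list(weights = weights, intakes = intakes, groups = groups,
         truth = truth)
  })
}

#' Simulate a complete feeding-trial dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_traits()].
#'
#' @param config A [sim_config()].
#' @return List: `geno`, `map`, `pedigree`, `weights`, `intakes`,
#'   `groups`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  c(g, simulate_traits(g, config))
}

#' Bundled deterministic mini-fixtures
#'
#' Small seed-fixed datasets used throughout the test-suite:
#' \describe{
#'   \item{qc_panel}{A genotype panel with exactly one planted violation of
#'     each animal- and marker-level QC rule.}
#'   \item{conjugate_toy}{20 animals x 5 markers with a known-variance
#'     normal model (for conjugate closed-form checks).}
#'   \item{recovery}{n = 500, M = 2,000 in 20 windows, two QTL windows
#'     planted at 5\% of additive variance each, h2 = 0.40.}
#'   \item{null}{Same scale with no planted QTL.}
#' }
#'
#' @param which One of `"qc_panel"`, `"conjugate_toy"`, `"recovery"`,
#'   `"null"`.
#' @param seed Seed (defaults differ per fixture but can be overridden to
#'   draw replicate datasets).
#' @return The fixture dataset (shape depends on `which`).
#' @export
fixture_suite <- function(which = c("qc_panel", "conjugate_toy",
                                    "recovery", "null"),
                          seed = NULL) {
  which <- match.arg(which)
  switch(which,
    qc_panel = .fixture_qc_panel(seed %||% 11L),
    conjugate_toy = .fixture_conjugate_toy(seed %||% 12L),
    recovery = simulate_dataset(recovery_config(seed %||% 13L)),
    null = simulate_dataset(null_config(seed %||% 14L)))
}

#' Recovery-fixture configuration
#'
#' n ~ 500 (25 sires x ~20 progeny), M = 2,000 markers in 20 windows over
#' 2 chromosomes, two MBW QTL windows ("1_3", "2_7") planted at 5\% of
#' additive variance each on 2 causal SNPs, all heritabilities 0.40. The
#' haplotype pool is small (8) so each 1-Mb window behaves as a tight
#' haplotype block, the regime in which a 5\%-of-variance window is
#' recoverable at this sample size.
#'
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
recovery_config <- function(seed = 13L) {
  sim_config(
    seed = seed, n_sires = 25, progeny_mean = 20,
    n_chrom = 2, mb_per_chrom = 10, snps_per_mb = 100,
    pool_size = 8, n_cg = 5,
    qtl = tibble::tibble(window = c("1_3", "2_7"), trait = "MBW",
                         frac_va = 0.05, n_snps = 2L),
    h2 = c(ADG = 0.40, MBW = 0.40, RFI = 0.40))
}

#' Null-fixture configuration (no QTL)
#'
#' Reduced scale for family-wise error checks: n ~ 300, M = 1,000 markers
#' in 20 windows, no planted QTL.
#'
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
null_config <- function(seed = 14L) {
  sim_config(
    seed = seed, n_sires = 15, progeny_mean = 20,
    n_chrom = 2, mb_per_chrom = 10, snps_per_mb = 50,
    n_cg = 5, qtl = NULL,
    h2 = c(ADG = 0.40, MBW = 0.40, RFI = 0.40))
}

.fixture_qc_panel <- function(seed) {
  local_seed(seed, {
    n <- 60; n_auto <- 60; n_x <- 40
    map <- tibble::tibble(
      marker_id = c(sprintf("a%03d", seq_len(n_auto)),
                    sprintf("x%02d", seq_len(n_x)), sprintf("px%02d", 1:4),
                    sprintf("y%02d", 1:4), sprintf("mt%02d", 1:4)),
      chrom = c(rep(c("1", "2"), each = n_auto / 2),
                rep("X", n_x), rep("paX", 4), rep("Y", 4), rep("MT", 4)),
      bp = as.integer(c(seq(1e5, 3e6, length.out = n_auto),
                        seq(1e5, 4e6, length.out = n_x),
                        seq(1e5, 4e5, length.out = 4),
                        seq(1e5, 4e5, length.out = 4),
                        seq(100, 400, length.out = 4))),
      allele_a = "A", allele_b = "B")
    M <- nrow(map)
    ids <- sprintf("an%02d", seq_len(n))
    # moderate allele frequencies keep baseline autosomal het ~0.3,
    # well clear of the 0.45 animal threshold
    freq <- runif(M, 0.08, 0.2)
    geno <- matrix(rbinom(n * M, 2L, rep(freq, each = n)), n, M,
                   dimnames = list(ids, map$marker_id))
    is_x <- map$chrom == "X"; is_y <- map$chrom == "Y"
    is_mt <- map$chrom == "MT"
    # default: everyone a clean HD male (hemizygous X/Y, haploid MT)
    geno[, is_x] <- rbinom(n * sum(is_x), 1L, 0.5) * 2L
    geno[, is_y] <- rbinom(n * sum(is_y), 1L, 0.5) * 2L
    geno[, is_mt] <- rbinom(n * sum(is_mt), 1L, 0.5) * 2L
    # an01: call rate ~0.80 (< 0.90)
    geno["an01", seq_len(round(0.2 * M))] <- NA_integer_
    # an02: autosomal heterozygosity 1 (> 0.45)
    geno["an02", map$chrom %in% c("1", "2")] <- 1L
    # an03: Klinefelter — heterozygous X together with Y calls
    geno["an03", is_x] <- 1L
    # an04-an06: females — diploid X, no Y calls
    females <- c("an04", "an05", "an06")
    geno[females, is_x] <- matrix(rbinom(length(females) * sum(is_x), 2L, 0.5),
                                  length(females))
    geno[females, map$chrom == "paX"] <-
      matrix(rbinom(length(females) * 4, 2L, 0.5), length(females))
    geno[females, is_y] <- NA_integer_
    # marker a001: call rate < 0.85 among kept animals
    geno[seq_len(round(0.25 * n)), "a001"] <- NA_integer_
    # marker a002: monomorphic (MAF 0 < 0.001)
    geno[, "a002"] <- 0L
    # marker a003: both homozygotes, no heterozygote (extreme HWE violation)
    geno[, "a003"] <- rep(c(0L, 2L), length.out = n)
    # marker x01: heterozygous in every male (marker-level het > 0.03) while
    # each male's own X het stays 1/n_x = 0.025 < 0.03
    geno[setdiff(ids, females), "x01"] <- 1L
    # marker mt01: heterozygous (> 0.03)
    geno[, "mt01"] <- 1L
    platform <- setNames(rep("assayHD", n), ids)
    list(geno = geno, map = map, platform = platform,
         planted = list(
           animals = c(an01 = "call_rate", an02 = "heterozygosity",
                       an03 = "klinefelter"),
           markers = c(a001 = "call_rate", a002 = "maf", a003 = "hwe",
                       x01 = "male_xy_het", mt01 = "mt_het")))
  })
}

.fixture_conjugate_toy <- function(seed) {
  local_seed(seed, {
    n <- 20; M <- 5
    geno <- matrix(rbinom(n * M, 2L, 0.5), n, M,
                   dimnames = list(sprintf("an%02d", 1:n),
                                   sprintf("m%02d", 1:M)))
    Z <- impute_and_center(geno)$Z
    a_true <- c(0.5, -0.3, 0.2, 0, 0.4)
    y <- 2 + as.vector(Z %*% a_true) + rnorm(n, 0, 0.5)
    list(geno = geno, Z = Z, y = y, a_true = a_true,
         sigma2_e = 0.25, sigma2_alpha = 0.2)
  })
}
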