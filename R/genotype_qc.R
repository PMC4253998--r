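# Genotype quality control: animal- and marker-level filters for SNP array
# data, including sex / XXY (Klinefelter) assignment from X heterozygosity
# and Y call rate.
#
# Genotypes are coded 0/1/2 (count of B alleles, Illumina A/B convention)
# with NA for no-calls, in an animals x markers integer matrix whose dimnames
# carry animal and marker ids. The marker map is a tibble with columns
# marker_id, chrom, bp (1-based), allele_a, allele_b; chrom labels come from
# {1..29, X, paX, Y, MT} — the pseudo-autosomal region of X is its own label
# ("paX") supplied by the map, never inferred from coordinates.

.chrom_levels <- c(as.character(1:29), "X", "paX", "Y", "MT")

#' Validate a marker map
#'
#' Checks the invariants the rest of the pipeline relies on: unique marker
#' ids, positive 1-based positions, and chromosome labels from
#' `{1..29, X, paX, Y, MT}`.
#'
#' @param map A data frame with columns `marker_id`, `chrom`, `bp` (and
#'   optionally `allele_a`, `allele_b`).
#' @return The map as a tibble, invisibly usable downstream.
#' @export
validate_marker_map <- function(map) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("marker_id", "chrom", "bp") %in% names(map)))
  map$chrom <- as.character(map$chrom)
  if (anyDuplicated(map$marker_id))
    stop("marker ids must be unique", call. = FALSE)
  if (any(map$bp < 1 | map$bp != round(map$bp)))
    stop("bp must be positive 1-based integer positions", call. = FALSE)
  bad <- setdiff(unique(map$chrom), .chrom_levels)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  map
}

.check_geno <- function(geno) {
  if (!is.matrix(geno)) stop("genotypes must be a matrix", call. = FALSE)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs animal rownames and marker colnames",
         call. = FALSE)
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  invisible(geno)
}

#' Per-animal genotype call rate
#'
#' Fraction of markers with a non-missing genotype for each animal.
#'
#' @param geno Animals x markers genotype matrix (codes 0/1/2, NA missing).
#' @param animal Optional animal id (or vector of ids); default all animals.
#' @return Named numeric vector of call rates in `[0, 1]`.
#' @export
animal_call_rate <- function(geno, animal = NULL) {
  .check_geno(geno)
  if (!is.null(animal)) {
    missing_ids <- setdiff(animal, rownames(geno))
    if (length(missing_ids))
      stop("unknown animal id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    geno <- geno[animal, , drop = FALSE]
  }
  rowMeans(!is.na(geno))
}

# marker-class selector -> logical index into map rows
.marker_subset <- function(map, subset) {
  switch(subset,
    autosomes = map$chrom %in% as.character(1:29),
    x         = map$chrom == "X",    # non-pseudo-autosomal X
    pax       = map$chrom == "paX",
    y         = map$chrom == "Y",
    mt        = map$chrom == "MT",
    stop("unknown marker subset: ", subset, call. = FALSE)
  )
}

#' Per-animal heterozygosity over a chromosome class
#'
#' Fraction of heterozygous (code 1) genotypes among non-missing genotypes in
#' the selected marker class. Missing genotypes are excluded from the
#' denominator. If an animal has no non-missing genotype in the subset the
#' value is `NA` (undefined, not zero).
#'
#' @param geno Genotype matrix.
#' @param map Marker map (see [validate_marker_map()]).
#' @param subset One of `"autosomes"`, `"x"` (non-pseudo-autosomal X),
#'   `"pax"`, `"y"`, `"mt"`.
#' @param animal Optional animal id(s); default all.
#' @return Named numeric vector of heterozygosities (`NA` where undefined).
#' @export
heterozygosity <- function(geno, map, subset = "autosomes", animal = NULL) {
  .check_geno(geno)
  map <- validate_marker_map(map)
  keep <- map$marker_id[.marker_subset(map, subset)]
  keep <- intersect(colnames(geno), keep)
  if (!is.null(animal)) {
    missing_ids <- setdiff(animal, rownames(geno))
    if (length(missing_ids))
      stop("unknown animal id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
  } else animal <- rownames(geno)
  if (!length(keep))
    return(setNames(rep(NA_real_, length(animal)), animal))
  sub <- geno[animal, keep, drop = FALSE]
  nobs <- rowSums(!is.na(sub))
  het <- rowSums(sub == 1L, na.rm = TRUE) / nobs
  het[nobs == 0] <- NA_real_
  het
}

#' Assign sex from X heterozygosity and Y call rate
#'
#' On the lower-density assay (`"assay50K"`) sex is assigned male when
#' non-pseudo-autosomal X heterozygosity is below `x_het_threshold`
#' (default 0.03) and female otherwise; Y markers are ignored. On the
#' high-density assay (`"assayHD"`) Y call rate enters as well: male when
#' X het is low and Y call rate is at least `y_call_threshold` (default 0.5),
#' female when X het is high and Y call rate is low, and Klinefelter (XXY)
#' when X het is high together with a high Y call rate. The remaining HD
#' combination (low X het, low Y call rate) is assigned male with a warning,
#' since low X heterozygosity is the primary male criterion.
#'
#' @param pax_het Non-pseudo-autosomal X heterozygosity, in `[0, 1]`.
#' @param y_call_rate Y-marker call rate, in `[0, 1]` (ignored for
#'   `"assay50K"`, may be `NA` there).
#' @param platform `"assay50K"` or `"assayHD"`, recycled as needed.
#' @param x_het_threshold,y_call_threshold Decision thresholds.
#' @return Character vector with values `"male"`, `"female"`,
#'   `"klinefelter"`.
#' @export
assign_sex <- function(pax_het, y_call_rate, platform,
                       x_het_threshold = 0.03, y_call_threshold = 0.5) {
  n <- max(length(pax_het), length(y_call_rate), length(platform))
  pax_het <- rep_len(pax_het, n)
  y_call_rate <- rep_len(y_call_rate, n)
  platform <- rep_len(platform, n)
  if (!all(platform %in% c("assay50K", "assayHD")))
    stop("platform must be 'assay50K' or 'assayHD'", call. = FALSE)
  ok <- function(x) is.na(x) | (x >= 0 & x <= 1)
  if (!all(ok(pax_het)) || !all(ok(y_call_rate)))
    stop("heterozygosity and call rate must lie in [0, 1]", call. = FALSE)
  if (any(is.na(pax_het)))
    stop("pax_het must be non-missing for sex assignment", call. = FALSE)

  low_x <- pax_het < x_het_threshold
  out <- character(n)
  is50 <- platform == "assay50K"
  out[is50] <- ifelse(low_x[is50], "male", "female")

  hd <- !is50
  if (any(hd)) {
    if (any(is.na(y_call_rate[hd])))
      stop("y_call_rate required for assayHD animals", call. = FALSE)
    high_y <- y_call_rate >= y_call_threshold
    out[hd &  low_x &  high_y] <- "male"
    out[hd & !low_x & !high_y] <- "female"
    out[hd & !low_x &  high_y] <- "klinefelter"
    odd <- hd & low_x & !high_y
    if (any(odd)) {
      warning(sum(odd), " HD animal(s) with low X heterozygosity but low Y ",
              "call rate; assigned male", call. = FALSE)
      out[odd] <- "male"
    }
  }
  out
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df chi-square goodness-of-fit test of the observed
#' genotype counts against Hardy-Weinberg expectations at the sample allele
#' frequency; `method = "exact"` gives the conditional exact test (mid-less
#' summation of heterozygote-count probabilities no larger than the observed
#' one). Monomorphic markers return 1 (they are caught by the MAF filter
#' instead).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (vectors recycle).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return P-value vector.
#' @export
hwe_pvalue <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, n); n_ab <- rep_len(n_ab, n); n_bb <- rep_len(n_bb, n)
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("counts must be >= 0", call. = FALSE)
  tot <- n_aa + n_ab + n_bb
  if (any(tot == 0)) stop("total genotype count is zero", call. = FALSE)
  if (method == "chisq") {
    p <- (2 * n_aa + n_ab) / (2 * tot)
    mono <- p == 0 | p == 1
    e_aa <- tot * p^2; e_ab <- 2 * tot * p * (1 - p); e_bb <- tot * (1 - p)^2
    stat <- ifelse(mono, 0,
                   (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                   (n_bb - e_bb)^2 / e_bb)
    pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    vapply(seq_len(n), function(i) .hwe_exact(n_aa[i], n_ab[i], n_bb[i]),
           numeric(1))
  }
}

# Conditional exact HWE test: probability mass over heterozygote counts with
# the minor-allele total fixed; p-value sums masses <= observed mass.
.hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab
  n_minor <- min(n_b, 2 * n - n_b)
  if (n_minor == 0) return(1.0)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- if (n_b <= n) n_ab else n_ab # het count is n_ab either way
  idx <- match(obs, hets)
  if (is.na(idx)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(prob[prob <= prob[idx] * (1 + 1e-12)]))
}

#' Default QC thresholds
#'
#' Thresholds used by [qc_animals()] and [qc_markers()]: animal call rate
#' >= 0.90, autosomal heterozygosity <= 0.45, no Klinefelter animals;
#' marker call rate >= 0.85, minor allele frequency >= 0.001,
#' Hardy-Weinberg P >= 3e-9, male X/Y heterozygosity <= 0.03, mitochondrial
#' heterozygosity <= 0.03.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(animal_call_rate = 0.90, max_autosomal_het = 0.45,
       marker_call_rate = 0.85, min_maf = 0.001, hwe_p = 3e-9,
       male_xy_het = 0.03, mt_het = 0.03,
       x_het_threshold = 0.03, y_call_threshold = 0.5)
}

#' Animal-level QC report
#'
#' Computes per-animal call rate, autosomal and non-pseudo-autosomal X
#' heterozygosity and Y call rate, assigns sex, and flags animals for
#' removal: call rate below threshold, autosomal heterozygosity above
#' threshold, or predicted Klinefelter. Each removed animal carries exactly
#' one primary reason, assigned in that order.
#'
#' @param geno Genotype matrix.
#' @param map Marker map.
#' @param platform Named character vector (`"assay50K"`/`"assayHD"`) per
#'   animal, or a single value recycled to all animals.
#' @param thresholds See [qc_thresholds()].
#' @return Tibble with one row per animal: `animal_id`, `call_rate`,
#'   `autosomal_het`, `pax_het`, `y_call_rate`, `sex`, `kept`, `reason`.
#' @export
qc_animals <- function(geno, map, platform = "assay50K",
                       thresholds = qc_thresholds()) {
  .check_geno(geno)
  map <- validate_marker_map(map)
  ids <- rownames(geno)
  if (is.null(names(platform))) platform <- setNames(rep_len(platform, length(ids)), ids)
  platform <- platform[ids]

  cr <- animal_call_rate(geno)
  auto_het <- heterozygosity(geno, map, "autosomes")
  pax_het <- heterozygosity(geno, map, "x")
  y_ids <- map$marker_id[map$chrom == "Y"]
  y_ids <- intersect(colnames(geno), y_ids)
  y_cr <- if (length(y_ids)) rowMeans(!is.na(geno[, y_ids, drop = FALSE]))
          else setNames(rep(NA_real_, length(ids)), ids)

  # X-less panels (e.g. autosome-only fixtures) cannot assign sex
  sex <- rep(NA_character_, length(ids))
  has_x <- !is.na(pax_het)
  if (any(has_x))
    sex[has_x] <- assign_sex(pax_het[has_x], y_cr[has_x], platform[has_x],
                             x_het_threshold = thresholds$x_het_threshold,
                             y_call_threshold = thresholds$y_call_threshold)

  reason <- rep(NA_character_, length(ids))
  reason[is.na(reason) & cr < thresholds$animal_call_rate] <- "call_rate"
  reason[is.na(reason) & !is.na(auto_het) &
           auto_het > thresholds$max_autosomal_het] <- "heterozygosity"
  reason[is.na(reason) & !is.na(sex) & sex == "klinefelter"] <- "klinefelter"

  tibble::tibble(
    animal_id = ids, call_rate = unname(cr),
    autosomal_het = unname(auto_het), pax_het = unname(pax_het),
    y_call_rate = unname(y_cr), sex = unname(sex),
    kept = is.na(reason), reason = reason)
}

#' Marker-level QC report
#'
#' Per-marker call rate, minor allele frequency, Hardy-Weinberg P-value
#' (autosomes), male heterozygosity for non-pseudo-autosomal X and Y
#' markers, and mitochondrial heterozygosity; markers failing any rule are
#' flagged with one primary reason in the fixed order call_rate, maf, hwe,
#' male_xy_het, mt_het (so reason labels are deterministic).
#'
#' @param geno Genotype matrix (animals already filtered).
#' @param map Marker map.
#' @param sex Named character vector of sex assignments per animal (needed
#'   for the male X/Y heterozygosity rule); from [qc_animals()].
#' @param thresholds See [qc_thresholds()].
#' @param hwe_method Passed to [hwe_pvalue()].
#' @return Tibble with one row per marker: `marker_id`, `chrom`, `bp`,
#'   `call_rate`, `maf`, `hwe_p`, `male_het`, `mt_het`, `kept`, `reason`.
#' @export
qc_markers <- function(geno, map, sex = NULL, thresholds = qc_thresholds(),
                       hwe_method = "chisq") {
  .check_geno(geno)
  map <- validate_marker_map(map)
  map <- map[match(colnames(geno), map$marker_id), ]
  if (anyNA(map$marker_id))
    stop("genotype matrix contains markers absent from the map", call. = FALSE)

  cr <- colMeans(!is.na(geno))
  n_bb <- colSums(geno == 2L, na.rm = TRUE)
  n_ab <- colSums(geno == 1L, na.rm = TRUE)
  n_obs <- colSums(!is.na(geno))
  p_b <- (2 * n_bb + n_ab) / (2 * pmax(n_obs, 1L))
  maf <- pmin(p_b, 1 - p_b)
  maf[n_obs == 0] <- 0

  is_auto <- map$chrom %in% as.character(1:29)
  hwe_p <- rep(NA_real_, ncol(geno))
  idx <- which(is_auto & n_obs > 0)
  if (length(idx)) {
    n_aa <- n_obs[idx] - n_ab[idx] - n_bb[idx]
    hwe_p[idx] <- hwe_pvalue(n_aa, n_ab[idx], n_bb[idx], method = hwe_method)
  }

  # male heterozygosity on non-paX X and Y markers; MT het on all animals
  male_het <- rep(NA_real_, ncol(geno))
  xy <- map$chrom %in% c("X", "Y")
  if (any(xy)) {
    if (is.null(sex))
      stop("sex assignments are required to QC X/Y markers", call. = FALSE)
    sx <- sex[rownames(geno)]
    males <- rownames(geno)[!is.na(sx) & sx == "male"]
    if (length(males)) {
      sub <- geno[males, xy, drop = FALSE]
      nob <- colSums(!is.na(sub))
      mh <- colSums(sub == 1L, na.rm = TRUE) / pmax(nob, 1L)
      mh[nob == 0] <- NA_real_
      male_het[xy] <- mh
    }
  }
  mt_het <- rep(NA_real_, ncol(geno))
  mt <- map$chrom == "MT"
  if (any(mt)) {
    sub <- geno[, mt, drop = FALSE]
    nob <- colSums(!is.na(sub))
    mh <- colSums(sub == 1L, na.rm = TRUE) / pmax(nob, 1L)
    mh[nob == 0] <- NA_real_
    mt_het[mt] <- mh
  }

  reason <- rep(NA_character_, ncol(geno))
  reason[is.na(reason) & cr < thresholds$marker_call_rate] <- "call_rate"
  reason[is.na(reason) & maf < thresholds$min_maf] <- "maf"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < thresholds$hwe_p] <- "hwe"
  reason[is.na(reason) & !is.na(male_het) &
           male_het > thresholds$male_xy_het] <- "male_xy_het"
  reason[is.na(reason) & !is.na(mt_het) & mt_het > thresholds$mt_het] <- "mt_het"

  tibble::tibble(
    marker_id = colnames(geno), chrom = map$chrom, bp = map$bp,
    call_rate = unname(cr), maf = unname(maf), hwe_p = hwe_p,
    male_het = male_het, mt_het = mt_het,
    kept = is.na(reason), reason = reason)
}

#' Filter animals failing QC
#'
#' @inheritParams qc_animals
#' @return List with `geno` (kept rows), `platform`, `sex` (named, kept
#'   animals) and the full `report` tibble.
#' @export
filter_animals <- function(geno, map, platform = "assay50K",
                           thresholds = qc_thresholds()) {
  rep_ <- qc_animals(geno, map, platform, thresholds)
  keep <- rep_$animal_id[rep_$kept]
  if (is.null(names(platform)))
    platform <- setNames(rep_len(platform, nrow(geno)), rownames(geno))
  list(geno = geno[keep, , drop = FALSE],
       platform = platform[keep],
       sex = setNames(rep_$sex, rep_$animal_id)[keep],
       report = rep_)
}

#' Filter markers failing QC
#'
#' @inheritParams qc_markers
#' @return List with `geno` (kept columns), `map` (kept rows) and the full
#'   `report` tibble.
#' @export
filter_markers <- function(geno, map, sex = NULL,
                           thresholds = qc_thresholds(),
                           hwe_method = "chisq") {
  rep_ <- qc_markers(geno, map, sex, thresholds, hwe_method)
  keep <- rep_$marker_id[rep_$kept]
  map <- validate_marker_map(map)
  list(geno = geno[, keep, drop = FALSE],
       map = map[map$marker_id %in% keep, ],
       report = rep_)
}

#' Mean-impute missing genotypes and center columns
#'
#' Missing codes are replaced by the marker's mean observed code and every
#' column is then centered to mean zero, the form the whole-genome
#' regression consumes. The per-marker means are returned so the coded
#' matrix can be reconstructed.
#'
#' @param geno Genotype matrix after QC.
#' @return List with `Z` (numeric centered matrix) and `means` (named
#'   per-marker mean codes).
#' @export
impute_and_center <- function(geno) {
  .check_geno(geno)
  n_obs <- colSums(!is.na(geno))
  if (any(n_obs == 0))
    stop("marker(s) with all genotypes missing: ",
         paste(head(colnames(geno)[n_obs == 0]), collapse = ", "),
         call. = FALSE)
  means <- colMeans(geno, na.rm = TRUE)
  Z <- sweep(ifelse(is.na(geno), rep(means, each = nrow(geno)), geno),
             2, means)
  dimnames(Z) <- dimnames(geno)
  list(Z = Z, means = means)
}
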