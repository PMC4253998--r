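# Trait derivation from raw feeding-trial records: average daily gain (ADG)
# and mid-test weight by ordinary least squares on serial weights, mid-test
# metabolic body weight (MBW = mid-test weight^0.75), average daily dry
# matter intake (DMI), expected heterosis from parental breed compositions,
# and the fixed-effects design for the whole-genome regression.

#' Fit the growth line: ADG and mid-test weight
#'
#' ADG is the ordinary least-squares slope of weight on day on feed; the
#' mid-test weight is the fitted value at the midpoint of the first and
#' last weigh day. Works per animal over a long-format weights table.
#'
#' @param weights Data frame with columns `animal_id`, `day`, `weight_kg`
#'   (at least two distinct days per animal; weights positive).
#' @return Tibble: `animal_id`, `adg` (kg/d), `midwt` (kg), `mbw`
#'   (kg^0.75).
#' @export
fit_growth <- function(weights) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("animal_id", "day", "weight_kg") %in% names(weights)))
  if (any(weights$weight_kg <= 0))
    stop("weights must be positive", call. = FALSE)
  out <- weights |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      adg = {
        if (dplyr::n_distinct(.data$day) < 2) NA_real_
        else cov(.data$day, .data$weight_kg) / var(.data$day)
      },
      midwt = {
        if (dplyr::n_distinct(.data$day) < 2) NA_real_
        else mean(.data$weight_kg) +
          (cov(.data$day, .data$weight_kg) / var(.data$day)) *
          ((min(.data$day) + max(.data$day)) / 2 - mean(.data$day))
      },
      .groups = "drop")
  if (any(out$n_days < 2))
    stop("animal(s) with fewer than 2 distinct weigh days: ",
         paste(head(out$animal_id[out$n_days < 2]), collapse = ", "),
         call. = FALSE)
  out |>
    dplyr::mutate(mbw = metabolic_weight(.data$midwt)) |>
    dplyr::select("animal_id", "adg", "midwt", "mbw")
}

#' Metabolic body weight
#'
#' @param weight_kg Positive body weight (kg).
#' @return `weight_kg^0.75` (kg^0.75).
#' @export
metabolic_weight <- function(weight_kg) {
  if (any(weight_kg <= 0)) stop("weight must be positive", call. = FALSE)
  weight_kg^0.75
}

#' Average daily dry matter intake
#'
#' Mean daily as-fed intake over the test period times the ration's dry
#' matter fraction.
#'
#' @param intakes Data frame with columns `animal_id`, `intake_asfed_kg`
#'   (one row per on-feed day) and `dm_fraction` (constant within animal,
#'   in (0, 1]).
#' @return Tibble: `animal_id`, `dmi` (kg/d).
#' @export
dmi <- function(intakes) {
  intakes <- tibble::as_tibble(intakes)
  stopifnot(all(c("animal_id", "intake_asfed_kg", "dm_fraction") %in%
                  names(intakes)))
  if (any(intakes$intake_asfed_kg < 0))
    stop("intakes must be >= 0", call. = FALSE)
  if (any(intakes$dm_fraction <= 0 | intakes$dm_fraction > 1))
    stop("dm_fraction must lie in (0, 1]", call. = FALSE)
  intakes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(dmi = mean(.data$intake_asfed_kg) *
                       .data$dm_fraction[1], .groups = "drop")
}

#' Expected heterosis from parental breed compositions
#'
#' The probability that an individual's two alleles at a locus derive from
#' different breeds: `1 - sum_b sire_b * dam_b`.
#'
#' @param sire_comp,dam_comp Breed-fraction vectors (or matrices, one row
#'   per animal, same breed columns); each row must be non-negative and sum
#'   to 1 within `tol`.
#' @param tol Tolerance on the composition sums.
#' @return Numeric vector of expected heterosis values in `[0, 1]`.
#' @export
expected_heterosis <- function(sire_comp, dam_comp, tol = 1e-6) {
  if (is.vector(sire_comp)) sire_comp <- matrix(sire_comp, nrow = 1)
  if (is.vector(dam_comp)) dam_comp <- matrix(dam_comp, nrow = 1)
  stopifnot(ncol(sire_comp) == ncol(dam_comp),
            nrow(sire_comp) == nrow(dam_comp))
  if (any(sire_comp < 0) || any(dam_comp < 0))
    stop("breed fractions must be non-negative", call. = FALSE)
  if (any(abs(rowSums(sire_comp) - 1) > tol) ||
      any(abs(rowSums(dam_comp) - 1) > tol))
    stop("breed compositions must sum to 1", call. = FALSE)
  unname(1 - rowSums(sire_comp * dam_comp))
}

#' Assemble derived phenotypes
#'
#' Joins the growth fit, DMI and grouping/covariate table into the
#' one-row-per-animal phenotype tibble the model consumes.
#'
#' @param weights Serial weights (see [fit_growth()]).
#' @param intakes Daily intakes (see [dmi()]).
#' @param groups Data frame with `animal_id`, `cg` (contemporary-group
#'   label) and any covariate columns (breed fractions, heterosis, ...).
#' @return Tibble: `animal_id`, `adg`, `midwt`, `mbw`, `dmi`, `cg`,
#'   covariates.
#' @export
derive_phenotypes <- function(weights, intakes, groups) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("animal_id", "cg") %in% names(groups)))
  fit_growth(weights) |>
    dplyr::inner_join(dmi(intakes), by = "animal_id") |>
    dplyr::inner_join(groups, by = "animal_id")
}

#' Build the response and fixed-effects design for one trait
#'
#' The design holds an intercept, contemporary-group indicators
#' (drop-first-level coding, so the intercept absorbs the reference group)
#' and any requested covariate columns. For `trait = "RFI"` the response is
#' DMI and partial-regression covariates for ADG and MBW are appended, so
#' residual feed intake is realised inside the model rather than as a
#' pre-computed residual.
#'
#' @param pheno Phenotype tibble from [derive_phenotypes()].
#' @param trait One of `"ADG"`, `"DMI"`, `"MBW"`, `"RFI"`.
#' @param covariates Character vector of covariate column names in `pheno`
#'   (e.g. breed fractions, expected heterosis).
#' @return List: `y` (response), `X` (design matrix), `animals` (ids in row
#'   order), `dropped` (tibble of animals removed for missing values),
#'   `trait`.
#' @export
build_design <- function(pheno, trait = c("ADG", "DMI", "MBW", "RFI"),
                         covariates = character()) {
  trait <- match.arg(trait)
  pheno <- tibble::as_tibble(pheno)
  resp_col <- c(ADG = "adg", DMI = "dmi", MBW = "mbw", RFI = "dmi")[[trait]]
  covs <- covariates
  if (trait == "RFI") covs <- unique(c(covs, "adg", "mbw"))
  need <- c("animal_id", "cg", resp_col, covs)
  miss_col <- setdiff(need, names(pheno))
  if (length(miss_col))
    stop("phenotype table lacks column(s): ",
         paste(miss_col, collapse = ", "), call. = FALSE)
  if (any(pheno$cg == "" | is.na(pheno$cg)))
    stop("contemporary-group labels must be non-empty", call. = FALSE)

  ok <- complete.cases(pheno[, need])
  dropped <- pheno[!ok, c("animal_id", need[-1])]
  pheno <- pheno[ok, ]

  cg <- factor(pheno$cg)
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  if (nlevels(cg) > 1) {
    ind <- stats::model.matrix(~ cg)[, -1, drop = FALSE]
    colnames(ind) <- paste0("cg", levels(cg)[-1])
    X <- cbind(X, ind)
  }
  if (length(covs)) {
    cm <- as.matrix(pheno[, covs, drop = FALSE])
    storage.mode(cm) <- "double"
    X <- cbind(X, cm)
  }
  list(y = pheno[[resp_col]], X = X, animals = pheno$animal_id,
       dropped = dropped, trait = trait)
}

#' Classical phenotypic residual feed intake
#'
#' Convenience only (used by the simulator's checks): residuals of the
#' ordinary regression of DMI on ADG and MBW. In the GWAS itself, RFI is
#' realised by fitting ADG and MBW as covariates inside the Bayesian model
#' (see [build_design()]).
#'
#' @param pheno Phenotype tibble with `dmi`, `adg`, `mbw`.
#' @return Tibble: `animal_id`, `rfi`.
#' @export
classical_rfi <- function(pheno) {
  fit <- lm(dmi ~ adg + mbw, data = pheno)
  tibble::tibble(animal_id = pheno$animal_id, rfi = unname(residuals(fit)))
}
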