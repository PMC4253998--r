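# Window-level significance: 1-Mb window labels, phenotype permutation,
# the permutation null of window variance shares, a Johnson Su parametric
# model of that null, Bonferroni correction and QTL calling with lead-SNP
# selection.

#' 1-Mb window label for a genomic position
#'
#' Half-open 1-based megabase bins: positions 1..1,000,000 map to megabase
#' index 0, so the label is `chrom_floor((bp - 1)/1e6)` (e.g. a site at
#' 23,456,789 bp on chromosome 7 is in window `"7_23"`).
#'
#' @param chrom Chromosome label(s) from `{1..29, X, paX, Y, MT}`.
#' @param bp 1-based position(s), `>= 1`.
#' @return Character vector of window labels.
#' @export
window_of <- function(chrom, bp) {
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), .chrom_levels)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(bp < 1)) stop("bp must be >= 1", call. = FALSE)
  paste0(chrom, "_", (as.numeric(bp) - 1) %/% 1e6)
}

#' Permute phenotype rows against genotypes
#'
#' Randomly reassigns genotype rows to (response, fixed-effects) rows: the
#' response and its fixed-effect row travel together, so the trait's
#' distribution and its relation to the systematic effects are preserved
#' while any genotype-phenotype association is destroyed.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix.
#' @param seed Integer seed (reproducible permutation).
#' @return List `y`, `X` (rows permuted identically), `perm` (the
#'   permutation applied).
#' @export
permute_phenotypes <- function(y, X, seed = 1L) {
  n <- length(y)
  if (n < 2) stop("need at least 2 animals to permute", call. = FALSE)
  perm <- local_seed(seed, sample.int(n))
  list(y = y[perm], X = X[perm, , drop = FALSE], perm = perm)
}

#' Build the permutation null of window variance shares
#'
#' For each replicate: permute the phenotype rows, rerun the BayesB model
#' with identical settings, and collect every window's posterior-mean
#' variance share. The shares from all replicates are pooled into one null
#' sample; its size `n` is (number of windows) x (number of replicates).
#'
#' @param y,X,Z,map,spec,... As in [bayesb()].
#' @param n_replicates Number of permutation replicates (one gives a null
#'   the size of the window count; 10 or more gives a more stable tail).
#' @param seed Base seed; replicate r permutes with `seed + r` and runs its
#'   chain with the spec's seed offset by `r`.
#' @return Tibble of class `null_sample`: `replicate`, `window`, `share`,
#'   with attributes `seeds` and `n_windows`.
#' @export
build_null <- function(y, X, Z, map = NULL, spec = bayesb_spec(),
                       n_replicates = 1, seed = 1L, ...) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    perm <- permute_phenotypes(y, X, seed = seed + r)
    rspec <- spec
    rspec$seed <- spec$seed + r
    fit <- bayesb(perm$y, perm$X, Z, map = map, spec = rspec, ...)
    dplyr::mutate(window_shares(fit), replicate = r, .before = 1)
  })
  out <- dplyr::bind_rows(reps) |>
    dplyr::select("replicate", "window", share = "pct_va")
  structure(tibble::new_tibble(out, class = "null_sample"),
            seeds = seed + seq_len(n_replicates),
            n_windows = length(unique(out$window)))
}

# ---- Johnson Su distribution ------------------------------------------

#' Johnson Su parameter set
#'
#' The unbounded Johnson system: `z = gamma + delta * asinh((x - theta) /
#' sigma)` is standard normal. `gamma` and `delta > 0` are shapes, `theta`
#' a location and `sigma > 0` a scale, all on the window-share (%) scale.
#'
#' @param gamma,delta,theta,sigma Parameters (`delta`, `sigma` positive).
#' @return List of class `johnson_su`.
#' @export
johnson_su_params <- function(gamma, delta, theta, sigma) {
  if (delta <= 0 || sigma <= 0)
    stop("delta and sigma must be positive", call. = FALSE)
  structure(list(gamma = gamma, delta = delta, theta = theta, sigma = sigma),
            class = "johnson_su")
}

.js_z <- function(x, p) p$gamma + p$delta * asinh((x - p$theta) / p$sigma)

#' Johnson Su distribution functions
#'
#' Density, distribution function, upper-tail probability, quantile
#' function and random generation for the Johnson Su distribution.
#' `js_sf(x) = P(X > x)` is the nominal P-value of a window share `x`
#' under the permutation-null model.
#'
#' @param x Quantile vector.
#' @param params A [johnson_su_params()].
#' @name johnson_su_distribution
#' @return Numeric vector.
#' @export
js_density <- function(x, params) {
  u <- (x - params$theta) / params$sigma
  params$delta / (params$sigma * sqrt(1 + u^2)) * dnorm(.js_z(x, params))
}

#' @rdname johnson_su_distribution
#' @export
js_cdf <- function(x, params) pnorm(.js_z(x, params))

#' @rdname johnson_su_distribution
#' @export
js_sf <- function(x, params) pnorm(.js_z(x, params), lower.tail = FALSE)

#' @rdname johnson_su_distribution
#' @param p Probability vector.
#' @export
js_quantile <- function(p, params) {
  params$theta + params$sigma * sinh((qnorm(p) - params$gamma) / params$delta)
}

#' @rdname johnson_su_distribution
#' @param n Number of draws.
#' @param seed Optional seed.
#' @export
js_sample <- function(n, params, seed = NULL) {
  local_seed(seed, params$theta +
               params$sigma * sinh((rnorm(n) - params$gamma) / params$delta))
}

.js_neg2ll <- function(x, p) {
  u <- (x - p$theta) / p$sigma
  -2 * sum(log(p$delta) - log(p$sigma) - 0.5 * log1p(u^2) +
             dnorm(p$gamma + p$delta * asinh(u), log = TRUE))
}

# quantile-matching initial values (Slifker-Shapiro style spread ratios)
.js_init <- function(x) {
  z0 <- 0.5244005 # standard normal quantile at p = 0.7
  q <- quantile(x, pnorm(c(-3, -1, 1, 3) * z0), names = FALSE, type = 8)
  m <- q[4] - q[3]; nn <- q[2] - q[1]; pp <- q[3] - q[2]
  inits <- list()
  if (pp > 0 && m > 0 && nn > 0 && (m / pp + nn / pp) / 2 > 1 + 1e-8 &&
      m * nn / pp^2 > 1 + 1e-8) {
    ratio <- (m / pp + nn / pp) / 2
    delta <- 2 * z0 / acosh(ratio)
    gamma <- delta * asinh((nn / pp - m / pp) /
                             (2 * sqrt(m * nn / pp^2 - 1)))
    sigma <- 2 * pp * sqrt(m * nn / pp^2 - 1) /
      ((m / pp + nn / pp - 2) * sqrt(m / pp + nn / pp + 2))
    theta <- (q[2] + q[3]) / 2 + pp * (nn / pp - m / pp) /
      (2 * (m / pp + nn / pp - 2))
    if (is.finite(delta) && delta > 0 && is.finite(sigma) && sigma > 0 &&
        is.finite(gamma) && is.finite(theta))
      inits <- list(c(gamma, log(delta), theta, log(sigma)))
  }
  # fallbacks: a near-normal start and skewed variants
  s <- sd(x); md <- median(x)
  inits <- c(inits, list(
    c(0, log(1.5), md, log(max(s, 1e-8))),
    c(-1, log(1), md - s / 2, log(max(s / 2, 1e-8))),
    c(1, log(1), md + s / 2, log(max(s / 2, 1e-8)))))
  inits
}

#' Fit a Johnson Su distribution by maximum likelihood
#'
#' Maximum-likelihood estimation of the four Johnson Su parameters with
#' quantile-matching initial values and multiple starts, the shape `delta`
#' and scale `sigma` kept positive by optimising on the log scale. Used to
#' model the pooled permutation-null window shares.
#'
#' @param x Sample (e.g. a `null_sample`'s `share` column); `n >= 100`
#'   recommended and enforced by default.
#' @param min_n Minimum sample size.
#' @return Object of class `johnson_su_fit`: `params`
#'   ([johnson_su_params()]), `n`, `neg2loglik`, `convergence`.
#' @export
fit_johnson_su <- function(x, min_n = 100) {
  if (inherits(x, "null_sample")) x <- x$share
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " values to fit the null model",
         call. = FALSE)
  nll <- function(par) {
    p <- list(gamma = par[1], delta = exp(par[2]),
              theta = par[3], sigma = exp(par[4]))
    v <- .js_neg2ll(x, p) / 2
    if (!is.finite(v)) 1e300 else v
  }
  fits <- lapply(.js_init(x), function(st) {
    tryCatch(optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("Johnson Su fit failed from every start",
                          call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- best$par
  structure(list(
    params = johnson_su_params(par[1], exp(par[2]), par[3], exp(par[4])),
    n = length(x), neg2loglik = 2 * best$value,
    convergence = best$convergence), class = "johnson_su_fit")
}

#' @export
print.johnson_su_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Johnson Su fit (n = %d): gamma = %.3f, delta = %.3f,",
                     " theta = %.4f, sigma = %.4f\n  -2logLik = %.3f\n"),
              x$n, p$gamma, p$delta, p$theta, p$sigma, x$neg2loglik))
  invisible(x)
}

#' @export
tidy.johnson_su_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("gamma", "delta", "theta", "sigma"),
                 estimate = c(p$gamma, p$delta, p$theta, p$sigma))
}

#' @export
glance.johnson_su_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(gamma = p$gamma, delta = p$delta, theta = p$theta,
                 sigma = p$sigma, n = x$n, neg2loglik = x$neg2loglik,
                 convergence = x$convergence)
}

#' Bonferroni correction
#'
#' `min(1, n_tests * p)`; `n_tests` is the number of 1-Mb windows tested in
#' the population (window counts differ between genotyping platforms).
#'
#' @param p Nominal P-value(s) in `[0, 1]`.
#' @param n_tests Number of tests, `>= 1`.
#' @return Corrected P-value(s).
#' @export
bonferroni <- function(p, n_tests) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  pmin(1, n_tests * p)
}

#' Call QTL from window shares and a fitted null
#'
#' Each window's nominal P-value is the Johnson Su upper-tail probability
#' of its variance share under the permutation-null model; the Bonferroni
#' correction uses the number of windows tested; windows with corrected
#' P below `alpha` are significant QTL. Within each window the lead-SNP is
#' the marker with the highest sPPI (ties: smallest bp, then id).
#'
#' A trait-to-parameter map supports reusing one trait's null for another
#' (e.g. when a trait's own fitted null is ill-behaved).
#'
#' @param windows Window tibble (`window`, `n_snps`, `pct_va`), e.g.
#'   [window_shares()].
#' @param params A [johnson_su_params()] / `johnson_su_fit`, or a named
#'   list of them keyed by trait together with `trait`.
#' @param effects Per-marker tibble with `marker_id`, `window`, `sppi` and
#'   optionally `bp` (e.g. [tidy.bayesb_fit()]); used for lead-SNPs.
#' @param n_tests Number of windows tested (default `nrow(windows)`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param trait Trait label used to look up `params` when it is a map.
#' @return Tibble: `window`, `n_snps`, `pct_va`, `nominal_p`,
#'   `bonferroni_p`, `significant`, `lead_snp`, `lead_sppi`, ordered by
#'   chromosome and Mb.
#' @export
call_qtl <- function(windows, params, effects = NULL,
                     n_tests = nrow(windows), alpha = 0.05,
                     trait = NULL) {
  if (inherits(params, "johnson_su_fit")) params <- params$params
  if (!inherits(params, "johnson_su")) {
    if (is.null(trait) || is.null(params[[trait]]))
      stop("no null parameters available for trait ",
           trait %||% "<missing>", "; fit or supply one", call. = FALSE)
    params <- params[[trait]]
    if (inherits(params, "johnson_su_fit")) params <- params$params
  }
  windows <- tibble::as_tibble(windows)
  out <- windows |>
    dplyr::mutate(nominal_p = js_sf(.data$pct_va, params),
                  bonferroni_p = bonferroni(.data$nominal_p, n_tests),
                  significant = .data$bonferroni_p < alpha)
  if (!is.null(effects)) {
    leads <- tibble::as_tibble(effects) |>
      dplyr::group_by(.data$window) |>
      dplyr::arrange(dplyr::desc(.data$sppi),
                     if ("bp" %in% names(effects)) .data$bp else .data$marker_id,
                     .data$marker_id, .by_group = TRUE) |>
      dplyr::summarise(lead_snp = .data$marker_id[1],
                       lead_sppi = .data$sppi[1], .groups = "drop")
    out <- dplyr::left_join(out, leads, by = "window")
  }
  # sort by chromosome then Mb (chromosome order as in the map)
  parts <- strsplit(out$window, "_")
  chr <- vapply(parts, `[[`, character(1), 1)
  mb <- suppressWarnings(as.numeric(vapply(parts, function(z)
    z[[length(z)]], character(1))))
  ord <- order(match(chr, .chrom_levels), mb, na.last = TRUE)
  out[ord, ]
}
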