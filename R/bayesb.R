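# BayesB whole-genome regression: mixture-prior marker effects with a
# proportion pi of null markers, fixed effects with a flat prior, posterior
# variance components, per-marker posterior probability of inclusion (sPPI)
# and per-1-Mb-window additive-variance partitioning.

#' BayesB model specification
#'
#' Bundles the sampler settings. `pi` is the prior proportion of markers
#' with no effect: around 0.99 for ~50K panels and 0.9995 for ~770K panels,
#' so that roughly `(1 - pi) * M` markers are fitted each iteration. The
#' default chain length is 41,040 iterations with the first 1,000 discarded
#' as burn-in.
#'
#' @param pi Prior null-marker proportion, in `[0, 1)`.
#' @param n_iter Total MCMC iterations.
#' @param burn_in Burn-in iterations (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param df_alpha,df_e Prior degrees of freedom for the locus-effect and
#'   residual scaled-inverse-chi-square priors.
#' @param va_prior,ve_prior Assumed total additive-genetic and residual
#'   variance, used only to set the prior scales (defaults: half the
#'   response variance each).
#' @param seed Integer seed; the chain is bit-for-bit reproducible.
#' @return A list of class `bayesb_spec`.
#' @export
bayesb_spec <- function(pi = 0.99, n_iter = 41040, burn_in = 1000, thin = 1,
                        df_alpha = 4.2, df_e = 10,
                        va_prior = NULL, ve_prior = NULL, seed = 1L) {
  if (pi < 0 || pi >= 1) stop("pi must lie in [0, 1)", call. = FALSE)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(pi = pi, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 df_alpha = df_alpha, df_e = df_e,
                 va_prior = va_prior, ve_prior = ve_prior,
                 seed = as.integer(seed)),
            class = "bayesb_spec")
}

#' Fit a BayesB whole-genome regression
#'
#' Single-site Gibbs sampler: fixed effects from their flat-prior normal
#' conditionals; each marker's inclusion indicator from the conditional
#' odds with its effect integrated out, its effect (when included) from the
#' normal conditional, and its locus variance from the scaled-inverse-
#' chi-square conditional (prior draw when excluded); the residual variance
#' from its scaled-inverse-chi-square conditional. The residual and
#' genomic-value vectors are maintained incrementally.
#'
#' Per saved iteration the additive genetic variance is the empirical
#' variance across animals of the genomic values `g_i = sum_j z_ij a_j`,
#' and each 1-Mb window's share is 100 x var(window genomic values) /
#' var(g) (0 when var(g) is 0). Posterior means of these per-iteration
#' quantities are reported.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix (first column the intercept; use
#'   [build_design()]).
#' @param Z Centered genotype matrix animals x markers (use
#'   [impute_and_center()]).
#' @param map Marker map for the columns of `Z` (used to assign 1-Mb
#'   windows). If `NULL`, all markers fall in one window `"all_0"`.
#' @param spec A [bayesb_spec()].
#' @param fixed_sigma2_alpha,fixed_sigma2_e Optional fixed values of the
#'   locus-effect and residual variances (no sampling of that component);
#'   used for conjugate checks.
#' @param store_effects Store the per-iteration marker-effect samples
#'   (memory heavy; for small problems only).
#' @param trait Optional trait label carried into outputs.
#' @return Object of class `bayesb_fit`; see [tidy.bayesb_fit()],
#'   [glance.bayesb_fit()], [window_shares()].
#' @export
bayesb <- function(y, X, Z, map = NULL, spec = bayesb_spec(),
                   fixed_sigma2_alpha = NULL, fixed_sigma2_e = NULL,
                   store_effects = FALSE, trait = NA_character_) {
  stopifnot(inherits(spec, "bayesb_spec"))
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    stop("rows of X and Z must match length(y)", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design is rank deficient", call. = FALSE)
  M <- ncol(Z)

  if (is.null(map)) {
    win <- rep("all_0", M)
  } else {
    map <- validate_marker_map(map)
    idx <- match(colnames(Z), map$marker_id)
    if (anyNA(idx)) stop("markers in Z missing from map", call. = FALSE)
    win <- window_of(map$chrom[idx], map$bp[idx])
  }
  winf <- factor(win, levels = unique(win))

  va_prior <- spec$va_prior %||% (var(y) / 2)
  ve_prior <- spec$ve_prior %||% (var(y) / 2)
  colv <- apply(Z, 2, var)
  vbar <- mean(colv[colv > 0])
  # per-locus effect variance implied by the assumed genetic variance
  s2a_target <- va_prior / ((1 - spec$pi) * M * vbar)
  scale_alpha <- if (spec$df_alpha > 2)
    s2a_target * (spec$df_alpha - 2) / spec$df_alpha else s2a_target
  scale_e <- if (spec$df_e > 2)
    ve_prior * (spec$df_e - 2) / spec$df_e else ve_prior

  res <- local_seed(spec$seed, .bayesb_mcmc(
    y, X, Z, as.integer(winf) - 1L, nlevels(winf),
    spec$pi, spec$n_iter, spec$burn_in, spec$thin,
    spec$df_alpha, scale_alpha, spec$df_e, scale_e,
    fixed_sigma2_alpha, fixed_sigma2_e, store_effects))

  effects <- tibble::tibble(
    marker_id = colnames(Z), window = win,
    effect_mean = res$effect_mean, sppi = res$sppi)
  if (!is.null(map)) {
    idx <- match(colnames(Z), map$marker_id)
    effects$chrom <- map$chrom[idx]
    effects$bp <- map$bp[idx]
    effects <- effects[, c("marker_id", "chrom", "bp", "window",
                           "effect_mean", "sppi")]
  }
  windows <- tibble::tibble(
    window = levels(winf),
    n_snps = as.integer(table(winf)[levels(winf)]),
    pct_va = res$window_share_mean)

  samples <- tibble::tibble(
    va = res$va_samples, ve = res$ve_samples, h2 = res$h2_samples,
    n_included = res$n_included)

  out <- list(
    trait = trait, effects = effects, windows = windows, samples = samples,
    va = mean(samples$va), ve = mean(samples$ve),
    h2 = mean(samples$h2),
    h2_ratio_of_means = mean(samples$va) / (mean(samples$va) + mean(samples$ve)),
    fixed = tibble::tibble(term = colnames(X), estimate = res$fixed_mean),
    spec = spec, n_saved = res$n_saved)
  if (store_effects) {
    out$effect_samples <- res$effect_samples
    colnames(out$effect_samples) <- colnames(Z)
  }
  structure(out, class = "bayesb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bayesb_fit <- function(x, ...) {
  cat("BayesB fit", if (!is.na(x$trait)) paste0(" (", x$trait, ")"), "\n",
      sep = "")
  cat(sprintf("  markers: %d  windows: %d  saved samples: %d\n",
              nrow(x$effects), nrow(x$windows), x$n_saved))
  cat(sprintf("  V_A = %.4g  V_E = %.4g  h2 = %.3f (ratio of means %.3f)\n",
              x$va, x$ve, x$h2, x$h2_ratio_of_means))
  cat(sprintf("  mean markers in model per iteration: %.1f\n",
              mean(x$samples$n_included)))
  invisible(x)
}

#' Tidy per-marker posterior summaries
#'
#' @param x A `bayesb_fit`.
#' @param ... Unused.
#' @return Tibble with one row per marker: posterior mean effect and sPPI
#'   (fraction of post-burn-in samples in which the marker is in the
#'   model).
#' @export
tidy.bayesb_fit <- function(x, ...) x$effects

#' One-row model summary
#'
#' @param x A `bayesb_fit`.
#' @param ... Unused.
#' @return Tibble: posterior-mean `va`, `ve`, `h2` (posterior mean of
#'   per-iteration ratios), `h2_ratio_of_means`, chain bookkeeping.
#' @export
glance.bayesb_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, va = x$va, ve = x$ve, h2 = x$h2,
                 h2_ratio_of_means = x$h2_ratio_of_means,
                 n_markers = nrow(x$effects), n_saved = x$n_saved,
                 mean_included = mean(x$samples$n_included))
}

#' Per-window posterior mean variance shares
#'
#' @param fit A `bayesb_fit`.
#' @return Tibble: `window`, `n_snps`, `pct_va` (posterior mean percentage
#'   of additive genetic variance explained by the window).
#' @export
window_shares <- function(fit) {
  stopifnot(inherits(fit, "bayesb_fit"))
  fit$windows
}

#' Posterior probability of inclusion for a marker
#'
#' @param fit A `bayesb_fit`.
#' @param marker_id Marker id(s).
#' @return Numeric sPPI value(s).
#' @export
sppi <- function(fit, marker_id) {
  stopifnot(inherits(fit, "bayesb_fit"))
  idx <- match(marker_id, fit$effects$marker_id)
  if (anyNA(idx))
    stop("unknown marker id(s): ",
         paste(marker_id[is.na(idx)], collapse = ", "), call. = FALSE)
  fit$effects$sppi[idx]
}

#' Heritability from variance components
#'
#' @param va Additive genetic variance (>= 0).
#' @param ve Residual variance (> 0, or >= 0 with `va + ve > 0`).
#' @return `va / (va + ve)`.
#' @export
heritability <- function(va, ve) {
  if (any(va < 0) || any(ve < 0))
    stop("variances must be non-negative", call. = FALSE)
  if (any(va + ve == 0))
    stop("va + ve must be positive", call. = FALSE)
  va / (va + ve)
}

#' Genomic variance of one effect sample
#'
#' Empirical variance across animals of the genomic values `Z %*% effects`
#' for a single sampled effect vector; the per-iteration quantity whose
#' posterior mean is the reported additive genetic variance.
#'
#' @param effects Marker-effect vector.
#' @param Z Centered genotype matrix.
#' @return Scalar variance.
#' @export
genomic_variance <- function(effects, Z) {
  as.numeric(var(Z %*% effects))
}

#' Manhattan-style plot of window variance shares
#'
#' @param object A `bayesb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bayesb_fit <- function(object, ...) {
  d <- object$windows |>
    tidyr::separate_wider_delim("window", "_", names = c("chrom", "mb"),
                                cols_remove = FALSE) |>
    dplyr::mutate(mb = as.numeric(.data$mb),
                  chrom = factor(.data$chrom,
                                 levels = unique(.data$chrom)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mb, y = .data$pct_va,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "% additive genetic variance per 1-Mb window") +
    ggplot2::theme_minimal()
}
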