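#' Classify growth regimes
#'
#' Splits phenotypes into a low and a high growth-rate regime. The default
#' fixed threshold is 0.039 h^-1 (the antimode of the bimodal realized
#' growth-rate distribution in the reference study; the boundary itself is
#' classified as high). With `method = "mixture"` the threshold is instead
#' estimated from the data as the density antimode between the two components
#' of a Gaussian mixture fitted to `log10(r_realized)` (requires the mclust
#' package).
#'
#' @param phenotypes data frame with a `r_realized` column (h^-1).
#' @param threshold regime boundary, h^-1.
#' @param method `"fixed"` or `"mixture"`.
#' @return The input tibble with a `regime` factor (`low`/`high`) appended;
#'   the threshold used is stored in `attr(, "threshold")`.
#' @export
classify_regimes <- function(phenotypes, threshold = 0.039,
                             method = c("fixed", "mixture")) {
  method <- match.arg(method)
  phenotypes <- as_tibble(phenotypes)
  if (!nrow(phenotypes)) abort("empty phenotype table")
  if (!"r_realized" %in% names(phenotypes)) {
    abort("phenotype table lacks 'r_realized'")
  }
  if (method == "mixture") {
    threshold <- mixture_antimode(phenotypes$r_realized)
  }
  out <- phenotypes |>
    mutate(regime = factor(ifelse(.data$r_realized >= threshold,
                                  "high", "low"),
                           levels = c("low", "high")))
  attr(out, "threshold") <- threshold
  out
}

#' Antimode of a two-component growth-rate mixture
#'
#' Fits a two-component Gaussian mixture to `log10(r)` and returns the
#' density minimum between the two component means, back-transformed to
#' h^-1. Used by [classify_regimes()] in data-driven mode.
#'
#' @param r positive growth rates, h^-1.
#' @return The antimode, h^-1.
#' @export
mixture_antimode <- function(r) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    abort("method = 'mixture' requires the mclust package")
  }
  x <- log10(r[is.finite(r) & r > 0])
  # Mclust resolves mclustBIC in the calling frame
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  grid <- seq(mu[1], mu[2], length.out = 512)
  dens <- mclust::dens(modelName = "V", data = grid,
                       parameters = fit$parameters)
  10^grid[which.min(dens)]
}

#' Scaling of biomass production with respiration
#'
#' Ordinary least squares of `log10(BP)` on `log10(BR)`, optionally within a
#' growth regime, with a one-sample t-test of the slope against unity
#' (proportional scaling). Scaling is assessed on production and respiration
#' *rates* (`BP_rate`, `BR_rate`, mol C per litre per hour) when those
#' columns are present — cumulative batch totals are anticomplementary
#' (production plus respiration is bounded by the carbon consumed), so the
#' power-law signature lives in the rates. Rows with non-positive values are
#' dropped with a warning.
#'
#' @param phenotypes data frame with `BP`, `BR` (or `BP_rate`, `BR_rate`;
#'   and `regime` if `regime` given).
#' @param regime optional regime label to subset on.
#' @param rate use the rate columns when available.
#' @return An object of class `deb_scaling` wrapping the `lm` fit; see
#'   [tidy.deb_scaling()] and [glance.deb_scaling()].
#' @export
bp_br_scaling <- function(phenotypes, regime = NULL, rate = TRUE) {
  df <- as_tibble(phenotypes)
  if (!is.null(regime)) df <- df |> filter(.data$regime == !!regime)
  if (rate && all(c("BP_rate", "BR_rate") %in% names(df))) {
    df$BP <- df$BP_rate
    df$BR <- df$BR_rate
  }
  bad <- !is.finite(df$BP) | !is.finite(df$BR) | df$BP <= 0 | df$BR <= 0
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " row(s) with non-positive BP/BR"))
    df <- df[!bad, ]
  }
  if (nrow(df) < 3) abort("need at least 3 rows with positive BP and BR")
  fit <- lm(log10(BP) ~ log10(BR), data = df)
  structure(list(fit = fit, n = nrow(df), regime = regime,
                 null_slope = 1),
            class = "deb_scaling")
}

#' Rate-yield regression on substrate-class medians
#'
#' Tests the trade-off between realized growth rate and carbon use efficiency
#' within a growth regime. Following the study design, the units of analysis
#' are substrate-class medians: per class, the median `r_realized` and median
#' `CUE` are computed and CUE is regressed on rate by OLS.
#'
#' @param phenotypes data frame with `class`, `r_realized`, `CUE` (and
#'   `regime` if `regime` given).
#' @param regime optional regime label to subset on.
#' @return A `deb_scaling` object (null slope 0); `$medians` holds the
#'   class-median table.
#' @export
rate_yield_regression <- function(phenotypes, regime = NULL) {
  df <- as_tibble(phenotypes)
  if (!is.null(regime)) df <- df |> filter(.data$regime == !!regime)
  med <- df |>
    filter(is.finite(.data$r_realized), is.finite(.data$CUE)) |>
    group_by(.data$class) |>
    summarise(r_realized = median(.data$r_realized),
              CUE = median(.data$CUE), .groups = "drop")
  if (nrow(med) < 3) abort("need medians for at least 3 substrate classes")
  fit <- lm(CUE ~ r_realized, data = med)
  structure(list(fit = fit, n = nrow(med), regime = regime,
                 null_slope = 0, medians = med),
            class = "deb_scaling")
}

#' @export
print.deb_scaling <- function(x, ...) {
  g <- glance(x)
  cat("<deb_scaling> n = ", x$n,
      if (!is.null(x$regime)) paste0(" (", x$regime, " regime)"), "\n",
      sep = "")
  cat(sprintf("  slope %.3f [%.3f, %.3f], r^2 %.3f, t vs %g = %.2f (p = %.3g)\n",
              g$slope, g$conf_low, g$conf_high, g$r_squared, x$null_slope,
              g$t_vs_null, g$p_vs_null))
  invisible(x)
}

#' Tidy coefficients of a scaling fit
#'
#' @param x a `deb_scaling` object.
#' @param conf_level confidence level for the interval.
#' @param ... unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
tidy.deb_scaling <- function(x, conf_level = 0.95, ...) {
  cf <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = conf_level)
  tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
         conf_low = ci[, 1], conf_high = ci[, 2])
}

#' One-row summary of a scaling fit
#'
#' Reports the slope with confidence interval, r-squared, and the one-sample
#' t-test of the slope against the fit's null value (1 for BP-BR scaling,
#' 0 for rate-yield).
#'
#' @param x a `deb_scaling` object.
#' @param conf_level confidence level.
#' @param ... unused.
#' @export
glance.deb_scaling <- function(x, conf_level = 0.95, ...) {
  cf <- summary(x$fit)$coefficients
  slope <- cf[2, 1]; se <- cf[2, 2]
  ci <- confint(x$fit, level = conf_level)[2, ]
  dfree <- x$fit$df.residual
  tstat <- (slope - x$null_slope) / se
  r2 <- summary(x$fit)$r.squared
  resp <- x$fit$model[[1]]
  if (!is.finite(r2) || stats::var(resp) < 1e-20 * mean(resp)^2) {
    r2 <- 0 # constant response carries no variance to explain
  }
  tibble(
    slope = slope, std_error = se,
    conf_low = ci[1], conf_high = ci[2],
    r_squared = r2,
    t_vs_null = tstat,
    p_vs_null = 2 * pt(-abs(tstat), dfree),
    df = dfree, n = x$n
  )
}

#' Group differences in mixed-medium substrate uptake
#'
#' From a mixed-medium uptake ledger, computes per substrate the mean
#' depletion fraction (percent of the initial supply consumed) within each of
#' two response groups and their difference in percentage points, ranked by
#' absolute difference. Positive differences mean the first group consumed
#' more.
#'
#' @param ledger uptake ledger from [simulate_mixed()] (needs `substrate`,
#'   `fraction`, and a grouping column).
#' @param groups length-2 character vector of group labels to contrast.
#' @param group_col name of the grouping column.
#' @return A tibble with `substrate`, `class`, mean percent depletion per
#'   group, and `delta_pp` (percentage points), sorted by `abs(delta_pp)`.
#' @export
preference_differences <- function(ledger, groups = c("positive", "negative"),
                                   group_col = "response_group") {
  stopifnot(length(groups) == 2)
  df <- as_tibble(ledger)
  if (!group_col %in% names(df)) {
    abort(paste0("ledger lacks grouping column '", group_col, "'"))
  }
  df <- df |> filter(.data[[group_col]] %in% groups)
  for (g in groups) {
    if (!any(df[[group_col]] == g)) {
      abort(paste0("group '", g, "' has no consumers in the ledger"))
    }
  }
  wide <- df |>
    group_by(.data$substrate, .data$class, grp = .data[[group_col]]) |>
    summarise(pct = 100 * mean(.data$fraction), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "grp", values_from = "pct")
  wide$delta_pp <- wide[[groups[1]]] - wide[[groups[2]]]
  wide |> arrange(desc(abs(.data$delta_pp)))
}

#' Levins niche breadth
#'
#' `B = 1 / sum(p_i^2)` over normalized consumption proportions: 1 for a
#' strict specialist, `n` for a perfect generalist over `n` resources.
#'
#' @param p non-negative consumption proportions (normalized internally).
#' @return Niche breadth in `[1, length(p)]`; `NA` if total consumption is
#'   zero.
#' @examples
#' levins_index(c(0.5, 0.5, 0)) # 2
#' @export
levins_index <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0)) abort("consumption proportions must be non-negative")
  s <- sum(p)
  if (s == 0) return(NA_real_)
  p <- p / s
  1 / sum(p^2)
}

#' Variance in a phenotype explained by genomic predictors
#'
#' OLS r-squared of a phenotype on genomic predictors, by default the
#' standard model with rRNA operon copies, genome size and their interaction
#' (`response ~ rrn_copies * genome_size`), optionally per regime.
#'
#' @param data joined phenotype-trait table.
#' @param response column name of the response.
#' @param predictors character vector of predictor column names; the full
#'   factorial interaction model is fitted.
#' @param regime optional regime to subset on.
#' @return A tibble with `regime`, `r_squared`, `adj_r_squared`, `n`, `rank`
#'   (rank deficiency is reported, not hidden).
#' @export
variance_explained <- function(data, response = "r_realized",
                               predictors = c("rrn_copies", "genome_size"),
                               regime = NULL) {
  df <- as_tibble(data)
  if (!is.null(regime)) df <- df |> filter(.data$regime == !!regime)
  df <- df |> filter(is.finite(.data[[response]]))
  rhs <- paste(predictors, collapse = " * ")
  fit <- lm(stats::as.formula(paste(response, "~", rhs)), data = df)
  sm <- summary(fit)
  tibble(
    regime = regime %||% NA_character_,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = nrow(df),
    rank = fit$rank,
    rank_deficient = fit$rank < length(coef(fit))
  )
}

#' Kruskal-Wallis differences between response groups
#'
#' Thin wrapper over [stats::kruskal.test()] followed by pairwise Wilcoxon
#' tests with Benjamini-Hochberg correction, for parity with standard
#' trait-distribution comparisons.
#'
#' @param data data frame.
#' @param value column name of the trait.
#' @param group column name of the grouping factor.
#' @return A list with `kruskal` (htest) and `pairwise` (pairwise.htest).
#' @export
group_trait_test <- function(data, value, group = "response_group") {
  x <- data[[value]]; g <- factor(data[[group]])
  list(
    kruskal = stats::kruskal.test(x, g),
    pairwise = stats::pairwise.wilcox.test(x, g, p.adjust.method = "BH",
                                           exact = FALSE)
  )
}
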