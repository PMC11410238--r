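# Postzygotic reproductive isolation: spore-viability statistics with exact
# binomial uncertainty, and the viability-versus-identity regression.

#' Spore viability with exact binomial confidence interval
#'
#' `viability = 100 * viable / dissected`, with a Clopper-Pearson 95%
#' interval. Vectorized over crosses.
#'
#' @param viable viable-spore count(s).
#' @param dissected dissected-spore count(s), >= 1.
#' @param parent_a,parent_b optional strain/lineage labels.
#' @param conf_level confidence level for the exact interval.
#' @return data.frame `parent_a`, `parent_b`, `dissected`, `viable`,
#'   `viability`, `ci_low`, `ci_high` (all percentages).
#' @export
spore_viability <- function(viable, dissected, parent_a = NA_character_,
                            parent_b = NA_character_, conf_level = 0.95) {
  if (length(viable) != length(dissected))
    stop_bad("viable and dissected must have equal length")
  if (any(dissected < 1)) stop_bad("dissected must be >= 1")
  if (any(viable < 0) || any(viable > dissected))
    stop_bad("need 0 <= viable <= dissected")
  ci <- t(mapply(function(v, d)
    stats::binom.test(v, d, conf.level = conf_level)$conf.int,
    viable, dissected))
  data.frame(parent_a = rep_len(parent_a, length(viable)),
             parent_b = rep_len(parent_b, length(viable)),
             dissected = as.integer(dissected), viable = as.integer(viable),
             viability = 100 * viable / dissected,
             ci_low = 100 * ci[, 1L], ci_high = 100 * ci[, 2L],
             stringsAsFactors = FALSE)
}

#' Linear regression of spore viability on nucleotide identity
#'
#' Ordinary least squares `viability = a + b * identity` with r-squared,
#' adjusted r-squared (`1 - (1 - r2)(n - 1)/(n - 2)` for the single
#' predictor) and the two-sided slope p-value (t, n - 2 df). The x axis is
#' nucleotide identity in percent (`100 - 100 * divergence`).
#'
#' @param points data.frame with columns `identity` (percent) and
#'   `viability` (percent); n >= 3 and non-degenerate identity values.
#' @return list of class `viability_fit`: `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n_points`, `model` (the `lm` object).
#' @export
fit_viability_regression <- function(points) {
  if (!is.data.frame(points) || !all(c("identity", "viability") %in% names(points)))
    stop_bad("points must carry identity and viability columns")
  n <- nrow(points)
  if (n < 3L) stop_bad("need at least 3 points")
  if (stats::var(points$identity) == 0)
    stop_bad("identity values are all equal; slope is undefined")
  if (stats::var(points$viability) == 0) {
    # flat response: slope 0, no variance explained
    return(structure(list(slope = 0, intercept = mean(points$viability),
                          r_squared = 0,
                          adj_r_squared = 1 - (n - 1) / (n - 2),
                          p_value = 1, n_points = n, model = NULL),
                     class = "viability_fit"))
  }
  fit <- stats::lm(viability ~ identity, data = points)
  # collinear input (r2 = 1) is legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n_points = n, model = fit),
            class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  cat(sprintf(
    "<viability_fit> viability = %.3f + %.3f * identity (adj R2 = %.4f, p = %.3g, n = %d)\n",
    x$intercept, x$slope, x$adj_r_squared, x$p_value, x$n_points))
  invisible(x)
}

#' Classify a cross by spore viability
#'
#' Below `isolated_below` percent the cross is called reproductively
#' isolated; above `compatible_above`, compatible; in between, partial
#' isolation. The defaults (20/50) separate the far-below-random viabilities
#' of interspecies hybrids from the 50%+ typical of intraspecies crosses;
#' raw values always travel with the class.
#'
#' @param viability percent in `[0, 100]` (vectorized).
#' @param isolated_below,compatible_above thresholds in percent.
#' @return character vector: `"reproductively isolated"`,
#'   `"partial isolation"` or `"compatible"`.
#' @export
isolation_class <- function(viability, isolated_below = 20,
                            compatible_above = 50) {
  if (isolated_below >= compatible_above)
    stop_bad("thresholds inverted: need isolated_below < compatible_above")
  if (any(viability < 0 | viability > 100, na.rm = TRUE))
    stop_bad("viability must lie in [0, 100]")
  ifelse(viability < isolated_below, "reproductively isolated",
         ifelse(viability > compatible_above, "compatible",
                "partial isolation"))
}
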