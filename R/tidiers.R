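# broom-style tidiers for fitted result objects.

#' Tidy a residual analysis
#'
#' @param x An `mt_residuals` object.
#' @param ... Unused.
#' @return The per-category tibble (category, observed, simulated,
#'   residual, std_residual, outlier, direction).
#' @export
tidy.mt_residuals <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a residual analysis
#'
#' @param x An `mt_residuals` object.
#' @param ... Unused.
#' @return A tibble with `pearson_r`, `p.value`, `n_categories`,
#'   `n_outliers`, `threshold`, `method`.
#' @export
glance.mt_residuals <- function(x, ...) {
  ct <- attr(x, "pearson")
  tibble(
    pearson_r = unname(ct$estimate),
    p.value = ct$p.value,
    n_categories = nrow(x),
    n_outliers = sum(x$outlier),
    threshold = attr(x, "threshold"),
    method = attr(x, "method")
  )
}

#' Tidy a density table
#'
#' @param x An `mt_density` object.
#' @param ... Unused.
#' @return The per-group tibble.
#' @export
tidy.mt_density <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a density comparison
#'
#' @param x An `mt_density` object.
#' @param ... Unused.
#' @return A tibble with the chi-square statistic, df and p-value (NA when
#'   the test was not computable).
#' @export
glance.mt_density <- function(x, ...) {
  t <- attr(x, "test")
  tibble(
    statistic = if (is.null(t)) NA_real_ else unname(t$statistic),
    df = if (is.null(t)) NA_real_ else unname(t$parameter),
    p.value = if (is.null(t)) NA_real_ else t$p.value,
    grouping = attr(x, "grouping")
  )
}

#' One-row summary of a heteroplasmy comparison
#'
#' @param x An `mt_het_compare` object.
#' @param ... Unused.
#' @return A tibble with the test statistic, its name and the p-value.
#' @export
glance.mt_het_compare <- function(x, ...) {
  t <- attr(x, "test")
  if (inherits(t, "aov")) {
    s <- summary(t)[[1]]
    tibble(statistic = s$`F value`[1], p.value = s$`Pr(>F)`[1],
           test = "ANOVA")
  } else {
    tibble(statistic = unname(t$statistic), p.value = t$p.value,
           test = "t-test")
  }
}
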