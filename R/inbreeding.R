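#' Relative inbreeding depression
#'
#' `b_R = -b / trait_mean`: the fractional decline in the trait per unit
#' increase in individual genomic homozygosity, where `b` is the regression
#' coefficient of the trait on homozygosity and `trait_mean` the raw
#' population mean. Dimensionless, and invariant to rescaling the trait.
#'
#' @param b regression coefficient (trait units per unit homozygosity).
#' @param trait_mean raw phenotypic mean (trait units).
#' @return The scalar `b_R`.
#' @export
relative_depression <- function(b, trait_mean) {
  if (trait_mean == 0) stop("trait mean is zero; relative depression undefined", call. = FALSE)
  -b / trait_mean
}

#' Summarize inbreeding depression from a fitted model
#'
#' Extracts the homozygosity regression coefficient `b` from a fit that
#' includes the genomic-homozygosity covariate and combines it with the
#' empirical homozygosity distribution: `b_R = -b / mean(y)` (relative
#' depression), the 5th/95th homozygosity percentiles (linear-interpolation
#' quantiles), their gap, and the performance difference `|b| * gap` between
#' the upper and lower tails of the population, in trait units.
#'
#' @param fit a `gv_fit` whose fixed solutions include the homozygosity
#'   covariate.
#' @param homozygosity per-individual homozygosity fractions
#'   (see [individual_homozygosity()]) for the analysed population.
#' @param phenotypes raw trait values used for the population mean.
#' @param covariate name of the covariate in the fit's fixed solutions.
#' @return One-row tibble: `b`, `b_se`, `trait_mean`, `b_r`, `q05`, `q95`,
#'   `gap`, `difference`.
#' @export
depression_summary <- function(fit, homozygosity, phenotypes,
                               covariate = "homozygosity") {
  stopifnot(inherits(fit, "gv_fit"))
  row <- fit$fixed[fit$fixed$term == covariate, ]
  if (nrow(row) != 1L) {
    stop("fit does not include the '", covariate,
         "' covariate; refit with include_homozygosity = TRUE", call. = FALSE)
  }
  b <- row$estimate
  trait_mean <- mean(phenotypes, na.rm = TRUE)
  qs <- stats::quantile(homozygosity, c(0.05, 0.95), names = FALSE, type = 7)
  gap <- qs[2] - qs[1]
  tibble::tibble(
    b = b, b_se = row$se, trait_mean = trait_mean,
    b_r = relative_depression(b, trait_mean),
    q05 = qs[1], q95 = qs[2], gap = gap,
    difference = abs(b) * gap
  )
}
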