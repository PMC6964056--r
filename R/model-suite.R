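suite_codes <- c("A", "AD", "AE", "AM", "ADE", "ADM", "AME", "ADME")

code_letters <- function(code) {
  main <- sub("\\+.*$", "", code)
  extra <- regmatches(code, gregexpr("\\+(ad|dd)", code))[[1]]
  if (!main %in% suite_codes) {
    stop("unknown model code '", code, "'; valid codes: ",
         paste(suite_codes, collapse = ", "),
         " (optionally with '+ad'/'+dd' epistatic extensions)", call. = FALSE)
  }
  list(main = strsplit(main, "")[[1]], extra = sub("\\+", "", extra))
}

#' Build one model of the GBLUP model family
#'
#' Translates a model code into a [model_spec()]. The code letters select
#' random terms: `A` additive, `D` dominance, `E` additive-by-additive
#' epistasis, `M` maternal (identity covariance over dams); a residual is
#' always present. The genomic-homozygosity covariate for directional
#' dominance is included unless `include_homozygosity = FALSE`. Optional
#' suffixes `+ad` / `+dd` add additive-by-dominance / dominance-by-dominance
#' epistatic kernels (extensions outside the standard eight-model family).
#'
#' @param code one of `"A"`, `"AD"`, `"AE"`, `"AM"`, `"ADE"`, `"ADM"`,
#'   `"AME"`, `"ADME"`, optionally followed by `"+ad"`/`"+dd"`.
#' @param kernels named list with elements `additive` and, as required by the
#'   code, `dominance`, `epistatic_aa`, `epistatic_ad`, `epistatic_dd` (see
#'   [suite_kernels()]).
#' @param response trait column name.
#' @param fixed categorical fixed-effect columns.
#' @param dam_col column identifying the dam (maternal family).
#' @param include_homozygosity include the homozygosity covariate?
#' @param homozygosity_col covariate column name.
#' @param id_col individual-id column name.
#' @return A [model_spec()].
#' @export
build_model <- function(code, kernels, response = "trait",
                        fixed = c("cross", "batch", "day"),
                        dam_col = "dam", include_homozygosity = TRUE,
                        homozygosity_col = "homozygosity", id_col = "id") {
  parsed <- code_letters(code)
  letters <- parsed$main
  random <- list()
  need <- function(k) {
    if (is.null(kernels[[k]])) {
      stop("model '", code, "' requires kernel '", k, "'", call. = FALSE)
    }
    kernels[[k]]
  }
  random$additive <- need("additive")
  if ("D" %in% letters) random$dominance <- need("dominance")
  if ("E" %in% letters) random$epistatic_aa <- need("epistatic_aa")
  for (ex in parsed$extra) {
    random[[paste0("epistatic_", ex)]] <- need(paste0("epistatic_", ex))
  }
  if ("M" %in% letters) random$maternal <- dam_col
  model_spec(
    response = response, fixed = fixed,
    covariates = if (include_homozygosity) homozygosity_col else character(),
    random = random, id_col = id_col
  )
}

#' Build the kernel set for the model suite
#'
#' Convenience constructor of the additive, dominance and epistatic kernels a
#' model-suite run needs, from complete genotypes, under one approach.
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param approach `"noia"` or `"hwe"`.
#' @param extended also build the `epistatic_ad` and `epistatic_dd` kernels.
#' @return Named list of `gv_kernel`s: `additive`, `dominance`,
#'   `epistatic_aa` (and optionally `epistatic_ad`, `epistatic_dd`).
#' @export
suite_kernels <- function(g, approach = c("noia", "hwe"), extended = FALSE) {
  approach <- match.arg(approach)
  stats <- locus_stats(g)
  G <- build_grm(additive_contrasts(g, stats, approach), stats, approach)
  D <- build_drm(dominance_contrasts(g, stats, approach), stats, approach)
  out <- list(additive = G, dominance = D, epistatic_aa = build_epistatic(G, G))
  if (extended) {
    out$epistatic_ad <- build_epistatic(G, D)
    out$epistatic_dd <- build_epistatic(D, D)
  }
  out
}

#' Boundary-corrected mixture chi-square critical values and p-values
#'
#' Likelihood-ratio statistics for testing `q` variance components against
#' their zero boundary are distributed, under the null, as the mixture
#' `sum_k choose(q, k) / 2^q * chi^2_k` (with `chi^2_0` a point mass at 0).
#' `mixture_critical_value()` root-finds the critical value `c` with
#' `sum_k w_k P(chi^2_k > c) = alpha`; `mixture_pvalue()` evaluates the
#' mixture tail probability of an observed statistic.
#'
#' @param n_components number of variance components tested (`q >= 1`).
#' @param alpha type-I error rate in (0, 1).
#' @return `mixture_critical_value()`: the scalar critical value;
#'   `mixture_pvalue()`: the p-value.
#' @export
mixture_critical_value <- function(n_components, alpha) {
  q <- as.integer(n_components)
  stopifnot(q >= 1L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  w <- stats::dbinom(0:q, q, 0.5)
  tail_prob <- function(c) sum(w[-1] * stats::pchisq(c, df = 1:q, lower.tail = FALSE))
  if (alpha >= 1 - w[1]) return(0)
  stats::uniroot(function(c) tail_prob(c) - alpha,
                 lower = 0, upper = 200, tol = 1e-10)$root
}

#' @rdname mixture_critical_value
#' @param lrt_stat observed likelihood-ratio statistic (values in
#'   `[-1e-6, 0)` are clamped to 0).
#' @export
mixture_pvalue <- function(n_components, lrt_stat) {
  q <- as.integer(n_components)
  if (q == 0L) return(1)
  if (lrt_stat < -1e-6) stop("negative LRT statistic", call. = FALSE)
  lrt_stat <- max(lrt_stat, 0)
  w <- stats::dbinom(0:q, q, 0.5)
  p <- sum(w[-1] * stats::pchisq(lrt_stat, df = 1:q, lower.tail = FALSE))
  if (lrt_stat <= 0) p <- p + w[1]
  p
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Fit and compare the eight-model GBLUP family
#'
#' Fits the models A, AD, AE, AM, ADE, ADM, AME and ADME to one trait and
#' computes likelihood-ratio statistics of each sub-model against the full
#' ADME model with boundary-corrected mixture chi-square p-values (degrees of
#' freedom = number of omitted variance components). The best-fit model is
#' chosen by backward elimination from the full model: a term (D, E or M) is
#' retained exactly when dropping it alone from ADME is significant at level
#' `alpha` on the one-component mixture — the rule implied by star-table
#' model choices, and more powerful for detecting individual terms than
#' requiring the sub-model's joint test against ADME to reject.
#' Non-converged fits are flagged and excluded from selection.
#'
#' @param data phenotype data frame (ids, trait, fixed effects, dam,
#'   homozygosity).
#' @param kernels kernel list from [suite_kernels()].
#' @param alpha selection level for the LRT against ADME.
#' @param approach label recorded on the result (`"noia"` or `"hwe"`).
#' @inheritParams build_model
#' @return A `gv_suite`: list with `table` (model, n_components, df, logl,
#'   lrt, p_value, stars, converged), `fits`, `best_model`, `approach`,
#'   `alpha`.
#' @export
fit_suite <- function(data, kernels, response = "trait",
                      fixed = c("cross", "batch", "day"), dam_col = "dam",
                      include_homozygosity = TRUE,
                      homozygosity_col = "homozygosity", id_col = "id",
                      approach = c("noia", "hwe"), alpha = 0.05) {
  approach <- match.arg(approach)
  fits <- stats::setNames(vector("list", length(suite_codes)), suite_codes)
  for (code in suite_codes) {
    spec <- build_model(code, kernels, response = response, fixed = fixed,
                        dam_col = dam_col,
                        include_homozygosity = include_homozygosity,
                        homozygosity_col = homozygosity_col, id_col = id_col)
    fits[[code]] <- reml_fit(spec, data)
  }
  nc <- vapply(fits, function(f) length(f$components) - 1L, integer(1))
  logl <- vapply(fits, function(f) f$logl, numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$degenerate),
                 logical(1))
  df <- nc[["ADME"]] - nc
  lrt <- pmax(2 * (logl[["ADME"]] - logl), 0)
  pv <- vapply(seq_along(lrt), function(i) mixture_pvalue(df[i], lrt[i]), numeric(1))
  tab <- tibble::tibble(
    model = suite_codes, n_components = unname(nc), df = unname(as.integer(df)),
    logl = unname(logl), lrt = unname(lrt), p_value = pv,
    stars = significance_stars(pv), converged = unname(conv)
  )
  if (any(!conv)) {
    warning("non-converged model(s) excluded from selection: ",
            paste(suite_codes[!conv], collapse = ", "), call. = FALSE)
  }
  # backward elimination: keep D/E/M iff its single-term drop from ADME is
  # significant (ADME without D = AME, without E = ADM, without M = ADE)
  drop_of <- c(D = "AME", E = "ADM", M = "ADE")
  kept <- names(drop_of)[vapply(drop_of, function(code) {
    conv[[code]] && tab$p_value[tab$model == code] < alpha
  }, logical(1))]
  best <- paste0("A", paste(intersect(c("D", "M", "E"), kept), collapse = ""))
  if (!best %in% suite_codes) best <- "ADME" # unreachable fallback
  structure(list(table = tab, fits = fits, best_model = best,
                 approach = approach, alpha = alpha, response = response),
            class = "gv_suite")
}

#' @export
print.gv_suite <- function(x, ...) {
  cat(sprintf("<gv_suite> trait '%s' (%s approach), best model: %s\n",
              x$response, x$approach, x$best_model))
  print(as.data.frame(x$table), digits = 5)
  invisible(x)
}

#' Variance ratios with reference-population correction
#'
#' Multiplies each fitted variance component by its kernel's
#' [legarra_factor()] (factor 1 for identity-covariance terms and the
#' residual; approximately 1 for NOIA kernels built from sample frequencies),
#' sums them into the phenotypic variance, and returns the classical ratios
#' with first-order delta-method standard errors: narrow-sense heritability
#' `h2`, dominance ratio `d2`, maternal ratio `m2`, epistatic ratio `e2_aa`
#' and broad-sense heritability `H2` (all genetic components over phenotypic
#' variance). Terms absent from the model contribute 0.
#'
#' @param fit a converged `gv_fit`, or a named numeric vector of variance
#'   components including `residual` (for worked examples; SEs then `NA`).
#' @param kernels optional named list of kernels; defaults to the kernels
#'   stored in the fit's model spec.
#' @param apply_legarra apply the reference-population correction?
#' @return A tibble with columns `quantity`, `estimate`, `se` and a `factors`
#'   attribute recording the per-term corrections used.
#' @export
variance_ratios <- function(fit, kernels = NULL, apply_legarra = TRUE) {
  if (is.numeric(fit)) {
    comp <- fit
    if (!"residual" %in% names(comp)) {
      stop("component vector must include a 'residual' element", call. = FALSE)
    }
    fit_obj <- NULL
  } else {
    stopifnot(inherits(fit, "gv_fit"))
    if (!fit$converged) stop("fit did not converge; ratios unavailable", call. = FALSE)
    comp <- fit$components
    fit_obj <- fit
    kernels <- kernels %||% Filter(Negate(is.character), fit$spec$random)
  }
  terms <- names(comp)
  factors <- stats::setNames(rep(1, length(terms)), terms)
  if (apply_legarra && length(kernels)) {
    for (k in intersect(names(kernels), terms)) {
      factors[k] <- legarra_factor(kernels[[k]])
    }
  }
  corrected <- comp * factors
  all_known <- c("additive", "dominance", "epistatic_aa", "epistatic_ad",
                 "epistatic_dd", "maternal", "residual")
  genetic <- intersect(terms, setdiff(all_known, c("maternal", "residual")))
  sigma2_p <- sum(corrected)
  if (sigma2_p <= 0) stop("phenotypic variance is zero; ratios undefined", call. = FALSE)
  comp0 <- function(k) if (k %in% terms) corrected[[k]] else 0
  quantities <- list(
    sigma2_P = list(num = terms, est = sigma2_p),
    h2   = list(num = "additive",     est = comp0("additive") / sigma2_p),
    d2   = list(num = "dominance",    est = comp0("dominance") / sigma2_p),
    m2   = list(num = "maternal",     est = comp0("maternal") / sigma2_p),
    e2_aa = list(num = "epistatic_aa", est = comp0("epistatic_aa") / sigma2_p),
    H2   = list(num = genetic,        est = sum(corrected[genetic]) / sigma2_p)
  )
  se <- vapply(names(quantities), function(qn) {
    qd <- quantities[[qn]]
    if (is.null(fit_obj) || !length(intersect(qd$num, terms))) return(NA_real_)
    if (qn == "sigma2_P") {
      free <- setdiff(terms[comp > 0], fit_obj$boundary_terms)
      if (!length(free)) return(NA_real_)
      Cf <- tryCatch(solve(fit_obj$ai[free, free, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(Cf)) return(NA_real_)
      gf <- factors[free]
      return(sqrt(max(drop(gf %*% Cf %*% gf), 0)))
    }
    num <- intersect(qd$num, terms)
    if (!length(num)) return(NA_real_)
    ratio_se(fit_obj, numerator = num, denominator = terms,
             factors = factors)$se
  }, numeric(1))
  out <- tibble::tibble(
    quantity = names(quantities),
    estimate = unname(vapply(quantities, `[[`, numeric(1), "est")),
    se = unname(se)
  )
  attr(out, "factors") <- factors
  attr(out, "corrected_components") <- corrected
  out
}

#' Expected excess variance within full-sib families
#'
#' With dominance and epistasis present, full-sib families share variance
#' beyond the additive sire/dam contribution:
#' `1/4 sigma2_D + 1/8 sigma2_Eaa + 1/8 sigma2_Ead + 1/8 sigma2_Edd`.
#'
#' @param sigma_d2,sigma_eaa2,sigma_ead2,sigma_edd2 non-negative variance
#'   components (dominance; additive-by-additive, additive-by-dominance and
#'   dominance-by-dominance epistasis).
#' @return The scalar expected excess full-sib variance.
#' @export
fullsib_excess_variance <- function(sigma_d2, sigma_eaa2 = 0, sigma_ead2 = 0,
                                    sigma_edd2 = 0) {
  vals <- c(sigma_d2, sigma_eaa2, sigma_ead2, sigma_edd2)
  if (any(vals < 0)) stop("variance components must be non-negative", call. = FALSE)
  sum(vals * c(1 / 4, 1 / 8, 1 / 8, 1 / 8))
}
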