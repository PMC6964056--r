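#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' One row per variance component (plus the fixed-effect solutions when
#' `effects = "fixed"`), with delta-method standard errors from the inverse
#' average-information matrix (NA for boundary terms).
#'
#' @param x a `gv_fit`.
#' @param effects `"variances"` (default) or `"fixed"`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.gv_fit <- function(x, effects = c("variances", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") return(x$fixed)
  nm <- names(x$components)
  free <- setdiff(nm[x$components > 0], x$boundary_terms)
  se <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (length(free)) {
    Cf <- tryCatch(solve(x$ai[free, free, drop = FALSE]), error = function(e) NULL)
    if (!is.null(Cf)) se[free] <- sqrt(pmax(diag(Cf), 0))
  }
  tibble::tibble(
    term = nm,
    estimate = unname(x$components),
    se = unname(se),
    boundary = nm %in% x$boundary_terms
  )
}

#' @rdname tidy.gv_fit
#' @export
glance.gv_fit <- function(x, ...) {
  tibble::tibble(
    logl = x$logl,
    n = x$n,
    n_components = length(x$components),
    converged = x$converged,
    degenerate = isTRUE(x$degenerate),
    n_boundary = length(x$boundary_terms)
  )
}

#' Tidy a model-suite comparison
#'
#' The per-model table: log-likelihood, LRT against the full ADME model,
#' boundary-corrected mixture chi-square p-value and significance stars.
#'
#' @param x a `gv_suite`.
#' @param ... unused.
#' @return A tibble, one row per model.
#' @export
tidy.gv_suite <- function(x, ...) x$table

#' @rdname tidy.gv_suite
#' @export
glance.gv_suite <- function(x, ...) {
  tibble::tibble(
    best_model = x$best_model,
    approach = x$approach,
    alpha = x$alpha,
    n_models = nrow(x$table),
    n_converged = sum(x$table$converged)
  )
}
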