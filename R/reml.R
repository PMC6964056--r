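#' Declare a variance-component mixed model
#'
#' A `gv_model_spec` names the response, the categorical fixed effects, the
#' numeric covariates (e.g. genomic homozygosity) and an ordered list of
#' random terms. Each random term is either a relationship kernel (a
#' [new_kernel()] / symmetric matrix with row names covering the data ids) or
#' the name of a grouping column in the data, fitted with an identity
#' covariance over its levels (e.g. a maternal effect per dam). A residual
#' term is always added.
#'
#' @param response name of the trait column.
#' @param fixed character vector of categorical fixed-effect columns.
#' @param covariates character vector of numeric covariate columns.
#' @param random named list of random terms (kernel or grouping-column name);
#'   names must be unique.
#' @param id_col column holding individual ids (matched against kernel
#'   dimnames).
#' @return A `gv_model_spec`.
#' @export
model_spec <- function(response, fixed = character(), covariates = character(),
                       random = list(), id_col = "id") {
  stopifnot(is.character(response), length(response) == 1L, is.list(random))
  if (length(random) && (is.null(names(random)) || anyDuplicated(names(random)))) {
    stop("random terms must have unique names", call. = FALSE)
  }
  structure(
    list(response = response, fixed = fixed, covariates = covariates,
         random = random, id_col = id_col),
    class = "gv_model_spec"
  )
}

#' @export
print.gv_model_spec <- function(x, ...) {
  cat(sprintf("<gv_model_spec> %s ~ %s | random: %s + residual\n",
              x$response,
              paste(c("1", x$fixed, x$covariates), collapse = " + "),
              paste(names(x$random), collapse = " + ")))
  invisible(x)
}

# Align data and build y, X and the n x n covariance structures per term.
prepare_model <- function(spec, data) {
  data <- as.data.frame(data)
  needed <- c(spec$id_col, spec$response, spec$fixed, spec$covariates,
              unlist(Filter(is.character, spec$random)))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[, c(spec$response, spec$fixed, spec$covariates,
                                         unlist(Filter(is.character, spec$random))),
                                     drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d individual(s) with missing response/fixed-effect values", n_dropped))
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 2L) stop("fewer than 2 usable phenotyped individuals", call. = FALSE)
  ids <- as.character(data[[spec$id_col]])
  y <- as.numeric(data[[spec$response]])
  n <- length(y)

  # fixed-effect design: intercept + treatment-coded factors + covariates
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in spec$fixed) {
    fac <- droplevels(factor(data[[f]]))
    if (nlevels(fac) < 2L) {
      warning(sprintf("fixed factor '%s' has a single level; dropped", f), call. = FALSE)
      next
    }
    mm <- stats::model.matrix(~fac)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(fac)[-1])
    X <- cbind(X, mm)
  }
  for (cv in spec$covariates) {
    X <- cbind(X, as.numeric(data[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effects design is singular; confounded columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  terms <- names(spec$random)
  Q <- vector("list", length(terms)); names(Q) <- terms
  Zt <- vector("list", length(terms)); names(Zt) <- terms  # effect -> obs map
  Kt <- vector("list", length(terms)); names(Kt) <- terms
  effect_ids <- vector("list", length(terms)); names(effect_ids) <- terms
  for (k in terms) {
    term <- spec$random[[k]]
    if (is.character(term) && length(term) == 1L) {
      fac <- factor(data[[term]])
      Z <- stats::model.matrix(~ 0 + fac)
      Q[[k]] <- tcrossprod(Z)
      Zt[[k]] <- Z
      Kt[k] <- list(NULL) # identity over levels
      effect_ids[[k]] <- levels(fac)
    } else {
      K <- as.matrix(term)
      if (is.null(rownames(K))) stop(sprintf("kernel '%s' lacks row names", k), call. = FALSE)
      if (!all(ids %in% rownames(K))) {
        stop(sprintf("kernel '%s' does not cover all phenotyped ids", k), call. = FALSE)
      }
      Ksub <- K[ids, ids]
      Q[[k]] <- Ksub
      Zt[k] <- list(NULL) # identity design
      Kt[[k]] <- Ksub
      effect_ids[[k]] <- ids
    }
  }
  list(y = y, X = X, Q = Q, Z = Zt, K = Kt, ids = ids, n = n,
       effect_ids = effect_ids, terms = terms, n_dropped = n_dropped)
}

# -2 logL pieces at theta; returns logL, P y, and intermediates
reml_eval <- function(m, theta, want_P = FALSE) {
  n <- m$n
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(m$Q)) if (theta[k] != 0) V <- V + theta[k] * m$Q[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), m$y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), m$X))
  XtViX <- crossprod(m$X, Vi_X)
  chx <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(m$X, Vi_y)))
  Py <- Vi_y - Vi_X %*% beta
  yPy <- sum(m$y * Py)
  out <- list(
    logl = -0.5 * (logdetV + logdetX + yPy),
    Py = Py, beta = drop(beta), XtViX_chol = chx
  )
  if (want_P) {
    Vi <- chol2inv(ch)
    W <- backsolve(chx, t(Vi_X), transpose = TRUE)  # chx^-T Vi_X^T
    out$P <- Vi - crossprod(W)
  }
  out
}

#' REML log-likelihood at a given component vector
#'
#' Evaluates the restricted log-likelihood
#' `logL = -1/2 (log|V| + log|X'V^-1 X| + y'Py)` (the `n log 2 pi` constant is
#' omitted consistently, so only differences between models on the same data
#' are meaningful).
#'
#' @param spec a [model_spec()].
#' @param data data frame with response, fixed effects, covariates, ids.
#' @param theta named or ordered numeric vector of variance components: one
#'   per random term in `spec$random` order, then the residual (last).
#' @return The scalar REML log-likelihood.
#' @export
reml_logl <- function(spec, data, theta) {
  m <- prepare_model(spec, data)
  stopifnot(length(theta) == length(m$terms) + 1L)
  if (any(theta[seq_along(m$terms)] < 0) || theta[length(theta)] <= 0) {
    stop("variance components must be >= 0 with residual > 0", call. = FALSE)
  }
  ev <- reml_eval(m, as.numeric(theta))
  if (is.null(ev)) stop("V not positive definite at theta", call. = FALSE)
  ev$logl
}

#' Fit a variance-component model by average-information REML
#'
#' Maximizes the restricted likelihood over the non-negative orthant with
#' average-information (AI) updates and step-halving back to expectation-
#' maximisation-sized steps whenever an AI step would decrease the
#' likelihood or leave the feasible region. Components whose update goes
#' negative while the gradient points outward are pinned at zero (boundary
#' terms). Convergence requires `|change in logL| < 1e-8` and a maximum
#' relative component change `< 1e-6`.
#'
#' @param spec a [model_spec()].
#' @param data data frame with response, fixed effects, covariates and ids.
#' @param max_iter maximum AI iterations.
#' @param verbose print the iteration trace.
#' @return A `gv_fit` with elements `components` (named, boundary terms
#'   reported as 0), `logl`, `ai` (average-information matrix at convergence,
#'   terms + residual), `fixed` (tibble of fixed-effect solutions and SEs),
#'   `blups` (list of per-term effect tibbles), `converged`,
#'   `boundary_terms`, `n`, `trace`.
#' @export
reml_fit <- function(spec, data, max_iter = 100L, verbose = FALSE) {
  m <- prepare_model(spec, data)
  nterm <- length(m$terms)
  ntheta <- nterm + 1L
  theta_names <- c(m$terms, "residual")
  vy <- stats::var(m$y)

  if (!is.finite(vy) || vy <= 0) {
    # constant response: nothing to partition
    comp <- stats::setNames(rep(0, ntheta), theta_names)
    return(new_gv_fit(comp, logl = NA_real_, ai = matrix(NA_real_, ntheta, ntheta,
                                                         dimnames = list(theta_names, theta_names)),
                      fixed = tibble::tibble(term = colnames(m$X),
                                             estimate = c(mean(m$y), rep(0, ncol(m$X) - 1L)),
                                             se = NA_real_),
                      blups = stats::setNames(
                        lapply(m$terms, function(k) tibble::tibble(
                          id = m$effect_ids[[k]], blup = 0)), m$terms),
                      converged = TRUE, boundary = m$terms, n = m$n,
                      degenerate = TRUE, spec = spec,
                      trace = tibble::tibble(iter = integer(), logl = numeric())))
  }

  floor_val <- 1e-10 * vy
  theta <- rep(vy / ntheta, ntheta)  # equal split of phenotypic variance
  ev <- reml_eval(m, theta, want_P = TRUE)
  if (is.null(ev)) stop("initial V not positive definite; non-PSD kernel?", call. = FALSE)

  trace <- list()
  converged <- FALSE
  grad <- rep(NA_real_, ntheta)
  AI <- matrix(NA_real_, ntheta, ntheta)

  for (iter in seq_len(max_iter)) {
    Py <- ev$Py
    P <- ev$P
    # u_k = Q_k P y (residual: Q = I)
    U <- matrix(0, m$n, ntheta)
    for (k in seq_len(nterm)) U[, k] <- m$Q[[k]] %*% Py
    U[, ntheta] <- Py
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    trPQ <- c(vapply(seq_len(nterm), function(k) sum(P * m$Q[[k]]), numeric(1)),
              sum(diag(P)))
    yPQPy <- colSums(U * c(Py))
    grad <- -0.5 * (trPQ - yPQPy)

    # active set: pinned components stay at the floor
    pinned <- theta <= floor_val & grad < 0
    pinned[ntheta] <- FALSE
    free <- which(!pinned)
    step <- rep(0, ntheta)
    Afree <- AI[free, free, drop = FALSE]
    step[free] <- tryCatch(
      solve(Afree + diag(1e-10 * max(diag(Afree)), length(free)), grad[free]),
      error = function(e) grad[free] * theta[free] / max(abs(grad[free]) * theta[free], 1)
    )

    lambda <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- pmax(theta + lambda * step, floor_val)
      cand[pinned] <- floor_val
      cand[ntheta] <- max(cand[ntheta], floor_val)
      ev_cand <- reml_eval(m, cand, want_P = TRUE)
      if (!is.null(ev_cand) && ev_cand$logl >= ev$logl - 1e-10) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) { cand <- theta; ev_cand <- ev }
    dll <- abs(ev_cand$logl - ev$logl)
    rel <- max(abs(cand - theta) / pmax(theta, floor_val))
    if (verbose) {
      message(sprintf("iter %2d logL %.6f theta %s", iter, ev_cand$logl,
                      paste(signif(cand, 4), collapse = " ")))
    }
    trace[[iter]] <- c(iter = iter, logl = ev_cand$logl)
    theta <- cand
    ev <- ev_cand
    if (dll < 1e-8 && rel < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("REML did not converge within max_iter; returning last iterate", call. = FALSE)
  }

  boundary <- theta_names[seq_len(nterm)][theta[seq_len(nterm)] <= floor_val * 1.01]
  comp <- theta
  comp[theta <= floor_val * 1.01] <- 0
  names(comp) <- theta_names
  dimnames(AI) <- list(theta_names, theta_names)

  # fixed-effect solutions and SEs
  XtViX_inv <- chol2inv(ev$XtViX_chol)
  fixed <- tibble::tibble(
    term = colnames(m$X),
    estimate = ev$beta,
    se = sqrt(pmax(diag(XtViX_inv), 0))
  )

  # BLUPs: u_hat_k = sigma2_k K Z' P y
  blups <- stats::setNames(vector("list", nterm), m$terms)
  for (k in seq_len(nterm)) {
    uk <- if (comp[k] == 0) {
      rep(0, length(m$effect_ids[[k]]))
    } else if (is.null(m$Z[[k]])) {
      comp[k] * drop(m$K[[k]] %*% ev$Py)
    } else {
      comp[k] * drop(crossprod(m$Z[[k]], ev$Py))
    }
    blups[[k]] <- tibble::tibble(id = m$effect_ids[[k]], blup = unname(uk))
  }

  new_gv_fit(comp, logl = ev$logl, ai = AI, fixed = fixed, blups = blups,
             converged = converged, boundary = boundary, n = m$n,
             degenerate = FALSE, spec = spec,
             trace = dplyr::bind_rows(lapply(trace, function(r)
               tibble::tibble(iter = r[["iter"]], logl = r[["logl"]]))))
}

new_gv_fit <- function(components, logl, ai, fixed, blups, converged,
                       boundary, n, degenerate, spec, trace) {
  structure(
    list(components = components, logl = logl, ai = ai, fixed = fixed,
         blups = blups, converged = converged, boundary_terms = boundary,
         n = n, degenerate = degenerate, spec = spec, trace = trace),
    class = "gv_fit"
  )
}

#' @export
print.gv_fit <- function(x, ...) {
  cat(sprintf("<gv_fit> %s, n = %d, logL = %.4f%s\n",
              x$spec$response, x$n, x$logl,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$components, 6))
  invisible(x)
}

#' Extract BLUP effect predictions from a fitted model
#'
#' Returns the mixed-model-equation solutions for one or all random terms;
#' terms with a zero variance component have all-zero predictions.
#'
#' @param fit a `gv_fit`.
#' @param term optional term name; default returns all terms stacked.
#' @return A tibble with columns `term`, `id`, `blup`.
#' @export
blup_predict <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "gv_fit"))
  terms <- term %||% names(fit$blups)
  bad <- setdiff(terms, names(fit$blups))
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dplyr::bind_rows(lapply(terms, function(k) {
    dplyr::mutate(fit$blups[[k]], term = k, .before = 1L)
  }))
}

#' Delta-method standard error for a variance-component ratio
#'
#' Computes `r = sum(c_k theta_k, k in numerator) / sum(c_k theta_k, k in
#' denominator)` and its first-order delta-method standard error, using the
#' inverse average-information matrix as the covariance of the estimated
#' components. Components on the zero boundary are treated as fixed (zero
#' variance, zero covariance). `c_k` are optional per-term scale factors
#' (e.g. reference-population corrections).
#'
#' @param fit a converged `gv_fit`.
#' @param numerator character vector of term names (may include
#'   `"residual"`).
#' @param denominator character vector of term names; default all terms plus
#'   residual (the phenotypic variance).
#' @param factors optional named numeric of per-term scale factors, default 1.
#' @return A one-row tibble with `estimate` and `se`.
#' @export
ratio_se <- function(fit, numerator, denominator = NULL, factors = NULL) {
  stopifnot(inherits(fit, "gv_fit"))
  theta <- fit$components
  nm <- names(theta)
  denominator <- denominator %||% nm
  stopifnot(all(numerator %in% nm), all(denominator %in% nm))
  cvec <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(factors)) cvec[names(factors)] <- factors
  sc <- cvec * theta
  N <- sum(sc[numerator]); D <- sum(sc[denominator])
  if (D <= 0) stop("denominator variance is zero; ratio undefined", call. = FALSE)
  est <- N / D
  free <- setdiff(nm[theta > 0], fit$boundary_terms)
  if (!length(free)) {
    return(tibble::tibble(estimate = est, se = NA_real_))
  }
  C <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  Cf <- tryCatch(solve(fit$ai[free, free, drop = FALSE]), error = function(e) NULL)
  if (is.null(Cf)) return(tibble::tibble(estimate = est, se = NA_real_))
  C[free, free] <- Cf
  g <- cvec * ((nm %in% numerator) * D - N * (nm %in% denominator)) / D^2
  tibble::tibble(estimate = est, se = sqrt(max(drop(g %*% C %*% g), 0)))
}
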