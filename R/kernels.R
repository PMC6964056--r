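#' @rdname additive_contrasts
#' @export
new_contrasts <- function(values, kind, approach) {
  stopifnot(is.matrix(values), kind %in% c("additive", "dominance"),
            approach %in% c("hwe", "noia"))
  structure(values, class = c("gv_contrasts", "matrix", "array"),
            kind = kind, approach = approach)
}

#' Additive and dominance genotype contrasts
#'
#' `additive_contrasts()` assigns each genotype the centred allele dosage
#' `h_a[i, j] = x_ij - 2 p_j`. The additive contrasts are identical under the
#' HWE and NOIA parameterizations; only the kernel scaling differs.
#'
#' `dominance_contrasts()` assigns dominance coefficients. Under HWE they are
#' `(-2p^2, 2pq, -2q^2)` for dosages 0/1/2 (orthogonal to the additive
#' contrast if the sample is in Hardy-Weinberg equilibrium). Under NOIA they
#' are `(-2 p1 p2, 4 p0 p2, -2 p0 p1) / (p0 + p2 - (p0 - p2)^2)`, built from
#' the observed genotype frequencies so that orthogonality to the additive
#' contrast holds exactly in the analysed sample, without assuming HWE.
#' Loci with a zero NOIA denominator (e.g. monomorphic) get an all-zero
#' column and are reported in a warning; they contribute nothing to kernels
#' while keeping the locus panel (and hence the divisors) intact.
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param stats optional precomputed [locus_stats()].
#' @param approach `"noia"` or `"hwe"`.
#' @return A `gv_contrasts` matrix (individuals x loci) tagged with its kind
#'   and approach.
#' @export
additive_contrasts <- function(g, stats = NULL, approach = c("noia", "hwe")) {
  approach <- match.arg(approach)
  g <- assert_genotypes(g)
  if (any(is.na(g))) stop("contrasts require complete genotypes; impute first", call. = FALSE)
  stats <- stats %||% locus_stats(g)
  h <- sweep(unclass(g) + 0, 2L, 2 * stats$p, "-")
  new_contrasts(h, "additive", approach)
}

#' @rdname additive_contrasts
#' @export
dominance_contrasts <- function(g, stats = NULL, approach = c("noia", "hwe")) {
  approach <- match.arg(approach)
  g <- assert_genotypes(g)
  if (any(is.na(g))) stop("contrasts require complete genotypes; impute first", call. = FALSE)
  stats <- stats %||% locus_stats(g)
  x <- unclass(g)
  n <- nrow(x); m <- ncol(x)
  h <- matrix(0, n, m, dimnames = dimnames(x))
  if (approach == "hwe") {
    p <- stats$p; q <- 1 - p
    v0 <- -2 * p^2; v1 <- 2 * p * q; v2 <- -2 * q^2
    for (j in seq_len(m)) h[, j] <- c(v0[j], v1[j], v2[j])[x[, j] + 1L]
  } else {
    p0 <- stats$p0; p1 <- stats$p1; p2 <- stats$p2
    den <- p0 + p2 - (p0 - p2)^2
    degen <- den <= 1e-12
    if (any(degen)) {
      warning(sprintf(
        "%d locus/loci with zero NOIA dominance contrast set to zero columns: %s",
        sum(degen),
        paste(utils::head(stats$locus_id[degen], 5L), collapse = ", ")
      ), call. = FALSE)
    }
    for (j in seq_len(m)) {
      if (degen[j]) next
      vals <- c(-2 * p1[j] * p2[j], 4 * p0[j] * p2[j], -2 * p0[j] * p1[j]) / den[j]
      h[, j] <- vals[x[, j] + 1L]
    }
  }
  new_contrasts(h, "dominance", approach)
}

kernel_components <- c("additive", "dominance", "epistatic_aa", "epistatic_ad",
                       "epistatic_dd", "pedigree_A")

#' Construct a relationship matrix object
#'
#' @param values symmetric n x n matrix.
#' @param component one of `"additive"`, `"dominance"`, `"epistatic_aa"`,
#'   `"epistatic_ad"`, `"epistatic_dd"`, `"pedigree_A"`.
#' @param approach `"hwe"`, `"noia"` or `"pedigree"`.
#' @param scale_denominator the positive scalar the cross-product was divided
#'   by (1 for unscaled kernels).
#' @return A `gv_kernel` matrix tagged with its metadata.
#' @export
new_kernel <- function(values, component, approach, scale_denominator = 1) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  component <- match.arg(component, kernel_components)
  approach <- match.arg(approach, c("hwe", "noia", "pedigree"))
  if (max(abs(values - t(values))) > 1e-10) {
    stop("relationship matrix is not symmetric", call. = FALSE)
  }
  structure((values + t(values)) / 2,
            class = c("gv_kernel", "matrix", "array"),
            component = component, approach = approach,
            scale_denominator = scale_denominator)
}

#' @export
print.gv_kernel <- function(x, ...) {
  cat(sprintf("<gv_kernel> %s (%s), %d x %d, trace mean %.4f\n",
              attr(x, "component"), attr(x, "approach"),
              nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Additive genomic relationship matrix
#'
#' Builds `G` from additive contrasts `H_a`. Under NOIA the cross-product is
#' divided by `tr(H_a H_a') / n` so the mean diagonal of `G` is exactly 1;
#' under HWE the divisor is `2 * sum_j p_j (1 - p_j)` (VanRaden method 1).
#'
#' @param h additive [additive_contrasts()].
#' @param stats the [locus_stats()] the contrasts were built from (needed for
#'   the HWE divisor).
#' @param approach `"noia"` or `"hwe"`; defaults to the contrasts' tag.
#' @return A `gv_kernel` of component `"additive"`.
#' @export
build_grm <- function(h, stats = NULL, approach = NULL) {
  stopifnot(inherits(h, "gv_contrasts"))
  if (attr(h, "kind") != "additive") stop("build_grm() needs additive contrasts", call. = FALSE)
  approach <- approach %||% attr(h, "approach")
  approach <- match.arg(approach, c("noia", "hwe"))
  hh <- tcrossprod(unclass(h))
  den <- if (approach == "noia") {
    sum(diag(hh)) / nrow(hh)
  } else {
    if (is.null(stats)) stop("HWE scaling needs locus_stats (allele frequencies)", call. = FALSE)
    2 * sum(stats$p * (1 - stats$p))
  }
  if (!is.finite(den) || den <= 0) {
    stop("non-positive GRM divisor: all loci monomorphic?", call. = FALSE)
  }
  new_kernel(hh / den, "additive", approach, den)
}

#' Dominance genomic relationship matrix
#'
#' `D_HWE = H_d H_d' / (4 sum_j p_j^2 (1-p_j)^2)`;
#' `D_NOIA = H_d H_d' / (tr(H_d H_d') / n)`, so `D_NOIA` has unit mean
#' diagonal.
#'
#' @param h dominance [dominance_contrasts()] of matching approach.
#' @inheritParams build_grm
#' @return A `gv_kernel` of component `"dominance"`.
#' @export
build_drm <- function(h, stats = NULL, approach = NULL) {
  stopifnot(inherits(h, "gv_contrasts"))
  if (attr(h, "kind") != "dominance") stop("build_drm() needs dominance contrasts", call. = FALSE)
  approach <- approach %||% attr(h, "approach")
  approach <- match.arg(approach, c("noia", "hwe"))
  if (approach != attr(h, "approach")) {
    stop("dominance contrasts were built under the other approach", call. = FALSE)
  }
  hh <- tcrossprod(unclass(h))
  den <- if (approach == "noia") {
    sum(diag(hh)) / nrow(hh)
  } else {
    if (is.null(stats)) stop("HWE scaling needs locus_stats", call. = FALSE)
    4 * sum(stats$p^2 * (1 - stats$p)^2)
  }
  if (!is.finite(den) || den <= 0) {
    stop(sprintf("non-positive dominance divisor (%s): no dominance contrast in panel",
                 approach), call. = FALSE)
  }
  new_kernel(hh / den, "dominance", approach, den)
}

#' Epistatic relationship kernels by scaled Hadamard products
#'
#' The additive-by-additive kernel is the Hadamard (elementwise) square of
#' `G`; additive-by-dominance and dominance-by-dominance kernels are the
#' corresponding mixed products. Under the HWE approach the scaling constant
#' is `k = 1`; under NOIA the product is divided by its own trace mean so the
#' kernel's mean diagonal is 1.
#'
#' @param a,b `gv_kernel` objects of matching dimension and approach, each
#'   additive or dominance.
#' @return A `gv_kernel` of component `"epistatic_aa"`, `"epistatic_ad"` or
#'   `"epistatic_dd"`.
#' @export
build_epistatic <- function(a, b = a) {
  stopifnot(inherits(a, "gv_kernel"), inherits(b, "gv_kernel"))
  if (!identical(dim(a), dim(b))) stop("kernel dimension mismatch", call. = FALSE)
  approach <- attr(a, "approach")
  if (!identical(approach, attr(b, "approach"))) {
    stop("kernels built under different approaches", call. = FALSE)
  }
  pair <- sort(c(attr(a, "component"), attr(b, "component")))
  component <- if (identical(pair, c("additive", "additive"))) {
    "epistatic_aa"
  } else if (identical(pair, c("additive", "dominance"))) {
    "epistatic_ad"
  } else if (identical(pair, c("dominance", "dominance"))) {
    "epistatic_dd"
  } else {
    stop("epistatic kernels are products of additive/dominance kernels", call. = FALSE)
  }
  prod <- unclass(a) * unclass(b)
  den <- if (approach == "noia") mean(diag(prod)) else 1
  if (!is.finite(den) || den <= 0) stop("zero-trace Hadamard product", call. = FALSE)
  new_kernel(prod / den, component, approach, den)
}

#' Reference-population rescaling factor
#'
#' The factor `mean(diag(V)) - mean(V)` by which a variance component fitted
#' with kernel `V` is multiplied so that estimates from differently scaled
#' kernels refer to the same reference population. For NOIA kernels built
#' from sample frequencies the factor is 1 (trace mean exactly 1, grand mean
#' essentially 0), so no correction is needed.
#'
#' @param v a square matrix or `gv_kernel`.
#' @return The scalar correction factor.
#' @export
legarra_factor <- function(v) {
  v <- as.matrix(v)
  stopifnot(nrow(v) == ncol(v))
  mean(diag(v)) - mean(v)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive numerator relationship matrix `A` from a pedigree by
#' the tabular method, assuming non-inbred unrelated founders. Unknown
#' parents are coded `NA`, `0` or `""`. Provided for comparison of
#' genomic- and pedigree-based variance components.
#'
#' @param ped data frame with columns `id`, `sire`, `dam`.
#' @return A `gv_kernel` of component `"pedigree_A"` with rows/cols in the
#'   order of `ped$id`.
#' @export
pedigree_numerator <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree", call. = FALSE)
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  sire <- clean(ped$sire); dam <- clean(ped$dam)
  unknown_parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(unknown_parents)) {
    stop("parents absent from pedigree id column: ",
         paste(unknown_parents, collapse = ", "), call. = FALSE)
  }
  # topological order: parents before offspring; stalled pass => cycle
  placed <- character(0)
  remaining <- seq_along(id)
  order_idx <- integer(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(sire[i]) || sire[i] %in% placed) &&
        (is.na(dam[i]) || dam[i] %in% placed)
    }, logical(1))]
    if (!length(ready)) stop("cycle detected in pedigree", call. = FALSE)
    order_idx <- c(order_idx, ready)
    placed <- c(placed, id[ready])
    remaining <- setdiff(remaining, ready)
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  pos <- stats::setNames(seq_len(n), id)
  for (k in order_idx) {
    s <- if (is.na(sire[k])) 0L else pos[[sire[k]]]
    d <- if (is.na(dam[k])) 0L else pos[[dam[k]]]
    i <- pos[[id[k]]]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    for (j in setdiff(order_idx[seq_len(which(order_idx == k) - 1L)], k)) {
      jj <- pos[[id[j]]]
      aij <- 0.5 * ((if (s > 0L) A[jj, s] else 0) + (if (d > 0L) A[jj, d] else 0))
      A[i, jj] <- A[jj, i] <- aij
    }
  }
  new_kernel(A, "pedigree_A", "pedigree", 1)
}
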