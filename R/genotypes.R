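#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores allele counts of an arbitrarily chosen allele at
#' biallelic SNPs: an integer matrix of individuals (rows) by loci (columns)
#' with entries in \{0, 1, 2\}. Missing calls are stored as `NA` (a dedicated
#' sentinel, never conflated with the homozygote code 0).
#'
#' @param codes numeric/integer matrix, entries in \{0, 1, 2\} or `NA`.
#' @param ids character vector of unique individual identifiers (defaults to
#'   existing rownames or `ind_1...`).
#' @param locus_ids character vector of unique locus identifiers (defaults to
#'   existing colnames or `snp_1...`).
#' @return An object of class `genotype_matrix` (an integer matrix with
#'   dimnames).
#' @export
genotype_matrix <- function(codes, ids = NULL, locus_ids = NULL) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 1L || ncol(codes) < 1L) {
    stop("genotype matrix must have at least one individual and one locus", call. = FALSE)
  }
  vals <- codes[!is.na(codes)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing genotype codes must be 0, 1 or 2", call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  if (is.null(ids)) {
    ids <- rownames(codes) %||% paste0("ind_", seq_len(nrow(codes)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(codes) %||% paste0("snp_", seq_len(ncol(codes)))
  }
  if (anyDuplicated(ids)) stop("individual ids must be unique", call. = FALSE)
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique", call. = FALSE)
  if (length(ids) != nrow(codes) || length(locus_ids) != ncol(codes)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(codes) <- list(as.character(ids), as.character(locus_ids))
  class(codes) <- c("genotype_matrix", class(codes))
  codes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci (%.2f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  invisible(x)
}

is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

assert_genotypes <- function(g) {
  if (!is_genotype_matrix(g)) g <- genotype_matrix(g)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-locus allele and genotype frequencies
#'
#' Computes, over non-missing calls only, the frequency `p` of the counted
#' allele, the observed genotype frequencies `p0`, `p1`, `p2`, the minor
#' allele frequency and the call rate for every locus. Loci with zero
#' non-missing calls are flagged `valid = FALSE` and must be excluded from
#' downstream kernels.
#'
#' @param g a [genotype_matrix()].
#' @return A tibble with one row per locus: `locus_id`, `p`, `p0`, `p1`, `p2`,
#'   `maf`, `call_rate`, `n_called`, `valid`.
#' @export
locus_stats <- function(g) {
  g <- assert_genotypes(g)
  n <- nrow(g)
  n0 <- unname(colSums(g == 0L, na.rm = TRUE))
  n1 <- unname(colSums(g == 1L, na.rm = TRUE))
  n2 <- unname(colSums(g == 2L, na.rm = TRUE))
  nc <- n0 + n1 + n2
  p  <- ifelse(nc > 0, (n1 + 2 * n2) / (2 * nc), NA_real_)
  tibble::tibble(
    locus_id  = colnames(g),
    p         = p,
    p0        = ifelse(nc > 0, n0 / nc, NA_real_),
    p1        = ifelse(nc > 0, n1 / nc, NA_real_),
    p2        = ifelse(nc > 0, n2 / nc, NA_real_),
    maf       = pmin(p, 1 - p),
    call_rate = nc / n,
    n_called  = as.integer(nc),
    valid     = nc > 0
  )
}

#' Filter loci on minor allele frequency and call rate
#'
#' Keeps loci with `maf >= maf_min` and `call_rate >= callrate_min` (both
#' thresholds inclusive); locus order is preserved. Invalid loci (no calls)
#' are always removed.
#'
#' @param g a [genotype_matrix()].
#' @param stats optional precomputed [locus_stats()] for `g`.
#' @param maf_min,callrate_min inclusive thresholds in \[0, 1\].
#' @return The filtered `genotype_matrix`.
#' @export
filter_loci <- function(g, stats = NULL, maf_min = 0.05, callrate_min = 0.97) {
  g <- assert_genotypes(g)
  if (maf_min < 0 || maf_min > 1 || callrate_min < 0 || callrate_min > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  stats <- stats %||% locus_stats(g)
  keep <- stats$valid & stats$maf >= maf_min & stats$call_rate >= callrate_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop("all loci removed by QC filters: empty SNP panel", call. = FALSE)
  }
  genotype_matrix(g[, keep, drop = FALSE])
}

#' Impute missing genotypes by genotype-frequency sampling
#'
#' Each missing call at a locus is drawn from \{0, 1, 2\} with probabilities
#' equal to that locus's observed genotype frequencies. Non-missing entries
#' are untouched; the draw is reproducible for a fixed seed.
#'
#' @param g a [genotype_matrix()].
#' @param stats optional precomputed [locus_stats()] for `g`.
#' @param seed integer seed for the imputation draw.
#' @return A `genotype_matrix` with no missing entries.
#' @export
impute_missing <- function(g, stats = NULL, seed = 1L) {
  g <- assert_genotypes(g)
  stats <- stats %||% locus_stats(g)
  if (!any(is.na(g))) return(g)
  bad <- !stats$valid & colSums(is.na(unclass(g))) > 0
  if (any(bad)) {
    stop("cannot impute locus with zero non-missing calls: ",
         paste(stats$locus_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- unclass(g)
  withr_seed(seed, {
    for (j in which(colSums(is.na(out)) > 0)) {
      miss <- which(is.na(out[, j]))
      out[miss, j] <- sample(
        0:2, length(miss), replace = TRUE,
        prob = c(stats$p0[j], stats$p1[j], stats$p2[j])
      )
    }
  })
  genotype_matrix(out)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Per-individual genomic homozygosity
#'
#' The proportion of an individual's loci that are homozygous (code 0 or 2).
#' Used as the directional-dominance covariate measuring inbreeding depression.
#'
#' @param g a [genotype_matrix()] with no missing entries (impute first).
#' @return Named numeric vector of homozygosity fractions in \[0, 1\].
#' @export
individual_homozygosity <- function(g) {
  g <- assert_genotypes(g)
  if (any(is.na(g))) {
    stop("genotypes contain missing entries; run impute_missing() first",
         call. = FALSE)
  }
  rowMeans(unclass(g) != 1L)
}
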