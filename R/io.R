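#' Read SNP genotypes into a genotype matrix
#'
#' Supported formats: VCF (biallelic records; genotype coded as the ALT-allele
#' dosage, multi-allelic records skipped with a warning), PLINK `.raw`
#' additive coding (`NA` = missing), and plain CSV (rows = individuals, first
#' column = id, one column per locus, empty cell = missing).
#'
#' @param path file path.
#' @param format `"vcf"`, `"plink_raw"` or `"csv"` (guessed from the file
#'   extension by default).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink_raw", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", gz = "vcf", raw = "plink_raw", csv = "csv",
                     stop("cannot guess format from extension of ", path, call. = FALSE))
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink_raw = read_genotypes_raw(path),
         csv = read_genotypes_csv(path))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sprintf("skipped %d multi-allelic VCF record(s)", sum(!bi)), call. = FALSE)
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  ids[is.na(ids) | ids == "."] <- paste0(
    vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))[is.na(ids) | ids == "."]
  x <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  a1 <- sub("/.*$", "", x)
  a2 <- sub("^.*/", "", x)
  bad <- is.na(x) | !grepl("/", x) | a1 == "." | a2 == "."
  code <- ifelse(bad, NA_integer_, (a1 != "0") + (a2 != "0"))
  codes <- t(matrix(as.integer(code), nrow(gt), ncol(gt)))  # samples x loci
  genotype_matrix(codes, ids = colnames(gt), locus_ids = ids)
}

read_genotypes_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(c("FID", "IID") %in% names(tab))) {
    stop("not a PLINK .raw file (FID/IID header missing): ", path, call. = FALSE)
  }
  snp_cols <- setdiff(names(tab), meta)
  codes <- as.matrix(tab[, snp_cols, drop = FALSE])
  storage.mode(codes) <- "integer"
  genotype_matrix(codes, ids = as.character(tab$IID),
                  locus_ids = sub("_[ACGT0-9]+$", "", snp_cols))
}

read_genotypes_csv <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  codes <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  genotype_matrix(codes, ids = as.character(tab[[1]]),
                  locus_ids = colnames(tab)[-1])
}

#' Write a genotype matrix as CSV
#'
#' Inverse of [read_genotypes()] with `format = "csv"`: rows = individuals,
#' first column `id`, missing calls as empty cells.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  g <- assert_genotypes(g)
  df <- data.frame(id = rownames(g), unclass(g), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' QC a genotype panel and report what was dropped
#'
#' Applies the call-rate and minor-allele-frequency filters (inclusive
#' thresholds, in that order of accounting) and returns the filtered panel
#' together with a machine-readable report of loci dropped per filter.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,callrate_min inclusive thresholds.
#' @return List with `genotypes` (filtered) and `report` (list: loci in/out,
#'   counts dropped per filter, thresholds).
#' @export
qc_genotypes <- function(g, maf_min = 0.05, callrate_min = 0.97) {
  g <- assert_genotypes(g)
  stats <- locus_stats(g)
  fail_invalid <- !stats$valid
  fail_callrate <- stats$valid & stats$call_rate < callrate_min
  fail_maf <- stats$valid & stats$call_rate >= callrate_min & stats$maf < maf_min
  out <- filter_loci(g, stats, maf_min = maf_min, callrate_min = callrate_min)
  report <- list(
    loci_in = ncol(g), loci_out = ncol(out),
    dropped_no_calls = sum(fail_invalid),
    dropped_callrate = sum(fail_callrate),
    dropped_maf = sum(fail_maf),
    maf_min = maf_min, callrate_min = callrate_min
  )
  list(genotypes = out, report = report)
}

#' Read a phenotype/covariate table
#'
#' Reads a CSV with a header and an id column; errors on duplicate ids, and
#' reports ids without genotypes when `genotype_ids` is supplied. Per-trait
#' missingness is handled downstream: an individual with a missing cell is
#' excluded from that trait's fit only.
#'
#' @param path CSV path.
#' @param id_col id column name.
#' @param genotype_ids optional character vector to check ids against.
#' @return A tibble.
#' @export
read_phenotypes <- function(path, id_col = "id", genotype_ids = NULL) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!id_col %in% names(tab)) {
    stop("phenotype file lacks id column '", id_col, "'", call. = FALSE)
  }
  if (anyDuplicated(tab[[id_col]])) {
    stop("duplicate ids in phenotype file", call. = FALSE)
  }
  if (!is.null(genotype_ids)) {
    orphan <- setdiff(tab[[id_col]], genotype_ids)
    if (length(orphan)) {
      warning(sprintf("%d phenotyped id(s) have no genotype and are excluded: %s%s",
                      length(orphan), paste(utils::head(orphan, 3), collapse = ", "),
                      if (length(orphan) > 3) ", ..." else ""), call. = FALSE)
      tab <- tab[tab[[id_col]] %in% genotype_ids, , drop = FALSE]
    }
  }
  tibble::as_tibble(tab)
}

#' Write / read relationship matrices
#'
#' `write_grm()` stores a kernel either as plain CSV or as the GCTA binary
#' triple: `<prefix>.grm.bin` (single-precision lower triangle, row by row),
#' `<prefix>.grm.N.bin` (per-pair SNP counts, single precision) and
#' `<prefix>.grm.id` (tab-separated FID/IID). A sidecar `<prefix>.json`
#' records the component and approach. `read_grm()` reads either format back.
#'
#' @param v a `gv_kernel` (or plain symmetric matrix with dimnames).
#' @param prefix output prefix (CSV: `<prefix>.csv`).
#' @param format `"gcta"` or `"csv"`.
#' @param n_snps SNP count recorded in `.grm.N.bin`.
#' @return The prefix, invisibly (`write_grm`); a `gv_kernel` (`read_grm`).
#' @export
write_grm <- function(v, prefix, format = c("gcta", "csv"), n_snps = 1L) {
  format <- match.arg(format)
  vm <- as.matrix(v)
  if (any(!is.finite(vm))) stop("relationship matrix has non-finite entries", call. = FALSE)
  ids <- rownames(vm) %||% paste0("ind_", seq_len(nrow(vm)))
  meta <- list(component = attr(v, "component") %||% "additive",
               approach = attr(v, "approach") %||% "noia",
               scale_denominator = attr(v, "scale_denominator") %||% 1,
               n = nrow(vm))
  if (format == "csv") {
    utils::write.csv(data.frame(id = ids, vm, check.names = FALSE),
                     paste0(prefix, ".csv"), row.names = FALSE)
  } else {
    lower <- vm[lower.tri(vm, diag = TRUE)]
    # GCTA order: for i in 1..n, j in 1..i — column-major lower.tri is j-major
    idx <- which(lower.tri(matrix(0, nrow(vm), nrow(vm)), diag = TRUE), arr.ind = TRUE)
    ord <- order(idx[, "row"], idx[, "col"])
    con <- file(paste0(prefix, ".grm.bin"), "wb")
    writeBin(as.numeric(lower[ord]), con, size = 4L)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(rep(as.numeric(n_snps), length(lower)), con, size = 4L)
    close(con)
    utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE,
                       sep = "\t")
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix, format = c("gcta", "csv")) {
  format <- match.arg(format)
  meta_path <- paste0(prefix, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (format == "csv") {
    tab <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
    vm <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(vm) <- list(tab[[1]], tab[[1]])
  } else {
    ids <- utils::read.table(paste0(prefix, ".grm.id"),
                             stringsAsFactors = FALSE)[[2]]
    n <- length(ids)
    con <- file(paste0(prefix, ".grm.bin"), "rb")
    lower <- readBin(con, numeric(), n * (n + 1) / 2, size = 4L)
    close(con)
    vm <- matrix(0, n, n, dimnames = list(ids, ids))
    k <- 1L
    for (i in seq_len(n)) {
      vm[i, 1:i] <- lower[k:(k + i - 1L)]
      k <- k + i
    }
    vm <- vm + t(vm) - diag(diag(vm))
  }
  new_kernel(vm,
             component = meta$component %||% "additive",
             approach = meta$approach %||% "noia",
             scale_denominator = meta$scale_denominator %||% 1)
}

#' Run manifest for bit-identical re-runs
#'
#' Collects everything needed to reproduce a pipeline run: input paths with
#' MD5 checksums, the master seed, QC thresholds, kernel approach, model
#' codes, package version and a timestamp. `write_manifest()` serializes it
#' to JSON.
#'
#' @param inputs character vector of input file paths.
#' @param seed master seed.
#' @param maf_min,callrate_min QC thresholds.
#' @param approach kernel approach used.
#' @param models model codes fitted.
#' @return A `gv_manifest` list.
#' @export
run_manifest <- function(inputs = character(), seed = NA_integer_,
                         maf_min = 0.05, callrate_min = 0.97,
                         approach = "noia", models = suite_codes) {
  structure(list(
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    seed = seed, maf_min = maf_min, callrate_min = callrate_min,
    approach = approach, models = models,
    package_version = as.character(utils::packageVersion("gvcomp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "gv_manifest")
}

#' @rdname run_manifest
#' @param manifest a `gv_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
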