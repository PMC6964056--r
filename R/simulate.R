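#' Configuration for the mating-design simulator
#'
#' Defaults describe the desk-scale study the package is designed around: two
#' founder groups crossed reciprocally in a partial-factorial design (every
#' sire and dam contributes to at least two full-sib families, so offspring
#' have both full- and half-sibs), unbalanced family sizes, ~2000 biallelic
#' SNPs, and a trait with additive, (directional) dominance,
#' additive-by-additive epistatic, maternal and residual variance plus
#' reciprocal-cross/batch/day/filleter fixed effects.
#'
#' Default true components `(sigma2_a, sigma2_d, sigma2_eaa, sigma2_m,
#' sigma2_e) = (0.10, 0.01, 0.15, 0.09, 0.65)` put the variance ratios at
#' `h2 = 0.10`, `m2 = 0.09`, `e2_aa = 0.15` with near-zero dominance
#' variance, and `delta = 6.5` with intercept 10 makes the relative
#' inbreeding depression `b_R` approximately 1 — the infinitesimal-dominance
#' regime (depression without dominance variance).
#'
#' @param n_sires_a,n_dams_a,n_sires_b,n_dams_b founder counts per group.
#' @param matings_per_parent full-sib families each sire enters (>= 2 for the
#'   partial factorial).
#' @param offspring_mean,offspring_dispersion mean and negative-binomial size
#'   of family sizes (truncated at 1).
#' @param m_loci number of biallelic SNPs.
#' @param beta_a,beta_b `c(shape1, shape2)` of the Beta law each group's
#'   per-locus allele frequencies are drawn from (independently per group).
#' @param sigma2_a,sigma2_d,sigma2_eaa,sigma2_m,sigma2_e true variance
#'   components (trait units squared).
#' @param delta directional-dominance depression: expected trait decline per
#'   unit increase in individual homozygosity (trait units, >= 0).
#' @param n_epistatic_pairs locus pairs carrying additive-by-additive effects.
#' @param intercept trait intercept (trait units).
#' @param cross_effects,batch_effects,day_effects,filleter_effects fixed-effect
#'   values per level (first level is the reference).
#' @param missing_genotype_rate fraction of genotype calls set missing.
#' @param trait_name name of the trait column in the phenotype table.
#' @param seed integer seed; all randomness in the simulation flows from it.
#' @return A `gv_sim_config` list.
#' @export
sim_config <- function(n_sires_a = 20, n_dams_a = 20,
                       n_sires_b = 20, n_dams_b = 20,
                       matings_per_parent = 2,
                       offspring_mean = 15, offspring_dispersion = 2,
                       m_loci = 2000,
                       beta_a = c(3, 3), beta_b = c(3, 3),
                       sigma2_a = 0.10, sigma2_d = 0.01, sigma2_eaa = 0.15,
                       sigma2_m = 0.09, sigma2_e = 0.65,
                       delta = 6.5, n_epistatic_pairs = 500,
                       intercept = 10,
                       cross_effects = c(0, 0.25),
                       batch_effects = c(0, 0.30, -0.20),
                       day_effects = seq(-0.35, 0.35, length.out = 8),
                       filleter_effects = c(0, 0.15, -0.15),
                       missing_genotype_rate = 0.004,
                       trait_name = "trait",
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_sires_a, n_dams_a, n_sires_b, n_dams_b, matings_per_parent,
              m_loci, n_epistatic_pairs)
  if (any(counts < 1)) stop("all design counts must be >= 1", call. = FALSE)
  if (any(c(sigma2_a, sigma2_d, sigma2_eaa, sigma2_m, sigma2_e) < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (delta < 0) stop("delta must be >= 0 (depression)", call. = FALSE)
  if (any(c(beta_a, beta_b) <= 0)) stop("degenerate Beta parameters", call. = FALSE)
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1) {
    stop("missing_genotype_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "gv_sim_config")
}

#' Simulate founder haplotypes for two parental groups
#'
#' Draws per-locus allele frequencies independently for groups A and B from
#' the configured Beta laws, then founder haplotypes Bernoulli per allele.
#' Independent per-group frequency draws create divergent groups, so the
#' crossbred offspring genuinely depart from Hardy-Weinberg proportions (an
#' excess of heterozygotes) — the condition under which the NOIA and HWE
#' kernels differ.
#'
#' @param config a [sim_config()].
#' @return List with `table` (id, group, sex), haplotype matrices `hap1`,
#'   `hap2` (founders x loci, allele counts 0/1) and `group_freq` (loci x 2).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "gv_sim_config"))
  m <- config$m_loci
  freq <- cbind(
    A = stats::rbeta(m, config$beta_a[1], config$beta_a[2]),
    B = stats::rbeta(m, config$beta_b[1], config$beta_b[2])
  )
  tab <- tibble::tibble(
    id = c(sprintf("A_S%02d", seq_len(config$n_sires_a)),
           sprintf("A_D%02d", seq_len(config$n_dams_a)),
           sprintf("B_S%02d", seq_len(config$n_sires_b)),
           sprintf("B_D%02d", seq_len(config$n_dams_b))),
    group = rep(c("A", "B"),
                c(config$n_sires_a + config$n_dams_a,
                  config$n_sires_b + config$n_dams_b)),
    sex = c(rep(c("M", "F"), c(config$n_sires_a, config$n_dams_a)),
            rep(c("M", "F"), c(config$n_sires_b, config$n_dams_b)))
  )
  nf <- nrow(tab)
  pmat <- t(freq[, ifelse(tab$group == "A", 1L, 2L)])  # founders x loci
  hap1 <- matrix(stats::rbinom(nf * m, 1L, pmat), nf, m)
  hap2 <- matrix(stats::rbinom(nf * m, 1L, pmat), nf, m)
  rownames(hap1) <- rownames(hap2) <- tab$id
  list(table = tab, hap1 = hap1, hap2 = hap2, group_freq = freq)
}

# chain partial factorial for one cross direction
chain_pairs <- function(sires, dams, r) {
  s <- length(sires); d <- length(dams)
  if (s * r < 2 * d || r < 2) {
    stop("infeasible partial-factorial connectivity: each parent needs >= 2 families",
         call. = FALSE)
  }
  do.call(rbind, lapply(seq_len(s), function(i) {
    data.frame(sire = sires[i], dam = dams[((i - 1 + seq_len(r) - 1) %% d) + 1])
  }))
}

#' Mate founders and gene-drop offspring genotypes
#'
#' Builds the reciprocal partial-factorial design (group-A sires x group-B
#' dams and vice versa; each sire mates `matings_per_parent` dams in a chain,
#' so every parent appears in at least two full-sib families), draws family
#' sizes from a truncated negative binomial, and generates each offspring
#' genotype by Mendelian sampling of one parental allele per locus
#' (independent loci).
#'
#' @param founders output of [simulate_founders()].
#' @param config a [sim_config()].
#' @return List with `pedigree` (id, sire, dam, family, cross) covering
#'   founders and offspring, and `genotypes` (complete [genotype_matrix()] of
#'   founders + offspring).
#' @export
mate_and_drop <- function(founders, config) {
  tab <- founders$table
  pick <- function(g, s) tab$id[tab$group == g & tab$sex == s]
  pairs <- rbind(
    cbind(chain_pairs(pick("A", "M"), pick("B", "F"), config$matings_per_parent),
          cross = "AxB"),
    cbind(chain_pairs(pick("B", "M"), pick("A", "F"), config$matings_per_parent),
          cross = "BxA")
  )
  nfam <- nrow(pairs)
  sizes <- integer(nfam)
  todo <- seq_len(nfam)
  while (length(todo)) { # negative binomial truncated at >= 1
    sizes[todo] <- stats::rnbinom(length(todo), size = config$offspring_dispersion,
                                  mu = config$offspring_mean)
    todo <- which(sizes < 1L)
  }
  m <- config$m_loci
  n_off <- sum(sizes)
  geno_off <- matrix(0L, n_off, m)
  off_ids <- sprintf("O%05d", seq_len(n_off))
  ped_rows <- vector("list", nfam)
  row0 <- 0L
  for (f in seq_len(nfam)) {
    ns <- sizes[f]
    idx <- row0 + seq_len(ns)
    s <- pairs$sire[f]; d <- pairs$dam[f]
    for (par in c(s, d)) {
      h1 <- matrix(founders$hap1[par, ], ns, m, byrow = TRUE)
      h2 <- matrix(founders$hap2[par, ], ns, m, byrow = TRUE)
      take2 <- matrix(stats::runif(ns * m) < 0.5, ns, m)
      h1[take2] <- h2[take2]
      geno_off[idx, ] <- geno_off[idx, , drop = FALSE] + h1
    }
    ped_rows[[f]] <- tibble::tibble(
      id = off_ids[idx], sire = s, dam = d,
      family = sprintf("F%03d", f), cross = pairs$cross[f]
    )
    row0 <- row0 + ns
  }
  rownames(geno_off) <- off_ids
  geno_founders <- founders$hap1 + founders$hap2
  locus_ids <- sprintf("snp_%04d", seq_len(m))
  codes <- rbind(geno_founders, geno_off)
  colnames(codes) <- locus_ids
  pedigree <- dplyr::bind_rows(
    tibble::tibble(id = tab$id, sire = NA_character_, dam = NA_character_,
                   family = NA_character_, cross = NA_character_),
    dplyr::bind_rows(ped_rows)
  )
  list(pedigree = pedigree, genotypes = genotype_matrix(codes))
}

rescale_to <- function(u, target, what) {
  if (target == 0) return(rep(0, length(u)))
  v <- stats::var(u)
  if (!is.finite(v) || v == 0) {
    stop("requested ", what, " variance unachievable: simulated effect has zero variance",
         call. = FALSE)
  }
  u * sqrt(target / v)
}

#' Simulate phenotypes on a gene-dropped population
#'
#' Builds the trait for the offspring generation. Additive, dominance and
#' additive-by-additive effect vectors are constructed in the NOIA contrast
#' basis of the offspring sample (per-locus effects, locus-pair products for
#' epistasis) and rescaled so their realized variances equal the configured
#' components exactly; one maternal effect per dam and the residual are drawn
#' normal and rescaled likewise. Directional dominance enters as a mean
#' decline of `delta` trait units per unit individual homozygosity (a common
#' positive dominance effect across heterozygous loci), producing inbreeding
#' depression while leaving dominance variance at its small configured value.
#' Fixed effects (reciprocal cross, batch, day, filleter) are assigned and
#' added.
#'
#' @param dropped output of [mate_and_drop()].
#' @param config a [sim_config()].
#' @return List with `phenotypes` (tibble: id, sire, dam, family, cross,
#'   batch, day, filleter, homozygosity, trait) and `truth` (realized effect
#'   vectors, their variances, and the config).
#' @export
simulate_phenotypes <- function(dropped, config) {
  ped_off <- dropped$pedigree[!is.na(dropped$pedigree$sire), ]
  g_off <- genotype_matrix(unclass(dropped$genotypes)[ped_off$id, , drop = FALSE])
  n <- nrow(g_off)
  stats <- locus_stats(g_off)
  ha <- unclass(additive_contrasts(g_off, stats))
  hd <- unclass(suppressWarnings(dominance_contrasts(g_off, stats, "noia")))

  u_a <- rescale_to(drop(ha %*% stats::rnorm(ncol(ha))), config$sigma2_a, "additive")
  u_d <- rescale_to(drop(hd %*% stats::rnorm(ncol(hd))), config$sigma2_d, "dominance")

  poly <- which(stats$maf > 0)
  if (length(poly) < 2 && config$sigma2_eaa > 0) {
    stop("requested epistatic variance unachievable: fewer than 2 polymorphic loci",
         call. = FALSE)
  }
  npairs <- min(config$n_epistatic_pairs, choose(length(poly), 2))
  j1 <- sample(poly, npairs, replace = TRUE)
  j2 <- vapply(j1, function(j) sample(setdiff(poly, j), 1L), integer(1))
  u_e <- rescale_to(drop((ha[, j1] * ha[, j2]) %*% stats::rnorm(npairs)),
                    config$sigma2_eaa, "epistatic")

  dams <- unique(ped_off$dam)
  m_eff <- stats::setNames(rescale_to(stats::rnorm(length(dams)), config$sigma2_m,
                                      "maternal"), dams)
  u_m <- m_eff[ped_off$dam]
  e <- rescale_to(stats::rnorm(n), config$sigma2_e, "residual")
  hom <- individual_homozygosity(g_off)

  batch <- sample(seq_along(config$batch_effects), n, replace = TRUE)
  day <- sample(seq_along(config$day_effects), n, replace = TRUE)
  filleter <- sample(seq_along(config$filleter_effects), n, replace = TRUE)
  cross_i <- ifelse(ped_off$cross == "AxB", 1L, 2L)
  fixed_part <- config$cross_effects[cross_i] + config$batch_effects[batch] +
    config$day_effects[day] + config$filleter_effects[filleter]

  y <- config$intercept + fixed_part - config$delta * hom +
    u_a + u_d + u_e + u_m + e

  phen <- tibble::tibble(
    id = ped_off$id, sire = ped_off$sire, dam = ped_off$dam,
    family = ped_off$family, cross = factor(ped_off$cross),
    batch = factor(paste0("b", batch)), day = factor(paste0("d", day)),
    filleter = factor(paste0("f", filleter)),
    homozygosity = hom
  )
  phen[[config$trait_name]] <- y

  truth <- list(
    additive = u_a, dominance = u_d, epistatic_aa = u_e,
    maternal = stats::setNames(as.numeric(m_eff), dams),
    residual = e, homozygosity = hom,
    components = c(additive = stats::var(u_a), dominance = stats::var(u_d),
                   epistatic_aa = stats::var(u_e),
                   maternal = stats::var(as.numeric(m_eff)),
                   residual = stats::var(e)),
    delta = config$delta, config = config
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_founders()], [mate_and_drop()] and [simulate_phenotypes()]
#' under a single seed, then masks genotype calls at the configured missing
#' rate. The result carries everything the analysis pipeline consumes plus
#' the simulation truth for recovery tests.
#'
#' @param config a [sim_config()].
#' @return A `gv_sim` list: `genotypes` (founders + offspring, with missing
#'   calls), `pedigree`, `phenotypes` (offspring), `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "gv_sim_config"))
  withr_seed(config$seed, {
    founders <- simulate_founders(config)
    dropped <- mate_and_drop(founders, config)
    sim <- simulate_phenotypes(dropped, config)
    geno <- unclass(dropped$genotypes)
    if (config$missing_genotype_rate > 0) {
      mask <- stats::runif(length(geno)) < config$missing_genotype_rate
      geno[mask] <- NA_integer_
    }
    structure(
      list(genotypes = genotype_matrix(geno), pedigree = dropped$pedigree,
           phenotypes = sim$phenotypes, truth = sim$truth),
      class = "gv_sim"
    )
  })
}

#' @export
print.gv_sim <- function(x, ...) {
  cat(sprintf(
    "<gv_sim> %d genotyped individuals (%d phenotyped offspring in %d families), %d loci\n",
    nrow(x$genotypes), nrow(x$phenotypes),
    length(unique(stats::na.omit(x$pedigree$family))), ncol(x$genotypes)))
  invisible(x)
}
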