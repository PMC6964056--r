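# Small genotype fixtures and independent oracles used across tests.

# the canonical 4-individual, exact-HWE single locus: codes 0,1,1,2
g_hwe1 <- function() genotype_matrix(matrix(c(0L, 1L, 1L, 2L), ncol = 1))

# random small genotype matrix (complete calls)
g_random <- function(n, m, seed) {
  set.seed(seed)
  genotype_matrix(matrix(sample(0:2, n * m, replace = TRUE), n, m))
}

# Brute-force kernel oracle: per-locus scalar summation, written independently
# of the matrix-algebra path in the package.
oracle_kernels <- function(codes, approach) {
  n <- nrow(codes); m <- ncol(codes)
  p <- p0 <- p1 <- p2 <- numeric(m)
  for (j in 1:m) {
    p0[j] <- mean(codes[, j] == 0)
    p1[j] <- mean(codes[, j] == 1)
    p2[j] <- mean(codes[, j] == 2)
    p[j] <- mean(codes[, j]) / 2
  }
  ha <- matrix(0, n, m); hd <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    x <- codes[i, j]
    ha[i, j] <- x - 2 * p[j]
    if (approach == "hwe") {
      q <- 1 - p[j]
      hd[i, j] <- if (x == 0) -2 * p[j]^2 else if (x == 1) 2 * p[j] * q else -2 * q^2
    } else {
      den <- p0[j] + p2[j] - (p0[j] - p2[j])^2
      if (den > 1e-12) {
        hd[i, j] <- if (x == 0) {
          -2 * p1[j] * p2[j] / den
        } else if (x == 1) {
          4 * p0[j] * p2[j] / den
        } else {
          -2 * p0[j] * p1[j] / den
        }
      }
    }
  }
  GG <- matrix(0, n, n); DD <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    GG[i, k] <- sum(ha[i, ] * ha[k, ])
    DD[i, k] <- sum(hd[i, ] * hd[k, ])
  }
  if (approach == "hwe") {
    G <- GG / (2 * sum(p * (1 - p)))
    D <- DD / (4 * sum(p^2 * (1 - p)^2))
    E <- G * G
  } else {
    G <- GG / (mean(diag(GG)))
    D <- DD / (mean(diag(DD)))
    E <- (G * G) / mean(diag(G * G))
  }
  list(G = G, D = D, E = E, ha = ha, hd = hd)
}

# balanced one-way data: g groups, r replicates, for the ANOVA REML oracle
oneway_data <- function(n_groups, r, sigma_g2, sigma_e2, seed) {
  set.seed(seed)
  grp <- rep(seq_len(n_groups), each = r)
  u <- rnorm(n_groups, 0, sqrt(sigma_g2))
  y <- 5 + u[grp] + rnorm(n_groups * r, 0, sqrt(sigma_e2))
  tibble::tibble(id = paste0("i", seq_along(y)), grp = factor(paste0("g", grp)), y = y)
}

# closed-form REML on balanced one-way data (equals ANOVA estimators)
anova_reml <- function(data, r) {
  means <- tapply(data$y, data$grp, mean)
  msb <- r * var(means)
  msw <- sum((data$y - means[data$grp])^2) / (nrow(data) - length(means))
  c(group = max((msb - msw) / r, 0), residual = msw)
}

# small simulated dataset for pipeline-level tests
small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(
    n_sires_a = 6, n_dams_a = 6, n_sires_b = 6, n_dams_b = 6,
    offspring_mean = 8, m_loci = 300, n_epistatic_pairs = 100,
    seed = seed, ...
  ))
}

# align offspring genotypes/phenotypes for fitting
sim_analysis_frame <- function(sim, impute_seed = 99) {
  g <- impute_missing(sim$genotypes, seed = impute_seed)
  g_off <- genotype_matrix(unclass(g)[sim$phenotypes$id, , drop = FALSE])
  ph <- sim$phenotypes
  ph$homozygosity <- individual_homozygosity(g_off)
  list(genotypes = g_off, phenotypes = ph)
}
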