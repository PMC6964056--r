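test_that("build_model translates codes into random-term sets", {
  sim <- small_sim(seed = 15)
  fr <- sim_analysis_frame(sim)
  kern <- suppressWarnings(suite_kernels(fr$genotypes, "noia", extended = TRUE))

  expect_equal(names(build_model("A", kern)$random), "additive")
  expect_equal(names(build_model("ADME", kern)$random),
               c("additive", "dominance", "epistatic_aa", "maternal"))
  expect_equal(names(build_model("AME", kern)$random),
               c("additive", "epistatic_aa", "maternal"))
  expect_equal(names(build_model("ADME+ad+dd", kern)$random),
               c("additive", "dominance", "epistatic_aa",
                 "epistatic_ad", "epistatic_dd", "maternal"))

  spec <- build_model("AM", kern, include_homozygosity = FALSE)
  expect_length(spec$covariates, 0)
  spec2 <- build_model("AM", kern)
  expect_equal(spec2$covariates, "homozygosity")

  expect_error(build_model("AX", kern), "valid codes")
  expect_error(build_model("ADME", kern["additive"]), "requires kernel")
})

test_that("mixture critical values reproduce the published values per d.f.", {
  printed <- rbind(
    c(2.71, 5.42, 9.55),   # 1 component
    c(4.24, 7.29, 11.77),  # 2 components
    c(5.44, 8.75, 13.48)   # 3 components
  )
  alphas <- c(0.05, 0.01, 0.001)
  t0 <- Sys.time()
  for (q in 1:3) {
    for (a in seq_along(alphas)) {
      expect_equal(mixture_critical_value(q, alphas[a]), printed[q, a],
                   tolerance = 0.005)
    }
  }
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_error(mixture_critical_value(1, 0), "alpha")
  expect_error(mixture_critical_value(1, 1), "alpha")
})

test_that("mixture p-values invert the critical values and decrease in the statistic", {
  expect_equal(mixture_pvalue(1, 0), 1)
  expect_equal(mixture_pvalue(1, 2.7055), 0.05, tolerance = 1e-3)
  for (q in 1:3) {
    crit <- mixture_critical_value(q, 0.01)
    expect_equal(mixture_pvalue(q, crit), 0.01, tolerance = 1e-9)
    stats <- seq(0.01, 15, length.out = 50)
    pv <- vapply(stats, function(s) mixture_pvalue(q, s), numeric(1))
    expect_true(all(diff(pv) < 0))
  }
  # tiny negative statistics clamp to zero
  expect_equal(mixture_pvalue(2, -1e-8), 1)
  expect_error(mixture_pvalue(2, -0.01), "negative")
})

test_that("variance ratios recompute the published worked examples", {
  # body-depth AME components (additive, epistatic_aa, maternal, residual)
  bd <- c(additive = 0.086, epistatic_aa = 0.080, maternal = 0.047,
          residual = 0.328)
  vr <- variance_ratios(bd, apply_legarra = FALSE)
  get <- function(tab, q) tab$estimate[tab$quantity == q]
  expect_equal(get(vr, "sigma2_P"), 0.541, tolerance = 1e-10)
  # ratios agree with the published values to their rounding
  expect_lt(abs(get(vr, "H2") - 0.307), 1e-3)
  expect_lt(abs(get(vr, "m2") - 0.087), 1e-3)
  expect_lt(abs(get(vr, "e2_aa") - 0.148), 1e-3)
  # epistatic share of total genetic variance: 48%
  expect_lt(abs(100 * get(vr, "e2_aa") / get(vr, "H2") - 48), 0.5)

  # body-weight-at-harvest AME components
  bwh <- c(additive = 699, epistatic_aa = 1183, maternal = 635, residual = 4540)
  vr2 <- variance_ratios(bwh, apply_legarra = FALSE)
  expect_lt(abs(get(vr2, "m2") - 0.090), 1e-3)
  expect_lt(abs(get(vr2, "e2_aa") - 0.167), 1e-3)
  expect_lt(abs(100 * get(vr2, "e2_aa") / get(vr2, "H2") - 63), 0.5)

  # equal components split the phenotypic variance equally
  eq <- c(additive = 1, maternal = 1, residual = 1)
  vr3 <- variance_ratios(eq, apply_legarra = FALSE)
  expect_equal(get(vr3, "h2"), 1 / 3, tolerance = 1e-12)
  expect_equal(get(vr3, "m2"), 1 / 3, tolerance = 1e-12)
})

test_that("full-sib excess variance uses weights (1/4, 1/8, 1/8, 1/8)", {
  expect_equal(fullsib_excess_variance(8, 8, 8, 8), 5)
  expect_equal(fullsib_excess_variance(4, 0, 0, 0), 1)
  expect_equal(fullsib_excess_variance(0, 0, 0, 0), 0)
  expect_error(fullsib_excess_variance(-1, 0, 0, 0), "non-negative")
})

test_that("suite LRTs are nonnegative, ADME tests itself at zero", {
  sim <- small_sim(seed = 18)
  fr <- sim_analysis_frame(sim)
  kern <- suppressWarnings(suite_kernels(fr$genotypes, "noia"))
  suite <- suppressMessages(
    fit_suite(fr$phenotypes, kern, fixed = c("cross", "batch"))
  )
  tab <- tidy(suite)
  expect_true(all(tab$lrt >= 0))
  adme <- tab[tab$model == "ADME", ]
  expect_equal(adme$lrt, 0, tolerance = 1e-6)
  expect_equal(adme$p_value, 1)
  expect_equal(adme$df, 0L)
  expect_equal(tab$df[tab$model == "A"], 3L)
  expect_equal(sort(tab$model[tab$df == 2L]), c("AD", "AE", "AM"))
  expect_s3_class(glance(suite), "tbl_df")
})

test_that("HWE and NOIA give identical logL for dominance-free models", {
  sim <- small_sim(seed = 20)
  fr <- sim_analysis_frame(sim)
  kn <- suppressWarnings(suite_kernels(fr$genotypes, "noia"))
  kh <- suppressWarnings(suite_kernels(fr$genotypes, "hwe"))
  for (code in c("A", "AM", "AE", "AME")) {
    fn <- suppressMessages(reml_fit(build_model(code, kn, fixed = "cross"),
                                    fr$phenotypes))
    fh <- suppressMessages(reml_fit(build_model(code, kh, fixed = "cross"),
                                    fr$phenotypes))
    expect_equal(fn$logl, fh$logl, tolerance = 1e-4)
  }
})

test_that("reference-population correction reconciles HWE and NOIA estimates", {
  sim <- small_sim(seed = 22)
  fr <- sim_analysis_frame(sim)
  kn <- suppressWarnings(suite_kernels(fr$genotypes, "noia"))
  kh <- suppressWarnings(suite_kernels(fr$genotypes, "hwe"))
  fn <- suppressMessages(reml_fit(build_model("AME", kn, fixed = "cross"),
                                  fr$phenotypes))
  fh <- suppressMessages(reml_fit(build_model("AME", kh, fixed = "cross"),
                                  fr$phenotypes))
  cn <- attr(variance_ratios(fn), "corrected_components")
  ch <- attr(variance_ratios(fh), "corrected_components")
  nonzero <- cn > 1e-8 & ch > 1e-8
  expect_true(any(nonzero))
  expect_equal(cn[nonzero], ch[nonzero], tolerance = 1e-3)
})

test_that("under a purely additive architecture the selector picks model A", {
  hits <- 0L
  for (r in 1:20) {
    sim <- small_sim(seed = 300 + r, sigma2_a = 3, sigma2_d = 0,
                     sigma2_eaa = 0, sigma2_m = 0, sigma2_e = 7, delta = 0)
    fr <- sim_analysis_frame(sim)
    kern <- suppressWarnings(suite_kernels(fr$genotypes, "noia"))
    suite <- suppressMessages(suppressWarnings(
      fit_suite(fr$phenotypes, kern, fixed = c("cross", "batch"))
    ))
    if (suite$best_model == "A") hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("a strong maternal effect is detected against the additive model", {
  hits <- 0L
  for (r in 1:20) {
    # n about 600 with 48 dams, as the power experiment requires
    sim <- simulate_dataset(sim_config(
      n_sires_a = 12, n_dams_a = 12, n_sires_b = 12, n_dams_b = 12,
      offspring_mean = 13, m_loci = 300, n_epistatic_pairs = 100,
      sigma2_a = 0.2, sigma2_d = 0, sigma2_eaa = 0, sigma2_m = 0.2,
      sigma2_e = 0.6, seed = 500 + r))
    fr <- sim_analysis_frame(sim)
    s <- locus_stats(fr$genotypes)
    G <- build_grm(additive_contrasts(fr$genotypes, s), s, "noia")
    kern <- list(additive = G)
    fa <- suppressMessages(reml_fit(build_model("A", kern, fixed = "cross"),
                                    fr$phenotypes))
    fm <- suppressMessages(reml_fit(build_model("AM", kern, fixed = "cross"),
                                    fr$phenotypes))
    lrt <- max(2 * (fm$logl - fa$logl), 0)
    if (lrt > mixture_critical_value(1, 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})
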