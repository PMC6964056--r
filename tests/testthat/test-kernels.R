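test_that("additive contrasts are centred dosages, flipping negates them", {
  g <- g_hwe1()
  ha <- additive_contrasts(g)
  expect_equal(as.numeric(ha), c(-1, 0, 0, 1))

  g2 <- g_random(12, 5, seed = 21)
  ha2 <- additive_contrasts(g2)
  expect_equal(colSums(unclass(ha2)), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  flipped <- genotype_matrix(2L - unclass(g2))
  expect_equal(unclass(additive_contrasts(flipped)), -unclass(ha2),
               ignore_attr = TRUE)
})

test_that("dominance contrasts: NOIA equals HWE on an exact-HWE sample", {
  g <- g_hwe1() # genotype counts 1:2:1 at p = 0.5, exactly HWE
  hn <- dominance_contrasts(g, approach = "noia")
  hh <- dominance_contrasts(g, approach = "hwe")
  expect_equal(as.numeric(hn), c(-0.5, 0.5, 0.5, -0.5))
  expect_equal(as.numeric(hh), as.numeric(hn), tolerance = 1e-12)
})

test_that("NOIA dominance column vanishes without heterozygotes", {
  g <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L), ncol = 1))
  hd <- dominance_contrasts(g, approach = "noia")
  expect_equal(as.numeric(hd), rep(0, 4))
})

test_that("NOIA dominance contrasts are orthogonal to additive contrasts", {
  for (seed in 1:5) {
    g <- g_random(20, 6, seed = seed)
    ha <- unclass(additive_contrasts(g))
    hd <- unclass(suppressWarnings(dominance_contrasts(g, approach = "noia")))
    expect_lt(max(abs(colSums(ha * hd))), 1e-9)
    expect_lt(max(abs(colSums(hd))), 1e-9) # columns centred too
  }
})

test_that("build_grm matches hand computation and forces unit trace mean", {
  g <- g_hwe1()
  s <- locus_stats(g)
  G_noia <- build_grm(additive_contrasts(g, s), s, "noia")
  expect_equal(diag(G_noia), c(2, 0, 0, 2), ignore_attr = TRUE)
  expect_equal(G_noia[1, 4], -2)
  G_hwe <- build_grm(additive_contrasts(g, s), s, "hwe")
  expect_equal(unclass(G_hwe), unclass(G_noia), ignore_attr = TRUE)

  # no heterozygotes: tr/n = 1 vs 2*sum(pq) = 0.5
  g2 <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L), ncol = 1))
  s2 <- locus_stats(g2)
  Gn <- build_grm(additive_contrasts(g2, s2), s2, "noia")
  Gh <- build_grm(additive_contrasts(g2, s2), s2, "hwe")
  expect_equal(diag(Gn), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(Gh), rep(2, 4), ignore_attr = TRUE)
  expect_equal(unclass(Gh), 2 * unclass(Gn), ignore_attr = TRUE)

  for (seed in 6:8) {
    g3 <- g_random(15, 8, seed = seed)
    s3 <- locus_stats(g3)
    G3 <- build_grm(additive_contrasts(g3, s3), s3, "noia")
    expect_equal(mean(diag(G3)), 1, tolerance = 1e-12)
  }
})

test_that("build_drm scalings and NOIA structural zeros", {
  g <- g_hwe1()
  s <- locus_stats(g)
  D <- build_drm(dominance_contrasts(g, s, "noia"), s, "noia")
  expect_equal(diag(D), rep(1, 4), ignore_attr = TRUE)
  # like contrasts attract, unlike repel
  expect_equal(D[2, 3], 1)
  expect_equal(D[1, 2], -1)
  expect_equal(sum(D), 0, tolerance = 1e-8)

  g2 <- g_random(18, 7, seed = 31)
  s2 <- locus_stats(g2)
  D2 <- build_drm(suppressWarnings(dominance_contrasts(g2, s2, "noia")), s2, "noia")
  expect_equal(mean(diag(D2)), 1, tolerance = 1e-12)
  expect_equal(sum(D2), 0, tolerance = 1e-8)
})

test_that("monomorphic panel gives an error, not a kernel", {
  g <- genotype_matrix(matrix(2L, 4, 3))
  s <- locus_stats(g)
  expect_error(build_grm(additive_contrasts(g, s), s, "hwe"), "monomorphic")
})

test_that("epistatic kernels are scaled Hadamard products", {
  G <- new_kernel(matrix(c(1, 0.5, 0.5, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  "additive", "noia")
  E <- build_epistatic(G, G)
  expect_equal(unclass(E), matrix(c(1, 0.25, 0.25, 1), 2), ignore_attr = TRUE)
  expect_equal(attr(E, "component"), "epistatic_aa")

  # NOIA rescaling removes any scalar on the inputs
  cG <- new_kernel(3 * unclass(G), "additive", "noia")
  expect_equal(unclass(build_epistatic(cG, cG)), unclass(E), ignore_attr = TRUE)

  # identity in, identity out under both approaches
  I4 <- new_kernel(diag(4), "additive", "noia")
  expect_equal(unclass(build_epistatic(I4, I4)), diag(4), ignore_attr = TRUE)
  I4h <- new_kernel(diag(4), "additive", "hwe")
  expect_equal(unclass(build_epistatic(I4h, I4h)), diag(4), ignore_attr = TRUE)

  D <- new_kernel(diag(2), "dominance", "noia")
  expect_equal(attr(build_epistatic(G, D), "component"), "epistatic_ad")
  expect_equal(attr(build_epistatic(D, D), "component"), "epistatic_dd")
  expect_error(build_epistatic(G, new_kernel(diag(3), "additive", "noia")),
               "dimension")
})

test_that("legarra factor is mean(diag) minus grand mean", {
  expect_equal(legarra_factor(diag(c(2, 2))), 1)
  expect_equal(legarra_factor(diag(3)), 2 / 3)
  # NOIA G from sample frequencies: trace mean 1 and grand sum 0, so factor 1
  for (seed in 11:13) {
    g <- g_random(20, 10, seed = seed)
    s <- locus_stats(g)
    G <- build_grm(additive_contrasts(g, s), s, "noia")
    expect_equal(legarra_factor(G), 1, tolerance = 1e-8)
  }
})

test_that("kernel entries match the brute-force per-locus oracle", {
  cases <- expand.grid(n = c(4, 6), m = c(2, 4), seed = c(101, 202))
  for (i in seq_len(nrow(cases))) {
    g <- g_random(cases$n[i], cases$m[i], seed = cases$seed[i])
    s <- locus_stats(g)
    if (any(s$maf == 0)) next # oracle HWE dominance divisor may vanish
    for (app in c("noia", "hwe")) {
      o <- oracle_kernels(unclass(g), app)
      if (sum(o$hd^2) == 0) next # no dominance contrast anywhere in the panel
      G <- build_grm(additive_contrasts(g, s, app), s, app)
      D <- build_drm(suppressWarnings(dominance_contrasts(g, s, app)), s, app)
      E <- build_epistatic(G, G)
      expect_equal(unclass(G), o$G, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(unclass(D), o$D, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(unclass(E), o$E, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("kernels are symmetric PSD and allele-flip invariant", {
  for (seed in 41:43) {
    g <- g_random(12, 6, seed = seed)
    s <- locus_stats(g)
    # flip the counted allele at half the loci
    codes <- unclass(g)
    flip <- seq(1, ncol(codes), by = 2)
    codes[, flip] <- 2L - codes[, flip]
    gf <- genotype_matrix(codes)
    sf <- locus_stats(gf)
    for (app in c("noia", "hwe")) {
      G <- build_grm(additive_contrasts(g, s, app), s, app)
      Gf <- build_grm(additive_contrasts(gf, sf, app), sf, app)
      expect_equal(unclass(G), unclass(Gf), tolerance = 1e-10, ignore_attr = TRUE)
      D <- build_drm(suppressWarnings(dominance_contrasts(g, s, app)), s, app)
      Df <- build_drm(suppressWarnings(dominance_contrasts(gf, sf, app)), sf, app)
      expect_equal(unclass(D), unclass(Df), tolerance = 1e-10, ignore_attr = TRUE)
      for (K in list(G, D)) {
        expect_lt(max(abs(K - t(K))), 1e-10)
        expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                  -1e-8)
      }
    }
  }
})

test_that("G_HWE is a single positive scalar times G_NOIA", {
  g <- g_random(25, 12, seed = 55)
  s <- locus_stats(g)
  Gn <- build_grm(additive_contrasts(g, s), s, "noia")
  Gh <- build_grm(additive_contrasts(g, s), s, "hwe")
  ratio <- unclass(Gh) / unclass(Gn)
  ratio <- ratio[abs(unclass(Gn)) > 1e-10]
  expect_lt(diff(range(ratio)), 1e-10)
  expect_gt(ratio[1], 0)
})

test_that("D_NOIA equals D_HWE on an exact-HWE sample at every locus", {
  # counts 1:2:1 (p=0.5) and 4:4:1 (p=2/3) both satisfy p0=q^2, p1=2pq, p2=p^2
  col1 <- c(rep(0L, 9), rep(1L, 18), rep(2L, 9))
  col2 <- c(rep(0L, 16), rep(1L, 16), rep(2L, 4))
  g <- genotype_matrix(cbind(col1, c(col2, 0L, 0L)[1:36]))
  s <- locus_stats(g)
  # verify the fixture really is at exact HWE
  expect_equal(s$p1, 2 * s$p * (1 - s$p), tolerance = 1e-12)
  Dn <- build_drm(dominance_contrasts(g, s, "noia"), s, "noia")
  Dh <- build_drm(dominance_contrasts(g, s, "hwe"), s, "hwe")
  expect_equal(unclass(Dn), unclass(Dh), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pedigree numerator matrix: textbook relationships", {
  ped <- tibble::tibble(
    id = c("s", "d", "o1", "o2"),
    sire = c(NA, NA, "s", "s"),
    dam = c(NA, NA, "d", "d")
  )
  A <- pedigree_numerator(ped)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(diag(unclass(A)), rep(1, 4), ignore_attr = TRUE)

  ped2 <- tibble::tibble(
    id = c("s", "d1", "d2", "h1", "h2"),
    sire = c(NA, NA, NA, "s", "s"),
    dam = c(NA, NA, NA, "d1", "d2")
  )
  A2 <- pedigree_numerator(ped2)
  expect_equal(A2["h1", "h2"], 0.25)

  # offspring listed before parents still works (sorting), cycles error
  ped3 <- ped[c(3, 4, 1, 2), ]
  expect_equal(unclass(pedigree_numerator(ped3))[c("o1", "o2"), c("o1", "o2")],
               unclass(A)[c("o1", "o2"), c("o1", "o2")])
  cyc <- tibble::tibble(id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA))
  expect_error(pedigree_numerator(cyc), "cycle")
})

test_that("inbred pedigree raises the diagonal via parental kinship", {
  ped <- tibble::tibble(
    id = c("s", "d", "o1", "o2", "x"),
    sire = c(NA, NA, "s", "s", "o1"),
    dam = c(NA, NA, "d", "d", "o2")
  )
  A <- pedigree_numerator(ped)
  expect_equal(A["x", "x"], 1.25) # full-sib mating: F = 0.25
})
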