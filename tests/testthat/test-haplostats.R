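test_that("EHH matches brute-force pairwise identity on random panels", {
  set.seed(101)
  for (rep in 1:40) {
    n_hap <- sample(seq(4, 20, 2), 1)
    n_snp <- sample(10:50, 1)
    panel <- random_panel(n_hap, n_snp, seed = 1000 + rep)
    A <- panel$alleles
    core <- sample(2:(n_snp - 1), 1)
    for (al in 0:1) {
      if (sum(A[, core] == al) < 2) next
      curve <- ehh_curve(panel, core, al)
      # spot-check several distances on each side against brute force
      for (k in sample(seq_len(nrow(curve$right) - 1),
                       min(4, nrow(curve$right) - 1))) {
        expect_equal(curve$right$ehh[k + 1], brute_ehh(A, core, al, core + k))
      }
      for (k in sample(seq_len(nrow(curve$left) - 1),
                       min(4, nrow(curve$left) - 1))) {
        expect_equal(curve$left$ehh[k + 1], brute_ehh(A, core, al, core - k))
      }
    }
  }
})

test_that("EHH is 1 at the core and non-increasing with distance", {
  for (rep in 1:20) {
    panel <- random_panel(12, 40, seed = 2000 + rep)
    core <- 20L
    al <- if (sum(panel$alleles[, core] == 1L) >= 2) 1L else 0L
    curve <- ehh_curve(panel, core, al)
    expect_equal(curve$right$ehh[1], 1)
    expect_equal(curve$left$ehh[1], 1)
    expect_true(all(diff(curve$right$ehh) <= 1e-12))
    expect_true(all(diff(curve$left$ehh) <= 1e-12))
  }
  # identical carriers keep EHH at 1 over the chromosome
  A <- rbind(matrix(1L, 3, 10), matrix(0L, 3, 10))
  p <- tiny_panel(A)
  cv <- ehh_curve(p, 5, 1)
  expect_true(all(cv$right$ehh == 1))
  expect_true(all(cv$left$ehh == 1))
})

test_that("three carriers splitting 2-1 give EHH 1/3", {
  # carriers of allele 1 at core extend one site with alleles {0, 0, 1}
  A <- matrix(c(
    1, 0,
    1, 0,
    1, 1,
    0, 0), nrow = 4, byrow = TRUE)
  p <- tiny_panel(A)
  cv <- ehh_curve(p, 1, 1)
  expect_equal(cv$right$ehh[2], 1 / 3)
})

test_that("iHH integrates the decay curve to the cutoff crossing", {
  # four carriers whose identity splits 2-2 one marker to the right
  A <- matrix(c(
    0, 1, 0,
    1, 1, 0,
    0, 1, 1,
    1, 1, 1), nrow = 4, byrow = TRUE)
  p <- tiny_panel(A, spacing = 10000L)  # 0.01 cM between markers
  curve <- ehh_curve(p, 2, 1)
  expect_equal(curve$right$ehh, c(1, 1 / 3))
  # two carriers that differ immediately on both sides: EHH 1 -> 0 over
  # 0.01 cM per side; cutoff crossing at 0.0095 cM, hand trapezoid
  A3 <- matrix(c(
    0, 1, 1,
    1, 1, 0), nrow = 2, byrow = TRUE)
  p3 <- tiny_panel(A3, spacing = 10000L)
  res3 <- ihh(p3, core = 2, allele = 1, decay_cutoff = 0.05)
  side <- 0.0095 * (1 + 0.05) / 2
  expect_equal(res3$ihh, 2 * side, tolerance = 1e-12)
  expect_true(res3$valid)
})

test_that("iHH is linear in the genetic-map scale and flags non-decay", {
  panel <- random_panel(10, 60, seed = 31)
  core <- 30L
  al <- if (sum(panel$alleles[, core] == 1L) >= 2) 1L else 0L
  a <- ihh(panel, core, al, cm_per_mb = 1)
  b <- ihh(panel, core, al, cm_per_mb = 2)
  expect_equal(b$ihh, 2 * a$ihh, tolerance = 1e-9)
  # identical carriers never decay -> invalid at chromosome end
  A <- rbind(matrix(1L, 3, 10), matrix(0L, 3, 10))
  res <- ihh(tiny_panel(A), 5, 1)
  expect_false(res$valid)
})

test_that("iHH is invariant under haplotype order permutation", {
  set.seed(77)
  panel <- random_panel(14, 50, seed = 78)
  core <- 25L
  al <- if (sum(panel$alleles[, core] == 1L) >= 2) 1L else 0L
  ref <- ihh(panel, core, al)
  for (rep in 1:5) {
    perm <- panel
    ord <- sample(nrow(panel$alleles))
    perm$alleles <- panel$alleles[ord, ]
    expect_equal(ihh(perm, core, al)$ihh, ref$ihh)
  }
})

test_that("iHS standardization gives mean 0 / SD 1 within frequency bins", {
  cfg <- sim_config(n_ind_per_pop = 40, n_snps = 300, chrom_length = 3e6,
                    seed = 51)
  panel <- sim_mosaic_haplotypes(cfg)
  sc <- ihs_scan(panel, n_freq_bins = 10)
  expect_true(all(is.finite(sc$ihs_std[sc$valid])))
  bins <- cut(sc$freq_derived, seq(0, 1, length.out = 11),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- which(sc$valid & bins == b & !is.na(sc$ihs_unstd))
    if (length(i) < 3) next
    if (sd(sc$ihs_unstd[i]) == 0) next
    expect_equal(mean(sc$ihs_std[i]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$ihs_std[i]), 1, tolerance = 1e-9)
  }
  # equal integrals give unstandardized zero
  i0 <- which(abs(sc$ihh_anc - sc$ihh_der) < 1e-12 & sc$valid)
  if (length(i0) > 0) expect_true(all(abs(sc$ihs_unstd[i0]) < 1e-12))
})

test_that("XP-EHH is zero against an identical panel and antisymmetric", {
  cfg <- sim_config(n_ind_per_pop = 25, n_snps = 150, chrom_length = 1.5e6,
                    seed = 61)
  a <- sim_mosaic_haplotypes(cfg)
  same <- xpehh_scan(a, a)
  expect_true(all(abs(same$xpehh_unstd[same$valid]) < 1e-12))
  cfg2 <- sim_config(n_ind_per_pop = 25, n_snps = 150, chrom_length = 1.5e6,
                     seed = 62)
  b <- sim_mosaic_haplotypes(cfg2, positions = a$positions)
  ab <- xpehh_scan(a, b)
  ba <- xpehh_scan(b, a)
  expect_equal(ab$xpehh_unstd, -ba$xpehh_unstd, tolerance = 1e-12)
  expect_equal(ab$valid, ba$valid)
})

test_that("subsample averaging with one bin equals the plain scan and is seeded", {
  cfg <- sim_config(n_ind_per_pop = 20, n_snps = 120, chrom_length = 1.2e6,
                    seed = 71)
  panel <- sim_mosaic_haplotypes(cfg)
  plain <- ihs_scan(panel)
  one <- subsample_average(panel, n_bins = 1, seed = 1)
  expect_equal(one$track$ihs_std_mean,
               ifelse(is.na(plain$ihs_std), NaN, plain$ihs_std),
               tolerance = 1e-12)
  two_a <- subsample_average(panel, n_bins = 2, seed = 5)
  two_b <- subsample_average(panel, n_bins = 2, seed = 5)
  expect_identical(two_a$group_tracks, two_b$group_tracks)
  expect_error(subsample_average(panel, n_bins = 15, seed = 1), "fewer")
})

test_that("group tracks from sample bins correlate on a larger panel", {
  cfg <- sim_config(n_ind_per_pop = 100, n_snps = 400, chrom_length = 4e6,
                    seed = 81,
                    sweep_specs = list(list(pop = 1, core_bp = 2e6,
                                            target_freq = 0.8,
                                            flank_bp = 2.5e5,
                                            taper_bp = 1e5)))
  fx <- sim_two_pop_fixture(cfg)
  res <- subsample_average(fx$panel1, n_bins = 2, seed = 3, n_freq_bins = 10)
  expect_gt(res$group_correlations[1, 2], 0.5)
})
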