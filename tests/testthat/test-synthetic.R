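test_that("simulation config validates its invariants", {
  expect_error(sim_config(fst_param = 1), "fst_param")
  expect_error(sim_config(switch_rate = -1))
  expect_error(sim_config(ancestral_freq_range = c(0, 0.9)))
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
})

test_that("Balding-Nichols with F = 0 gives both populations the ancestral frequency", {
  cfg <- sim_config(n_ind_per_pop = 20, n_snps = 100, fst_param = 0, seed = 2)
  bn <- sim_balding_nichols(cfg)
  expect_equal(bn$pop_freq[1, ], bn$ancestral_freq)
  expect_equal(bn$pop_freq[2, ], bn$ancestral_freq)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_ind_per_pop = 15, n_snps = 80, seed = 9,
                    fst_param = 0.1,
                    sweep_specs = list(list(pop = 1, core_bp = 2.5e6,
                                            target_freq = 0.7)))
  a <- sim_balding_nichols(cfg)
  b <- sim_balding_nichols(cfg)
  expect_identical(a$pop1$genotypes, b$pop1$genotypes)
  fa <- sim_two_pop_fixture(cfg)
  fb <- sim_two_pop_fixture(cfg)
  expect_identical(fa$panel1$alleles, fb$panel1$alleles)
  expect_identical(fa$sweep_truth, fb$sweep_truth)
})

test_that("mosaic haplotypes copy founders exactly when switching is off", {
  cfg <- sim_config(n_ind_per_pop = 10, n_snps = 60, n_founders = 5,
                    switch_rate = 0, seed = 6)
  panel <- sim_mosaic_haplotypes(cfg)
  founders <- attr(panel, "founders")
  for (h in seq_len(nrow(panel$alleles))) {
    match_any <- any(apply(founders, 1, function(f)
      all(f == panel$alleles[h, ])))
    expect_true(match_any)
  }
  mono <- sim_mosaic_haplotypes(sim_config(n_ind_per_pop = 5, n_snps = 20,
                                           n_founders = 1, seed = 1))
  expect_true(isTRUE(attr(mono, "monomorphic")))
})

test_that("large switch rates drive adjacent-SNP LD to the permuted baseline", {
  cfg <- sim_config(n_ind_per_pop = 100, n_snps = 60, chrom_length = 6e6,
                    n_founders = 10, switch_rate = 1, seed = 8)
  panel <- sim_mosaic_haplotypes(cfg)
  A <- panel$alleles
  poly <- which(apply(A, 2, var) > 0)
  adj <- poly[which(diff(poly) == 1)]
  r2 <- mean(sapply(adj, function(j) cor(A[, j], A[, j + 1])^2))
  set.seed(1)
  Aperm <- apply(A, 2, sample)
  r2perm <- mean(sapply(adj, function(j) cor(Aperm[, j], Aperm[, j + 1])^2))
  expect_lt(abs(r2 - r2perm), 0.02)
  # and a low switch rate gives adjacent LD well above the permuted baseline
  cfg2 <- sim_config(n_ind_per_pop = 100, n_snps = 60, chrom_length = 6e6,
                     n_founders = 10, switch_rate = 1e-6, seed = 8)
  A2 <- sim_mosaic_haplotypes(cfg2)$alleles
  poly2 <- which(apply(A2, 2, var) > 0)
  adj2 <- poly2[which(diff(poly2) == 1)]
  r2low <- mean(sapply(adj2, function(j) cor(A2[, j], A2[, j + 1])^2))
  expect_gt(r2low, 10 * r2perm)
})

test_that("sweep injection reaches the target carrier count without touching flanks", {
  cfg <- sim_config(n_ind_per_pop = 100, n_snps = 200, chrom_length = 2e6,
                    seed = 12)
  panel <- sim_mosaic_haplotypes(cfg)
  core <- 100L
  al <- if (mean(panel$alleles[, core]) <= 0.5) 1L else 0L
  before <- panel$alleles
  res <- inject_sweep(panel, core, target_freq = 0.8, flank_bp = 2e5,
                      allele = al, seed = 5)
  A <- res$panel$alleles
  n_hap <- nrow(A)
  expect_equal(sum(A[, core] == al), ceiling(0.8 * n_hap))
  expect_equal(res$truth$realized_freq, 0.8, tolerance = 1 / n_hap)
  out <- abs(panel$positions - panel$positions[core]) > 2e5
  expect_identical(A[, out], before[, out])
  # carrier frequency never decreases
  expect_gte(sum(A[, core] == al), sum(before[, core] == al))
  # target below current frequency: warning and no-op
  expect_warning(res2 <- inject_sweep(res$panel, core, 0.5, allele = al),
                 "no-op")
  expect_identical(res2$panel$alleles, A)
  expect_false(res2$truth$swept)
})

test_that("a whole-chromosome flank makes every carrier identical", {
  cfg <- sim_config(n_ind_per_pop = 30, n_snps = 80, chrom_length = 8e5,
                    seed = 13)
  panel <- sim_mosaic_haplotypes(cfg)
  core <- 40L
  al <- if (mean(panel$alleles[, core]) <= 0.5) 1L else 0L
  res <- inject_sweep(panel, core, 0.9, flank_bp = Inf, allele = al, seed = 2)
  A <- res$panel$alleles
  carriers <- which(A[, core] == al)
  new_carriers <- setdiff(carriers, which(panel$alleles[, core] == al))
  donorlike <- A[new_carriers, , drop = FALSE]
  expect_true(all(apply(donorlike, 1, function(x)
    all(x == donorlike[1, ]))))
})

test_that("sweep injection never lowers EHH around the core", {
  cfg <- sim_config(n_ind_per_pop = 40, n_snps = 100, chrom_length = 1e6,
                    seed = 14)
  panel <- sim_mosaic_haplotypes(cfg)
  core <- 50L
  al <- if (mean(panel$alleles[, core]) <= 0.5) 1L else 0L
  res <- inject_sweep(panel, core, 0.85, flank_bp = Inf, allele = al,
                      seed = 3)
  before <- ehh_curve(panel, core, al)
  after <- ehh_curve(res$panel, core, al)
  n <- min(nrow(before$right), nrow(after$right))
  expect_true(all(after$right$ehh[1:n] >= before$right$ehh[1:n] - 1e-12))
  nl <- min(nrow(before$left), nrow(after$left))
  expect_true(all(after$left$ehh[1:nl] >= before$left$ehh[1:nl] - 1e-12))
})

test_that("planted homozygous intervals behave as identity on empty input", {
  cfg <- sim_config(n_ind_per_pop = 10, n_snps = 100, chrom_length = 1e6,
                    seed = 15)
  G <- hap_to_geno(sim_mosaic_haplotypes(cfg))
  expect_identical(plant_roh(G, integer(), c(1e5, 5e5)), G)
  planted <- plant_roh(G, 1:4, c(2e5, 6e5))
  j <- which(G$positions >= 2e5 & G$positions <= 6e5)
  expect_true(all(planted$genotypes[1:4, j] %in% c(0L, 2L)))
  expect_identical(planted$genotypes[5:10, ], G$genotypes[5:10, ])
})

test_that("fixture truth tables index valid SNPs and individuals", {
  cfg <- sim_config(n_ind_per_pop = 25, n_snps = 400, chrom_length = 4e6,
                    seed = 16,
                    sweep_specs = list(list(pop = 1, core_bp = 1e6,
                                            target_freq = 0.7),
                                       list(pop = 2, core_bp = 3e6,
                                            target_freq = 0.6)),
                    roh_specs = list(list(pop = 1, frac = 0.4,
                                          start_bp = 2e6, end_bp = 3e6)))
  fx <- sim_two_pop_fixture(cfg)
  expect_equal(nrow(fx$sweep_truth), 2L)
  expect_true(all(fx$sweep_truth$core_index >= 1 &
                    fx$sweep_truth$core_index <= 400))
  expect_equal(fx$sweep_truth$pop, c(1, 2))
  ids <- as.integer(strsplit(fx$roh_truth$individuals, ";")[[1]])
  expect_true(all(ids >= 1 & ids <= 25))
  expect_equal(length(ids), 10L)
})
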