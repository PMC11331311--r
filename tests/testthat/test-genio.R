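test_that("hand-written phased VCF is transcribed exactly", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
           "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
           "1\t200\t.\tG\tT\t.\tPASS\t.\tGT\t0|0\t1|0",
           "1\t300\t.\tT\tA\t.\tPASS\t.\tGT\t1|0\t0|0")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- read_vcf_haplotypes(f)
  expect_equal(dim(p$alleles), c(4L, 3L))
  # rows: s1 hapA, s1 hapB, s2 hapA, s2 hapB
  expect_equal(p$alleles[, 1], c(0L, 1L, 1L, 1L))
  expect_equal(p$alleles[, 2], c(0L, 0L, 1L, 0L))
  expect_equal(p$alleles[, 3], c(1L, 0L, 0L, 0L))
  expect_equal(p$positions, c(100L, 200L, 300L))
  expect_equal(p$ref, c("A", "G", "T"))
})

test_that("unphased records error in strict mode and are skipped otherwise", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
           "1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1",
           "1\t200\t.\tG\tT\t.\tPASS\t.\tGT\t0/1",
           "1\t300\t.\tT\tA,G\t.\tPASS\t.\tGT\t1|1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_error(read_vcf_haplotypes(f, strict = TRUE), "1:200")
  p <- read_vcf_haplotypes(f, strict = FALSE)
  expect_equal(ncol(p$alleles), 1L)
  expect_equal(unname(attr(p, "skipped")),
               c(1L, 1L))
})

test_that("VCF and PLINK round-trips preserve the simulated data", {
  cfg <- sim_config(n_ind_per_pop = 10, n_snps = 50, chrom_length = 5e5,
                    seed = 4)
  panel <- sim_mosaic_haplotypes(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_haplotypes(panel, f)
  back <- read_vcf_haplotypes(f)
  expect_equal(unname(back$alleles), unname(panel$alleles))
  expect_equal(back$positions, panel$positions)
  G <- hap_to_geno(panel)
  G$genotypes[1, 3] <- NA  # exercise the missing code
  prefix <- withr::local_tempfile()
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_equal(unname(G2$genotypes), unname(G$genotypes))
  expect_equal(G2$positions, G$positions)
})

test_that("site intersection keeps shared sites in order and harmonizes alleles", {
  mk <- function(pos, ref, alt, hap) {
    haplotype_panel(hap, pos, "1", ref = ref, alt = alt)
  }
  a <- mk(c(100, 200, 300, 400, 500), rep("A", 5), rep("C", 5),
          matrix(c(0L, 1L), 2, 5))
  b <- mk(c(100, 300, 500), c("A", "C", "A"), c("C", "A", "G"),
          matrix(1L, 2, 3))
  res <- intersect_sites(a, b)
  # site 500 has irreconcilable alleles (C vs G) -> dropped
  expect_equal(res$sites$pos, c(100, 300))
  expect_equal(res$n_dropped, 1L)
  # swapped REF/ALT at 300: b's alleles flipped so allele 1 = same nucleotide
  expect_equal(unname(res$b$alleles[, 2]), rep(0L, 2))
  expect_equal(res$b$ref[2], "A")
  # identical inputs come back unchanged
  same <- intersect_sites(a, a)
  expect_equal(same$a$positions, a$positions)
  expect_error(intersect_sites(a, b, strict = TRUE), "500")
})

test_that("frequencies refer to the same allele after harmonization", {
  set.seed(9)
  A <- matrix(rbinom(40, 1, 0.3), 4, 10)
  pa <- haplotype_panel(A, 1:10 * 100L, ref = rep("A", 10), alt = rep("G", 10))
  B <- 1L - A  # same nucleotides, swapped REF/ALT coding
  pb <- haplotype_panel(B, 1:10 * 100L, ref = rep("G", 10), alt = rep("A", 10))
  res <- intersect_sites(pa, pb)
  expect_equal(colMeans(res$a$alleles), colMeans(res$b$alleles))
})

test_that("BED and GFF3 annotations unify to 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneX", bed)
  g <- read_gene_annotation(bed)
  expect_equal(g$start, 100)
  expect_equal(g$end, 200)
  expect_equal(g$gene_id, "geneX")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1;Name=geneY",
               "chr1\tsrc\texon\t100\t150\t.\t+\t.\tID=e1"), gff)
  g2 <- read_gene_annotation(gff)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$gene_id, "geneY")
  expect_equal(c(g2$start, g2$end), c(100, 200))
})
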