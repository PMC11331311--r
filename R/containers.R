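#' Phased haplotype panel
#'
#' Container for a phased biallelic haplotype matrix: one row per haplotype
#' (two consecutive rows per individual), one column per SNP. Allele 0 is the
#' REF allele, allele 1 the ALT allele. Physical positions must be strictly
#' increasing within each chromosome; genetic positions default to a linear
#' 1 cM/Mb map when not supplied.
#'
#' @param alleles integer matrix of 0/1 values, `2 * n_ind` rows, `L` columns.
#' @param positions integer vector of base-pair positions, length `L`.
#' @param chrom chromosome label per SNP (recycled if length 1).
#' @param samples character vector of individual ids (`nrow(alleles) / 2`).
#' @param ref,alt allele strings per SNP (defaults `"A"`/`"B"` placeholders).
#' @param genetic_pos optional numeric vector of genetic positions in cM.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `alleles`, `positions`, `chrom`, `samples`, `ref`, `alt`, `genetic_pos`.
#' @export
haplotype_panel <- function(alleles, positions, chrom = "1", samples = NULL,
                            ref = NULL, alt = NULL, genetic_pos = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  L <- ncol(alleles)
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (two haplotypes per individual)")
  if (length(positions) != L)
    stop("length(positions) must equal ncol(alleles)")
  positions <- as.integer(positions)
  chrom <- as.character(rep_len(chrom, L))
  for (cc in unique(chrom)) {
    p <- positions[chrom == cc]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  if (!all(alleles %in% c(0L, 1L)))
    stop("alleles must be 0/1")
  if (is.null(samples))
    samples <- sprintf("ind%03d", seq_len(nrow(alleles) / 2L))
  if (length(samples) != nrow(alleles) / 2L)
    stop("need one sample id per individual")
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("B", L)
  if (!is.null(genetic_pos) && length(genetic_pos) != L)
    stop("genetic_pos length mismatch")
  structure(
    list(alleles = alleles, positions = positions, chrom = chrom,
         samples = as.character(samples), ref = as.character(ref),
         alt = as.character(alt), genetic_pos = genetic_pos),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d individuals) x %d SNPs on %d chromosome(s)\n",
              nrow(x$alleles), length(x$samples), ncol(x$alleles),
              length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' Per-individual genotype matrix
#'
#' Container for diploid genotypes coded 0/1/2 (count of the ALT allele) with
#' `NA` for missing calls; one row per individual, one column per SNP.
#'
#' @param genotypes integer matrix in `{0, 1, 2, NA}`.
#' @param positions base-pair positions, one per column.
#' @param chrom chromosome label per SNP (recycled if length 1).
#' @param samples individual ids (default generated).
#' @param ref,alt allele strings per SNP.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, positions, chrom = "1", samples = NULL,
                            ref = NULL, alt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  L <- ncol(genotypes)
  if (length(positions) != L)
    stop("length(positions) must equal ncol(genotypes)")
  positions <- as.integer(positions)
  chrom <- as.character(rep_len(chrom, L))
  for (cc in unique(chrom)) {
    p <- positions[chrom == cc]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotypes must be 0/1/2/NA")
  if (is.null(samples))
    samples <- sprintf("ind%03d", seq_len(nrow(genotypes)))
  if (length(samples) != nrow(genotypes))
    stop("need one sample id per individual")
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("B", L)
  structure(
    list(genotypes = genotypes, positions = positions, chrom = chrom,
         samples = as.character(samples), ref = as.character(ref),
         alt = as.character(alt)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Collapse a phased panel to per-individual genotypes
#'
#' Sums the two haplotypes of each individual, giving the 0/1/2 ALT-allele
#' dosage used by the ROH and allele-frequency stages.
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_matrix()] with the same site index.
#' @export
hap_to_geno <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  idx <- seq(1L, nrow(A), by = 2L)
  G <- A[idx, , drop = FALSE] + A[idx + 1L, , drop = FALSE]
  genotype_matrix(G, panel$positions, panel$chrom, panel$samples,
                  panel$ref, panel$alt)
}

# Genetic positions in cM: stored map if present, else 1 cM/Mb linear.
genetic_positions <- function(panel, cm_per_mb = 1) {
  if (!is.null(panel$genetic_pos)) return(as.numeric(panel$genetic_pos))
  panel$positions * cm_per_mb / 1e6
}

# Subset SNP columns of either container, keeping metadata aligned.
subset_sites <- function(x, keep) {
  if (inherits(x, "haplotype_panel")) {
    haplotype_panel(x$alleles[, keep, drop = FALSE], x$positions[keep],
                    x$chrom[keep], x$samples, x$ref[keep], x$alt[keep],
                    if (!is.null(x$genetic_pos)) x$genetic_pos[keep])
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$genotypes[, keep, drop = FALSE], x$positions[keep],
                    x$chrom[keep], x$samples, x$ref[keep], x$alt[keep])
  } else stop("unsupported container")
}
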