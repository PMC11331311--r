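#' Per-SNP ALT-allele frequencies
#'
#' Frequency of allele 1 (ALT) per SNP: ALT-allele count divided by twice the
#' number of non-missing individuals. SNPs with zero non-missing calls are
#' returned as `NA`.
#'
#' @param G a [genotype_matrix()], or a plain 0/1/2/NA matrix.
#' @return Numeric vector of frequencies in `[0, 1]` (NA where uncallable).
#' @export
allele_frequencies <- function(G) {
  g <- if (inherits(G, "genotype_matrix")) G$genotypes else as.matrix(G)
  counts <- colSums(g, na.rm = TRUE)
  n_called <- colSums(!is.na(g))
  out <- counts / (2 * n_called)
  out[n_called == 0L] <- NA_real_
  out
}

#' Per-SNP fixation index against the mean-frequency baseline
#'
#' FST per SNP for two equally weighted populations: with baseline
#' `p_bar = (p1 + p2) / 2`, the between-population variance is
#' `sigma^2 = (p1 - p_bar)^2` (identical to `(p2 - p_bar)^2` with equal
#' weights) and `FST = sigma^2 / (p_bar (1 - p_bar))`. Sites where the
#' baseline is monomorphic (`p_bar (1 - p_bar) = 0`) or either frequency is
#' missing are masked (`NA`) rather than set to zero, so they are excluded
#' from rank-based p-values downstream.
#'
#' @param p1,p2 per-SNP allele-1 frequency vectors of equal length.
#' @return data.frame with columns `fst` (NA where masked), `p_bar`, `mask`.
#' @export
fst_per_snp <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("p1 and p2 lengths differ")
  p_bar <- (p1 + p2) / 2
  sigma2 <- (p1 - p_bar)^2
  denom <- p_bar * (1 - p_bar)
  mask <- is.na(denom) | denom == 0
  fst <- ifelse(mask, NA_real_, sigma2 / denom)
  data.frame(fst = fst, p_bar = p_bar, mask = mask)
}

#' Mean observed heterozygosity
#'
#' Proportion of non-missing genotype calls that are heterozygous, pooled
#' over all SNPs and individuals.
#'
#' @param G a [genotype_matrix()], or a plain 0/1/2/NA matrix.
#' @return A single proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(G) {
  g <- if (inherits(G, "genotype_matrix")) G$genotypes else as.matrix(G)
  if (length(g) == 0L) stop("empty genotype matrix")
  n_called <- sum(!is.na(g))
  if (n_called == 0L) stop("no non-missing genotype calls")
  sum(g == 1L, na.rm = TRUE) / n_called
}
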