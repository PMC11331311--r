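#' Parameters for the sliding-window ROH caller
#'
#' Defaults mirror the widely used genotype-based ROH screen: a 100-SNP
#' scanning window (increased from 50 for dense sequence data) allowing at
#' most 1 heterozygote and 5 missing calls, a 5% window-hit threshold per
#' SNP, and segment filters of at least 100 SNPs, at least 1000 kb, at most
#' 50 kb per SNP and no internal gap above 1000 kb.
#'
#' @param window_snp SNPs per scanning window.
#' @param window_het_max maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param window_hit_threshold minimum fraction of overlapping homozygous
#'   windows for a SNP to be eligible, in `(0, 1]`.
#' @param min_snp minimum SNPs per accepted segment.
#' @param min_length_kb minimum segment length in kb.
#' @param max_inverse_density maximum kb per SNP within a segment.
#' @param max_internal_gap_kb segments are split at adjacent-SNP gaps larger
#'   than this (kb).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 100, window_het_max = 1,
                       window_missing_max = 5, window_hit_threshold = 0.05,
                       min_snp = 100, min_length_kb = 1000,
                       max_inverse_density = 50, max_internal_gap_kb = 1000) {
  stopifnot(window_snp >= 1, window_het_max >= 0, window_missing_max >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_snp >= 1, min_length_kb >= 0, max_inverse_density > 0,
            max_internal_gap_kb > 0)
  structure(list(window_snp = as.integer(window_snp),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_threshold = window_hit_threshold,
                 min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb,
                 max_inverse_density = max_inverse_density,
                 max_internal_gap_kb = max_internal_gap_kb),
            class = "roh_params")
}

# Window sums of a 0/1 vector, full windows only (length L - W + 1).
.win_sums <- function(x, W) {
  cs <- c(0, cumsum(x))
  cs[(W + 1L):length(cs)] - cs[1L:(length(cs) - W)]
}

#' Call runs of homozygosity per individual
#'
#' Sliding-window screen: per individual and chromosome, a full window of
#' `window_snp` consecutive SNPs is homozygous when it contains at most
#' `window_het_max` heterozygotes and `window_missing_max` missing calls.
#' Each SNP's hit fraction is the proportion of full windows overlapping it
#' that are homozygous; SNPs at or above `window_hit_threshold` are eligible.
#' Maximal runs of eligible SNPs are split at adjacent-SNP gaps above
#' `max_internal_gap_kb` and kept when they satisfy the SNP-count, length and
#' density filters. Windows truncated at chromosome ends are never formed;
#' chromosomes with fewer SNPs than `window_snp` yield no calls. Calls are
#' invariant to which homozygote (0 or 2) occurs.
#'
#' @param G a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame with columns `iid`, `chrom`, `start`, `end` (bp,
#'   inclusive), `n_snps`, `length_kb`.
#' @export
detect_roh <- function(G, params = roh_params()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(params, "roh_params"))
  W <- params$window_snp
  out <- list()
  for (cc in unique(G$chrom)) {
    jj <- which(G$chrom == cc)
    L <- length(jj)
    if (L < W) next
    pos <- G$positions[jj]
    gap_kb <- diff(pos) / 1000
    for (i in seq_len(nrow(G$genotypes))) {
      g <- G$genotypes[i, jj]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      hom_win <- .win_sums(het, W) <= params$window_het_max &
        .win_sums(mis, W) <= params$window_missing_max
      nw <- length(hom_win)
      # windows overlapping SNP k start in [max(1, k-W+1), min(k, nw)]
      cs <- c(0, cumsum(hom_win))
      lo <- pmax(1L, seq_len(L) - W + 1L)
      hi <- pmin(seq_len(L), nw)
      hits <- cs[hi + 1L] - cs[lo]
      frac <- hits / (hi - lo + 1L)
      eligible <- frac >= params$window_hit_threshold
      r <- rle(eligible)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]
        # split at large internal gaps before filtering
        cuts <- if (b > a) which(gap_kb[a:(b - 1L)] >
                                   params$max_internal_gap_kb) else integer()
        seg_starts <- c(a, a + cuts)
        seg_ends <- c(a + cuts - 1L, b)
        for (s in seq_along(seg_starts)) {
          sa <- seg_starts[s]; sb <- seg_ends[s]
          n_snps <- sb - sa + 1L
          len_kb <- (pos[sb] - pos[sa] + 1) / 1000
          if (n_snps >= params$min_snp && len_kb >= params$min_length_kb &&
              len_kb / n_snps <= params$max_inverse_density) {
            out[[length(out) + 1L]] <-
              data.frame(iid = G$samples[i], chrom = cc,
                         start = pos[sa], end = pos[sb],
                         n_snps = n_snps, length_kb = len_kb,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(iid = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-SNP autozygosity from called ROH segments
#'
#' For each SNP, the proportion of individuals having at least one ROH
#' segment covering its position (inclusive). An individual with several
#' overlapping segments at a SNP is counted once.
#'
#' @param segments data.frame from [detect_roh()].
#' @param sites data.frame with `chrom` and `pos` columns (the site index).
#' @param n_ind total number of individuals (the denominator).
#' @return Numeric vector in `[0, 1]`, one value per site.
#' @export
autozygosity <- function(segments, sites, n_ind) {
  if (n_ind <= 0L) stop("n_ind must be positive")
  counts <- numeric(nrow(sites))
  if (nrow(segments) > 0L) {
    for (id in unique(segments$iid)) {
      seg <- segments[segments$iid == id, , drop = FALSE]
      covered <- logical(nrow(sites))
      for (s in seq_len(nrow(seg)))
        covered <- covered | (sites$chrom == seg$chrom[s] &
                                sites$pos >= seg$start[s] &
                                sites$pos <= seg$end[s])
      counts <- counts + covered
    }
  }
  counts / n_ind
}

#' Summary statistics for a set of ROH segments
#'
#' Per-animal segment counts (mean, SD, min, max), segment-length statistics
#' (kb), length-class counts on half-open Mb bins
#' `[1,5) [5,10) [15,20) [20,25) [25,30) [30,Inf)`, and the percentage of
#' animals with at least one ROH.
#'
#' @param segments data.frame from [detect_roh()].
#' @param n_ind total number of animals (for the percentage; default: number
#'   of distinct ids present).
#' @return Named list of summary values; single-segment SD is reported as NA.
#' @export
roh_summary <- function(segments, n_ind = NULL) {
  if (is.null(n_ind)) n_ind <- length(unique(segments$iid))
  if (nrow(segments) == 0L) {
    return(list(n_segments = 0L, per_animal = c(mean = 0, sd = NA, min = 0,
                                                max = 0),
                length_kb = c(mean = NA, sd = NA, median = NA, min = NA,
                              max = NA),
                class_counts = stats::setNames(rep(0L, 7L),
                  c("1-5", "5-10", "10-15", "15-20", "20-25", "25-30", ">30")),
                pct_animals_with_roh = 0))
  }
  per <- table(segments$iid)
  len <- segments$length_kb
  mb <- len / 1000
  breaks <- c(0, 5, 10, 15, 20, 25, 30, Inf)
  cls <- table(cut(mb, breaks, right = FALSE))
  names(cls) <- c("1-5", "5-10", "10-15", "15-20", "20-25", "25-30", ">30")
  list(n_segments = nrow(segments),
       per_animal = c(mean = mean(per),
                      sd = if (length(per) > 1L) stats::sd(per) else NA,
                      min = min(per), max = max(per)),
       length_kb = c(mean = mean(len),
                     sd = if (length(len) > 1L) stats::sd(len) else NA,
                     median = stats::median(len), min = min(len),
                     max = max(len)),
       class_counts = cls,
       pct_animals_with_roh = 100 * length(per) / n_ind)
}
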