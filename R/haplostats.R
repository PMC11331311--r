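# Extended haplotype homozygosity and its integrals.
#
# EHH at a marker distance d from a core SNP is the probability that two
# randomly chosen carrier haplotypes are identical over the closed interval
# between the core and that marker. It is computed by maintaining a partition
# of the carriers into identity groups and refining it one marker at a time:
# EHH = sum_g C(n_g, 2) / C(n, 2).

# Walk one side (dir = +1 right, -1 left) from the core, refining the group
# partition. Stops when EHH < stop_below or at the chromosome end. Returns
# marker offsets (genetic distance from core, cM), EHH at each step, whether
# the curve crossed stop_below, and the interpolated crossing distance.
.ehh_side <- function(A, members, core, dir, gpos, stop_below = 0,
                      init_groups = NULL, chrom_range = NULL,
                      max_dist = Inf) {
  n <- length(members)
  if (is.null(chrom_range)) chrom_range <- c(1L, ncol(A))
  g <- if (is.null(init_groups)) rep(1L, n) else init_groups
  denom <- n * (n - 1)
  counts <- tabulate(g)
  e0 <- sum(counts * (counts - 1L)) / denom
  dist <- 0
  ehh <- e0
  j <- core
  last_e <- e0
  crossed <- FALSE
  cross_at <- Inf
  if (e0 < stop_below) {
    return(list(dist = 0, ehh = e0, crossed = TRUE, cross_at = 0))
  }
  repeat {
    j <- j + dir
    if (j < chrom_range[1L] || j > chrom_range[2L]) break
    key <- g * 2L + A[members, j]
    g <- match(key, unique(key))
    counts <- tabulate(g)
    e <- sum(counts * (counts - 1L)) / denom
    d <- abs(gpos[j] - gpos[core])
    dist <- c(dist, d)
    ehh <- c(ehh, e)
    if (e < stop_below) {
      d_prev <- dist[length(dist) - 1L]
      cross_at <- d_prev + (d - d_prev) * (last_e - stop_below) /
        (last_e - e)
      crossed <- TRUE
      break
    }
    last_e <- e
    if (e == 0 || d >= max_dist) break
  }
  list(dist = dist, ehh = ehh, crossed = crossed, cross_at = cross_at)
}

# column range of the core's chromosome
.chrom_range <- function(chrom, core) {
  jj <- which(chrom == chrom[core])
  c(min(jj), max(jj))
}

#' EHH decay curve around a core SNP
#'
#' Computes extended haplotype homozygosity for carriers of one core allele,
#' left and right of the core, out to the chromosome ends (or until EHH
#' reaches 0, beyond which it stays 0). EHH is 1 at the core and
#' non-increasing with distance.
#'
#' @param panel a [haplotype_panel()].
#' @param core column index of the core SNP.
#' @param allele core allele (0 or 1) whose carriers are followed.
#' @param cm_per_mb genetic-map scale used when the panel carries no map.
#' @return List of class `ehh_curve` with data.frames `left` and `right`
#'   (columns `dist_cm`, `ehh`; distance 0 row included on both sides) and
#'   the carrier count `n_carriers`.
#' @export
ehh_curve <- function(panel, core, allele = 1L, cm_per_mb = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  members <- which(A[, core] == allele)
  if (length(members) < 2L)
    stop("fewer than 2 carrier haplotypes at the core; EHH undefined")
  gpos <- genetic_positions(panel, cm_per_mb)
  cr <- .chrom_range(panel$chrom, core)
  l <- .ehh_side(A, members, core, -1L, gpos, 0, chrom_range = cr)
  r <- .ehh_side(A, members, core, +1L, gpos, 0, chrom_range = cr)
  structure(list(left = data.frame(dist_cm = l$dist, ehh = l$ehh),
                 right = data.frame(dist_cm = r$dist, ehh = r$ehh),
                 n_carriers = length(members), core = core, allele = allele),
            class = "ehh_curve")
}

# Trapezoidal integral of a piecewise-linear EHH side curve, truncated at the
# interpolated point where EHH first falls below `cutoff`. Returns the
# integral and whether the curve decayed before the chromosome end.
.integrate_side <- function(side, cutoff) {
  d <- side$dist
  e <- side$ehh
  if (length(d) == 1L) {
    # no flanking markers: nothing to integrate, curve never decayed
    return(list(ihh = 0, decayed = side$crossed))
  }
  if (side$crossed) {
    k <- length(d)  # crossing happened between k-1 and k
    x <- side$cross_at
    dd <- c(d[seq_len(k - 1L)], x)
    ee <- c(e[seq_len(k - 1L)], cutoff)
  } else {
    dd <- d
    ee <- e
  }
  ihh <- sum(diff(dd) * (utils::head(ee, -1L) + utils::tail(ee, -1L)) / 2)
  list(ihh = ihh, decayed = side$crossed)
}

#' Integrated haplotype homozygosity for one core allele
#'
#' Trapezoidal integral of the EHH decay curve over genetic distance (cM),
#' accumulated outward from the core separately left and right. Each side is
#' truncated at the linearly interpolated point where EHH first falls below
#' `decay_cutoff`; a side that reaches a chromosome end before decaying marks
#' the result invalid (such SNPs are excluded from standardization).
#'
#' @inheritParams ehh_curve
#' @param decay_cutoff EHH level at which integration stops (default 0.05).
#' @return List with `ihh` (left + right), `valid` (both sides decayed),
#'   `left`, `right` (per-side integrals).
#' @export
ihh <- function(panel, core, allele = 1L, decay_cutoff = 0.05,
                cm_per_mb = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  members <- which(A[, core] == allele)
  if (length(members) < 2L)
    return(list(ihh = NA_real_, valid = FALSE, left = NA_real_,
                right = NA_real_))
  gpos <- genetic_positions(panel, cm_per_mb)
  cr <- .chrom_range(panel$chrom, core)
  l <- .ehh_side(A, members, core, -1L, gpos, decay_cutoff, chrom_range = cr)
  r <- .ehh_side(A, members, core, +1L, gpos, decay_cutoff, chrom_range = cr)
  il <- .integrate_side(l, decay_cutoff)
  ir <- .integrate_side(r, decay_cutoff)
  list(ihh = il$ihh + ir$ihh, valid = il$decayed && ir$decayed,
       left = il$ihh, right = ir$ihh)
}

#' Genome scan of the integrated haplotype score (iHS)
#'
#' For each SNP with derived-allele frequency inside
#' `[maf_min, 1 - maf_min]`, computes iHH for the ancestral and derived
#' alleles and the unstandardized score `ln(iHH_ancestral / iHH_derived)`.
#' Scores are standardized to mean 0 / SD 1 within equal-width
#' derived-allele-frequency bins, so that the score is comparable across
#' frequencies; bins with zero SD yield standardized 0. SNPs whose EHH fails
#' to decay below `decay_cutoff` before a chromosome end on any side are
#' flagged invalid and excluded from standardization.
#'
#' @param panel a [haplotype_panel()].
#' @param ancestral per-SNP ancestral allele (0/1 vector), or a single value;
#'   default 0 (REF treated as ancestral).
#' @param decay_cutoff EHH integration cutoff.
#' @param n_freq_bins number of equal-width frequency bins for
#'   standardization.
#' @param maf_min minimum derived-allele frequency scanned.
#' @param cm_per_mb genetic-map scale when the panel carries no map.
#' @return data.frame with one row per SNP: `chrom`, `pos`, `freq_derived`,
#'   `ihh_anc`, `ihh_der`, `ihs_unstd`, `ihs_std`, `valid`.
#' @export
ihs_scan <- function(panel, ancestral = 0L, decay_cutoff = 0.05,
                     n_freq_bins = 50, maf_min = 0.05, cm_per_mb = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  A <- panel$alleles
  L <- ncol(A)
  anc <- as.integer(rep_len(ancestral, L))
  gpos <- genetic_positions(panel, cm_per_mb)
  freq_der <- colMeans(A == rep(1L - anc, each = nrow(A)))
  ihh_a <- ihh_d <- rep(NA_real_, L)
  valid <- rep(FALSE, L)
  for (core in seq_len(L)) {
    fd <- freq_der[core]
    if (is.na(fd) || fd < maf_min || fd > 1 - maf_min) next
    cr <- .chrom_range(panel$chrom, core)
    ok <- TRUE
    vals <- numeric(2L)
    for (w in 1:2) {
      al <- if (w == 1L) anc[core] else 1L - anc[core]
      members <- which(A[, core] == al)
      if (length(members) < 2L) { ok <- FALSE; break }
      l <- .ehh_side(A, members, core, -1L, gpos, decay_cutoff,
                     chrom_range = cr)
      r <- .ehh_side(A, members, core, +1L, gpos, decay_cutoff,
                     chrom_range = cr)
      il <- .integrate_side(l, decay_cutoff)
      ir <- .integrate_side(r, decay_cutoff)
      vals[w] <- il$ihh + ir$ihh
      if (!(il$decayed && ir$decayed)) ok <- FALSE
    }
    if (length(vals) == 2L) {
      ihh_a[core] <- vals[1L]
      ihh_d[core] <- vals[2L]
    }
    valid[core] <- ok && all(vals > 0)
  }
  unstd <- ifelse(valid, log(ihh_a / ihh_d), NA_real_)
  if (all(!valid)) warning("no valid iHS values; empty track")
  std <- .standardize_by_bin(unstd, freq_der, valid, n_freq_bins)
  data.frame(chrom = panel$chrom, pos = panel$positions,
             freq_derived = freq_der, ihh_anc = ihh_a, ihh_der = ihh_d,
             ihs_unstd = unstd, ihs_std = std, valid = valid,
             stringsAsFactors = FALSE)
}

# Standardize x within equal-width frequency bins over (0, 1); SD-0 bins
# give standardized 0. Only `use` entries contribute to and receive values.
.standardize_by_bin <- function(x, freq, use, n_bins) {
  std <- rep(NA_real_, length(x))
  if (!any(use)) return(std)
  bin <- cut(freq, breaks = seq(0, 1, length.out = n_bins + 1L),
             include.lowest = TRUE)
  for (b in levels(bin)) {
    i <- which(use & bin == b & !is.na(x))
    if (length(i) == 0L) next
    mu <- mean(x[i])
    sdv <- stats::sd(x[i])
    std[i] <- if (is.na(sdv) || sdv == 0) 0 else (x[i] - mu) / sdv
  }
  std
}

#' Cross-population EHH scan (XP-EHH)
#'
#' For each shared SNP, integrates the all-haplotype EHH (haplotypes
#' partitioned by the core allele, no allele split) in each population. Both
#' populations are truncated at the same boundary: the interpolated point,
#' per side, where the EHH of the pooled haplotypes of both populations
#' drops below `decay_cutoff` — so a population holding a long haplotype
#' keeps accumulating homozygosity while the other decays, which is where
#' the statistic's power comes from.
#' The unstandardized score is `ln(iHH_A / iHH_B)`,
#' standardized genome-wide; positive values indicate longer haplotypes
#' (selection) in population A. SNPs where neither population decays before
#' a chromosome end, or with zero iHH, are flagged invalid and excluded from
#' standardization. Swapping the populations negates the score.
#'
#' @param panel_a,panel_b [haplotype_panel()]s on the same site index (use
#'   [intersect_sites()] first).
#' @param decay_cutoff EHH integration cutoff.
#' @param cm_per_mb genetic-map scale when the panels carry no map.
#' @return data.frame per SNP: `chrom`, `pos`, `ihh_a`, `ihh_b`,
#'   `xpehh_unstd`, `xpehh_std`, `valid`.
#' @export
xpehh_scan <- function(panel_a, panel_b, decay_cutoff = 0.05,
                       cm_per_mb = 1) {
  stopifnot(inherits(panel_a, "haplotype_panel"),
            inherits(panel_b, "haplotype_panel"))
  if (!identical(panel_a$positions, panel_b$positions) ||
      !identical(panel_a$chrom, panel_b$chrom))
    stop("panels must share the site index; run intersect_sites() first")
  A <- panel_a$alleles
  B <- panel_b$alleles
  P <- rbind(A, B)
  L <- ncol(A)
  gpa <- genetic_positions(panel_a, cm_per_mb)
  ihh_a <- ihh_b <- rep(NA_real_, L)
  valid <- rep(FALSE, L)
  for (core in seq_len(L)) {
    cr <- .chrom_range(panel_a$chrom, core)
    ga <- match(A[, core], unique(A[, core]))
    gb <- match(B[, core], unique(B[, core]))
    gp <- match(P[, core], unique(P[, core]))
    ok <- TRUE
    tot_a <- tot_b <- 0
    for (dir in c(-1L, 1L)) {
      # stopping boundary: pooled-haplotype EHH decays below the cutoff
      sp <- .ehh_side(P, seq_len(nrow(P)), core, dir, gpa, decay_cutoff,
                      init_groups = gp, chrom_range = cr)
      boundary <- sp$cross_at
      if (!is.finite(boundary)) { ok <- FALSE; break }
      sa <- .ehh_side(A, seq_len(nrow(A)), core, dir, gpa, 0,
                      init_groups = ga, chrom_range = cr,
                      max_dist = boundary)
      sb <- .ehh_side(B, seq_len(nrow(B)), core, dir, gpa, 0,
                      init_groups = gb, chrom_range = cr,
                      max_dist = boundary)
      tot_a <- tot_a + .integrate_to(sa, boundary, decay_cutoff)
      tot_b <- tot_b + .integrate_to(sb, boundary, decay_cutoff)
    }
    if (ok) {
      ihh_a[core] <- tot_a
      ihh_b[core] <- tot_b
      valid[core] <- tot_a > 0 && tot_b > 0
    }
  }
  unstd <- ifelse(valid, log(ihh_a / ihh_b), NA_real_)
  v <- unstd[valid]
  std <- rep(NA_real_, L)
  if (sum(valid) >= 2L && stats::sd(v) > 0)
    std[valid] <- (v - mean(v)) / stats::sd(v)
  data.frame(chrom = panel_a$chrom, pos = panel_a$positions,
             ihh_a = ihh_a, ihh_b = ihh_b, xpehh_unstd = unstd,
             xpehh_std = std, valid = valid, stringsAsFactors = FALSE)
}

# Integrate a side curve from 0 to `boundary` (cM). The curve is piecewise
# linear through its sampled points, with value `cutoff` at its own crossing.
.integrate_to <- function(side, boundary, cutoff) {
  d <- side$dist
  e <- side$ehh
  if (side$crossed) {
    k <- length(d)
    d <- c(d[seq_len(k - 1L)], side$cross_at)
    e <- c(e[seq_len(k - 1L)], cutoff)
  }
  keep <- d <= boundary
  dd <- d[keep]
  ee <- e[keep]
  if (max(dd) < boundary) {
    # interpolate the curve value at the boundary
    i <- sum(keep)
    if (i < length(d)) {
      eb <- e[i] + (e[i + 1L] - e[i]) * (boundary - d[i]) / (d[i + 1L] - d[i])
      dd <- c(dd, boundary)
      ee <- c(ee, eb)
    }
  }
  if (length(dd) < 2L) return(0)
  sum(diff(dd) * (utils::head(ee, -1L) + utils::tail(ee, -1L)) / 2)
}

#' Average an iHS scan over random sample bins
#'
#' Randomly partitions the individuals into `n_bins` near-equal groups, runs
#' [ihs_scan()] within each group, and returns the per-SNP average of the
#' standardized scores, together with the pairwise correlations between the
#' group tracks (a consistency diagnostic). With `n_bins = 1` this equals a
#' plain scan on the full panel.
#'
#' @param panel a [haplotype_panel()].
#' @param n_bins number of groups (each must hold at least 2 individuals).
#' @param seed integer seed for the partition.
#' @param ... passed to [ihs_scan()].
#' @return List with `track` (data.frame `chrom`, `pos`, `ihs_std_mean`),
#'   `group_tracks` (matrix, SNP x group) and `group_correlations`
#'   (pairwise Pearson, pairwise-complete).
#' @export
subsample_average <- function(panel, n_bins, seed = 1L, ...) {
  stopifnot(inherits(panel, "haplotype_panel"), n_bins >= 1)
  n_ind <- length(panel$samples)
  if (n_ind / n_bins < 2) stop("groups would hold fewer than 2 individuals")
  set.seed(seed)
  grp <- sample(rep_len(seq_len(n_bins), n_ind))
  tracks <- sapply(seq_len(n_bins), function(b) {
    ind <- which(grp == b)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    sub <- haplotype_panel(panel$alleles[rows, , drop = FALSE],
                           panel$positions, panel$chrom,
                           panel$samples[ind], panel$ref, panel$alt,
                           panel$genetic_pos)
    ihs_scan(sub, ...)$ihs_std
  })
  tracks <- matrix(tracks, ncol = n_bins)
  cors <- if (n_bins > 1L)
    stats::cor(tracks, use = "pairwise.complete.obs") else matrix(1, 1, 1)
  list(track = data.frame(chrom = panel$chrom, pos = panel$positions,
                          ihs_std_mean = rowMeans(tracks, na.rm = TRUE)),
       group_tracks = tracks, group_correlations = cors)
}
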