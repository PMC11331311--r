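# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs in minutes.

# tiny deterministic panel: explicit allele matrix, evenly spaced positions
tiny_panel <- function(alleles, spacing = 10000L, chrom = "1") {
  alleles <- as.matrix(alleles)
  haplotype_panel(alleles, seq_len(ncol(alleles)) * spacing, chrom)
}

# random panel for property tests
random_panel <- function(n_hap, n_snp, seed, spacing = 10000L) {
  set.seed(seed)
  A <- matrix(rbinom(n_hap * n_snp, 1L, runif(n_snp, 0.2, 0.8)[rep(
    seq_len(n_snp), each = n_hap)]), nrow = n_hap)
  # ensure no monomorphic columns confuse carrier selection
  tiny_panel(A, spacing)
}

# brute-force EHH: fraction of identical carrier pairs over the closed
# interval core..marker, by explicit O(n^2) pair comparison
brute_ehh <- function(A, core, allele, marker) {
  carriers <- which(A[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  rng <- min(core, marker):max(core, marker)
  same <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (all(A[carriers[i], rng] == A[carriers[j], rng])) same <- same + 1L
  }
  same / choose(n, 2)
}

# brute-force BH step-up: on the ascending order, q_(i) = min_{j>=i} p_(j)*n/j
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- sapply(seq_len(n), function(i) min(pmin(ps[i:n] * n / (i:n), 1)))
  q <- numeric(n)
  q[o] <- qs
  q
}

# brute-force ROH caller following the window rules literally
brute_roh <- function(g, pos, par) {
  W <- par$window_snp
  L <- length(g)
  if (L < W) return(data.frame())
  hom_win <- sapply(seq_len(L - W + 1L), function(s) {
    w <- g[s:(s + W - 1L)]
    sum(!is.na(w) & w == 1L) <= par$window_het_max &&
      sum(is.na(w)) <= par$window_missing_max
  })
  eligible <- sapply(seq_len(L), function(k) {
    s <- max(1L, k - W + 1L):min(k, L - W + 1L)
    mean(hom_win[s]) >= par$window_hit_threshold
  })
  segs <- list()
  r <- rle(eligible)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- s[k]:e[k]
    # split at big gaps
    brk <- which(diff(pos[idx]) / 1000 > par$max_internal_gap_kb)
    pieces <- split(idx, cumsum(seq_along(idx) %in% (brk + 1L)))
    for (pc in pieces) {
      n_snps <- length(pc)
      len_kb <- (pos[max(pc)] - pos[min(pc)] + 1) / 1000
      if (n_snps >= par$min_snp && len_kb >= par$min_length_kb &&
          len_kb / n_snps <= par$max_inverse_density)
        segs[[length(segs) + 1L]] <- data.frame(start = pos[min(pc)],
                                                end = pos[max(pc)],
                                                n_snps = n_snps)
    }
  }
  if (length(segs) == 0L) data.frame() else do.call(rbind, segs)
}
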