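#' Running median with symmetrically shrinking end windows
#'
#' Centered running median of window `k` (odd). Within `k %/% 2` positions of
#' either end the window shrinks symmetrically to `k' = 2 * min(i - 1, n - i)
#' + 1`, so the output has the input's length and the first/last values pass
#' through unchanged. Missing values are excluded from each window's median;
#' a window of only missing values yields `NA`.
#'
#' @param values numeric vector (may contain NA).
#' @param k odd window size, `k <= length(values)`.
#' @return Numeric vector of the same length.
#' @export
running_median <- function(values, k = 1001) {
  n <- length(values)
  if (k %% 2 == 0) stop("window size k must be odd")
  if (k > n) stop("window size k exceeds track length")
  h <- k %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    w <- values[(i - hh):(i + hh)]
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Right-tailed fractional-rank p-values
#'
#' Converts a statistic track to p-values by ascending fractional ranks with
#' ties averaged: `p = 1 - (rank - 0.5) / n`, so the largest statistic gets
#' the smallest p and all p lie strictly inside (0, 1) — required because the
#' DCMS log term diverges at 0 and 1. Missing values are excluded from `n`
#' and returned as `NA`.
#'
#' @param values numeric statistic vector (larger = more extreme).
#' @return Numeric p-value vector of the same length.
#' @export
rank_pvalues <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing")
  n <- sum(ok)
  p <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  p[ok] <- 1 - (r - 0.5) / n
  p
}

#' Pairwise correlation matrix between signal tracks
#'
#' Pearson correlations between per-SNP statistic tracks, computed on
#' pairwise-complete observations. The caller passes the tracks on the scale
#' entering the composite (absolute-value transforms applied beforehand
#' where applicable).
#'
#' @param tracks data.frame or matrix, one column per signal.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
signal_correlation <- function(tracks) {
  m <- as.matrix(tracks)
  if (ncol(m) < 2L) stop("need at least 2 tracks")
  vars <- apply(m, 2L, stats::var, na.rm = TRUE)
  if (any(is.na(vars) | vars == 0)) {
    bad <- colnames(m)[which(is.na(vars) | vars == 0)[1L]]
    stop("track with zero variance: ", bad)
  }
  r <- stats::cor(m, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Decorrelated composite of multiple signals (DCMS)
#'
#' Combines per-track right-tailed p-values into one composite score per
#' locus: `DCMS_l = sum_t w_t log((1 - p_lt) / p_lt)` where the weight
#' `w_t = 1 / sum_i |r_it|` down-weights each statistic by its summed
#' absolute correlation with all statistics (self term included). A
#' duplicated signal therefore halves its weights instead of doubling its
#' contribution. Loci missing any track's p-value are emitted as `NA`
#' (complete-case); optionally missing p's can be imputed at the
#' uninformative value 0.5.
#'
#' @param P numeric matrix, loci x tracks, of p-values strictly in (0, 1).
#' @param r tracks x tracks correlation matrix (symmetric, unit diagonal).
#' @param impute_missing impute missing p-values at 0.5 instead of dropping
#'   the locus.
#' @return Numeric DCMS vector, one value per locus.
#' @export
dcms_score <- function(P, r, impute_missing = FALSE) {
  P <- as.matrix(P)
  r <- as.matrix(r)
  K <- ncol(P)
  if (!identical(dim(r), c(K, K))) stop("r must be K x K for K tracks")
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-8)) stop("r must have unit diagonal")
  if (any(P <= 0 | P >= 1, na.rm = TRUE))
    stop("p-values must lie strictly in (0, 1); clip external p explicitly")
  w <- 1 / colSums(abs(r))
  if (impute_missing) P[is.na(P)] <- 0.5
  terms <- log((1 - P) / P)
  out <- as.vector(terms %*% w)
  out[apply(P, 1L, anyNA)] <- NA_real_
  out
}

#' Empirical-normal p-values for DCMS scores
#'
#' Upper-tail normal probability of each score after standardizing by the
#' empirical mean and SD of the non-missing scores themselves (high DCMS =
#' candidate selection signal).
#'
#' @param dcms numeric DCMS vector (NA allowed).
#' @return Numeric p-value vector of the same length.
#' @export
empirical_pvalues <- function(dcms) {
  v <- dcms[!is.na(dcms)]
  if (length(v) < 2L) stop("need at least 2 non-missing DCMS values")
  s <- stats::sd(v)
  if (s == 0) stop("DCMS standard deviation is zero")
  stats::pnorm(dcms, mean = mean(v), sd = s, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) and the `q < alpha`
#' significance flag.
#'
#' @param p numeric p-value vector in (0, 1] (NA allowed).
#' @param alpha FDR level for the flags.
#' @return List with `q` (adjusted p-values) and `significant` (logical;
#'   `FALSE` where p is missing).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  q <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(q) & q < alpha
  list(q = q, significant = sig)
}
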