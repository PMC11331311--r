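#' Simulation configuration for two-population fixtures
#'
#' Bundles every knob of the synthetic-data generator: two diverged
#' populations with tunable differentiation (Balding-Nichols `fst_param`),
#' founder-mosaic background LD, optional hard-sweep injections and planted
#' homozygous segments, plus a seed for bit-identical replay.
#'
#' @param n_ind_per_pop individuals per population.
#' @param n_snps number of SNPs on the single simulated chromosome.
#' @param chrom_length chromosome length in bp.
#' @param fst_param Balding-Nichols differentiation parameter F in `[0, 1)`.
#' @param ancestral_freq_range range the per-SNP ancestral allele frequency is
#'   drawn from (uniform).
#' @param n_founders number of founder haplotypes the mosaic copies from.
#' @param switch_rate per-bp probability of switching founder between
#'   adjacent SNPs; smaller values mean longer shared haplotype blocks.
#' @param sweep_specs list of sweeps, each
#'   `list(pop = 1 or 2, core_bp = position, target_freq = carrier frequency)`.
#' @param roh_specs list of homozygous-segment plants, each
#'   `list(pop, frac = fraction of individuals, start_bp, end_bp)`.
#' @param missing_rate per-call probability of a missing genotype (applied to
#'   genotype matrices only; haplotypes stay complete).
#' @param chrom chromosome label.
#' @param seed integer seed; identical seed + config gives identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_ind_per_pop = 50, n_snps = 1000,
                       chrom_length = 5e6, fst_param = 0.1,
                       ancestral_freq_range = c(0.05, 0.95),
                       n_founders = 50, switch_rate = 2e-5,
                       sweep_specs = list(), roh_specs = list(),
                       missing_rate = 0, chrom = "1", seed = 1L) {
  stopifnot(fst_param >= 0, fst_param < 1,
            all(ancestral_freq_range > 0), all(ancestral_freq_range < 1),
            n_founders >= 1, switch_rate >= 0, n_snps >= 2,
            missing_rate >= 0, missing_rate < 1,
            n_ind_per_pop >= 1, chrom_length >= n_snps)
  for (s in sweep_specs)
    stopifnot(s$pop %in% 1:2, s$core_bp >= 1, s$core_bp <= chrom_length,
              s$target_freq > 0, s$target_freq < 1)
  for (r in roh_specs)
    stopifnot(r$pop %in% 1:2, r$frac > 0, r$frac <= 1,
              r$start_bp >= 1, r$end_bp <= chrom_length,
              r$start_bp <= r$end_bp)
  structure(list(n_ind_per_pop = as.integer(n_ind_per_pop),
                 n_snps = as.integer(n_snps),
                 chrom_length = as.integer(chrom_length),
                 fst_param = fst_param,
                 ancestral_freq_range = ancestral_freq_range,
                 n_founders = as.integer(n_founders),
                 switch_rate = switch_rate, sweep_specs = sweep_specs,
                 roh_specs = roh_specs, missing_rate = missing_rate,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "sim_config")
}

# Evenly spread, jittered, strictly increasing positions on [1, chrom_length].
sim_positions <- function(config) {
  L <- config$n_snps
  step <- config$chrom_length / L
  pos <- round((seq_len(L) - 0.5) * step +
                 stats::runif(L, -0.25, 0.25) * step)
  pos <- as.integer(pmin(pmax(pos, 1), config$chrom_length))
  # enforce strict increase after jitter
  while (any(diff(pos) <= 0L)) {
    i <- which(diff(pos) <= 0L) + 1L
    pos[i] <- pos[i - 1L] + 1L
  }
  pos
}

#' Simulate two diverged populations under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency `p` is drawn uniformly from
#' `ancestral_freq_range`; each population's frequency is then drawn from a
#' Beta distribution with mean `p` and variance `F p (1 - p)`, and genotypes
#' are sampled binomially per individual. Sites are unlinked (no LD): this
#' fixture exercises allele-frequency statistics, not haplotype statistics.
#' `fst_param = 0` degenerates to both populations sharing `p` exactly.
#'
#' @param config a [sim_config()].
#' @return List with `pop1`, `pop2` ([genotype_matrix()]s), `ancestral_freq`,
#'   `pop_freq` (2 x L matrix of realized population frequencies).
#' @export
sim_balding_nichols <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_snps
  n <- config$n_ind_per_pop
  Fst <- config$fst_param
  p <- stats::runif(L, config$ancestral_freq_range[1L],
                    config$ancestral_freq_range[2L])
  pos <- sim_positions(config)
  if (Fst == 0) {
    pk <- rbind(p, p)
  } else {
    shape <- (1 - Fst) / Fst
    pk <- rbind(stats::rbeta(L, p * shape, (1 - p) * shape),
                stats::rbeta(L, p * shape, (1 - p) * shape))
  }
  draw <- function(freq) {
    g <- matrix(stats::rbinom(n * L, 2L, rep(freq, each = n)), nrow = n)
    if (config$missing_rate > 0)
      g[stats::runif(n * L) < config$missing_rate] <- NA_integer_
    genotype_matrix(g, pos, config$chrom)
  }
  list(pop1 = draw(pk[1L, ]), pop2 = draw(pk[2L, ]),
       ancestral_freq = p, pop_freq = pk)
}

#' Simulate a phased panel with background LD from a founder mosaic
#'
#' Founder haplotypes are drawn per site from uniform ancestral frequencies;
#' each sample haplotype is then a mosaic of the founders, switching founder
#' between adjacent SNPs with probability `1 - exp(-switch_rate * gap_bp)`.
#' Small `switch_rate` yields long shared blocks (strong LD); large values
#' approach independent draws.
#'
#' @param config a [sim_config()]; `n_founders >= 2` required for a
#'   polymorphic panel.
#' @param n_haplotypes number of sample haplotypes (default
#'   `2 * n_ind_per_pop`).
#' @param positions optional pre-drawn bp positions (shared across
#'   populations by [sim_two_pop_fixture()]).
#' @param site_freq optional per-site allele frequencies the founders are
#'   drawn from (default: uniform in `ancestral_freq_range`).
#' @return A [haplotype_panel()]; founder haplotypes are attached as
#'   attribute `founders`.
#' @export
sim_mosaic_haplotypes <- function(config, n_haplotypes = NULL,
                                  positions = NULL, site_freq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$switch_rate < 0) stop("switch_rate must be >= 0")
  set.seed(config$seed)
  L <- config$n_snps
  K <- config$n_founders
  if (is.null(n_haplotypes)) n_haplotypes <- 2L * config$n_ind_per_pop
  pos <- if (is.null(positions)) sim_positions(config) else
    as.integer(positions)
  p <- if (is.null(site_freq))
    stats::runif(L, config$ancestral_freq_range[1L],
                 config$ancestral_freq_range[2L])
  else site_freq
  founders <- matrix(stats::rbinom(K * L, 1L, rep(p, each = K)), nrow = K)
  gaps <- diff(pos)
  p_switch <- 1 - exp(-config$switch_rate * gaps)
  A <- matrix(0L, nrow = n_haplotypes, ncol = L)
  for (h in seq_len(n_haplotypes)) {
    f <- integer(L)
    f[1L] <- sample.int(K, 1L)
    sw <- stats::runif(L - 1L) < p_switch
    new_f <- sample.int(K, L - 1L, replace = TRUE)
    for (j in 2L:L) f[j] <- if (sw[j - 1L]) new_f[j - 1L] else f[j - 1L]
    A[h, ] <- founders[cbind(f, seq_len(L))]
  }
  panel <- haplotype_panel(A, pos, config$chrom)
  if (K == 1L) attr(panel, "monomorphic") <- TRUE
  attr(panel, "founders") <- founders
  panel
}

#' Inject a hard sweep into a haplotype panel
#'
#' Emulates a recent hard sweep: one carrier haplotype of the core allele is
#' chosen as donor and its alleles over `[core - flank_bp, core + flank_bp]`
#' are copied onto randomly chosen non-carrier haplotypes until the carrier
#' fraction of the core allele reaches `target_freq`. This produces the long
#' shared haplotype around a high-frequency allele that EHH-based statistics
#' detect. Sites outside the flank window are never altered, and the core
#' allele frequency never decreases.
#'
#' With `taper_bp` set, each recipient copies the donor over its own random
#' interval around the core, with exponentially distributed one-sided
#' lengths (mean `taper_bp`, truncated at `flank_bp`). This mimics
#' recombination during the sweep: the shared haplotype is longest at the
#' core and frays outward, so haplotype statistics peak at the core instead
#' of forming a plateau over a rectangular block.
#'
#' @param panel a [haplotype_panel()].
#' @param core_index column index of the core SNP.
#' @param target_freq desired carrier fraction of the core allele in `(0,1)`.
#' @param flank_bp half-width of the copied window in bp.
#' @param allele core allele to sweep (default 1, the derived/ALT allele).
#' @param taper_bp mean one-sided copied length in bp (`NULL` = no taper:
#'   every recipient copies the full flank).
#' @param seed integer seed for donor/recipient choice.
#' @return List with `panel` (modified) and `truth`: a one-row data.frame
#'   (core_index, core_bp, allele, target_freq, realized_freq, flank_bp,
#'   swept). `swept` is `FALSE` (no-op, with a warning) when the allele
#'   already exceeds `target_freq`.
#' @export
inject_sweep <- function(panel, core_index, target_freq, flank_bp = Inf,
                         allele = 1L, taper_bp = NULL, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"),
            target_freq > 0, target_freq < 1)
  set.seed(seed)
  A <- panel$alleles
  n_hap <- nrow(A)
  carriers <- which(A[, core_index] == allele)
  if (length(carriers) == 0L) stop("core SNP not segregating for the allele")
  need <- ceiling(target_freq * n_hap)
  truth <- function(realized, swept)
    data.frame(core_index = core_index, core_bp = panel$positions[core_index],
               allele = allele, target_freq = target_freq,
               realized_freq = realized, flank_bp = flank_bp, swept = swept)
  if (length(carriers) >= need) {
    warning("core allele already at or above target frequency; no-op")
    return(list(panel = panel,
                truth = truth(length(carriers) / n_hap, FALSE)))
  }
  donor <- carriers[sample.int(length(carriers), 1L)]
  recipients <- sample(setdiff(seq_len(n_hap), carriers),
                       need - length(carriers))
  on_chrom <- panel$chrom == panel$chrom[core_index]
  offset <- panel$positions - panel$positions[core_index]
  if (is.null(taper_bp)) {
    win <- which(on_chrom & abs(offset) <= flank_bp)
    A[recipients, win] <- rep(A[donor, win], each = length(recipients))
  } else {
    for (h in recipients) {
      ext <- pmin(stats::rexp(2L, 1 / taper_bp), flank_bp)
      win <- which(on_chrom & offset >= -ext[1L] & offset <= ext[2L])
      A[h, win] <- A[donor, win]
    }
  }
  panel$alleles <- A
  realized <- sum(A[, core_index] == allele) / n_hap
  list(panel = panel, truth = truth(realized, TRUE))
}

#' Plant homozygous segments into a genotype matrix
#'
#' Makes the listed individuals homozygous over a bp interval, fixing each
#' site at its per-site major allele — the footprint a runs-of-homozygosity
#' caller should recover. An empty individual list is an identity.
#'
#' @param G a [genotype_matrix()].
#' @param individuals integer indices (or sample ids) of individuals.
#' @param interval length-2 bp vector `c(start, end)`, inclusive.
#' @param chrom chromosome the interval lies on (default first).
#' @return The modified [genotype_matrix()].
#' @export
plant_roh <- function(G, individuals, interval, chrom = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), length(interval) == 2L,
            interval[1L] <= interval[2L])
  if (is.character(individuals))
    individuals <- match(individuals, G$samples)
  if (length(individuals) == 0L) return(G)
  if (is.null(chrom)) chrom <- G$chrom[1L]
  j <- which(G$chrom == chrom & G$positions >= interval[1L] &
               G$positions <= interval[2L])
  if (length(j) == 0L) return(G)
  freq <- colMeans(G$genotypes[, j, drop = FALSE], na.rm = TRUE) / 2
  major <- ifelse(freq >= 0.5, 2L, 0L)
  G$genotypes[individuals, j] <- rep(major, each = length(individuals))
  G
}

#' Generate a full two-population fixture with truth tables
#'
#' Draws one shared site index and per-SNP ancestral frequencies, then per
#' population draws Balding-Nichols-differentiated site frequencies
#' (variance `fst_param * p (1 - p)`) and an independent founder mosaic, so
#' the two panels share positions but differ in allele frequencies and
#' haplotype structure. Every sweep in `sweep_specs` is applied to its
#' target population, genotypes are collapsed from the haplotypes, every ROH
#' spec is planted, and the truth tables downstream tests score against are
#' returned.
#'
#' @param config a [sim_config()].
#' @return List with `panel1`, `panel2` (phased [haplotype_panel()]s),
#'   `geno1`, `geno2` ([genotype_matrix()]s), `sweep_truth` (data.frame with
#'   a `pop` column), `roh_truth` (data.frame: pop, individual ids
#'   semicolon-joined, start_bp, end_bp).
#' @export
sim_two_pop_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pos <- sim_positions(config)
  p_anc <- stats::runif(config$n_snps, config$ancestral_freq_range[1L],
                        config$ancestral_freq_range[2L])
  pop_freq <- function() {
    if (config$fst_param == 0) return(p_anc)
    shape <- (1 - config$fst_param) / config$fst_param
    stats::rbeta(config$n_snps, p_anc * shape, (1 - p_anc) * shape)
  }
  freqs <- list(pop_freq(), pop_freq())
  make_pop <- function(k) {
    cfg <- config
    cfg$seed <- config$seed + k * 1000L
    sim_mosaic_haplotypes(cfg, positions = pos, site_freq = freqs[[k]])
  }
  panels <- list(make_pop(1L), make_pop(2L))
  sweep_truth <- NULL
  for (i in seq_along(config$sweep_specs)) {
    s <- config$sweep_specs[[i]]
    pnl <- panels[[s$pop]]
    # emulate selection on a recent mutation: among SNPs within 100 kb of
    # the requested core, sweep the one whose minor allele is rarest (but
    # still segregating), so nearly all post-sweep carriers share the donor
    # haplotype -- the hard-sweep footprint EHH statistics are built for
    near <- which(abs(pnl$positions - s$core_bp) <= 1e5)
    maf <- pmin(colMeans(pnl$alleles[, near, drop = FALSE]),
                1 - colMeans(pnl$alleles[, near, drop = FALSE]))
    cand <- near[maf > 0]
    core <- cand[which.min(maf[maf > 0])]
    # default flank 100 kb with a 30 kb exponential taper: the swept
    # haplotype is shared at high frequency near the core and frays
    # outward, so haplotype statistics peak at the core while the sweep
    # occupies only a few percent of the chromosome
    flank <- if (is.null(s$flank_bp)) 1e5 else s$flank_bp
    taper <- if (is.null(s$taper_bp)) 3e4 else s$taper_bp
    al <- if (mean(pnl$alleles[, core]) <= 0.5) 1L else 0L
    res <- inject_sweep(pnl, core, s$target_freq, flank, allele = al,
                        taper_bp = taper, seed = config$seed + 77L * i)
    panels[[s$pop]] <- res$panel
    sweep_truth <- rbind(sweep_truth, cbind(pop = s$pop, res$truth))
  }
  genos <- lapply(panels, hap_to_geno)
  if (config$missing_rate > 0) {
    set.seed(config$seed + 5L)
    for (k in 1:2) {
      g <- genos[[k]]$genotypes
      g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
      genos[[k]]$genotypes <- g
    }
  }
  roh_truth <- NULL
  for (i in seq_along(config$roh_specs)) {
    r <- config$roh_specs[[i]]
    set.seed(config$seed + 31L * i)
    n <- config$n_ind_per_pop
    ids <- sort(sample.int(n, round(r$frac * n)))
    genos[[r$pop]] <- plant_roh(genos[[r$pop]], ids,
                                c(r$start_bp, r$end_bp))
    roh_truth <- rbind(roh_truth,
                       data.frame(pop = r$pop,
                                  individuals = paste(ids, collapse = ";"),
                                  start_bp = r$start_bp, end_bp = r$end_bp))
  }
  list(panel1 = panels[[1L]], panel2 = panels[[2L]],
       geno1 = genos[[1L]], geno2 = genos[[2L]],
       sweep_truth = sweep_truth, roh_truth = roh_truth)
}
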