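#' Full per-breed selection scan
#'
#' Orchestrates the whole scan for one focal breed against a reference
#' breed: site intersection, per-SNP autozygosity from ROH calls, smoothed
#' |iHS|, smoothed per-SNP FST, |XP-EHH|, right-tailed fractional-rank
#' p-values, signal correlation, DCMS, empirical-normal p-values, BH FDR,
#' and merging/annotation of significant regions.
#'
#' Tracks entering the composite (all oriented so large = candidate
#' selection in the focal breed): the focal breed's autozygosity, the focal
#' breed's smoothed absolute standardized iHS, the smoothed two-population
#' FST, and the absolute standardized XP-EHH (focal vs reference). A track
#' that is constant over the shared sites (e.g. an all-zero autozygosity
#' track when no ROH are called) carries no ranking information and is
#' dropped from the composite with a log note.
#'
#' @param panel_focal,panel_ref phased [haplotype_panel()]s for the focal
#'   and reference populations.
#' @param genes optional gene annotation data.frame
#'   ([read_gene_annotation()]).
#' @param roh_par [roh_params()] for the ROH stage.
#' @param smooth_k odd running-median window (SNPs) for |iHS| and FST.
#' @param smooth_xpehh also smooth the |XP-EHH| track (default off).
#' @param decay_cutoff,n_freq_bins,maf_min,cm_per_mb passed to the EHH
#'   stages.
#' @param alpha FDR significance level.
#' @param max_gap region-merge threshold in bp.
#' @param impute_missing impute missing per-track p-values at 0.5 instead of
#'   dropping the locus from the composite.
#' @param out_dir optional directory; when given, all intermediate tracks,
#'   the per-SNP table, the regions table (TSV and BED) and the log are
#'   written there.
#' @return List with `snp_table` (per-SNP data.frame: chrom, pos, the four
#'   tracks, per-track p, dcms, p, q, significant), `regions`, `summary`,
#'   `cor_matrix`, `dropped_tracks` and `log` (character vector).
#' @export
run_breed_scan <- function(panel_focal, panel_ref, genes = NULL,
                           roh_par = roh_params(), smooth_k = 1001,
                           smooth_xpehh = FALSE, decay_cutoff = 0.05,
                           n_freq_bins = 50, maf_min = 0.05, cm_per_mb = 1,
                           alpha = 0.05, max_gap = 1e6,
                           impute_missing = FALSE, out_dir = NULL) {
  log <- character()
  note <- function(stage, msg) {
    line <- sprintf("%s\t%s\t%s", stage, format(Sys.time(), "%H:%M:%S"), msg)
    log <<- c(log, line)
  }
  stage <- "intersect"
  res <- tryCatch({
    shared <- intersect_sites(panel_focal, panel_ref)
    note(stage, sprintf("%d shared sites (%d dropped for allele mismatch)",
                        nrow(shared$sites), shared$n_dropped))
    pf <- shared$a
    pr <- shared$b
    sites <- shared$sites
    L <- nrow(sites)
    gf <- hap_to_geno(pf)
    gr <- hap_to_geno(pr)

    stage <- "roh"
    segs <- detect_roh(gf, roh_par)
    auto <- autozygosity(segs, sites, length(gf$samples))
    note(stage, sprintf("%d segments called; mean autozygosity %.4f",
                        nrow(segs), mean(auto)))

    stage <- "ihs"
    ihs <- ihs_scan(pf, decay_cutoff = decay_cutoff,
                    n_freq_bins = n_freq_bins, maf_min = maf_min,
                    cm_per_mb = cm_per_mb)
    ihs_abs <- abs(ihs$ihs_std)
    ihs_sm <- running_median(ihs_abs, min(smooth_k, .odd_floor(L)))
    note(stage, sprintf("%d valid iHS of %d sites", sum(ihs$valid), L))

    stage <- "fst"
    ft <- fst_per_snp(allele_frequencies(gf), allele_frequencies(gr))
    fst_sm <- running_median(ft$fst, min(smooth_k, .odd_floor(L)))
    note(stage, sprintf("%d sites masked (monomorphic baseline)",
                        sum(ft$mask)))

    stage <- "xpehh"
    xp <- xpehh_scan(pf, pr, decay_cutoff = decay_cutoff,
                     cm_per_mb = cm_per_mb)
    xp_abs <- abs(xp$xpehh_std)
    if (smooth_xpehh)
      xp_abs <- running_median(xp_abs, min(smooth_k, .odd_floor(L)))
    note(stage, sprintf("%d valid XP-EHH of %d sites", sum(xp$valid), L))

    stage <- "composite"
    tracks <- data.frame(autozygosity = auto, ihs_abs_sm = ihs_sm,
                         fst_sm = fst_sm, xpehh_abs = xp_abs)
    const <- vapply(tracks, function(x) {
      v <- stats::var(x, na.rm = TRUE); is.na(v) || v == 0
    }, logical(1L))
    dropped <- names(tracks)[const]
    if (length(dropped) > 0L)
      note(stage, paste("dropped constant track(s):",
                        paste(dropped, collapse = ", ")))
    use <- tracks[, !const, drop = FALSE]
    if (ncol(use) < 2L) stop("fewer than 2 informative tracks")
    P <- vapply(use, rank_pvalues, numeric(L))
    r <- signal_correlation(use)
    dcms <- dcms_score(P, r, impute_missing = impute_missing)
    p <- empirical_pvalues(dcms)
    fdr <- bh_fdr(p, alpha)
    note(stage, sprintf("%d significant SNPs at q < %g",
                        sum(fdr$significant), alpha))

    stage <- "regions"
    regions <- merge_regions(sites, fdr$significant, max_gap)
    if (!is.null(genes)) regions <- annotate_regions(regions, genes)
    summ <- summarize_regions(regions)
    note(stage, sprintf("%d regions, total %.0f bp", summ$n_regions,
                        summ$total_length_bp))

    snp_table <- cbind(sites, tracks,
                       as.data.frame(P, col.names = paste0("p_", colnames(P))),
                       data.frame(dcms = dcms, p = p, q = fdr$q,
                                  significant = fdr$significant))
    names(snp_table)[seq_len(ncol(P)) + ncol(sites) + ncol(tracks)] <-
      paste0("p_", colnames(P))
    list(snp_table = snp_table, regions = regions, summary = summ,
         cor_matrix = r, dropped_tracks = dropped, log = log,
         roh_segments = segs)
  }, error = function(e) {
    stop(sprintf("scan failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$snp_table, file.path(out_dir, "snp_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$regions) > 0L)
      write_regions_bed(res$regions, file.path(out_dir, "regions.bed"))
    utils::write.table(res$roh_segments,
                       file.path(out_dir, "roh_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$log, file.path(out_dir, "scan.log"))
  }
  res
}

.odd_floor <- function(n) if (n %% 2L == 1L) n else n - 1L

#' Generate and write a complete simulated fixture set
#'
#' Runs [sim_two_pop_fixture()] and writes, per population, a phased VCF and
#' a PLINK fileset, plus TSV truth tables and a YAML copy of the
#' configuration. Identical seed + config gives byte-identical text outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return The fixture list from [sim_two_pop_fixture()], invisibly, with a
#'   `files` element listing the written paths.
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- sim_two_pop_fixture(config)
  files <- c(pop1_vcf = file.path(out_dir, "pop1.vcf"),
             pop2_vcf = file.path(out_dir, "pop2.vcf"),
             pop1_plink = file.path(out_dir, "pop1"),
             pop2_plink = file.path(out_dir, "pop2"),
             sweep_truth = file.path(out_dir, "sweep_truth.tsv"),
             roh_truth = file.path(out_dir, "roh_truth.tsv"),
             config = file.path(out_dir, "config.yaml"))
  write_vcf_haplotypes(fx$panel1, files[["pop1_vcf"]])
  write_vcf_haplotypes(fx$panel2, files[["pop2_vcf"]])
  write_plink(fx$geno1, files[["pop1_plink"]])
  write_plink(fx$geno2, files[["pop2_plink"]])
  st <- fx$sweep_truth
  if (is.null(st)) st <- data.frame()
  utils::write.table(st, files[["sweep_truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rt <- fx$roh_truth
  if (is.null(rt)) rt <- data.frame()
  utils::write.table(rt, files[["roh_truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(config), files[["config"]])
  fx$files <- files
  invisible(fx)
}
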