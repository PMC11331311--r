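#' Merge significant SNPs into genomic regions
#'
#' Chains consecutive significant SNPs whose inter-SNP distance is strictly
#' below `max_gap`; each maximal chain becomes one region spanning its first
#' to last SNP (1-based inclusive). Chains never cross chromosomes. A gap of
#' exactly `max_gap` does not merge. Region length is `end - start + 1` bp,
#' so a single-SNP region has length 1.
#'
#' @param sites data.frame with `chrom` and `pos` (sorted within chromosome).
#' @param flags logical significance vector aligned to `sites`.
#' @param max_gap merge threshold in bp (default 1 Mb).
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `length_bp`;
#'   empty when no SNP is significant.
#' @export
merge_regions <- function(sites, flags, max_gap = 1e6) {
  stopifnot(nrow(sites) == length(flags))
  keep <- which(flags %in% TRUE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      length_bp = numeric(), stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(empty)
  chrom <- sites$chrom[keep]
  pos <- sites$pos[keep]
  new_chain <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                   diff(pos) >= max_gap)
  chain <- cumsum(new_chain)
  out <- do.call(rbind, lapply(split(seq_along(chain), chain), function(i) {
    data.frame(chrom = chrom[i[1L]], start = min(pos[i]), end = max(pos[i]),
               n_snps = length(i),
               length_bp = max(pos[i]) - min(pos[i]) + 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Annotate regions with overlapping genes
#'
#' Assigns a gene to a region when their 1-based inclusive intervals share at
#' least one bp (overlap computed with `GenomicRanges::findOverlaps`).
#' Genes are listed in genomic order, semicolon-joined. A warning reports
#' chromosome names present in only one of the inputs.
#'
#' @param regions data.frame from [merge_regions()].
#' @param genes data.frame from [read_gene_annotation()].
#' @return `regions` with added columns `n_genes` and `genes`.
#' @export
annotate_regions <- function(regions, genes) {
  regions$n_genes <- integer(nrow(regions))
  regions$genes <- character(nrow(regions))
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(regions)
  only_r <- setdiff(unique(regions$chrom), unique(genes$chrom))
  only_g <- setdiff(unique(genes$chrom), unique(regions$chrom))
  if (length(only_r) > 0L)
    warning(length(only_r),
            " region chromosome(s) absent from the annotation")
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start, regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(regions))) {
    g <- sh[qh == i]
    g <- g[order(genes$start[g])]
    regions$n_genes[i] <- length(g)
    regions$genes[i] <- paste(genes$gene_id[g], collapse = ";")
  }
  regions
}

#' Summarize a set of selected regions
#'
#' @param regions data.frame from [merge_regions()] (optionally annotated).
#' @return Named list: region count, total/mean/SD length (bp; SD `NA` for a
#'   single region), per-chromosome counts, and the distinct gene count when
#'   a `genes` column is present.
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0L)
    return(list(n_regions = 0L, total_length_bp = 0, mean_length_bp = NA,
                sd_length_bp = NA, per_chrom = table(character()),
                n_genes_distinct = 0L))
  len <- regions$length_bp
  genes <- if ("genes" %in% names(regions))
    unique(unlist(strsplit(regions$genes[nzchar(regions$genes)], ";")))
  else character()
  list(n_regions = nrow(regions),
       total_length_bp = sum(len),
       mean_length_bp = mean(len),
       sd_length_bp = if (length(len) > 1L) stats::sd(len) else NA,
       per_chrom = table(regions$chrom),
       n_genes_distinct = length(genes))
}

#' Export regions as a BED file
#'
#' Converts the 1-based inclusive regions to 0-based half-open BED lines.
#'
#' @param regions data.frame from [merge_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   sprintf("region%03d", seq_len(nrow(regions))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
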