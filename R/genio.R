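#' Read phased haplotypes from a VCF file
#'
#' Loads biallelic SNP records with phased GT fields into a
#' [haplotype_panel()]. Multiallelic records are always skipped (with a
#' count); unphased genotypes either abort (`strict = TRUE`, naming the first
#' offending record) or cause the record to be skipped.
#'
#' @param path VCF file (plain text or gzipped).
#' @param strict error on unphased GT instead of skipping the record.
#' @return A [haplotype_panel()]; skipped-record counts are attached as
#'   attribute `skipped` (named integer vector).
#' @export
read_vcf_haplotypes <- function(path, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | fix[, "ALT"] == "." |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  phased <- apply(gt, 1L, function(r) all(grepl("|", r, fixed = TRUE)))
  if (strict && any(!phased & !multi)) {
    bad <- which(!phased & !multi)[1L]
    stop(sprintf("unphased GT at record %s:%s in strict mode",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  keep <- !multi & phased
  skipped <- c(multiallelic = sum(multi), unphased = sum(!phased & !multi))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  n_ind <- ncol(gt)
  L <- nrow(gt)
  alleles <- matrix(0L, nrow = 2L * n_ind, ncol = L)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  alleles[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(as.integer(a1 == "1"),
                                                      nrow = L))
  alleles[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(as.integer(a2 == "1"),
                                                      nrow = L))
  panel <- haplotype_panel(alleles, as.integer(fix[, "POS"]), fix[, "CHROM"],
                           colnames(gt), fix[, "REF"], fix[, "ALT"])
  attr(panel, "skipped") <- skipped
  panel
}

#' Write a haplotype panel as a phased VCF 4.2 file
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_haplotypes <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_ind <- length(panel$samples)
  i1 <- seq(1L, 2L * n_ind, by = 2L)
  gt <- matrix(paste0(t(panel$alleles[i1, , drop = FALSE]), "|",
                      t(panel$alleles[i1 + 1L, , drop = FALSE])),
               nrow = ncol(panel$alleles))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  body <- paste(panel$chrom, panel$positions,
                paste0("snp", seq_along(panel$positions)),
                panel$ref, panel$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as a PLINK .bed/.bim/.fam fileset
#'
#' SNP-major PLINK 1 binary layout. Allele codes: A1 = ALT, A2 = REF, so the
#' stored genotype counts the ALT allele, matching the internal 0/1/2 coding.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  bim <- data.frame(chrom = G$chrom, id = paste0("snp", seq_along(G$positions)),
                    cm = 0, pos = G$positions, a1 = G$alt, a2 = G$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$samples, iid = G$samples, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # PLINK 2-bit codes indexed by dosage 0/1/2; NA -> 01 (missing)
  code <- c(`0` = 0L, `1` = 2L, `2` = 3L)
  n <- nrow(G$genotypes)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(ncol(G$genotypes))) {
    g <- G$genotypes[, j]
    bits <- ifelse(is.na(g), 1L, code[as.character(g)])
    pad <- (-n) %% 4L
    bits <- c(bits, rep(0L, pad))
    m <- matrix(bits, nrow = 4L)
    bytes <- m[1L, ] + m[2L, ] * 4L + m[3L, ] * 16L + m[4L, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Supports the SNP-major PLINK 1 binary format only. Genotypes are returned
#' as the count of the .bim A1 allele.
#'
#' @param prefix path prefix of the fileset.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  n <- nrow(fam)
  L <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n / 4) * L)
  if (!identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01))))
    stop("not a SNP-major PLINK 1 .bed file")
  body <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  geno <- matrix(NA_integer_, nrow = n, ncol = L)
  # decode 2-bit fields: 00=hom A1(2 copies? no: 00 = hom minor/A1... ) --
  # PLINK: 00 hom A1 -> dosage 0 under our write (code 0 for dosage 0),
  # 10 -> het, 11 -> hom A2, 01 -> missing; invert write mapping
  look <- c(0L, NA_integer_, 1L, 2L)
  for (j in seq_len(L)) {
    bytes <- body[((j - 1L) * bpv + 1L):(j * bpv)]
    q <- c(bytes %% 4L, (bytes %/% 4L) %% 4L, (bytes %/% 16L) %% 4L,
           (bytes %/% 64L) %% 4L)
    q <- matrix(q, ncol = 4L)
    vals <- as.vector(t(q))[seq_len(n)]
    geno[, j] <- look[vals + 1L]
  }
  genotype_matrix(geno, bim[[4L]], bim[[1L]], fam[[2L]],
                  ref = bim[[6L]], alt = bim[[5L]])
}

#' Restrict two panels to their shared sites
#'
#' Matches sites on chromosome + position, harmonizes the allele encoding on
#' REF/ALT strings (a site with swapped REF/ALT in one panel has that panel's
#' alleles flipped so allele 1 refers to the same nucleotide in both), and
#' drops (or errors on, in strict mode) sites whose allele pairs cannot be
#' reconciled. Strand flips are not supported.
#'
#' @param a,b two [haplotype_panel()] or [genotype_matrix()] objects.
#' @param strict error on irreconcilable alleles instead of dropping the site.
#' @return List with elements `a`, `b` (subset, harmonized), `sites`
#'   (data.frame of shared chrom/pos) and `n_dropped` (allele mismatches).
#' @export
intersect_sites <- function(a, b, strict = FALSE) {
  key_a <- paste(a$chrom, a$positions)
  key_b <- paste(b$chrom, b$positions)
  m <- match(key_a, key_b)
  ia <- which(!is.na(m))
  ib <- m[ia]
  same <- a$ref[ia] == b$ref[ib] & a$alt[ia] == b$alt[ib]
  swap <- a$ref[ia] == b$alt[ib] & a$alt[ia] == b$ref[ib]
  bad <- !(same | swap)
  if (any(bad) && strict)
    stop(sprintf("allele mismatch at %s:%d", a$chrom[ia[bad][1L]],
                 a$positions[ia[bad][1L]]))
  keep <- !bad
  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]
  a2 <- subset_sites(a, ia)
  b2 <- subset_sites(b, ib)
  if (any(swap)) {
    if (inherits(b2, "haplotype_panel")) {
      b2$alleles[, swap] <- 1L - b2$alleles[, swap]
    } else {
      b2$genotypes[, swap] <- 2L - b2$genotypes[, swap]
    }
    r <- b2$ref[swap]; b2$ref[swap] <- b2$alt[swap]; b2$alt[swap] <- r
  }
  list(a = a2, b = b2,
       sites = data.frame(chrom = a2$chrom, pos = a2$positions,
                          stringsAsFactors = FALSE),
       n_dropped = sum(bad))
}

#' Read gene annotation intervals
#'
#' Reads gene intervals from BED (0-based half-open) or GFF3 (1-based
#' inclusive) and unifies them to 1-based inclusive internal coordinates.
#' For GFF3 only records of type `gene` are kept; the gene id is taken from
#' the `Name` attribute, falling back to `ID`.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"` (default guessed from the extension).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("gene%05d", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    ids <- as.character(gr$Name)
    if (all(is.na(ids)) || is.null(gr$Name)) ids <- as.character(gr$ID)
  }
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start))
    stop("annotation line ", which(out$end < out$start)[1L],
         ": end < start after coordinate conversion")
  out
}

#' Write a per-SNP track as TSV
#'
#' @param sites data.frame with `chrom` and `pos` columns.
#' @param values named list or data.frame of per-SNP value columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(sites, values, path) {
  df <- cbind(sites[, c("chrom", "pos")], as.data.frame(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
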