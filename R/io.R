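#' Read a phased VCF into a haplotype panel
#'
#' Reads a single-chromosome VCF of phased diploid genotypes and returns a
#' [haplotype_panel()] with two haplotypes per sample. Records declared
#' multi-allelic (more than one ALT allele) are removed, and sites whose
#' minor allele frequency is at or below `maf_threshold` are filtered out.
#'
#' Missing genotypes are not supported: panels are assumed complete and
#' phased, and a record with a missing or unphased GT is an error naming the
#' record (no imputation is attempted).
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param map optional [genetic_map()] used to annotate genetic positions by
#'   linear interpolation. When `NULL`, a neutral 1 cM/Mb map is assumed.
#' @param maf_threshold sites with MAF less than or equal to this value are
#'   removed (default 0.01); set to a negative value to keep all sites.
#' @return A [haplotype_panel()].
#' @export
read_vcf <- function(path, map = NULL, maf_threshold = 0.01) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  if (nrow(gt) == 0L) stop("VCF contains no records")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- unique(as.character(GenomeInfoDb::seqnames(rr)))
  if (length(chroms) > 1L)
    stop("multi-chromosome VCF: found ", paste(chroms, collapse = ", "),
         "; read one chromosome per call")
  pos <- GenomicRanges::start(rr)
  rec <- rownames(gt)
  if (is.null(rec)) rec <- sprintf("%s:%d", chroms, pos)

  multi <- lengths(VariantAnnotation::alt(vcf)) > 1L
  if (any(multi)) {
    gt <- gt[!multi, , drop = FALSE]
    pos <- pos[!multi]
    rec <- rec[!multi]
  }
  if (nrow(gt) == 0L) stop("no bi-allelic records left after removing multi-allelic sites")

  bad_missing <- which(apply(gt, 1L, function(g) any(g %in% c(".", "./.", ".|."))))
  if (length(bad_missing))
    stop("missing GT in record ", rec[bad_missing[1L]], " (no imputation)")
  bad_unphased <- which(apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE))))
  if (length(bad_unphased))
    stop("unphased genotype in record ", rec[bad_unphased[1L]])
  bad_multi <- which(apply(gt, 1L, function(g) any(grepl("[2-9]", g))))
  if (length(bad_multi))
    stop("multi-allelic genotype code in record ", rec[bad_multi[1L]])

  samples <- colnames(gt)
  n <- nrow(gt); ns <- length(samples)
  # gt entries are "x|y"; expand to an (2*ns) x n matrix, haplotype-major
  h0 <- substr(gt, 1L, 1L)
  h1 <- substr(gt, 3L, 3L)
  alleles <- matrix(0L, nrow = 2L * ns, ncol = n)
  alleles[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(as.integer(h0), nrow = n))
  alleles[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(as.integer(h1), nrow = n))

  ord <- order(pos)
  pos <- pos[ord]
  alleles <- alleles[, ord, drop = FALSE]

  f1 <- colMeans(alleles)
  maf <- pmin(f1, 1 - f1)
  keep <- maf > maf_threshold
  if (!any(keep)) stop("all sites filtered out at MAF threshold ", maf_threshold)
  alleles <- alleles[, keep, drop = FALSE]
  pos <- pos[keep]

  cm <- if (is.null(map)) pos * 1e-6 else interpolate_cm(map, pos)
  hap_ids <- as.vector(rbind(paste0(samples, "_0"), paste0(samples, "_1")))
  haplotype_panel(alleles, pos, cm, hap_ids)
}

#' Write a haplotype panel as a phased VCF
#'
#' Serializes a panel as a minimal VCFv4.2 file with one phased diploid
#' sample per haplotype pair (haplotypes `2i`, `2i+1` become sample `i`).
#' Round-trips through [read_vcf()] losslessly for alleles and positions.
#'
#' @param panel a [haplotype_panel()] with an even number of haplotypes.
#' @param path output file path.
#' @param chrom chromosome name written in the CHROM column.
#' @export
write_vcf <- function(panel, path, chrom = "1") {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- panel$n_haps
  if (m %% 2L != 0L) stop("panel must have an even number of haplotypes to pair into samples")
  samples <- unique(sub("_[01]$", "", panel$hap_ids))
  if (length(samples) != m / 2L) samples <- sprintf("S%d", seq_len(m / 2L))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  g0 <- panel$alleles[seq(1L, m, by = 2L), , drop = FALSE]
  g1 <- panel$alleles[seq(2L, m, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(g0, "|", g1), nrow = m / 2L) # samples x sites
  body <- vapply(seq_len(panel$n_sites), function(j) {
    paste(c(chrom, panel$site_bp[j], ".", "A", "G", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genetic map
#'
#' Supported dialects: `"hapmap"` (whitespace-separated columns
#' `chromosome position rate cM`, or `position rate cM`, with or without a
#' header line) and `"plink"` (`.map`: `chromosome id cM bp`).
#'
#' @param path path to the map file.
#' @param dialect one of `"hapmap"`, `"plink"`.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = c("hapmap", "plink")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty genetic map file: ", path)
  fields <- strsplit(trimws(first), "\\s+")[[1L]]
  # plink's second column is a marker id; sniff the header on a column that
  # must be numeric in each dialect
  probe <- if (dialect == "plink") fields[4L] else fields[2L]
  has_header <- is.na(suppressWarnings(as.numeric(probe)))
  tab <- utils::read.table(path, header = FALSE, skip = as.integer(has_header),
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty genetic map file: ", path)
  if (dialect == "hapmap") {
    if (ncol(tab) >= 4L && !is.numeric(tab[[1L]])) {
      bp <- tab[[2L]]; cm <- tab[[4L]]
    } else if (ncol(tab) >= 4L && is.numeric(tab[[1L]])) {
      # chrom coded numerically: fall back on column count
      bp <- tab[[2L]]; cm <- tab[[4L]]
    } else if (ncol(tab) == 3L) {
      bp <- tab[[1L]]; cm <- tab[[3L]]
    } else stop("unrecognized hapmap-style map layout (", ncol(tab), " columns)")
  } else {
    if (ncol(tab) < 4L) stop("plink .map needs 4 columns: chrom id cM bp")
    bp <- tab[[4L]]; cm <- tab[[3L]]
  }
  ord <- order(bp)
  genetic_map(bp[ord], cm[ord])
}

.ibd_cols <- c("query_hap", "panel_hap", "start_site", "end_site",
               "start_bp", "end_bp", "cm_length")

#' Write reported IBD segments
#'
#' Tab-separated table with header columns `query_hap`, `panel_hap`,
#' `start_site`, `end_site`, `start_bp`, `end_bp`, `cm_length`. Site indices
#' are 0-based and end-inclusive; bp positions are 1-based as in VCF. Rows
#' are written as-is: duplicate or overlapping segments are not silently
#' deduplicated.
#'
#' @param segments data frame of IBD segments (e.g. from [ibd_query()]).
#' @param path output file path.
#' @export
write_ibd <- function(segments, path) {
  miss <- setdiff(.ibd_cols, names(segments))
  if (length(miss)) stop("segments lack columns: ", paste(miss, collapse = ", "))
  utils::write.table(segments[, .ibd_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IBD segment table written by [write_ibd()]
#'
#' @param path path to the TSV file.
#' @return data frame with the seven segment columns.
#' @export
read_ibd <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer",
                                          "integer", "numeric", "numeric",
                                          "numeric"))
  if (!identical(names(tab), .ibd_cols))
    stop("not an IBD table: header mismatch in ", path)
  for (col in c("start_bp", "end_bp"))
    if (all(tab[[col]] == as.integer(tab[[col]]), na.rm = TRUE) &&
        all(abs(tab[[col]]) < .Machine$integer.max))
      tab[[col]] <- as.integer(tab[[col]])
  tab
}
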