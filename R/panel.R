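#' Phased haplotype panel
#'
#' Container for a panel of `m` phased haplotypes over `n` bi-allelic sites.
#' Rows of `alleles` are haplotypes, columns are sites in ascending physical
#' position. Site indices used throughout the package (match and IBD tables)
#' are 0-based and end-inclusive; physical positions are 1-based as in VCF.
#'
#' @param alleles integer matrix of 0/1 values, `m` haplotypes x `n` sites.
#' @param site_bp integer vector of physical positions (bp), strictly
#'   increasing.
#' @param site_cm numeric vector of genetic positions (cM), non-decreasing.
#' @param hap_ids character vector of haplotype identifiers, conventionally
#'   `<sample>_0` / `<sample>_1` for the two phases of a diploid sample.
#'
#' @return An object of class `haplotype_panel`: a list with fields
#'   `alleles`, `site_bp`, `site_cm`, `hap_ids`, `maf` (per-site minor allele
#'   frequency, recomputed from `alleles`), `n_haps`, `n_sites`.
#' @export
haplotype_panel <- function(alleles, site_bp, site_cm, hap_ids = NULL) {
  if (!is.matrix(alleles)) alleles <- matrix(alleles, nrow = 1L)
  storage.mode(alleles) <- "integer"
  m <- nrow(alleles); n <- ncol(alleles)
  if (m < 1L || n < 1L) stop("panel must have at least one haplotype and one site")
  if (anyNA(alleles) || any(alleles != 0L & alleles != 1L))
    stop("alleles must be 0/1 with no missing values")
  site_bp <- as.integer(site_bp)
  site_cm <- as.numeric(site_cm)
  if (length(site_bp) != n || length(site_cm) != n)
    stop("site_bp and site_cm must have one entry per site")
  if (n > 1L && any(diff(site_bp) <= 0L))
    stop("site_bp must be strictly increasing")
  if (n > 1L && any(diff(site_cm) < 0))
    stop("site_cm must be non-decreasing")
  if (is.null(hap_ids)) hap_ids <- sprintf("hap%d", seq_len(m) - 1L)
  if (length(hap_ids) != m) stop("hap_ids must have one entry per haplotype")
  f1 <- colMeans(alleles)
  structure(list(alleles = alleles,
                 site_bp = site_bp,
                 site_cm = site_cm,
                 hap_ids = as.character(hap_ids),
                 maf = pmin(f1, 1 - f1),
                 n_haps = m, n_sites = n),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites\n", x$n_haps, x$n_sites))
  cat(sprintf("  bp range: %d..%d; genetic span: %.3f cM\n",
              x$site_bp[1L], x$site_bp[x$n_sites],
              x$site_cm[x$n_sites] - x$site_cm[1L]))
  cat(sprintf("  median MAF: %.3f\n", stats::median(x$maf)))
  invisible(x)
}

#' Genetic map
#'
#' Physical position to genetic position lookup for one chromosome.
#'
#' @param bp integer vector of physical positions, strictly increasing.
#' @param cm numeric vector of genetic positions (cM), non-decreasing.
#' @return Object of class `genetic_map`.
#' @export
genetic_map <- function(bp, cm) {
  bp <- as.numeric(bp); cm <- as.numeric(cm)
  if (length(bp) == 0L) stop("empty genetic map")
  if (length(bp) != length(cm)) stop("bp and cm must have equal length")
  if (any(diff(bp) <= 0)) stop("map bp must be strictly increasing")
  if (any(diff(cm) < 0)) stop("map cM must be non-decreasing")
  structure(list(bp = bp, cm = cm), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d points, %.0f..%.0f bp, %.3f..%.3f cM\n",
              length(x$bp), x$bp[1L], x$bp[length(x$bp)],
              x$cm[1L], x$cm[length(x$cm)]))
  invisible(x)
}

#' Interpolate genetic positions
#'
#' Linear interpolation between flanking map points; constant extrapolation
#' outside the map range. Monotone non-decreasing in `bp` for any valid map.
#'
#' @param map a [genetic_map()].
#' @param bp positions to interpolate at.
#' @return numeric vector of genetic positions (cM).
#' @export
interpolate_cm <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(map$bp) == 1L) return(rep(map$cm, length(bp)))
  stats::approx(map$bp, map$cm, xout = as.numeric(bp), method = "linear",
                rule = 2, ties = "ordered")$y
}
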