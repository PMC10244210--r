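#' Sum of IBD length per individual pair
#'
#' Aggregates reported IBD segments into per-pair totals of genetic length,
#' summing over the four haplotype pairings of two diploid individuals. The
#' genealogical-search cutoff (default 7 cM and 700 markers, the
#' conventional minimum used by direct-to-consumer matching services) is
#' applied before aggregation. Exact duplicate segments (same pair and
#' coordinates) are counted once, with a warning. Self pairs — including
#' within-individual haplotype matches — are excluded.
#'
#' @param segments data frame of IBD segments with columns `query_hap`,
#'   `panel_hap`, `start_site`, `end_site`, `cm_length`.
#' @param hap_map either a named character vector mapping haplotype id to
#'   individual id, or `NULL` to derive the individual by stripping a
#'   trailing `_0` / `_1` from the haplotype id.
#' @param min_cm,min_markers genealogical cutoff applied to each segment.
#' @param labels optional named vector (by individual pair key `"A|B"` with
#'   `A < B`, or a function of the two ids) of relatedness degree labels.
#' @return data frame with columns `id_a`, `id_b` (with `id_a < id_b`),
#'   `total_cm`, `n_segments`, and `degree` when labels are supplied; pairs
#'   with no surviving segments are omitted.
#' @export
pair_totals <- function(segments, hap_map = NULL, min_cm = 7,
                        min_markers = 700L, labels = NULL) {
  if (nrow(segments) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      total_cm = numeric(), n_segments = integer()))
  to_ind <- function(h) {
    if (is.null(hap_map)) return(sub("_[01]$", "", h))
    out <- unname(hap_map[h])
    if (anyNA(out)) stop("unmapped haplotype id: ",
                         paste(unique(h[is.na(out)]), collapse = ", "))
    out
  }
  seg <- as.data.frame(segments)
  nm <- seg$end_site - seg$start_site + 1L
  seg <- seg[seg$cm_length >= min_cm & nm >= min_markers, , drop = FALSE]
  if (nrow(seg) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      total_cm = numeric(), n_segments = integer()))
  dup <- duplicated(seg[, c("query_hap", "panel_hap", "start_site", "end_site")])
  if (any(dup)) {
    warning(sum(dup), " duplicate segment row(s) counted once")
    seg <- seg[!dup, , drop = FALSE]
  }
  ia <- to_ind(seg$query_hap); ib <- to_ind(seg$panel_hap)
  self <- ia == ib
  seg <- seg[!self, , drop = FALSE]
  if (nrow(seg) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      total_cm = numeric(), n_segments = integer()))
  a <- pmin(ia[!self], ib[!self]); b <- pmax(ia[!self], ib[!self])
  key <- paste(a, b, sep = "|")
  tot <- tapply(seg$cm_length, key, sum)
  cnt <- tapply(seg$cm_length, key, length)
  ab <- do.call(rbind, strsplit(names(tot), "|", fixed = TRUE))
  out <- data.frame(id_a = ab[, 1L], id_b = ab[, 2L],
                    total_cm = as.numeric(tot),
                    n_segments = as.integer(cnt))
  rownames(out) <- NULL
  if (!is.null(labels)) {
    out$degree <- if (is.function(labels)) {
      mapply(labels, out$id_a, out$id_b, USE.NAMES = FALSE)
    } else unname(labels[paste(out$id_a, out$id_b, sep = "|")])
  }
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' ROC AUC between two relatedness degrees
#'
#' Area under the ROC curve of `total_cm` as a score separating the pairs of
#' the closer degree `degree_a` (positives) from `degree_b`, computed with
#' the rank statistic (Mann-Whitney; ties counted half). An AUC near 1
#' means the two degrees are separable by total shared IBD length; the
#' statistic is invariant under any strictly monotone transform of the
#' totals.
#'
#' @param summaries data frame from [pair_totals()] with a `degree` column.
#' @param degree_a,degree_b labels of the positive (closer) and negative
#'   class.
#' @return AUC in `[0, 1]`.
#' @export
degree_auc <- function(summaries, degree_a, degree_b) {
  if (!"degree" %in% names(summaries)) stop("summaries need a degree column")
  x <- summaries$total_cm[summaries$degree == degree_a]
  y <- summaries$total_cm[summaries$degree == degree_b]
  if (!length(x) || !length(y))
    stop("both degree classes need at least one pair (",
         degree_a, ": ", length(x), ", ", degree_b, ": ", length(y), ")")
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (as.numeric(length(x)) * length(y))
}
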