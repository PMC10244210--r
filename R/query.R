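#' Match length threshold
#'
#' A minimum match length in either site count or genetic distance. A match
#' over 0-based inclusive sites `[s, e]` qualifies when `e - s + 1 >= value`
#' (`kind = "sites"`) or `site_cm[e] - site_cm[s] >= value` (`kind = "cM"`).
#'
#' @param value positive length.
#' @param kind `"sites"` or `"cM"`.
#' @return Object of class `length_threshold`.
#' @export
length_threshold <- function(value, kind = c("sites", "cM")) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  if (length(value) != 1L || is.na(value) || value <= 0)
    stop("threshold value must be a positive number")
  if (kind == "sites" && value != round(value))
    stop("a site-count threshold must be a whole number")
  structure(list(kind = kind, value = value), class = "length_threshold")
}

.as_threshold <- function(L) {
  if (inherits(L, "length_threshold")) return(L)
  if (is.numeric(L) && length(L) == 1L) return(length_threshold(L, "sites"))
  stop("L must be a length_threshold or a single site count")
}

#' Site distance track index
#'
#' For a scan position `k`, the closest earlier site at least `L` cM away:
#' `max{ i <= k : site_cm[k] - site_cm[i] >= L }`, or `NA` if no site
#' qualifies. During a left-to-right scan the index is maintained with a
#' monotone pointer, so the total update cost is linear in the number of
#' sites; this function computes it directly for a single `k`.
#'
#' @param site_cm non-decreasing per-site genetic positions (cM).
#' @param k 0-based site index.
#' @param L genetic distance in cM, `>= 0`.
#' @return 0-based site index, or `NA_integer_`.
#' @export
site_distance_index <- function(site_cm, k, L) {
  if (L < 0) stop("L must be non-negative")
  if (k < 0L || k >= length(site_cm)) stop("site index k out of range")
  ok <- which(site_cm[k + 1L] - site_cm[seq_len(k + 1L)] >= L)
  if (!length(ok)) NA_integer_ else max(ok) - 1L
}

#' Find all long matches between a query haplotype and a panel
#'
#' Single-sweep PBWT long-match query: returns every maximal exact match
#' between the query and each panel haplotype whose length meets the
#' threshold `L` (site count, or genetic span via the site distance track
#' index). Each match is reported once as 0-based inclusive site indices
#' `[start, end]`, with a mismatch or panel boundary at `start - 1` and
#' `end + 1`. Haplotypes with identical sequences are reported individually.
#' Output rows are ordered by scan position; callers must not rely on order.
#'
#' @param index a `pbwt_index` from [build_pbwt_index()].
#' @param query integer vector of 0/1 alleles, length `n_sites`.
#' @param L a [length_threshold()], or a plain number interpreted as a site
#'   count.
#' @return data frame with columns `hap` (0-based panel haplotype id),
#'   `start`, `end`.
#' @export
long_match_query <- function(index, query, L) {
  stopifnot(inherits(index, "pbwt_index"))
  L <- .as_threshold(L)
  query <- as.integer(query)
  if (length(query) != index$n_sites)
    stop("query length ", length(query), " does not match index n_sites ",
         index$n_sites)
  if (anyNA(query) || any(query != 0L & query != 1L))
    stop("query alleles must be 0/1")
  cpp_long_match_query(index$panel$alleles, index$a, index$d, index$u,
                       index$c, query,
                       mode = if (L$kind == "sites") 0L else 1L,
                       L = L$value, cm = index$panel$site_cm)
}

#' Brute-force long match enumeration (test oracle)
#'
#' Direct `O(nm)` scan enumerating, for every panel haplotype, the maximal
#' runs of agreement with the query, filtered by the length threshold.
#' Defines the ground truth for [long_match_query()].
#'
#' @inheritParams long_match_query
#' @param panel a [haplotype_panel()].
#' @return data frame with columns `hap`, `start`, `end` (0-based).
#' @export
brute_force_long_matches <- function(panel, query, L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  L <- .as_threshold(L)
  query <- as.integer(query)
  if (length(query) != panel$n_sites) stop("query length does not match panel")
  out <- vector("list", panel$n_haps)
  for (h in seq_len(panel$n_haps)) {
    agree <- panel$alleles[h, ] == query
    r <- rle(agree)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (!length(runs)) next
    s <- starts[runs] - 1L; e <- ends[runs] - 1L # 0-based inclusive
    keep <- if (L$kind == "sites") (e - s + 1L) >= L$value
            else (panel$site_cm[e + 1L] - panel$site_cm[s + 1L]) >= L$value
    if (any(keep))
      out[[h]] <- data.frame(hap = h - 1L, start = s[keep], end = e[keep])
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.frame(hap = integer(), start = integer(), end = integer()))
  do.call(rbind, out)
}
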