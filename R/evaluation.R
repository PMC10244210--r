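#' @name ibd_accuracy
#' @title Site-level IBD detection accuracy
#'
#' @description
#' The accuracy of a set of reported IBD segments against a planted or
#' simulated truth set is measured at site granularity. The false negative
#' rate is the average, over true segments, of the proportion of a true
#' segment's sites not covered by any reported segment of the same pair;
#' the false positive rate is the symmetric average over reported segments.
#' Both are invariant under segment order and under splitting a segment into
#' abutting halves.
#'
#' Truth and call tables are data frames with columns `query_hap`,
#' `panel_hap`, `start_site`, `end_site` (0-based, end-inclusive) and
#' `cm_length`. Pairing is by haplotype pair by default; at
#' `level = "individual"`, haplotype ids ending in `_0` / `_1` are collapsed
#' to their individual and coverage is the union over the four haplotype
#' pairings.
NULL

.pair_key <- function(df, level) {
  if (level == "haplotype") paste(df$query_hap, df$panel_hap, sep = "\r")
  else {
    a <- sub("_[01]$", "", df$query_hap)
    b <- sub("_[01]$", "", df$panel_hap)
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
}

# per row of `target`, the fraction of its sites covered by the union of
# `cover` segments sharing the pair key
.covered_fraction <- function(target, cover, level) {
  if (nrow(target) == 0L) return(numeric())
  tkey <- .pair_key(target, level)
  out <- numeric(nrow(target))
  if (nrow(cover) == 0L) return(out)
  ckey <- .pair_key(cover, level)
  cov_by <- split(seq_len(nrow(cover)), ckey)
  for (i in seq_len(nrow(target))) {
    idx <- cov_by[[tkey[i]]]
    if (is.null(idx)) next
    s <- target$start_site[i]; e <- target$end_site[i]
    mi <- .merge_intervals(cover$start_site[idx], cover$end_site[idx])
    ov <- pmin(mi$end, e) - pmax(mi$start, s) + 1L
    out[i] <- sum(ov[ov > 0L]) / (e - s + 1L)
  }
  out
}

#' @rdname ibd_accuracy
#' @param truth data frame of true IBD segments.
#' @param calls data frame of reported IBD segments.
#' @param level `"haplotype"` (default) or `"individual"` pairing.
#' @return `false_negative_rate()` and `false_positive_rate()` return a
#'   single rate in `[0, 1]`.
#' @export
false_negative_rate <- function(truth, calls, level = c("haplotype", "individual")) {
  level <- match.arg(level)
  if (nrow(truth) == 0L) stop("false negative rate undefined for an empty truth set")
  mean(1 - .covered_fraction(truth, calls, level))
}

#' @rdname ibd_accuracy
#' @export
false_positive_rate <- function(calls, truth, level = c("haplotype", "individual")) {
  level <- match.arg(level)
  if (nrow(calls) == 0L) stop("false positive rate undefined for an empty call set")
  mean(1 - .covered_fraction(calls, truth, level))
}

#' Binned false negative and false positive rates
#'
#' Segments are assigned to genetic-length bins (defaults 2-5, 5-7, 7-9,
#' 9-12, 12-15, 15-18 and >= 18 cM) according to their own `cm_length`, and
#' the site-level rates are computed per bin. The covering set is filtered
#' by a length floor: for the false negative rate only reported segments of
#' at least `min_len_rep` cM may cover a true segment (default 2), and for
#' the false positive rate only true segments of at least `min_len_true` cM
#' may cover a reported one (default 1.5). A bin with no segments reports
#' `NA`, not 0.
#'
#' @inheritParams false_negative_rate
#' @param bins ascending bin edges in cM; the last bin is open-ended when the
#'   final edge is `Inf`.
#' @param min_len_rep,min_len_true covering-set length floors in cM.
#' @return data frame with one row per bin: `bin_lo`, `bin_hi`, `n_true`,
#'   `fnr`, `n_rep`, `fpr`.
#' @export
binned_rates <- function(truth, calls, bins = c(2, 5, 7, 9, 12, 15, 18, Inf),
                         min_len_rep = 2, min_len_true = 1.5,
                         level = c("haplotype", "individual")) {
  level <- match.arg(level)
  if (is.unsorted(bins, strictly = TRUE)) stop("bin edges must be ascending")
  nb <- length(bins) - 1L
  cover_for_fnr <- calls[calls$cm_length >= min_len_rep, , drop = FALSE]
  cover_for_fpr <- truth[truth$cm_length >= min_len_true, , drop = FALSE]
  fnr_all <- .covered_fraction(truth, cover_for_fnr, level)
  fpr_all <- .covered_fraction(calls, cover_for_fpr, level)
  tb <- findInterval(truth$cm_length, bins, rightmost.closed = FALSE)
  cb <- findInterval(calls$cm_length, bins, rightmost.closed = FALSE)
  out <- data.frame(bin_lo = bins[seq_len(nb)], bin_hi = bins[-1L],
                    n_true = NA_integer_, fnr = NA_real_,
                    n_rep = NA_integer_, fpr = NA_real_)
  for (b in seq_len(nb)) {
    ti <- which(tb == b); ci <- which(cb == b)
    out$n_true[b] <- length(ti)
    out$n_rep[b] <- length(ci)
    if (length(ti)) out$fnr[b] <- mean(1 - fnr_all[ti])
    if (length(ci)) out$fpr[b] <- mean(1 - fpr_all[ci])
  }
  out
}

#' RMS genetic length discrepancy
#'
#' Each reported segment is paired with the true segment of the same pair
#' having maximal site overlap, and the root mean square of
#' `cm_length_reported - cm_length_true` is taken over reported segments.
#' A reported segment overlapping no true segment contributes its full
#' genetic length as the discrepancy.
#'
#' @inheritParams false_negative_rate
#' @return RMS discrepancy in cM.
#' @export
length_discrepancy_rms <- function(calls, truth, level = c("haplotype", "individual")) {
  level <- match.arg(level)
  if (nrow(calls) == 0L) stop("length discrepancy undefined for an empty call set")
  ckey <- .pair_key(calls, level)
  tkey <- if (nrow(truth)) .pair_key(truth, level) else character()
  t_by <- split(seq_len(nrow(truth)), tkey)
  delta <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    idx <- t_by[[ckey[i]]]
    if (is.null(idx)) { delta[i] <- calls$cm_length[i]; next }
    ov <- pmin(truth$end_site[idx], calls$end_site[i]) -
          pmax(truth$start_site[idx], calls$start_site[i]) + 1L
    if (all(ov <= 0L)) { delta[i] <- calls$cm_length[i]; next }
    j <- idx[which.max(ov)]
    delta[i] <- calls$cm_length[i] - truth$cm_length[j]
  }
  sqrt(mean(delta^2))
}
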