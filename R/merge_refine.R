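#' Group projection matches by end position
#'
#' First stage of IBD identification: detected matches from the projection
#' runs are bucketed by their (full-resolution) end site, and within a bucket
#' keyed by panel haplotype id, keeping the multiset of start positions.
#' Exact duplicates within one run (same `run`, `hap`, `start`, `end`) are
#' collapsed so a run contributes at most one match per coordinate, while
#' duplicates across runs retain multiplicity — they are the support counted
#' by the `c` rule.
#'
#' @param matches data frame with columns `hap`, `start`, `end` and
#'   optionally `run` (full-resolution coordinates, as returned by
#'   [run_projection_queries()]).
#' @return Object of class `end_group_table`: a data frame of the grouped
#'   matches sorted by `(end, hap, start)`.
#' @export
group_by_end <- function(matches) {
  cols <- c("hap", "start", "end")
  if (!all(cols %in% names(matches)))
    stop("matches need columns hap, start, end")
  df <- as.data.frame(matches)
  if ("run" %in% names(df)) {
    df <- df[!duplicated(df[, c("run", "hap", "start", "end")]), , drop = FALSE]
  }
  df <- df[order(df$end, df$hap, df$start), cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("end_group_table", "data.frame")
  df
}

#' Identify fragmented IBDs by the count rule
#'
#' Within each `(end, hap)` group, the match with the `c`-th smallest start
#' position (duplicates counted with multiplicity) is kept as a fragmented
#' IBD and the others are discarded; groups with fewer than `c` matches emit
#' nothing. Because matches in a group share their end, the kept match is
#' completely overlapped by at least `c` matches from the projection runs.
#'
#' @param table an `end_group_table` from [group_by_end()].
#' @param c count parameter, `>= 1`.
#' @return data frame with columns `hap`, `start`, `end`, one row per
#'   surviving group.
#' @export
fragmented_ibds <- function(table, c = 2L) {
  stopifnot(inherits(table, "end_group_table"))
  c <- as.integer(c)
  if (c < 1L) stop("count parameter c must be >= 1")
  if (nrow(table) == 0L)
    return(data.frame(hap = integer(), start = integer(), end = integer()))
  key <- paste(table$end, table$hap, sep = ":")
  # table is sorted by (end, hap, start): within each group the c-th row is
  # the c-th smallest start
  pos <- stats::ave(seq_along(key), key, FUN = seq_along)
  cnt <- stats::ave(seq_along(key), key, FUN = length)
  out <- table[pos == c & cnt >= c, c("hap", "start", "end"), drop = FALSE]
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out[order(out$hap, out$end), , drop = FALSE]
}

.merge_intervals <- function(start, end) {
  ord <- order(start, end)
  s <- start[ord]; e <- end[ord]
  ms <- s[1L]; me <- e[1L]
  out_s <- integer(); out_e <- integer()
  if (length(s) > 1L) for (i in 2L:length(s)) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Merge fragmented IBDs into candidate IBDs
#'
#' Per panel haplotype, fragmented IBDs are evaluated in ascending order of
#' their end positions and any two that overlap (share at least one site,
#' end-inclusive) are replaced by their union; disjoint fragments remain
#' separate candidates.
#'
#' @param fragments data frame with columns `hap`, `start`, `end` from
#'   [fragmented_ibds()].
#' @return Object of class `candidate_table`: data frame of pairwise disjoint
#'   candidate intervals per haplotype, sorted by `(hap, start)`.
#' @export
merge_candidates <- function(fragments) {
  if (nrow(fragments) == 0L) {
    out <- data.frame(hap = integer(), start = integer(), end = integer())
    class(out) <- c("candidate_table", "data.frame")
    return(out)
  }
  parts <- lapply(split(fragments, fragments$hap), function(fr) {
    mi <- .merge_intervals(fr$start, fr$end)
    data.frame(hap = fr$hap[1L], start = mi$start, end = mi$end)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$hap, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Refine candidate IBDs against full-resolution exact matches
#'
#' The reported boundaries of an IBD come from the exact matches found on
#' the full-resolution panel: each candidate is replaced by the union of all
#' full-resolution exact matches overlapping it (a candidate overlapping no
#' exact match is dropped, and exact matches overlapping no candidate are
#' discarded). Refined pieces of the same haplotype whose genetic gap —
#' measured from the end of one piece to the start of the next — is at most
#' `gmax` cM are stitched into one segment spanning both; such a gap is
#' treated as a genotyping error, mutation or gene conversion the projection
#' runs did not pick up. Finally, segments shorter than `L_final` cM or
#' `min_markers` sites are removed.
#'
#' @param candidates a `candidate_table` from [merge_candidates()].
#' @param exact_full data frame of full-resolution exact matches (`hap`,
#'   `start`, `end`) from [long_match_query()] at the refinement cutoff.
#' @param site_cm,site_bp per-site genetic (cM) and physical (bp) positions
#'   of the full-resolution panel.
#' @param gmax maximum stitched gap in cM (`>= 0`).
#' @param L_final minimum reported genetic length in cM.
#' @param min_markers minimum reported site count.
#' @param query_hap,hap_ids identifiers used to label the reported segments.
#' @return data frame of IBD segments with columns `query_hap`, `panel_hap`,
#'   `start_site`, `end_site`, `start_bp`, `end_bp`, `cm_length`,
#'   `n_markers`, sorted by `(panel_hap, start_site)`.
#' @export
refine <- function(candidates, exact_full, site_cm, site_bp,
                   gmax = 2, L_final = 7, min_markers = 700L,
                   query_hap = "query", hap_ids = NULL) {
  if (gmax < 0) stop("gmax must be non-negative")
  empty <- data.frame(query_hap = character(), panel_hap = character(),
                      start_site = integer(), end_site = integer(),
                      start_bp = integer(), end_bp = integer(),
                      cm_length = numeric(), n_markers = integer())
  if (nrow(candidates) == 0L || nrow(exact_full) == 0L) return(empty)

  ex_by_hap <- split(as.data.frame(exact_full), exact_full$hap)
  out <- list()
  for (h in unique(candidates$hap)) {
    cand <- candidates[candidates$hap == h, , drop = FALSE]
    ex <- ex_by_hap[[as.character(h)]]
    if (is.null(ex)) next
    # pieces: union of exact matches overlapping any candidate of this pair
    keep <- logical(nrow(ex))
    for (i in seq_len(nrow(ex)))
      keep[i] <- any(ex$start[i] <= cand$end & ex$end[i] >= cand$start)
    if (!any(keep)) next
    pieces <- .merge_intervals(ex$start[keep], ex$end[keep])
    ps <- pieces$start; pe <- pieces$end
    # stitch consecutive pieces across genetic gaps <= gmax
    if (length(ps) > 1L) {
      ss <- ps[1L]; se <- pe[1L]; st_s <- integer(); st_e <- integer()
      for (i in 2L:length(ps)) {
        gap <- site_cm[ps[i] + 1L] - site_cm[se + 1L]
        if (gap <= gmax) se <- pe[i]
        else { st_s <- c(st_s, ss); st_e <- c(st_e, se); ss <- ps[i]; se <- pe[i] }
      }
      ps <- c(st_s, ss); pe <- c(st_e, se)
    }
    cm_len <- site_cm[pe + 1L] - site_cm[ps + 1L]
    nm <- pe - ps + 1L
    ok <- cm_len >= L_final & nm >= min_markers
    if (!any(ok)) next
    out[[length(out) + 1L]] <-
      data.frame(query_hap = query_hap,
                 panel_hap = if (is.null(hap_ids)) as.character(h)
                             else hap_ids[h + 1L],
                 start_site = ps[ok], end_site = pe[ok],
                 start_bp = site_bp[ps[ok] + 1L], end_bp = site_bp[pe[ok] + 1L],
                 cm_length = cm_len[ok], n_markers = nm[ok])
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$panel_hap, out$start_site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pre-process a panel into a query bundle
#'
#' Builds everything the query stage needs: the full-resolution PBWT index,
#' the projection scheme, and one PBWT index per low-resolution sub-panel.
#'
#' @param panel a [haplotype_panel()].
#' @param w window size in sites (see [make_projection()]). The default
#'   picks `w` so that a segment of `L_final` cM spans about
#'   `windows_per_cutoff` windows at the panel's mean marker density.
#' @param r number of projection runs.
#' @param seed RNG seed for the projection scheme.
#' @param L_final intended minimum reported IBD length in cM (used only for
#'   the default `w`).
#' @param windows_per_cutoff target number of windows per minimum-length
#'   segment when `w` is not given.
#' @return Object of class `ibd_bundle` with fields `panel`, `index`,
#'   `scheme`, `sub_indexes`, `params`.
#' @export
index_bundle <- function(panel, w = NULL, r = 10L, seed = 1L,
                         L_final = 7, windows_per_cutoff = 10L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(w)) {
    dens <- (panel$n_sites - 1L) /
      max(panel$site_cm[panel$n_sites] - panel$site_cm[1L], .Machine$double.eps)
    w <- max(1L, as.integer(round(L_final * dens / windows_per_cutoff)))
    w <- min(w, panel$n_sites)
  }
  scheme <- make_projection(panel, w = w, r = r, seed = seed)
  sub_indexes <- lapply(scheme$sub_indices,
                        function(si) build_pbwt_index(project(panel, si)))
  structure(list(panel = panel,
                 index = build_pbwt_index(panel),
                 scheme = scheme,
                 sub_indexes = sub_indexes,
                 params = list(w = scheme$w, r = scheme$r, seed = scheme$seed)),
            class = "ibd_bundle")
}

#' @export
print.ibd_bundle <- function(x, ...) {
  cat(sprintf("ibd_bundle: %d haplotypes x %d sites; %d projection runs, window %d\n",
              x$panel$n_haps, x$panel$n_sites, x$scheme$r, x$scheme$w))
  invisible(x)
}

#' Error-tolerant one-versus-all IBD query
#'
#' Full query pipeline for one haplotype against a pre-processed panel:
#' projection queries on the low-resolution indexes, end-position grouping,
#' the `c`-th-smallest-start count rule, candidate merging, and refinement
#' against the full-resolution exact matches at the `refine_cm` cutoff with
#' `gmax` gap stitching and the final length filters. Deterministic given
#' the bundle (whose scheme fixes the projection seed); no intermediate
#' files are produced.
#'
#' @param bundle an `ibd_bundle` from [index_bundle()].
#' @param query 0/1 allele vector over the panel's sites.
#' @param L_final minimum reported IBD length in cM (default 7, the
#'   conventional genealogical-search cutoff).
#' @param min_markers minimum reported site count (default 700, ditto).
#' @param refine_cm cutoff (cM) of the full-resolution exact-match run used
#'   for boundary refinement; 0.5 is recommended for sequencing-density
#'   panels and 1.0 for SNP-array density.
#' @param c count rule parameter: windows of a reported segment must be
#'   supported by at least `c` projection runs (default 2).
#' @param gmax maximum stitched genetic gap in cM (default 2).
#' @param L_lowres optional override of the low-resolution threshold in
#'   windows; the default is `round(L_final_sites / w)` at the panel's mean
#'   marker density.
#' @param query_hap label for the query haplotype in the output.
#' @return data frame of IBD segments (see [refine()] for columns).
#' @export
ibd_query <- function(bundle, query,
                        L_final = 7, min_markers = 700L, refine_cm = 0.5,
                        c = 2L, gmax = 2, L_lowres = NULL,
                        query_hap = "query") {
  stopifnot(inherits(bundle, "ibd_bundle"))
  panel <- bundle$panel
  if (is.null(L_lowres)) {
    dens <- (panel$n_sites - 1L) /
      max(panel$site_cm[panel$n_sites] - panel$site_cm[1L], .Machine$double.eps)
    L_lowres <- max(1L, as.integer(round(L_final * dens / bundle$scheme$w)))
  }
  low <- run_projection_queries(bundle$sub_indexes, query, L_lowres,
                                bundle$scheme)
  frag <- fragmented_ibds(group_by_end(low), c = c)
  cand <- merge_candidates(frag)
  exact <- long_match_query(bundle$index, query,
                            length_threshold(refine_cm, "cM"))
  refine(cand, exact, panel$site_cm, panel$site_bp,
         gmax = gmax, L_final = L_final, min_markers = min_markers,
         query_hap = query_hap, hap_ids = panel$hap_ids)
}
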