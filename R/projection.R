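#' Random projection scheme
#'
#' Divides the `n` sites into `ceiling(n / w)` windows of `w` sites (the last
#' window may be shorter) and, for each of `r` runs, samples one site per
#' window with probability proportional to the site's minor allele frequency
#' within the window. Rare-allele-rich sites are the informative ones for
#' distinguishing haplotypes, hence the MAF weighting; a window whose MAFs
#' are all zero falls back to uniform sampling.
#'
#' Each run draws from its own RNG substream (L'Ecuyer-CMRG), so schemes are
#' reproducible given `seed` and extending `r` leaves earlier runs unchanged.
#'
#' @param panel a [haplotype_panel()].
#' @param w window size in sites, `1 <= w <= n`.
#' @param r number of projection runs (`>= 0`).
#' @param seed integer RNG seed.
#' @return Object of class `projection_scheme`: list with `w`, `r`, `n`,
#'   `seed` and `sub_indices`, a list of `r` strictly increasing vectors of
#'   0-based full-resolution site indices (one per window).
#' @export
make_projection <- function(panel, w, r, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- panel$n_sites
  w <- as.integer(w); r <- as.integer(r)
  if (w < 1L || w > n) stop("window size w must be in [1, n]")
  if (r < 0L) stop("r must be non-negative")
  nw <- ceiling(n / w)
  win_lo <- (seq_len(nw) - 1L) * w            # 0-based window starts
  win_hi <- pmin(win_lo + w, n) - 1L          # 0-based inclusive ends

  sub_indices <- vector("list", r)
  if (r > 0L) {
    old_kind <- RNGkind("L'Ecuyer-CMRG")
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      RNGkind(old_kind[1L])
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
    stream <- get(".Random.seed", globalenv())
    for (j in seq_len(r)) {
      stream <- parallel::nextRNGStream(stream)
      assign(".Random.seed", stream, globalenv())
      sub_indices[[j]] <- vapply(seq_len(nw), function(s) {
        sites <- win_lo[s]:win_hi[s]
        if (length(sites) == 1L) return(sites)
        wts <- panel$maf[sites + 1L]
        if (sum(wts) <= 0) sites[sample.int(length(sites), 1L)]
        else sites[sample.int(length(sites), 1L, prob = wts)]
      }, integer(1L))
    }
  }
  structure(list(w = w, r = r, n = n, seed = as.integer(seed),
                 sub_indices = sub_indices),
            class = "projection_scheme")
}

#' @export
print.projection_scheme <- function(x, ...) {
  cat(sprintf("projection_scheme: %d runs, window %d sites, %d windows over %d sites (seed %d)\n",
              x$r, x$w, ceiling(x$n / x$w), x$n, x$seed))
  invisible(x)
}

#' Project a panel or query onto one sub-index
#'
#' Column subset in sub-index order; low-resolution genetic and physical
#' positions carry the sampled sites' coordinates.
#'
#' @param x a [haplotype_panel()] or a 0/1 allele vector.
#' @param sub_index strictly increasing vector of 0-based site indices (one
#'   entry of `projection_scheme$sub_indices`).
#' @return A [haplotype_panel()] or an allele vector over the sampled sites.
#' @export
project <- function(x, sub_index) {
  sub_index <- as.integer(sub_index)
  if (inherits(x, "haplotype_panel")) {
    if (any(sub_index < 0L | sub_index >= x$n_sites))
      stop("sub-index out of range for panel")
    haplotype_panel(x$alleles[, sub_index + 1L, drop = FALSE],
                    x$site_bp[sub_index + 1L], x$site_cm[sub_index + 1L],
                    x$hap_ids)
  } else {
    if (any(sub_index < 0L | sub_index >= length(x)))
      stop("sub-index out of range for query")
    x[sub_index + 1L]
  }
}

#' Rescale a low-resolution match to full resolution
#'
#' A match over window indices `[h', t']` found on a low-resolution panel
#' with window size `w` is rescaled to full-resolution site indices
#' `[w * h', w * (t' + 1) - 1]`, the window-aligned hull of the matched
#' windows, clipped to `n - 1` when the final window is partial.
#'
#' @param match data frame with columns `hap`, `start`, `end` (0-based
#'   low-resolution window indices).
#' @param w window size in sites.
#' @param n full-resolution site count used for clipping (default `Inf`, no
#'   clipping).
#' @return data frame with the same rows at full-resolution coordinates.
#' @export
rescale_match <- function(match, w, n = Inf) {
  if (nrow(match) == 0L) return(match)
  if (any(match$start < 0L) || any(match$end < 0L))
    stop("negative low-resolution coordinates")
  out <- match
  out$start <- as.integer(w * match$start)
  out$end <- as.integer(pmin(w * (match$end + 1L) - 1L, n - 1L))
  out
}

#' Run all projection queries for one query haplotype
#'
#' Projects the query onto each run's sub-index, runs the PBWT long-match
#' query on the corresponding low-resolution index with a window-count
#' threshold, and rescales the matches to full resolution. Matches are
#' returned with multiplicity across runs, tagged by run number.
#'
#' @param sub_indexes list of `pbwt_index` objects, one per run, built from
#'   `project(panel, scheme$sub_indices[[j]])`.
#' @param query full-resolution 0/1 allele vector.
#' @param L_lowres match threshold in windows (low-resolution sites).
#' @param scheme the [make_projection()] scheme the sub-indexes were built
#'   from.
#' @return data frame with columns `run`, `hap`, `start`, `end`
#'   (full-resolution, 0-based, window-aligned).
#' @export
run_projection_queries <- function(sub_indexes, query, L_lowres, scheme) {
  stopifnot(inherits(scheme, "projection_scheme"))
  if (length(sub_indexes) != scheme$r)
    stop("scheme/index mismatch: ", length(sub_indexes), " indexes for ",
         scheme$r, " runs")
  if (length(query) != scheme$n)
    stop("query length does not match scheme site count")
  out <- vector("list", scheme$r)
  for (j in seq_len(scheme$r)) {
    idx <- sub_indexes[[j]]
    si <- scheme$sub_indices[[j]]
    if (!inherits(idx, "pbwt_index") || idx$n_sites != length(si))
      stop("scheme/index mismatch in run ", j)
    mt <- long_match_query(idx, project(query, si),
                           length_threshold(L_lowres, "sites"))
    mt <- rescale_match(mt, scheme$w, scheme$n)
    if (nrow(mt)) out[[j]] <- cbind(run = j, mt)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.frame(run = integer(), hap = integer(),
                      start = integer(), end = integer()))
  do.call(rbind, out)
}
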