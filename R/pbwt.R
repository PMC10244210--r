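#' Build a PBWT index for a haplotype panel
#'
#' Constructs the positional Burrows-Wheeler transform arrays used by all
#' queries, in a single left-to-right sweep (time linear in `m * n`):
#'
#' * `a` — per-boundary prefix arrays: column `k+1` (1-based) holds the
#'   0-based haplotype ids sorted by their reversed prefixes over sites
#'   `[0, k)`;
#' * `d` — per-boundary divergence arrays: `d[i+1, k+1]` is the smallest `j`
#'   such that the haplotypes at sorted positions `i` and `i-1` agree on all
#'   sites `[j, k)`; sentinel `d[1, k+1] = k`;
#' * `u`, `c` — cumulative 0-allele counts enabling sorted-interval extension
#'   (`v` counts are implied by `i - u`).
#'
#' @param panel a [haplotype_panel()].
#' @return Object of class `pbwt_index` with fields `a`, `d`, `u`, `c`
#'   (0-based values, see above), `n_haps`, `n_sites`, and the `panel` it was
#'   built from.
#' @export
build_pbwt_index <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  idx <- cpp_pbwt_build(panel$alleles)
  idx$panel <- panel
  class(idx) <- "pbwt_index"
  idx
}

#' @export
print.pbwt_index <- function(x, ...) {
  cat(sprintf("pbwt_index: %d haplotypes x %d sites\n", x$n_haps, x$n_sites))
  invisible(x)
}

#' Extend a sorted haplotype interval through one site
#'
#' Maps the sorted interval `[f, g)` at site boundary `k` to the interval at
#' boundary `k+1` of those haplotypes that carry allele `a` at site `k`.
#' All coordinates are 0-based; `0 <= f <= g <= m`, `k < n`. An empty input
#' interval maps to an empty interval, and for any `[f, g)` the sizes of the
#' two allele extensions partition `g - f`.
#'
#' @param index a `pbwt_index`.
#' @param k 0-based site index.
#' @param f,g interval bounds, `0 <= f <= g <= m`.
#' @param a allele, 0 or 1.
#' @return integer vector `c(f', g')`.
#' @export
extend_interval <- function(index, k, f, g, a) {
  stopifnot(inherits(index, "pbwt_index"))
  m <- index$n_haps
  if (k < 0L || k >= index$n_sites) stop("site index k out of range")
  if (f < 0L || g < f || g > m) stop("interval [f, g) out of range")
  if (!a %in% c(0L, 1L)) stop("allele must be 0 or 1")
  cpp_extend_interval(index$u, index$c, as.integer(k), as.integer(f),
                      as.integer(g), as.integer(a))
}
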