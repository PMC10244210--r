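#' Synthetic genetic map
#'
#' Piecewise-linear map over `n_points` anchor positions spanning
#' `length_bp` base pairs and `length_cm` centiMorgans. With a seed, the
#' per-interval recombination rates are jittered (gamma-distributed
#' increments renormalized to the total length) to emulate local rate
#' variation; without one the rate is constant.
#'
#' @param length_bp physical span in bp.
#' @param length_cm genetic span in cM.
#' @param n_points number of map anchor points (>= 2).
#' @param seed optional seed for rate jitter.
#' @return A [genetic_map()] from bp 1 to `length_bp`.
#' @export
synthetic_map <- function(length_bp, length_cm, n_points = 21L, seed = NULL) {
  n_points <- max(2L, as.integer(n_points))
  bp <- round(seq(1, length_bp, length.out = n_points))
  if (is.null(seed)) {
    cm <- seq(0, length_cm, length.out = n_points)
  } else {
    inc <- withr_seed(seed, stats::rgamma(n_points - 1L, shape = 3, rate = 3))
    cm <- c(0, cumsum(inc) / sum(inc) * length_cm)
  }
  genetic_map(bp, cm)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random haplotype panel
#'
#' Sites are independent: at site `k` a target allele-1 frequency is drawn
#' from `maf_sampler` and every haplotype carries allele 1 with that
#' probability. There is no linkage and no background relatedness by
#' construction, so long shared segments between generated haplotypes are
#' exponentially rare — planted segments (see [plant_ibd()]) are the only
#' long IBD.
#'
#' @param m number of haplotypes.
#' @param n number of sites.
#' @param maf_sampler function of one integer argument returning that many
#'   target frequencies in `[0, 1]`; default uniform on `[0.05, 0.5]`.
#' @param map a [genetic_map()]; the default spans `1000 * n` bp and
#'   `n / 100` cM (100 markers per cM, a sequencing-like density).
#' @param seed integer seed; the same seed reproduces the same panel.
#' @return A [haplotype_panel()] with sites evenly spaced in bp.
#' @export
generate_panel <- function(m, n, maf_sampler = NULL, map = NULL, seed = 1L) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L || n < 1L) stop("m and n must be >= 1")
  if (is.null(maf_sampler)) maf_sampler <- function(k) stats::runif(k, 0.05, 0.5)
  if (is.null(map)) map <- synthetic_map(1000 * n, n / 100)
  withr_seed(seed, {
    freq <- maf_sampler(n)
    if (anyNA(freq) || any(freq < 0 | freq > 1))
      stop("maf_sampler must return probabilities in [0, 1]")
    alleles <- matrix(stats::rbinom(m * n, 1L, rep(freq, each = m)), nrow = m)
    bp <- unique(round(seq(1, max(map$bp), length.out = n)))
    if (length(bp) < n) bp <- seq_len(n) # degenerate tiny map: 1 bp spacing
    haplotype_panel(alleles, bp, interpolate_cm(map, bp))
  })
}

#' Specification of planted IBD segments
#'
#' @param n_segments number of segments to plant.
#' @param len_range segment genetic length range in cM; lengths are drawn
#'   uniformly.
#' @param recipients,donors 0-based haplotype indices eligible as recipient
#'   (copy target) and donor (copy source); `NULL` means all haplotypes.
#'   Keeping recipients disjoint from the panel rows that will be indexed
#'   lets planted queries be searched against a panel not containing them.
#' @param seed integer seed.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(n_segments, len_range = c(3, 20), recipients = NULL,
                       donors = NULL, seed = 1L) {
  structure(list(n_segments = as.integer(n_segments),
                 len_range = as.numeric(len_range),
                 recipients = recipients, donors = donors,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant ground-truth IBD segments into a panel
#'
#' For each planted segment a recipient and a distinct donor haplotype are
#' drawn, a genetic length is drawn from the spec's range, a start position
#' is drawn uniformly over the feasible genetic span, the interval is
#' snapped to sites, and the donor's alleles are copied onto the recipient
#' over the interval. Planted segments never overlap on the same recipient;
#' infeasible placements are retried and an error reports the retry count
#' when a segment cannot be placed.
#'
#' @param panel a [haplotype_panel()].
#' @param spec a [plant_spec()].
#' @param max_retries placement retries per segment before giving up.
#' @return list with `panel` (alleles modified) and `truth`, a data frame of
#'   planted segments with columns `query_hap` (recipient), `panel_hap`
#'   (donor), `start_site`, `end_site`, `start_bp`, `end_bp`, `cm_length`
#'   (of the snapped interval).
#' @export
plant_ibd <- function(panel, spec, max_retries = 100L) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "plant_spec"))
  m <- panel$n_haps
  recipients <- if (is.null(spec$recipients)) 0:(m - 1L) else as.integer(spec$recipients)
  donors <- if (is.null(spec$donors)) 0:(m - 1L) else as.integer(spec$donors)
  cm <- panel$site_cm
  span <- cm[panel$n_sites] - cm[1L]
  if (max(spec$len_range) > span)
    stop("planted length range exceeds the panel's genetic span (", round(span, 2), " cM)")
  alleles <- panel$alleles
  placed <- lapply(seq_len(m), function(i) NULL) # per-recipient intervals
  rows <- vector("list", spec$n_segments)
  withr_seed(spec$seed, {
    for (i in seq_len(spec$n_segments)) {
      done <- FALSE
      for (try in seq_len(max_retries)) {
        rec <- recipients[sample.int(length(recipients), 1L)]
        don <- donors[sample.int(length(donors), 1L)]
        if (don == rec) next
        len <- stats::runif(1L, spec$len_range[1L], spec$len_range[2L])
        start_cm <- stats::runif(1L, cm[1L], cm[panel$n_sites] - len)
        s <- which(cm >= start_cm)[1L]
        e <- which(cm >= start_cm + len)[1L]
        if (is.na(s) || is.na(e) || e <= s) next
        prev <- placed[[rec + 1L]]
        if (!is.null(prev) && any(s <= prev[, 2L] & e >= prev[, 1L])) next
        placed[[rec + 1L]] <- rbind(prev, c(s, e))
        alleles[rec + 1L, s:e] <- alleles[don + 1L, s:e]
        rows[[i]] <- data.frame(query_hap = panel$hap_ids[rec + 1L],
                                panel_hap = panel$hap_ids[don + 1L],
                                start_site = s - 1L, end_site = e - 1L,
                                start_bp = panel$site_bp[s],
                                end_bp = panel$site_bp[e],
                                cm_length = cm[e] - cm[s])
        done <- TRUE
        break
      }
      if (!done)
        stop("could not place planted segment ", i, " after ", max_retries,
             " retries")
    }
  })
  truth <- if (spec$n_segments == 0L) {
    data.frame(query_hap = character(), panel_hap = character(),
               start_site = integer(), end_site = integer(),
               start_bp = integer(), end_bp = integer(), cm_length = numeric())
  } else do.call(rbind, rows)
  list(panel = haplotype_panel(alleles, panel$site_bp, panel$site_cm,
                               panel$hap_ids),
       truth = truth)
}

#' Add genotyping error to a panel
#'
#' Flips each allele independently with probability `rate`. Typical rates:
#' 0.0004 (0.04%, whole-genome sequencing) and 0.0013 (0.13%, SNP array).
#'
#' @param panel a [haplotype_panel()].
#' @param rate per-allele flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A new [haplotype_panel()] with flipped alleles.
#' @export
add_genotyping_error <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(panel)
  alleles <- panel$alleles
  total <- length(alleles)
  withr_seed(seed, {
    nflip <- stats::rbinom(1L, total, rate)
    if (nflip > 0L) {
      idx <- sample.int(total, nflip)
      alleles[idx] <- 1L - alleles[idx]
    }
  })
  haplotype_panel(alleles, panel$site_bp, panel$site_cm, panel$hap_ids)
}

#' Worked merge-and-refine example fixture
#'
#' A frozen desk-scale input for the IBD identification stages: six
#' end-position groups of projection matches for one haplotype pair, of
#' which one group (G3) holds a single match and is discarded by the count
#' rule at `c = 2`; the five fragmented IBDs merge into three candidates
#' (two adjacent ones and one union of three mutually overlapping
#' fragments); refinement against three full-resolution exact matches
#' stitches the first two candidates across a sub-gmax gap and trims the
#' third on both ends, yielding two final segments.
#'
#' @return list with `lowres` (run-tagged matches at full resolution),
#'   `exact` (full-resolution exact matches), `site_cm`, `site_bp`,
#'   `hap_ids` and `params` (`c = 2`, `gmax = 2` cM, plus the final length
#'   filters the example assumes).
#' @export
merge_refine_example <- function() {
  lowres <- data.frame(
    run = c(1L, 2L, 3L,   1L, 2L,   1L,   1L, 2L, 3L,   1L, 2L,   1L, 2L),
    hap = 7L,
    start = c(0L, 2L, 4L,  15L, 16L,  26L,  33L, 35L, 38L,  32L, 34L,  30L, 36L),
    end = c(14L, 14L, 14L, 24L, 24L,  30L,  50L, 50L, 50L,  52L, 52L,  55L, 55L))
  exact <- data.frame(hap = 7L,
                      start = c(1L, 16L, 38L),
                      end = c(15L, 25L, 53L))
  n <- 60L
  list(lowres = lowres,
       exact = exact,
       site_cm = (seq_len(n) - 1L) * 0.2,
       site_bp = (seq_len(n) - 1L) * 10000L + 1L,
       hap_ids = sprintf("hap%d", 0:9),
       params = list(c = 2L, gmax = 2, L_final = 2, min_markers = 10L))
}
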