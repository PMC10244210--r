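#' Specification of a forward pedigree simulation
#'
#' The mating design: at each generation up to `couples` non-overlapping
#' male/female couples are formed from the previous generation, the
#' population size stays at `founders` individuals per generation, and each
#' child's father is replaced, with probability `extra_pair`, by a different
#' male from the same generation as the couple. Per meiosis the crossover
#' count is Poisson with mean `Lt / 50` (`Lt` = chromosome length in cM) and
#' crossover positions are uniform in genetic distance.
#'
#' @param founders number of founder individuals (generation 0); also the
#'   population size of every later generation.
#' @param generations number of generations to simulate after the founders.
#' @param couples maximum number of couples per generation (default 500).
#' @param extra_pair probability that a child's father is a different male
#'   from the couple's generation (default 0.2).
#' @param Lt chromosome genetic length(s) in cM; a vector simulates a
#'   multi-chromosome genome over one shared pedigree.
#' @param seed integer seed.
#' @return Object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(founders, generations, couples = 500L,
                          extra_pair = 0.2, Lt = 200, seed = 1L) {
  if (extra_pair < 0 || extra_pair > 1) stop("extra_pair must be in [0, 1]")
  if (any(Lt <= 0)) stop("Lt must be positive")
  if (founders < 2L * min(couples, floor(founders / 2)))
    stop("founders must allow at least one couple") # degenerate guard
  structure(list(founders = as.integer(founders),
                 generations = as.integer(generations),
                 couples = as.integer(couples),
                 extra_pair = extra_pair,
                 Lt = as.numeric(Lt),
                 seed = as.integer(seed)),
            class = "pedigree_spec")
}

# one gamete: recombine the parent's two haplotype mosaics.
# A mosaic is a matrix with columns (start_cm, founder_hap); segment i spans
# [start_i, start_{i+1}) and the last segment runs to Lt.
.gamete <- function(mosA, mosB, Lt) {
  ncross <- stats::rpois(1L, Lt / 50)
  first <- sample.int(2L, 1L)
  if (ncross == 0L) return(list(mos = if (first == 1L) mosA else mosB, ncross = 0L))
  breaks <- sort(stats::runif(ncross, 0, Lt))
  bounds <- c(0, breaks, Lt)
  src <- rep_len(if (first == 1L) c(1L, 2L) else c(2L, 1L), length(bounds) - 1L)
  out_s <- numeric(0); out_h <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (hi <= lo) next
    mos <- if (src[i] == 1L) mosA else mosB
    j0 <- findInterval(lo, mos[, 1L])
    j1 <- findInterval(hi, mos[, 1L], left.open = TRUE)
    s <- mos[j0:j1, 1L]; h <- mos[j0:j1, 2L]
    s[1L] <- lo
    out_s <- c(out_s, s); out_h <- c(out_h, h)
  }
  keep <- c(TRUE, out_h[-1L] != out_h[-length(out_h)])
  list(mos = cbind(out_s[keep], out_h[keep]), ncross = ncross)
}

#' Forward pedigree simulation with tracked transmission
#'
#' Simulates `generations` generations from a founder panel under the
#' [pedigree_spec()] mating design, tracking every haplotype as a mosaic of
#' founder-haplotype segments. Because transmission paths are tracked
#' exactly, true IBD between any two simulated individuals — the genomic
#' intervals on which they carry the same founder haplotype — and pedigree
#' relationships can be emitted exactly (see [pedigree_truth()]).
#'
#' @param founder_panel a [haplotype_panel()] with `2 * founders`
#'   haplotypes, or a list of such panels (one per chromosome when `Lt` is a
#'   vector); may be `NULL` when `build_panel = FALSE`.
#' @param spec a [pedigree_spec()].
#' @param build_panel construct allele panels for the extracted descendants
#'   (the last `min(4, generations)` generations) by copying founder alleles
#'   through the mosaics. Set to `FALSE` for relatedness studies that only
#'   need the tracked truth.
#' @return Object of class `pedigree_sim`: list with `pedigree` (data frame
#'   `id`, `father`, `mother`, `sex`, `generation`), `mosaics` (per
#'   chromosome, a list of mosaic matrices named `<id>_0` / `<id>_1`),
#'   `extracted` (ids of the last up-to-four generations), `panels`
#'   (optional, per chromosome), `crossover_counts` (all Poisson draws, for
#'   auditing) and `spec`.
#' @export
simulate_pedigree <- function(founder_panel, spec, build_panel = TRUE) {
  stopifnot(inherits(spec, "pedigree_spec"))
  n_chrom <- length(spec$Lt)
  panels <- if (is.null(founder_panel)) NULL
            else if (inherits(founder_panel, "haplotype_panel")) list(founder_panel)
            else founder_panel
  if (build_panel) {
    if (is.null(panels)) stop("build_panel = TRUE needs a founder panel")
    if (length(panels) != n_chrom)
      stop("need one founder panel per chromosome (", n_chrom, ")")
    for (p in panels)
      if (p$n_haps != 2L * spec$founders)
        stop("founder panel must have 2 * founders haplotypes")
  }

  F <- spec$founders
  ped <- data.frame(id = sprintf("G0_%d", seq_len(F)),
                    father = NA_character_, mother = NA_character_,
                    sex = NA_character_, generation = 0L,
                    stringsAsFactors = FALSE)
  cross_counts <- integer(0)

  # mosaics[[chrom]] is an environment keyed by haplotype id "<ind>_0|1"
  mosaics <- lapply(seq_len(n_chrom), function(ci) {
    e <- new.env(parent = emptyenv())
    for (i in seq_len(F)) {
      assign(sprintf("G0_%d_0", i), cbind(0, 2L * (i - 1L)), envir = e)
      assign(sprintf("G0_%d_1", i), cbind(0, 2L * i - 1L), envir = e)
    }
    e
  })

  withr_seed(spec$seed, {
    ped$sex <- sample(c("M", "F"), F, replace = TRUE)
    prev <- ped
    for (g in seq_len(spec$generations)) {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      nc <- min(spec$couples, length(males), length(females))
      if (nc < 1L) stop("generation ", g, ": no couples can be formed")
      cm_ <- sample(males, nc); cf <- sample(females, nc)
      kids <- data.frame(id = sprintf("G%d_%d", g, seq_len(F)),
                         father = NA_character_, mother = NA_character_,
                         sex = sample(c("M", "F"), F, replace = TRUE),
                         generation = g, stringsAsFactors = FALSE)
      for (k in seq_len(F)) {
        cp <- sample.int(nc, 1L)
        father <- cm_[cp]; mother <- cf[cp]
        if (length(males) > 1L && stats::runif(1L) < spec$extra_pair) {
          repeat { f2 <- males[sample.int(length(males), 1L)]; if (f2 != father) break }
          father <- f2
        }
        kids$father[k] <- father; kids$mother[k] <- mother
        for (ci in seq_len(n_chrom)) {
          e <- mosaics[[ci]]; Lt <- spec$Lt[ci]
          gp <- .gamete(get(paste0(father, "_0"), e), get(paste0(father, "_1"), e), Lt)
          gm <- .gamete(get(paste0(mother, "_0"), e), get(paste0(mother, "_1"), e), Lt)
          cross_counts <- c(cross_counts, gp$ncross, gm$ncross)
          assign(paste0(kids$id[k], "_0"), gp$mos, envir = e)
          assign(paste0(kids$id[k], "_1"), gm$mos, envir = e)
        }
      }
      ped <- rbind(ped, kids)
      prev <- kids
    }
  })

  keep_gen <- if (spec$generations == 0L) integer(0)
              else seq(max(1L, spec$generations - 3L), spec$generations)
  extracted <- ped$id[ped$generation %in% keep_gen]

  out_panels <- NULL
  if (build_panel && length(extracted)) {
    out_panels <- lapply(seq_len(n_chrom), function(ci) {
      fp <- panels[[ci]]
      cm_scale <- fp$site_cm - fp$site_cm[1L] # mosaics live on [0, Lt]
      e <- mosaics[[ci]]
      hap_ids <- as.vector(rbind(paste0(extracted, "_0"), paste0(extracted, "_1")))
      alleles <- matrix(0L, nrow = length(hap_ids), ncol = fp$n_sites)
      for (r in seq_along(hap_ids)) {
        mos <- get(hap_ids[r], e)
        piece <- findInterval(cm_scale, mos[, 1L])
        piece[piece < 1L] <- 1L
        src <- mos[piece, 2L]
        for (fh in unique(src)) {
          sel <- src == fh
          alleles[r, sel] <- fp$alleles[fh + 1L, sel]
        }
      }
      haplotype_panel(alleles, fp$site_bp, fp$site_cm, hap_ids)
    })
  }

  structure(list(pedigree = ped, mosaics = mosaics, extracted = extracted,
                 panels = out_panels, crossover_counts = cross_counts,
                 spec = spec),
            class = "pedigree_sim")
}

#' @export
print.pedigree_sim <- function(x, ...) {
  cat(sprintf("pedigree_sim: %d founders, %d generations, %d chromosome(s) (%.0f cM total)\n",
              x$spec$founders, x$spec$generations, length(x$spec$Lt),
              sum(x$spec$Lt)))
  invisible(x)
}

#' Pedigree kinship coefficient
#'
#' Exact kinship from the recorded pedigree by the standard recursion:
#' founders are unrelated and non-inbred; for a pair where `a` is the later
#' individual, `phi(a, b) = (phi(father_a, b) + phi(mother_a, b)) / 2`;
#' `phi(a, a) = 1/2 + phi(father_a, mother_a) / 2`.
#'
#' @param ped pedigree data frame from [simulate_pedigree()].
#' @param a,b individual ids.
#' @param memo optional environment reused across calls for memoization.
#' @return kinship coefficient in `[0, 1]`.
#' @export
pedigree_kinship <- function(ped, a, b, memo = new.env(parent = emptyenv())) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- if (x <= y) paste0(x, "\r", y) else paste0(y, "\r", x)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (x == y) {
      0.5 + 0.5 * phi(ped$father[idx[[x]]], ped$mother[idx[[x]]])
    } else {
      gx <- ped$generation[idx[[x]]]; gy <- ped$generation[idx[[y]]]
      if (gx == 0L && gy == 0L) 0
      else if (gx >= gy)
        0.5 * (phi(ped$father[idx[[x]]], y) + phi(ped$mother[idx[[x]]], y))
      else
        0.5 * (phi(ped$father[idx[[y]]], x) + phi(ped$mother[idx[[y]]], x))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Relatedness degree from a kinship coefficient
#'
#' Standard kinship ranges: first degree (0.177, 0.354], second
#' (0.0884, 0.177], third (0.0442, 0.0884], fourth (0.0221, 0.0442];
#' anything lower is labelled `"unrelated"`.
#'
#' @param phi kinship coefficient(s).
#' @return character vector of labels `"1"`..`"4"` or `"unrelated"`.
#' @export
kinship_degree <- function(phi) {
  cut(phi, breaks = c(-Inf, 0.0221, 0.0442, 0.0884, 0.177, Inf),
      labels = c("unrelated", "4", "3", "2", "1")) |> as.character()
}

#' True IBD segments between two simulated individuals
#'
#' Intersects the founder-haplotype mosaics of the four haplotype pairings
#' of two individuals: an interval is IBD for a pairing when both
#' haplotypes descend from the same founder haplotype there. Segments are
#' reported per haplotype pairing (a region shared on both pairings is two
#' segments, matching how called IBD is summed) and filtered by `min_cm`.
#'
#' @param sim a `pedigree_sim`.
#' @param id_a,id_b individual ids present in the simulation.
#' @param min_cm minimum segment genetic length in cM (default 7).
#' @return data frame with columns `hap_a`, `hap_b`, `chrom`, `start_cm`,
#'   `end_cm`, `cm_length`.
#' @export
mosaic_ibd <- function(sim, id_a, id_b, min_cm = 7) {
  stopifnot(inherits(sim, "pedigree_sim"))
  out <- list()
  for (ci in seq_along(sim$mosaics)) {
    e <- sim$mosaics[[ci]]; Lt <- sim$spec$Lt[ci]
    for (pa in 0:1) for (pb in 0:1) {
      ha <- sprintf("%s_%d", id_a, pa); hb <- sprintf("%s_%d", id_b, pb)
      ma <- get(ha, e); mb <- get(hb, e)
      bounds <- sort(unique(c(ma[, 1L], mb[, 1L], Lt)))
      lo <- bounds[-length(bounds)]; hi <- bounds[-1L]
      fa <- ma[findInterval(lo, ma[, 1L]), 2L]
      fb <- mb[findInterval(lo, mb[, 1L]), 2L]
      same <- fa == fb
      if (!any(same)) next
      mi <- .merge_float_intervals(lo[same], hi[same])
      len <- mi$end - mi$start
      keep <- len >= min_cm
      if (!any(keep)) next
      out[[length(out) + 1L]] <-
        data.frame(hap_a = ha, hap_b = hb, chrom = ci,
                   start_cm = mi$start[keep], end_cm = mi$end[keep],
                   cm_length = len[keep])
    }
  }
  if (!length(out))
    return(data.frame(hap_a = character(), hap_b = character(),
                      chrom = integer(), start_cm = numeric(),
                      end_cm = numeric(), cm_length = numeric()))
  do.call(rbind, out)
}

# merge abutting/overlapping real-valued intervals
.merge_float_intervals <- function(start, end, tol = 1e-9) {
  ord <- order(start)
  s <- start[ord]; e <- end[ord]
  ms <- s[1L]; me <- e[1L]; out_s <- numeric(); out_e <- numeric()
  if (length(s) > 1L) for (i in 2L:length(s)) {
    if (s[i] <= me + tol) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Pairwise relatedness truth for a set of simulated individuals
#'
#' For every pair among `ids`, the exact pedigree kinship, its degree label,
#' and the total true IBD length above the genealogical cutoff. Pairs with
#' zero kinship share no founder haplotype and are total 0 by construction,
#' so their mosaics are not scanned.
#'
#' @param sim a `pedigree_sim`.
#' @param ids individual ids (default: the simulation's extracted set).
#' @param min_cm minimum per-segment length in cM (default 7).
#' @return data frame with columns `id_a`, `id_b`, `kinship`, `degree`,
#'   `total_cm`, `n_segments`.
#' @export
pedigree_truth <- function(sim, ids = sim$extracted, min_cm = 7) {
  stopifnot(inherits(sim, "pedigree_sim"))
  if (length(ids) < 2L) stop("need at least two individuals")
  memo <- new.env(parent = emptyenv())
  prs <- utils::combn(ids, 2L)
  n <- ncol(prs)
  kin <- numeric(n); tot <- numeric(n); nseg <- integer(n)
  for (i in seq_len(n)) {
    kin[i] <- pedigree_kinship(sim$pedigree, prs[1L, i], prs[2L, i], memo)
    if (kin[i] > 0) {
      seg <- mosaic_ibd(sim, prs[1L, i], prs[2L, i], min_cm = min_cm)
      tot[i] <- sum(seg$cm_length)
      nseg[i] <- nrow(seg)
    }
  }
  data.frame(id_a = prs[1L, ], id_b = prs[2L, ], kinship = kin,
             degree = kinship_degree(kin), total_cm = tot, n_segments = nseg)
}
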