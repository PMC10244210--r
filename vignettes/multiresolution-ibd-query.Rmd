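---
title: "Multi-resolution PBWT queries for error-tolerant IBD search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution PBWT queries for error-tolerant IBD search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdquery)
```

## The problem and the model

Two individuals who share a recent common ancestor carry, on some
chromosome, a contiguous segment inherited identical by descent (IBD). On
phased bi-allelic data an IBD segment manifests as a long, *near*-exact
match between two haplotypes: exact but for occasional discordant sites
caused by genotyping error, gene conversion or recent mutation. Genealogical
search asks, for one query haplotype against a large panel, for all panel
haplotypes sharing such a segment of at least `L` centiMorgans, and for the
segment coordinates.

`ibdquery` decomposes this into two sub-problems.

**Exact long matches.** The positional Burrows–Wheeler transform keeps the
panel sorted at every site boundary by reversed prefixes. Haplotypes that
agree with the query over a site range are contiguous in that order, so the
set of haplotypes whose agreement covers a moving window `[W(k), k]` is an
interval — the *long-match block* — that can be maintained through one
left-to-right sweep: extension through site `k` via cumulative allele
counts, expansion at the edges via divergence values, and reporting when a
member carries the opposite allele at the next site (a break). The window
start `W(k)` is `k + 1 − L` for a site-count threshold, or the *site
distance track index* `max{ i ≤ k : cm[k] − cm[i] ≥ L }` for a genetic
threshold; the index is maintained by a pointer that only moves forward, so
threshold handling costs O(n) overall and the sweep needs no bp-to-cM
conversion table at query time.

Two implementation points deserve note, because they are where a PBWT
long-match query usually goes wrong:

* *Exact neighbour agreement.* The sweep tracks the query's insertion
  position and the start of its maximal agreement run with the sorted
  neighbour directly below and above. Divergence chains give a sound bound
  for these starts, but with binary alleles the bound is not always tight
  (if two haplotypes first differ exactly where the first one breaks with
  the query, the second one *agrees* with the query there). The
  implementation therefore verifies the chain value by direct allele
  comparison, walking left only over sites it actually proves; the walk is
  what makes reported matches exactly maximal, and is also why the
  worst-case cost is O(nm) while the typical cost stays O(n + output).
* *Report-time start recovery.* A haplotype leaving the block is known to
  agree with the query at least back to the current window start, so its
  maximal start is recovered by walking left from there, not from the match
  end — cost proportional to the overhang, not the match length.

The block contract is checked against a brute-force oracle (maximal
agreement runs per haplotype, filtered by the threshold) on a thousand
random instances in the acceptance suite; the oracle, not the
implementation, defines correctness.

**Mismatch tolerance by random projection.** The panel is divided into
`⌈n/w⌉` windows of `w` sites; each of `r` projection runs samples one site
per window, with probability proportional to the site's minor allele
frequency within the window (common variants carry little identity
information; rare alleles distinguish haplotype backgrounds). A mismatch
inside a window is invisible to a run that happened to sample a different
site, so an IBD segment with scattered errors still produces full-length
exact matches on most low-resolution panels. A low-resolution match over
windows `[h′, t′]` rescales to sites `[w·h′, w·(t′+1)−1]` (clipped to
`n−1` in a partial last window).

**Merging and refinement.** Matches pooled over runs are grouped by end
position and panel haplotype; in each group the match with the `c`-th
smallest start (multiplicity counted) is kept — since all matches in a group
share an end, that match is completely overlapped by at least `c` run
matches, which is the support requirement. Surviving *fragmented IBDs* that
overlap are unioned into *candidate IBDs*. Finally the exact long-match
query is run once on the full-resolution panel at a short `refine` cutoff,
and each candidate is replaced by the union of the exact matches overlapping
it, so reported boundaries always lie on exact-match boundaries (trimming
window-aligned overshoot, extending through sampled-over ends). Refined
pieces of a haplotype pair separated by a genetic gap of at most `gmax` are
stitched — the gap is attributed to a genotyping error, mutation or gene
conversion that the projection runs did not sample around. Segments below
`L_final` cM or `min_markers` sites are dropped. Everything is deterministic
given the projection seed and uses no intermediate files.

## Parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `L_final` | cM | 7 | conventional genealogical-search cutoff used by consumer matching services |
| `min_markers` | sites | 700 | companion marker floor to the 7 cM convention |
| `refine_cm` | cM | 0.5 | exact-match cutoff for refinement; 0.5 suits sequencing density, 1.0 array density — smaller values recover boundaries more aggressively (lower FNR, slightly higher FPR) |
| `r` | runs | 10 | projection runs; detection of a segment with per-window miss probability `1/w` behaves like a Binomial(`r`, `q`) exceeding `c` |
| `c` | runs | 2 | support threshold; raising it trades sensitivity for specificity |
| `w` | sites | `L_final`-dependent | chosen so a minimum-length segment spans ~10 windows at the panel's mean marker density (`index_bundle(windows_per_cutoff = 10)`) |
| `gmax` | cM | 2 | maximum stitched gap between refined pieces |
| `maf_threshold` | frequency | 0.01 | sites with MAF ≤ threshold are filtered at panel load |

The low-resolution threshold defaults to `round(L_sites / w)` windows, with
`L_sites` the site-count equivalent of `L_final` at mean marker density;
rounding (rather than flooring) was chosen so that a non-integral ratio
splits the difference instead of systematically loosening the cutoff. It can
be overridden via `ibd_query(L_lowres = )`.

## Coordinate and container conventions

Site indices in every match and segment table are 0-based and
end-inclusive — the rescaling identity `[w·h′, w·(t′+1)−1]` and the window
arithmetic assume exactly this — while bp positions are 1-based as in VCF.
Panels are plain matrices wrapped in a light S3 class with per-site bp/cM
tracks; the PBWT index stores all per-boundary arrays (O(mn) integers)
because queries re-enter arbitrary boundaries, matching the pre-processed
in-memory usage pattern the query workflow assumes. Genetic positions come
from HapMap-style or PLINK-style map files by linear interpolation between
flanking points and constant extrapolation outside the map (the
interpolation rule is a package choice; monotonicity is guaranteed and
tested). Missing genotypes are unsupported by design: panels are assumed
complete and phased, and `read_vcf()` fails loudly rather than imputing.

## Design decisions where the procedure was open

* *Grouping key.* End-position groups are keyed by panel haplotype as well
  as end site; without this the `c`-th-smallest-start rule would mix
  matches from different haplotypes sharing an end.
* *Unsupported candidates are dropped.* A candidate overlapping no
  full-resolution exact match at the `refine` cutoff does not survive.
  Reported boundaries must be exact-match boundaries; a candidate with no
  exact support above `refine_cm` has no credible boundary evidence and, at
  sequencing density, a genuine segment of `L_final` cM with realistic
  error rates essentially always contains exact stretches longer than
  0.5 cM.
* *Stitching operates after refinement,* between refined pieces of the same
  haplotype pair, using the genetic distance from the end of one piece to
  the start of the next; whether the pieces descend from one candidate or
  two is irrelevant (only the distance rule applies).
* *Duplicate handling.* A run contributes at most one match per
  `(haplotype, start, end)`; identical matches from different runs retain
  multiplicity, which is precisely what the `c` rule counts.
* *Ties in the sampler.* An all-zero-MAF window (possible after filtering)
  falls back to uniform sampling; weighted sampling is undefined there.
* *Haplotype-level pairing in the metrics.* The rate equations compare
  segments "of the same sampled id"; the package defaults to haplotype
  pairs and offers `level = "individual"`, which collapses `_0`/`_1`
  suffixes and takes coverage as the union over the four pairings.
* *RMS pairing rule.* The length-discrepancy metric needs a reported-to-true
  pairing the equations do not specify; maximal site overlap within the
  pair is used, and a reported segment with no overlapping truth contributes
  its full length (a conservative penalty).
* *Worked-example fixture.* The merge/refine walk-through fixture
  (`merge_refine_example()`) realizes the narrated structure — six end groups, one
  single-member group discarded, five fragments, three candidates, a
  sub-`gmax` stitch and a two-sided trim, ending in two segments. Its
  numeric coordinates are frozen package choices; only the structure and the
  5 → 3 → 2 counts are externally fixed.

## What the synthetic generators do and do not emulate

`generate_panel()` draws sites independently from a target frequency
spectrum: there is no linkage disequilibrium, no population structure, and
hence no background relatedness — long shared segments exist only where
`plant_ibd()` copies donor alleles onto a recipient. This makes planted
panels ideal for controlled power/accuracy measurements (the planted truth
is exact, and false positives cannot hide in real background IBD), but it
means a green planted-segment test establishes algorithmic correctness, not
calibration on coalescent data: with independent sites, random exact matches
above ~0.5 cM are astronomically rare, so refinement has an easier job than
on real sequences. Genotyping error is independent per-allele flipping at
the stated rate (0.04% sequencing-like, 0.13% array-like); phasing error is
not modelled.

The pedigree simulator draws crossovers per meiosis as Poisson with mean
`Lt/50` with positions uniform in genetic distance (no interference), mates
up to 500 non-overlapping couples per generation with a 0.2 extra-pair
paternity rate, and tracks every transmitted segment, so true IBD and exact
pedigree kinship are emitted by construction rather than estimated. Degree
labels use the standard kinship ranges (first degree (0.177, 0.354], then
halving per degree, "unrelated" below 0.0221) — note that this labels
distant-but-real relatives (e.g. second cousins) "unrelated", which is
faithful to how biobank ground truth is thresholded.

The degree-separation acceptance test simulates a 22-chromosome genome with
per-chromosome lengths of 100–280 cM over one shared pedigree. A single
chromosome in that range cannot separate fourth-degree pairs from unrelated
ones at AUC ≥ 0.9 no matter how the detector performs: a fourth-degree pair
expects on the order of one ≥7 cM segment per ~200 cM chromosome, so a
large fraction of such pairs share nothing at all on one chromosome. The
multi-chromosome genome mirrors the multi-autosome design of relatedness
studies while keeping each chromosome in the stated length band; the test
asserts strictly decreasing class means and AUC ≥ 0.9 between adjacent
degrees, with totals taken from tracked truth above the 7 cM genealogical
cutoff.

## Numerical and degenerate-input choices

* Thresholds: a site-count cutoff must be a whole positive number; a
  genetic cutoff of 0 is allowed in the distance index (`i = k`) but
  queries require `L > 0`. A cM-threshold match is emitted only if its
  realized span meets `L`, guarding window-edge rounding.
* Interval semantics: merging treats intervals sharing at least one site as
  overlapping; abutting-but-disjoint intervals (`start = end + 1`) are not
  merged — stitching across them is `gmax`'s job and is measured in cM.
* Degenerate panels: single-haplotype and all-identical panels exercise the
  divergence sentinels (`d[0] = k`) and are tested explicitly; empty panels
  are rejected at construction.
* Reproducibility: every generator takes a seed and restores the caller's
  RNG state; projection runs draw from per-run L'Ecuyer-CMRG substreams so
  extending `r` never reshuffles earlier runs.
* Binned rates report `NA` (not 0) for empty bins, and the covering set is
  length-floored per the binned definitions (reported ≥ 2 cM for FNR,
  true ≥ 1.5 cM for FPR).

## Known limitations

* No missing-genotype or unphased-data support; no BCF/tabix, one
  chromosome per VCF call.
* The index holds all per-boundary arrays in memory (~12 bytes per
  haplotype-site); biobank-scale panels need more economical storage than
  this implementation aims for.
* Exact-match refinement assumes marker density high enough that true
  segments contain ≥ `refine_cm` exact stretches; very sparse panels should
  raise `refine_cm` and accept coarser boundaries.
* The optional coalescent replication (demographic-model simulation,
  external recombination maps) is deliberately outside the package; the
  synthetic stack here is the tested core.
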