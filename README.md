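# ibdquery

Error-tolerant, one-versus-all identity-by-descent (IBD) segment search in R.

`ibdquery` answers the genealogical-search question: given one phased query
haplotype and a panel of *m* phased haplotypes over *n* bi-allelic sites,
which panel haplotypes share a chromosomal segment of at least *L* cM with
the query, and where? Such long shared segments are the signature of recent
common ancestry, and their summed length separates first- through
fourth-degree relatives. The intended users are statistical geneticists and
tool builders who need out-of-panel IBD queries (the panel is indexed once,
queries arrive one at a time) rather than all-versus-all detection.

## Method

Exact matching uses the positional Burrows–Wheeler transform (PBWT): at
every site boundary *k* the panel is kept sorted by reversed prefixes
(prefix array *p*, divergence array *d*), and cumulative allele counts
(*u*, *v*) extend any sorted interval through a site in O(1). A single
left-to-right sweep maintains the query's virtual insertion position, its
exact agreement spans with its sorted neighbours, and the *long-match
block* — the interval of haplotypes whose agreement with the query covers
the moving window `[W(k), k]`, where `W(k) = k + 1 − L` for a site-count
cutoff or the tracked site-distance index `max{ i ≤ k : cm[k] − cm[i] ≥ L }`
for a genetic cutoff. Haplotypes leaving the block on an allele break are
reported as maximal matches; worst-case time is O(nm), typically
O(n + output).

Real IBD segments contain mismatches (genotyping error, mutation, gene
conversion), so exact matching alone under-calls. The pipeline therefore
projects the panel onto `r` low-resolution sub-panels — one site sampled per
`w`-site window, with probability proportional to the site's minor allele
frequency — and runs the exact query on each. Low-resolution matches are
grouped by end position; within each `(end, haplotype)` group the match with
the `c`-th smallest start is kept (guaranteeing support from ≥ `c` of the
`r` runs), overlapping survivors are merged into candidates, and candidates
are refined against full-resolution exact matches above a short `refine`
cutoff (0.5–2 cM): reported boundaries come from the exact matches, pieces
separated by a genetic gap ≤ `gmax` are stitched, and segments shorter than
`L_final` cM or `min_markers` sites are dropped.

The package also implements the matching evaluation metrics — site-level
false negative rate `1/|I_T| Σ_it 1/|it| Σ_{st∈it} [st uncovered]`, the
symmetric false positive rate, binned variants, RMS genetic-length
discrepancy — plus sum-of-IBD relatedness analysis (pair totals, ROC AUC
between degree classes) and the synthetic generators used to benchmark all
of it: random panels, planted IBD segments, genotyping-error injection, and
a forward pedigree simulator with Poisson(Lt/50) crossovers and tracked
transmission.

## Worked example

```r
library(ibdquery)

# a 100-haplotype panel spanning 50 cM, with one out-of-panel query carrying
# two planted segments and 0.04% genotyping error
sim     <- generate_panel(101, 5000, seed = 42)
planted <- plant_ibd(sim, plant_spec(2, len_range = c(8, 12),
                                     recipients = 100L, donors = 0:99,
                                     seed = 43))
noisy   <- add_genotyping_error(planted$panel, 4e-4, seed = 44)
panel   <- haplotype_panel(noisy$alleles[1:100, ], noisy$site_bp,
                           noisy$site_cm, noisy$hap_ids[1:100])

bundle <- index_bundle(panel, r = 10, seed = 45, L_final = 3)
calls  <- ibd_query(bundle, noisy$alleles[101, ], L_final = 3,
                      min_markers = 250, refine_cm = 0.5,
                      query_hap = noisy$hap_ids[101])
calls
#>   query_hap panel_hap start_site end_site start_bp  end_bp cm_length n_markers
#> 1    hap100     hap39       2946     3769  2946590 3769754   8.23164       824
#> 2    hap100     hap76        640     1599   640129 1599321   9.59192       960

false_negative_rate(planted$truth, calls)
#> [1] 0
length_discrepancy_rms(calls, planted$truth)
#> [1] 0.01414214
```

Both planted segments (truth: `hap39` sites 2946–3769, `hap76` sites
642–1599) are recovered despite the injected allele flips; the second call
over-extends by two sites at one boundary — an error flip landed next to the
true endpoint and the flanking exact match absorbed it — giving the 0.014 cM
RMS length discrepancy. Site indices are 0-based and end-inclusive, bp
positions 1-based as in VCF, and `cm_length` is the genetic span of the
call.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline behaviour from scratch: it synthesizes a
300-haplotype, 12,000-site panel (120 cM) with 80 planted segments of
3–20 cM and 0.04% genotyping error, indexes it, runs the error-tolerant
query for every planted recipient haplotype, and prints the overall and
binned false negative / false positive rates and the RMS length discrepancy
of the calls against the planted truth, writing the JSON report to `--out`.
All randomness derives from `--seed`.
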