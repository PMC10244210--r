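# Shared fixtures and independent oracles, built in code.

rand_panel <- function(m, n, seed, p1 = NULL) {
  set.seed(seed)
  if (is.null(p1)) p1 <- stats::runif(1, 0.2, 0.8)
  alleles <- matrix(stats::rbinom(m * n, 1L, p1), nrow = m)
  cm <- cumsum(stats::runif(n, 0, 0.5))
  haplotype_panel(alleles, seq_len(n) * 100L, cm)
}

# Brute-force PBWT: order haplotypes at every boundary by reversed prefix
# (stable, so ties keep original index order) and recompute divergences by
# direct suffix comparison.
pbwt_brute <- function(X) {
  m <- nrow(X); n <- ncol(X)
  a <- matrix(0L, m, n + 1L); d <- matrix(0L, m, n + 1L)
  for (k in 0:n) {
    ord <- if (k == 0L) seq_len(m)
           else do.call(order, c(unname(as.data.frame(X[, k:1, drop = FALSE])),
                                 list(seq_len(m))))
    a[, k + 1L] <- ord - 1L
    d[1L, k + 1L] <- k
    if (m > 1L) for (i in 2:m) {
      x <- ord[i]; y <- ord[i - 1L]
      j <- k
      while (j > 0L && X[x, j] == X[y, j]) j <- j - 1L
      d[i, k + 1L] <- j
    }
  }
  list(a = a, d = d)
}

norm_matches <- function(df) {
  df <- as.data.frame(df)[, c("hap", "start", "end")]
  df <- df[order(df$hap, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

# minimal phased VCF writer for hand-built fixtures
write_vcf_lines <- function(path, samples, records) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(pos, gts, alt = "G") {
  paste(c("1", pos, ".", "A", alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
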