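test_that("group_by_end buckets matches by end and haplotype", {
  m <- data.frame(run = c(1L, 2L, 1L),
                  hap = c(1L, 1L, 1L),
                  start = c(0L, 2L, 0L),
                  end = c(9L, 9L, 5L))
  tab <- group_by_end(m)
  expect_s3_class(tab, "end_group_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$start[tab$end == 9L], c(0L, 2L))
  expect_equal(tab$start[tab$end == 5L], 0L)
  expect_equal(nrow(group_by_end(m[0, ])), 0L)
  # within-run exact duplicates collapse; cross-run duplicates persist
  dup <- data.frame(run = c(1L, 1L, 2L), hap = 3L, start = 4L, end = 8L)
  expect_equal(nrow(group_by_end(dup)), 2L)
  # distinct haplotypes never share a (end, hap) group
  two <- group_by_end(data.frame(hap = c(1L, 2L), start = 0L, end = 9L))
  expect_equal(nrow(fragmented_ibds(two, c = 1L)), 2L)
})

test_that("fragmented_ibds picks the c-th smallest start per group", {
  tab <- group_by_end(data.frame(hap = 0L, start = c(9L, 4L, 7L), end = 20L))
  expect_equal(fragmented_ibds(tab, c = 2L)$start, 7L)
  expect_equal(fragmented_ibds(tab, c = 1L)$start, 4L)
  # a group with a single match is discarded at c = 2
  single <- group_by_end(data.frame(hap = 0L, start = 5L, end = 20L))
  expect_equal(nrow(fragmented_ibds(single, c = 2L)), 0L)
  # duplicates count with multiplicity
  dup <- group_by_end(data.frame(run = 1:3, hap = 0L, start = c(5L, 5L, 8L),
                                 end = 20L))
  expect_equal(fragmented_ibds(dup, c = 2L)$start, 5L)
  expect_error(fragmented_ibds(tab, c = 0L), ">= 1")
})

test_that("increasing c never increases the number of fragmented IBDs", {
  set.seed(12)
  for (i in 1:10) {
    n <- 200L
    m <- data.frame(run = sample.int(8, n, TRUE),
                    hap = sample.int(5, n, TRUE),
                    start = sample.int(50, n, TRUE))
    m$end <- m$start + sample.int(40, n, TRUE)
    tab <- group_by_end(m)
    counts <- vapply(1:6, function(cc) nrow(fragmented_ibds(tab, cc)), integer(1L))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("merge_candidates unions overlapping fragments per haplotype", {
  fr <- data.frame(hap = c(0L, 0L), start = c(10L, 15L), end = c(20L, 30L))
  expect_equal(as.data.frame(merge_candidates(fr)),
               data.frame(hap = 0L, start = 10L, end = 30L))
  fr2 <- data.frame(hap = c(0L, 0L), start = c(10L, 25L), end = c(20L, 30L))
  expect_equal(nrow(merge_candidates(fr2)), 2L)
  fr3 <- data.frame(hap = 2L, start = 5L, end = 9L)
  expect_equal(as.data.frame(merge_candidates(fr3)), fr3)
  # candidates stay disjoint per haplotype
  set.seed(5)
  fr4 <- data.frame(hap = sample.int(3, 50, TRUE), start = sample.int(80, 50, TRUE))
  fr4$end <- fr4$start + sample.int(20, 50, TRUE)
  cand <- merge_candidates(fr4)
  for (h in unique(cand$hap)) {
    iv <- cand[cand$hap == h, ]
    if (nrow(iv) > 1L) expect_true(all(iv$start[-1L] > iv$end[-nrow(iv)] ))
  }
})

test_that("refine trims, stitches and filters candidates", {
  cm <- (0:59) * 0.5; bp <- (0:59) * 1000L + 1L
  cand <- merge_candidates(data.frame(hap = 0L, start = 10L, end = 30L))
  exact <- data.frame(hap = 0L, start = c(8L, 21L), end = c(18L, 29L))
  # gap 18 -> 21 is 1.5 cM <= gmax: one stitched segment [8, 29]
  got <- refine(cand, exact, cm, bp, gmax = 2, L_final = 1, min_markers = 2)
  expect_equal(got$start_site, 8L)
  expect_equal(got$end_site, 29L)
  expect_equal(got$cm_length, cm[30] - cm[9])
  # with gmax below the gap the pieces stay apart
  got2 <- refine(cand, exact, cm, bp, gmax = 1, L_final = 1, min_markers = 2)
  expect_equal(got2$start_site, c(8L, 21L))
  # a candidate overlapping no exact match is dropped
  far <- data.frame(hap = 0L, start = 50L, end = 55L)
  expect_equal(nrow(refine(merge_candidates(far), exact, cm, bp,
                           gmax = 2, L_final = 1, min_markers = 2)), 0L)
  # exact matches not touching any candidate are discarded
  exact3 <- rbind(exact, data.frame(hap = 0L, start = 45L, end = 59L))
  got3 <- refine(cand, exact3, cm, bp, gmax = 2, L_final = 1, min_markers = 2)
  expect_equal(got3$start_site, 8L)
  expect_error(refine(cand, exact, cm, bp, gmax = -1), "non-negative")
})

test_that("the worked merge-and-refine example yields 5 -> 3 -> 2", {
  fx <- merge_refine_example()
  frag <- fragmented_ibds(group_by_end(fx$lowres), c = fx$params$c)
  expect_equal(nrow(frag), 5L)
  cand <- merge_candidates(frag)
  expect_equal(nrow(cand), 3L)
  fin <- refine(cand, fx$exact, fx$site_cm, fx$site_bp,
                gmax = fx$params$gmax, L_final = fx$params$L_final,
                min_markers = fx$params$min_markers, hap_ids = fx$hap_ids)
  expect_equal(nrow(fin), 2L)
  # first segment stitched across the sub-gmax gap, second trimmed inwards
  expect_equal(fin$start_site, c(1L, 38L))
  expect_equal(fin$end_site, c(25L, 53L))
})

test_that("ibd_query composes the stages deterministically", {
  set.seed(61)
  panel <- generate_panel(40, 3000, seed = 15) # 30 cM at default density
  bundle <- index_bundle(panel, r = 8, seed = 5, L_final = 3)
  # querying an exact copy of a panel haplotype finds (nearly) the whole span
  q <- panel$alleles[11, ]
  got <- ibd_query(bundle, q, L_final = 3, min_markers = 100,
                     refine_cm = 0.5)
  seg <- got[got$panel_hap == panel$hap_ids[11], ]
  expect_equal(nrow(seg), 1L)
  expect_lte(seg$start_site, 5L)
  expect_gte(seg$end_site, 2994L)
  # determinism: identical bundle and query give identical output
  expect_identical(ibd_query(bundle, q, L_final = 3, min_markers = 100,
                               refine_cm = 0.5), got)
  # unrelated random query yields (near-)empty output at a long cutoff
  qr <- rbinom(3000, 1, 0.5)
  expect_equal(nrow(ibd_query(bundle, qr, L_final = 7, min_markers = 100)), 0L)
})

test_that("raising refine_cm never increases the exact match count", {
  panel <- rand_panel(25, 400, seed = 77)
  idx <- build_pbwt_index(panel)
  set.seed(8)
  q <- panel$alleles[3, ]
  q[sample.int(400, 4)] <- 1L - q[sample.int(400, 4)]
  counts <- vapply(c(0.5, 1, 2, 4), function(rc)
    nrow(long_match_query(idx, q, length_threshold(rc, "cM"))), integer(1L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("reported segments are window-supported by at least c runs", {
  # planted copy with scattered flips: every non-stitched window of a
  # reported segment must appear in >= c run matches
  panel <- generate_panel(30, 2000, seed = 19)
  bundle <- index_bundle(panel, r = 10, seed = 2, L_final = 3)
  w <- bundle$scheme$w
  q <- panel$alleles[5, ]
  set.seed(3)
  q[sample.int(2000, 2)] <- 1L - q[sample.int(2000, 2)]
  low <- run_projection_queries(bundle$sub_indexes, q,
                                max(1L, round(300 / w)), bundle$scheme)
  got <- ibd_query(bundle, q, L_final = 3, min_markers = 100, refine_cm = 0.5)
  seg <- got[got$panel_hap == panel$hap_ids[5], ]
  expect_equal(nrow(seg), 1L)
  support <- low[low$hap == 4L, ]
  # count supporting runs per window inside the called segment
  wins <- seq(floor(seg$start_site / w), floor(seg$end_site / w))
  cover <- vapply(wins, function(s) {
    length(unique(support$run[support$start <= s * w &
                              support$end >= min(s * w + w - 1L, 1999L)]))
  }, integer(1L))
  expect_true(mean(cover >= 2L) > 0.9) # allow stitched flip windows
})
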