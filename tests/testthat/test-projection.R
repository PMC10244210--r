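test_that("projection schemes respect windows and are reproducible", {
  panel <- rand_panel(8, 53, seed = 4) # 11 windows of 5, last partial
  sch <- make_projection(panel, w = 5, r = 6, seed = 42)
  expect_length(sch$sub_indices, 6L)
  for (si in sch$sub_indices) {
    expect_length(si, ceiling(53 / 5))
    expect_true(all(diff(si) > 0))
    win <- si %/% 5L
    expect_equal(win, 0:10) # one site inside each window
    expect_true(all(si >= 0 & si < 53))
  }
  expect_identical(make_projection(panel, 5, 6, seed = 42)$sub_indices,
                   sch$sub_indices)
  # substreams: extending r keeps earlier runs unchanged
  expect_identical(make_projection(panel, 5, 9, seed = 42)$sub_indices[1:6],
                   sch$sub_indices)
  # single window when w = n
  expect_length(make_projection(panel, 53, 2, seed = 1)$sub_indices[[1L]], 1L)
  expect_error(make_projection(panel, 54, 2, seed = 1), "\\[1, n\\]")
})

test_that("sampling weight is proportional to within-window MAF", {
  # window MAFs [0.4, 0.1, 0.0] -> selection frequencies ~ [0.8, 0.2, 0.0]
  alleles <- rbind(matrix(c(1L, 0L, 0L), 10, 3, byrow = TRUE),
                   matrix(c(0L, 1L, 0L), 4, 3, byrow = TRUE),
                   matrix(0L, 26, 3))
  panel <- haplotype_panel(alleles[sample(40), , drop = FALSE], 1:3, 0:2 * 0.1)
  expect_equal(panel$maf, c(0.25, 0.1, 0)) # 10/40, 4/40, 0
  r <- 20000L
  sch <- make_projection(panel, w = 3, r = r, seed = 7)
  picks <- vapply(sch$sub_indices, `[`, integer(1L), 1L)
  freq <- tabulate(picks + 1L, nbins = 3L) / r
  p <- c(0.25, 0.1, 0) / 0.35
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / r) + 1e-12))
  expect_equal(freq[3L], 0)
  # all-zero-MAF window falls back to uniform sampling
  zero <- haplotype_panel(matrix(0L, 5, 4), 1:4, 0:3 * 0.1)
  sz <- make_projection(zero, w = 2, r = 500, seed = 1)
  first <- vapply(sz$sub_indices, `[`, integer(1L), 1L)
  expect_true(all(sort(unique(first)) == c(0L, 1L)))
})

test_that("project gathers columns and coordinates", {
  panel <- rand_panel(6, 20, seed = 9)
  ident <- project(panel, 0:19)
  expect_equal(ident$alleles, panel$alleles, ignore_attr = TRUE)
  expect_equal(project(c(0L,1L,0L,1L,0L,1L), c(1L, 4L)), c(1L, 0L))
  sub <- c(2L, 7L, 13L)
  low <- project(panel, sub)
  expect_equal(low$alleles, panel$alleles[, sub + 1L], ignore_attr = TRUE)
  expect_equal(low$site_cm, panel$site_cm[sub + 1L])
  expect_equal(low$site_bp, panel$site_bp[sub + 1L])
  expect_error(project(panel, c(0L, 25L)), "out of range")
})

test_that("rescale_match applies the window formula with clipping", {
  m <- data.frame(hap = 3L, start = 2L, end = 4L)
  expect_equal(rescale_match(m, w = 5),
               data.frame(hap = 3L, start = 10L, end = 24L))
  m2 <- data.frame(hap = 0:4, start = 0:4, end = 2:6)
  expect_equal(rescale_match(m2, w = 1), m2) # identity at w = 1
  expect_equal(rescale_match(data.frame(hap = 0L, start = 1L, end = 2L),
                             w = 4, n = 10),
               data.frame(hap = 0L, start = 4L, end = 9L)) # clipped 11 -> 9
  expect_error(rescale_match(data.frame(hap = 0L, start = -1L, end = 2L), 2),
               "negative")
})

test_that("projection queries keep exact duplicates at every run", {
  panel <- rand_panel(10, 60, seed = 21)
  sch <- make_projection(panel, w = 5, r = 4, seed = 3)
  subs <- lapply(sch$sub_indices, function(si) build_pbwt_index(project(panel, si)))
  q <- panel$alleles[7, ]
  got <- run_projection_queries(subs, q, L_lowres = 12, sch)
  full <- got[got$hap == 6 & got$start == 0 & got$end == 59, ]
  expect_equal(sort(full$run), 1:4) # every run reports the duplicate in full
  # r = 0 -> empty
  sch0 <- make_projection(panel, w = 5, r = 0, seed = 3)
  expect_equal(nrow(run_projection_queries(list(), q, 12, sch0)), 0L)
  expect_error(run_projection_queries(subs[1:2], q, 12, sch), "mismatch")
})

test_that("a single in-window mismatch is skipped at the expected rate", {
  # planted 10-window identical segment with one flipped site; a run detects
  # it iff its sampled site in the affected window avoids the flip:
  # probability (1 - 1/w) under uniform MAF weights
  w <- 5L; nwin <- 10L; n <- w * nwin
  reps <- 300L; r <- 4L
  hits <- 0L; total <- 0L
  for (rep in seq_len(reps)) {
    panel <- rand_panel(6, n, seed = 3e4 + rep, p1 = 0.5)
    q <- panel$alleles[1, ]
    flip <- sample.int(n, 1L)
    q[flip] <- 1L - q[flip]
    sch <- make_projection(panel, w = w, r = r, seed = rep)
    subs <- lapply(sch$sub_indices, function(si) build_pbwt_index(project(panel, si)))
    got <- run_projection_queries(subs, q, L_lowres = nwin, sch)
    full <- got[got$hap == 0L & got$start == 0L & got$end == n - 1L, ]
    hits <- hits + nrow(full)
    total <- total + r
  }
  phat <- hits / total
  p <- 1 - 1 / w
  # the flip site is MAF-weighted, not uniform, so allow a generous band
  expect_gt(phat, p - 4 * sqrt(p * (1 - p) / total) - 0.05)
  expect_lt(phat, 1)
})

test_that("multi-run detection beats the binomial lower bound", {
  # segment spanning W windows with k flips in distinct windows: claiming a
  # hit when >= c runs report the full window span must be at least
  # P(Binom(r, q) >= c) with q = (1 - 1/w)^k under uniform weights
  w <- 5L; nwin <- 8L; n <- w * nwin; k <- 2L
  r <- 10L; cc <- 2L
  reps <- 200L
  hit <- logical(reps)
  for (rep in seq_len(reps)) {
    panel <- rand_panel(5, n, seed = 5e4 + rep, p1 = 0.5)
    q <- panel$alleles[2, ]
    wins <- sample.int(nwin, k) - 1L
    flips <- wins * w + sample.int(w, k, replace = TRUE) - 1L
    q[flips + 1L] <- 1L - q[flips + 1L]
    sch <- make_projection(panel, w = w, r = r, seed = rep)
    subs <- lapply(sch$sub_indices, function(si) build_pbwt_index(project(panel, si)))
    got <- run_projection_queries(subs, q, L_lowres = nwin, sch)
    full <- got[got$hap == 1L & got$start == 0L & got$end == n - 1L, ]
    hit[rep] <- nrow(full) >= cc
  }
  qdet <- (1 - 1 / w)^k
  bound <- stats::pbinom(cc - 1L, r, qdet, lower.tail = FALSE)
  phat <- mean(hit)
  expect_gt(phat, bound - 3 * sqrt(bound * (1 - bound) / reps) - 0.05)
})
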