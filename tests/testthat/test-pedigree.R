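test_that("crossover counts follow the stated Poisson mean", {
  sim <- simulate_pedigree(NULL,
                           pedigree_spec(founders = 100L, generations = 10L,
                                         couples = 50L, Lt = 100, seed = 4),
                           build_panel = FALSE)
  draws <- sim$crossover_counts
  expect_gt(length(draws), 1500L)
  lambda <- 100 / 50
  expect_lt(abs(mean(draws) - lambda), 3 * sqrt(lambda / length(draws)))
})

test_that("transmission truth: parent-offspring shares the whole map", {
  spec <- pedigree_spec(founders = 20L, generations = 1L, couples = 10L,
                        Lt = 150, seed = 7)
  sim <- simulate_pedigree(NULL, spec, build_panel = FALSE)
  kids <- sim$pedigree[sim$pedigree$generation == 1L, ]
  kid <- kids[1, ]
  ibd_m <- mosaic_ibd(sim, kid$id, kid$mother, min_cm = 0)
  expect_equal(sum(ibd_m$cm_length), 150, tolerance = 1e-6)
  # and the child's genome tiles between its two parents without overlap
  ibd_f <- mosaic_ibd(sim, kid$id, kid$father, min_cm = 0)
  expect_equal(sum(ibd_f$cm_length), 150, tolerance = 1e-6)
  # haplotype 0 is the paternal gamete, haplotype 1 the maternal one
  expect_true(all(ibd_m$hap_a == paste0(kid$id, "_1")))
  expect_true(all(ibd_f$hap_a == paste0(kid$id, "_0")))
  # the maternal-side share partitions [0, Lt] exactly
  mm <- ibd_m[order(ibd_m$start_cm), ]
  expect_equal(mm$start_cm[1L], 0)
  expect_equal(mm$end_cm[nrow(mm)], 150)
  if (nrow(mm) > 1L)
    expect_equal(mm$start_cm[-1L], mm$end_cm[-nrow(mm)], tolerance = 1e-9)
})

test_that("pedigree kinship matches hand values and degree labels", {
  spec <- pedigree_spec(founders = 30L, generations = 2L, couples = 15L,
                        Lt = 100, seed = 12)
  sim <- simulate_pedigree(NULL, spec, build_panel = FALSE)
  ped <- sim$pedigree
  kid <- ped[ped$generation == 1L, ][1, ]
  expect_equal(pedigree_kinship(ped, kid$id, kid$father), 0.25)
  expect_equal(pedigree_kinship(ped, kid$id, kid$mother), 0.25)
  # two founders are unrelated
  expect_equal(pedigree_kinship(ped, ped$id[1], ped$id[2]), 0)
  # full siblings have kinship 1/4, half siblings 1/8
  g1 <- ped[ped$generation == 1L, ]
  fam <- paste(g1$father, g1$mother)
  if (any(duplicated(fam))) {
    sibs <- g1$id[fam == fam[duplicated(fam)][1]][1:2]
    expect_equal(pedigree_kinship(ped, sibs[1], sibs[2]), 0.25)
  }
  # grandchild-grandparent kinship 1/8 (for a grandparent unrelated to the
  # other parental line, so the relationship is exactly grandparental)
  ancestors <- function(id) {
    out <- character()
    todo <- id
    while (length(todo)) {
      row <- ped[ped$id == todo[1], ]
      todo <- todo[-1]
      for (p in c(row$father, row$mother)) if (!is.na(p)) {
        out <- c(out, p); todo <- c(todo, p)
      }
    }
    unique(out)
  }
  found <- FALSE
  for (i in which(ped$generation == 2L)) {
    g2 <- ped[i, ]
    gm <- ped$mother[ped$id == g2$mother]
    if (!(gm %in% ancestors(g2$father))) {
      expect_equal(pedigree_kinship(ped, g2$id, gm), 0.125)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_equal(kinship_degree(c(0.25, 0.125, 0.0625, 0.03, 0.01)),
               c("1", "2", "3", "4", "unrelated"))
})

test_that("descendant panels are mosaics of founder haplotypes", {
  founder <- generate_panel(40, 400, seed = 3) # 20 founders
  spec <- pedigree_spec(founders = 20L, generations = 2L, couples = 10L,
                        Lt = founder$site_cm[400] - founder$site_cm[1],
                        seed = 5)
  sim <- simulate_pedigree(founder, spec)
  pan <- sim$panels[[1L]]
  expect_equal(pan$n_haps, 2L * length(sim$extracted))
  # every descendant site allele equals the founder allele of its mosaic piece
  e <- sim$mosaics[[1L]]
  cm0 <- founder$site_cm - founder$site_cm[1L]
  for (r in sample(seq_len(pan$n_haps), 5)) {
    mos <- get(pan$hap_ids[r], e)
    piece <- pmax(findInterval(cm0, mos[, 1L]), 1L)
    src <- mos[piece, 2L]
    expect_equal(pan$alleles[r, ], founder$alleles[cbind(src + 1L, seq_len(400))],
                 ignore_attr = TRUE)
  }
  # determinism
  sim2 <- simulate_pedigree(founder, spec)
  expect_identical(sim2$panels[[1L]]$alleles, pan$alleles)
})

test_that("zero generations leaves the founders unchanged", {
  spec <- pedigree_spec(founders = 10L, generations = 0L, couples = 5L,
                        Lt = 50, seed = 2)
  sim <- simulate_pedigree(NULL, spec, build_panel = FALSE)
  expect_equal(nrow(sim$pedigree), 10L)
  expect_true(all(sim$pedigree$generation == 0L))
  expect_length(sim$extracted, 0L)
})

test_that("pedigree truth separates degrees on a small simulation", {
  spec <- pedigree_spec(founders = 60L, generations = 3L, couples = 30L,
                        Lt = c(150, 200, 250), seed = 21)
  sim <- simulate_pedigree(NULL, spec, build_panel = FALSE)
  tr <- pedigree_truth(sim, ids = sim$extracted, min_cm = 7)
  expect_true(all(tr$total_cm >= 0))
  expect_true(all(tr$n_segments[tr$kinship == 0] == 0L))
  agg <- tapply(tr$total_cm, tr$degree, mean)
  expect_gt(agg[["1"]], agg[["2"]])
  if (!is.na(agg["3"])) expect_gt(agg[["2"]], agg[["3"]])
})
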