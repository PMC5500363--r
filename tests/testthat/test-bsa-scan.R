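test_that("lod_score matches worked 2x2 odds-ratio examples", {
  expect_equal(lod_score(20, 20, 20, 20), 0)
  expect_equal(lod_score(10, 30, 30, 10),
               abs(log10((30.5 / 10.5) / (10.5 / 30.5))), tolerance = 1e-12)
  expect_equal(lod_score(10, 30, 30, 10), 0.9262211, tolerance = 1e-6)
  # complete selection at depth 40 clears the LOD-3 cutoff
  expect_equal(lod_score(40, 0, 0, 40), log10(6561), tolerance = 1e-12)
  expect_gt(lod_score(40, 0, 0, 40), 3)
  expect_error(lod_score(0, 0, 10, 10), "positive")
})

test_that("lod_score equals the brute-force corrected odds ratio on all small tables", {
  # exhaustive oracle over every count table with entries 0..30
  grid <- expand.grid(ar = 0:30, aa = 0:30, br = 0:30, ba = 0:30)
  grid <- grid[grid$ar + grid$aa > 0 & grid$br + grid$ba > 0, ]
  oracle <- with(grid, abs(log10(((aa + 0.5) * (br + 0.5)) /
                                   ((ar + 0.5) * (ba + 0.5)))))
  got <- lod_score(grid$ar, grid$aa, grid$br, grid$ba)
  expect_equal(got, oracle, tolerance = 1e-12)
  # swap symmetry on the same grid
  expect_equal(got, lod_score(grid$br, grid$ba, grid$ar, grid$aa),
               tolerance = 1e-12)
  # ref/alt swap in both pools simultaneously
  expect_equal(got, lod_score(grid$aa, grid$ar, grid$ba, grid$br),
               tolerance = 1e-12)
})

test_that("LOD is monotone in the frequency difference at fixed depth", {
  # move pool A's counts from balanced toward all-alternate; B fixed at 0.5
  lods <- lod_score(20:0, 20:40, 20, 20)
  expect_true(all(diff(lods) >= -1e-12))
  # and toward all-reference, the mirror path
  lods2 <- lod_score(20:40, 20:0, 20, 20)
  expect_true(all(diff(lods2) >= -1e-12))
})

test_that("scan joins pools on the marker set and skips zero-depth sites", {
  s <- sites_at("chrA", c(100, 200, 300, 400))
  a <- counts_at(s, ref = c(10L, 0L, 5L, 8L), alt = c(10L, 0L, 15L, 2L), "A")
  b <- counts_at(s, ref = c(12L, 9L, 2L, 0L), alt = c(8L, 11L, 18L, 10L), "B")
  tr <- bsa_scan(s, a, b)
  expect_equal(nrow(tr), 3)          # site 200 has zero depth in pool A
  expect_equal(attr(tr, "n_skipped"), 1L)
  expect_equal(tr$lod, lod_score(a$ref_depth[-2], a$alt_depth[-2],
                                 b$ref_depth[-2], b$alt_depth[-2]))
  # sitewise symmetry under pool swap
  tr_swap <- bsa_scan(s, b, a)
  expect_equal(tr$lod, tr_swap$lod)
  # single shared site gives a length-1 track
  s1 <- sites_at("chrA", 100)
  expect_equal(nrow(bsa_scan(s1, a, b)), 1)
  # empty join errors
  s_none <- sites_at("chrZ", 999)
  expect_error(bsa_scan(s_none, a, b), "no shared sites")
})

test_that("pools drawn from the same segregants give a null LOD track", {
  g <- tiny_genome()
  s <- simulate_parent_sites(1000, g, seed = 51)
  segs <- simulate_meiosis(s, cross_config(n_segregants = 40, seed = 51,
    qtl_major = list(chrom = "chrA", pos = 50000L),
    qtl_minor = list(chrom = "chrB", pos = 100000L)), g)
  segs$phenotype <- factor(rep("Sensitive", 40),
                           levels = bsaqtl:::phenotype_levels())
  a <- simulate_pool_reads(segs, "Sensitive", depth_model(80), seed = 52)
  b <- simulate_pool_reads(segs, "Sensitive", depth_model(80), seed = 53)
  tr <- bsa_scan(s, a, b)
  expect_lt(max(tr$lod), 1)
})

test_that("QTL intervals follow the 1-LOD drop rule on a hand-walked track", {
  tr <- track_from(seq(10000, 90000, by = 10000),
                   c(0, 1, 2, 4, 5, 4, 2, 1, 0))
  iv <- call_qtl(tr, threshold = 3, drop = 1)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$peak_pos, 50000L)
  expect_equal(iv$peak_lod, 5)
  expect_equal(iv$start, 40000L)
  expect_equal(iv$end, 60000L)
  # all below threshold: no calls
  expect_equal(nrow(call_qtl(track_from(1:5 * 1000, c(0, 1, 2.9, 1, 0)))), 0)
  # drop never reached: interval runs to the chromosome's scanned ends
  iv2 <- call_qtl(track_from(1:3 * 1000, c(4.5, 5, 4.6)))
  expect_equal(iv2$start, 1000L)
  expect_equal(iv2$end, 3000L)
  # overlapping-interval peaks merge, keeping the higher peak
  iv3 <- call_qtl(track_from(1:7 * 1000, c(0, 5, 4.5, 4.8, 4.2, 1, 0)))
  expect_equal(nrow(iv3), 1)
  expect_equal(iv3$peak_pos, 2000L)
  # equal-LOD adjacent maxima: leftmost wins
  iv4 <- call_qtl(track_from(1:4 * 1000, c(0, 5, 5, 0)))
  expect_equal(iv4$peak_pos, 2000L)
})

test_that("common_region reproduces the printed chrXII intersection", {
  a <- data.frame(chrom = "chrXII", start = 512000L, end = 560000L)
  b <- data.frame(chrom = "chrXII", start = 527000L, end = 572000L)
  cr <- common_region(a, b)
  expect_equal(cr$start, 527000L)
  expect_equal(cr$end, 560000L)
  # commutative, idempotent, contained in both inputs
  expect_equal(common_region(b, a)[, c("start", "end")],
               cr[, c("start", "end")])
  expect_equal(common_region(a, a)$start, a$start)
  expect_true(cr$start >= max(a$start[1], b$start[1]) - 0 &&
                cr$end <= min(a$end[1], b$end[1]))
  # disjoint intervals and different chromosomes give nothing
  expect_equal(nrow(common_region(a, transform(b, start = 600000L,
                                               end = 700000L))), 0)
  expect_equal(nrow(common_region(a, transform(b, chrom = "chrIV"))), 0)
})

test_that("three-pool comparison recovers the planted architecture", {
  g <- genome_spec(c(chrA = 400000L, chrB = 400000L, chrC = 400000L),
                   recombination_rate = 0.35)
  cross <- cross_config(n_segregants = 300, seed = 61,
                        qtl_major = list(chrom = "chrA", pos = 200000L),
                        qtl_minor = list(chrom = "chrB", pos = 200000L),
                        intermediate_fraction = 0)
  s <- simulate_parent_sites(1200, g, seed = 61)
  segs <- assign_phenotypes(simulate_meiosis(s, cross, g))
  # deep error-free pools: every planted peak resolves past LOD 3
  dm <- depth_model(mean_depth = 2000, error_rate = 0)
  pools <- lapply(stats::setNames(nm = c("Sensitive", "ResistantParental",
                                         "ResistantEvolved")),
                  function(p) simulate_pool_reads(segs, p, dm,
                                                  seed = 62 + match(p, levels(segs$phenotype))))
  cmp <- compare_all_pools(s, pools)
  # major locus: both sensitive-vs-resistant comparisons, not RPvRE
  # (both resistant pools are fixed for the major allele)
  expect_true("chrA" %in% cmp$intervals$SvRP$chrom)
  expect_true("chrA" %in% cmp$intervals$SvRE$chrom)
  expect_false("chrA" %in% cmp$intervals$RPvRE$chrom)
  # modifier locus: strongest in RPvRE (fixed 0 vs fixed 1) and visible
  # in SvRE (0.5 vs 1) at this depth
  expect_true("chrB" %in% cmp$intervals$SvRE$chrom)
  expect_true("chrB" %in% cmp$intervals$RPvRE$chrom)
  # no comparison calls the neutral chromosome
  expect_false(any(vapply(cmp$intervals, function(iv) "chrC" %in% iv$chrom,
                          logical(1))))
  # the common region contains the planted major locus
  expect_true(nrow(cmp$common) >= 1)
  expect_true(any(cmp$common$chrom == "chrA" &
                    cmp$common$start <= 200000 & cmp$common$end >= 200000))
  # identical pool membership yields no intervals anywhere
  same <- list(Sensitive = pools$Sensitive,
               ResistantParental = pools$Sensitive,
               ResistantEvolved = pools$Sensitive)
  cmp0 <- compare_all_pools(s, same)
  expect_true(all(vapply(cmp0$intervals, nrow, integer(1)) == 0))
  expect_error(compare_all_pools(s, pools[1:2]), "missing pool")
})
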