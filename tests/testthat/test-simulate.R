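test_that("marker sites are unique, sorted, in-bounds and length-proportional", {
  g <- yeast_genome()
  s <- simulate_parent_sites(18000, g, seed = 1)
  expect_equal(nrow(s), 18000)
  expect_false(any(duplicated(paste(s$chrom, s$pos))))
  for (chr in unique(s$chrom)) {
    p <- s$pos[s$chrom == chr]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 1 & p <= g$chromosomes[chr]))
  }
  # per-chromosome counts within 3 sigma of the binomial expectation
  frac <- g$chromosomes / genome_length(g)
  n_chr <- table(factor(s$chrom, levels = names(frac)))
  expected <- 18000 * frac
  sigma <- sqrt(18000 * frac * (1 - frac))
  expect_true(all(abs(as.integer(n_chr) - expected) <= 3 * sigma))
})

test_that("a single site on a 1 kb chromosome is forced into bounds", {
  g <- genome_spec(c(chr1 = 1000L))
  s <- simulate_parent_sites(1, g, seed = 3)
  expect_equal(nrow(s), 1)
  expect_true(s$pos >= 1 && s$pos <= 1000)
  expect_error(simulate_parent_sites(1001, g), "exceeds total genome length")
})

test_that("zero recombination gives whole-chromosome haplotypes", {
  g <- tiny_genome(rate = 0)
  s <- simulate_parent_sites(200, g, seed = 2)
  segs <- simulate_meiosis(s, cross_config(n_segregants = 40, seed = 9), g)
  for (chr in c("chrA", "chrB")) {
    block <- segs$geno[, s$chrom == chr, drop = FALSE]
    expect_true(all(block == block[, 1]))
  }
  expect_true(all(segs$geno %in% c(0L, 1L)))
})

test_that("recombinant fraction follows Haldane's mapping function", {
  # two markers 50 cM apart: c = (1 - exp(-1)) / 2 ~ 0.3161
  g <- genome_spec(c(chr1 = 100000L), recombination_rate = 0.5) # 50 cM total
  s <- sites_at("chr1", c(1L, 100000L), genome = g)
  segs <- simulate_meiosis(s, cross_config(n_segregants = 10000, seed = 7), g)
  recomb <- mean(segs$geno[, 1] != segs$geno[, 2])
  expect_lt(abs(recomb - (1 - exp(-1)) / 2), 0.01)
})

test_that("marginal allele frequency across segregants is 1/2", {
  g <- tiny_genome()
  s <- simulate_parent_sites(100, g, seed = 4)
  segs <- simulate_meiosis(s, cross_config(n_segregants = 2000, seed = 11), g)
  af <- colMeans(segs$geno)
  sigma <- 0.5 / sqrt(2000)
  expect_true(all(abs(af - 0.5) <= 3 * sigma + 1e-12))
})

test_that("two-locus phenotype rule gives Mendelian class fractions", {
  g <- genome_spec(c(chrA = 100000L, chrB = 100000L), recombination_rate = 0.35)
  cross <- cross_config(n_segregants = 8000,
                        qtl_major = list(chrom = "chrA", pos = 50000L),
                        qtl_minor = list(chrom = "chrB", pos = 50000L),
                        intermediate_fraction = 0, seed = 5)
  s <- simulate_parent_sites(400, g, seed = 5)
  segs <- assign_phenotypes(simulate_meiosis(s, cross, g), cross)
  frac <- table(segs$phenotype) / cross$n_segregants
  # unlinked loci: 1/2 sensitive, 1/4 each resistant class
  expect_equal(unname(frac[["Sensitive"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(frac[["ResistantParental"]]), 0.25, tolerance = 0.1)
  expect_equal(unname(frac[["ResistantEvolved"]]), 0.25, tolerance = 0.1)
  expect_equal(unname(frac[["Intermediate"]]), 0)
  # all-0 at the major locus forces Sensitive
  segs0 <- segs
  segs0$geno[, segs0$qtl_sites["major"]] <- 0L
  segs0 <- assign_phenotypes(segs0, cross)
  expect_true(all(segs0$phenotype == "Sensitive"))
  # off-genome QTL errors
  bad <- cross_config(qtl_major = list(chrom = "chrA", pos = 999999L))
  expect_error(assign_phenotypes(segs, bad), "outside")
})

test_that("the observed 37/9/9/14 cluster configuration is realizable", {
  # under the default cross (69 segregants, intermediate_fraction 0.4) the
  # four classes land near the 37/9/9/14 split reported for such a cross
  g <- yeast_genome()
  s <- simulate_parent_sites(2000, g, seed = 8)
  tabs <- t(vapply(1:40, function(i) {
    cross <- cross_config(seed = i)
    segs <- assign_phenotypes(simulate_meiosis(s, cross, g), cross)
    as.integer(table(segs$phenotype))
  }, integer(4)))
  expect_equal(colMeans(tabs), c(34.5, 10.35, 10.35, 13.8), tolerance = 0.15)
  # at least one draw matches the printed configuration closely
  d <- apply(tabs, 1, function(x) sum(abs(x - c(37, 9, 9, 14))))
  expect_true(min(d) <= 10)
})

test_that("pooled read counts follow the binomial sampling model", {
  g <- tiny_genome()
  s <- simulate_parent_sites(10000, g, seed = 3)
  segs <- simulate_meiosis(s, cross_config(n_segregants = 8, seed = 13), g)
  segs$phenotype <- factor(rep("Sensitive", 8), levels = bsaqtl:::phenotype_levels())
  # force f = 0.5 at every site: half the pool carries each haplotype
  segs$geno[] <- rep(c(0L, 1L), each = 4)
  pc <- simulate_pool_reads(segs, "Sensitive",
                            depth_model(mean_depth = 80, error_rate = 0),
                            seed = 3)
  expect_equal(mean(pool_freq(pc)), 0.5, tolerance = 0.01 / 0.5)
  # f = 1 with no error: all reads alternate
  segs$geno[] <- 1L
  pc1 <- simulate_pool_reads(segs, "Sensitive",
                             depth_model(80, error_rate = 0), seed = 4)
  expect_true(all(pc1$ref_depth == 0))
  # f = 0 with error rate e: alternate fraction ~ e
  segs$geno[] <- 0L
  pc0 <- simulate_pool_reads(segs, "Sensitive",
                             depth_model(80, error_rate = 0.005), seed = 5)
  expect_equal(sum(pc0$alt_depth) / sum(pc0$ref_depth + pc0$alt_depth),
               0.005, tolerance = 0.5)
  expect_error(simulate_pool_reads(segs, "Intermediate", depth_model()),
               "empty")
})

test_that("coverage simulation scales window means with copy number", {
  g <- yeast_genome()
  cw2 <- simulate_coverage(g, integer(), mean_depth = 100, seed = 6)
  expect_equal(mean(cw2$depth), 100, tolerance = 0.01)
  cw3 <- simulate_coverage(g, c(chrI = 3L), mean_depth = 100, seed = 6)
  expect_equal(mean(cw3$depth[cw3$chrom == "chrI"]), 150, tolerance = 0.02)
  # windows tile each chromosome exactly
  for (chr in c("chrI", "chrXII")) {
    w <- cw3[cw3$chrom == chr, ]
    expect_equal(w$start, c(1, head(w$end, -1) + 1))
    expect_equal(w$end[nrow(w)], unname(g$chromosomes[chr]))
  }
  expect_error(simulate_coverage(g, c(chrZZ = 3L)), "unknown chromosome")
  expect_error(simulate_coverage(g, window = 5e6), "smallest chromosome")
})

test_that("expression dosage shifts chromosome means by log2(fold)", {
  sim <- simulate_expression(3000, dosage = c(chrI = 1.5), dispersion = 0,
                             seed = 10)
  fc <- log2_fold_change(sim$counts, sim$strain)
  on1 <- sim$genes$chrom == "chrI"
  expect_equal(mean(fc[on1]), log2(1.5), tolerance = 0.05)
  expect_equal(mean(fc[!on1]), 0, tolerance = 0.05)
  # dosage all 1, dispersion 0: both strains share expected counts
  sim0 <- simulate_expression(500, dosage = numeric(), dispersion = 0,
                              seed = 11)
  fc0 <- log2_fold_change(sim0$counts, sim0$strain)
  expect_equal(mean(fc0), 0, tolerance = 0.02)
  # default replicate structure is 3 parent vs 1 evolved
  expect_equal(as.integer(table(sim$strain)), c(3L, 1L))
  expect_error(simulate_expression(100, gene_chromosomes = rep("chrA", 100),
                                   dosage = c(chrB = 2)), "unknown chromosome")
})

test_that("all generators are bit-reproducible under a fixed seed", {
  g <- tiny_genome()
  s1 <- simulate_parent_sites(500, g, seed = 42)
  s2 <- simulate_parent_sites(500, g, seed = 42)
  expect_identical(s1, s2)
  cross <- cross_config(n_segregants = 30, seed = 42,
                        qtl_major = list(chrom = "chrA", pos = 50000L),
                        qtl_minor = list(chrom = "chrB", pos = 100000L))
  m1 <- assign_phenotypes(simulate_meiosis(s1, cross, g))
  m2 <- assign_phenotypes(simulate_meiosis(s2, cross, g))
  expect_identical(m1$geno, m2$geno)
  expect_identical(m1$phenotype, m2$phenotype)
  p1 <- simulate_pool_reads(m1, "Sensitive", depth_model(), seed = 42)
  p2 <- simulate_pool_reads(m2, "Sensitive", depth_model(), seed = 42)
  expect_identical(p1, p2)
  expect_identical(simulate_coverage(g, c(chrA = 3L), seed = 42),
                   simulate_coverage(g, c(chrA = 3L), seed = 42))
  expect_identical(simulate_expression(200, seed = 42)$counts,
                   simulate_expression(200, seed = 42)$counts)
})
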