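# small genomes and hand-written VCF fixtures used across test files

tiny_genome <- function(rate = 0.35) {
  genome_spec(c(chrA = 100000L, chrB = 200000L), recombination_rate = rate)
}

# a het_sites table at explicit positions (no simulation)
sites_at <- function(chrom, pos, genome = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                   ref = rep_len("A", n), alt = rep_len("T", n),
                   stringsAsFactors = FALSE)
  bsaqtl:::new_het_sites(df, genome = genome)
}

counts_at <- function(sites, ref, alt, pool = "pool") {
  bsaqtl:::new_pooled_counts(sites, ref, alt, pool = pool)
}

# minimal multi-sample VCF written line by line, independent of the
# package's own writer
write_fixture_vcf <- function(path, rows, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ...) {
  ads <- list(...)
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "AD:DP",
          vapply(ads, function(ad)
            sprintf("%d,%d:%d", ad[1], ad[2], ad[1] + ad[2]),
            character(1))),
        collapse = "\t")
}

# deterministic lod_track from bare vectors for peak-calling tests
track_from <- function(pos, lod, chrom = "chrA") {
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       freq_a = NA_real_, freq_b = NA_real_, lod = lod,
                       stringsAsFactors = FALSE),
            class = c("lod_track", "data.frame"),
            pools = c("A", "B"), n_skipped = 0L,
            chrom_levels = unique(chrom))
}
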