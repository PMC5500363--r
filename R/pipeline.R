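#' Phenotype-cluster bookkeeping report
#'
#' Counts segregants per phenotype class with percentages rounded to
#' the nearest integer (so 37 of 69 sensitive clones reports as 54%).
#'
#' @param labels Vector/factor of phenotype labels, one per segregant.
#' @return A `cluster_report` data frame: `phenotype`, `n`, `percent`,
#'   with the total as an attribute.
#' @examples
#' cluster_report(rep(c("Sensitive", "ResistantParental",
#'                      "ResistantEvolved", "Intermediate"),
#'                    c(37, 9, 9, 14)))
#' @export
cluster_report <- function(labels) {
  if (length(labels) == 0) stop("labels is empty")
  labels <- as.factor(labels)
  tab <- table(labels)
  out <- data.frame(phenotype = names(tab), n = as.integer(tab),
                    percent = as.integer(round(100 * as.integer(tab) /
                                                 length(labels))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cluster_report", "data.frame"),
            total = length(labels))
}

#' @exportS3Method base::print
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d segregants\n", attr(x, "total")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

# deterministic per-stage seed fan-out from one global seed, kept within
# 32-bit integer range so every stage is independently reproducible
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 7919L
}

#' Default pipeline configuration
#'
#' The simulated study conditions: a diploid parent heterozygous at
#' ~18,000 sites on a 16-chromosome yeast genome, 69 haploid
#' segregants, pooled sequencing at 80x with a deeper 133x parental
#' library, a whole-chromosome 3-copy gain on chrI at 100x coverage,
#' and 6,000 genes with a 1.5-fold chrI expression dosage (3 parent vs
#' 1 evolved replicates).
#'
#' @param seed Global seed fanned out to every stage.
#' @return Named list accepted by [run_bsa_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_sites = 18047L,
    n_segregants = 69L,
    recombination_rate = 0.35,
    qtl_major = list(chrom = "chrXII", pos = 543500L),
    qtl_minor = list(chrom = "chrIV", pos = 471500L),
    intermediate_fraction = 0.4,
    pool_depth = 80, parent_depth = 133, error_rate = 0.002,
    af_min = 0.25, af_max = 0.75, min_depth = 20,
    lod_threshold = 3, lod_drop = 1,
    coverage_depth = 100, window = 1000L,
    copy_numbers = list(chrI = 3L), baseline_ploidy = 2L,
    cnv_tolerance = 0.15,
    n_genes = 6000L, dosage = list(chrI = 1.5), dispersion = 0.05,
    n_reps = c(3L, 1L))
}

#' Run the full simulated bulk-segregant analysis pipeline
#'
#' Orchestrates every stage from one configuration: simulate the
#' heterozygous parent and the cross, write the pooled counts as a
#' multi-sample VCF, read it back and re-call the heterozygous marker
#' set, run the three pairwise LOD scans with QTL and common-region
#' calls, detect aneuploidy from simulated 1000-bp coverage windows,
#' summarize the expression dosage effect, and write a Table-2-style
#' phenotype cluster report.  All stage outputs land in `out_dir` as
#' plain-text VCF/TSV/BED/JSON; a manifest records parameters, stage
#' seeds and md5 checksums, so re-running the same configuration is
#' bit-identical.
#'
#' @param config Named list as from [default_config()], or a path to a
#'   YAML file holding one; missing entries take the defaults.
#' @param out_dir Output directory (created if needed).
#' @return A `bsa_run` manifest (invisibly): parameters, file paths,
#'   checksums, and the in-memory stage results in `$results`.
#' @export
run_bsa_pipeline <- function(config = default_config(), out_dir = tempfile("bsa_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$af_min <= cfg$af_max, cfg$lod_threshold > 0,
            cfg$lod_drop > 0, cfg$window >= 100)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  genome <- yeast_genome(cfg$recombination_rate)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- cross simulation ------------------------------------------------
  res <- list()
  run_stage("simulate", {
    sites <- simulate_parent_sites(cfg$n_sites, genome,
                                   seed = stage_seed(cfg$seed, 1L))
    cross <- cross_config(cfg$n_segregants, cfg$qtl_major, cfg$qtl_minor,
                          cfg$intermediate_fraction,
                          seed = stage_seed(cfg$seed, 2L))
    segs <- assign_phenotypes(simulate_meiosis(sites, cross, genome))
    res$segregants <- segs
    parent <- simulate_parent_reads(
      sites, depth_model(cfg$parent_depth, cfg$error_rate),
      seed = stage_seed(cfg$seed, 3L))
    dm <- depth_model(cfg$pool_depth, cfg$error_rate)
    pools <- list(
      Sensitive = simulate_pool_reads(segs, "Sensitive", dm,
                                      seed = stage_seed(cfg$seed, 4L)),
      ResistantParental = simulate_pool_reads(segs, "ResistantParental", dm,
                                              seed = stage_seed(cfg$seed, 5L)),
      ResistantEvolved = simulate_pool_reads(segs, "ResistantEvolved", dm,
                                             seed = stage_seed(cfg$seed, 6L)))
    write_sites_vcf(path("cross.vcf"), sites,
                    c(list(parent = parent), pools), genome)
  })

  # -- variant IO: read back through the real file format --------------
  run_stage("het_sites", {
    vcf <- read_vcf(path("cross.vcf"))
    het <- call_het_sites(vcf, "parent", cfg$af_min, cfg$af_max,
                          cfg$min_depth)
    res$het_sites <- het
    res$pools <- lapply(stats::setNames(nm = c(
      "Sensitive", "ResistantParental", "ResistantEvolved")),
      function(s) pool_counts(vcf, s))
    utils::write.table(as.data.frame(het), path("het_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- LOD scans, QTL calls, common region -----------------------------
  run_stage("bsa_scan", {
    cmp <- compare_all_pools(res$het_sites, res$pools,
                             threshold = cfg$lod_threshold,
                             drop = cfg$lod_drop)
    res$comparison <- cmp
    for (nm in names(cmp$tracks))
      utils::write.table(as.data.frame(cmp$tracks[[nm]]),
                         path(sprintf("lod_%s.tsv", nm)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    all_iv <- do.call(rbind, lapply(names(cmp$intervals), function(nm) {
      iv <- as.data.frame(cmp$intervals[[nm]])
      if (nrow(iv)) iv$name <- nm
      iv
    }))
    if (is.null(all_iv))
      all_iv <- data.frame(chrom = character(), start = integer(),
                           end = integer(), name = character())
    write_bed(all_iv, path("qtl_intervals.bed"),
              name_col = if (nrow(all_iv)) "name" else NULL)
    write_bed(cmp$common, path("common_region.bed"))
  })

  # -- coverage and aneuploidy -----------------------------------------
  run_stage("cnv", {
    cw <- simulate_coverage(genome, unlist(cfg$copy_numbers),
                            window = cfg$window,
                            mean_depth = cfg$coverage_depth,
                            seed = stage_seed(cfg$seed, 7L))
    write_bedgraph(cw, path("coverage.bedgraph"))
    ratios <- chromosome_ratios(cw)
    calls <- call_aneuploidy(ratios, cfg$baseline_ploidy, cfg$cnv_tolerance)
    res$aneuploidy <- calls
    utils::write.table(as.data.frame(calls), path("aneuploidy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- expression dosage -----------------------------------------------
  run_stage("expression", {
    sim <- simulate_expression(cfg$n_genes, dosage = unlist(cfg$dosage),
                               n_reps = cfg$n_reps,
                               dispersion = cfg$dispersion,
                               genome = genome,
                               seed = stage_seed(cfg$seed, 8L))
    fc <- log2_fold_change(sim$counts, sim$strain)
    dosage <- chromosome_dosage_summary(fc, sim$genes$chrom)
    res$dosage <- dosage
    res$fc_bins <- bin_fold_changes(fc, chromosomes = sim$genes$chrom,
                                     exclude_chromosomes = names(cfg$dosage))
    counts_out <- data.frame(gene = sim$genes$gene, chrom = sim$genes$chrom,
                             sim$counts, check.names = FALSE)
    utils::write.table(counts_out, path("expression_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(dosage), path("dosage_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- bookkeeping -----------------------------------------------------
  run_stage("report", {
    creport <- cluster_report(res$segregants$phenotype)
    res$clusters <- creport
    utils::write.table(as.data.frame(creport), path("cluster_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- list(qtl_major = cfg$qtl_major, qtl_minor = cfg$qtl_minor,
                  copy_numbers = cfg$copy_numbers, dosage = cfg$dosage,
                  seed = cfg$seed)
    jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  })

  files <- c("cross.vcf", "het_sites.tsv",
             sprintf("lod_%s.tsv", names(res$comparison$tracks)),
             "qtl_intervals.bed", "common_region.bed",
             "coverage.bedgraph", "aneuploidy.tsv",
             "expression_counts.tsv", "dosage_summary.tsv",
             "cluster_report.tsv", "truth.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(package_version = as.character(utils::packageVersion("bsaqtl")),
                   config = cfg,
                   stage_seeds = stats::setNames(
                     vapply(1:8, function(i) stage_seed(cfg$seed, i),
                            numeric(1)),
                     c("sites", "cross", "parent_reads", "pool_S", "pool_RP",
                       "pool_RE", "coverage", "expression")),
                   files = as.list(checksums))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  out <- structure(list(out_dir = out_dir, manifest = manifest,
                        results = res),
                   class = "bsa_run")
  invisible(out)
}

#' @exportS3Method base::print
print.bsa_run <- function(x, ...) {
  cat(sprintf("<bsa_run> seed %d -> %s\n", x$manifest$config$seed, x$out_dir))
  cat(sprintf("  %d artifacts: %s\n", length(x$manifest$files),
              paste(utils::head(names(x$manifest$files), 5), collapse = ", ")))
  print(x$results$clusters)
  if (nrow(x$results$comparison$common))
    cat(sprintf("  common QTL region: %s %.0f-%.0f\n",
                x$results$comparison$common$chrom,
                x$results$comparison$common$start,
                x$results$comparison$common$end), sep = "")
  hits <- x$results$aneuploidy[x$results$aneuploidy$flagged, , drop = FALSE]
  if (nrow(hits))
    cat(sprintf("  aneuploidy: %s ratio %.2f (copy %d)\n", hits$chrom,
                hits$ratio, hits$copy_estimate), sep = "")
  invisible(x)
}
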