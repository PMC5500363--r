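#' Simulate pooled sequencing read counts for one phenotype pool
#'
#' The pool's true allele frequency at each site is the mean haplotype
#' among pool members; per-site read depth is Poisson (or negative
#' binomial if the depth model has dispersion) around `mean_depth`, and
#' alternate-read counts are Binomial(depth, f(1-e) + (1-f)e) where `e`
#' is the per-read error rate.
#'
#' @param segregants A phenotyped `segregant_set`.
#' @param pool_label One of `"Sensitive"`, `"ResistantParental"`,
#'   `"ResistantEvolved"`, `"Intermediate"`.
#' @param depth A [depth_model()].
#' @param seed Integer seed; defaults to the depth model's seed.
#' @return A `pooled_counts` data frame: `chrom`, `pos`, `ref_depth`,
#'   `alt_depth`, with the pool name and member count as attributes.
#' @export
simulate_pool_reads <- function(segregants, pool_label, depth = depth_model(),
                                seed = depth$seed) {
  members <- which(segregants$phenotype == pool_label)
  if (length(members) == 0) stop("pool '", pool_label, "' is empty")
  f <- colMeans(segregants$geno[members, , drop = FALSE])
  counts <- sample_allele_counts(f, depth, seed)
  new_pooled_counts(segregants$sites, counts$ref, counts$alt,
                    pool = pool_label, n_members = length(members))
}

#' Simulate the diploid parent's own sequencing reads
#'
#' Every marker site is heterozygous in the parent, so the true allele
#' frequency is 0.5 at each site; read sampling follows the same depth
#' model as the pools.  The parental library ran deeper than the pools
#' in the study design, hence the higher default depth.
#'
#' @param sites A `het_sites` table.
#' @param depth A [depth_model()]; default mean depth 133.
#' @param seed Integer seed.
#' @return A `pooled_counts` data frame (pool name `"parent"`).
#' @export
simulate_parent_reads <- function(sites, depth = depth_model(mean_depth = 133),
                                  seed = depth$seed) {
  counts <- sample_allele_counts(rep(0.5, nrow(sites)), depth, seed)
  new_pooled_counts(sites, counts$ref, counts$alt, pool = "parent",
                    n_members = 1L)
}

sample_allele_counts <- function(f, depth, seed) {
  set.seed(as.integer(seed))
  n <- length(f)
  dp <- if (depth$depth_dispersion > 0) {
    stats::rnbinom(n, mu = depth$mean_depth, size = 1 / depth$depth_dispersion)
  } else {
    stats::rpois(n, depth$mean_depth)
  }
  e <- depth$error_rate
  alt <- stats::rbinom(n, dp, f * (1 - e) + (1 - f) * e)
  list(ref = dp - alt, alt = alt)
}

new_pooled_counts <- function(sites, ref_depth, alt_depth, pool, n_members = NA) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref_depth = as.integer(ref_depth),
                    alt_depth = as.integer(alt_depth),
                    stringsAsFactors = FALSE)
  structure(out, class = c("pooled_counts", "data.frame"),
            pool = pool, n_members = n_members,
            chrom_levels = attr(sites, "chrom_levels"))
}

#' Allele frequencies of a pooled count table
#' @param x A `pooled_counts` data frame.
#' @return Numeric vector alt/(ref+alt); NA where total depth is zero.
#' @export
pool_freq <- function(x) {
  tot <- x$ref_depth + x$alt_depth
  ifelse(tot > 0, x$alt_depth / tot, NA_real_)
}

#' @exportS3Method base::print
print.pooled_counts <- function(x, ...) {
  cat(sprintf("<pooled_counts> pool '%s': %d sites, mean depth %.1f\n",
              attr(x, "pool"), nrow(x), mean(x$ref_depth + x$alt_depth)))
  invisible(x)
}

#' Simulate a genome-wide read-depth track with planted copy-number changes
#'
#' Tiles each chromosome with fixed-width windows and draws each
#' window's mean depth from a Poisson model scaled by chromosome copy
#' number: a chromosome at copy `k` in a genome of baseline ploidy 2 has
#' expected depth `mean_depth * k / 2`.
#'
#' @param genome A [genome_spec()].
#' @param copy_numbers Named integer vector of per-chromosome copies;
#'   chromosomes not named default to 2 (diploid).
#' @param window Window width in bp (>= 100).
#' @param mean_depth Expected depth at copy 2.
#' @param seed Integer seed.
#' @return A `coverage_windows` data frame: `chrom`, `start`, `end`
#'   (1-based closed), `depth` (mean per-base depth in the window).
#' @examples
#' cw <- simulate_coverage(yeast_genome(), c(chrI = 3L), seed = 1)
#' chromosome_ratios(cw)[1, ]
#' @export
simulate_coverage <- function(genome, copy_numbers = integer(),
                              window = 1000L, mean_depth = 100,
                              seed = 1L) {
  if (window < 100) stop("window must be >= 100 bp")
  if (window > min(genome$chromosomes))
    stop("window larger than the smallest chromosome")
  copies <- stats::setNames(rep(2L, length(genome$chromosomes)),
                            chrom_names(genome))
  if (length(copy_numbers)) {
    unknown <- setdiff(names(copy_numbers), names(copies))
    if (length(unknown)) stop("unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
    if (any(copy_numbers < 1)) stop("copy numbers must be >= 1")
    copies[names(copy_numbers)] <- as.integer(copy_numbers)
  }
  set.seed(as.integer(seed))
  pieces <- lapply(chrom_names(genome), function(chr) {
    len <- unname(genome$chromosomes[chr])
    start <- seq(1L, len, by = window)
    end <- pmin(start + window - 1L, len)
    wlen <- end - start + 1L
    lambda <- mean_depth * copies[chr] / 2 * wlen
    data.frame(chrom = chr, start = start, end = end,
               depth = stats::rpois(length(start), lambda) / wlen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, class = c("coverage_windows", "data.frame"),
            window = as.integer(window),
            chrom_levels = chrom_names(genome),
            copy_numbers = copies)
}

#' Simulate a two-strain expression count matrix with a chromosome dosage effect
#'
#' Gene baseline means are drawn log-uniform; the evolved strain's means
#' are multiplied by the dosage fold of the gene's chromosome (1.5 for a
#' trisomic chromosome in a diploid); counts are negative binomial with
#' the given dispersion (Poisson at dispersion 0).  The default replicate
#' structure is 3 parent cultures vs 1 evolved culture, the design the
#' dosage summary must cope with.
#'
#' @param n_genes Number of genes.
#' @param gene_chromosomes Character vector of per-gene chromosome
#'   assignments (length `n_genes`), or NULL to allocate genes to the
#'   genome's chromosomes proportionally to length.
#' @param dosage Named numeric vector chromosome -> fold change of the
#'   evolved strain's expected expression (default none).
#' @param n_reps Integer vector `c(parent, evolved)` replicate counts.
#' @param dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson counts.
#' @param mean_range Range of baseline means, sampled log-uniformly.
#' @param genome Genome used when `gene_chromosomes` is NULL.
#' @param seed Integer seed.
#' @return An `expression_sim` list: integer `counts` matrix (genes x
#'   samples), `genes` data frame (`gene`, `chrom`, `base_mean`), and
#'   `strain` factor per sample.
#' @export
simulate_expression <- function(n_genes = 6000L, gene_chromosomes = NULL,
                                dosage = numeric(), n_reps = c(3L, 1L),
                                dispersion = 0.05, mean_range = c(10, 1000),
                                genome = yeast_genome(), seed = 1L) {
  stopifnot(n_genes >= 1, length(n_reps) == 2, all(n_reps >= 1),
            dispersion >= 0)
  set.seed(as.integer(seed))
  if (is.null(gene_chromosomes)) {
    gene_chromosomes <- sample(chrom_names(genome), n_genes, replace = TRUE,
                               prob = genome$chromosomes)
  }
  stopifnot(length(gene_chromosomes) == n_genes)
  if (length(dosage)) {
    unknown <- setdiff(names(dosage), unique(gene_chromosomes))
    if (length(unknown)) stop("dosage names unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
  }
  base_mean <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  fold <- rep(1, n_genes)
  if (length(dosage)) {
    hit <- gene_chromosomes %in% names(dosage)
    fold[hit] <- dosage[gene_chromosomes[hit]]
  }
  strain <- factor(rep(c("parent", "evolved"), n_reps),
                   levels = c("parent", "evolved"))
  draw <- function(mu) {
    if (dispersion > 0)
      as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
    else as.integer(stats::rpois(length(mu), mu))
  }
  counts <- vapply(seq_along(strain), function(s) {
    mu <- if (strain[s] == "evolved") base_mean * fold else base_mean
    draw(mu)
  }, integer(n_genes))
  colnames(counts) <- paste0(as.character(strain),
                             "_", stats::ave(seq_along(strain),
                                             strain, FUN = seq_along))
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = gene_chromosomes, base_mean = base_mean,
                      stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene
  structure(list(counts = counts, genes = genes, strain = strain,
                 dosage = dosage, dispersion = dispersion),
            class = "expression_sim")
}

#' @exportS3Method base::print
print.expression_sim <- function(x, ...) {
  cat(sprintf("<expression_sim> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$strain), table(x$strain), sep = ":",
                    collapse = ", ")))
  invisible(x)
}
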