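#' Simulate parent-heterozygous marker sites
#'
#' Places `n_sites` unique marker positions on the genome, allocated to
#' chromosomes proportionally to length and uniformly within each
#' chromosome, and assigns each a reference and alternate allele.  These
#' sites stand for the SNPs/InDels called heterozygous in the diploid
#' parent after allele-frequency and depth filtering; they are the
#' coordinate backbone of the whole scan.  The default count matches the
#' marker density such studies report after filtering (~18,000 sites).
#'
#' @param n_sites Number of marker sites (>= 1).
#' @param genome A [genome_spec()].
#' @param seed Integer seed.
#' @return A `het_sites` data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, sorted by genome order then position, unique positions.
#' @examples
#' s <- simulate_parent_sites(100, yeast_genome(), seed = 1)
#' table(s$chrom)[1:3]
#' @export
simulate_parent_sites <- function(n_sites = 18047L, genome = yeast_genome(),
                                  seed = 1L) {
  stopifnot(n_sites >= 1)
  total <- genome_length(genome)
  if (n_sites > total)
    stop("n_sites (", n_sites, ") exceeds total genome length (", total,
         "): marker density infeasible")
  set.seed(as.integer(seed))
  # sample genome-wide offsets without replacement: proportional-to-length
  # allocation and uniqueness within chromosome come for free
  offs <- sort(sample(total, n_sites))
  ends <- cumsum(genome$chromosomes)
  idx <- findInterval(offs - 1, c(0, ends), rightmost.closed = FALSE)
  pos <- as.integer(offs - c(0, ends)[idx])
  chrom <- chrom_names(genome)[idx]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  new_het_sites(out, genome = genome)
}

new_het_sites <- function(df, genome = NULL, filter = NULL) {
  chrom_levels <- if (!is.null(genome)) chrom_names(genome) else unique(df$chrom)
  o <- order(match(df$chrom, chrom_levels), df$pos)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("het_sites", "data.frame"),
            chrom_levels = chrom_levels, filter = filter)
}

#' @exportS3Method base::print
print.het_sites <- function(x, ...) {
  cat(sprintf("<het_sites> %d parent-heterozygous sites on %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  f <- attr(x, "filter")
  if (!is.null(f))
    cat(sprintf("  filter: AF in [%.2f, %.2f], depth >= %d (%d SNP, %d InDel)\n",
                f$af_min, f$af_max, f$min_depth, f$n_snp, f$n_indel))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Simulate meiosis: haploid segregant genotypes from a heterozygous diploid
#'
#' Each segregant chromosome starts from parental haplotype A (coded 0)
#' or B (coded 1) with probability 1/2; crossover counts are Poisson with
#' mean equal to the chromosome's genetic length in Morgans and breakpoints
#' uniform (no interference), so recombinant fractions follow Haldane's
#' mapping function c = (1 - exp(-2d))/2.
#'
#' @param sites A `het_sites` table (the marker map).
#' @param cross A [cross_config()].
#' @param genome A [genome_spec()].
#' @return A `segregant_set`: list with `sites`, a 0/1 `geno` matrix
#'   (segregant x site), and a `phenotype` factor (NA until
#'   [assign_phenotypes()] is run).
#' @export
simulate_meiosis <- function(sites, cross, genome = yeast_genome()) {
  if (nrow(sites) == 0) stop("sites is empty")
  set.seed(cross$seed)
  n <- cross$n_segregants
  geno <- matrix(0L, nrow = n, ncol = nrow(sites))
  for (chr in unique(sites$chrom)) {
    cols <- which(sites$chrom == chr)
    pos <- sites$pos[cols]
    len <- unname(genome$chromosomes[chr])
    L <- chrom_morgans(genome, chr)
    for (i in seq_len(n)) {
      start <- stats::rbinom(1, 1, 0.5)
      nco <- stats::rpois(1, L)
      if (nco == 0) {
        geno[i, cols] <- start
      } else {
        bp <- sort(stats::runif(nco, 0, len))
        # haplotype flips at each crossover breakpoint
        geno[i, cols] <- (start + findInterval(pos, bp)) %% 2L
      }
    }
  }
  structure(list(sites = sites, geno = geno,
                 phenotype = factor(rep(NA_character_, n),
                                    levels = phenotype_levels()),
                 cross = cross, genome = genome),
            class = "segregant_set")
}

phenotype_levels <- function() {
  c("Sensitive", "ResistantParental", "ResistantEvolved", "Intermediate")
}

#' @exportS3Method base::print
print.segregant_set <- function(x, ...) {
  cat(sprintf("<segregant_set> %d segregants x %d sites\n",
              nrow(x$geno), ncol(x$geno)))
  if (!all(is.na(x$phenotype))) print(table(x$phenotype))
  invisible(x)
}

#' @exportS3Method base::summary
summary.segregant_set <- function(object, ...) {
  if (all(is.na(object$phenotype)))
    stop("phenotypes not assigned; run assign_phenotypes() first")
  cluster_report(object$phenotype)
}

# index of the marker nearest to a QTL position, validating coordinates
nearest_site <- function(sites, genome, qtl) {
  if (!qtl$chrom %in% chrom_names(genome))
    stop("QTL chromosome '", qtl$chrom, "' not in genome")
  if (qtl$pos < 1 || qtl$pos > genome$chromosomes[qtl$chrom])
    stop("QTL position ", qtl$pos, " outside ", qtl$chrom)
  cols <- which(sites$chrom == qtl$chrom)
  if (length(cols) == 0) stop("no marker sites on ", qtl$chrom)
  cols[which.min(abs(sites$pos[cols] - qtl$pos))]
}

#' Assign two-locus resistance phenotypes to segregants
#'
#' Deterministic epistatic rule at the markers nearest the two planted
#' QTL: haplotype 0 at the major locus gives Sensitive; haplotype 1 at
#' the major locus gives ResistantEvolved when the modifier is also 1,
#' ResistantParental when it is 0.  Each resistant-genotype segregant is
#' then relabeled Intermediate with probability
#' `cross$intermediate_fraction`, modelling plate-score ambiguity.
#'
#' @param segregants A `segregant_set` from [simulate_meiosis()].
#' @param cross A [cross_config()]; defaults to the one stored in
#'   `segregants`.
#' @return The `segregant_set` with `phenotype` filled.
#' @export
assign_phenotypes <- function(segregants, cross = segregants$cross) {
  g <- segregants$genome
  i_major <- nearest_site(segregants$sites, g, cross$qtl_major)
  i_minor <- nearest_site(segregants$sites, g, cross$qtl_minor)
  gm <- segregants$geno[, i_major]
  gn <- segregants$geno[, i_minor]
  lab <- ifelse(gm == 0L, "Sensitive",
                ifelse(gn == 1L, "ResistantEvolved", "ResistantParental"))
  set.seed(cross$seed + 1L)
  res <- which(gm == 1L)
  if (length(res) && cross$intermediate_fraction > 0) {
    flip <- stats::runif(length(res)) < cross$intermediate_fraction
    lab[res[flip]] <- "Intermediate"
  }
  segregants$phenotype <- factor(lab, levels = phenotype_levels())
  segregants$qtl_sites <- c(major = i_major, minor = i_minor)
  segregants
}
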