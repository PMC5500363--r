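#' Genome specification for the cross simulator
#'
#' A `genome_spec` is an ordered set of chromosomes with lengths in base
#' pairs plus a uniform recombination rate in centimorgans per kilobase.
#' All simulators and the phenotype model take their coordinate system
#' from this object.
#'
#' @param chromosomes Named integer vector of chromosome lengths in bp,
#'   in genome order.  Names must be unique, lengths positive.
#' @param recombination_rate Uniform recombination rate, cM/kb.  The
#'   default 0.35 cM/kb is the S. cerevisiae genome average.
#' @return An object of class `genome_spec`.
#' @examples
#' g <- genome_spec(c(chrA = 200000L, chrB = 400000L))
#' genome_length(g)
#' @export
genome_spec <- function(chromosomes, recombination_rate = 0.35) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must be a named vector with unique names")
  len <- as.numeric(chromosomes)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("chromosome lengths must be positive")
  if (!is.numeric(recombination_rate) || recombination_rate < 0)
    stop("recombination_rate must be >= 0")
  structure(
    list(chromosomes = stats::setNames(len, names(chromosomes)),
         recombination_rate = recombination_rate),
    class = "genome_spec")
}

#' Default yeast genome (16 chromosomes, S288c-like lengths)
#'
#' Chromosome lengths follow the S288c reference assembly, the standard
#' coordinate system for S. cerevisiae resequencing studies.
#'
#' @inheritParams genome_spec
#' @return A `genome_spec` with 16 chromosomes, chrI-chrXVI.
#' @export
yeast_genome <- function(recombination_rate = 0.35) {
  genome_spec(c(
    chrI    = 230218L,  chrII   = 813184L,  chrIII  = 316620L,
    chrIV   = 1531933L, chrV    = 576874L,  chrVI   = 270161L,
    chrVII  = 1090940L, chrVIII = 562643L,  chrIX   = 439888L,
    chrX    = 745751L,  chrXI   = 666816L,  chrXII  = 1078177L,
    chrXIII = 924431L,  chrXIV  = 784333L,  chrXV   = 1091291L,
    chrXVI  = 948066L), recombination_rate)
}

#' @exportS3Method base::print
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %.3f Mb total, %.2f cM/kb\n",
              length(x$chromosomes), sum(x$chromosomes) / 1e6,
              x$recombination_rate))
  invisible(x)
}

#' Total genome length in bp
#' @param genome A `genome_spec`.
#' @return Numeric scalar.
#' @export
genome_length <- function(genome) sum(genome$chromosomes)

chrom_names <- function(genome) names(genome$chromosomes)

# Genetic length of one chromosome in Morgans under the uniform map.
chrom_morgans <- function(genome, chrom) {
  unname(genome$chromosomes[chrom]) / 1000 * genome$recombination_rate / 100
}

#' Cross configuration: segregant number, QTL placement, phenotype noise
#'
#' Describes the mapping cross: how many haploid segregants to draw from
#' the heterozygous diploid parent, where the large-effect resistance
#' locus and the smaller modifier locus sit, and the probability that a
#' resistant-genotype segregant is scored Intermediate on plates.
#'
#' @param n_segregants Number of monosporic clones to simulate (default
#'   69, the dissected-clone count typical of such crosses).
#' @param qtl_major `list(chrom=, pos=)` for the large-effect locus
#'   (default mid chrXII common region).
#' @param qtl_minor `list(chrom=, pos=)` for the modifier locus
#'   (default mid chrIV support interval).
#' @param intermediate_fraction Probability a resistant-genotype
#'   segregant is labeled Intermediate (plate-phenotype noise class).
#' @param seed Integer seed for the meiosis and phenotype draws.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_segregants = 69L,
                         qtl_major = list(chrom = "chrXII", pos = 543500L),
                         qtl_minor = list(chrom = "chrIV",  pos = 471500L),
                         intermediate_fraction = 0.4,
                         seed = 1L) {
  stopifnot(n_segregants >= 1,
            intermediate_fraction >= 0, intermediate_fraction < 1)
  structure(list(n_segregants = as.integer(n_segregants),
                 qtl_major = qtl_major, qtl_minor = qtl_minor,
                 intermediate_fraction = intermediate_fraction,
                 seed = as.integer(seed)),
            class = "cross_config")
}

#' Sequencing depth model for pooled reads
#'
#' @param mean_depth Mean read depth per site (the study's pools ran at
#'   66-133x; default 80).
#' @param error_rate Probability a read reports the wrong allele
#'   (default 0.002, typical short-read substitution error).
#' @param depth_dispersion Extra-Poisson depth dispersion; 0 gives
#'   Poisson depths, >0 negative-binomial with size 1/dispersion.
#' @param seed Integer seed.
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 80, error_rate = 0.002,
                        depth_dispersion = 0, seed = 1L) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.01,
            depth_dispersion >= 0)
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "depth_model")
}
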