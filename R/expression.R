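#' Median-of-ratios size factors for a count matrix
#'
#' The standard normalization for two-strain count comparisons: each
#' sample's factor is the median, over genes with nonzero counts in
#' every sample, of that sample's count divided by the gene's geometric
#' mean across samples.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stop("no gene has nonzero counts in all samples")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(sweep(lg, 1, geo)), 2, stats::median)
}

#' Per-gene log2 fold change between two strains
#'
#' Counts are divided by median-of-ratios size factors, averaged within
#' strain, and compared as `log2((evolved + pc) / (parent + pc))`; the
#' pseudocount keeps low-count genes finite and makes a gene absent
#' from both strains score exactly 0.
#'
#' @param counts Integer matrix, genes x samples.
#' @param strain Factor/character per sample with levels `parent` and
#'   `evolved`.
#' @param pseudocount Added to both normalized means (default 0.5).
#' @return Named numeric vector of per-gene log2 fold changes
#'   (evolved over parent).
#' @export
log2_fold_change <- function(counts, strain, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  strain <- as.character(strain)
  if (length(strain) != ncol(counts))
    stop("strain must label every sample")
  if (!all(c("parent", "evolved") %in% strain))
    stop("need at least one 'parent' and one 'evolved' sample")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  m_par <- rowMeans(norm[, strain == "parent", drop = FALSE])
  m_evo <- rowMeans(norm[, strain == "evolved", drop = FALSE])
  stats::setNames(log2((m_evo + pseudocount) / (m_par + pseudocount)),
                  rownames(counts))
}

#' Chromosome-level dosage summary of log2 fold changes
#'
#' For each chromosome: the mean log2 fold change of its genes and the
#' mean over all other chromosomes taken together — the comparison that
#' exposes a whole-chromosome dosage effect (a trisomic chromosome in a
#' diploid is expected near log2(1.5) ~ 0.585 against a background
#' near 0).  When significance flags are supplied the same means are
#' also reported over flagged genes only, since a study may compute
#' either variant.
#'
#' @param fc Numeric vector of per-gene log2 fold changes.
#' @param chromosomes Character vector assigning each gene to a
#'   chromosome (same length/order as `fc`).
#' @param flags Optional logical vector of per-gene significance.
#' @return A `dosage_summary` data frame: `chrom`, `n_genes`,
#'   `mean_fc`, `complement_mean_fc`, and (with flags) `n_sig`,
#'   `mean_fc_sig`, `complement_mean_fc_sig`.
#' @export
chromosome_dosage_summary <- function(fc, chromosomes, flags = NULL) {
  if (length(chromosomes) != length(fc))
    stop("chromosomes must be given for every gene")
  if (anyNA(chromosomes)) stop("unknown (NA) chromosome assignment")
  if (!is.null(flags) && length(flags) != length(fc))
    stop("flags length does not match fc")
  chroms <- unique(chromosomes)
  row_for <- function(ch) {
    on <- chromosomes == ch
    r <- data.frame(chrom = ch, n_genes = sum(on), mean_fc = mean(fc[on]),
                    complement_mean_fc = mean(fc[!on]),
                    stringsAsFactors = FALSE)
    if (!is.null(flags)) {
      r$n_sig <- sum(on & flags)
      r$mean_fc_sig <- if (any(on & flags)) mean(fc[on & flags]) else NA_real_
      r$complement_mean_fc_sig <-
        if (any(!on & flags)) mean(fc[!on & flags]) else NA_real_
    }
    r
  }
  out <- do.call(rbind, lapply(chroms, row_for))
  rownames(out) <- NULL
  structure(out, class = c("dosage_summary", "data.frame"))
}

#' @exportS3Method base::print
print.dosage_summary <- function(x, ...) {
  cat("<dosage_summary> mean log2 FC per chromosome vs all others\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Bin significant genes by fold-change direction and magnitude
#'
#' Drops genes on excluded chromosomes (e.g. an aneuploid chromosome
#' whose dosage effect would swamp the comparison), keeps flagged
#' genes, and counts them as up- (FC > 0) or down-regulated (FC < 0),
#' split at a two-fold difference (|log2 FC| >= 1, inclusive).
#'
#' @param fc Numeric vector of per-gene log2 fold changes.
#' @param flags Logical per-gene significance flags (e.g. FDR < 0.05);
#'   NULL keeps every gene.
#' @param chromosomes Per-gene chromosome assignment; required when
#'   `exclude_chromosomes` is given.
#' @param exclude_chromosomes Chromosomes whose genes are dropped
#'   before binning.
#' @return A `fc_bins` data frame with rows up/down x (>=2-fold,
#'   <2-fold); attributes `n_kept` and `n_zero` (genes with FC exactly
#'   0, counted in neither direction).
#' @export
bin_fold_changes <- function(fc, flags = NULL, chromosomes = NULL,
                             exclude_chromosomes = NULL) {
  n <- length(fc)
  if (is.null(flags)) flags <- rep(TRUE, n)
  if (length(flags) != n) stop("flags length does not match fc")
  keep <- flags
  if (!is.null(exclude_chromosomes)) {
    if (is.null(chromosomes) || length(chromosomes) != n)
      stop("chromosomes required (per gene) to exclude chromosomes")
    keep <- keep & !(chromosomes %in% exclude_chromosomes)
  }
  f <- fc[keep]
  out <- data.frame(
    direction = c("up", "up", "down", "down"),
    magnitude = c(">=2-fold", "<2-fold", ">=2-fold", "<2-fold"),
    n_genes = c(sum(f > 0 & f >= 1), sum(f > 0 & f < 1),
                sum(f < 0 & f <= -1), sum(f < 0 & f > -1)),
    stringsAsFactors = FALSE)
  structure(out, class = c("fc_bins", "data.frame"),
            n_kept = sum(keep), n_zero = sum(f == 0))
}

#' @exportS3Method base::print
print.fc_bins <- function(x, ...) {
  cat(sprintf("<fc_bins> %d significant gene(s) after exclusions\n",
              attr(x, "n_kept")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}
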