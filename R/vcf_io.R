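#' Write marker sites and per-sample allele depths as a VCF 4.2 file
#'
#' Emits a minimal multi-sample VCF with per-sample `AD` (ref,alt read
#' depths) and `DP` fields, the format the analysis side of the package
#' consumes, so simulated crosses flow through the same file formats as
#' real pooled-sequencing data.
#'
#' @param path Output file path.
#' @param sites A `het_sites` table (`chrom`, `pos`, `ref`, `alt`).
#' @param counts Named list of `pooled_counts` tables aligned to
#'   `sites` (same chrom/pos order); names become VCF sample names.
#' @param genome Optional [genome_spec()] used to write contig headers.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(path, sites, counts, genome = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1, !is.null(names(counts)))
  for (nm in names(counts)) {
    cc <- counts[[nm]]
    if (nrow(cc) != nrow(sites) || any(cc$chrom != sites$chrom) ||
        any(cc$pos != sites$pos))
      stop("counts for sample '", nm, "' are not aligned to sites")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsaqtl")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chrom_names(genome),
                          as.integer(genome$chromosomes)))
  hdr <- c(hdr,
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(counts)), collapse = "\t"))
  sample_cols <- lapply(counts, function(cc)
    sprintf("%d,%d:%d", cc$ref_depth, cc$alt_depth,
            cc$ref_depth + cc$alt_depth))
  body <- do.call(paste, c(list(sites$chrom, sites$pos, ".", sites$ref,
                                sites$alt, ".", "PASS", ".", "AD:DP"),
                           sample_cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF with per-sample allele depths
#'
#' Parses a VCF (via vcfR) and extracts per-sample reference and
#' alternate read depths from the `AD` field.  Multiallelic records are
#' skipped (their count is kept in the result); records lacking `AD` for
#' any sample raise an error naming the sample and site.
#'
#' @param path VCF file path.
#' @return A `vcf_sites` object: list with `sites` (data frame `chrom`,
#'   `pos`, `ref`, `alt`, `class` in SNP/InDel), `ref_depth` and
#'   `alt_depth` (site x sample integer matrices), `samples`, and
#'   `n_multiallelic`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD field: per-sample allele depths required")
  keep <- which(!multi)
  if (length(keep) == 0) stop("no biallelic records in ", path)
  ad <- ad[keep, , drop = FALSE]
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  ref <- fix[keep, "REF"]
  alt <- alt[keep]
  miss <- which(is.na(ad) | ad == ".", arr.ind = TRUE)
  if (nrow(miss)) {
    stop(sprintf("missing AD for sample '%s' at %s:%d",
                 colnames(ad)[miss[1, 2]], chrom[miss[1, 1]],
                 pos[miss[1, 1]]))
  }
  split_ad <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    bad <- which(lengths(parts) < 2)
    if (length(bad))
      stop(sprintf("malformed AD '%s' at %s:%d", col[bad[1]],
                   chrom[bad[1]], pos[bad[1]]))
    m <- vapply(parts, function(p) as.integer(p[1:2]), integer(2))
    t(m)
  }
  mats <- lapply(seq_len(ncol(ad)), function(j) split_ad(ad[, j]))
  ref_depth <- vapply(mats, function(m) m[, 1], integer(length(keep)))
  alt_depth <- vapply(mats, function(m) m[, 2], integer(length(keep)))
  if (is.null(dim(ref_depth))) {
    ref_depth <- matrix(ref_depth, ncol = ncol(ad))
    alt_depth <- matrix(alt_depth, ncol = ncol(ad))
  }
  colnames(ref_depth) <- colnames(alt_depth) <- colnames(ad)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      class = ifelse(nchar(ref) == nchar(alt) &
                                       nchar(ref) == 1L, "SNP", "InDel"),
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, ref_depth = ref_depth,
                 alt_depth = alt_depth, samples = colnames(ad),
                 n_multiallelic = sum(multi)),
            class = "vcf_sites")
}

#' @exportS3Method base::print
print.vcf_sites <- function(x, ...) {
  cat(sprintf("<vcf_sites> %d biallelic sites (%d SNP, %d InDel), samples: %s\n",
              nrow(x$sites), sum(x$sites$class == "SNP"),
              sum(x$sites$class == "InDel"),
              paste(x$samples, collapse = ", ")))
  if (x$n_multiallelic > 0)
    cat(sprintf("  %d multiallelic record(s) skipped\n", x$n_multiallelic))
  invisible(x)
}

#' Extract one sample's allele counts from a parsed VCF
#'
#' @param x A `vcf_sites` object from [read_vcf()].
#' @param sample Sample name.
#' @return A `pooled_counts` data frame for that sample.
#' @export
pool_counts <- function(x, sample) {
  if (!sample %in% x$samples)
    stop("sample '", sample, "' not in VCF (has: ",
         paste(x$samples, collapse = ", "), ")")
  new_pooled_counts(x$sites, x$ref_depth[, sample], x$alt_depth[, sample],
                    pool = sample)
}

#' Call parent-heterozygous marker sites with AF and depth filters
#'
#' Retains the sites whose allele frequency in the designated parent
#' sample lies within `[af_min, af_max]` (bounds inclusive, so the
#' nominal 0.25-0.75 band is attainable) and whose parent depth is at
#' least `min_depth`.  These are the markers segregating in the cross;
#' everything downstream scans only them.
#'
#' @param x A `vcf_sites` object.
#' @param parent_sample Name of the parent strain's sample in the VCF.
#' @param af_min,af_max Inclusive allele-frequency bounds (defaults
#'   0.25 and 0.75).
#' @param min_depth Minimum parent read depth (default 20).
#' @return A `het_sites` data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `class`, parent `ref_depth`/`alt_depth`), with the filter
#'   parameters and retained SNP/InDel counts as attributes.
#' @export
call_het_sites <- function(x, parent_sample, af_min = 0.25, af_max = 0.75,
                           min_depth = 20) {
  if (!parent_sample %in% x$samples)
    stop("parent sample '", parent_sample, "' not in VCF")
  stopifnot(af_min <= af_max, min_depth >= 0)
  r <- x$ref_depth[, parent_sample]
  a <- x$alt_depth[, parent_sample]
  dp <- r + a
  af <- ifelse(dp > 0, a / dp, NA_real_)
  keep <- !is.na(af) & dp >= min_depth & af >= af_min & af <= af_max
  df <- x$sites[keep, , drop = FALSE]
  df$ref_depth <- r[keep]
  df$alt_depth <- a[keep]
  new_het_sites(df, filter = list(
    af_min = af_min, af_max = af_max, min_depth = min_depth,
    parent_sample = parent_sample,
    n_snp = sum(df$class == "SNP"), n_indel = sum(df$class == "InDel")))
}

#' De-novo variants of the evolved strain by parental subtraction
#'
#' Returns the evolved strain's variants whose (chrom, pos, ref, alt)
#' key is absent both from the parent's variant set and from the parent
#' heterozygous set: matching requires the identical alternate allele,
#' not just the position.  This is the set-subtraction step that
#' separates mutations arisen during selection from re-assorted
#' parental heterozygosity.
#'
#' @param evolved_records Data frame with columns `chrom`, `pos`,
#'   `ref`, `alt` (a `het_sites` table or `vcf_sites$sites` works).
#' @param parent_records Same layout: variants called in the parent.
#' @param parent_het Optional third table of parent heterozygous sites,
#'   also subtracted (pass when `parent_records` holds homozygous calls
#'   only).
#' @return The de-novo subset of `evolved_records`, with attributes
#'   `n_removed`, `n_snp`, `n_indel`.
#' @export
subtract_parental_variants <- function(evolved_records, parent_records,
                                       parent_het = NULL) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  drop_keys <- key(parent_records)
  if (!is.null(parent_het)) drop_keys <- c(drop_keys, key(parent_het))
  keep <- !(key(evolved_records) %in% drop_keys)
  out <- evolved_records[keep, , drop = FALSE]
  rownames(out) <- NULL
  cls <- if ("class" %in% names(out)) out$class
         else ifelse(nchar(out$ref) == nchar(out$alt) & nchar(out$ref) == 1L,
                     "SNP", "InDel")
  structure(out, n_removed = sum(!keep),
            n_snp = sum(cls == "SNP"), n_indel = sum(cls == "InDel"))
}

#' Write genomic intervals as a BED file
#'
#' Internal coordinates are 1-based closed (VCF convention); BED is
#' 0-based half-open, so `start - 1` is written.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (1-based closed); extra columns are appended after the name field.
#' @param path Output path.
#' @param name_col Optional column used as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  lines <- "#chrom\tstart\tend\tname"
  if (nrow(intervals)) {
    nm <- if (!is.null(name_col)) as.character(intervals[[name_col]])
          else rep(".", nrow(intervals))
    lines <- c(lines, paste(intervals$chrom,
                            format(intervals$start - 1L, scientific = FALSE,
                                   trim = TRUE),
                            format(intervals$end, scientific = FALSE,
                                   trim = TRUE),
                            nm, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file back into 1-based closed intervals
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end` (1-based closed), `name`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           fill = TRUE)
  if (nrow(raw) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = raw$chrom, start = as.integer(raw$start) + 1L,
             end = as.integer(raw$end), name = raw$name,
             stringsAsFactors = FALSE)
}

#' Write a coverage-window table as 4-column bedGraph
#' @param windows A `coverage_windows` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, path) {
  writeLines(c("track type=bedGraph",
               paste(windows$chrom,
                     format(windows$start - 1L, scientific = FALSE, trim = TRUE),
                     format(windows$end, scientific = FALSE, trim = TRUE),
                     format(windows$depth, scientific = FALSE, trim = TRUE),
                     sep = "\t")),
             path)
  invisible(path)
}

#' Read a 4-column bedGraph depth track
#' @param path bedGraph path (optional `track` header line tolerated).
#' @return Data frame `chrom`, `start` (0-based), `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  raw <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("chrom", "start", "end", "depth"),
                           stringsAsFactors = FALSE)
  raw
}
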