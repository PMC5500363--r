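#' Absolute log10 odds-ratio LOD score for two pooled allele counts
#'
#' The association statistic of the scan: the absolute log10 of the
#' odds ratio of the alternate-allele frequencies in two pools, with a
#' Haldane-Anscombe 1/2 continuity correction so zero counts score
#' finite.  Symmetric under swapping the two pools and under swapping
#' ref/alt in both pools simultaneously.  Vectorized.
#'
#' @param a_ref,a_alt Reference/alternate read counts in pool A.
#' @param b_ref,b_alt Reference/alternate read counts in pool B.
#' @return Nonnegative LOD score(s); total depth must be positive in
#'   both pools.
#' @examples
#' lod_score(20, 20, 20, 20)   # identical odds -> 0
#' lod_score(40, 0, 0, 40)     # complete selection -> ~3.82
#' @export
lod_score <- function(a_ref, a_alt, b_ref, b_alt) {
  if (any(a_ref + a_alt <= 0) || any(b_ref + b_alt <= 0))
    stop("total depth must be positive in both pools")
  abs(log10(((a_alt + 0.5) / (a_ref + 0.5)) /
              ((b_alt + 0.5) / (b_ref + 0.5))))
}

#' Genome-wide LOD scan of two segregant pools
#'
#' Joins the two pools' counts on the parent-heterozygous marker set
#' (inner join on chromosome and position), drops sites with zero total
#' depth in either pool (their count is recorded), and scores each
#' remaining site with [lod_score()].  An optional rolling-median
#' smoother (window in sites) is available for noisy low-depth data;
#' per-variant LOD with no smoothing is the default.
#'
#' @param het_sites A `het_sites` table, or NULL to scan the sites the
#'   pools share.
#' @param pool_a,pool_b `pooled_counts` tables.
#' @param smooth_window Odd integer rolling-median window in sites;
#'   0 disables smoothing (default).
#' @return A `lod_track` data frame: `chrom`, `pos`, `freq_a`,
#'   `freq_b`, `lod`, sorted by genome order; attributes `pools` and
#'   `n_skipped`.
#' @export
bsa_scan <- function(het_sites, pool_a, pool_b, smooth_window = 0L) {
  key_a <- paste(pool_a$chrom, pool_a$pos)
  key_b <- paste(pool_b$chrom, pool_b$pos)
  if (is.null(het_sites)) {
    keys <- intersect(key_a, key_b)
    chrom_levels <- attr(pool_a, "chrom_levels")
  } else {
    keys <- intersect(paste(het_sites$chrom, het_sites$pos),
                      intersect(key_a, key_b))
    chrom_levels <- attr(het_sites, "chrom_levels")
  }
  if (length(keys) == 0) stop("no shared sites between pools and marker set")
  ia <- match(keys, key_a)
  ib <- match(keys, key_b)
  tot_a <- pool_a$ref_depth[ia] + pool_a$alt_depth[ia]
  tot_b <- pool_b$ref_depth[ib] + pool_b$alt_depth[ib]
  ok <- tot_a > 0 & tot_b > 0
  n_skipped <- sum(!ok)
  ia <- ia[ok]; ib <- ib[ok]
  df <- data.frame(
    chrom = pool_a$chrom[ia], pos = pool_a$pos[ia],
    freq_a = pool_a$alt_depth[ia] / (pool_a$ref_depth[ia] + pool_a$alt_depth[ia]),
    freq_b = pool_b$alt_depth[ib] / (pool_b$ref_depth[ib] + pool_b$alt_depth[ib]),
    lod = lod_score(pool_a$ref_depth[ia], pool_a$alt_depth[ia],
                    pool_b$ref_depth[ib], pool_b$alt_depth[ib]),
    stringsAsFactors = FALSE)
  if (is.null(chrom_levels)) chrom_levels <- unique(df$chrom)
  df <- df[order(match(df$chrom, chrom_levels), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (smooth_window >= 3) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) k <- k + 1L
    for (chr in unique(df$chrom)) {
      i <- which(df$chrom == chr)
      if (length(i) >= k)
        df$lod[i] <- as.numeric(stats::runmed(df$lod[i], k, endrule = "median"))
    }
  }
  structure(df, class = c("lod_track", "data.frame"),
            pools = c(attr(pool_a, "pool"), attr(pool_b, "pool")),
            n_skipped = n_skipped, chrom_levels = chrom_levels,
            smooth_window = as.integer(smooth_window))
}

#' @exportS3Method base::print
print.lod_track <- function(x, ...) {
  p <- attr(x, "pools")
  cat(sprintf("<lod_track> %s vs %s: %d sites, max LOD %.2f",
              p[1], p[2], nrow(x), max(x$lod)))
  if (attr(x, "n_skipped") > 0)
    cat(sprintf(" (%d zero-depth sites skipped)", attr(x, "n_skipped")))
  cat("\n")
  invisible(x)
}

#' Plot a genome-wide LOD track
#'
#' Per-variant LOD against genomic position, chromosomes laid side by
#' side in alternating shades with the QTL threshold drawn as a
#' horizontal line.
#'
#' @param x A `lod_track`.
#' @param threshold QTL threshold line (default 3).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @exportS3Method graphics::plot
plot.lod_track <- function(x, threshold = 3, ...) {
  levels <- attr(x, "chrom_levels")
  levels <- levels[levels %in% x$chrom]
  span <- vapply(levels, function(ch) max(x$pos[x$chrom == ch]), numeric(1))
  offset <- stats::setNames(cumsum(c(0, span[-length(span)])), levels)
  gx <- offset[x$chrom] + x$pos
  col <- c("grey30", "steelblue")[(match(x$chrom, levels) %% 2L) + 1L]
  p <- attr(x, "pools")
  graphics::plot(gx, x$lod, pch = 16, cex = 0.4, col = col,
                 xlab = "genome position (bp)", ylab = "LOD",
                 main = sprintf("%s vs %s", p[1], p[2]), xaxt = "n", ...)
  mid <- offset + span / 2
  graphics::axis(1, at = mid, labels = levels, las = 2, cex.axis = 0.7)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Call QTL peaks with 1-LOD support intervals
#'
#' Peaks are local maxima exceeding `threshold` (leftmost site wins a
#' tie between equal-LOD neighbours).  Each peak's support interval
#' extends outward to the first flanking site on each side whose LOD
#' has dropped to `peak - drop` or below (the chromosome end if the
#' drop is never reached); endpoints are reported at marker positions,
#' the data's resolution.  Peaks whose intervals overlap on one
#' chromosome are merged, keeping the higher peak.
#'
#' @param track A `lod_track`.
#' @param threshold Minimum peak LOD (default 3).
#' @param drop LOD drop defining the support interval (default 1).
#' @return A `qtl_intervals` data frame: `chrom`, `peak_pos`,
#'   `peak_lod`, `start`, `end`, `pool_a`, `pool_b`.
#' @export
call_qtl <- function(track, threshold = 3, drop = 1) {
  if (nrow(track) == 0) stop("empty LOD track")
  p <- attr(track, "pools")
  if (is.null(p)) p <- c(NA_character_, NA_character_)
  res <- list()
  for (chr in unique(track$chrom)) {
    i <- which(track$chrom == chr)
    lod <- track$lod[i]
    pos <- track$pos[i]
    n <- length(lod)
    left <- c(-Inf, lod[-n])
    right <- c(lod[-1], -Inf)
    # strict vs left neighbour makes the leftmost of an equal-LOD plateau
    # the peak; >= vs right keeps it a local maximum
    cand <- which(lod > threshold & lod > left & lod >= right)
    if (length(cand) == 0) next
    cand <- cand[order(-lod[cand], pos[cand])]
    accepted <- list()
    for (pk in cand) {
      lim <- lod[pk] - drop
      l <- pk
      while (l > 1 && lod[l] > lim) l <- l - 1
      r <- pk
      while (r < n && lod[r] > lim) r <- r + 1
      iv <- c(pos[l], pos[r])
      overlaps <- any(vapply(accepted, function(a)
        iv[1] <= a$end && a$start <= iv[2], logical(1)))
      if (!overlaps)
        accepted[[length(accepted) + 1]] <-
          list(chrom = chr, peak_pos = pos[pk], peak_lod = lod[pk],
               start = iv[1], end = iv[2])
    }
    res <- c(res, accepted)
  }
  out <- if (length(res)) {
    do.call(rbind, lapply(res, function(a)
      data.frame(chrom = a$chrom, peak_pos = a$peak_pos,
                 peak_lod = a$peak_lod, start = a$start, end = a$end,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(chrom = character(), peak_pos = integer(),
               peak_lod = numeric(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }
  out$pool_a <- rep(p[1], nrow(out))
  out$pool_b <- rep(p[2], nrow(out))
  chrom_levels <- attr(track, "chrom_levels")
  out <- out[order(match(out$chrom, chrom_levels), out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("qtl_intervals", "data.frame"),
            threshold = threshold, drop = drop)
}

#' @exportS3Method base::print
print.qtl_intervals <- function(x, ...) {
  cat(sprintf("<qtl_intervals> %d interval(s) (LOD > %s, %s-LOD support)\n",
              nrow(x), format(attr(x, "threshold")), format(attr(x, "drop"))))
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Intersect QTL support intervals from two comparisons
#'
#' Pairwise intersections of overlapping intervals on the same
#' chromosome — the "common region" shared by two scans.  Commutative;
#' empty when all pairs are disjoint; each intersection is contained in
#' both inputs.
#'
#' @param intervals_a,intervals_b Interval data frames (`chrom`,
#'   `start`, `end`), e.g. from [call_qtl()].
#' @return Data frame `chrom`, `start`, `end` of intersections.
#' @examples
#' a <- data.frame(chrom = "chrXII", start = 512000, end = 560000)
#' b <- data.frame(chrom = "chrXII", start = 527000, end = 572000)
#' common_region(a, b)  # 527000-560000
#' @export
common_region <- function(intervals_a, intervals_b) {
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(intervals_a))) {
    for (j in seq_len(nrow(intervals_b))) {
      if (intervals_a$chrom[i] != intervals_b$chrom[j]) next
      s <- max(intervals_a$start[i], intervals_b$start[j])
      e <- min(intervals_a$end[i], intervals_b$end[j])
      if (s <= e)
        out <- rbind(out, data.frame(chrom = intervals_a$chrom[i],
                                     start = s, end = e,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Run all three pairwise pool comparisons of a bulk-segregant design
#'
#' Scans Sensitive vs ResistantParental, Sensitive vs ResistantEvolved
#' and ResistantParental vs ResistantEvolved, calls QTL intervals in
#' each, and intersects the two sensitive-vs-resistant interval sets
#' into the common region that localizes the major locus.
#'
#' @param het_sites A `het_sites` marker table (or NULL).
#' @param pools Named list of `pooled_counts` containing at least
#'   `Sensitive`, `ResistantParental` and `ResistantEvolved`.
#' @param threshold,drop Passed to [call_qtl()].
#' @param smooth_window Passed to [bsa_scan()].
#' @return A `bsa_comparison`: list with `tracks`, `intervals` (both
#'   named by comparison) and `common` (intersection of the two
#'   sensitive-vs-resistant calls).
#' @export
compare_all_pools <- function(het_sites, pools, threshold = 3, drop = 1,
                              smooth_window = 0L) {
  need <- c("Sensitive", "ResistantParental", "ResistantEvolved")
  missing <- setdiff(need, names(pools))
  if (length(missing))
    stop("missing pool(s): ", paste(missing, collapse = ", "))
  pairs <- list(
    SvRP  = c("Sensitive", "ResistantParental"),
    SvRE  = c("Sensitive", "ResistantEvolved"),
    RPvRE = c("ResistantParental", "ResistantEvolved"))
  tracks <- lapply(pairs, function(p)
    bsa_scan(het_sites, pools[[p[1]]], pools[[p[2]]],
             smooth_window = smooth_window))
  intervals <- lapply(tracks, call_qtl, threshold = threshold, drop = drop)
  structure(list(tracks = tracks, intervals = intervals,
                 common = common_region(intervals$SvRP, intervals$SvRE)),
            class = "bsa_comparison")
}

#' @exportS3Method base::print
print.bsa_comparison <- function(x, ...) {
  cat("<bsa_comparison> three pairwise pool scans\n")
  for (nm in names(x$intervals)) {
    iv <- x$intervals[[nm]]
    cat(sprintf("  %-5s: %d site(s), %d QTL interval(s)\n",
                nm, nrow(x$tracks[[nm]]), nrow(iv)))
    if (nrow(iv))
      cat(sprintf("      %s: peak %.0f (LOD %.1f), interval %.0f-%.0f\n",
                  iv$chrom, iv$peak_pos, iv$peak_lod, iv$start, iv$end), sep = "")
  }
  if (nrow(x$common))
    cat(sprintf("  common region: %s %.0f-%.0f\n", x$common$chrom,
                x$common$start, x$common$end), sep = "")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.bsa_comparison <- function(x, threshold = 3, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$tracks)) plot(x$tracks[[nm]], threshold = threshold, ...)
  invisible(x)
}
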