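#' Aggregate a depth track into fixed-width coverage windows
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp
#' and computes each window's mean per-base depth; the final partial
#' window is normalized by its true length.  Accepts either a per-base
#' table (`chrom`, `pos`, `depth`, 1-based) or a bedGraph-style
#' interval table (`chrom`, `start`, `end`, `depth`, 0-based
#' half-open).  Positions uncovered by any record count as depth 0.
#'
#' @param depth Depth table in one of the two layouts above.
#' @param window Window width in bp (default 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   when absent the last covered base defines each chromosome's end.
#' @return A `coverage_windows` data frame: `chrom`, `start`, `end`
#'   (1-based closed), `depth`.
#' @export
window_depth <- function(depth, window = 1000L, chrom_lengths = NULL) {
  window <- as.integer(window)
  stopifnot(window >= 1)
  per_base <- all(c("chrom", "pos", "depth") %in% names(depth))
  bedgraph <- all(c("chrom", "start", "end", "depth") %in% names(depth))
  if (!per_base && !bedgraph)
    stop("depth must have columns (chrom, pos, depth) or (chrom, start, end, depth)")
  chroms <- unique(depth$chrom)
  pieces <- lapply(chroms, function(chr) {
    d <- depth[depth$chrom == chr, , drop = FALSE]
    key <- if (per_base) d$pos else d$start
    if (is.unsorted(key, strictly = FALSE))
      stop("depth records for ", chr, " are not sorted by position")
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      as.integer(chrom_lengths[chr])
    else if (per_base) max(d$pos) else max(d$end)
    wstart <- seq(1L, len, by = window)
    wend <- pmin(wstart + window - 1L, len)
    wlen <- wend - wstart + 1L
    sums <- numeric(length(wstart))
    if (per_base) {
      wi <- (d$pos - 1L) %/% window + 1L
      agg <- tapply(d$depth, wi, sum)
      sums[as.integer(names(agg))] <- agg
    } else {
      # split each interval's mass across the windows it overlaps
      for (k in seq_len(nrow(d))) {
        s <- d$start[k] + 1L   # to 1-based closed
        e <- d$end[k]
        w1 <- (s - 1L) %/% window + 1L
        w2 <- (e - 1L) %/% window + 1L
        for (w in w1:w2) {
          ov <- min(e, wend[w]) - max(s, wstart[w]) + 1L
          sums[w] <- sums[w] + ov * d$depth[k]
        }
      }
    }
    data.frame(chrom = chr, start = wstart, end = wend,
               depth = sums / wlen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, class = c("coverage_windows", "data.frame"),
            window = window, chrom_levels = chroms)
}

#' @exportS3Method base::print
print.coverage_windows <- function(x, ...) {
  cat(sprintf("<coverage_windows> %d windows of %d bp on %d chromosomes, median depth %.1f\n",
              nrow(x), attr(x, "window"), length(unique(x$chrom)),
              stats::median(x$depth)))
  invisible(x)
}

#' Plot per-window depth across the genome
#' @param x A `coverage_windows` data frame.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @exportS3Method graphics::plot
plot.coverage_windows <- function(x, ...) {
  levels <- attr(x, "chrom_levels")
  if (is.null(levels)) levels <- unique(x$chrom)
  span <- vapply(levels, function(ch) max(x$end[x$chrom == ch]), numeric(1))
  offset <- stats::setNames(cumsum(c(0, span[-length(span)])), levels)
  gx <- offset[x$chrom] + (x$start + x$end) / 2
  col <- c("grey30", "darkorange")[(match(x$chrom, levels) %% 2L) + 1L]
  graphics::plot(gx, x$depth, pch = 16, cex = 0.3, col = col,
                 xlab = "genome position (bp)", ylab = "window depth", ...)
  graphics::abline(h = stats::median(x$depth), lty = 2)
  invisible(x)
}

#' Per-chromosome depth ratios relative to the genome median
#'
#' Ratio of each chromosome's median window depth to the genome-wide
#' median window depth.  Medians rather than means keep the baseline
#' robust to segmental CNV; ratios are invariant to global depth
#' scaling.  A 3:2 ratio (1.5) in a diploid indicates trisomy.
#'
#' @param windows A `coverage_windows` data frame.
#' @return Data frame `chrom`, `median_depth`, `ratio`, `n_windows`.
#' @export
chromosome_ratios <- function(windows) {
  g <- stats::median(windows$depth)
  if (g <= 0) stop("genome-wide median depth is zero")
  chroms <- unique(windows$chrom)
  med <- vapply(chroms, function(ch)
    stats::median(windows$depth[windows$chrom == ch]), numeric(1))
  n <- vapply(chroms, function(ch) sum(windows$chrom == ch), integer(1))
  out <- data.frame(chrom = chroms, median_depth = med, ratio = med / g,
                    n_windows = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call whole-chromosome aneuploidy from depth ratios
#'
#' A chromosome is flagged when its depth ratio sits within `tolerance`
#' of an integer copy-number grid point `k / baseline_ploidy` with
#' `k != baseline_ploidy`; the copy estimate is that `k`.  Unflagged
#' chromosomes are reported with their ratio only.
#'
#' @param ratios Data frame from [chromosome_ratios()].
#' @param baseline_ploidy Baseline ploidy (default 2, diploid).
#' @param tolerance Maximum |ratio - k/ploidy| to call copy `k`
#'   (default 0.15).
#' @return An `aneuploidy_calls` data frame: `chrom`, `ratio`,
#'   `copy_estimate` (NA when unflagged), `flagged`.
#' @export
call_aneuploidy <- function(ratios, baseline_ploidy = 2L, tolerance = 0.15) {
  stopifnot(baseline_ploidy >= 1, tolerance > 0)
  k <- pmax(0L, as.integer(round(ratios$ratio * baseline_ploidy)))
  dev <- abs(ratios$ratio - k / baseline_ploidy)
  flagged <- k != baseline_ploidy & dev <= tolerance
  out <- data.frame(chrom = ratios$chrom, ratio = ratios$ratio,
                    copy_estimate = ifelse(flagged, k, NA_integer_),
                    flagged = flagged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("aneuploidy_calls", "data.frame"),
            baseline_ploidy = as.integer(baseline_ploidy),
            tolerance = tolerance)
}

#' @exportS3Method base::print
print.aneuploidy_calls <- function(x, ...) {
  hits <- x[x$flagged, , drop = FALSE]
  cat(sprintf("<aneuploidy_calls> %d/%d chromosome(s) flagged (ploidy %d, tol %.2f)\n",
              nrow(hits), nrow(x), attr(x, "baseline_ploidy"),
              attr(x, "tolerance")))
  if (nrow(hits))
    cat(sprintf("  %s: ratio %.2f -> %d copies\n", hits$chrom, hits$ratio,
                hits$copy_estimate))
  invisible(x)
}

#' Segmental CNV candidates as runs of aberrant windows
#'
#' Reports runs of at least `min_run` consecutive windows whose depth,
#' relative to the genome median, deviates from 1 by more than
#' `tolerance` — a deliberately simple screen for within-chromosome
#' copy changes that whole-chromosome ratios would average away.
#'
#' @param windows A `coverage_windows` data frame.
#' @param tolerance Relative deviation from the diploid baseline
#'   (default 0.25).
#' @param min_run Minimum run length in windows (default 10).
#' @return Data frame `chrom`, `start`, `end`, `n_windows`,
#'   `mean_ratio`.
#' @export
segmental_cnv <- function(windows, tolerance = 0.25, min_run = 10L) {
  g <- stats::median(windows$depth)
  if (g <= 0) stop("genome-wide median depth is zero")
  rel <- windows$depth / g
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_windows = integer(), mean_ratio = numeric(),
                    stringsAsFactors = FALSE)
  for (chr in unique(windows$chrom)) {
    i <- which(windows$chrom == chr)
    ab <- abs(rel[i] - 1) > tolerance
    r <- rle(ab)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      seg <- i[starts[j]:stops[j]]
      out <- rbind(out, data.frame(
        chrom = chr, start = windows$start[seg[1]],
        end = windows$end[seg[length(seg)]],
        n_windows = length(seg), mean_ratio = mean(rel[seg]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
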