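# Windowed introgression scan: candidate tracts are runs of fixed-size
# windows with zero SNP density and high mapping coverage, the signature of
# sequence recently acquired from the mapped donor lineage.

#' Per-window SNP density and mean coverage
#'
#' Tiles the reference (extent taken from the coverage table) into
#' non-overlapping windows. A 1-based SNP position `p` falls in window
#' `floor((p - 1) / window)`; coverage is averaged into windows weighted by
#' overlap, so re-windowed coverage tables are handled and short terminal
#' windows are pro-rated.
#'
#' @param variants a [variant_table()] or data.frame with `chrom`, `pos`
#'   (1-based).
#' @param coverage data.frame `chrom`, `start` (0-based), `end`, `mean_cov`.
#' @param window window size in bp (>= 100).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `snp_count`, `mean_cov`.
#' @export
window_stats <- function(variants, coverage, window = 1000L) {
  if (!.is_count(window) || window < 100)
    stop_bad("window size must be an integer >= 100")
  if (inherits(variants, "variant_table")) variants <- variants$sites
  need <- c("chrom", "start", "end", "mean_cov")
  if (!is.data.frame(coverage) || !all(need %in% names(coverage)))
    stop_bad("coverage must carry chrom, start, end, mean_cov")
  out <- lapply(unique(coverage$chrom), function(ch) {
    cov_ch <- coverage[coverage$chrom == ch, , drop = FALSE]
    L <- max(cov_ch$end)
    start <- seq.int(0L, L - 1L, by = window)
    end <- pmin(start + window, L)
    wi <- data.frame(chrom = ch, start = start, end = end,
                     stringsAsFactors = FALSE)
    pos <- variants$pos[variants$chrom == ch]
    idx <- pmin(floor((pos - 1) / window) + 1L, nrow(wi))
    wi$snp_count <- as.integer(tabulate(idx, nbins = nrow(wi)))
    # overlap-weighted coverage
    cov_acc <- numeric(nrow(wi)); len_acc <- numeric(nrow(wi))
    for (j in seq_len(nrow(cov_ch))) {
      w1 <- floor(cov_ch$start[j] / window) + 1L
      w2 <- min(floor((cov_ch$end[j] - 1L) / window) + 1L, nrow(wi))
      for (w in w1:w2) {
        ov <- min(cov_ch$end[j], wi$end[w]) - max(cov_ch$start[j], wi$start[w])
        if (ov > 0) {
          cov_acc[w] <- cov_acc[w] + ov * cov_ch$mean_cov[j]
          len_acc[w] <- len_acc[w] + ov
        }
      }
    }
    wi$mean_cov <- ifelse(len_acc > 0, cov_acc / len_acc, 0)
    wi
  })
  do.call(rbind, out)
}

#' Flag candidate introgression windows
#'
#' A window is flagged iff `snp_count <= max_snps` and
#' `mean_cov > min_coverage` (strict, the "more than 20x" rule).
#'
#' @param stats [window_stats()] output.
#' @param max_snps maximum SNP count (default 0, the zero-density rule).
#' @param min_coverage coverage threshold in x (exclusive).
#' @return the flagged subset of `stats`.
#' @export
flag_windows <- function(stats, max_snps = 0L, min_coverage = 20) {
  stats[stats$snp_count <= max_snps & stats$mean_cov > min_coverage, ,
        drop = FALSE]
}

#' Merge flagged windows into tracts
#'
#' Consecutive flagged windows (up to `max_gap_windows` unflagged windows
#' bridged) merge into one tract; tracts shorter than `min_tract` bp, or made
#' up solely of short terminal windows, are dropped.
#'
#' @param flagged flagged windows (sorted; as from [flag_windows()]).
#' @param window nominal window size in bp.
#' @param max_gap_windows unflagged windows allowed inside a tract.
#' @param min_tract minimum tract length in bp.
#' @return data.frame `chrom`, `start`, `end`, `length`, `n_windows`,
#'   `mean_cov`.
#' @export
merge_tracts <- function(flagged, window = 1000L, max_gap_windows = 0L,
                         min_tract = 2000L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_windows = integer(0), mean_cov = numeric(0))
  if (nrow(flagged) == 0L) return(empty)
  flagged <- flagged[order(flagged$chrom, flagged$start), , drop = FALSE]
  gap_bp <- (max_gap_windows + 1L) * window
  new_run <- c(TRUE, flagged$chrom[-1L] != flagged$chrom[-nrow(flagged)] |
                 flagged$start[-1L] - flagged$start[-nrow(flagged)] > gap_bp)
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(flagged, run), function(fw) {
    data.frame(chrom = fw$chrom[1L], start = min(fw$start), end = max(fw$end),
               length = max(fw$end) - min(fw$start),
               n_windows = nrow(fw), mean_cov = mean(fw$mean_cov),
               stringsAsFactors = FALSE)
  }))
  full <- vapply(split(flagged, run), function(fw)
    any(fw$end - fw$start == window), logical(1))
  out <- out[out$length >= min_tract & full, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for introgression tracts
#'
#' Deterministic composition of [window_stats()], [flag_windows()] and
#' [merge_tracts()].
#'
#' @inheritParams window_stats
#' @inheritParams flag_windows
#' @inheritParams merge_tracts
#' @return list with `tracts` and the per-window `windows` report.
#' @export
scan_introgressions <- function(variants, coverage, window = 1000L,
                                max_snps = 0L, min_coverage = 20,
                                max_gap_windows = 0L, min_tract = 2000L) {
  stats <- window_stats(variants, coverage, window)
  flagged <- flag_windows(stats, max_snps, min_coverage)
  tracts <- merge_tracts(flagged, window, max_gap_windows, min_tract)
  list(tracts = tracts, windows = stats)
}
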