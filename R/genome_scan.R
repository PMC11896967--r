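#' Sliding-window mean of a per-site statistic
#'
#' Windows are anchored at position 1 on each chromosome: window `k`
#' (k = 0, 1, ...) covers positions `k*step_bp + 1` to
#' `k*step_bp + window_bp` inclusive. Each window's score is the mean of
#' the chosen per-site statistic over the sites it contains; empty
#' windows are omitted. Averaging per window removes the dependence of
#' raw window sums on local variant density.
#'
#' @param site_stats table from [site_stats()] (needs `chrom`, `pos` and
#'   the `stat` column), sorted or not.
#' @param window_bp window size in bp (default 1 Mb).
#' @param step_bp step between window starts in bp (default 100 kb).
#' @param stat name of the statistic column to average (default `"ed"`).
#' @param chrom_lengths optional named vector bounding window starts.
#' @return `data.frame(chrom, start, end, n_sites, mean_stat)` with
#'   1-based inclusive `start`/`end`, sorted by chromosome then start.
#' @export
sliding_window_mean <- function(site_stats, window_bp = 1e6,
                                step_bp = 1e5, stat = "ed",
                                chrom_lengths = NULL) {
  if (!is.numeric(window_bp) || window_bp <= 0) stop("window_bp must be > 0")
  if (!is.numeric(step_bp) || step_bp <= 0) stop("step_bp must be > 0")
  if (!stat %in% names(site_stats)) stop("no column '", stat, "'")
  if (nrow(site_stats) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      mean_stat = numeric(0)))
  chroms <- unique(site_stats$chrom)
  out <- lapply(chroms, function(chr) {
    sub <- site_stats[site_stats$chrom == chr, , drop = FALSE]
    pos <- sub$pos
    val <- sub[[stat]]
    k_lo <- pmax(0, ceiling((pos - window_bp) / step_bp))
    k_hi <- floor((pos - 1) / step_bp)
    if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      k_hi <- pmin(k_hi, floor((chrom_lengths[[chr]] - 1) / step_bp))
    n_win <- k_hi - k_lo + 1
    ks <- unlist(mapply(seq, k_lo, k_hi, SIMPLIFY = FALSE))
    vals <- rep(val, n_win)
    sums <- rowsum(vals, ks)
    cnts <- rowsum(rep(1L, length(ks)), ks)
    k <- as.numeric(rownames(sums))
    data.frame(chrom = chr, start = k * step_bp + 1,
               end = k * step_bp + window_bp,
               n_sites = as.integer(cnts[, 1]),
               mean_stat = sums[, 1] / cnts[, 1])
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, chroms), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call candidate regions from window scores
#'
#' Thresholds window scores at an empirical quantile (linear
#' interpolation between order statistics, genome-wide by default) and
#' merges consecutive or overlapping above-threshold windows into maximal
#' regions.
#'
#' @param windows output of [sliding_window_mean()].
#' @param quantile quantile of `mean_stat` defining the threshold
#'   (default 0.99, i.e. the top 1 percent of windows).
#' @param per_chrom compute the threshold per chromosome instead of
#'   genome-wide.
#' @return `data.frame(chrom, start, end, n_windows, peak_pos, peak_stat,
#'   threshold)`, one row per merged region.
#' @export
call_candidate_regions <- function(windows, quantile = 0.99,
                                   per_chrom = FALSE) {
  if (is.null(windows) || nrow(windows) == 0L)
    stop("no nonempty windows to threshold")
  .check_num(quantile, "quantile", 0, 1)
  thr_of <- function(x) stats::quantile(x, quantile, names = FALSE, type = 7)
  windows$.thr <- if (per_chrom)
    stats::ave(windows$mean_stat, windows$chrom, FUN = thr_of)
  else thr_of(windows$mean_stat)
  sel <- windows[windows$mean_stat >= windows$.thr, , drop = FALSE]
  if (nrow(sel) == 0L) return(sel[, c("chrom", "start", "end")])
  out <- lapply(split(sel, sel$chrom), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    new_block <- c(TRUE, sub$start[-1] > cummax(sub$end[-nrow(sub)]) + 1)
    block <- cumsum(new_block)
    do.call(rbind, lapply(split(sub, block), function(b) {
      pk <- which.max(b$mean_stat)
      data.frame(chrom = b$chrom[1], start = min(b$start),
                 end = max(b$end), n_windows = nrow(b),
                 peak_pos = floor((b$start[pk] + b$end[pk]) / 2),
                 peak_stat = b$mean_stat[pk], threshold = b$.thr[1])
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, unique(windows$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate sites by closeness to the recessive ideal frequency
#'
#' Restricts to sites inside candidate regions (and, optionally, to
#' chosen functional region classes), sorts ascending by
#' `ed_ideal` (ties broken by position, then chromosome) and flags the
#' smallest `ceiling(top_fraction * n_eligible)` as selected.
#'
#' @param site_stats table with `ed_ideal` (and `region_class` when
#'   `region_classes` is used).
#' @param regions output of [call_candidate_regions()].
#' @param region_classes classes eligible for ranking (default exonic +
#'   promoter); `NULL` disables the class restriction.
#' @param top_fraction fraction of eligible sites selected (default 0.05).
#' @return eligible sites with added `rank` and `selected` columns,
#'   sorted by rank; zero rows (with a warning) when nothing is eligible.
#' @export
rank_candidate_sites <- function(site_stats, regions,
                                 region_classes = c("exonic", "promoter"),
                                 top_fraction = 0.05) {
  if (!"ed_ideal" %in% names(site_stats))
    stop("site_stats lacks 'ed_ideal'; run site_stats() first")
  .check_num(top_fraction, "top_fraction", 0, 1)
  in_region <- rep(FALSE, nrow(site_stats))
  for (i in seq_len(nrow(regions))) {
    in_region <- in_region |
      (site_stats$chrom == regions$chrom[i] &
       site_stats$pos >= regions$start[i] &
       site_stats$pos <= regions$end[i])
  }
  eligible <- in_region
  if (!is.null(region_classes)) {
    if (!"region_class" %in% names(site_stats))
      stop("region_classes given but site_stats lacks 'region_class'")
    eligible <- eligible & site_stats$region_class %in% region_classes
  }
  out <- site_stats[eligible, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no eligible candidate sites")
    out$rank <- integer(0); out$selected <- logical(0)
    return(out)
  }
  o <- order(out$ed_ideal, out$pos, out$chrom)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= ceiling(top_fraction * nrow(out))
  rownames(out) <- NULL
  out
}

#' Export windows or regions as BED
#'
#' BED uses 0-based half-open coordinates; the package's 1-based
#' inclusive `start`/`end` convert as `start - 1`, `end`.
#'
#' @param x a windows or regions table with `chrom`, `start`, `end` and
#'   optionally `mean_stat`/`peak_stat` (written as the score column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  score <- x$mean_stat %||% x$peak_stat %||% rep(0, nrow(x))
  df <- data.frame(x$chrom, format(x$start - 1, scientific = FALSE,
                                   trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   ".", signif(score, 6))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
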