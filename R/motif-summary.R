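#' Summarise motif hits per interval
#'
#' For each grid interval (typically the 10-kb census windows) reports, per
#' motif class: the number of motifs whose leftmost base falls in the
#' interval (a boundary-spanning motif is counted once), the union of motif
#' footprints clipped to the interval (a boundary-spanning motif contributes
#' clipped bases to both sides), the longest motif span among the counted
#' motifs, plus the union across all classes (`composite_bases`) and a
#' `pause` flag set when the interval overlaps any pause annotation.
#'
#' @param hits Motif-hit data frame (e.g. from [scan_all()]).
#' @param grid Interval data frame (e.g. [tile_regions()] at 10 kb).
#' @param pause_labels Optional `genomic_interval` of pause sites.
#' @return Data frame, one row per grid interval, with `count_<class>`,
#'   `bases_<class>`, `longest_<class>`, `composite_bases`, `pause`.
#' @export
summarize_by_interval <- function(hits, grid, pause_labels = NULL) {
  classes <- .motif_classes
  n <- nrow(grid)
  out <- as.data.frame(grid)
  for (cl in classes) {
    out[[paste0("count_", cl)]] <- 0L
    out[[paste0("bases_", cl)]] <- 0L
    out[[paste0("longest_", cl)]] <- 0L
  }
  out$composite_bases <- 0L
  for (i in seq_len(n)) {
    w <- grid[i, ]
    on_chrom <- hits[hits$chrom == w$chrom, , drop = FALSE]
    # clipped overlaps for base footprints
    ov <- on_chrom[on_chrom$start < w$end & on_chrom$end > w$start, ,
                   drop = FALSE]
    if (nrow(ov) > 0L) {
      cs <- pmax(ov$start, w$start)
      ce <- pmin(ov$end, w$end)
      all_r <- IRanges::IRanges(start = cs + 1L, end = ce)
      out$composite_bases[i] <- sum(IRanges::width(IRanges::reduce(all_r)))
      for (cl in unique(ov$motif_class)) {
        sel <- ov$motif_class == cl
        out[[paste0("bases_", cl)]][i] <-
          sum(IRanges::width(IRanges::reduce(all_r[sel])))
      }
    }
    # counts/longest by leftmost-base assignment
    inw <- on_chrom[on_chrom$start >= w$start & on_chrom$start < w$end, ,
                    drop = FALSE]
    if (nrow(inw) > 0L) {
      for (cl in unique(inw$motif_class)) {
        sel <- inw$motif_class == cl
        out[[paste0("count_", cl)]][i] <- sum(sel)
        out[[paste0("longest_", cl)]][i] <-
          max(inw$end[sel] - inw$start[sel])
      }
    }
  }
  out$pause <- .overlaps_any(grid, pause_labels)
  out
}

#' Flag intervals enriched above mean + k standard deviations
#'
#' The reference-line rule of the per-interval bar plots: an interval is
#' flagged when its metric strictly exceeds `mean + k * SD`, where mean and
#' population SD are computed over all intervals of the same segment
#' (chrom).
#'
#' @param summaries Output of [summarize_by_interval()] (or any interval
#'   data frame).
#' @param field Name of the metric column (e.g. `"count_inverted_repeat"`).
#' @param k SD multiplier; the plots' reference line uses 3.
#' @return `summaries` columns `chrom`, `start`, `end`, the metric, plus
#'   `threshold` and logical `flagged`.
#' @export
flag_enriched <- function(summaries, field, k = 3) {
  if (!field %in% names(summaries)) stop("no such metric column: ", field)
  x <- summaries[[field]]
  out <- summaries[, c("chrom", "start", "end", field)]
  out$threshold <- NA_real_
  out$flagged <- NA
  for (ch in unique(summaries$chrom)) {
    idx <- which(summaries$chrom == ch)
    if (length(idx) < 2L)
      stop("flag_enriched needs >= 2 intervals per segment (", ch, ")")
    mu <- mean(x[idx])
    sdpop <- sqrt(mean((x[idx] - mu)^2))
    thr <- mu + k * sdpop
    out$threshold[idx] <- thr
    out$flagged[idx] <- x[idx] > thr
  }
  out
}
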