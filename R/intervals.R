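#' Construct genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optional `label`, in 0-based half-open coordinates. This constructor
#' validates the invariants (`0 <= start < end`).
#'
#' @param chrom Character vector of sequence identifiers.
#' @param start,end Integer vectors; 0-based half-open.
#' @param label Optional character vector of free-text labels (e.g. "P1").
#' @return A data frame with class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 0, 10000, "P1")
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Tile a region into fixed-width windows
#'
#' Produces the window grid used throughout the pipeline: 10-kb intervals for
#' the motif census (the resolution of the pause-site annotations) and
#' 500-base intervals for folding, composition, and SNP statistics. A
#' trailing remainder shorter than `width` is dropped, so with `step ==
#' width` a region of length `L` yields `floor(L / width)` disjoint windows.
#'
#' @param region A one-row `genomic_interval` (or list with `chrom`, `start`,
#'   `end`).
#' @param width Window width in bases (>= 1).
#' @param step Step between window starts; defaults to `width` (disjoint
#'   tiling).
#' @return A `window_grid`: a `genomic_interval` data frame of windows with
#'   attributes `parent`, `width`, `step`. Window labels are `w1`, `w2`, ...
#'   May contain zero rows when `width` exceeds the region length.
#' @examples
#' tile_windows(genomic_interval("chr1", 0, 10000), 500)
#' @export
tile_windows <- function(region, width, step = width) {
  if (width < 1 || step < 1) stop("width and step must be >= 1")
  chrom <- as.character(region$chrom[1])
  lo <- as.numeric(region$start[1])
  hi <- as.numeric(region$end[1])
  starts <- seq(lo, hi, by = step)
  starts <- starts[starts + width <= hi]
  if (length(starts) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = chrom, start = starts, end = starts + width,
                      label = paste0("w", seq_along(starts)),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("window_grid", "genomic_interval", "data.frame")
  attr(out, "parent") <- c(chrom = chrom, start = lo, end = hi)
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

#' Tile several regions at once
#'
#' Convenience wrapper applying [tile_windows()] to each row of an interval
#' data frame (or to every sequence of a genome) and row-binding the result.
#'
#' @param regions A `genomic_interval` data frame, or a named character
#'   vector of sequences (each tiled over its full length).
#' @inheritParams tile_windows
#' @return A `window_grid` data frame (attributes `width`, `step`).
#' @export
tile_regions <- function(regions, width, step = width) {
  if (is.character(regions)) {
    regions <- data.frame(chrom = names(regions), start = 0,
                          end = nchar(regions), stringsAsFactors = FALSE)
  }
  parts <- lapply(seq_len(nrow(regions)), function(i)
    tile_windows(regions[i, , drop = FALSE], width, step))
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), label = character())
  class(out) <- c("window_grid", "genomic_interval", "data.frame")
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

# Overlap indicator: does interval row i of x overlap any interval in y
# (same chrom, half-open overlap)?
.overlaps_any <- function(x, y) {
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
}
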