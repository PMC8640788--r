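#' Classify a substitution into the six pyrimidine-collapsed classes
#'
#' Purine-reference substitutions are complemented onto the pyrimidine
#' strand (A>G becomes T>C, G>A becomes C>T, ...), so the twelve ordered
#' ref/alt pairs collapse two-to-one onto `C>A, C>G, C>T, T>A, T>C, T>G`.
#' `T>C` and `T>G` aggregate to T>(C+G) (TA-to-CG changes); `C>A` and `C>T`
#' aggregate to C>(A+T) (CG-to-TA changes).
#'
#' @param ref,alt Single bases in `{A, C, G, T}` (vectorised); `ref != alt`.
#' @return Character vector of classes.
#' @examples
#' classify_snp("G", "A") # "C>T"
#' @export
classify_snp <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ambiguous or invalid base in ref/alt")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  ref[flip] <- .complement_map[ref[flip]]
  alt[flip] <- .complement_map[alt[flip]]
  paste0(ref, ">", alt)
}

.spectrum_counts <- function(classes) {
  counts <- table(factor(classes, levels = .classes6))
  setNames(as.integer(counts), .classes6)
}

#' Per-window SNP density and spectrum
#'
#' Assigns each biallelic SNV to the unique grid window containing its base
#' (VCF positions are converted to 0-based on the fly); SNVs falling in no
#' window (dropped remainders) are discarded with a logged count. Windows
#' inherit the pause label of their parent pause interval.
#'
#' @param snps Data frame from [read_snvs()] (`pos` 1-based).
#' @param grid A `window_grid` of analysis windows.
#' @param pause_labels Optional `genomic_interval` of pause sites.
#' @return Data frame, one row per window: `n_snps`, `n_per_10kb` (count
#'   normalised to 10 kb), the six class counts (`C.A` ... `T.G` columns),
#'   `t_to_cg`, `c_to_at`, `pause`. Attribute `dropped` counts discarded
#'   SNVs.
#' @export
window_variation <- function(snps, grid, pause_labels = NULL) {
  n <- nrow(grid)
  cls_cols <- gsub(">", ".", .classes6, fixed = TRUE)
  out <- as.data.frame(grid)
  out$n_snps <- 0L
  for (cc in cls_cols) out[[cc]] <- 0L
  pos0 <- snps$pos - 1
  unknown <- !(snps$chrom %in% grid$chrom)
  if (any(unknown))
    stop("SNV record on unknown sequence: ", snps$chrom[unknown][1], ":",
         snps$pos[unknown][1])
  widx <- rep(NA_integer_, nrow(snps))
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    si <- which(snps$chrom == ch)
    if (length(si) == 0L) next
    # windows are disjoint: locate by start
    o <- findInterval(pos0[si], grid$start[gi])
    hit <- o > 0 & pos0[si] < grid$end[gi][pmax(o, 1L)]
    widx[si[hit]] <- gi[o[hit]]
  }
  dropped <- sum(is.na(widx))
  if (dropped > 0L)
    message("window_variation: ", dropped,
            " SNV(s) outside the window grid were discarded")
  keep <- !is.na(widx)
  if (any(keep)) {
    classes <- classify_snp(snps$ref[keep], snps$alt[keep])
    tab <- table(factor(widx[keep], levels = seq_len(n)),
                 factor(classes, levels = .classes6))
    out$n_snps <- as.integer(rowSums(tab))
    for (j in seq_along(.classes6))
      out[[cls_cols[j]]] <- as.integer(tab[, j])
  }
  out$t_to_cg <- out$T.C + out$T.G
  out$c_to_at <- out$C.A + out$C.T
  out$n_per_10kb <- out$n_snps * 10000 / (out$end - out$start)
  out$pause <- .overlaps_any(grid, pause_labels)
  attr(out, "dropped") <- dropped
  out
}

#' Mann-Whitney comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact enumeration when
#' both groups have at most 20 observations and no ties, the tie-corrected
#' normal approximation otherwise. Two identical constant groups give p = 1.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param names Group names for the output.
#' @return List of class `comparison_result`: `groups`, `n`, `median`,
#'   `mean`, `statistic` (U for the first group), `p_value`, `method`.
#' @export
compare_groups <- function(a, b, names = c("a", "b")) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 20L && length(b) <= 20L
  if (stats::sd(c(a, b)) == 0) {
    w <- list(statistic = c(W = length(a) * length(b) / 2), p.value = 1)
    method <- "degenerate (all values tied)"
  } else {
    w <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = !exact))
    method <- if (exact) "exact" else "normal approximation, tie-corrected"
  }
  structure(list(groups = names,
                 n = c(length(a), length(b)),
                 median = c(stats::median(a), stats::median(b)),
                 mean = c(mean(a), mean(b)),
                 statistic = unname(w$statistic),
                 p_value = w$p.value,
                 method = method),
            class = "comparison_result")
}

#' Quantile-bin windows by folding energy
#'
#' Orders windows by increasing delta-G, splits them into `n_bins`
#' equal-count bins (sizes differing by at most one; ties broken by window
#' order), and reports per bin the mean delta-G, the mean normalised SNP
#' count, and the within-bin correlation between SNP count and delta-G.
#'
#' @param folds Output of [fold_windows()].
#' @param variation Output of [window_variation()] on the identical grid.
#' @param n_bins Number of bins (the genome-wide analysis uses 100).
#' @param method Correlation flavour: `"pearson"` (default) or
#'   `"spearman"`.
#' @return Data frame: `bin`, `n`, `mean_delta_g`, `mean_snps_per_10kb`,
#'   `r`, `p_value`.
#' @export
bin_by_energy <- function(folds, variation, n_bins = 100,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  key <- function(d) paste(d$chrom, d$start, d$end)
  m <- match(key(folds), key(variation))
  if (anyNA(m))
    stop("folds and variation must be aligned on identical windows")
  n <- nrow(folds)
  if (n < n_bins)
    stop("only ", n, " windows for ", n_bins,
         " bins; use a smaller n_bins")
  dg <- folds$delta_g
  snp <- variation$n_per_10kb[m]
  ord <- order(dg)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_of <- rep(seq_len(n_bins), times = sizes)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- ord[bin_of == b]
    r <- p <- NA_real_
    if (length(idx) >= 3L && stats::sd(dg[idx]) > 0 &&
        stats::sd(snp[idx]) > 0) {
      ct <- suppressWarnings(stats::cor.test(snp[idx], dg[idx],
                                             method = method))
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    data.frame(bin = b, n = length(idx), mean_delta_g = mean(dg[idx]),
               mean_snps_per_10kb = mean(snp[idx]), r = r, p_value = p)
  }))
  rownames(out) <- NULL
  attr(out, "bin_assignment") <- data.frame(
    chrom = folds$chrom[ord], start = folds$start[ord],
    end = folds$end[ord], bin = bin_of)
  out
}

#' Sample random fixed-width windows from a genome
#'
#' Uniform sampling (with replacement) over every valid start position on
#' every sequence, excluding windows with more than `max_n_frac` ambiguous
#' bases. Reproducible for a fixed seed.
#'
#' @param genome Named character vector of sequences.
#' @param n Number of windows (the randomisation null uses 1,000).
#' @param width Window width in bases (default 10 kb).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param max_n_frac Maximum tolerated `N` fraction per window.
#' @return A `genomic_interval` data frame of `n` windows.
#' @export
random_windows <- function(genome, n = 1000, width = 10000, seed = NULL,
                           max_n_frac = 0.1) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lens <- nchar(genome)
  nstarts <- pmax(lens - width + 1, 0)
  if (sum(nstarts) == 0) stop("no sequence long enough for width ", width)
  # prefix counts of N for O(1) window N-fraction checks
  ncum <- lapply(genome, function(s)
    c(0, cumsum(strsplit(s, "", fixed = TRUE)[[1]] == "N")))
  picks <- data.frame(chrom = character(n), start = numeric(n))
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 50L * n + 100L)
      stop("could not find enough windows passing the N policy")
    u <- sample.int(sum(nstarts), 1L)
    ci <- findInterval(u - 1, cumsum(nstarts), left.open = FALSE) + 1L
    offset <- u - c(0, cumsum(nstarts))[ci] - 1L
    chrom <- names(genome)[ci]
    nc <- ncum[[ci]]
    nfrac <- (nc[offset + width + 1] - nc[offset + 1]) / width
    if (nfrac > max_n_frac) next
    got <- got + 1L
    picks$chrom[got] <- chrom
    picks$start[got] <- offset
  }
  genomic_interval(picks$chrom, picks$start, picks$start + width,
                   label = paste0("rand", seq_len(n)))
}

#' Count the analysis windows tiling the distinct pause intervals
#'
#' Identical pause intervals (a site detected in two cell types mapping to
#' one 10-kb interval) collapse to one before tiling, so fifteen distinct
#' 10-kb intervals yield 300 500-base windows.
#'
#' @param pause_intervals `genomic_interval` of pause annotations.
#' @param width Analysis window width (default 500).
#' @return Integer window count.
#' @export
pause_window_count <- function(pause_intervals, width = 500) {
  if (is.null(pause_intervals) || nrow(pause_intervals) == 0L) return(0L)
  d <- unique(pause_intervals[, c("chrom", "start", "end")])
  sum((d$end - d$start) %/% width)
}

#' Mutational-spectrum report per window group
#'
#' Aggregates the six-class spectrum over groups of windows (by default the
#' pause/nonpause split), reporting counts, rates normalised to 10 kb, the
#' T>(C+G) and C>(A+T) aggregates, and between-group rate ratios.
#'
#' @param variation Output of [window_variation()].
#' @param grouping Factor/character vector over windows; defaults to
#'   `variation$pause` rendered as `"pause"`/`"nonpause"`.
#' @return List of class `spectrum_report`: `counts` (per-group data frame
#'   with totals and per-10-kb rates) and `ratios` (pairwise rate ratios
#'   between the first two groups, when two or more groups exist).
#' @export
spectrum_report <- function(variation, grouping = NULL) {
  if (is.null(grouping))
    grouping <- ifelse(variation$pause, "pause", "nonpause")
  if (length(grouping) != nrow(variation))
    stop("grouping must label every window")
  cls_cols <- gsub(">", ".", .classes6, fixed = TRUE)
  groups <- unique(grouping)
  counts <- do.call(rbind, lapply(groups, function(g) {
    idx <- grouping == g
    bases <- sum(variation$end[idx] - variation$start[idx])
    cnt <- vapply(cls_cols, function(cc) sum(variation[[cc]][idx]),
                  numeric(1))
    row <- data.frame(group = g, n_windows = sum(idx), bases = bases,
                      t(cnt), total = sum(cnt),
                      t_to_cg = cnt[["T.C"]] + cnt[["T.G"]],
                      c_to_at = cnt[["C.A"]] + cnt[["C.T"]])
    for (cc in c(cls_cols, "total", "t_to_cg", "c_to_at"))
      row[[paste0("rate10kb_", cc)]] <- row[[cc]] * 10000 / bases
    row
  }))
  rownames(counts) <- NULL
  ratios <- NULL
  if (length(groups) >= 2L) {
    r1 <- counts[1, ]
    r2 <- counts[2, ]
    rate_cols <- grep("^rate10kb_", names(counts), value = TRUE)
    ratios <- setNames(as.numeric(r1[rate_cols]) / as.numeric(r2[rate_cols]),
                       sub("^rate10kb_", "", rate_cols))
    names(ratios) <- paste0(names(ratios), " (", r1$group, "/", r2$group, ")")
  }
  structure(list(counts = counts, ratios = ratios),
            class = "spectrum_report")
}
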