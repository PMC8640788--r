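#' Reverse-complement a nucleotide string
#'
#' Alphabet `{A, C, G, T, N}`; `N` maps to `N`. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq Nucleotide string (character scalar or vector).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Base composition and TT-dinucleotide density per window
#'
#' For each window the GC fraction is computed over unambiguous bases only
#' (`gc = (#G + #C) / (len - #N)`); `tt_count` counts overlapping `TT`
#' dinucleotides on the plus strand (minus-strand `AA` is not added; set
#' `symmetric = TRUE` to count both). An all-`N` window gets `gc_fraction
#' NA`.
#'
#' @param seq Nucleotide string the windows refer to (one sequence), or a
#'   named vector of sequences covering every chrom in `windows`.
#' @param windows A `genomic_interval` data frame of windows resolvable
#'   against `seq`.
#' @param symmetric Count `AA` (the minus-strand `TT`) as well. Default
#'   `FALSE`, recorded in the `tt_strand` attribute.
#' @return Data frame: window columns plus `gc_fraction`, `tt_count`,
#'   `n_count`.
#' @export
window_composition <- function(seq, windows, symmetric = FALSE) {
  if (is.null(names(seq)) && length(seq) == 1L)
    names(seq) <- unique(windows$chrom)[1]
  missing <- setdiff(unique(windows$chrom), names(seq))
  if (length(missing) > 0L)
    stop("windows refer to unknown sequence: ", missing[1])
  res <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(idx) {
    chrom <- windows$chrom[idx[1]]
    s <- Biostrings::DNAString(seq[[chrom]])
    w <- windows[idx, , drop = FALSE]
    if (any(w$end > length(s)))
      stop("window extends past end of sequence ", chrom)
    v <- Biostrings::Views(s, start = w$start + 1L, end = w$end)
    lf <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    tt <- Biostrings::vcountPattern("TT", v)
    if (symmetric) tt <- tt + Biostrings::vcountPattern("AA", v)
    len <- w$end - w$start
    denom <- len - lf[, "N"]
    gc <- ifelse(denom > 0, (lf[, "G"] + lf[, "C"]) / denom, NA_real_)
    cbind(w, data.frame(gc_fraction = gc, tt_count = tt,
                        n_count = lf[, "N"], row.names = NULL))
  })
  ord <- unlist(split(seq_len(nrow(windows)), windows$chrom),
                use.names = FALSE)
  out <- do.call(rbind, res)[order(ord), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tt_strand") <- if (symmetric) "both" else "plus"
  out
}

# fraction of N in each window; used by the >10% N exclusion policy
.n_fraction <- function(seq, windows) {
  comp <- window_composition(seq, windows)
  comp$n_count / (comp$end - comp$start)
}
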