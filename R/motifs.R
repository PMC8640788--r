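# Non-B DNA motif scanners. Each scanner returns a motif-hit data frame:
# chrom, start, end (0-based half-open span), motif_class, arm_len,
# spacer_len, unit, copies, strand, footprint. Hits are maximal, perfect
# (0 mismatches), and reported in deterministic coordinate order.

.empty_hits <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             motif_class = character(), arm_len = integer(),
             spacer_len = integer(), unit = character(), copies = integer(),
             strand = character(), footprint = numeric(),
             stringsAsFactors = FALSE)
}

.hits_df <- function(chrom, start, end, motif_class, arm_len = 0L,
                     spacer_len = 0L, unit = NA_character_, copies = NA_integer_,
                     strand = "+") {
  if (length(start) == 0L) return(.empty_hits())
  out <- data.frame(chrom = chrom, start = start, end = end,
                    motif_class = motif_class, arm_len = as.integer(arm_len),
                    spacer_len = as.integer(spacer_len), unit = unit,
                    copies = as.integer(copies), strand = strand,
                    footprint = end - start, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find maximal perfect inverted repeats (cruciform motifs)
#'
#' An inverted repeat is an arm, a spacer (the prospective cruciform loop),
#' and the arm's reverse complement. Hits are maximal: the arms can be
#' extended neither outward nor inward (a hit whose spacer ends still pair
#' is subsumed by the longer-armed hit). `N` never pairs.
#'
#' @param seq Nucleotide string.
#' @param cfg A [motif_config()]; uses `ir_min_arm`, `ir_spacer_min`,
#'   `ir_spacer_max`.
#' @param chrom Sequence name for the output.
#' @return Motif-hit data frame (`motif_class = "inverted_repeat"`).
#' @export
find_inverted_repeats <- function(seq, cfg = motif_config(), chrom = "seq") {
  h <- .find_ir_cpp(.encode_seq(seq), cfg$ir_min_arm,
                    cfg$ir_spacer_min, cfg$ir_spacer_max)
  .hits_df(chrom, h$start, h$end, "inverted_repeat",
           arm_len = h$arm_len, spacer_len = h$spacer_len)
}

#' Find mirror-symmetric homopurine/homopyrimidine (triplex) motifs
#'
#' A triplex (H-DNA) motif is a tract whose two arms read identically
#' forward and backward around a short central spacer, with every arm base
#' purine or every arm base pyrimidine; the spacer's composition is
#' unconstrained. Hits are maximal by arm extension, and hits whose span is
#' contained in a longer hit's span are collapsed onto the outermost hit
#' (a perfect repeat such as fifteen TTCTT units is mirror-symmetric about
#' every unit junction; only the full-tract hit is reported).
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame (`motif_class = "mirror_triplex"`) with an
#'   extra `arm_class` column (`"purine"`/`"pyrimidine"`). `end - start` is
#'   the tract length.
#' @export
find_mirror_triplex <- function(seq, cfg = motif_config(), chrom = "seq") {
  h <- .find_mirror_cpp(.encode_seq(seq), cfg$mr_min_arm,
                        cfg$mr_spacer_min, cfg$mr_spacer_max,
                        cfg$mr_min_tract)
  if (nrow(h) == 0L) {
    out <- .empty_hits()
    out$arm_class <- character(0)
    return(out)
  }
  # containment collapse: keep outermost spans; for identical spans keep the
  # largest arm, then the smallest spacer (stable sort preserves this order)
  h <- h[order(h$start, -h$end, -h$arm_len, h$spacer_len), , drop = FALSE]
  h <- .containment_collapse(h)
  out <- .hits_df(chrom, h$start, h$end, "mirror_triplex",
                  arm_len = h$arm_len, spacer_len = h$spacer_len)
  out$arm_class <- ifelse(h$arm_class[order(h$start, h$end)] == 0,
                          "purine", "pyrimidine")
  out
}

# drop rows whose [start, end) span is strictly contained in another row's
# span (rows must carry start/end; ties on identical spans keep the first)
.containment_collapse <- function(d) {
  d <- d[order(d$start, -d$end), , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  maxend <- -Inf
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (d$end[i] > maxend) {
      keep[i] <- TRUE
      maxend <- d$end[i]
    }
  }
  d[keep, , drop = FALSE]
}

# shared maximal-run machinery for tandem/direct repeats
.tandem_runs <- function(seq, unit_min, unit_max, min_copies) {
  runs <- .find_tandem_cpp(.encode_seq(seq), unit_max)
  if (nrow(runs) == 0L) return(runs[0, ])
  # collapse identical spans found at several periods to the primitive one
  runs <- runs[order(runs$start, runs$end, runs$period), , drop = FALSE]
  runs <- runs[!duplicated(runs[, c("start", "end")]), , drop = FALSE]
  len <- runs$end - runs$start
  copies <- len %/% runs$period
  keep <- runs$period >= unit_min & copies >= min_copies
  runs <- cbind(runs[keep, , drop = FALSE], copies = copies[keep])
  # a qualifying run nested inside a longer qualifying run (e.g. the T runs
  # inside a TTCTT tract) is reported once, as the outermost run
  .containment_collapse(runs)
}

# lexicographically least rotation of a string
.least_rotation <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  rots <- vapply(seq_len(n) - 1L, function(k)
    paste0(substr(x, k + 1L, n), substr(x, 1L, k)), character(1))
  min(rots)
}

#' Find maximal tandem repeats (slipped-strand motifs)
#'
#' Maximal runs of a repeat unit (default unit length 1-20) repeated at
#' least `tr_min_copies` times; a trailing partial copy is part of the span
#' but not of `copies`. The reported unit is the lexicographically least
#' rotation of the primitive period, and rotated re-descriptions of the same
#' run are collapsed to one hit.
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame (`motif_class = "tandem_repeat"`).
#' @export
find_tandem_repeats <- function(seq, cfg = motif_config(), chrom = "seq") {
  runs <- .tandem_runs(seq, cfg$tr_unit_min, cfg$tr_unit_max,
                       cfg$tr_min_copies)
  if (nrow(runs) == 0L) return(.empty_hits())
  unit <- vapply(seq_len(nrow(runs)), function(i)
    .least_rotation(substr(seq, runs$start[i] + 1L,
                           runs$start[i] + runs$period[i])),
    character(1))
  .hits_df(chrom, runs$start, runs$end, "tandem_repeat",
           unit = unit, copies = runs$copies)
}

#' Find direct repeats (long-unit duplications)
#'
#' The tandem detector restricted to long units (default >= 10 bases) where
#' two copies already qualify. A long-unit run with three or more copies
#' also appears in [find_tandem_repeats()] output when its unit length
#' overlaps that range; the two classes are reported separately and never
#' silently merged.
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame (`motif_class = "direct_repeat"`).
#' @export
find_direct_repeats <- function(seq, cfg = motif_config(), chrom = "seq") {
  runs <- .tandem_runs(seq, cfg$dr_unit_min, cfg$dr_unit_max,
                       cfg$dr_min_copies)
  if (nrow(runs) == 0L) return(.empty_hits())
  unit <- vapply(seq_len(nrow(runs)), function(i)
    .least_rotation(substr(seq, runs$start[i] + 1L,
                           runs$start[i] + runs$period[i])),
    character(1))
  .hits_df(chrom, runs$start, runs$end, "direct_repeat",
           unit = unit, copies = runs$copies)
}

#' Find Z-DNA-favouring alternating purine-pyrimidine tracts
#'
#' Maximal tracts of length >= `z_min_tract` in which every dinucleotide
#' step belongs to the allowed set `{GC, CG, GT, TG, AC, CA}` (`AT`/`TA`
#' steps excluded by default; include them with `z_allow_at = TRUE`).
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame (`motif_class = "zdna"`).
#' @export
find_zdna <- function(seq, cfg = motif_config(), chrom = "seq") {
  n <- nchar(seq)
  if (n < cfg$z_min_tract) return(.empty_hits())
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  steps <- paste0(x[-n], x[-1])
  allowed <- c("GC", "CG", "GT", "TG", "AC", "CA")
  if (isTRUE(cfg$z_allow_at)) allowed <- c(allowed, "AT", "TA")
  ok <- steps %in% allowed
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & (r$lengths + 1L) >= cfg$z_min_tract)
  .hits_df(chrom, starts[sel] - 1L, ends[sel] + 1L, "zdna")
}

# chain runs (two-column start/end matrix, sorted) with gaps in
# [gap_min, gap_max]; returns groups of >= min_runs as span start/end
.chain_runs <- function(rs, re, gap_min, gap_max, min_runs) {
  if (length(rs) == 0L) return(NULL)
  gap <- rs[-1] - re[-length(re)]
  brk <- c(TRUE, !(gap >= gap_min & gap <= gap_max))
  grp <- cumsum(brk)
  sizes <- tabulate(grp)
  keep <- which(sizes >= min_runs)
  if (length(keep) == 0L) return(NULL)
  last <- length(grp) + 1L - match(keep, rev(grp))
  data.frame(start = rs[match(keep, grp)], end = re[last])
}

#' Find G-quadruplex motifs
#'
#' Four or more runs of three-plus guanines separated by 1-7 nt spacers, on
#' both strands: minus-strand hits (runs of C on the plus strand) are
#' reported with `strand = "-"` in plus-strand coordinates. Hits are maximal
#' chains of qualifying G-runs.
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame (`motif_class = "g4"`).
#' @export
find_g4 <- function(seq, cfg = motif_config(), chrom = "seq") {
  seq <- toupper(seq)
  one_strand <- function(base) {
    m <- gregexpr(paste0(base, "{", cfg$g4_min_run, ",}"), seq)[[1]]
    if (m[1] == -1L) return(NULL)
    rs <- as.integer(m) - 1L
    re <- rs + attr(m, "match.length")
    .chain_runs(rs, re, cfg$g4_spacer_min, cfg$g4_spacer_max,
                cfg$g4_min_runs)
  }
  plus <- one_strand("G")
  minus <- one_strand("C")
  out <- rbind(
    if (!is.null(plus))
      .hits_df(chrom, plus$start, plus$end, "g4", strand = "+"),
    if (!is.null(minus))
      .hits_df(chrom, minus$start, minus$end, "g4", strand = "-"))
  if (is.null(out)) return(.empty_hits())
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AT-cruciform census
#'
#' [find_inverted_repeats()] under the `at_cruciform_census` preset (arm >=
#' 12 bp, loop 0-7 bases, perfect arms), with each hit flagged `pure_at`
#' when its footprint contains only A and T — the palindromic `[AT]n`
#' repeats implicated in chromosome fragility.
#'
#' Unlike the raw scanner, the census collapses hits strictly contained in a
#' longer hit's span (a pure `[AT]n` tract carries phase-shifted nested
#' maximal repeats; the census counts the locus once).
#'
#' @inheritParams find_inverted_repeats
#' @return Motif-hit data frame with logical column `pure_at`.
#' @export
find_at_cruciforms <- function(seq, chrom = "seq") {
  cfg <- motif_config("at_cruciform_census")
  hits <- find_inverted_repeats(seq, cfg, chrom)
  hits <- hits[order(hits$start, -hits$end, -hits$arm_len,
                     hits$spacer_len), , drop = FALSE]
  hits <- .containment_collapse(hits)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits$pure_at <- vapply(seq_len(nrow(hits)), function(i) {
    sub <- substr(seq, hits$start[i] + 1L, hits$end[i])
    grepl("^[ATat]*$", sub)
  }, logical(1))
  hits
}

#' Scan one sequence for all motif classes
#'
#' Runs the inverted-repeat, direct-repeat, tandem-repeat, mirror/triplex,
#' Z-DNA, and G4 scanners and returns the coordinate-sorted concatenation.
#'
#' @param seq Nucleotide string, or a named vector of sequences (each
#'   scanned under its own name).
#' @param cfg A [motif_config()].
#' @param chrom Sequence name when `seq` is a single unnamed string.
#' @return Motif-hit data frame; the `motif_config` used is attached as
#'   attribute `config`.
#' @export
scan_all <- function(seq, cfg = motif_config(), chrom = "seq") {
  if (length(seq) > 1L || !is.null(names(seq))) {
    nm <- names(seq)
    out <- do.call(rbind, lapply(seq_along(seq), function(i)
      scan_all(unname(seq[[i]]), cfg, chrom = nm[i])))
    attr(out, "config") <- cfg
    return(out)
  }
  parts <- list(
    find_inverted_repeats(seq, cfg, chrom),
    find_direct_repeats(seq, cfg, chrom),
    find_tandem_repeats(seq, cfg, chrom),
    find_mirror_triplex(seq, cfg, chrom)[, names(.empty_hits())],
    find_zdna(seq, cfg, chrom),
    find_g4(seq, cfg, chrom))
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$end, out$motif_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}
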