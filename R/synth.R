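# Synthetic study bundle: a multi-segment mini-genome emulating a set of
# fragile-site restriction segments, with planted non-B motifs, designated
# pause intervals (reduced GC, elevated TT), and simulated SNPs whose
# density and T>(C+G) fraction are boosted at pause windows by known
# multipliers. Every random draw goes through R's RNG under the caller's
# seed, so bundles are reproducible bit-for-bit.

#' Specification of a synthetic study bundle
#'
#' Defaults emulate the six restriction segments of the fragile-site study
#' design: printed lengths 280, 305, 231, 213, 199, 296 kb; fifteen distinct
#' pause-containing 10-kb intervals; AT-rich background (GC 0.42) with
#' pause intervals at GC 0.36 and a 1.5x T-after-T transition boost; SNPs at
#' 30 per 10 kb with a 1.3x density multiplier and a 1.5x T>(C+G) rate boost
#' at pause windows.
#'
#' @param segments Named integer vector of segment lengths (bases).
#' @param gc_background,gc_pause Background GC fractions outside/inside
#'   pause intervals.
#' @param tt_boost Multiplier on the T-to-T transition probability inside
#'   pause intervals (first-order chain; elevates TT-dinucleotide density).
#' @param n_pause Number of distinct pause intervals.
#' @param pause_width Pause interval width (bases).
#' @param rate_per_10kb Baseline SNP rate per 10 kb.
#' @param pause_multiplier Multiplier on the per-window SNP rate (all
#'   classes) at pause windows.
#' @param spectrum Named baseline probabilities of the six collapsed classes
#'   (must sum to 1).
#' @param tcg_boost Multiplier on the absolute T>C and T>G rates at pause
#'   windows (other class rates unchanged).
#' @param gc_slope Linear GC modifier on SNP rate:
#'   `1 + gc_slope * (gc - gc_background)`. Default 0 keeps the rate
#'   composition-independent so planted multipliers stay directly
#'   identifiable.
#' @param snp_window SNP-simulation window width (bases).
#' @param plants List of motif plants; see [default_plants()].
#' @param markov_background Use a first-order background chain outside pause
#'   intervals too (default: i.i.d. bases).
#' @return List of class `study_spec`.
#' @export
study_spec <- function(segments = c(segA = 280000L, segB = 305000L,
                                    segC = 231000L, segD = 213000L,
                                    segE = 199000L, segF = 296000L),
                       gc_background = 0.42, gc_pause = 0.36,
                       tt_boost = 1.5, n_pause = 15L, pause_width = 10000L,
                       rate_per_10kb = 30, pause_multiplier = 1.3,
                       spectrum = c("C>A" = 0.09, "C>G" = 0.08,
                                    "C>T" = 0.30, "T>A" = 0.08,
                                    "T>C" = 0.33, "T>G" = 0.12),
                       tcg_boost = 1.5, gc_slope = 0,
                       snp_window = 500L, plants = default_plants(),
                       markov_background = FALSE) {
  if (any(segments <= 0)) stop("segment lengths must be positive")
  if (abs(sum(spectrum) - 1) > 1e-8)
    stop("spectrum probabilities must sum to 1")
  if (!setequal(names(spectrum), .classes6))
    stop("spectrum must name the six collapsed classes")
  if (pause_multiplier <= 0 || tcg_boost <= 0 || tt_boost <= 0)
    stop("multipliers must be positive")
  structure(list(segments = segments, gc_background = gc_background,
                 gc_pause = gc_pause, tt_boost = tt_boost,
                 n_pause = as.integer(n_pause),
                 pause_width = as.integer(pause_width),
                 rate_per_10kb = rate_per_10kb,
                 pause_multiplier = pause_multiplier,
                 spectrum = spectrum[.classes6], tcg_boost = tcg_boost,
                 gc_slope = gc_slope, snp_window = as.integer(snp_window),
                 plants = plants,
                 markov_background = markov_background),
            class = "study_spec")
}

#' Default motif plants
#'
#' One exemplar of each motif family, placed in successive pause intervals:
#' the 75-base fifteen-unit TTCTT mirror/triplex tract; a 134-base perfect
#' inverted repeat (67-bp arms, no spacer); a pure (AT)13 cruciform; a
#' four-run G4; a (TG)10 Z-DNA tract; plus a cluster of five 40-base
#' inverted repeats in pause interval 1 to create one motif-dense interval
#' for the enrichment-flag rule.
#'
#' @param seed Seed used to draw the random arms of the planted inverted
#'   repeats (kept separate from genome generation so plant sequences are
#'   stable across bundles).
#' @return List of plants, each `list(name, class, seq, pause_index)`.
#' @export
default_plants <- function(seed = 20260101) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rand_arm <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  ir_seq <- function(arm, spacer = "")
    paste0(arm, spacer, reverse_complement(arm))
  plants <- list(
    list(name = "ttctt_tract", class = "mirror_triplex",
         seq = strrep("TTCTT", 15), pause_index = 2L),
    list(name = "big_ir_134", class = "inverted_repeat",
         seq = ir_seq(rand_arm(67)), pause_index = 3L),
    list(name = "at_cruciform", class = "inverted_repeat",
         seq = strrep("AT", 13), pause_index = 4L),
    list(name = "g4_plus", class = "g4",
         seq = "GGGTTGGGTTGGGTTGGG", pause_index = 5L),
    list(name = "zdna_tg10", class = "zdna",
         seq = strrep("TG", 10), pause_index = 6L))
  for (i in 1:5) {
    plants[[length(plants) + 1L]] <-
      list(name = paste0("ir_cluster_", i), class = "inverted_repeat",
           seq = ir_seq(rand_arm(20), "TTTT"), pause_index = 1L)
  }
  plants
}

# sample a sequence with given GC; optionally a first-order chain with the
# T->T transition probability multiplied by tt_boost (renormalised)
.sample_seq <- function(n, gc, tt_boost = 1) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(p)
  if (tt_boost == 1) {
    return(paste(sample(bases, n, replace = TRUE, prob = p), collapse = ""))
  }
  pt <- p
  pt["T"] <- pt["T"] * tt_boost
  pt <- pt / sum(pt)
  # vectorised chain: draw both candidate streams, then resolve states
  iid <- sample.int(4L, n, replace = TRUE, prob = p)
  aft <- sample.int(4L, n, replace = TRUE, prob = pt)
  out <- integer(n)
  out[1] <- iid[1]
  tcode <- 4L
  for (i in 2:n) out[i] <- if (out[i - 1] == tcode) aft[i] else iid[i]
  paste(bases[out], collapse = "")
}

#' Generate the synthetic mini-genome
#'
#' Background bases are i.i.d. at the segment GC; pause intervals are
#' regenerated at reduced GC with a boosted T-after-T transition
#' (elevated TT density); motifs are planted by overwriting the background
#' at recorded coordinates, rejecting colliding placements. Deterministic
#' for a fixed seed.
#'
#' @param spec A [study_spec()].
#' @param seed Integer seed.
#' @return List: `genome` (named character vector), `truth` (pause
#'   intervals, plant coordinates, and all generator parameters).
#' @export
generate_genome <- function(spec = study_spec(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  segs <- spec$segments
  genome <- setNames(vapply(segs, function(L)
    .sample_seq(L, spec$gc_background,
                if (spec$markov_background) spec$tt_boost else 1),
    character(1)), names(segs))

  # distribute pause intervals round-robin over segments, on aligned
  # pause-width slots away from the segment ends
  slot_pool <- do.call(rbind, lapply(names(segs), function(nm) {
    nslots <- segs[[nm]] %/% spec$pause_width
    if (nslots < 3L) return(NULL)
    data.frame(chrom = nm, slot = 1:(nslots - 2L))   # skip first/last slot
  }))
  seg_order <- rep(names(segs), length.out = spec$n_pause)
  pause <- do.call(rbind, lapply(seq_len(spec$n_pause), function(i) {
    nm <- seg_order[i]
    avail <- slot_pool[slot_pool$chrom == nm, , drop = FALSE]
    if (nrow(avail) == 0L)
      stop("segment ", nm, " has no free pause slot left; ",
           "use fewer pause intervals or longer segments")
    pick <- avail[sample.int(nrow(avail), 1L), ]
    slot_pool <<- slot_pool[!(slot_pool$chrom == pick$chrom &
                                slot_pool$slot == pick$slot), ,
                            drop = FALSE]
    data.frame(chrom = pick$chrom,
               start = pick$slot * spec$pause_width,
               end = (pick$slot + 1L) * spec$pause_width)
  }))
  pause <- pause[order(pause$chrom, pause$start), ]
  pause <- genomic_interval(pause$chrom, pause$start, pause$end,
                            label = paste0("P", seq_len(nrow(pause))))

  # rewrite pause intervals with the pause composition model
  for (i in seq_len(nrow(pause))) {
    nm <- pause$chrom[i]
    sub <- .sample_seq(pause$end[i] - pause$start[i], spec$gc_pause,
                       spec$tt_boost)
    substr(genome[[nm]], pause$start[i] + 1L, pause$end[i]) <- sub
  }

  # plant motifs (overwrite background; reject collisions)
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), name = character(),
                       motif_class = character(), stringsAsFactors = FALSE)
  margin <- 25L
  for (pl in spec$plants) {
    L <- nchar(pl$seq)
    pi <- ((pl$pause_index - 1L) %% nrow(pause)) + 1L
    target <- pause[pi, ]
    if (L + 2L * margin > target$end - target$start)
      stop("plant ", pl$name, " longer than its target interval")
    ok <- FALSE
    for (try in 1:100) {
      s0 <- target$start + margin +
        sample.int(target$end - target$start - L - 2L * margin, 1L)
      clash <- any(placed$chrom == target$chrom &
                     placed$start < s0 + L + margin &
                     placed$end > s0 - margin)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place plant ", pl$name,
                  " without collision after bounded retries")
    substr(genome[[target$chrom]], s0 + 1L, s0 + L) <- pl$seq
    placed <- rbind(placed, data.frame(
      chrom = target$chrom, start = s0, end = s0 + L, name = pl$name,
      motif_class = pl$class, stringsAsFactors = FALSE))
  }

  truth <- list(spec = spec, seed = seed, pause = pause, plants = placed)
  list(genome = genome, truth = truth)
}

# per-window per-class expected counts under the generator model
.snp_rates <- function(spec, gc, pause) {
  base <- spec$rate_per_10kb * spec$snp_window / 10000
  gcmod <- 1 + spec$gc_slope * (gc - spec$gc_background)
  gcmod[!is.finite(gcmod) | gcmod < 0] <- 0
  lam <- outer(base * gcmod * ifelse(pause, spec$pause_multiplier, 1),
               spec$spectrum)
  lam[pause, c("T>C", "T>G")] <- lam[pause, c("T>C", "T>G")] * spec$tcg_boost
  lam
}

#' Simulate SNPs over a synthetic genome
#'
#' Per 500-base window and substitution class, counts are Poisson with rate
#' `base_rate x GC-modifier x pause-multiplier`, with the absolute T>C and
#' T>G rates additionally multiplied by the T>(C+G) boost at pause windows.
#' Positions are uniform among window positions whose reference base is
#' consistent with the drawn class on either strand (a `T>C` event lands on
#' a `T`, emitted as `T>C`, or on an `A`, emitted as `A>G`); a class with no
#' compatible base in a window is skipped with a log message.
#'
#' @param genome Named character vector from [generate_genome()].
#' @param truth Truth bundle from [generate_genome()].
#' @param seed Integer seed.
#' @return List: `snps` (data frame `chrom`, `pos` 1-based, `ref`, `alt`,
#'   `class`), `truth` (input truth plus the realised per-window rates).
#' @export
simulate_snps <- function(genome, truth, seed = 1) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  spec <- truth$spec
  grid <- tile_regions(genome, spec$snp_window)
  comp <- window_composition(genome, grid)
  pause <- .overlaps_any(grid, truth$pause)
  lam <- .snp_rates(spec, comp$gc_fraction, pause)
  complement <- .complement_map
  rows <- vector("list", nrow(grid))
  skipped <- 0L
  for (i in seq_len(nrow(grid))) {
    counts <- stats::rpois(6L, lam[i, ])
    if (sum(counts) == 0L) next
    wseq <- strsplit(substr(genome[[grid$chrom[i]]], grid$start[i] + 1L,
                            grid$end[i]), "", fixed = TRUE)[[1]]
    recs <- vector("list", 6L)
    for (j in which(counts > 0L)) {
      cls <- .classes6[j]
      py <- substr(cls, 1, 1)
      alt_py <- substr(cls, 3, 3)
      compat <- which(wseq == py | wseq == complement[[py]])
      if (length(compat) == 0L) { skipped <- skipped + counts[j]; next }
      k <- min(counts[j], length(compat))
      if (k < counts[j]) skipped <- skipped + counts[j] - k
      offs <- if (length(compat) == 1L) compat else
        sample(compat, k, replace = FALSE)
      refb <- wseq[offs]
      altb <- ifelse(refb == py, alt_py, complement[[alt_py]])
      recs[[j]] <- data.frame(chrom = grid$chrom[i],
                              pos = grid$start[i] + offs,   # 1-based
                              ref = refb, alt = altb, class = cls,
                              stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  snps <- do.call(rbind, rows)
  if (is.null(snps))
    snps <- data.frame(chrom = character(), pos = numeric(),
                       ref = character(), alt = character(),
                       class = character(), stringsAsFactors = FALSE)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  # drop the rare duplicate position hit by two classes
  dup <- duplicated(snps[, c("chrom", "pos")])
  skipped <- skipped + sum(dup)
  snps <- snps[!dup, , drop = FALSE]
  rownames(snps) <- NULL
  if (skipped > 0L)
    message("simulate_snps: ", skipped,
            " draw(s) without a compatible position were skipped")
  truth$snp_lambda <- lam
  truth$snp_grid <- as.data.frame(grid)
  truth$snp_pause <- pause
  list(snps = snps, truth = truth)
}

#' Write a complete study fixture to disk
#'
#' Generates the genome and SNPs and writes `genome.fa`, `pause.bed`,
#' `snps.vcf`, `plants.tsv`, and `truth.json` (generator parameters) into
#' `dir`. The bundle loads back through [read_fasta()], [read_bed()], and
#' [read_snvs()].
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param spec A [study_spec()].
#' @return Named list of file paths, invisibly; the truth bundle is
#'   attached as attribute `truth`.
#' @export
make_study_fixture <- function(dir, seed = 1, spec = study_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_genome(spec, seed)
  sim <- simulate_snps(g$genome, g$truth, seed = seed + 1L)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                bed = file.path(dir, "pause.bed"),
                vcf = file.path(dir, "snps.vcf"),
                plants = file.path(dir, "plants.tsv"),
                truth = file.path(dir, "truth.json"))
  write_fasta(g$genome, paths$fasta)
  write_bed(g$truth$pause, paths$bed)
  write_vcf(sim$snps[, c("chrom", "pos", "ref", "alt")], paths$vcf,
            contigs = nchar(g$genome))
  utils::write.table(g$truth$plants, paths$plants, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(seed = seed,
               segments = as.list(g$truth$spec$segments),
               gc_background = spec$gc_background,
               gc_pause = spec$gc_pause, tt_boost = spec$tt_boost,
               rate_per_10kb = spec$rate_per_10kb,
               pause_multiplier = spec$pause_multiplier,
               tcg_boost = spec$tcg_boost, gc_slope = spec$gc_slope,
               spectrum = as.list(spec$spectrum),
               n_pause = nrow(g$truth$pause))
  jsonlite::write_json(meta, paths$truth, auto_unbox = TRUE, digits = NA)
  out <- paths
  attr(out, "truth") <- sim$truth
  invisible(out)
}

#' Recover the planted pause effects from simulated data
#'
#' Moment estimators for the two planted multipliers, built to be
#' insensitive to each other: the density multiplier is estimated from the
#' per-10-kb rate ratio of the classes the T>(C+G) boost leaves untouched
#' (`C>A`, `C>G`, `C>T`, `T>A`), and the spectrum boost from the
#' pause/nonpause ratio of the T>(C+G)-to-other-class rate ratio, which
#' cancels the density multiplier.
#'
#' @param variation Output of [window_variation()] with a `pause` column.
#' @return List: `density_multiplier`, `spectrum_boost`.
#' @export
estimate_planted_effects <- function(variation) {
  p <- variation$pause
  if (!any(p) || !any(!p))
    stop("need both pause and nonpause windows")
  other <- c("C.A", "C.G", "C.T", "T.A")
  tcg <- c("T.C", "T.G")
  rate <- function(cols, idx) {
    sum(as.matrix(variation[idx, cols, drop = FALSE])) /
      sum(variation$end[idx] - variation$start[idx])
  }
  dens <- rate(other, p) / rate(other, !p)
  boost <- (rate(tcg, p) / rate(other, p)) /
    (rate(tcg, !p) / rate(other, !p))
  list(density_multiplier = dens, spectrum_boost = boost)
}
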