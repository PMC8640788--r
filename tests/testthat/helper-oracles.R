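# Independent brute-force enumerators for the motif definitions, written
# against the definitions directly (character vectors, explicit maximality
# predicates) rather than sharing code with the scanners.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_pairs <- function(a, b) {
  a != "N" && b != "N" && oracle_comp[[a]] == b
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# all maximal perfect inverted repeats (1-based internals, 0-based output)
oracle_ir <- function(seq, min_arm, smin, smax) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  hits <- list()
  for (g in 0:n) {
    for (sp in smin:smax) {
      if (g + sp > n) break
      if (sp >= 2 && oracle_pairs(x[g + 1], x[g + sp])) next # inward-ext.
      a <- 0
      while (g - a >= 1 && g + sp + a + 1 <= n &&
             oracle_pairs(x[g - a], x[g + sp + a + 1])) a <- a + 1
      if (a >= min_arm) {
        # explicit definition check: right arm is revcomp of left arm
        left <- paste(x[(g - a + 1):g], collapse = "")
        right <- paste(x[(g + sp + 1):(g + sp + a)], collapse = "")
        stopifnot(fragilescan::reverse_complement(left) == right)
        hits[[length(hits) + 1L]] <-
          data.frame(start = g - a, end = g + sp + a,
                     arm_len = a, spacer_len = sp)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      arm_len = integer(), spacer_len = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

# containment collapse by pairwise comparison, independent of the
# implementation's sorted sweep
oracle_collapse <- function(d, prefer = NULL) {
  if (nrow(d) <= 1L) return(d)
  if (!is.null(prefer)) d <- d[do.call(order, prefer(d)), , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  strict <- vapply(seq_len(nrow(d)), function(i)
    any(d$start <= d$start[i] & d$end >= d$end[i] &
          (d$end - d$start) > (d$end[i] - d$start[i])), logical(1))
  out <- d[!strict, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

# maximal mirror repeats with homopurine/homopyrimidine arms
oracle_mirror <- function(seq, min_arm, smin, smax, min_tract) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  is_pur <- function(b) b %in% c("A", "G")
  cls_of <- function(b) if (is_pur(b)) "purine" else "pyrimidine"
  hits <- list()
  for (g in 0:n) {
    for (sp in smin:smax) {
      if (g + sp > n) break
      a <- 0
      cls <- NA_character_
      repeat {
        l <- g - a
        r <- g + sp + a + 1
        if (l < 1 || r > n) break
        if (x[l] != x[r] || x[l] == "N") break
        c0 <- cls_of(x[l])
        if (is.na(cls)) cls <- c0 else if (c0 != cls) break
        a <- a + 1
      }
      if (a < min_arm || 2 * a + sp < min_tract) next
      if (sp >= 2 && x[g + 1] == x[g + sp] && x[g + 1] != "N" &&
          cls_of(x[g + 1]) == cls) next
      hits[[length(hits) + 1L]] <-
        data.frame(start = g - a, end = g + sp + a, arm_len = a,
                   spacer_len = sp, arm_class = cls)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      arm_len = integer(), spacer_len = integer(),
                      arm_class = character()))
  out <- do.call(rbind, hits)
  oracle_collapse(out, prefer = function(d)
    list(d$start, -d$end, -d$arm_len, d$spacer_len))
}

# maximal runs of period p (vectorised lag comparison), primitive-period
# dedupe, copies filter, containment collapse
oracle_tandem <- function(seq, unit_min, unit_max, min_copies) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  runs <- list()
  for (p in seq_len(min(unit_max, n %/% 2))) {
    m <- x[(p + 1):n] == x[1:(n - p)] & x[(p + 1):n] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k] + p
      if (len >= 2 * p)
        runs[[length(runs) + 1L]] <-
          data.frame(start = starts[k] - 1L, end = starts[k] - 1L + len,
                     period = p)
    }
  }
  if (length(runs) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), copies = integer()))
  d <- do.call(rbind, runs)
  d <- d[order(d$start, d$end, d$period), , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  d$copies <- (d$end - d$start) %/% d$period
  d <- d[d$period >= unit_min & d$copies >= min_copies, , drop = FALSE]
  oracle_collapse(d)
}

# Z-DNA tracts by per-position step check
oracle_zdna <- function(seq, min_tract, allow_at = FALSE) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  allowed <- c("GC", "CG", "GT", "TG", "AC", "CA")
  if (allow_at) allowed <- c(allowed, "AT", "TA")
  hits <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && paste0(x[j], x[j + 1]) %in% allowed) j <- j + 1L
    if (j - i + 1L >= min_tract)
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, end = j)
    i <- max(j, i + 1L)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer()))
  do.call(rbind, hits)
}

# G4 by explicit G-run chaining on each strand
oracle_g4 <- function(seq, min_run = 3, min_runs = 4, smin = 1, smax = 7) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  one <- function(base, strand) {
    r <- rle(x == base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_run)
    if (length(sel) == 0L) return(NULL)
    rs <- starts[sel] - 1L
    re <- ends[sel]
    # split run list wherever the gap leaves [smin, smax]
    grp <- cumsum(c(TRUE, !(rs[-1] - re[-length(re)] >= smin &
                              rs[-1] - re[-length(re)] <= smax)))
    out <- lapply(unique(grp), function(g) {
      idx <- which(grp == g)
      if (length(idx) < min_runs) return(NULL)
      data.frame(start = rs[idx[1]], end = re[idx[length(idx)]],
                 strand = strand)
    })
    do.call(rbind, out)
  }
  out <- rbind(one("G", "+"), one("C", "-"))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}
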