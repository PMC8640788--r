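#' Minimum-free-energy fold of one sequence
#'
#' Dynamic-programming minimum over all nested secondary structures under
#' the bundled nearest-neighbour model ([energy_model()]): helix stacks plus
#' hairpin/bulge/interior-loop penalties and an affine multibranch term. No
#' pseudoknots, coaxial stacking, or dangling ends. `N` never pairs. The
#' traceback is deterministic, preferring the pairing that closes at the
#' smallest 5' index.
#'
#' @param seq Nucleotide string (length <= `model$max_len`).
#' @param model An [energy_model()].
#' @return List of class `fold_result`: `delta_g` (kcal/mol, <= 0; 0 means
#'   no stabilising structure), `structure` (dot-bracket), `backend`
#'   (`"builtin"`).
#' @examples
#' fold_mfe("GCGCGCGCTTTTGCGCGCGC")
#' @export
fold_mfe <- function(seq, model = energy_model()) {
  if (nchar(seq) > model$max_len)
    stop("sequence longer than folding guard (", model$max_len, " nt)")
  if (nchar(seq) == 0L)
    return(structure(list(delta_g = 0, structure = "", backend = "builtin"),
                     class = "fold_result"))
  res <- .fold_mfe_cpp(.encode_seq(seq), model$stack, model$pairs,
                       model$wobble_stack, .finite_pen(model$hairpin),
                       .finite_pen(model$bulge), .finite_pen(model$internal),
                       model$ml_a, model$ml_b, model$ml_c,
                       model$maxloop, model$min_hairpin)
  structure(list(delta_g = res$delta_g, structure = res$structure,
                 backend = "builtin"),
            class = "fold_result")
}

#' Free energy of a given secondary structure
#'
#' Scores a dot-bracket structure under the same model as [fold_mfe()]; the
#' traceback structure of `fold_mfe` scores exactly to its `delta_g`, and
#' any valid structure scores at or above the MFE. Energies are accumulated
#' on the model's centi-kcal grid, so agreement with the DP is exact.
#'
#' @param seq Nucleotide string.
#' @param pairing Dot-bracket string of the same length; must be well
#'   nested.
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol (0 for the all-unpaired structure).
#' @export
energy_of_structure <- function(seq, pairing, model = energy_model()) {
  s <- .encode_seq(seq)
  n <- length(s)
  if (nchar(pairing) != n)
    stop("structure length does not match sequence length")
  ch <- strsplit(pairing, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("structure must contain only '.', '(', ')'")
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets in structure")
  bases <- c("A", "C", "G", "T", "N")
  pmat <- model$pairs
  cents <- 0L
  cc <- function(x) as.integer(round(x * 100))
  hairpin <- cc(.finite_pen(model$hairpin))
  bulge <- cc(.finite_pen(model$bulge))
  internal <- cc(.finite_pen(model$internal))

  score_pair <- function(i, j) {
    a <- s[i] + 1L; b <- s[j] + 1L
    if (a == 5L || b == 5L || !pmat[a, b])
      stop("paired bases ", bases[a], "/", bases[b],
           " are not complementary under the model (positions ",
           i, ", ", j, ")")
    # children: directly enclosed pairs
    children <- list()
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    if (length(children) == 0L) {
      L <- j - i - 1L
      if (L < model$min_hairpin)
        stop("hairpin loop shorter than ", model$min_hairpin, " bases")
      return(hairpin[min(L, length(hairpin))])
    }
    if (length(children) == 1L) {
      k <- children[[1]][1]; l <- children[[1]][2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      e <- if (l1 == 0L && l2 == 0L) {
        wc_outer <- (s[i] + s[j]) == 3L
        wc_inner <- (s[i + 1L] + s[j - 1L]) == 3L
        if (wc_outer && wc_inner)
          cc(model$stack[s[i] + 1L, s[i + 1L] + 1L])
        else cc(model$wobble_stack)
      } else if (l1 == 0L || l2 == 0L) {
        bulge[min(l1 + l2, length(bulge))]
      } else {
        internal[min(l1 + l2, length(internal))]
      }
      return(e + score_pair(k, l))
    }
    # multibranch: affine a + b * (children + closing)
    e <- cc(model$ml_a) + cc(model$ml_b) * (length(children) + 1L)
    for (chp in children) e <- e + score_pair(chp[1], chp[2])
    e
  }

  # top level: external loop is free; score each outermost pair
  total <- 0L
  k <- 1L
  while (k <= n) {
    if (partner[k] > k) {
      total <- total + score_pair(k, partner[k])
      k <- partner[k] + 1L
    } else k <- k + 1L
  }
  total / 100
}

#' Fold every window of a grid
#'
#' One [fold_mfe()] call per window; windows whose `N` fraction exceeds
#' `max_n_frac` are flagged and skipped (the exclusion policy shared with
#' the SNP statistics).
#'
#' @param seq Nucleotide string, or named vector of sequences covering the
#'   grid's chroms.
#' @param grid A `window_grid` of windows (each <= the model's guard
#'   length).
#' @param model An [energy_model()], or see `backend`.
#' @param max_n_frac Windows with more than this fraction of `N` are
#'   excluded.
#' @param backend `"builtin"` or a function `function(seq) -> numeric
#'   delta_g` adapting an external folding engine; downstream statistics are
#'   backend-agnostic.
#' @param keep_structure Retain dot-bracket structures (builtin backend
#'   only).
#' @return Data frame: `chrom`, `start`, `end`, `delta_g`, `backend`
#'   (+`structure`); attribute `excluded` holds the flagged windows.
#' @export
fold_windows <- function(seq, grid, model = energy_model(),
                         max_n_frac = 0.1, backend = "builtin",
                         keep_structure = FALSE) {
  if (is.null(names(seq)) && length(seq) == 1L)
    names(seq) <- unique(grid$chrom)[1]
  nfrac <- .n_fraction(seq, grid)
  excl <- nfrac > max_n_frac
  keep <- which(!excl)
  fold1 <- if (is.function(backend)) {
    backend_name <- "custom"
    backend
  } else {
    backend_name <- "builtin"
    function(s) fold_mfe(s, model)
  }
  rows <- lapply(keep, function(i) {
    sub <- substr(seq[[grid$chrom[i]]], grid$start[i] + 1L, grid$end[i])
    r <- fold1(sub)
    if (is.numeric(r)) r <- list(delta_g = r, structure = NA_character_)
    data.frame(chrom = grid$chrom[i], start = grid$start[i],
               end = grid$end[i], delta_g = r$delta_g,
               backend = backend_name,
               structure = if (keep_structure) r$structure else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               delta_g = numeric(), backend = character(),
               structure = character(), stringsAsFactors = FALSE)
  if (!keep_structure) out$structure <- NULL
  rownames(out) <- NULL
  attr(out, "excluded") <- as.data.frame(grid)[excl, , drop = FALSE]
  out
}
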