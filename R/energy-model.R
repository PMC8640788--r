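#' Nearest-neighbour DNA energy model
#'
#' The entire thermodynamic parameterisation used by [fold_mfe()] lives in
#' this one function so that every constant is visible and overridable.
#'
#' Stacking free energies are the unified DNA/DNA nearest-neighbour
#' parameters at 37 degrees C (kcal/mol), indexed by the 5'->3' top-strand
#' dinucleotide of a helix step; the ten unique values are expanded to all
#' sixteen Watson-Crick steps by reverse-complement symmetry. Loop penalties
#' use a short-loop anchor extended by a Jacobson-Stockmayer logarithmic
#' term `1.75 * R * T * ln(L / L0)` with `RT = 0.6163` kcal/mol at 310.15 K.
#' Multibranch loops carry an affine cost `a + b * branches` (the closing
#' helix counts as a branch); unpaired bases inside multiloops are free.
#' There is no salt correction and temperature is fixed at 37 degrees C.
#'
#' @param allow_gt Also allow G.T wobble pairs (off by default). Steps
#'   involving a wobble pair take the flat `wobble_stack` energy.
#' @param wobble_stack Stack energy (kcal/mol) for steps touching a wobble
#'   pair.
#' @param hairpin3,bulge1,internal2 Loop-penalty anchors (kcal/mol) at the
#'   smallest loop sizes (3, 1, and 2 unpaired bases respectively).
#' @param ml_a,ml_b Multibranch closing and per-branch penalties (kcal/mol).
#' @param maxloop Largest interior/bulge loop (unpaired bases) considered by
#'   the dynamic program; 30 is standard practice.
#' @param max_len Guard on sequence length for [fold_mfe()].
#' @return A list of class `energy_model`.
#' @export
energy_model <- function(allow_gt = FALSE, wobble_stack = -0.5,
                         hairpin3 = 3.5, bulge1 = 4.0, internal2 = 3.2,
                         ml_a = 4.6, ml_b = 0.4, maxloop = 30L,
                         max_len = 5000L) {
  # unified 37C DNA stack table; names are the 5'->3' top-strand step
  stacks <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
              CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tab <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
  for (x in bases) for (y in bases) {
    step <- paste0(x, y)
    rcstep <- paste0(comp[y], comp[x])
    tab[x, y] <- if (step %in% names(stacks)) stacks[[step]]
                 else stacks[[rcstep]]
  }
  pairmat <- matrix(FALSE, 4, 4, dimnames = list(bases, bases))
  pairmat["A", "T"] <- pairmat["T", "A"] <- TRUE
  pairmat["C", "G"] <- pairmat["G", "C"] <- TRUE
  if (allow_gt) pairmat["G", "T"] <- pairmat["T", "G"] <- TRUE

  rt <- 0.0019872 * 310.15       # kcal/mol
  js <- function(L, L0, anchor) anchor + 1.75 * rt * log(L / L0)
  L <- seq_len(200)
  hairpin <- ifelse(L < 3, Inf, ifelse(L == 3, hairpin3, js(L, 3, hairpin3)))
  bulge <- ifelse(L == 1, bulge1, js(L, 1, bulge1))
  internal <- ifelse(L < 2, Inf, ifelse(L == 2, internal2,
                                        js(L, 2, internal2)))
  structure(list(stack = tab, pairs = pairmat, wobble_stack = wobble_stack,
                 hairpin = hairpin, bulge = bulge, internal = internal,
                 ml_a = ml_a, ml_b = ml_b, ml_c = 0,
                 maxloop = as.integer(maxloop), min_hairpin = 3L,
                 max_len = as.integer(max_len),
                 temperature_c = 37),
            class = "energy_model")
}

# encode a nucleotide string as integer codes A=0 C=1 G=2 T=3 N=4
.encode_seq <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  out <- unname(code[x])
  if (anyNA(out)) stop("sequence contains characters outside {A,C,G,T,N}")
  out
}

# loop tables capped at a finite large value for the integer DP
.finite_pen <- function(x) {
  x[!is.finite(x)] <- 999
  x
}
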