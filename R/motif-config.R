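#' Motif search configuration and presets
#'
#' Every threshold used by the scanners lives here and is echoed into scan
#' output attributes, so no run depends on hidden constants.
#'
#' The `default` preset is the general census: inverted repeats arm >= 6,
#' spacer <= 100; mirror/triplex tract >= 10, arm >= 10, spacer <= 8; Z-DNA
#' tract >= 10; tandem units 1-20 with >= 3 copies; direct repeats unit >=
#' 10 with >= 2 copies; G4 = four or more runs of three-plus G with 1-7 nt
#' spacers. The `at_cruciform_census` preset is the AT-palindrome census:
#' inverted-repeat arm >= 12, loop 0-7 bases, no mismatches. The `g4_canonical`
#' preset pins the G4 rule above under an explicit name.
#'
#' All presets use 0 mismatches; the `mismatch` slot is accepted for forward
#' compatibility but only 0 is implemented.
#'
#' @param preset One of `"default"`, `"at_cruciform_census"`, `"g4_canonical"`.
#' @param ... Named overrides of individual slots.
#' @return List of class `motif_config`.
#' @export
motif_config <- function(preset = c("default", "at_cruciform_census",
                                    "g4_canonical"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    ir_min_arm = 6L, ir_spacer_min = 0L, ir_spacer_max = 100L,
    mr_min_tract = 10L, mr_min_arm = 10L, mr_spacer_min = 0L,
    mr_spacer_max = 8L,
    z_min_tract = 10L, z_allow_at = FALSE,
    tr_unit_min = 1L, tr_unit_max = 20L, tr_min_copies = 3L,
    dr_unit_min = 10L, dr_unit_max = 100L, dr_min_copies = 2L,
    g4_min_run = 3L, g4_min_runs = 4L, g4_spacer_min = 1L,
    g4_spacer_max = 7L,
    mismatch = 0L
  )
  if (preset == "at_cruciform_census") {
    cfg$ir_min_arm <- 12L
    cfg$ir_spacer_max <- 7L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown motif_config slot: ", unknown[1])
  cfg[names(dots)] <- dots
  if (cfg$mismatch != 0L)
    stop("only mismatch = 0 (perfect repeats) is implemented")
  structure(cfg, class = "motif_config")
}
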