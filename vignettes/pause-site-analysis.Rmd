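---
title: "Sequence features, folding energetics, and variation at replication pause sites"
author: "fragilescan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence features, folding energetics, and variation at replication pause sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragilescan)
```

## The question the package addresses

Common fragile sites (CFSs) are chromosomal regions prone to gaps and
breaks under replication stress. Single-molecule replication analysis can
localise fork *pause sites* within such regions at 10-kb resolution;
translesion polymerase eta appears to protect these loci, and in its
absence pausing concentrates at characteristic intervals. Given a genome
sequence, pause-site annotations (BED), and a catalogue of biallelic SNVs
(VCF), `fragilescan` asks what distinguishes pause-containing intervals
from their pause-free flanks along four axes:

1. **Non-B DNA motif content** — inverted repeats (cruciforms), mirror
   -symmetric homopurine/homopyrimidine tracts (triplex/H-DNA), direct and
   tandem repeats (slipped-strand DNA), alternating purine–pyrimidine
   tracts (Z-DNA), and G-quadruplex motifs, censused per 10-kb interval
   (counts, base footprints, composite footprint, longest motif) with a
   mean + 3 SD enrichment rule.
2. **Hairpin-folding thermodynamics** — the minimum free energy (ΔG,
   kcal/mol) of the most stable intramolecular fold of each 500-base
   window, under a documented nearest-neighbour DNA model.
3. **Base composition** — %C+G over unambiguous bases and overlapping TT
   dinucleotide counts per window (TT being the canonical substrate of
   UV-type damage bypassed by polymerase eta).
4. **Genetic variation** — SNP density per window (normalised to 10 kb),
   the strand-collapsed six-class substitution spectrum with its T>(C+G)
   and C>(A+T) aggregates, quantile binning of SNP density against ΔG,
   Mann–Whitney pause/nonpause comparisons, and a null built from randomly
   placed 10-kb windows.

Because the reference-scale inputs (a human assembly, population SNP
catalogues) are too large to bundle, the package ships a seeded
synthetic-study generator that emulates the statistical structure of this
design end to end with known ground truth. The same pipeline runs
unchanged on user-supplied region files.

## Coordinates and I/O conventions

All internal coordinates are 0-based half-open (BED native); VCF positions
are converted on read (`pos - 1`) and on write. FASTA input is uppercased
and every non-`ACGTN` character becomes `N`. Only biallelic
single-nucleotide substitutions survive `read_snvs()`; indel, multiallelic
and symbolic records are counted and skipped. Window grids drop a trailing
remainder shorter than the window width, so a region of length L yields
`floor(L / width)` whole windows — the interval counts the analysis reports
(20 windows per 10-kb interval; 300 windows for 15 distinct pause
intervals) presuppose whole-width windows, and the drop-remainder policy is
echoed in run metadata. Windows with more than 10% `N` are excluded from
folding and SNP statistics (flagged, configurable); `N` is excluded from
the GC denominator; and TT dinucleotides are counted with overlap on the
plus strand only (symmetric counting is a switch, recorded in output
attributes).

## Motif scanners

Every scanner reports *maximal perfect* hits (no mismatches) in
deterministic coordinate order; `N` never pairs and never matches. The
thresholds live in `motif_config()` presets and are echoed into outputs:

| class | preset `default` | notes |
|---|---|---|
| inverted repeat | arm ≥ 6, spacer 0–100 | arms not extendable outward or inward |
| mirror/triplex | arm ≥ 10, spacer 0–8, tract ≥ 10 | arms homopurine or homopyrimidine; spacer composition free |
| tandem repeat | unit 1–20, ≥ 3 copies | unit = least rotation of the primitive period |
| direct repeat | unit 10–100, ≥ 2 copies | long-unit duplications; may overlap the tandem class |
| Z-DNA | tract ≥ 10 | steps in {GC, CG, GT, TG, AC, CA}; AT/TA optional |
| G4 | ≥ 4 runs of G≥3, spacers 1–7 | both strands; minus-strand hits in plus coordinates |

The `at_cruciform_census` preset (arm ≥ 12, loop 0–7, perfect) reproduces
the AT-palindrome census, flagging hits whose footprint is pure A/T.

Three tie-break rules were genuinely open and are fixed as follows. First,
perfectly periodic sequences are mirror-symmetric about every unit junction
and carry phase-shifted nested maximal repeats; the mirror detector, the
tandem/direct detectors, and the AT-cruciform census therefore collapse any
hit whose span is strictly contained in a longer hit's span (equal spans
keep the larger arm, then the smaller spacer). The raw inverted-repeat
scanner does *not* collapse — it returns the complete set of maximal hits,
which is what the brute-force equivalence tests enumerate. Second, a motif
whose span crosses an interval boundary is *counted* in the interval
holding its leftmost base but contributes *clipped* bases to every interval
it touches; counts stay partition-additive while footprints remain
geometrically faithful. Third, enrichment flags use the population SD over
all intervals of a segment and a strict inequality, so an all-equal segment
flags nothing.

```{r motif-example}
tract <- strrep("TTCTT", 15)
find_mirror_triplex(tract)[, c("start", "end", "arm_len", "spacer_len")]
```

The fifteen-unit TTCTT tract is a 75-base pyrimidine tract whose maximal
mirror symmetry has 37-base arms around one unpaired centre base; the
tandem detector sees the same span as 15 copies of a 5-base unit.

## The folding model

`fold_mfe()` minimises over all nested secondary structures (no
pseudoknots, coaxial stacking, or dangling ends) with:

* the unified DNA/DNA nearest-neighbour stack table at 37 °C (ten unique
  Watson–Crick step energies, expanded to sixteen by reverse-complement
  symmetry), all negative;
* hairpin (≥ 3 unpaired bases), bulge, and interior-loop penalties anchored
  at small sizes (3.5, 4.0, 3.2 kcal/mol) and extended by a
  Jacobson–Stockmayer term `1.75·RT·ln(L/L0)` — positive and
  non-decreasing in loop length;
* an affine multibranch cost (closing 4.6 + 0.4 per branch, unpaired bases
  free), needed for the minimum over branched structures to be well
  defined;
* interior loops capped at 30 unpaired bases (standard practice), G·T
  wobble pairs off by default, no salt correction, temperature fixed at
  37 °C.

Every parameter lives in `energy_model()` — one file, no hidden constants —
and `fold_windows()` accepts a function backend so an external folding
engine can be slotted in; all downstream statistics consume ΔG values and
are backend-agnostic. Exact parity with mfold outputs is expressly not a
goal: the analysis rests on the *relative ordering* of window ΔG values,
not on engine-specific absolute numbers, which is why printed
engine-specific energies (e.g. for specific long cruciforms) are not
reproduction targets.

Numerics: the dynamic program and the structure scorer
(`energy_of_structure()`) both work on an integer centi-kcal grid, so the
traceback structure rescores to the DP minimum *exactly*, with no
floating-point tolerance. The traceback resolves ties by preferring the
pairing that closes at the smallest 5′ index, making structures
deterministic. `delta_g` is capped at 0 (an empty structure is always
available), and sequences longer than a 5,000-nt guard are refused.
Because the scorer applies the loop formulas at any size while the DP caps
interior loops at 30, a contrived structure with a larger interior loop
can in principle score below the DP minimum; within the model's search
space the bound `energy_of_structure ≥ fold_mfe` holds exactly.

The "reverse strand" refolding used for the extreme ΔG bin is implemented
as the reverse *complement* (the biologically meaningful strand); literal
reversal is available via `reverse = TRUE`-style preprocessing by the
caller, since a reversed string is not a molecule.

## Variation statistics

`classify_snp()` collapses the twelve ordered substitutions two-to-one
onto the pyrimidine-reference classes; T>(C+G) = T>C + T>G (TA→CG
changes) and C>(A+T) = C>A + C>T (CG→TA changes). SNVs are assigned to
the unique grid window containing their base; a 500-base window is a pause
window iff it overlaps a pause interval, which under aligned tiling equals
inheriting its parent 10-kb interval's label (15 distinct intervals → 300
pause windows).

`compare_groups()` uses exact Mann–Whitney enumeration when both groups
have ≤ 20 observations and no ties, and the tie-corrected normal
approximation otherwise; two identical constant groups give p = 1 by
convention. `bin_by_energy()` uses equal-count quantile bins (sizes differ
by at most one, ties broken by window order): the source analysis says
only "bins of increasing ΔG", and equal counts equalise the power of the
within-bin correlations; Pearson is the default flavour with Spearman
behind a flag. `random_windows()` samples uniformly with replacement over
all valid start positions, excluding windows > 10% `N`, under a restored
local RNG seed.

## What the synthetic generator emulates — and what it does not

`study_spec()` defaults define the study conditions: six segments at the
printed restriction-fragment lengths (280, 305, 231, 213, 199, 296 kb);
fifteen distinct pause-containing 10-kb intervals placed on aligned slots
away from segment ends; background bases i.i.d. at GC 0.42 with pause
intervals regenerated at GC 0.36 using a first-order chain whose T→T
transition is boosted 1.5× (lower %C+G and elevated TT density at pause
sites); exemplar motifs planted by overwriting background at recorded
coordinates (collision-checked), including the 75-base TTCTT tract and a
134-base perfect inverted repeat; SNPs Poisson per 500-base window at 30
per 10 kb (common-variant density scale), with a 1.3× all-class density
multiplier and a 1.5× absolute T>C/T>G rate boost at pause windows, each
SNV's reference base consistent with the genome on either strand.

The i.i.d. background makes brute-force motif-count expectations computable
in tests (a first-order background is available behind a flag). The GC
modifier on SNP rate (`gc_slope`) defaults to 0: a nonzero slope couples
density to composition the way genome-wide data do, but it also confounds
the planted pause multiplier; the default study condition keeps the two
planted effects directly identifiable, and `estimate_planted_effects()`
recovers them with estimators that are insensitive to each other (the
density multiplier from the classes the spectrum boost leaves untouched;
the boost from a ratio of class-rate ratios that cancels density).

What passing tests on this generator do **not** show about real data: no
linkage or allele-frequency structure, no mutation-rate heterogeneity
beyond the planted effects, no repeat families or segmental duplications,
no trinucleotide-context spectra, and motif densities far below genomic
reality away from the plants. Reference-scale printed counts (censuses on
a human assembly, population-catalogue elevations, tumour-signature
fractions) are inputs-dependent and are not desk-scale reproduction
targets; the external-data mode runs the identical pipeline on
user-supplied files with no numeric guarantee.

## Problem sizes used by the test suite

The suite runs the full design at reduced scale, chosen once: oracle
equivalence on 100 seeded random sequences up to 2 kb; folding
self-consistency on 50 windows of 400 nt; the null calibration of the
pause test on 1,000 regenerated SNP sets over a fixed 100-kb two-segment
genome (rejection rate checked against 5% ± 2%); parameter recovery over
50 seeds on a 180-kb three-segment genome (density 1.3 ± 0.1, spectrum
boost 1.5 ± 0.15); and one full-size genome generation to verify the
15-interval/300-window arithmetic and the 3,048-window total implied by
the printed segment lengths (the originally reported 3,060 cannot be
reproduced from the rounded printed lengths under any whole-window policy;
the bundle documents the discrepancy rather than tuning lengths to force
agreement).

## Running the pipeline

```{r pipeline, eval = FALSE}
cfg <- run_config(synth_spec = study_spec(), n_bins = 100,
                  fold_max_windows = 500, out_dir = "run1", seed = 1)
report <- run_analysis(cfg)
names(report)
```

Each stage writes its tables before the next begins; the effective
configuration, preset thresholds, and policies are echoed to
`run_metadata.yaml`, and reruns with the same config are byte-identical.
A thin command-line wrapper with `synth`, `scan`, `fold`, and `run`
subcommands is installed under `inst/cli/`.

## Known limitations

* Mismatch/bulge-tolerant repeat detection is out of scope (the engine
  accepts an allowance parameter but presets pin it to 0, matching the
  "perfect repeat" census definitions).
* Z-DNA and G4 detection are rule-based motif definitions, not
  stability scores (no Z-score/G4Hunter-style ranking).
* The folding model is deliberately simplified (no dangles, no coaxial
  stacking, flat wobble-stack energy when enabled); absolute ΔG values are
  model-specific and should only be compared within one backend.
* The interval census reports direct repeats and tandem repeats as
  separate classes that can overlap on long-unit runs; they are never
  silently merged, and composite base footprints de-duplicate overlap by
  union.
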