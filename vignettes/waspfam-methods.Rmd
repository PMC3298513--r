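---
title: "Detecting and classifying WASP-family proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying WASP-family proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waspfam)
```

## The problem

WASP-family proteins (WASP, WAVE/Scar, WASH, WHAMM, and the WAWH and WAML
types) are nucleation promoting factors that activate the ARP2/3 actin
nucleator. They are defined almost entirely by *short* sequence elements: a
family-specific N-terminal domain (WH1, WHD, WAHD, WMD or IMD), optional
basic and GTPase-binding (CRIB + WAID) regions, low-complexity
proline-rich stretches, and a C-terminal VCA module — one or two WH2
(G-actin binding) motifs, a central connector (C) and an acidic terminus
(A). Because the elements are short and often encoded across several small
exons, automated gene models frequently miss them; family membership is
instead decided by the *architecture*: which elements occur, in which
order. This package turns that decision procedure into code: detectors for
each element class, a resolver that builds one ordered architecture per
protein, a rule-based family/subtype classifier, and a Dollo-parsimony
profiler that converts per-species family inventories into gain and loss
events on a species tree.

## Element detectors

**Degenerate patterns.** WH2, C and CRIB are modelled as ordered residue
classes separated by bounded unconstrained runs. The WH2 model is
`[VILM]-[LM]-[ASED]-[ASDEQ]-[IL]-[KRQ]-x(6..14)-L-[KR]-[KR]-[VTA]`: an
amphipathic-helix block, a variable run, and the conserved LKKT(V) anchor.
The run bounds are configurable because the linker differs between
subfamilies (four to five residues in most, seven to eight in fungal
WASPs, ten in WASH); the default (6, 14) brackets all of these once the
C-terminal half of the helix is included in the run. The scanner
enumerates every admissible run length at every offset, so overlapping
placements are all reported; the score is the number of matched fixed
positions plus one if the run contains the hydrophobic (V/I/F) residue
that docks into actin's surface pocket. The C-domain model is
`[VILM]-x3-[VILM]-x3-[VILM]-x(0..6)-[KR]{2,3}-x(0..6)-[VILMY]`; the
spacings around the basic run are not constrained by the family alignment
and default to 0..6. CRIB is the literature-standard consensus
`[IV]-[ST]-x-P-x(2..4)-[FYW]-x-H-x-x-H-[VI]-[GA]`, exposed in the
configuration so a user can substitute their own.

**Composition windows.** Basic, poly-proline, serine-rich and long
charged regions are runs in which every sliding window satisfies a
minimum target-residue fraction (K/R ≥ 0.40 over 8; P ≥ 0.40 over 10;
S ≥ 0.40 over 10; E/R/K ≥ 0.80 over 200). Runs are trimmed to the
outermost target residues and near-adjacent runs merged, so the reported
boundary error is bounded by the windowing slack rather than the window
size. Only the charged-region parameters are anchored by a described
value (a region of about 800 residues that is about 90 % E/R/K); the
other thresholds were calibrated once on the synthetic generator and are
configuration entries, not constants.

**Acidic terminus.** The A domain is a D/E-rich segment (≥ 0.5 over
window 8) ending within 10 residues of the C-terminus, searched within
the last 60 residues. Trailing aromatics are absorbed into the call and
classified as `W`, `F_or_Y`, `W_plus_F_or_Y` or `none` — tryptophan is
the canonical ARP2/3-binding terminus, phenylalanine/tyrosine replaces it
in some lineages, and some WASH proteins have no aromatic at all. Because
the detector is anchored at the terminus, the interior acidic segment of
a tandem VCA is *not* reported as a second A call; the tandem form is
instead recognised from repeated WH2–C units (below).

**Coiled coils.** A 28-residue window is scored in all seven heptad
frames for hydrophobic (V/I/L/M/F/A) occupancy at the `a`/`d` core
positions; windows whose best frame reaches 0.6 are merged and the merged
span trimmed to the outermost hydrophobic core position, shedding
terminal stragglers until the core fraction again reaches the threshold.
This is a deliberately simple heuristic — a screening aid, not a
replacement for dedicated coiled-coil predictors.

**Profile models.** The N-terminal family domains and the short
family-specific motifs (plant-WAVE WAM1–4, the two WASH motifs) have no
compact consensus and are detected with ungapped position-specific
scoring matrices built from seed alignments: column frequencies with a
background-proportional pseudocount (λ = 1 over a uniform background),
log2 odds scores, and a default threshold of 60 % of the model's maximal
(consensus) score. The WMD is special: its class-2 form carries a long
(~120-residue) low-complexity insertion, so it is modelled as two
sub-profiles (N and C halves) that must occur in order within a
configurable 0–200-residue gap. Scanning is ungapped; `X` residues score
0 bits and never satisfy a pattern class.

## Architecture resolution and classification

Overlapping calls are resolved greedily by (score, then leftmost start,
then longer call); score scales are deliberately ordered — profile hits
(tens to hundreds of bits) dominate pattern hits (5–11 matched
positions), which dominate composition fractions (≤ 1) — so a chance
low-complexity call can never displace a family domain. One pipeline
exception: basic-region calls wholly inside a detected charged region are
suppressed before resolution, because a 90 % E/R/K region necessarily
contains K/R-rich sub-windows and the larger feature is the informative
one.

Family assignment is keyed on the N-terminal family domain: WH1 → WASP,
WHD → WAVE, WAHD → WASH, WMD → WHAMM, IMD → WAML; a GTPase-binding region
(CRIB and/or WAID) without any of these domains defines WAWH. The family
alignment practice supports this precedence — short WASPs lacking the
whole VCA are still grouped with WASP on the strength of WH1/CRIB/WAID
homology — and it makes family calls robust to degradation of the short
VCA motifs. Subtypes then refine the call:

* **S-WASP**: WH1 with CRIB/WAID but no C-plus-A pair. The rule is
  *not (C and A)* rather than "no C call at all", since an isolated
  chance C-pattern match must not veto the subtype.
* **tandem-PPR-VC**: two or more in-order PPR→WH2→C repeats and no acidic
  domain (the Trichomonas form).
* **tandem-VCA** (WASH): two in-order VCA groups, or — because interior A
  domains are undetectable by a terminus-anchored detector — two or more
  WH2→C units plus the terminal A (the Stramenopiles form).
* **no-WH2** (WASH): C and A present, WH2 absent (the Trypanosoma form).
* **WAML-short**: IMD + WAID without a VCA group. The defining loss is
  the VCA; poly-proline absence is reported in the rationale but not
  required, because composition detectors can fire by chance.
* **WAWH I/II/III** are tested in the order III → II → I (most specific
  evidence first): III by a ≥ 400-residue charged region (half the
  described ~800, to tolerate divergence), II by an N-terminal CxxC pair
  plus a serine-rich region before the GBD and a coiled-coil after it,
  I by default (with the basic region noted when present). The CxxC test
  needs the raw sequence; when only the architecture is available it is
  skipped and II is decided from the serine-rich/coiled-coil placement.

Completeness follows the 5 % rule: up to 1 % shorter than the expected
family length is Complete (length jitter), up to 5 % missing is a
Partial, beyond that a Fragment. Expected lengths default to the median
of classified records per family and can be overridden; on synthetic
proteomes with random linker lengths this length-only criterion is
intentionally *not* asserted, since linker variance swamps it. Pseudogene
flagging is CDS-based only: internal in-frame stops, missing start,
missing terminal stop and non-multiple-of-three length each count one
disablement, and two or more flags the gene — more damage than
sequencing error plausibly explains.

## Dollo profiling

Classified records are aggregated into a species × family count matrix
(pseudogenes excluded by default). For each family the single gain is
placed on the edge above the most recent common ancestor of all carrier
species, and losses on the maximal edges below it whose entire subtree
lacks the family. Among single-gain labellings this loss set is minimal,
which is verified against brute-force enumeration in the tests. Species
in the tree but absent from the matrix are treated as *no data* — an
unsequenced genome is not evidence of loss — and never generate loss
edges. Two standard Dollo caveats apply: a gain is only identifiable down
to the MRCA of its surviving carriers (a root gain whose carriers all sit
in one child clade will be reconstructed on that clade's stem), and
unrooted input trees must be rooted (at a named outgroup, else at the
midpoint, with a warning) before gains can be placed.

## The synthetic generator

Every pipeline stage is tested against generated proteomes with planted
ground truth, because the original curated dataset was hand-assembled
from hundreds of genomes and cannot be regenerated at desk scale. Each
synthetic protein is an N-to-C concatenation of sampled element instances
following one of 22 catalogued architectures (all canonical forms plus
the S-WASP, tandem, plant-WAVE, coiled-coil WAVE, WH2-less WASH,
insertion-bearing WHAMM, WAWH I–III and short-WAML variants), joined by
background linkers of 10–60 residues drawn uniformly over the 20-letter
alphabet. Pattern instances are sampled within their residue classes and
run bounds and self-checked against the pattern before emission;
composition blocks are emitted at 90 % target density (rejection keeps
short blocks within 5 points of nominal) with target residues forced at
both edges; coiled coils are perfect heptads whose planted coordinates
are the hydrophobic core the detector anchors on; family domains are
drawn once per run as random consensus strings and emitted alongside
20-sequence seed alignments at 5 % per-position divergence, from which
the scanning profiles are rebuilt — so the profile stage is exercised
end to end rather than fed its own answers.

Three generator policies make the planted truth unambiguous for *any*
seed, and they are design decisions, not tuning: (i) linkers are
rejection-sampled to contain no WH2/C/CRIB pattern match; (ii) linker
residues adjacent to a composition-defined block exclude that block's
target residues (and hydrophobics) over the windowing slack, so detected
and planted boundaries coincide; (iii) architectures *defined by the
absence* of an element — S-WASP and WAML-short (no C/A), the tandem
PPR-VC form (no A), the WH2-less WASH — are scanned after assembly and
resampled if a chance match for the missing element appears. The
generator therefore emulates the architecture grammar of the family, not
the statistics of real proteomes: real linkers are not motif-free, real
domains are not fixed-length consensus derivatives, and real composition
regions have softer edges. Passing the recovery suites demonstrates that
the detectors and rules implement the intended grammar faithfully; it
does not certify recall on genuine divergent homologs, which is why every
threshold is exposed in the configuration for use with real seed
alignments.

Noise is modelled as per-motif point substitution (each residue of each
planted element mutated with the configured probability), and truncation
as Partials (1–5 % trimmed) or Fragments (10–50 %) from either end, with
truth coordinates adjusted and elements lost to trimming removed from the
truth. Coding sequences are reverse-translated with the most frequent
human codon per residue, and requested disablements (internal stops,
start/stop removal, single-nucleotide deletion) injected
deterministically.

## Problem sizes and numerical choices

The bundled verification suites use: 1,000 random sequences of length
50–2,000 for scanner/oracle equivalence (the oracle is an independent
per-gap-length regex enumeration); a 200-protein proteome spanning all 22
architectures for parameter recovery (noise 0: families, subtypes and
planted boundaries exact; 5 % noise: family accuracy within the stated
95 % bound); 500 random trees of 3–8 leaves for Dollo/brute-force
agreement plus a fungal-WASH-loss scenario run end to end; and the exact
logo closed forms (log2 20 for an invariant column, 0 for uniform,
log2 20 − 1 for a 50/50 column, to 1e-9). Logo information content is
computed over non-gap residues per column; the optional small-sample
correction subtracts (20 − 1)/(2 ln 2 · n) and the result is clipped to
[0, log2 20]. All randomness flows through a single integer seed.

## Known limitations

* Ungapped profile scanning cannot follow insertions inside a family
  domain other than the explicitly modelled WMD split.
* The coiled-coil heuristic has no statistical calibration; scores are
  occupancy fractions, not probabilities.
* Pattern and composition scores have no null model (no e-values), so
  cross-kind score comparisons are only meaningful through the documented
  scale ordering.
* Subfamily *classes* that the original analysis derived from
  phylogenetic trees (WAVE classes 1–5, plant classes) are out of scope;
  the classifier stops at the architecture-defined subtypes.
* Dollo reconstruction reports copy-number counts descriptively but does
  not reconstruct duplications; orthology assignment needs gene trees.
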