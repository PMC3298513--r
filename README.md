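# waspfam

Domain-architecture classification and phylogenetic profiling of
WASP-family proteins in R.

WASP-family proteins (WASP, WAVE/Scar, WASH, WHAMM, and the WAWH and WAML
types) are the class-I nucleation promoting factors that switch on the
ARP2/3 actin nucleator. They are defined not by overall sequence
similarity but by an *architecture* of short elements: a family-specific
N-terminal domain (WH1, WHD, WAHD, WMD or IMD), optional basic and
GTPase-binding (CRIB + WAID) regions, low-complexity proline-rich
stretches, and the C-terminal VCA module — one or two WH2 motifs
(`[VILM]-[LM]-[ASED]-[ASDEQ]-[IL]-[KRQ]-x(6..14)-L-[KR]-[KR]-[VTA]`,
the LKKT(V) anchor), a central connector
(`[VILM]-x3-[VILM]-x3-[VILM]-x(0..6)-[KR]{2,3}-x(0..6)-[VILMY]`) and a
D/E-rich acidic terminus, usually ending in tryptophan. `waspfam` is for
anyone who needs to annotate these proteins in new proteomes: it detects
every element class, resolves the detections into one ordered
architecture per protein, assigns family, subtype (S-WASP, tandem forms,
WAWH types I–III, short WAML, WH2-less WASH, ...), completeness class
and pseudogene status, and reconstructs per-family gain/loss events on a
species tree by Dollo parsimony (single gain, minimal losses). A seeded
synthetic-proteome generator with full ground truth makes every stage
testable without any external data.

## Worked example

Simulate a small clade in which the fungi have lost WASH, classify the
proteome from scratch, and reconstruct the events:

```r
library(waspfam)

tree <- ape::read.tree(text = paste0(
  "((((human,mouse)mam,fly)meta,((yeast1,yeast2)dikarya,",
  "chytrid)fungi)opi,amoeba)root;"))
sc  <- generate_scenario(tree, losses = data.frame(family = "WASH",
                                                   edge = "fungi"))
sim <- generate_proteome(generator_config(seed = 42, plan = sc$plan))

profiles <- build_profiles(sim$seeds)            # PSSMs from seed alignments
cls <- classify_proteome(sim$records, profiles,
                         species_map = sim$species_map)
mat <- build_presence_matrix(cls)
mat[, c("WASP", "WAVE", "WASH")]
#>         WASP WAVE WASH
#> amoeba     1    1    1
#> chytrid    1    1    0
#> fly        1    1    1
#> human      1    1    1
#> mouse      1    1    1
#> yeast1     1    1    0
#> yeast2     1    1    0

dollo_reconstruct(sc$tree, mat)$events
#>   family  edge event
#> 1   WASP  root  gain
#> 2   WAVE  root  gain
#> 3   WASH  root  gain
#> 4   WASH fungi  loss
```

Each presence row comes from a full classification: the detectors find
the planted elements, e.g.

```r
cls[1, c("family", "subtype", "architecture")]
#>   family   subtype                      architecture
#> 1   WASP canonical WH1-B-CRIB-WAID-PPR-WH2-WH2-C-B-A
```

and the reconstruction places the single WASH gain at the root and one
loss on the fungal stem — exactly the planted scenario. On real data you
would start from `read_fasta()`, a species map (`read_species_map()`),
and seed alignments for the family domains (`load_profiles_dir()`), then
run the same `classify_proteome()` → `build_presence_matrix()` →
`dollo_reconstruct()` chain; `scan_proteome()` +
`write_domain_annotations()` export per-domain GFF3. A command-line
wrapper lives at `inst/cli/waspfam.R` (subcommands `simulate`, `scan`,
`classify`, `logo`, `profile`).

Sequence-logo tables (per-column frequencies and information content in
bits, with optional small-sample correction) come from `compute_logo()`
on any aligned FASTA.

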