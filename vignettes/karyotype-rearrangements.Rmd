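---
title: "Inferring chromosome fissions and fusions from whole-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosome fissions and fusions from whole-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoshift)
library(dplyr)
```

## The problem

Lepidopteran chromosomes are holocentric: spindle microtubules attach along
the whole chromosome, so fission and fusion products segregate normally and
karyotypes can be reshaped rapidly. Comparing several closely related
genomes against each other and against a species retaining the ancestral
karyotype makes it possible to count fissions and fusions per phylogenetic
branch, decide on which branch each event happened, and ask what kind of
sequence sits at the breakpoints.

karyoshift implements that comparative pipeline for coordinate-level
pairwise alignments (nucmer `show-coords` or PAF):

1. **Blocks** — alignments above 90% identity are sorted along each
   reference scaffold; short "singleton" interruptions are removed; maximal
   runs against one query scaffold become synteny blocks, kept when their
   aligned reference span exceeds 100 kb.
2. **Breakpoints** — the interval between adjacent blocks whose query
   scaffolds differ.
3. **Classification** — with one genome as reference and the others as
   queries, a breakpoint unique to one query is a fission in that query; a
   breakpoint shared by all queries is a fusion in the reference; a
   breakpoint shared by a proper subset is held for polarization.
4. **Polarization** — overlap with synteny breaks against an
   ancestral-karyotype genome tells whether the ancestor is split at that
   locus (so the joined state is derived: a fusion) or joined (the split is
   derived: a fission). Where the ancestor is uninformative, tandem
   telomeric repeats (TTAGG)n / (CCTAA)n at the junction mark a former
   chromosome end and hence a fusion. A per-branch summary reports the
   percentage of breakpoints resolved as fusions within the clade.
5. **Composition** — breakpoint regions, standardized to 100 kb around
   their midpoints (reference side) or two 50-kb windows toward the
   theoretical point of breakage (query side), are tested for
   enrichment/depletion of CDS and transposable-element classes against
   resampled random non-overlapping window sets, with Benjamini–Hochberg
   control across classes, plus a Fisher-exact screen for
   telomere-associated LINE families.
6. **Map concordance** — linkage-map marker tables are binned, offspring
   sex is assigned from normalized Z coverage, genetic-vs-physical
   collinearity is quantified by Spearman's rho, and per-family karyotype
   signatures (segregating fusions/fissions) are extracted.

Every stage is exercised against a built-in karyotype-evolution simulator
whose ground-truth event log is replayable, so the classifier can be scored
exactly.

## The species set and the tree

The simulator evolves a fixed four-taxon topology
`((pop1, pop2), sister), outgroup`: two conspecific populations, their
sister species, and a more distant congener. The simulated ancestral genome
itself stands in for the ancestral-karyotype reference used in
polarization, the role a distantly related species with a conserved
karyotype plays in real analyses. With that reference available, events on
all six branches (four terminal, two internal) are identifiable.

Branch event counts are explicit inputs rather than rates: parameter
recovery can then be checked event for event against the log.

```{r}
cfg <- sim_config(n_chromosomes = 12, element_densities = NULL,
                  singleton_noise_rate = 0, seed = 7)
sim <- simulate_karyotypes(cfg, data.frame(
  branch = c("pop1", "sister", "pop_stem"),
  fissions = c(2, 1, 0), fusions = c(1, 2, 2)))
summarize_log(sim$log)
```

```{r}
th <- thresholds(scale_factor = 1 / 100)
rec <- recover_events(sim, th)
score_recovery(rec, sim$log)
```

## Scale

All defaults describe a desk-scale genome: ~100-kb chromosomes standing in
for ~10-Mb ones, with every genomic distance — block threshold, windows,
margins, element lengths — at 1/100 of its full-genome counterpart
(`thresholds(scale_factor = 1/100)`). Ratios between thresholds and genome
size are preserved, so the geometry of the inference problem is unchanged
while simulations run in seconds. The test suite uses 20–40 chromosomes per
genome, 50 replicate simulations for recovery, 200 replicates for type-I
calibration and 2,000 resampling iterations (the full-scale default is
100,000); these sizes were chosen so the whole suite stays comfortably
interactive.

## Parameters that matter

* `min_identity` (90%, strict) and `min_block` (100 kb unscaled, strict):
  the block filters. Block size is measured as summed aligned reference bp;
  for contiguous alignment tilings this equals the block span, and it is
  robust to a sparse pair of spurious records straddling a wide span. The
  `> 100 kb` filter is applied on the reference side; the query-side span
  of a block is reported but not filtered on.
* `overlap_tolerance` (half the standardized breakpoint window, 50 kb
  unscaled): symmetric padding used whenever breakpoint intervals are
  intersected — across species, and against ancestral synteny breaks.
  Padded intervals that touch are counted as overlapping, so zero-length
  breakpoints (abutting blocks) behave as points.
* `internal_cutoff` (1 Mb): query-side breakpoints further than this from
  both scaffold ends are excluded from composition windows, because such
  cases reflect compound histories already counted elsewhere.
* `telomeric_region` (250 kb): the terminal zone used both for the
  telomere-associated LINE screen and for ancestral chromosome-end
  retention accounting (reused deliberately, to avoid a second free
  window parameter).
* `min_tandem_copies` (5): tandem TTAGG/CCTAA copies required to call a
  telomeric array. Five copies (25 bp) are far beyond random expectation in
  a 100-kb window yet tolerant of degraded remnants.
* `telomere_retention_prob` (1.0): probability that a fusion junction keeps
  a detectable internal telomere remnant. Whether real fusions retain
  arrays at detectable copy number is unknown; the default is the
  idealized detectable-remnant case, and lowering it lets tests probe how
  polarization degrades when the telomere evidence disappears.

## Polarization rules

Rules are applied per event in a fixed order and the applied rule is
recorded, so each call is auditable:

1. fusion call + ancestral-break overlap → confirmed fusion in the joined
   lineage(s);
2. no overlap but telomeric repeats at the junction → fusion restoring the
   ancestral joined state;
3. fusion call + no overlap + no repeats, breakers not a clade → ambiguous
   (recurrent fission or differentially sorted ancestral polymorphism);
4. shared-pair or fission call + overlap → fusion in the joined
   lineage(s);
5. otherwise, when the breaking lineages form a clade → one fission on
   that branch.

A lineage set that is not a clade of the tree is never force-assigned, and
an event whose required evidence is missing is reported `unresolved`. The
clade fusion fraction is `100 × (overlap-confirmed fusions) / (breakpoints
considered)`; ancestral-state restorations (rule 2) are not counted in the
numerator.

## What the simulator emulates — and what it does not

The simulator conserves every ancestral base (each tip genome is a signed
permutation of ancestral segments), places CDS/LINE/SINE/LTR/DNA/RC
annotation intervals to target genome fractions, writes telomere arrays at
chromosome ends and retained fusion remnants, fragments homologous
intervals into ~5-kb alignment pieces with identities in (90, 100], and can
add Poisson-distributed spurious short cross-chromosome records
("singleton noise"). Element enrichment near fusion sites is implemented
as elevated placement density in terminal zones of ancestral chromosomes —
fusions join chromosome ends, so junction windows sample exactly those
zones. (The two-step API fixes the ancestral genome before events are
drawn, so "future fusion sites" can only be anticipated as chromosome
ends.)

Three idealizations matter when reading test results:

* **Event loci are well separated.** Breaks are drawn at least
  `min_event_spacing` (2 kb at desk scale) apart in ancestral coordinates.
  Real genomes show breakpoint reuse; events closer than the overlap
  tolerance are unidentifiable for any implementation of this method, so
  the simulator does not generate them. Passing recovery tests therefore
  says nothing about reused breakpoints.
* **No convergent joins.** No second lineage independently joins a pair of
  ancestral chromosomes already co-resident on one chromosome elsewhere,
  and fusion partners never share ancestral material. When both flanks of
  a junction map to one query scaffold, run-merging by scaffold identity
  cannot see the junction — another intrinsic identifiability limit, not a
  solvable implementation detail.
* **Sequence is metadata.** Nucleotides are uniform-random except motif
  arrays; alignment identities are drawn, not realized by mutation. The
  pipeline consumes coordinates and identities, never base-level
  alignments, so nothing downstream can cheat by looking at sequence
  beyond the telomere scan.

Inversions are simulated but deliberately not called: an inverted segment
stays on the same query scaffold, so run-merging absorbs it, mirroring the
fact that inversion calls in practice require manual, contact-map-assisted
curation. Translocation patterns are reported separately
(`detect_translocations()`): a genuine reciprocal translocation and a
suitable double fission+fusion history produce the same block pattern, so
calls are labelled patterns, not proven mechanisms, and chromosomes both
fissioned and fused are left visible under both interpretations.

## Numerical choices

* Empirical p-values use add-one corrections: the randomization test
  reports `(#{null ≥ observed} + 1) / (n_iter + 1)`; the resampling test
  doubles the smaller add-one tail and caps at 1. Both are exact-valid
  (conservative); the type-I calibration in the test suite measures a
  rejection rate slightly below the nominal 5% as expected for a doubled
  discrete tail.
* Null windows are drawn uniformly, fully inside scaffolds, scaffold chosen
  proportionally to the number of valid starts; resampled window sets are
  non-overlapping within an iteration (rejection with a retry cap) and
  avoid the observed windows. Only the analyzed breakpoint windows are
  excluded from the null pool, not all rearranged regions. The
  randomization null places intervals independently of one another and
  does not preserve chromosome assignment; a chromosome-preserving null
  was considered and rejected as a second free choice without a stated
  justification.
* Block orientation is the majority strand by aligned bp, ties to `+`.
* All thresholds compare strictly (`> 90`, `> 100 kb`), as printed.
* BH adjustment is applied across element classes within one window-set
  type (fusion/fission × reference/query), matching per-panel FDR
  labelling; the grouping is recorded in the output.
* Coordinates are 0-based half-open internally; the coords dialect converts
  from 1-based inclusive at I/O, BED is half-open, and minus-strand coords
  records carry reversed query coordinates.

## Known limitations

* Rule 5's telomere check scans the junction window in the reference
  genome only (the reference is itself a joined lineage). A back-fusion
  private to a single non-reference lineage would be missed; projecting
  windows across genomes through the block map would be needed to close
  this gap.
* The fusion-fraction summary treats the published classification counts
  as exchangeable events; it does not model uncertainty in the underlying
  breakpoint calls.
* `karyotype_from_map()` flags multi-scaffold sex-linked linkage groups
  like any other fusion signature; splitting a Z-linkage group into its
  physical chromosomes (needed under female achiasmy, where all Z markers
  co-segregate) is left to the analyst.
* The telomeric LINE screen counts merged elements, so a family's count
  depends on the merge; the criteria (adjusted p, telomere-count floor,
  half-of-scaffolds presence) follow the published screen with the
  telomere count defaulting to twice the scaffold count.

## A worked composition example

```{r}
cfg <- sim_config(n_chromosomes = 20, element_densities = c(LINE = 0.12),
                  fusion_site_enrichment = c(LINE = 5),
                  singleton_noise_rate = 0, seed = 42)
sim <- simulate_karyotypes(cfg, data.frame(branch = "pop1", fusions = 8))
ref <- sim$tips$pop1
bp <- call_breakpoints(
  build_blocks(emit_alignments(ref, sim$tips$outgroup, cfg), th),
  chromosome_lengths(ref), "outgroup")
win <- standardize_breakpoints(bp, chromosome_lengths(ref), th, "reference")
tr <- element_track(ref)
res <- resample_test(win, tr[tr$class == "LINE", ], chromosome_lengths(ref),
                     n_iter = 2000, seed = 42, class = "LINE")
tidy(res)
```

The observed LINE density in fusion windows sits far above the resampled
null; `autoplot(res)` draws the null distribution with the observed value
marked.
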