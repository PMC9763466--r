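---
title: "Methods: phasing and evolutionary analysis of a cellular T-DNA locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasing and evolutionary analysis of a cellular T-DNA locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some plant lineages carry a *cellular T-DNA* (cT-DNA): an *Agrobacterium*
transferred-DNA fragment fixed in the nuclear genome of an ancestor. Because
a T-DNA insertion site is effectively unique, a shared cT-DNA insert marks a
clade descending from a single transformed plant, and the insert itself is a
clean, paralog-free marker for that clade's evolution. `ctdnatools`
implements the full analysis of one such locus in a diploid, outcrossing
host: a ~5.3 kb cT-DNA with ~950-nt terminal inverted repeats (IRs) and
three pseudogenized T-DNA genes (*acs*, *susL*, *rolB*), embedded in plant
flanking sequence. The package covers:

1. recruiting short reads homologous to a reference copy of the locus and
   separating them into the accession's one or two haplotype alleles;
2. comparing each allele's two inverted-repeat copies and dating the
   insertion from their divergence;
3. classifying structural architecture (standard versus an inverted-center
   rearrangement) and scanning the genes for disrupting mutations;
4. cataloging indels across alleles with a left-aligned position convention,
   including plant-derived inserts flanked by target-site duplications (TSDs)
   and tandem duplications;
5. reconstructing the pre-insertion ("empty") site from an insertion-free
   genome, with TSD and terminal-inverted-repeat detection on the inserts;
6. building a neighbor-joining allele tree, assigning the two principal
   allele groups (A/B) and marker-defined subgroups, and mapping diploid
   allele pairs onto the tree.

A seeded population simulator generates data with exactly this structure,
plus machine-readable truth tables, so every stage is testable without any
external download.

## Coordinate system

All coordinates are 1-based inclusive on a single local window: `flank_len`
nt of plant flank, the cT-DNA, and the other flank (default 200 + 5287 + 200
= 5687 nt). On this window the cT-DNA spans 201..5487, the left IR 201..1148
(948 nt), the right IR 4528..5487 (960 nt), and the genes *acs* 642..1840,
*susL* 2677..3657, *rolB* 4218..4532. These are the published reference
coordinates of the locus; the source material prints both 5287 and 5286 nt
for the cT-DNA length, and the package adopts 5287 (the end minus start plus
one of the printed genomic interval). The right IR is always stored as its
forward-strand interval; reverse-complementation happens only inside repeat
comparisons.

## The simulator: what it emulates

`sim_config()` fixes the study conditions; `build_ancestral_ctdna()` and
`evolve_population()` realize them:

* **Ancestral locus.** The two IRs are identical at insertion time (the
  right arm is an inverted copy of the left end of the T-DNA), and the three
  gene intervals carry intact open reading frames (*rolB*'s tail interrupted
  by the right repeat, as in the real locus).
* **Repeat divergence clock.** With substitution rate `mu` (default
  6.5e-9 /site/yr) and insertion age `T` (default 15 Myr), the two IR copies
  accumulate substitutions so that their pairwise divergence is about
  `mu * T` under the default `one_sided` dating convention, or `2 * mu * T`
  under `two_sided`. The load is decomposed into a *trunk* portion shared by
  all lineages plus the lineage-specific clade and tip loads, so per-allele
  repeat identities are tightly clustered (as observed in real data) while
  each lineage still carries the full clock signal. The post-trunk locus is
  also the run's working reference: a present-day sequence whose IR copies
  have diverged, against which short reads map uniquely.
* **Two clades and diploid pairing.** Alleles descend from two clade
  ancestors (A and B, pairwise divergence `clade_divergence`, default 4%)
  plus private tip divergence (default U(0.1%, 1.7%)), giving pairwise
  allele divergences in the ~0.2-7% range. An accession is heterozygous with
  probability 0.58, and a heterozygous accession pairs alleles across clades
  with probability 0.5 — the cross-group allele pairs characteristic of an
  outcrossing host.
* **Indels.** Clade ancestors carry shared marker indels and each allele
  draws private events from a spectrum modeled on the observed catalog:
  deletions 3-49 nt, insertions 3-40 nt, rare tandem duplications of the
  preceding 12-20 nt, and plant inserts of 20-60 nt flanked by a 5-10 nt
  duplicated target motif. All events are recorded left-aligned against the
  working reference; substitutions keep a small guard distance (5 nt) from
  indel boundaries so the injected and the re-called representation of every
  event coincide exactly. Real plant inserts can be kilobase-scale and
  highly repeated; the simulator's shorter inserts are an explicit
  simplification that keeps them spannable by 150-nt reads.
* **Rearranged lineage.** With per-accession probability
  `p_rearranged_lineage`, an accession carries the inverted-center
  structure: the unique segment between the IRs reverse-complemented,
  followed by two breakpoint deletions. This lineage branches directly off
  the pre-clade trunk (an early-diverging outgroup); its extra repeat load
  is shared by the accession's two alleles, which differ from each other by
  about 2%.
* **Reads.** Uniform-start 150-nt single-end reads from both haplotypes and
  both strands, at `coverage` fold per haplotype (default 50). Read starts
  may overhang the window (the locus sits in chromosomal context; overhangs
  are trimmed), so the window ends are covered. Errors are uniform
  substitutions at `read_error_rate` (default 0 — the acceptance fixtures
  are error-free; tests exercise 0.5% separately). Read names carry no
  information about the haplotype of origin.

Identical configurations produce byte-identical outputs; every source of
randomness derives from `seed`.

What the simulator does *not* model — and hence what passing tests do not
show about real data: sequencing indel errors and quality-score structure,
paired-end inserts, coverage biases, kilobase repeated plant inserts,
post-founding recombination between accessions, gene conversion between the
repeat copies, and selection.

## Read recruitment and allele phasing

`recruit_reads()` anchors reads on the reference by exact 13-mer seeds
(every 7 nt, both orientations), then verifies base-level identity over the
overlap (default `min_identity` 0.8 over at least 50 nt). Reads whose seeds
disagree — indel spanners — and reads with a dense mismatch run at either
end are re-aligned with an affine-gap aligner (match +1, mismatch -1, gap
open -4, extend -1; identity then counted over aligned columns so that
insert-carrying reads are not penalized for their novel sequence). Reads
whose two candidate placements tie exactly (reads from inside a repeat pair
with no distinguishing substitution) are dropped, as standard
mapping-quality filtering would do. Because the working reference's IR
copies are themselves diverged, such ties are rare in realistic data.

`phase_alleles()` then separates haplotypes:

1. Per-read variant ops (substitutions and left-aligned indels) come from
   the anchored comparison, with the affine-gap aligner for flagged reads.
   Alignment ends are trimmed to the outermost clean match runs — the
   aligner cannot soft-clip, so a read starting inside an insertion would
   otherwise smear its overhang into spurious mismatches.
2. Candidate variant columns are substitution sites where two states each
   have at least `min_var_reads = 2` supporting reads and a minor fraction
   of at least 0.2; singletons are treated as sequencing error. Sites within
   5 nt of a supported indel are excluded (alignments there admit
   alternative representations that mimic heterozygosity).
3. Columns co-spanned by reads form linkage blocks; within a block, reads
   are partitioned into two phases by transitive linkage with exact
   agreement at shared columns (`max_within_allele_mismatch = 0`, the
   strictest separation — able to split alleles down to ~10 differences
   over the locus).
4. Cross-block phase is not identifiable from short reads. Blocks are
   joined deterministically: phase 1 carries the reference-agreeing states
   of each block. For fixtures in which one haplotype is locally
   reference-like this reconstructs both haplotypes exactly; for two
   haplotypes that both diverge from the reference, block joins can swap
   phase between blocks (a switch error), which is a documented limitation
   of any read-backed single-locus phasing, not of the implementation.
5. Each group's consensus applies majority-supported ops to the reference
   scaffold. Indel heterozygosity is resolved per group at this stage; the
   support denominator counts only reads spanning the indel footprint with
   at least 25 nt of flank. Uncovered positions become `N`.

Accessions below `min_coverage` (default 10x mean over the locus; about 45
reads of 150 nt over this window is ~1.2x and clearly insufficient) are
flagged `insufficient` with no sequence emitted. A homozygous accession
yields one allele with status `unique`; two distinct consensus sequences
yield status `paired`. Read linkage that is inconsistent with two
haplotypes raises an `excess_haplotypes` warning with the best two-group
partition.

## Repeat comparison and dating

`extract_repeats()` lifts both IR intervals onto the allele through a global
alignment, reverse-complements the right copy, and aligns the two copies
end-free. Percent identity is computed over the columns between the first
and last aligned pair — terminal overhangs (the 12-nt length difference of
the printed intervals) are excluded — and each internal gap run counts as
*one* difference: an indel is one mutational event, and letting a 30-nt
deletion masquerade as 30 substitutions would wreck the molecular clock.

`date_insertion()` converts divergence `d = 1 - identity/100` into an age.
The default `one_sided` convention uses `T = d / mu`, reproducing the published
arithmetic (9.7% at 6.5e-9 /site/yr -> ~14.9, printed as 15 Myr). Standard
theory for two copies mutating independently gives pairwise divergence
`2 mu T`; this `two_sided` convention (`T = d / (2 mu)`) is exposed as a
switch, and the simulator honors whichever convention it is configured
with, so estimator and generator stay consistent. No multiple-hit
correction is applied by default (the published arithmetic uses raw
divergence); Jukes-Cantor is available as an option. Coincident and
repeated substitutions make observed divergence slightly sub-linear in the
mutation load, so simulated ages are recovered with a small (~5-8%)
downward bias — within the 10% design tolerance. Confidence intervals come
from the exact binomial interval on the mismatch count over aligned
columns.

## Structure classification and gene scan

`classify_structure()` locates both IRs on the allele, extracts the central
segment, and orients it against the reference center by shared-k-mer voting
(alignment scores as a fallback for ambiguous cases; a margin below 20
score points is reported `unresolved`). An inverted-center call also
reports gap runs of the oriented alignment as breakpoint deletions — for
the simulated rearrangement these recover the two deletions at the repeat
boundaries, the signature of IR-mediated recombination followed by
deletion. Central segments under 200 nt are not oriented.

`scan_gene_disruptions()` lifts each gene interval onto the allele and
reports premature stop codons (translated in the annotated frame, with a
12-nt context string ending at the stop, matching the printed context
style), frameshifts (gene-internal indels with length not divisible by 3),
and truncations (under half of the interval recovered). Positions index the
first base of the stop codon; the printed convention for one landmark stop
is ambiguous between first and last codon position, so the context string
is always reported alongside. Gene strands come from the feature table, not
from inference.

## Indel catalog

`call_indels()` turns alignment gap runs of at least 3 nt into events,
left-aligned (5'-most equivalent placement) and positioned at the last
unchanged reference base — the convention of the published catalog. Events
closer than 3 nt are flagged `compound` rather than force-decomposed, and
insertions containing `N` (unresolved repeat content) are flagged `partial`
with length as a lower bound. `detect_tandem_duplication()` re-types
insertions whose repeat unit (minimum 3 nt) equals the local reference
flank, with copy number from string periodicity.
`classify_plant_insert()` searches for the longest duplicated target motif
(3-12 nt): under left-alignment the motif appears as the insert's head and
as the reference immediately after the insertion point.
`aggregate_catalog()` merges events by (position, type, sequence) and
counts carrying alleles; `report_hypervariable_regions()` slides a 15-nt
window and reports maximal intervals where some window holds at least 5
distinct modified positions — counting positions rather than rows, so a
single position with many alternative events does not qualify by itself.
On the published catalog's positions this yields exactly the two known
hypervariable regions (438-449 and 2767-2781).

## Insertion-site reconstruction

`align_empty_vs_filled()` chains exact unique 21-mer anchors colinearly
(diagonal runs merged into blocks, then a longest-chain dynamic program),
refines block boundaries base-by-base, and reports every inter-block gap:
`filled_only` structures (the cT-DNA and sequences ligated to it) and
`empty_only` structures (sequence lost in the filled lineage, and inserts —
such as a transposon — present only in the empty-site genome). Overlaps
created by duplicated flank sequence are trimmed to a canonical placement.
`detect_tsd()` finds the longest motif (3-15 nt) duplicated on both sides
of a call, accepting the shifted placements in which one copy lies inside
the call, and shrinks the interval to the insert core so the reported
length excludes both flanking copies. `detect_terminal_ir()` scans prefix
lengths longest-first for a prefix whose reverse complement matches the
suffix within `max_mismatch`. Repetitive flanks lower anchor density and
therefore boundary confidence; with unique flanks and error-free sequences
boundaries are exact.

## Tree and concordance

`align_alleles()` builds a reference-anchored multiple alignment: each
allele is aligned globally to the reference once (alignments are cached
across stages), rows are stacked on reference columns, and insertion blocks
are added as extra padded columns. Columns with more than 20% gaps are then
dropped — the deterministic counterpart of removing indel columns by hand
before tree building. A generic progressive aligner is unnecessary here
because every allele is a haplotype of one known locus; anchoring on the
reference is both faster and deterministic. Inverted-center alleles are
re-oriented to the standard architecture (`standardize_structure()`) before
alignment so their center is colinear.

`build_tree()` runs neighbor joining on Jukes-Cantor distances with
pairwise gap deletion, nonparametric bootstrap (default 100-200
replicates), outgroup rooting and ladderization. Neighbor joining replaces
a maximum-likelihood engine deliberately: it is deterministic and fast at
this scale, and the Newick export allows re-estimation with an external ML
tool when engine fidelity matters. `assign_groups()` takes the two children
of the ingroup root as the principal groups, names the marker-richer side A
(the most frequent marker, ties broken lexicographically), derives
marker-defined monophyletic subgroups (A1, A2, ... ordered by marker
frequency), and lists carriers found in the wrong group as exceptions —
the marker-topology discordances. Early-diverged rearranged alleles stay
outside the A/B split (label `O`). `pair_spans()` tabulates, per
heterozygous accession, the groups of its two alleles and the cross-group
fraction.

## Numerical choices and degenerate inputs

* All pairwise alignments use match +1, mismatch -1, gap open -4, extend -1.
* Ties are broken deterministically throughout (leftmost column, larger
  read group, lexicographic sequence), so identical inputs give identical
  outputs; trees are ladderized to a canonical representation.
* Alleles whose repeat regions are mostly deleted return `unresolved`
  repeat pairs; dating refuses unresolved pairs and alignments under 100
  columns.
* An empty recruitment result is an empty set, not an error; an allele
  identical to the reference yields an empty catalog.
* Problem sizes used by the test-suite: populations of 5-60 accessions at
  20-50x coverage, 50 phasing replicates, 100 dated alleles, bootstrap
  10-50 — chosen so the whole suite exercises every stage at full locus
  scale while remaining quick on a laptop.

## Known limitations

* Cross-block phasing is a convention, not an inference (see above); with
  dense enough heterozygosity the locus is one block and phasing is exact.
* Phasing represents alleles on the reference scaffold, so a structural
  rearrangement cannot be discovered from 150-nt reads alone — rearranged
  architectures are detected on assembled or simulated alleles
  (`classify_structure`), matching how the rearranged lineage was found in
  practice.
* Allele counts follow `alleles = unique + 2 x paired`.
* Polyploid phasing (more than two haplotypes) is out of scope; excess
  linkage conflicts are reported, not resolved.
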