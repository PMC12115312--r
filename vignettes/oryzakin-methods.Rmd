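---
title: "Methods: genus-wide analysis of CPK-family kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genus-wide analysis of CPK-family kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oryzakin)
library(dplyr)
```

## The analysis

Calcium-dependent protein kinases (CPKs) and their relatives — CPK-related
kinases (CRKs), PEP-carboxylase kinases (PPCKs), PEP-carboxylase-related
kinases (PEPRKs) and calcium/calmodulin-dependent kinases (CCaMKs) — form a
gene family whose copy number, domain architecture, splice-variant
repertoire and expression balance vary across closely related plant genomes,
including the subgenomes of allopolyploids. `oryzakin` implements the
desk-scale computational core of such a genus-wide survey:

1. **Domain architecture**: detect the kinase domain, EF-hand motifs and
   calcium-binding sites in each protein; cluster the architectures within an
   ortholog group into a representative type and variants.
2. **Family assignment**: label each protein by its best-scoring seed under
   local alignment, cross-checked against per-family architecture rules.
3. **Duplication typing**: classify duplicate gene pairs into whole-genome
   (WGD), tandem (TD), proximal (PD), transposed (TRD) and dispersed (DSD)
   modes over gene orders, with collinear blocks found by chain dynamic
   programming.
4. **Splice-variant consequences**: map each transcript variant's
   architecture onto a nine-type truncation taxonomy.
5. **Homoeolog expression bias (HEB)**: classify each 1:1 homoeolog pair and
   tissue as balanced, dominant toward either subgenome, or not expressed.
6. **Atlas summaries**: per-tissue means, dominant tissues, and
   duplicate-pair divergence calls.

Every stage is driven, in testing, by a synthetic-data generator that plants
known truth; the generator is first-class, exported code.

## Motif and domain model

Real surveys scan proteins with profile tools; the two profiles involved
(kinase domain, EF-hand motif) are summarised here by sharp, testable
proxies, with `load_external_domains()` as the fidelity path for annotation
tables produced by profile scanners on real data.

**Calcium-binding site.** The canonical 12-coordinating-residue EF-loop
pattern (PROSITE PS00018),

```
D-x-[DNS]-{ILVFYW}-[DENSTG]-[DNQGHRK]-{GP}-[LIVMC]-[DENQSTAGC]-x(2)-[DE]-[LIVMFYW]
```

is matched by a built-in PROSITE-syntax engine. A strict match over a
13-residue window is a functional calcium-binding site.

**Degenerated EF-hand.** Published surveys report EF-hands that "cannot bind
calcium" without an operational rule. Here a window is a degenerated EF-hand
when all non-coordinating position classes hold, at most two of the
coordinating positions {1, 3, 5, 9, 12} are violated, and at least one
invariant anchor survives (D at position 1, or D/E at position 12).
Overlapping candidates are resolved greedily left to right — deterministic
and order-independent — with strict matches preferred at equal start.

**Kinase domain.** Three ordered anchor motifs stand in for the kinase
profile: the Walker-lysine context `[AV]-x-[IV]-K`, the catalytic `HRD`, and
the activation-segment `DFG`. The domain is *complete* when an ordered
triple spans 180–340 residues (the empirical length range of plant kinase
domains); a strict subset of anchors, or an inadmissible span, is
*incomplete*; no anchors, no domain.

**Lobes.** In a protein with a kinase domain and at least two EF-hands, the
last two EF-hands constitute the C-lobe of the calmodulin-like domain and
all preceding ones the N-lobe. This generalises the canonical 2+2 split of
4-EF CPKs to 3-EF proteins consistently with the reported C-lobe position of
the single calcium site in the CPK7/CPK23 group.

**Representative vs variant architectures.** Within a group, signatures
(kinase state plus the ordered calcium-site flags, e.g. `K|E*E*E*E*`)
supported by a single protein are excluded as solos; the maximal-support
signature is the representative, ties broken by more calcium sites, then
lexicographically. This mirrors the majority/minority language of published
domain-landscape analyses.

## Family assignment

Queries are scored against labelled seed proteins by Smith–Waterman local
alignment (BLOSUM62, gap open 11 / extend 1 — the standard protein-search
scoring). The best seed's family wins; scores below a raw-score floor
(default 100) yield no label. A raw-score floor replaces a database E-value
cutoff because no search-database statistics exist at this scale; the floor
is configurable and the emitted scores let real tabular-BLAST results be
substituted. The ambiguity residue `X` is scored 0 against everything and
never satisfies a pattern position, keeping motif and similarity calls
conservative. Architecture rules (CCaMK: complete kinase + 3 EF; CPK:
complete kinase + 3–4 EF; CRK: kinase with at most one calcium-blind
EF-hand; PPCK/PEPRK: kinase only) are checked after labelling and
violations attached as warnings rather than overriding the similarity vote.

## Duplication typing

Collinear blocks are maximal chains of homolog pairs with strictly monotone
gene-order ranks on both chromosomes (same or inverted orientation) and
consecutive rank gaps of at most `max_gap = 25`; chains shorter than
`min_anchors = 5` are discarded. The chain dynamic programme is exact for
this constraint structure, which the tests confirm against an exhaustive
subset oracle on small instances. Gene-order ranks derive from start
positions per chromosome, ties broken lexicographically by gene id, because
duplication typing needs a total order and input formats do not provide one.

Modes are assigned hierarchically, one mode per gene, in the priority order
WGD > TD > PD > TRD > DSD used by hierarchical duplication classifiers:

* **WGD** — the pair anchors a collinear block (anchors-only by default; a
  `block_envelope` option also accepts genes inside a block's rank
  envelope);
* **TD** — same chromosome, adjacent ranks;
* **PD** — same chromosome, rank distance in (1, `proximal_window = 10`];
* **TRD** — exactly one member sits at an ancestral locus (an anchor of a
  block against the outgroup genome) and the pair is in no intra-genome
  block;
* **DSD** — everything else; genes with no homolog pair are singletons.

## Splice-variant taxonomy

A variant's label depends on its *absolute* domain content relative to a
reference with a complete kinase and 3–4 EF-hands: complete kinase with
fewer EF-hands than the reference → Types 1–4 (3/2/1/0 EF-hands); an
incomplete kinase → Type 5 regardless of EF-hands; kinase absent → Types
6–9 (4/3/2/1 EF-hands). The absolute mapping (rather than a deficit
relative to the reference) is the only reading consistent with 3-EF
reference proteins whose 3- and 2-EF kinase-less variants are labelled
Types 7 and 8; an exhaustive sweep in the tests confirms the taxonomy tiles
all nine labels. Calcium-site flags are reported but do not affect the
label. Variants gaining domains relative to the reference are left
unclassified rather than forced into the taxonomy.

## Homoeolog expression bias

A gene is *expressed* in a tissue when its replicate-mean FPKM is strictly
above 0.5. Pairs in which neither member is expressed are `NOT_EXPRESSED`.
Otherwise the members' mean FPKMs are normalised to relative subgenome
contributions (a sub-threshold member keeps its measured value) and the
pair takes the category of the Euclidean-nearest ideal vector among
(1, 0), (0, 1) and (0.5, 0.5). These ideals are the geometrically natural
choice for the three categories and are configurable. Ties go to BALANCED —
the conservative direction, producing fewer false bias calls — which places
the decision boundary exactly at a dominant share of 0.75: dominance
requires p strictly above it. A pair with exactly one expressed member is
still classified (it will be dominant) rather than dropped, with the
unexpressed member's atlas cell flagged separately. Replicates are averaged
arithmetically before all rules. Inclusion requires at least one expressed
member by default; `require_both = TRUE` applies the stricter reading.

Atlas displays record `log10(FPKM + 0.01)` (so zero expression maps to −2)
and `log2(FPKM + 1)`; the 0.01 pseudocount is a display choice only.
Duplicate-pair comparisons call `one_silent` when exactly one member is
expressed nowhere, `redundant` when the tissue-profile Pearson correlation
is ≥ 0.8 and the mean absolute log2 ratio (pseudocount 1) is ≤ 1, else
`diverged`; with fewer than three tissues the correlation is undefined and
ratios alone decide.

## The synthetic-data generator

The generator emulates the statistical structure of a multi-genome,
multi-tissue survey, not its sequences:

* **Genomes.** Defaults: one cultivated-like diploid, two wild diploids,
  one allotetraploid contributing two subgenome units, and an outgroup in
  unduplicated ancestral order (ancestral-locus evidence for TRD requires
  one). Four chromosomes of 60 genes each keep every stage exercised while
  the whole pipeline runs in seconds.
* **Family census.** Per genome: 1 CCaMK, 29 CPK, 5 CRK, 2 PEPRK, 3 PPCK —
  the fixed census reported for cultivated accessions (40 genes).
* **Proteins.** Each family has a canonical layout (CPK: complete kinase +
  4 calcium-binding EF-hands; CCaMK: + 3; CRK: one degenerated EF-hand;
  PPCK/PEPRK: kinase only). Family members share a template whose linker
  segments mutate at rate 0.05 per residue, giving realistic within-family
  identity while cross-family identity is confined to the anchors. Linkers
  are drawn from an alphabet that provably cannot seed an EF window or a
  kinase anchor, and EF-loop residue pools are restricted at three
  positions so no shifted window can satisfy even the relaxed rule — the
  generator's closure (rescanning reproduces the planted layout) is by
  construction, not by rejection sampling. Degenerate loops flip 1–2 of the
  interior coordinating positions {3, 5, 9} to excluded residues, keeping
  both invariant anchors.
* **Duplications.** Each planted event realises its definitional signature:
  WGD copies a window of `wgd_block_anchor_count` (default 8) consecutive
  genes to another chromosome; TD/PD insert the copy at rank distance 1 /
  5–6; TRD transposes the copy to the head of another chromosome while the
  parent keeps its ancestral locus; DSD does the same but its ortholog
  group is absent from the outgroup, so neither member is
  outgroup-collinear. Transposed and dispersed copies land more than
  `max_gap` ranks away from any appended block so they cannot chain into
  one, and event groups are excluded from WGD windows.
* **Expression.** Per pair and tissue, total abundance is log-uniform in
  [2, 200] FPKM, split by the planted category with dominant fraction
  `p_dom = 0.9`; every replicate value carries multiplicative log-normal
  noise (sd 0.2 on the log scale — the standard RNA-seq abundance noise
  shape; surveys rarely state one). `NOT_EXPRESSED` pairs draw both values
  uniform below the 0.5 filter. The default tissue panel is root, stem,
  leaf, panicle with two replicates.
* **Splice variants.** Variant proteins are assembled from the canonical
  template's segments (truncated terminal exons for EF-side and kinase
  truncations, a skipped kinase exon for the EF-only types), so each
  variant realises exactly its requested type.

What the generator does **not** emulate: sequence-level homology structure
beyond the family template, annotation errors, expression correlation
across tissues, partial assemblies, or profile-scanner false positives.
Passing tests therefore demonstrate the correctness of the decision rules
under their stated definitions, not robustness to noisy real annotations —
for real data, the external-domain bypass and tabular-homology readers are
the supported entry points.

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; text formats use
  their native conventions at the boundary (GFF/GTF 1-based inclusive).
* Molecular weight uses average residue masses plus one water (`X` counts
  110 Da); the isoelectric point bisects the Henderson–Hasselbalch net
  charge with Bjellqvist-style pKa values (EMBOSS table selectable) until
  the absolute net charge falls below 1e-4 — an interval-width stop alone
  would not bound the residual charge for long peptides, whose charge
  slope grows with residue count.
* Lipidation prediction is a transparent consensus: the N-myristoylation
  glycine pattern `G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}` at position 2, and any
  cysteine in the first 25 residues as a palmitoylation candidate; a
  protein with either site is predicted membrane-targeted, matching the
  reported correspondence for this family. These are deliberately simple
  heuristics, labelled as such, not reimplementations of machine-learning
  predictors.
* Architecture clustering operates per ortholog group by default (the `by`
  argument accepts any grouping column, e.g. an evolutionary subgroup);
  group-level clustering is the finer, safer default when the subgroup
  structure is unknown.

## Problem sizes

The test suite and the acceptance script run the sweep taxonomy (30 cells),
200 variants per splice type, 1,000 homoeolog pairs, 1,000
pattern-oracle sequences of length ≤ 400, 100 chain instances of ≤ 12 pairs
against an exhaustive subset oracle, the default 6-unit genome set with one
planted event per mode, and 500 closure proteins — sizes chosen so each
stage's statistical claim is meaningful while the full run stays in the
minutes range on one core.

## Known limitations

* The anchor-motif kinase proxy and the strict/relaxed EF rule are
  deliberately sharp; real proteins scanned this way will show fewer, not
  more, motifs than profile tools report. Use external annotation tables
  for production scans.
* The similarity floor is a raw-score heuristic, not an E-value; family
  assignment on real proteomes should use curated seeds.
* HEB ideal vectors are configurable but default to the geometric choice;
  analyses replicating a specific published calibration should set them
  explicitly.
* Ks/Ka dating, subgenome phasing, transcript assembly and coding-potential
  assessment are out of scope.
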