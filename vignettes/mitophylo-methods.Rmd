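---
title: "mitophylo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitophylo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Human mitochondrial DNA is analysed almost universally as a set of
*differences* from the revised Cambridge Reference Sequence (rCRS,
NC_012920.1, 16 569 bp). A haplotype is the list of those differences —
substitutions (`709A`), insertions (`455.1T`), deletions (`16183-`) — and a
*haplogroup* is a named branch of the rooted mtDNA phylogeny, defined by the
motif of variants that arose on that branch. The *full signature* of a
haplogroup accumulates every branch motif from the root (mt-MRCA) down to the
node; a trailing `!` marks a back mutation that reverts an ancestral variant
to the reference allele.

Classification of a query haplotype against the tree is a nearest-profile
search: for every node the *cost* is the weighted count of unexplained
differences — *private* variants present in the query but not the signature,
plus *missing* motif variants absent from the query at positions the query
actually covers. A low cost means a confident assignment; a high cost means
sequencing problems or an uncharacterized branch.

`mitophylo` implements this stack end to end: notation parsing, alignment and
difference-coding of raw mitogenomes, the tree with signature accumulation
and nomenclature-aware growth, cost-based classification, quality control,
pathogenic-variant masking, metadata normalization, and a synthetic-data
generator that makes the whole pipeline testable offline.

## The bundled reference is a labelled synthetic stand-in

The GenBank rCRS record cannot be redistributed inside this package, and the
package is built to run fully offline. It therefore bundles
`inst/extdata/rCRS_synthetic.fasta`, a deterministic 16 569-bp stand-in
generated by `syntheticRCRS()`. Coordinates whose reference allele or local
context is documented in the difference-coding literature carry the real
value — the reference bases implied by prefixed tokens such as `G709A`,
`A13105G!` or `A0750G`; the 303–315 poly-C stretch with `310T`; the A-run
ending at 5752 (which is what makes a deletion reported at 5747 normalize to
`5752-`); and the 16 183 poly-A/poly-C context. All other bases are
seeded-random. Every coordinate-level behaviour the package tests is anchored
on the documented loci; for production analyses, pass the real NC_012920.1
FASTA to the `ref`/`refPath` arguments — nothing else changes.

## Alignment and the 3' convention

Full mitogenomes differ from the reference by well under a hundred edits, so
a full dynamic-programming matrix is wasteful. `alignToRCRS()`:

1. anchors the query with exact 31-mers near both sequence ends (a sequence
   that does not start near position 1 and end near 16 569 is rejected as
   mis-rotated rather than silently rotated);
2. runs a banded global alignment with affine gaps (Gotoh, in C++) over the
   covered window. Defaults: match +2, mismatch −2, IUPAC-compatible pair +1,
   gap open 6, gap extend 1, band width 60. The mismatch/gap balance makes a
   single substitution always cheaper than a deletion–insertion pair, which
   is the behaviour difference coding assumes; the band width of 60 exceeds
   any realistic cumulative indel displacement in human mtDNA;
3. converts the alignment to variants. `N` bases become *unknown positions*
   (no-calls), IUPAC ambiguity codes become ambiguity substitutions such as
   `3243R` (heteroplasmy calls; set `ambiguityAsUnknown = TRUE` to mask them
   instead), and truncated ends narrow the covered range instead of
   fabricating deletions.

Indel placement inside repeats is ambiguous; the package always reports the
3'-most equivalent placement (`shift3Prime()`), the phylogenetic convention
that makes indel notation comparable across datasets. The operation is
idempotent and is property-tested against an exhaustive-placement oracle on
small random sequences.

Indels inside length-heteroplasmy-prone regions (defaults 303–315, 515–524,
568–573, 16 180–16 194 — the poly-C/AC-repeat stretches plus the standard
forensic regions) are unstable within individuals and are excluded from motif
definitions; `dropLHIndels()` applies that rule, and the classifier ignores
such indels on both sides of the comparison.

## Tree, signatures, nomenclature

`HaplogroupTree` stores named nodes with branch motifs; names are unique
tree-wide and the root motif is empty. Signature accumulation replays motifs
root-to-node: a substitution at an already-variant position replaces the
earlier allele; a back mutation (odd number of `!`) removes the accumulated
variant at its position; a doubled `!!` nets out to the derived state. A back
mutation with no matching ancestral variant is kept literally with a warning
— dropping it silently would hide a curation error.

Subclade names alternate letter and number levels: a parent ending in a
digit gets lettered children (`W7` → `W7a`), a parent ending in a letter gets
numbered children (`T2h` → `T2h3` when `T2h1`/`T2h2` exist). Beyond `z` the
letter sequence continues bijectively (`aa`, `ab`, …); the convention has no
precedent at that depth, so the continuation is a documented choice.
`integrateSubclades()` resolves asterisk-named proposals with the smallest
unused suffix and rejects per item — flagged names, unknown parents, name
collisions, duplicate sibling motifs — while processing continues, producing
a reassignment report of (proposed, assigned, status).

## Clustering

Three nested groupings summarize assignments:

* **macrohaplogroup** — the nearest ancestor-or-self among the 35 top-level
  labels (A…Z, HV, L0–L7, R0, R+16189); walking upward from the node makes
  the deepest label win, so an H node reports H rather than HV, R0 or R.
* **first-level split** — the shallowest letter(s)+number ancestor that is
  not itself a macro label (`C1b` → `M8`, `H1a` → `H1`), starred when the
  cluster subtree contains names that do not extend the label (M8 contains
  the C and CZ clades). Macro label as fallback.
* **lineage** — R if the root path contains R, else N, else M, else L (with
  L0–L7 sublabels available).

The *phylopath* renders the placement as every ancestor-or-self that is a
macro label or matches the split pattern, hyphen-joined:
`L3-N-R-R0-HV-H-H3`. Published renderings are not perfectly self-consistent
about whether a letter+number *node itself* terminates its own path (an H3
path printed with a trailing H3, an I2 path without its I2); a single rule
cannot reproduce both, so the package always includes the matching self,
which reproduces every other worked example.

## Classification

The classifier scans every node (≤ ~6 500 at full scale — exhaustive scan is
cheap and exact; greedy descent can be trapped by back mutations), scores the
query against each full signature and returns the minimum cost. Ties break
toward the deeper node, then the lexicographically smaller name — both
arbitrary but deterministic.

The reference weight tables used by established estimation services are not
published, so the default `weightScheme()` is unit weight per variant with a
configurable override table (by token or by position). That reproduces the
*structure* of cost-based estimation — cost equals the number of unexplained
differences — while remaining fully auditable; cohort summaries under this
scheme show mean private counts tracking mean costs in the low-deviation
range, the qualitative behaviour expected of such pipelines. Substitutions at
16 519, a hypervariable position conventionally excluded from motifs, are
ignored by default. A query heteroplasmy whose IUPAC set contains the
expected signature allele satisfies the motif at zero cost; one that does not
leaves the motif variant missing and the query variant private. Missing motif
variants at uncovered or no-call positions are never penalized — a truncated
or N-masked genome should not be punished for what it cannot show.

Deviation categories partition the cost axis at 10/30/50
(minimal/moderate/substantial/extensive). Published category tables leave
small gaps between their observed bin edges (e.g. nothing observed between
29.96 and 30.03); the package closes the bins right-continuously so every
nonnegative cost has exactly one category.

## Quality control

`qcSequence()` evaluates every criterion without short-circuiting — more than
30 `N`s, called length below 16 519 bp, more than 30 ambiguous (non-ACGTN)
symbols, more than 50 internal gap characters, blocklist, organism label,
reference identifiers — so a verdict lists *all* triggered reasons.
Thresholds are strict inequalities: exactly 30 `N`s passes. Cost-based
exclusion is a separate verdict because it requires classification first; the
threshold is configurable and intentionally not hard-coded (500 as the
screening default, 100 as the stricter reporting variant seen in accounting
tables). For the accounting report a multi-reason sample is attributed to the
first triggered criterion in a fixed order (blocklist, Ns, length, ambiguity,
missing, cost, taxon, reference) so per-criterion counts sum exactly to the
number excluded; conservation (retained + excluded = batch size) is asserted
inside the function.

## Pathogenic masking

Screening is exact by (position, kind, derived allele): a homoplasmic
`14484C` entry does not hit a heteroplasmic `14484Y` call and vice versa,
because the two report genuinely different observations. An optional
permissive mode lets a heteroplasmic catalog code hit its component base
calls (`3243R` matching `3243G`) for users who want carrier-level
sensitivity. Multi-token entries (the paired `9205- 9206-` deletion) require
every token. Profiles with two or more distinct hits are flagged as
multi-pathogen-carrying (mpc).

`maskMotifs()` removes catalog variants from every branch motif — a masked
variant is never retained anywhere, including motifs that happen to list it
redundantly — and audits resolution: a node whose motif empties, or siblings
whose full signatures become identical, would mean masking degraded the
phylogeny's discriminating power, so both events are flagged. "No adverse
impact" is thus an operational criterion, not an assertion. Masking is
idempotent and never touches non-catalog variants.

## Metadata normalization

The geographic alias map (misspellings and synonyms to canonical countries,
nonspecific descriptors to `unresolved`) ships as an editable TSV seeded with
the standard worked examples; any study's full correction dictionary is a
replaceable input, not ground truth, and no geocoding service is consulted.
Technology grouping maps platforms into Illumina, Sanger, IonTorrent,
Roche 454 and Other; multi-platform annotations take the first-listed
platform's category with a `*` (the ordering rule is a documented choice —
annotation order is the only signal available). Unrecognized or empty
annotations become `No data`.

## Synthetic data: what a green test does and does not establish

The generator emulates the data world the pipeline targets: signature-derived
genomes, Poisson private substitutions (default λ = 3, the typical load of
well-classified cohorts), occasional heteroplasmy codes, N runs below the
QC threshold, deletions written as `D` (a frequent submitter artifact),
truncated ends, and configurable pathogenic spikes, with a truth table for
every injected feature. Private variants deliberately avoid motif positions,
length-heteroplasmy regions and 16 519, so under unit weights the
classification cost of a clean sample equals its injected private count
exactly — that identity is what the pipeline properties assert.

What the generator does **not** emulate: mutation-rate heterogeneity across
sites, recurrent/hotspot mutations, realistic indel load, selection,
contamination or chimerism. A green pipeline test therefore establishes the
correctness of the machinery (alignment, difference-coding, signature
algebra, scoring, accounting), not the biological fidelity of any particular
cohort-level statistic. Full-release cohort statistics (tens of thousands of
genomes from public archives plus access-restricted forensic data) are out of
desk-scale reach by construction and are replaced by these property checks.

## Numerical and degenerate-input choices

* Coordinates are 1-based, closed intervals throughout (Phylotree/EMPOP
  convention).
* Variant ordering is total: (position, substitution < deletion < insertion,
  insertion index, derived allele); re-parsing canonical output is a fixed
  point for every accepted dialect.
* Lowercase derived alleles are uppercased, **except** a bare lowercase
  letter after a leading reference base (`A16183c`), which is rejected as
  ambiguous — lowercase is reserved for extended-IUPAC uncertainty, where `c`
  can mean either a C call or a deletion. A permissive flag accepts it as an
  uppercase call.
* A token with digits but no derived allele (`C16187`) is rejected rather
  than guessed at; leading zeros (`A0750G`) are tolerated.
* Empty queries whose covered range is entirely no-call are refused as
  uninformative rather than assigned to the root.
* All generator randomness flows through a caller-isolated RNG (the caller's
  `.Random.seed` is saved and restored), so identical seeds give identical
  outputs without side effects.

## Limitations

* Only rCRS-oriented, rCRS-rotated full mitogenomes are aligned; there is no
  control-region-only mode and no automatic re-rotation.
* The synthetic reference stand-in is faithful only at documented loci;
  coordinate-level results at other positions are internally consistent but
  not biologically meaningful until the real reference is supplied.
* The weight scheme is structural (unit weights), not a reimplementation of
  any service's proprietary cost table; agreement with such services is
  expected at the level of assignments and private/missing sets, not numeric
  cost values.
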