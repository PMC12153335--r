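# mitophylo

Tools for curated human mtDNA phylogenetics: difference-coded haplotypes,
haplogroup trees, and cost-based haplogroup estimation.

## The problem

Human mitochondrial DNA analysis — in forensics, population genetics and
medical genetics — runs on a shared convention: a genome is reported as its
set of differences from the revised Cambridge Reference Sequence (rCRS,
NC_012920.1, 16 569 bp), and samples are placed on a rooted phylogeny of
named **haplogroups**, each defined by a motif of variants. Keeping such a
phylogeny curated requires a stack of small, exacting operations: parsing the
several notation dialects in circulation (`G709A`, `709A`, `16183-`,
`16183del`, `455.1T`, `14484Y`, `A13105G!`), placing indels at their 3'-most
(phylogenetically aligned) position, accumulating branch motifs into full
root-to-node signatures with back-mutation semantics, resolving asterisk
nomenclature for newly proposed subclades, scoring query haplotypes against
every node, excluding low-quality sequences reproducibly, and masking known
pathogenic variants out of the classification scheme without degrading its
resolution.

`mitophylo` implements that stack for R, with a synthetic-data generator so
every stage is testable offline, and a command-line pipeline binding the
stages together.

## The core model

For a query haplotype *q* and a haplogroup *g* with full signature *S(g)*
(the union of branch motifs from mt-MRCA to *g*, with later substitutions
replacing earlier alleles and back mutations `x!` removing the ancestral
variant), the assignment cost is

```
cost(q, g) = Σ w(v), v ∈ private(q, g)  +  Σ w(v), v ∈ missing(q, g)
```

where `private` are query variants not explained by the signature, `missing`
are signature variants absent at covered, called positions, and *w* is a
configurable weight scheme (unit weights by default; substitutions at 16 519
and length-heteroplasmy-region indels ignored). The estimated haplogroup is
the cost-minimizing node over an exhaustive scan of the tree; costs bin into
minimal (≤ 10), moderate (≤ 30), substantial (≤ 50) and extensive (> 50)
deviation.

**Reference note:** the bundled reference is a clearly labelled *synthetic*
stand-in (`inst/extdata/rCRS_synthetic.fasta`) that carries the documented
rCRS alleles and homopolymer contexts at the loci the package's behaviour
depends on, with seeded-random bases elsewhere; the GenBank record itself is
not redistributable here. Pass the real NC_012920.1 FASTA via the
`ref`/`refPath` arguments for production use. See the methods vignette.

## Worked example

```r
library(mitophylo)
ref <- loadReference()                      # bundled synthetic rCRS stand-in

# a genome differing from the reference by one substitution, one
# heteroplasmy and one deletion inside the A-run at 5747..5752
s <- ref
substring(s, 709, 709)   <- "A"
substring(s, 3243, 3243) <- "R"
s <- paste0(substring(s, 1, 5746), substring(s, 5748, nchar(s)))

h <- alignToRCRS(s, ref, sampleId = "demo")
h
#> Haplotype 'demo' | range 1-16569 | 3 variant(s), 0 unknown position(s)
#>   709A 3243R 5752-

tree <- haplogroupTree(
  c("mt-MRCA", "A", "A1", "A1a"),
  c(NA,        "mt-MRCA", "A", "A1"),
  list("",     "709A",    "5752-", "1555G"))

classifyHaplotype(h, tree)
#> 'demo' -> A1 | cost 1.00 (minimal) | 1 private, 0 missing
#>   private: 3243R
```

Three things to read off: the deletion was reported at its 3'-shifted
position `5752-` (not 5747, where it was applied — the phylogenetic
convention); the sample lands on `A1` because its variants explain that
node's full signature exactly; and the heteroplasmy call `3243R` is the one
unexplained difference, giving cost 1 and a *minimal* deviation rating.

## Command-line pipeline

```sh
Rscript inst/exec/mitophylo simulate --out sim --seed 3 --n-nodes 40
Rscript inst/exec/mitophylo encode   --fasta sim/cohort.fasta --out enc
Rscript inst/exec/mitophylo qc       --fasta sim/cohort.fasta --out qc
Rscript inst/exec/mitophylo classify --haplotypes enc/haplotypes.tsv --tree sim/tree.json --out cls
Rscript inst/exec/mitophylo screen   --haplotypes enc/haplotypes.tsv --out scr
Rscript inst/exec/mitophylo export   --tree sim/tree.json --out exp   # Newick + flat signatures
```

Other subcommands: `mask` (pathogenic masking with resolution audit),
`integrate` (asterisk-nomenclature subclade integration), `cluster`
(macrohaplogroup / first-level split / lineage / phylopath columns). Every
run writes a JSON manifest beside its outputs.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script rebuilds a 5435-node baseline tree with the synthetic generator,
feeds 945 proposed subclades (two of them on the rejection list) plus 31
further haplogroups through `integrateSubclades()`, and reports the number
of accepted proposals and the resulting node count as JSON.

## Layout

- `R/` — variant notation, alignment (`src/` holds the C++ banded aligner),
  tree and signatures, classification, QC, pathogenic screening/masking,
  metadata normalization, synthetic data, CLI.
- `inst/extdata/` — synthetic reference, pathogenic catalog TSV, geographic
  alias seed files.
- `vignettes/mitophylo-methods.Rmd` — the model, parameter rationale, design
  decisions and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
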