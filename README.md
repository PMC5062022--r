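# gh1profiler

Culture-independent surveys of **glycoside hydrolase family 1 (GH1)
β-glucosidases** — the enzymes that finish cellulose hydrolysis by cleaving
cellobiose to glucose — typically combine four kinds of evidence: metabolic
profiling of the source community on BIOLOG phenotype plates, PCR of a
conserved gene fragment with family-wide degenerate primers, dereplication
and identity-based classification of the resulting clone libraries, and
distance-based phylogenetics of the deduced proteins. `gh1profiler`
implements that whole workflow as a tested R package, together with a
synthetic-data generator that produces GH1-like families, clone libraries
and plate readings with known ground truth, so every stage can be validated
end to end without environmental samples.

It is aimed at microbial ecologists and enzyme miners who want a
reproducible, scriptable version of this survey design — and at method
developers who need a controlled test bed for degenerate-primer and clone
-library analytics.

## What it computes

**Community-level physiological profiling (CLPP).** Per 96-well plate, ODs
at 590 nm are corrected by the blank well A1 (clamped at 0) and summarised
as

- average well-colour development, `AWCD = Σ ODᵢ / 95`,
- substrate richness `S` = number of wells with corrected OD strictly
  greater than 0.25,
- Shannon–Weaver diversity `H = −Σ pᵢ ln pᵢ`, with `pᵢ = ODᵢ / Σ ODᵢ`,

plus per-substrate Welch t-tests (reported as −log₁₀ p) and average-linkage
clustering of substrate profiles cut at height 1.0.

**Degenerate primer design.** Columns of a family protein alignment are
profiled by information content `IC = log₂20 + Σ f log₂ f`; the most
conserved 9-residue blocks are back-translated codon-unions written as
minimal IUPAC codes, with fully degenerate positions replaced by **inosine**
(counted once in degeneracy, 0 toward GC). Primer pairs are ranked by total
degeneracy, then Tm and GC balance.

**In-silico PCR and RFLP.** Degenerate/inosine-aware site matching on both
strands, amplicon prediction between primer footprints, complete AluI
(`AG^CT`) digestion, and gel-resolution grouping of fragment patterns
(20 bp bins) for clone dereplication.

**Classification.** Six-frame translation, local alignment (BLOSUM62,
affine gaps) against a labelled reference panel, verification of the two
catalytic glutamates (~200 residues apart), novelty calls (<70% identity =
low identity; ≤75% = candidate novel OTU) and genus/division community
tables.

**Phylogenetics.** Protein p-distances with pairwise deletion (optional
Poisson correction), a deterministic neighbor-joining implementation
(lowest-index tie-break, negative branches clamped with the deficit moved
to the sister edge), bootstrap support by column resampling, newick output
via `ape`.

## Worked example

```r
library(gh1profiler)

# a synthetic GH1-like family, then primers straight off its alignment
fam <- simulate_protein_family(family_spec(n_taxa = 60, sub_rate = 0.2, seed = 101))
des <- design_primers(fam$proteins)
des$blocks[[1]]; des$blocks[[2]]; des$pairs[[1]]
#> Conserved block at column 40 (9 aa): TLYHWDLPQ  [mean IC 4.32 bits]
#> Conserved block at column 331 (9 aa): DNFEWAEGY  [mean IC 4.32 bits]
#> BGLF1 (27, forward): 5' ACIYTITAYCAYTGGGAYYTICCICAR 3'  deg=64  GC=40.7%  Tm=56.7C
#> BGLR1 (27, reverse): 5' RTAICCYTCIGCCCAYTCRAARTTRTC 3'  deg=64  GC=44.4%  Tm=58.2C
#> expected amplicon: 900 nt (blocks at columns 40 and 331)
```

The two top-ranked blocks are the family's anchor peptides; their
back-translations are 27-mers of degeneracy 64 (2⁶ from five Y and one R
position; every four-fold position is inosine), and the pair brackets a
900 nt fragment of the barrel domain. The full pipeline — plates, primers,
PCR, RFLP, classification, tree — runs from one seed:

```r
res <- run_pipeline(pipeline_config(seed = 7))
res
#> GH1 beta-glucosidase survey pipeline (synthetic run)
#>   seed 7 | 40 taxa | 20 clones at error rate 0.01
#>   primer pair: ACIYTITAYCAYTGGGAYYTICCICAR / RTAICCYTCIGCCCAYTCRAARTTRTC (expected amplicon 900 nt)
#>   RFLP groups: 12 | low-identity 0.0% | novel 0.0%
#>   community: 8 genera in 2 divisions

res$clpp[res$clpp$substrate_class == "C", ]
#>   sample_id substrate_class n_substrates      awcd richness  shannon
#> 1        S1               C          190 0.4818130      139 5.068462
#> 5        S2               C          190 0.5500493      154 5.090388
#> 9        S3               C          190 0.5319753      150 5.076017
```

Clones simulated at 1% read error still classify at ~100% identity to
their source taxa (hence 0% novelty), and the 20 clones collapse to 12 AluI
RFLP groups. A published-style clone-identity table can be tabulated
directly:

```r
tab <- read_identity_table(system.file("extdata", "clone_identities.tsv",
                                       package = "gh1profiler"))
community_table(tab[tab$library == "CD", ])
#> 20 clones in 14 genera across 3 divisions
```

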