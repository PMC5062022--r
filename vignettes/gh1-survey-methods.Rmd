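---
title: "Methods behind gh1profiler: CLPP, degenerate primers, RFLP, identity classification and NJ trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gh1profiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh1profiler)
```

`gh1profiler` models the standard survey design for family 1 glycoside
hydrolase (GH1) β-glucosidase diversity in environmental communities. This
vignette explains each stage's model and assumptions, the parameters that
matter, the numerical conventions, and what the synthetic generator does and
does not emulate.

## Community-level physiological profiling

A phenotype plate read is a 96-well vector of endpoint absorbances at
590 nm; well A1 holds the substrate-free blank. We subtract the blank from
every substrate well and clamp negative values to zero: a negative
blank-corrected OD has no physical interpretation as activity and would make
the Shannon proportions ill-defined. The three indices are

* `AWCD = Σ ODᵢ / n`, with `n = 95` substrate wells on a standard plate
  (dimensionless OD);
* richness `S`: the count of wells with corrected OD **strictly** greater
  than 0.25 — the threshold separates genuine colour development from dye
  background, and strictness is the literal reading of "greater than";
* Shannon–Weaver `H = −Σ pᵢ ln pᵢ` in natural-log units, with
  `pᵢ = ODᵢ/Σ ODᵢ` and the convention `0·ln 0 = 0`. An all-zero profile has
  no defined diversity and is signalled as an error rather than returned as
  0, which would be indistinguishable from a single-substrate community.

Replicate plates are averaged **before** index computation (one endpoint
profile per sample and class). Averaging first treats replicates as
technical, which matches how triplicate plates of a single inoculum are
used; computing indices per replicate and averaging after would instead
propagate read noise into the nonlinear `H`.

Per-substrate differences between two groups of plates use Welch's
two-sided t-test, the default family of microarray-style viewers; p values
are reported raw (with `-log10(p)`), and Benjamini–Hochberg correction is
available but off by default, matching common CLPP practice of screening on
raw p at α = 0.05. When both groups are constant the test statistic is
resolved directly (equal means: t = 0, p = 1; unequal: p floored at the
smallest positive double so `-log10 p` stays finite).

Substrate clustering uses Euclidean distance on AWCD-normalised profiles
(each sample column divided by its mean corrected OD — removing overall
activity differences before comparing utilisation shapes), average linkage,
and a tree cut at height 1.0. Neither the metric nor the linkage is forced
by the survey design; these are the most common CLPP defaults, and both the
cut height and normalisation are parameters.

## Conserved-block detection and degenerate primers

Alignment columns are profiled by gap-excluded residue frequencies and
information content `IC = log₂ 20 + Σ f log₂ f` (bits). We deliberately omit
the small-sample logo correction: for alignments of a few hundred family
members the correction is negligible, and the uncorrected form has an exact
closed form for tests (a perfectly conserved column scores `log₂ 20 ≈
4.32`; a 50/50 column loses exactly 1 bit).

Candidate blocks are fixed-length windows (default 9 residues, the length
of the classical GH1 anchor peptides `TLYHWDLPQ` and `DNFEWAEGY`) in which
every position has at most `max_variants_per_pos` residues above a
frequency floor and whose mean IC passes `min_mean_ic` (default 3 bits ≈
70% average conservation). Overlapping windows are resolved greedily, best
first. The consensus is the maximum-probability residue per position, ties
broken alphabetically for determinism.

Back-translation takes, per residue, the position-wise union of all its
standard codons and writes each base set as its minimal IUPAC code. A
position whose set is all four bases becomes **inosine**: inosine is a
single synthesisable universal-pairing nucleoside, so it counts 1 toward
degeneracy (where N would count 4) and 0 toward GC. Two- and three-base
sets stay as IUPAC codes. This rule exactly regenerates the classical GH1
anchor primers (`ACI YTI TAY CAY TGG GAY YTI CCI CAR` from `TLYHWDLPQ`,
degeneracy 2⁶ = 64), and it knowingly over-covers: `YTI` for Leu also
matches Phe codons, which is the accepted price of low degeneracy. An
optional concrete 5' clamp can be prepended; no clamp/truncation heuristics
are applied automatically, because such adjustments are lab-specific.

Melting temperature uses the composition-only GC-fraction formula
`Tm = 64.9 + 41 (E[G+C] − 16.4)/N` °C with expected GC counts under the
degenerate sets. At 17–27 nt the Wallace rule is inappropriate, and
nearest-neighbour thermodynamics is not meaningful for degenerate pools;
the linear formula is deterministic, monotone in GC, and adequate for
*ranking* pairs, which is its only use here.

Pairing selects among the **top-conserved blocks only** (default: the top
2) and ranks pairs lexicographically by total degeneracy, then |ΔTm|, then
|ΔGC|, then block position. Conservation gates the candidates because an
unconserved window with a low-degeneracy consensus would rank first yet
amplify almost nothing; degeneracy only discriminates among blocks that are
actually conserved. The expected amplicon spans the forward-block start to
the reverse-block end: `3(start_r − start_f) + 3·len_r` nt — 900 nt at the
default geometry.

## In-silico PCR and RFLP dereplication

Primer–template matching is set-membership per position (inosine matches
all four bases). A template `N` is an unknown base and fails matching by
default — a conservative choice, since predicting a product through unknown
sequence is speculation; a permissive flag reverses this. The reverse
primer is stored 5'→3' and located via its degenerate reverse complement on
the plus strand. Products include both primer footprints, as physical
amplicons do, and all coordinates are 1-based inclusive so that
`substr(template, start, end)` is the product.

Digestion (default AluI, `AG^CT`) is simulated to completion — consistent
with an overnight digest — by cutting at every site occurrence; fragment
lengths therefore always sum to the input length, which is the suite's
standing invariant. Gel grouping bins each fragment to
`round(length/bin_width)` with a 20 bp default bin, a plausible resolution
for small fragments on 3% agarose; two clones share a group iff their
binned sorted multisets coincide, which makes grouping an equivalence
relation by construction. Binned grouping is deliberately *coarser* than
exact pattern identity: distinct templates can legitimately collapse into
one gel group, exactly as on a real gel.

## Identity classification and novelty

Clones are translated in all six frames (partial trailing codons dropped;
any codon containing an ambiguous base becomes `X`) and aligned locally
(Smith–Waterman, BLOSUM62, affine gaps, opening 10 / extension 4) against
every panel protein; the best score wins, with ties broken by ascending
reference id, then frame order. Percent identity is identical pairs over
aligned columns excluding gaps, rounded half-up to an integer (half-up
because published tables print integers and R's banker's rounding would map
x.5 inconsistently). The aligner and matrix come from Biostrings, so
results are bit-reproducible on a given installation.

The GH1 fold carries an acid/base and a nucleophile glutamate ~200 residues
apart; a hit is verified by mapping the reference's two catalytic columns
through the local alignment and requiring `E` at both mapped clone
positions with a separation of 200 ± 40 residues. The ±40 tolerance absorbs
alignment wander and family-level indels while still rejecting single-domain
artifacts; fragments that do not span both columns fail and are flagged
`partial`.

Novelty thresholds follow the survey convention: identity < 70% marks a
low-identity sequence, ≤ 75% a candidate novel OTU, so low identity implies
novelty. Both bounds are parameters. Community structure is tabulated per
genus (first name token, square brackets stripped) and per division, with
the three Proteobacteria classes counted as distinct divisions.

## Neighbor joining and bootstrap

Distances default to the amino-acid p-distance with pairwise deletion (the
common default for protein NJ in survey work); a Poisson correction
`−ln(1−p)` is available. NJ is implemented in the package rather than
delegated, because two behaviours are contractual here and not exposed by
library implementations: Q-ties break deterministically by the lowest index
pair, and a negative branch length is clamped to zero with the deficit
moved to its sister edge, preserving the path length through the join. NJ
is consistent on additive matrices, and the test suite verifies exact
recovery (topology and branch lengths) against trees drawn at random, with
`ape::nj` as an independent topology oracle. Bootstrap support resamples
alignment columns with replacement, rebuilds the tree, and reports the
percentage of replicates containing each original bipartition; the
conventional 1000 replicates are the default, while tests run at 10–200
replicates — a size chosen to exercise the machinery, not to estimate
support precisely.

## The synthetic generator: what it does and does not emulate

The generator draws a random ancestor of 450 residues, writes the two
anchor peptides at columns 40 and 331 (291 residues between block starts,
making the predicted amplicon 900 nt — the size class of the ~876 bp
fragment family-wide GH1 primers amplify; the exact published figure has no
stated reference sequence, so the geometry targets its neighbourhood rather
than the digit), fixes glutamate at two catalytic columns, and substitutes
every other site i.i.d. uniformly over the 19 alternatives at `sub_rate`
(default 0.2; families align at roughly this diversity after trimming).
The default family size is 247 taxa, the size of a full family alignment;
pipeline examples and tests simulate 20–60 taxa, which already saturates
the block-detection behaviour.

One point deviates from a literal reading of the geometry sometimes quoted
for this family: with blocks at 40/331, catalytic columns at 170/370 would
put the nucleophile *outside* the amplified fragment, contradicting the
requirement that the fragment contain both glutamates. The defaults here
are 120 and 320 — exactly 200 residues apart, inside the amplicon, clear of
both anchor blocks.

Clone libraries draw amplicons from labelled templates with i.i.d. point
errors (no indels), plates add truncated Gaussian noise to per-substrate
activities, and a single global seed is split deterministically across
sub-generators, so every run is reproducible end to end.

Deliberately **not** modelled: phylogenetically realistic evolution (no
rate heterogeneity, indels, or codon bias), chimeras, sequencing-specific
error profiles, kinetic (time-course) plate reads, and primer
thermodynamics beyond composition. Consequently, a green synthetic suite
demonstrates the correctness of the computations and the internal
consistency of the pipeline — not that the primers would perform at a bench,
nor that real habitats would show any particular diversity pattern.

## Degenerate inputs and edge conventions

* All-zero activity profiles: Shannon errors; AWCD and richness return 0.
* Constant groups in the t-test: handled analytically (see above).
* Digest of a site-free sequence: one fragment, the whole length.
* A primer longer than its template: zero sites, not an error.
* Identical sequences into NJ/bootstrap: valid, deterministic output.
* Alignment ties everywhere resolve by fixed order (alphabetical residue,
  lowest id, lowest index pair) so that no result depends on hash or input
  order.

## Known limitations

Identity values from local alignment against a small synthetic panel are
not comparable to database-wide searches; published identity tables should
be consumed directly (`read_identity_table()`) when reproducing published
counts. The Tm formula is for ranking only. Gel binning at a fixed width is
a crude instrument model. The NJ implementation is quadratic-per-join and
intended for clone-library scale (tens of taxa), not for large phylogenies.
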