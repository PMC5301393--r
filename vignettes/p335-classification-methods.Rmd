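---
title: "Classifying lactococcal P335 phages: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lactococcal P335 phages: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p335typer)
```

## The problem

The P335 phages are a genetically heterogeneous group of *Siphoviridae*
infecting *Lactococcus lactis*, a persistent threat to dairy fermentations.
They are divided into four sub-groups (I–IV) on two coupled signals: overall
proteome relatedness, and the architecture of the **adhesion module** — the
gene span from the tail tape measure protein (TMP) through to, but not
including, the lysis cassette (holin + lysin). The module encodes the distal
tail protein (Dit), the tail-associated lysin (Tal), and either a
single-gene receptor binding protein (RBP) or a multi-component baseplate
(BppU/BppA/BppL). Because baseplate genes move by modular exchange, the two
signals can disagree: a phage may group with one sub-group by proteome
content while carrying another sub-group's RBP. `p335typer` computes both
signals, reconciles them, and flags discordance.

## The classification model

### Protein comparison

Pairwise comparison is Smith–Waterman local alignment with BLOSUM62 and
BLAST-convention affine gaps (open 11, extend 1: a gap of length $L$ costs
$11 + L$). E-values follow the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the gapped BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$) and a search space fixed per run as query
length × total database residues, for reproducibility. A hit is retained
when

* $E \le 10^{-4}$,
* identity $> 50\%$ (strict inequality; identity counts gap columns in the
  denominator, the BLAST convention), and
* **both** sequences are covered over at least 50% of their length.

The coverage rule is stated in the source classification scheme as "across
at least 50% of the amino acid sequence" without saying which sequence;
this package applies it to both, because the bidirectional procedure is
symmetric and the stricter reading avoids domain-only spurious orthology.
Pairs whose length ratio makes the identity/coverage thresholds provably
unsatisfiable (identity $\le$ len$_\text{short}$ / (min-coverage ·
len$_\text{long}$)) are skipped without aligning; the bound is exact, so the
retained-hit set is unchanged.

The aligner is a small C++ routine rather than a call to
`Biostrings::pairwiseAlignment()` purely for speed (the all-against-all
stage was ~10× slower through the generic interface); its tie-break rules
(first-maximum cell in row-major order, match-state preference) are
documented and mirrored by an independent pure-R dynamic-programming oracle
in the test suite.

### Bidirectional best hits and Markov clustering

For each ordered phage pair, each query's best-scoring subject is computed
(ties: higher identity, then lexicographic subject id); a protein pair is a
bidirectional best hit (BBH) when each is the other's best. BBH pairs form
an undirected graph weighted by percent identity (bounded, deterministic,
and independent of search-space conventions — the reason identity is
preferred over $-\log_{10} E$ as the edge weight).

Markov clustering (MCL) is implemented from scratch on a dense
column-stochastic matrix: self-loops equal to each node's maximum incident
weight (standard regularisation, prevents period-2 alternation), then
repeated expansion (matrix square), inflation (entrywise power 2.0,
column renormalisation) and pruning (entries < 1e-5), until the elementwise
change falls below 1e-8. Clusters are read from the attractor structure;
overlapping attractor systems are merged, and a node attracted to several
clusters is assigned to the lexicographically smallest family id (the tie
count is reported). The reference mclblastline settings behind the original
analysis are not published; inflation 2.0 and the aggregation rule below
are this package's own, configurable choices, and nothing downstream
depends on matching the reference implementation bit for bit.

### From families to phage groups

A phage's profile is its set of protein families. Pairwise similarity is
the Dice coefficient $2|A \cap B|/(|A|+|B|)$ and groups are connected
components of the graph with edges at similarity $\ge 0.5$. The published
analysis derives groups from MCL output without stating the aggregation
rule; Dice-over-families with components at 0.5 is recorded here as an
explicit design decision. Each group is then labelled with the modal RBP
sub-group of its members, so "proteome sub-group" and "RBP sub-group" can
be compared per phage; disagreement sets `concordant = FALSE`, reproducing
the discordance phenomenon (a sub-group II phage carrying a BK5-T-like
RBP domain).

### Adhesion-module typing

The module is located by homology to a labelled reference panel: the TMP is
the best panel-TMP homolog (fallback: the longest ORF ≥ 700 aa, since TMPs
are by far the longest tail genes), and the module ends just before the
first holin/lysin homolog downstream (with no detectable lysis cassette the
module runs to the genome end, with a warning). Role calls use panel
homology at identity > 0.3 over ≥ 0.5 coverage — the 30% floor follows the
weakest relatedness tier drawn in the source study's baseplate comparisons
(30–50% identity), and both are configurable. A raw-score floor of 40
avoids evaluating obvious noise; at the 30%-identity tier on the shortest
panel references a qualifying hit scores well above it.

Architecture classes come from size bands placed between the populated
size clusters of the sub-group exemplars:

| component | class | band (aa) | exemplars |
|---|---|---|---|
| Dit | classical | ≤ 270 | 253 (sub-group II) |
| Dit | classical_p2 | 271–350 | 290–298 (III/IV) |
| Dit | evolved | ≥ 450 | 512–548 (I) |
| Tal | short_p2like | ≤ 450 | 371–386 (III/IV) |
| Tal | long_PGNase | ≥ 850 | 906–961 (II) |
| BppU | extended | > 400 | 672–891 variants |

Lengths falling in a band gap resolve to the nearest band with a warning
(ties to the lower band). Note one deliberate divergence from the source
tables: the 298-aa sub-group III Dits are labelled "classical" there but
fall in the `classical_p2` band here, consistent with the accompanying text
that they are closer in size to the 936-group phage p2 Dit; sub-group
labels never rest on `dit_class` alone.

RBP sub-group assignment compares the candidate against one RBP
representative per sub-group; fused Tal-RBPs (sub-group I) are compared on
their C-terminal half only, where the receptor-interacting head domain
lives. Below threshold the call is `novel`. A hit to a fused reference that
covers less than 70% of it is reinterpreted as RBP-domain homology — this
is what recognises a standalone BK5-T-like RBP gene inside a sub-group II
backbone.

### In silico PCR

The typing panel is the published seven-pair set with expected products of
784 (sub-group IV), 268, 554 and 412 (sub-group II variants), 128
(sub-group III), 1002 bp (sub-group I), plus a BppU-detecting pair with no
validated size. Matching is exact by default — the wet assay was validated
for specificity, and exact matching is the conservative in silico analogue;
when mismatches are allowed, the 3'-terminal 5 nt of each primer must still
match (polymerase extension requires a matched 3' end). Amplicon length
spans both primers inclusively, the standard product-size convention.
Multiplex reactions are simulated as independent single-pair reactions:
primer competition — the reason the wet multiplex under-performed — is
deliberately not modelled. Labels are called within a 20-bp size tolerance
(a gel-resolution analogue; configurable). The CWPS strain-typing scheme
(442 bp = type A, 183 = B, 686 = C, 891 = rmlB control) ships with
*synthetic* primer sequences because the real ones belong to a different
publication; users type real strains by supplying their own panel TSV.

### Plaque statistics

Titres are `sum(counts) / sum(volumes)` with an exact (Garwood) Poisson 95%
interval on the summed counts. Zero counts are censored at the detection
limit `1/volume` — a bound, never a point value — so "unable to produce
plaques" is representable without a pseudo-count. Efficiency of plaquing
(EOP) is the titre ratio test/reference; a reduction of ≥ 4 log10 classifies
a phage calcium-dependent (the source's Results tier; its Discussion says
5-log for the same phages — the discrepancy is documented, the threshold
configurable, and 4 is the default). Antibody neutralisation uses the same
EOP machinery with tiers at ≥ 4 log (strong) and ≥ 2 log (partial); the
enumerated tiers leave 1–2 log unspecified, which this package folds into
`not_neutralized` (thresholds configurable). A pre-bleed serum control more
than 0.5 log away from EOP 1 flags the result non-specific.

## What the synthetic data emulates — and what it does not

`make_phage()` produces linear genomes at the scale of the sequenced
isolates (~30–40 kb, 45–60 ORFs): background ORFs drawn from a
per-sub-group seed pool, the adhesion module at the exemplar component
sizes, the holin/lysin pair immediately downstream (so the module-boundary
rule is exercised), and GC-steered intergenic filler. Every planted protein
is a reference seed mutated by independent per-residue substitution
(probability = divergence, default 0.05 — within-sub-group relatives in the
study sit at ~90–95% identity), and every placement is recorded in a truth
object. Generators are pure functions of their seed.

Known simplifications:

* Reference-panel proteins are deterministic pseudo-random sequences of the
  documented lengths, not the real proteins (the package never downloads);
  files and objects say "synthetic" where this matters.
* Back-translation uses the lexicographically first codon per residue, so
  coding GC is fixed by composition; the filler steer is clamped and the
  realised genome GC (~41%) overshoots the 36% target of real isolates.
  "Tuned toward" is therefore approximate by construction.
* All planted genes sit on the plus strand; no mosaicism, recombination,
  codon-usage realism or sequencing error.
* Cross-sub-group homology of true module proteins (real sub-group III and
  IV Dits are relatives) is not emulated; synthetic sub-groups are cleanly
  separated.

A green planted-truth test therefore establishes that the pipeline recovers
what was planted under the stated divergence — not that it reproduces wet
phenotypes (host range, EOP values, neutralisation titres), which are
inputs here, never outputs.

## Numerical choices and degenerate inputs

* MCL column sums are asserted to be within 1e-9 of 1 after every
  inflation; non-convergence after 200 iterations is an error naming the
  iteration count, never a silent truncation.
* Alignment tie-breaks are fixed and documented so the DP oracle can demand
  exact equality; scores are integer-valued sums, so `==` on doubles is
  safe.
* A single-phage input skips grouping with a warning but still types the
  module and runs PCR; an empty module, a missing Dit/Tal, or two claimants
  for a singleton role are errors, not guesses.
* ORF finding is an explicit stand-in for real gene prediction: external
  annotations are authoritative when supplied; the de-novo finder exists so
  synthetic and test genomes need no external caller. ORF counts of real
  genomes are not a validation surface (the original annotations were
  manually curated under unstated length/start policies).
* Circular genomes wrap in both ORF scanning and primer-site search;
  amplicons may span the origin.

## Limitations

Multiplex primer competition, detection limits in whey, structural-domain
(HHPred-style) assignment, phylogenetic tree construction and genome
assembly are out of scope. The accession-based reproduction targets
(printed amplicon sizes on the real genomes, the 94% LC3/Dub35A RBP
identity, the 253-aa sub-group II Dit) require downloading the study's
GenBank records and are therefore not asserted by the offline test suite;
the machinery to check them (`read_annotations()`, `align_pair()`,
`predict_amplicons()`) is the same code exercised by the planted-truth
tests.
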