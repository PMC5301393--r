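# p335typer

Classification and in silico typing of lactococcal P335 bacteriophages.

The P335 phages are a heterogeneous group of *Siphoviridae* infecting
*Lactococcus lactis* starter strains — the second most frequently isolated
phage group in industrial dairy fermentations. They are divided into four
sub-groups (I–IV) by overall proteome relatedness and by the architecture
of the **adhesion module**: the gene span from the tape measure protein
(TMP) through the distal tail protein (Dit), tail-associated lysin (Tal)
and receptor binding protein (RBP) or multi-component baseplate
(BppU/BppA/BppL), up to but not including the lysis cassette. Because
baseplate genes move by modular exchange, a phage can group with one
sub-group by genome content while carrying another sub-group's RBP —
`p335typer` computes both signals and flags such discordance.

For whom: phage researchers and starter-culture QC labs who need to place
new P335 isolates into the sub-group scheme, simulate the published PCR
typing assays, or analyse plaque-assay phenotypes.

## What it computes

* **Proteome grouping** — all-against-all Smith–Waterman (BLOSUM62, gap
  11/1, Karlin–Altschul E-values), retained at E ≤ 1e-4, identity > 50%,
  coverage ≥ 50% of both sequences; bidirectional best hits; from-scratch
  Markov clustering (inflation 2.0) into protein families; phage groups as
  connected components of Dice similarity ≥ 0.5 over family profiles.
* **Adhesion-module typing** — module location by panel homology
  (TMP → lysis cassette), role assignment, size-band architecture calls
  (classical/classical_p2/evolved Dit; short/long/fused Tal; extended
  BppU), RBP sub-group I–IV or novel (fused Tal-RBPs compared on the
  C-terminal half).
* **In silico PCR** — the published seven-pair P335 typing panel with
  expected products 784/268/554/412/128/1002 bp (+ a size-unvalidated
  BppU pair), exact matching with a 3'-anchor rule, multiplex as
  independent reactions, and the CWPS strain-typing scheme
  (442/183/686 bp + 891 bp rmlB control).
* **Phenotype statistics** — titres with exact Poisson intervals and
  explicit censoring, efficiency of plaquing (≥ 4-log reduction in EDTA vs
  10 mM CaCl2 = calcium-dependent), antibody-neutralisation tiers, and
  host-range × CWPS cross-tabulation.
* **Synthetic data** — phage genomes with planted adhesion modules, primer
  sites, Poisson plaque counts and host-range matrices, all with recorded
  ground truth, so the whole pipeline is testable offline.

## Worked example

Generate five synthetic phages — two sub-group II, two sub-group IV, and
one chimera (II backbone carrying a sub-group I RBP, mirroring naturally
occurring discordant isolates) — and classify them:

```r
library(p335typer)
templates <- list(phage_template("II"), phage_template("II"),
                  phage_template("IV"), phage_template("IV"),
                  phage_template("II", rbp_subgroup = "I"))
coh <- make_phage_set(templates, divergence = 0.05, seed = 42)
run <- run_classify(coh$phages)
run$report[, c("phage_id", "proteome_group", "proteome_subgroup",
               "rbp_subgroup", "dit_class", "tal_class", "concordant")]
```

```
[run_classify] input: 5 phages, 261 proteins
[run_classify] retained hits: 440
[run_classify] BBH pairs: 220
[run_classify] protein families: 103 (MCL iterations: 18)
[run_classify] proteome groups: 2
[run_classify] adhesion modules typed: 5
  phage_id proteome_group proteome_subgroup rbp_subgroup    dit_class    tal_class concordant
1 syn01_II          grp01                II           II    classical  long_PGNase       TRUE
2 syn02_II          grp01                II           II    classical  long_PGNase       TRUE
3 syn03_IV          grp02                IV           IV classical_p2 short_p2like       TRUE
4 syn04_IV          grp02                IV           IV classical_p2 short_p2like       TRUE
5 syn05_II          grp01                II            I    classical  long_PGNase      FALSE
```

The two templates separate into two proteome groups; each group's
sub-group label (the modal RBP sub-group of its members) matches the
planted truth; the chimera groups with II by proteome but carries a
sub-group I RBP, so it is flagged discordant (`concordant = FALSE`) — the
in silico analogue of the asterisked phages in the source classification.

PCR-type a genome carrying sub-group III primer sites 128 bp apart:

```r
g <- genome_record("survey1", random_dna_string)   # any 3 kb genome
g <- plant_primer_sites(g, p335_panel()$LC3, spacing_bp = 128, position = 700)
simulate_multiplex(g, p335_panel())
#> <typing_result> survey1: 1 amplicons; labels: sub-group III
```

Calcium dependence from plaque counts (titre ratio EDTA vs CaCl2):

```r
ref <- titre(make_plaque_data(2e8, 1,    1e-5, 3, seed = 7, condition = "Ca_10mM"))
tst <- titre(make_plaque_data(2e8, 1e-5, 1e-2, 3, seed = 8, condition = "EDTA_0.1mM"))
ref
#> <phage_titre> phage [Ca_10mM]: 2.03e+08 pfu/ml (95% CI 1.98e+08-2.08e+08)
compute_eop(tst, ref)
#> <eop_result> phage: EOP 9.7e-06 (5.01 log), dependent
```

A 5-log reduction classifies the phage calcium-**dependent** (threshold:
≥ 4 log, configurable).

## Command line

```sh
exec/p335 simulate --subgroups II,II,IV,IV --out synth/
exec/p335 classify --genomes synth/genomes.fasta --orfs synth/orfs.tsv --out results/
exec/p335 pcr --genome isolate.fasta                 # published 7-pair panel
exec/p335 survey --genomes fasta_dir/
exec/p335 eop --plaques plaques.tsv --test EDTA_0.1mM --ref Ca_10mM
exec/p335 crosstab --matrix hostrange.tsv
```

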