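# crossomics

Cross-species comparative transcriptomics and drug-target conservation for
translational research. When a model species (a minipig, a macaque, a dog) is
evaluated against human, the recurring questions are the same: which genes
mark which tissue, how similar are homologous tissue transcriptomes, which
genes vary too much between individuals to be reliable endpoints, which human
genes are pseudogenized in the model, which transcripts exist in the model
lineage only, and whether the residues a drug actually touches are conserved.
`crossomics` implements each of these analyses as a tested, reusable R
function, together with seeded synthetic-data generators that plant
recoverable ground truth for every stage.

## What it computes

**Tissue-specificity signatures.** For gene *g* with per-tissue mean
expression *x₁ … xₙ* (linear scale), the Gini index

&nbsp;&nbsp;&nbsp;&nbsp;G = Σᵢ Σⱼ |xᵢ − xⱼ| / (2 n² x̄)

is 0 for uniform expression and approaches (n−1)/n for single-tissue
expression. A gene joins the signature of its maximally expressing tissue when
G ≥ 0.7. Sample-level enrichment for a signature is the mean per-gene z-score
(a rank-percentile alternative is available).

**Normalization.** Quantile normalization (via limma) and global
rank-invariant set normalization (GRSN): genes with stable expression ranks
anchor a lowess fit of each sample's M-vs-A deviation from a reference, which
removes intensity-dependent distortions between platforms or species.

**Expression variability.** Per (gene, tissue, species) the coefficient of
variation CV = sd/mean on the linear scale; genes with CV > 10 % are flagged
as highly variable, species are compared with a two-proportion chi-square
test, and gene sets are tested for over-representation with the
hypergeometric distribution (BH-adjusted).

**Pseudogene screen.** Candidate orthologs are globally aligned (affine-gap
Needleman–Wunsch via Biostrings) against a functional reference CDS and
scanned for start-codon loss, frameshifting indels (net length not a multiple
of 3) and premature in-frame stops read in the reference frame. A gene is
called pseudogenized only when events appear in *every* required genome and
the gene has no annotated functional protein.

**Species-specific lncRNAs.** A four-stage cascade — contig length > 500 nt,
no protein-coding hit (identity ≥ 70 % over ≥ 0.5 coverage), absence from all
outgroup genomes, RPKM > 10 — followed by presence classification
(full / partial / absent) across the in-group genome panel and read-vote
detection (≥ 95 % identity over the full read) in unassembled WGS read sets.

**Drug-target contacts.** Ligand contact residues (any heavy-atom pair within
4.5 Å, inclusive) from a PDB structure, mapped through a cross-species
multiple alignment and reported as conserved / substituted (I272F-style
notation) / missing.

## Worked example

```r
library(crossomics)

sim <- simulate_expression(expression_sim_spec(
  n_genes = 2000, n_signature_genes_per_tissue = 20,
  n_high_cv_genes_per_tissue = 40, seed = 1))

sigs <- extract_signatures(sim$matrices$minipig, threshold = 0.7)
sigs$liver
#> tissue_signature 'liver' (synthetic): 20 genes, Gini >= 0.7

vt <- cv_table(sim$matrices$minipig)
count_high_variance(vt, cutoff = 0.10)[1:3, ]
#>       tissue species n_genes n_high fraction
#> 1 cerebellum minipig    2000     39   0.0195
#> 2   cerebrum minipig    2000     40   0.0200
#> 3      colon minipig    2000     40   0.0200

compare_species_proportions(900, 16032, 300, 16032)
#> two-proportion test: 900/16032 vs 300/16032
#>   chi-square = 311.7, p = 9.478e-70, fold = 3
```

The signature call returns exactly the 20 genes planted per tissue (the
home-tissue upshift of 6 log2 units forces the Gini index above 0.7); the
variability counts sit at the 40 planted high-CV genes per tissue give or
take binomial fluctuation; the proportion test shows how a 3-fold difference
in highly variable gene counts between species at this panel size is
overwhelming evidence (p ≪ 0.001).

A command-line entry point wraps the same functions:

```sh
exec/crossomics simulate --type transcripts --seed 7 --out work/
exec/crossomics lncrna --candidates work/candidates.fa --counts work/counts.tsv \
  --coding-hits work/coding_hits.tsv \
  --nonpig work/nonpig_genome_1.fa,work/nonpig_genome_2.fa,work/nonpig_genome_3.fa \
  --pig work/pig_genome_1.fa,work/pig_genome_2.fa --out work/cascade
```

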