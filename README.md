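# spaceqtl

Spatial eQTL mapping and cross-phenotype regulatory sharing via Hi-C
restriction-fragment contacts.

## What it does, and for whom

GWAS variants for psychiatric and cognitive phenotypes rarely sit inside
the genes they regulate. `spaceqtl` is for researchers who want to connect
phenotype-associated SNPs to their likely target genes through physical
chromatin contacts, and then ask whether *different* phenotypes converge on
shared genes and pathways — a regulatory account of multimorbidity.

The pipeline:

1. **Digest** the genome in silico with the Hi-C enzyme (MboI `GATC`, or
   HindIII `A^AGCTT`) into restriction fragments; locate each SNP's
   fragment.
2. **Capture** fragments in contact with SNP fragments per Hi-C library
   (11-column `merged_nodups`-style records; both ends mapq ≥ 30;
   libraries must pass QC: >90% alignable unique pairs, >50% unique
   contacts, <40% duplication).
3. **Pair** SNPs with genes overlapping captured fragments; classify pairs
   as cis (< 1 Mb SNP-to-gene-body gap), trans intra-chromosomal (≥ 1 Mb)
   or inter-chromosomal.
4. **Test**: join pairs to a multi-tissue eQTL association table, adjust
   all SNP–gene–tissue p-values with one pooled Benjamini–Hochberg
   correction, keep adjusted p < 0.05; flag brain-specific interactions
   (brain Hi-C library **and** brain/spinal tissue).
5. **Quantify sharing**: intersect per-phenotype eGene sets and test the
   observed overlap against a bootstrap null. Each of N = 10,000
   iterations draws phenotype-sized random gene sets from a reference
   universe (all genes, or only Hi-C-interacting genes) and the p-value is

   ```
   p = #( bootstrap overlap >= observed overlap ) / N
   ```

   with rejection of the chance hypothesis iff p < 0.01. The same test is
   applied to shared pathways (hypergeometric over-representation per
   phenotype, then overlap bootstrap against a 536-pathway universe).
6. **Annotate**: drug–gene interaction join with druggable fractions,
   per-tissue interaction counts vs sample-size Pearson correlations, and
   the fraction of significant pairs a nearest-gene heuristic would have
   found.

A synthetic-data generator (`sim_spec()` / `simulate_study()`) emulates
all seven inputs — genome FASTA, GENCODE-style GTF, SNP table, per-library
contact files + library QC table, GTEx-like association + tissue tables,
GMT pathways, DGIdb-like drug table — with planted spatial links, planted
eQTL effects, planted shared eGenes and shared pathways, so the whole
analysis is testable end to end without any external download.

## Worked example

```r
library(spaceqtl)

spec <- sim_spec(seed = 1)                      # default synthetic study
sim  <- simulate_study(spec, "simdata")         # writes the seven inputs
cfg  <- sim_pipeline_config("simdata", "results", spec,
                            analysis_config(seed = 1))
res  <- run_pipeline(cfg)
cat(readLines("results/summary.txt"), sep = "\n")
```

```
input SNPs (after GWAS p filter): 360
distinct SNPs: 360
spatial SNP-gene pairs: 377
significant eQTL-eGene-tissue tests: 1359
distinct eQTL SNPs: 275
distinct eGenes: 113
eGenes shared by all phenotypes: 33 (bootstrap p ref1 = 0, ref2 = 0)
pathways shared by all phenotypes: 5 (bootstrap p = 0)
druggable eGene fraction range: 0.191-0.304
closest-gene fraction (overall): 0.0885
brain-specific significant tests: 321
```

Reading this: of 360 suggestive SNPs across six phenotypes, 275 are
spatial eQTLs; the six phenotypes' eGene sets intersect in exactly the 33
genes the generator planted as shared, and in 10,000 bootstrap iterations
no random draw ever matched that overlap (p = 0 < 0.01) under either
reference universe — the sharing is not a set-size artifact. About 9% of
significant pairs involve the SNP's nearest gene, i.e. a
proximity-only mapping would have missed the vast majority.

```r
res$bootstraps$all_ref1
#> Bootstrap overlap test [ref1_all_genes]
#>   combination: ADHD+anxiety+BD+SCZ+UD+cognition
#>   observed overlap: 33
#>   N = 10000, #(null >= observed) = 0, p = 0 (p_upper = 9.999e-05)
```

Per-stage outputs (`pairs.tsv`, `significant.tsv`, `overlap_egenes.tsv`,
`bootstrap_egenes.tsv`, `pathway_enrichment.tsv`, `druggable.tsv`,
`tissue_counts.tsv`, `manifest.json`) are written to the result
directory. `inst/scripts/run_pipeline.R` wraps the same two entry points
for shell use.

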