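---
title: "Spatial eQTL mapping and cross-phenotype sharing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial eQTL mapping and cross-phenotype sharing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`spaceqtl` asks whether several phenotypes — in the motivating use case,
psychiatric disorders and cognitive traits — share a common regulatory
architecture: distinct GWAS variants converging on the same target genes
and pathways. The pipeline connects three kinds of evidence:

1. **Physical proximity.** Hi-C chromatin contacts are resolved at the
   level of restriction fragments. The genome is digested in silico with
   the enzyme used in library preparation (MboI, motif GATC, cutting 5' of
   the motif; or HindIII, A^AGCTT), SNP-containing fragments are
   identified, and every fragment captured in contact with them is
   collected per library. A SNP–gene candidate ("spatial pair") exists when
   a captured partner fragment overlaps a gene body by at least 1 bp.
2. **Regulatory association.** Spatial pairs are joined with a
   multi-tissue eQTL association table (a GTEx-like flat export). Nominal
   p-values of all retained SNP–gene–tissue tests are adjusted with a
   single pooled Benjamini–Hochberg correction; tests with adjusted
   p < 0.05 define the significant eQTL–eGene–tissue interactions, the
   eQTL SNPs and the eGenes.
3. **Convergence.** Per-phenotype eGene sets are intersected. The
   significance of an observed overlap is assessed by a bootstrap null:
   each iteration draws, independently per phenotype, a uniform
   without-replacement sample of that phenotype's eGene count from a
   reference universe and records the intersection size; the p-value is
   the fraction of iterations whose resampled overlap reaches the observed
   one,

   $$p = \frac{\sum_{i=1}^{N} \mathbb{1}\left[\,\mathrm{overlap}_i^{\,boot} \ge \mathrm{overlap}^{\,obs}\,\right]}{N},$$

   with N = 10,000 and rejection of the chance hypothesis iff p < 0.01
   (strictly). Two universes are used: all genes in the gene model
   ("reference set 1") and only genes found spatially interacting with
   SNP-containing fragments ("reference set 2"), which corrects for Hi-C
   gene-coverage bias. The same machinery tests pathway overlaps against a
   fixed-size pathway universe (536, the size of a KEGG-style collection).

Around this core sit a brain-specific sub-analysis (an interaction is
brain-specific iff its spatial pair is supported by at least one brain
Hi-C library **and** its tissue belongs to the brain/spinal group),
hypergeometric pathway over-representation, a drug–gene interaction join
with per-phenotype druggable fractions, Pearson correlations of per-tissue
interaction counts against tissue sample size, and a closest-gene
diagnostic (what fraction of significant pairs would a nearest-gene
heuristic have found?).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gwas_p_cut` | 1e-6 | suggestive GWAS association cut-off on input SNPs |
| `mapq_min` | 30 | per-end mapping-quality minimum, inclusive |
| library QC | >90, >50, <40 | % alignable unique pairs, % unique contacts, % duplication; strict inequalities, boundary values fail |
| `fdr_alpha` | 0.05 | pooled BH threshold; significance is adjusted p < alpha |
| `cis_max_bp` | 1e6 | cis/trans boundary; the gap of exactly 1 Mb is trans |
| `bootstrap_n` | 10,000 | Eq.-style bootstrap iterations |
| `bootstrap_sig` | 0.01 | strict rejection threshold on the bootstrap p |
| `pathway_universe_n` | 536 | pathway universe size for the pathway bootstrap |

Distance uses the SNP-position-to-gene-body gap (0 inside the body), not
TSS distance; gene "overlap" uses the whole annotated gene span, not the
promoter. Both choices are deliberate: fragment-level Hi-C evidence does
not resolve promoters, and the cis/trans taxonomy is printed with the
body-gap convention (999,999 bp cis; 1,000,000 bp trans;
inter-chromosomal pairs have no distance).

**BH pooling scope.** The correction is pooled once across all phenotypes'
SNP–gene–tissue tests in a run (`call_significant(..., by = NULL)`); a
per-phenotype mode is available via `by = "phenotype"` after joining
phenotype labels. Pooling across tissues is required; pooling across
phenotypes is the package's choice for a single-run analysis and is
recorded in the run manifest.

**Bootstrap conventions.** Sampling is without replacement (an eGene list
has no duplicates). For k > 2 phenotypes each phenotype's sample is drawn
independently. The p-value is reported exactly as count/N — p = 0 is
possible and printed as such — together with `p_upper = (count+1)/(N+1)`
for users who want a positive upper bound. Each phenotype combination gets
its own RNG substream derived deterministically from the run seed and the
combination label, so adding a combination never perturbs the others'
results.

## The synthetic-data generator

`sim_spec()` describes a complete desk-scale study and `simulate_study()`
materialises all seven inputs (FASTA genome, GTF genes, SNP table, contact
files + library table, association + tissue tables, GMT pathways, drug
table) plus a ground-truth record. The defaults are the study conditions
the rest of the package is validated under:

- three chromosomes totalling 8.5 Mb of uniform-random sequence; 300
  non-overlapping genes with log-uniform lengths in [1, 50] kb (placed
  longest-first by rejection sampling);
- six phenotypes (ADHD, anxiety, BD, SCZ, UD, cognition), 60 SNPs each at
  suggestive GWAS p; per phenotype, 45 SNPs carry planted regulatory links
  — one to each of 33 eGenes shared by **all** phenotypes (mirroring the
  headline structure of a shared-architecture analysis: shared eGenes,
  disjoint eQTLs) and one to each of 12 phenotype-specific eGenes;
- 70% of planted SNPs are placed within 1 Mb of their target (cis), 6%
  immediately adjacent (so the target is usually the nearest gene,
  emulating the small closest-gene fraction of real data), the rest
  anywhere (trans); all SNPs are intergenic;
- six QC-passing Hi-C libraries (two brain) plus one QC-failing library
  containing only background contacts; every planted link gets contacts in
  one non-brain and one brain library, so it can survive the
  brain-library criterion; 2,000 uniform background contacts per library,
  10% of which carry one end with mapq < 30;
- a 12-tissue panel (4 brain/spinal) with realistic sample sizes; planted
  associations appear in 5 sample-size-weighted tissues (≥ 1 brain) at
  nominal p ~ U(0, 1e-8); background spatial candidates receive rows at
  p ~ U(0, 1), so per-tissue row counts scale with sample size and the
  tissue correlation has signal;
- 120 pathways of 10–60 genes; 5 are over-populated with the 33 shared
  eGenes so they enrich in every phenotype; 18% of genes are druggable.

Planted nominal p-values sit far below alpha so desk-scale FDR behaviour
is unambiguous; effect sizes are not modelled because the pipeline
consumes p-values only. Background contacts are uniform over fragment
pairs rather than distance-decayed — the pipeline uses contact presence,
not frequency, so decay would only change how much background survives
capture. Everything is byte-reproducible given the spec's seed; each
generator runs in its own derived RNG substream.

What passing tests on these data do **not** show: behaviour under LD
structure (planted links are independent SNPs), realistic Hi-C contact
matrices (no TADs or compartments), allele-frequency or effect-size
effects, or pathway-topology effects — the over-representation stage is a
standard hypergeometric test, deliberately simpler than topology-aware
commercial scoring, so pathway identities on real data would not be
expected to match such tools exactly.

## Numerical and degenerate-input choices

- A SNP whose position coincides with a restriction cut site belongs to
  the single fragment whose half-open interval contains it; fragments are
  0-based half-open internally, SNPs/GTF 1-based at the boundary, with one
  documented conversion helper (`pos1_to_pos0()`).
- Self-contacts (both ends on the same fragment) are retained once and
  flagged; a SNP may regulate a gene on its own fragment.
- Empty chromosomes are rejected; a motif-free chromosome is one fragment.
- `bh_fdr()` validates p in [0, 1] and otherwise delegates to
  `stats::p.adjust`; the test suite checks it against the definitional
  step-up formula to 1e-12.
- Zero-variance tissue counts report r = 0 with an explicit flag rather
  than NA propagation; fewer than three tissues skips the correlation
  with a notice.
- A bootstrap `observed` above the smallest set size is impossible under
  the null and reported as p = 0 with an `unattainable` flag.
- SNPs on gene-free chromosomes are excluded from the closest-gene
  denominator and counted separately.

The null-calibration check draws six sets of 200 from a 300-gene universe:
at those sizes the all-phenotype intersection statistic takes enough
distinct values for a Kolmogorov–Smirnov uniformity check of the Monte
Carlo p to be informative; with small sets the statistic degenerates to 0
and every p is 1.

## Problem sizes

Unit and property tests run on toy fixtures and a reduced simulation (two
chromosomes, three phenotypes, 60 genes). The end-to-end checks and the
acceptance script use the full default spec above (8.5 Mb genome, ~33,000
fragments, 360 SNPs, ~16,000 contact records); a complete run — simulation
plus pipeline, including three 10,000-iteration bootstraps and fifteen
pairwise ones — takes well under a minute on one CPU.

## Known limitations

- The association table is an input, as in a database-query design; the
  package does not call eQTLs from genotype and expression matrices.
- Contact files are trusted to carry fragment ids consistent with the
  supplied fragment map; the pipeline derives SNP fragments itself but
  does not re-derive contact-end fragments from positions.
- Resumability covers the tabular stage boundaries (`pairs.tsv`,
  `significant.tsv`); earlier stages are cheap and recomputed
  deterministically.
- The tissue half of the brain-specificity condition is interpreted as
  membership of the eQTL's tissue in the brain-and-spinal-cord group —
  requiring significance in *every* such tissue simultaneously would
  leave a near-empty result. The tissue flag itself is an input.
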