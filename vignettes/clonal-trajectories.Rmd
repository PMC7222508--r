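---
title: "Tracking clonal dynamics across serially passaged xenografts"
author: "clonaltraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking clonal dynamics across serially passaged xenografts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaltraj)
```

## The problem

Acquired drug resistance in patient-derived xenograft (PDX) models can be
studied by passaging a tumor through successive cohorts of mice under
continuous treatment and profiling each passage.  The design this package
models is five passages (generations g1–g5) with three replicate mice per
arm: tumors respond to treatment in early passages and grow through it in
late ones.  Three molecular layers are collected along the way — exome
variants, gene expression (FPKM) and miRNA expression — plus caliper
measurements of tumor volume in treated and vehicle animals.

`clonaltraj` implements the full desk-side analysis of such a cohort:

1. **Efficacy metrics** per passage (tumor volume, T/C, TGI, a
   responsive/resistant call).
2. **Allele-frequency trajectories**: per-generation alternate-allele
   frequencies from a multi-sample VCF, a monotone trajectory filter that
   isolates loci under apparent selection, and classical MDS on genotype
   Hamming distances.
3. **Expression dynamics**: presence filtering, one-way ANOVA across
   generations, DEG selection, hierarchical sample clustering and
   per-feature trend classification.
4. **Integration**: mapping filtered loci to the genes containing them,
   genotype–expression association, intersection of candidate genes with
   an immune gene set, and miRNA–target trend concordance.
5. A **synthetic-cohort generator** that emulates the whole study design
   with planted, recoverable structure, and a **pipeline driver** that
   runs everything from files to a machine-readable report.

## Models and procedures

### Tumor growth efficacy

Caliper volume uses the standard ellipsoid approximation
$V = L \times W^2 / 2$ (mm³).  With group-mean volumes $T_{t0}, T_{ti}$
(treatment, baseline and day $i$) and $V_{c0}, V_{ci}$ (vehicle),

$$\mathrm{T/C} = \frac{T_{ti}-T_{t0}}{V_{ci}-V_{c0}} \times 100,
\qquad \mathrm{TGI} = 100 - \mathrm{T/C}.$$

TGI is stored as the exact complement of T/C, so the identity
T/C + TGI = 100 holds to the last bit of the complement; negative TGI
(treated tumors outgrowing vehicle) is permitted and occurs in resistant
passages.  Baselines are the group means on the first treatment day;
groups are unpaired cohorts, so group means rather than per-animal pairs
enter the formulas.  Group SD uses the $n-1$ denominator.  A passage is
called *responsive* when TGI ≥ 30% — a conventional, configurable
cut-off, not a quantity estimated from data.

### Allele-frequency trajectories

For locus $j$ and generation $g$ the frequency is
$\hat p_{jg} = \sum_i d_{ij} / (2 n_g)$ where $d_{ij} \in \{0,1,2\}$ are
alternate-allele dosages over the $n_g$ mice with a non-missing call;
missing genotypes leave both numerator and denominator (no imputation).
This is the tracked non-reference allele frequency — it may exceed 0.5
and is deliberately not folded to a minor-allele frequency, since
trajectories of interest run the full range from 0 toward 1.

The trajectory filter keeps a locus when its five frequencies are
monotone non-decreasing with $\hat p_1 \le 1/3$ and $\hat p_5 \ge 2/3$,
or the mirror image.  Monotonicity is non-strict: with six chromosomes
per generation the observable frequencies are multiples of 1/6 and ties
between adjacent generations are common; the canonical passing
trajectory 0, 1/6, 1/3, 1/3, 2/3 contains one.  Boundary comparisons use
`<=`/`>=` exactly; because every observable frequency and both
thresholds are correctly rounded small rationals, the comparisons have
no floating-point boundary artifacts.

Genetic distance between samples is the Hamming proportion over
mutually callable loci, and the embedding is classical (Torgerson) MDS —
double-centering of squared distances and eigendecomposition, computed
by `stats::cmdscale` with a deterministic sign convention (the
largest-magnitude entry of each coordinate is positive).  A
silhouette-style score on the first two coordinates quantifies how well
a declared generation (typically g5) separates from the rest; on
simulated cohorts this score rises when the distance matrix is
restricted to filter-passing loci, mirroring the sharpened separation
seen after filtering in real serial-passage data.

### Expression dynamics

A gene is *expressed* when some generation has all three replicates
above FPKM 5 (strict).  Differential expression across generations uses
the classical one-way fixed-effects ANOVA ($F$ with 4 and 10 degrees of
freedom in the full design) on $\log_2(\mathrm{FPKM}+1)$; the log
transform stabilizes the variance of FPKM-like abundances, and a
raw-scale mode is retained for sensitivity checks.  DEG lists use raw
(unadjusted) thresholds $P<0.05$ and $P<0.001$ — following the
convention of the study design emulated here.  The caveat is real: with
~10,000 expressed genes a 0.05 threshold admits hundreds of false
positives, which is why the strict list and downstream intersection
steps do the actual candidate narrowing.

Per-feature temporal trends are Spearman rank correlations between
abundance and generation index, called up/down when the correlation test
gives $P<0.05$.  Sample clustering on DEGs uses average-linkage
hierarchical clustering of Euclidean distances on row-standardized
log values — the common heatmap default; linkage, distance and
standardization are configurable.  miRNA matrices flow through the same
machinery with a lower default presence threshold (1), since FPKM > 5 is
a gene-level convention.

### Integration

Filtered loci are assigned to genes by positional containment
(strand-ignorant); VCF positions are 1-based and BED intervals are
converted once at read time, so a BED interval `[100,200)` contains
1-based positions 101–200.  A locus inside two overlapping genes yields
two pairs, which is one reason candidate locus counts exceed candidate
gene counts.  Genotype–expression association is a simple linear
regression of $\log_2(\mathrm{FPKM}+1)$ on additive dosage (0/1/2)
across all non-missing samples, tested by the regression F statistic;
candidates are associations with $P<0.01$, with the gene list
de-duplicated.  A genotype-as-factor ANOVA mode would be a natural
extension; the additive model is the standard eQTL default and is what
the package ships.

miRNA–target pairs (an input list; target prediction is upstream) are
scored by trend concordance.  The default mode is **same-trend** —
matching the reported behaviour of serial-passage cohorts — even though
canonical miRNA repression predicts inverse trends; an `inverse` mode is
provided, and the discrepancy is worth keeping in mind when
interpreting concordant pairs mechanistically.

### Open design points, resolved

Several procedural details are not fixed by the study convention this
package follows; the choices here are:

- Association uses all 15 samples jointly (not per-generation means):
  more degrees of freedom, and the generation structure is already
  captured by the trajectory filter upstream.
- Missing genotypes are excluded from frequency denominators rather
  than imputed; with three mice per generation any imputation model
  would dominate the data.
- Multi-allelic VCF records are split per alternate allele so dosage is
  well defined per allele.
- Hamming distance is a proportion over mutually callable loci
  (PLINK-like), making distances comparable across pairs with
  different missingness.

## The synthetic-cohort generator

`sim_config()` + `simulate_cohort()` generate a complete cohort with
known truth.  The defaults *are* the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| design | 5 × 3 | generations × replicate mice (15 samples) |
| `n_loci` | 2000 | exome-scale variant panel, reduced for desk scale |
| `frac_selected_up/down` | 0.01 / 0.01 | loci on rising / falling latent paths |
| `selected_path` | 0, 1/6, 1/3, 1/3, 2/3 | the canonical observed trajectory |
| `n_genes` | 500 | expressed-gene panel, reduced for desk scale |
| `n_planted_degs` | 25 | genes with a monotone generation trend |
| `deg_effect_sd_units` | 3 | per-generation shift in replicate-noise SDs |
| `n_eqtl_links` / `n_eqtl_genes` | 15 / 12 | genotype-linked loci / genes (loci > genes) |
| `eqtl_slope` | 2 | log2 expression per alternate allele |
| `n_target_pairs` / `n_concordant_pairs` | 50 / 16 | miRNA–target pairs / planted same-trend pairs |
| `n_immune_planted` (+ extra) | 10 (+40) | immune labels on eQTL genes, plus off-panel filler |
| `noise_sd` | 0.25 | log2-scale replicate noise (0 = exact regime) |
| `response_tgi_percent` | 44.62, 43.93, −44.04, 7.42 | endpoint TGI for passages 2–5 |
| `baseline_range` | 100–300 mm³ | randomization window for engraftment volume |

Rationale for the key values: latent allele-frequency paths are defined
on the population and then realized on six chromosomes, because observed
frequencies are constrained to multiples of 1/6 — the canonical planted
path is exactly the trajectory the filter must accept, tie included.
Replicate noise of 0.25 on the log2 scale is a typical biological CV for
bulk RNA-seq replicates; planted effects are expressed in units of that
SD, with a floor of 0.25 so the noise-free regime still plants nonzero
effects.  Growth noise is lognormal (volumes stay positive, spreads of
the ~20% magnitude seen in real caliper data); treatment curves are
constructed as baseline plus $(1-\mathrm{TGI}/100)$ times the mean
vehicle growth, so with noise off `efficacy()` inverts the construction
exactly.  The default scale keeps a full simulate-write-analyze cycle
in seconds; the generator happily scales to larger panels when asked.

What the generator does **not** emulate: linkage between loci, clonal
phylogenies or Wright–Fisher drift (frequency paths are independent per
locus), mapping biases, library-size effects, batch structure, or any
dependence between the miRNA and genotype layers.  Tests passing on
these cohorts therefore demonstrate correctness of the computations and
recoverability of planted signals — not robustness to the full
messiness of real sequencing data.

Planted-signal recoverability is structural in the exact regime
(`noise_sd = 0`): neutral loci keep constant frequencies and cannot
satisfy both boundary conditions, only eQTL loci are placed inside gene
bodies, and perfect fits drive association and ANOVA p-values to their
flagged degenerate limit of 0.  The end-to-end test asserts exact
truth-table recovery there, and statistical calibration (ANOVA and
association false-positive rates, permutation-null uniformity) is
tested separately in the noisy regime.

## Numerical choices and degenerate inputs

- All-identical ANOVA input: $F$ undefined, $P=1$ by convention; zero
  within-group variance with unequal means: $F=\infty$, $P=0$, flagged
  `degenerate`.
- Association on monomorphic or nearly empty dosages is skipped with a
  recorded reason rather than returning a meaningless fit.
- An all-zero distance matrix embeds to all-zero coordinates (valid);
  identical expression columns cluster arbitrarily but
  deterministically, flagged `degenerate`.
- The `[0,1]` frequency bounds, `<=`/`>=` boundary semantics, strict
  `<` p-value thresholds and strict `>` presence threshold are all
  property-tested, including a brute-force enumeration of every
  trajectory on the 1/6 grid.
- Problem sizes in the test suite (e.g. 2,000-gene null calibration,
  100,000-locus neutral symmetry check, 16,807-trajectory enumeration)
  were chosen to give the relevant statistics a few percent of sampling
  error while keeping the suite fast.

## Limitations

- The trajectory filter is a deterministic rule, not an inference; it
  has no error model and its pass counts depend strongly on the
  missingness pattern and the 1/3–2/3 boundaries (both exposed as
  parameters).
- Unadjusted p-value thresholds throughout mirror the emulated
  convention; users wanting FDR control should apply `p.adjust` to the
  returned tables.
- The additive association model sees only loci inside gene bodies;
  regulatory variants outside genes are invisible to the default
  containment mapping.
- Same-trend miRNA concordance is a descriptive screen, not evidence of
  direct regulation (which would predict the inverse pattern).
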