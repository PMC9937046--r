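---
title: "Detecting genomic imprinting from reciprocal-cross allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from reciprocal-cross allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintase)
```

## The design and the model

Genomic imprinting is parent-of-origin-dependent monoallelic expression:
a diploid cell expresses only (or mostly) the maternally inherited copy
of a gene (a MEG) or only the paternal copy (a PEG). To detect it from
RNA-seq one must know which allele came from which parent, which is what
a **reciprocal cross** between two genetically distinct stocks provides.
With stocks LL1 and LL2, the two matings LL1(dam) × LL2(sire) and
LL2(dam) × LL1(sire) produce F1 individuals in which, at any site where
the stocks are fixed for opposite alleles, every read's parental origin
is unambiguous.

Let `p1` be the LL1-allele expression fraction in LL1×LL2 F1s and `p2`
the LL1-allele fraction in LL2×LL1 F1s. The key identification idea is
the **flip**:

* a MEG favors the maternal allele in both directions, so the LL1 allele
  is favored when LL1 is the dam and disfavored when it is the sire:
  `p1 > 0.65` and `p2 < 0.35`;
* a PEG shows the mirror pattern: `p1 < 0.35` and `p2 > 0.65`;
* a *cis*-regulatory (cis-eQTL) bias rides the allele itself and does
  **not** flip: `p1` and `p2` sit on the same side of 0.5, whatever their
  magnitude. Such genes are never called imprinted, however extreme the
  bias.

Genes with both ratios inside `[0.35, 0.65]` are biallelic. Everything
else — same-side patterns, one extreme and one central direction, or a
direction with no usable coverage — is *undetermined*, because the
flipped pattern is the only positive evidence the design admits. The
cutoffs are strict inequalities; a ratio exactly at a cutoff never
produces an imprinting call.

An additional rule handles marsupial X biology: the paternal X is
silenced (imprinted X-chromosome inactivation), so every X-linked gene
looks like a 100%-maternal MEG. Maternal calls on the X or on unplaced
scaffolds (`chrUn`, where unassembled X material accumulates) whose
maternal fraction reaches `xci_maternal_min` in every covered sample are
re-labeled `xci_candidate` and excluded from autosomal summaries.

## Informative SNPs and filtering

A site enters the analysis only if it survives, in order:

1. **Discovery depth**: total depth pooled over all samples ≥ 40 (the
   `min_pooled_depth` of `discover_candidate_snps()`), matching SNP
   discovery from a combined alignment of all transcriptomes.
2. **Masks**: sites inside repeat intervals (BED, 0-based half-open) or
   within `boundary_distance` (default 5 bp) of an exon–intron junction
   are removed; both are alignment-artifact hotspots. The 5 bp default
   is our choice of a minimal splice-junction guard; it is a parameter,
   not a published value.
3. **Stock genotypes** (`genotype_stocks()`): counts pooled over each
   stock's parental samples call a stock homozygous when the minor
   fraction is ≤ 0.05 (sequencing-error tolerance), heterozygous at
   ≥ 0.20, otherwise unknown; unknown below 8 pooled reads.
4. **Informativeness** (`assess_informativeness()`): opposite homozygous
   stocks, each stock's own allele at ≥ 8 parental reads, and ≥ 3 of the
   4 F1 samples of the tissue at ≥ 8 reads.

Because stock genotypes are inferred from *RNA* counts, two realistic
failure modes exist, and both are exercised by the synthetic generator:

* a site segregating in both stocks can, by sampling luck in a handful
  of parental animals, look fixed-opposite and slip into the informative
  set with a scrambled origin map;
* at an imprinted gene a truly heterozygous parent can look homozygous,
  because one allele is silenced in the RNA.

The remedy used in practice is genotype confirmation on genomic DNA; the
package mirrors it with the known-genotype override of
`assess_informativeness()`: stock-level corrections, plus per-F1-sample
homozygosity records that disqualify a site outright (an F1 homozygote
means the apparent SNP was miscalled). The packaged
`example_candidates()` fixture reproduces this exact mechanism: 22
flipped-pattern candidates of which three (Matn2-, Prkaa2-, Parp4-like)
are eliminated by F1 homozygosity, leaving 19.

## Quantification choices

Gene-level ratios pool **raw counts** over all informative SNPs and both
F1 replicates within a cross direction; `p1`/`p2` are ratios of summed
counts, not means of per-SNP ratios. Pooling weights each SNP by its
depth, which is the efficient estimator under the shared underlying
allelic fraction, and matches per-gene percentages derived from multiple
SNPs of unequal depth. Whether the original analyses pooled or averaged
replicates is not stated; we pool, and retain per-sample fractions in
the output for concordance inspection. SNPs overlapping several gene
models go to the lexicographically first gene id, with a message — a
tie-break that matters only for overlapping annotations.

Expression detectability is a separate gate (FPKM ≥ 1, or the simulated
analogue): *not detectable* is a statement about expression, distinct
from *no informative SNP*, which is a statement about the cross.

`xci_maternal_min` defaults to 0.99 rather than literal 1.0 because
published "100% maternal" figures come from finite read counts; one
stray read in a few hundred should not disqualify a gene. Note the rule
is per sample: at modest simulated depths (~50×) a single stray read in
one sample can hold a true XCI gene at MEG, which the caller reports
with a warning. At the read depths of real studies this is rare.

## Promoter methylation and DMR classification

Bisulfite conversion turns unmethylated C to T; at each reference CpG a
retained C is a methylated call (M), a T unmethylated (U), anything else
missing. Missing calls never enter any denominator. Non-CpG cytosines
must all convert, so their conversion rate is a per-clone QC measure;
clones below 0.95 are excluded — a standard bisulfite QC convention we
adopt explicitly (no filter is stated in the source protocols).

A promoter CpG island whose two parental alleles are differentially
methylated averages ~50% methylation. `classify_dmr()` screens with a
band of [0.30, 0.70] (chosen to enclose, with margin, the 35.6–59.6%
range observed for such promoters), calls unmethylated below 0.20 and
methylated above 0.80, and confirms a DMR only when per-allele means
differ by ≥ 0.40 — wide enough that a 96%-vs-18% maternal/paternal split
is a confident DMR while leaving intermediate-but-uniform regions
`intermediate_unresolved`. All four numbers are exposed parameters.
Allele partitioning relies on a single perfectly linked SNP in the
amplicon (the design validated for an Npdc1-style promoter); multi-SNP
phasing is not modeled.

## Genome-wide extrapolation

Informative SNPs cover only a fraction `c` of expressed genes (random-
bred stocks share much of their variation — in this design LL2 carries
roughly 1:7 admixture from the LL1 source population, so shared
segregating polymorphism dominates). With `n` detected autosomal
MEG/PEG genes the genome-wide point estimate is `n / c`. For an
interval we treat `n` as a binomial draw from the covered gene set and
scale the Clopper–Pearson interval by `1/c`; when the covered-set size
is unknown, an exact Poisson interval on the count is scaled instead.
Both are exact small-count constructions; the published figure is a
point estimate only, and the numerator's ambiguity (12 autosomal
candidates in one tally, 13 in another) is left to the caller via the
explicit `n_detected` argument.

## What the generator emulates, and what it does not

`simulate_cross_dataset()` reproduces the study layout: 2 parental-cross
fetuses per stock and 2 F1 fetuses per reciprocal direction, each
sampled in fetal brain and placenta (16 samples). Sites are
fixed-different between stocks with probability `stock_divergence`
(default 0.08), segregating in both with probability
`shared_polymorphism_fraction` (default 0.55), else fixed identical —
defaults chosen so that, at ~3 SNPs per gene, roughly 20% of genes end
up covered by informative SNPs, the coverage regime the design operates
in. Depth is negative binomial (mean 50, size 5), our model for
overdispersed RNA-seq coverage at expressed exonic sites given that only
the 8× and 40× cutoffs are stated upstream; allele counts are binomial
given depth, with a symmetric 0.005 error so homozygotes are not
noise-free. Imprinting applies to every fetus (parental-cross fetuses
included), with `imprint_strength` defaulting to 0.97, inside the
95.5–100% range of validated expressed-allele percentages.

Not emulated: read-level artifacts (mapping bias, duplicates), isoform
structure, batch effects, sex differences beyond the `xci` class, and
linkage between neighboring genes. Passing tests therefore demonstrate
the *logic* of the pipeline — filtering, orientation, thresholds,
guards — under faithful sampling noise, not robustness to alignment
pathologies, which the repeat/junction masks only approximate.

## Validation problem sizes

The test-suite and acceptance runs use desk-scale problems chosen to
make each property measurable in seconds: 300-gene crosses at 60× mean
depth for MEG/PEG recovery (≥ 95% of strength-0.95 genes with ≥ 40
pooled reads per direction recovered; 0% of cis-eQTL genes called),
20,000 synthetic biallelic genes per depth for the false-positive check
against the closed-form binomial-tail product, 200-SNP random tables
against a brute-force informativeness oracle, 200-clone bisulfite sets
for allele-mean recovery within binomial 99% intervals, and 100 seeded
120-gene replicates for interval coverage of the genome-wide estimate
(≥ 90% of replicates bracket the true count).

## Known limitations

* Stock genotyping from RNA inherits allelic-silencing blind spots; the
  override interface is the supported correction path.
* Genes whose only informative sites are false informatives (shared
  polymorphism masquerading as fixed) can be mis-oriented; with two F1s
  per direction this usually lands in `undetermined`, not in a wrong
  call, but it is not impossible.
* The extrapolation assumes detected imprinting is independent of
  informative-SNP coverage; genes imprinted only below the expression
  gate, or partially imprinted below the ratio cutoffs, are invisible,
  so the genome-wide figure is a floor for weak imprinting.
* Indel markers are out of scope; markers are SNVs only.
```
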