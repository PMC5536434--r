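---
title: "Methods: colocalizing risk loci with HIF binding and dissecting candidate variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalizing risk loci with HIF binding and dissecting candidate variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifreg)
```

This vignette is the package's account of its statistical models, the
choices behind their implementation, and what the synthetic-data tests do
and do not establish.

## Coordinates and interval semantics

All intervals are 0-based half-open `[start, end)` (the BED convention);
1-based inputs (VCF positions, SNP tables) are converted at I/O
boundaries. Two consequences are deliberate and tested: abutting
intervals do not overlap, and `merge_intervals(x, min_gap = 0)` merges
only genuinely overlapping intervals (a gap of `g` bp merges when
`g < min_gap`). A SNP is the 1-bp interval `[pos, pos + 1)` wherever it is
intersected with peaks. Keeping a single internal convention eliminates
whole classes of off-by-one errors; the GenomicRanges `reduce`/
`countOverlaps` machinery is used in the test suite as an independent
oracle rather than as the implementation, so the convention stays visible
in the package's own code.

Consensus peaks implement the replicate-reproducibility rule "present in
at least k of n datasets". "Present" is defined on the merged pooled
peaks: a merged region's support is the number of datasets contributing
at least one overlapping peak, and regions with support ≥ k are kept.
This is the simplest reproducible reading of the rule; peak overlap is
≥ 1 bp (a minimum-fraction criterion was considered and rejected as an
extra free parameter with no stated value).

## Linkage disequilibrium and haplotype blocks

`r_squared` computes r² from phased haplotypes by direct counting:
D = p_AB − p_A p_B and r² = D²/(p_A p_a p_B p_b), which is identical to
the squared Pearson correlation of the two 0/1 haplotype columns (the
test suite asserts agreement to 1e-12). LD with a monomorphic SNP is
undefined and raises an error rather than returning 0.

A haplotype block is the index SNP plus every panel SNP on the same
chromosome within a search window whose r² with the index *strictly*
exceeds the threshold (default 0.8); a SNP at exactly the threshold is
excluded, and the suite pins this with a haplotype configuration
(AB = 36, Ab = 4, aB = 0, ab = 32) whose r² is exactly 0.8. The search
window defaults to 1 Mb either side of the index SNP. That value is this
package's choice, not an inherited one: genome-wide LD above 0.8 rarely
extends beyond a few hundred kb in outbred human populations, so 1 Mb is
generous without scanning whole chromosomes. It is configurable.

Unphased genotypes are not accepted for LD: phasing uncertainty would
silently bias D. The VCF reader therefore keeps only fully phased
(`|`-separated) biallelic SNVs and drops other records.

## The permutation enrichment test

The central statistic asks whether GWAS haplotype blocks and binding
sites colocalize more than chance allows, in both directions.

**Observed statistic.** Under the default `snp_in_peak` rule a block
overlaps a peak iff some member SNP lies inside it. This rule is the
reason block structure matters: enhancer-scale peaks are hundreds of bp
while block spans are tens of kb, so span intersection would saturate.
A `span_overlap` alternative is provided.

**Null model, loci direction.** Each block is reduced to its rigid
SNP-offset structure and relocated uniformly over every genome position
where the whole structure fits on one chromosome, the chromosome drawn
with probability proportional to its number of valid anchor positions.
Internal offsets are preserved exactly. Shuffled loci may overlap one
another and any real feature except an optional exclusion mask (default
none): this is the simplest null, and the mask hook is the place to
exclude assembly gaps when running on real genomes.

**Null model, peaks direction.** The observed peaks are replaced by
surrogates drawn uniformly without replacement from an enhancer
universe; each surrogate keeps one of the original peak widths (widths
paired to sampled elements by a uniform random bijection) and is centered
on the sampled element's midpoint, clipped at chromosome ends. Centering
on the element was chosen over uniform placement within it because
universe elements are themselves enhancer-scale; both options exist.

**Empirical p.** `plug_in` is `#{null ≥ obs}/n_iter`, which reproduces
the granularity of printed permutation p-values at 100,000 iterations but
can return 0; `add_one` adds one to numerator and denominator, never
returns 0, and is the recommended estimator. Both are exposed and the
suite checks both against hand-computed tails.

**Numerics and reproducibility.** One seeded generator drives a run
sequentially, so a fixed seed and iteration count give a bit-identical
null histogram regardless of how the work is batched internally; the
placement loop is vectorized across iterations per structure, which is
why 100,000 iterations over 9 multi-SNP blocks take well under a second.
Correctness is anchored to an exhaustive-enumeration oracle: on toy
genomes every anchor position is enumerated, giving the exact null
(a Poisson-binomial over per-block hit probabilities), and the
Monte-Carlo histogram is required to pass a chi-square goodness-of-fit
against it, with a discrete Kolmogorov-Smirnov check (bootstrap critical
values) confirming that add-one p-values are uniform over replicate
null datasets.

## Allele-specific quantification

Allele counting is a quality-filtered pileup (defaults: base quality
≥ 20, mapping quality ≥ 10 — common pileup practice, configurable, and
not inherited from any published value). Bases matching neither allele
are tracked separately in `n_other`, never merged; reads with a deletion
or reference skip at the site contribute to nothing. Counts are conserved
by construction and the suite asserts it.

The calibration mirrors allele-discrimination assay practice: input DNA
from a heterozygote carries both alleles 1:1, so the mean of its measured
B/A ratios over serial dilutions estimates platform bias; that mean is
set to 1 and assay ratios are divided by it. The arithmetic mean is the
default; a geometric option exists because ratios are multiplicative.
The B/A (minor/major) orientation is fixed package-wide and recorded in
outputs. A site with `count_a = 0` (the homozygous-control pattern) has
no defined ratio and raises an error directing the caller to one-sided
enrichment, rather than returning `Inf` into downstream arithmetic.

Imbalance testing is an exact two-sided binomial test on read counts
(null success probability `null_ratio/(1 + null_ratio)`), or a two-sided
Mann-Whitney-Wilcoxon rank-sum test when comparing calibrated ratio
samples between conditions. ΔΔCt fold changes assume amplification
efficiency 2 per cycle.

## HRE motif model

The motif model is deliberately the exact 5-mer consensus RCGTG
(R = A/G) and nothing more — no position-weight matrix — because the
biological reasoning the package supports is presence/absence of the
core element (ACATG disrupted vs ACGTG intact). Both strands are scanned
by default since HREs act orientation-independently; a plus-only flag
exists. Variant classification scans the ≤ 9-bp window of 5-mers
containing the SNP for both alleles and compares hit sets keyed by
(offset, strand): `gained`, `lost`, `both`, or `none`. The test suite
proves the acceptance set over all 1,024 5-mers is exactly
{ACGTG, GCGTG} and that swapping ref/alt swaps gained/lost. Where an
enhancer carries additional non-polymorphic HREs, the package reports
all hits and leaves their joint interpretation to the caller — no
multi-HRE weighting rule is assumed.

## Conditional eQTL

Counts are normalized with median-of-ratios size factors (total-count
scaling when fewer than 10 genes are positive in all samples). The
metagene activity score is the mean across set genes of the per-gene
z-score of log2(normalized count + 1); the score's definition is this
package's choice — the metagene gene lists themselves are user-supplied
inputs. Samples are split into rank-based tertiles with sizes balanced to
within one (extras to `low`, then `mid`; ties broken by stable sample
order), making labels invariant to monotone transforms of the score.

Per gene, a negative-binomial GLM with log link and log-size-factor
offset is fitted with and without genotype. The dispersion is estimated
by maximum likelihood under the alternative (via `MASS::glm.nb`) and
shared by both fits, so the likelihood ratio 2(llₐ − ll₀) is referred to
chi-square with the number of genotype parameters (categorical coding by
default, df = observed groups − 1; additive coding with df = 1 reports
the per-allele log fold change). Sharing the dispersion keeps the test
well defined; a free per-model dispersion would make the null
occasionally "fit better" for spurious reasons. A genotype group that is
entirely zero separates the categorical fit; such genes are flagged and
refit additively. Non-convergence is reported per gene, not fatal.
Benjamini-Hochberg correction is applied by callers that scan many genes.

Two notes on fidelity. First, when several panels of a stratified
analysis are each reported with a chi-square p-value, this package
interprets that as the chi-square reference distribution of the LRT
within each stratum; a contingency-table chi-square on discretized
expression is a different test and is intentionally not implemented.
Second, exact invariance of the LRT to rescaling one sample's counts
together with its size factor does not hold for the negative-binomial
likelihood (it is a Poisson-only identity); the suite asserts approximate
invariance instead, which is what the normalization contract actually
guarantees.

The conditional design — run the LRT separately within activity
tertiles — is what turns "the eQTL requires high pathway activity" into
a testable pattern: power concentrated in the high tertile with the low
tertile at the nominal false-positive rate.

## Capture-C interaction calling

Contact frequency decays with genomic distance, so expected counts are
estimated by binning |distance| into 50 log-spaced bins, taking a
per-bin trimmed mean (the top 1% of counts — always at least one value —
is excluded so a genuine interaction spike cannot inflate its own
background), enforcing monotone non-increase by weighted
pool-adjacent-violators, and interpolating on log distance. Fragments
outside the fitted distance range reuse the nearest bin's expectation
and are flagged `extrapolated`. Observed counts are tested against a
Poisson upper tail at the interpolated expectation with BH correction.
The Poisson choice is the simplest defensible null for a stand-in model:
this module deliberately re-implements only the published *idea*
(distance-decay background) rather than any specific pipeline's
estimator, and is validated purely on synthetic profiles.

## The synthetic-data generators

Every generator is a pure function of its parameters and seed (byte-
identical text outputs across runs), and each writes its ground truth so
expected statistics can be recomputed without re-reading the data.
Defaults encode the study conditions the package is shaped around:

* **Regions**: 3 chromosomes × 2 Mb, 400 non-overlapping enhancers, 30+
  true binding sites placed inside enhancers and present identically in
  ≥ 2 of 5 replicate peak sets (plus single-dataset noise peaks placed
  disjointly, so the 2-of-5 consensus recovers the truth exactly); 9
  GWAS blocks of 4–12 SNPs spanning ≤ 20 kb, of which 4 carry a SNP in a
  true peak and 6 peaks in total are hit.
* **LD**: linked SNPs copy the index allele with probability √r² and are
  otherwise redrawn at the same frequency — a two-locus
  haplotype-frequency construction whose column correlation is exactly
  the copy probability, so allele frequency is preserved and expected r²
  equals the target (0.956 and 0.107 are the regimes of interest);
  realized r² is recorded. A symmetric "flip" construction was rejected
  because flipping changes the allele frequency whenever p ≠ 0.5.
* **Allelic reads**: minor-allele counts ~ Binomial(depth, ρ/(1+ρ)) at
  true calibrated ratio ρ (default 2.0, depth 1,000, 50 sites), inputs
  Binomial(depth, ½); homozygous controls exercise the undefined-ratio
  path. A minimal SAM writer produces text alignment fixtures for the
  pileup path.
* **Expression**: 450 samples; latent activities a₁, a₂ ~ N(0,1) load on
  two 50-gene metagene sets (loading 0.5 on log-mean); genotypes are
  Hardy-Weinberg at risk-allele frequency 0.3; the target gene's mean is
  multiplied by exp(β·dose) with β = log(1.5) only in samples whose a₁
  is in the top tertile (conditional mode); counts are NB with
  dispersion 0.2 around lognormal library-size factors.
* **Viewpoint**: 1,000 × 500-bp fragments, expectation ∝ |d|^−γ (γ = 1),
  Poisson observations, listed spikes multiply the expectation.

What passing on synthetic data does *not* show: the generators contain
no mappability structure, GC or fragment-length bias, reference-mapping
bias at heterozygous sites, LD between distinct blocks, population
stratification, or dispersion trends across genes. Results on real data
depend on those; the enrichment mask hook, the configurable quality
filters and the user-supplied metagene lists are the intended adjustment
points.

## Problem sizes in the routine checks

The shipped test suite runs the enumeration-vs-Monte-Carlo comparison at
100,000 iterations, p-value calibration over 200 replicate null datasets
(999 iterations each), 1,000 null genes and 200 effect genes for the NB
LRT at n = 150, 100 replicate cohorts of n = 450 for the conditional
pattern, 10,000 sites for the binomial type-I rate, and 100 simulated
viewpoint profiles; the acceptance script uses the same shapes with 30
cohort replicates and 50 viewpoint profiles. These sizes give the
assertions comfortable statistical margins while keeping a full run in
the low minutes on one core.

## Known limitations

* The enrichment null treats the genome as uniformly placeable; without
  an exclusion mask, real-genome runs will include gaps and unmappable
  regions in the anchor space.
* NB dispersion is estimated per gene with no shrinkage across genes;
  for genome-wide scans a shrinkage estimator would be preferable.
* The Capture-C module is a simplified surrogate and should not be
  compared numerically against dedicated 3C pipelines.
* Phasing of assay alleles to transcribed-SNP alleles is out of scope;
  imbalance at a transcribed SNP is evidence of cis-regulation without
  assigning direction to a specific regulatory allele.
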