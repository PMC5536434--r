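# hifreg

Linking cancer GWAS risk loci to the hypoxia-inducible factor (HIF)
cis-acting apparatus.

## The scientific problem

Most cancer-susceptibility polymorphisms found by genome-wide association
studies are extragenic, and interpreting them requires a functional
framework. In clear cell renal cell carcinoma (ccRCC), loss of the von
Hippel-Lindau tumor suppressor constitutively activates the HIF
transcription factors, so the genomic binding sites of HIF define a
pre-specified regulatory pathway against which risk variants can be
tested. `hifreg` implements the computational machinery for that test and
for the follow-up dissection of individual loci:

1. **Haplotype blocks** — each risk locus is represented by its index SNP
   plus all panel SNPs in high linkage disequilibrium with it
   (strictly r² > 0.8 by direct haplotype counting,
   r² = D²/(p_A p_a p_B p_b)).
2. **Bidirectional permutation enrichment** — the observed number of
   blocks with a member SNP inside a consensus ChIP-seq peak (peaks
   "present in ≥ 2 of k replicate datasets") is compared with a null built
   by relocating the rigid SNP structures uniformly around the genome
   100,000 times; conversely, peaks are resampled among the elements of
   an enhancer universe with blocks held fixed. Empirical p is the
   upper-tail frequency (plug-in or add-one estimator).
3. **Allele-specific assays** — pileup-based allele counting at
   heterozygous SNPs, the input-dilution calibration that sets the mean
   input B/A ratio to 1, exact binomial and Mann-Whitney imbalance tests,
   input-normalized site enrichment, and 2^−ΔΔCt fold changes.
4. **HRE motif effects** — exact scanning for the hypoxia response
   element core RCGTG (R = A/G) on both strands, and gain/loss/neutral
   classification of variants (e.g. the A>G exchange turning the
   disrupted core ACATG into the intact ACGTG).
5. **Activity-conditional eQTL** — negative-binomial GLM likelihood-ratio
   tests of genotype against expression, run within tertiles of
   metagene-derived HIF-1/HIF-2 activity scores, to ask whether an eQTL
   is conditional on pathway activity.
6. **Capture-C interaction calls** — a distance-decay background
   (log-binned trimmed means, monotone non-increasing) with Poisson
   upper-tail tests and Benjamini-Hochberg correction.

A first-class synthetic-data module (`simulate_*`, `simulate_bundle`)
generates every input with known ground truth, so the whole pipeline is
testable end to end without external downloads.

## Worked example

```r
library(hifreg)

# Synthetic study: 9 GWAS blocks, 4 planted to overlap 6 binding sites,
# 5 replicate peak datasets, 2-of-5 consensus.
rs <- simulate_region_sets(n_overlap_peaks = 6, seed = 1)
peaks <- consensus_peaks(rs$peak_sets, min_support = 2)

res <- run_enrichment(rs$blocks, peaks, rs$genome,
                      config = shuffle_config(n_iter = 100000, seed = 2,
                                              p_estimator = "add_one"))
res
#> enrichment_result (loci_shuffle, snp_in_peak rule)
#>   observed overlap: 4
#>   empirical p (add_one): 1e-05  [100,000 iterations]
```

Four of the nine blocks carry a SNP inside a consensus peak, and no
permutation among 100,000 reached that overlap, so the add-one empirical
p-value is 1/(100,000 + 1) ≈ 1e-05: the planted colocalization is
recovered as highly non-random.

```r
# Is the genotype effect on the target gene conditional on pathway activity?
sim <- simulate_expression(n_samples = 450, seed = 11)
conditional_eqtl(sim$counts, sim$genotype, sim$metagenes$HIF1, "TARGET")[,
  c("stratum", "n", "lrt_stat", "df", "p_value")]
#>   stratum   n    lrt_stat df      p_value
#> 1     low 150  0.04966837  2 9.754716e-01
#> 2     mid 150  2.57537479  2 2.759081e-01
#> 3    high 150 41.53087983  2 9.587029e-10
```

The simulated genotype effect exists only in samples with high latent
HIF-1 activity; the likelihood-ratio test detects it in the high
metagene tertile (p ≈ 1e-09) and nowhere else — the signature of an
activity-conditional eQTL.

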