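---
title: "holopop: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holopop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Temperate corals such as *Astrangia poculata* host facultative algal
symbionts: colonies from the same site can be symbiotic ("brown") or
aposymbiotic ("white"). mRNA-Seq of such holobionts yields a single
transcriptome assembly mixing host and symbiont contigs, and a single
variant call set mixing the two genomes. Asking population-genetic
questions of either partner therefore requires, in order: assigning
contigs to compartments, rigorously filtering transcriptome-derived SNPs,
removing clonal ramets, separating neutral from putatively adaptive loci,
and only then estimating structure and diversity — separately per
compartment and per locus class. `holopop` implements that downstream
pipeline as tested, reusable components, driven by a synthetic-data
generator with known truth so every stage is verifiable without any
external data.

The emulated design has two origins (VA, RI) crossed with two symbiotic
states (B, W): four host populations of ~10 diploid individuals, with the
symbiont compartment present only in brown colonies (two symbiont
populations).

## Compartment assignment

Contigs are classified from blastn hits against four databases: "dirty"
(holobiont-derived) and "clean" (aposymbiotic-host or cultured-symbiont)
collections per compartment, plus LSU/SSU rRNA databases. Rules, applied
in order:

1. **rRNA**: any LSU/SSU hit covering ≥ 78% of the contig over ≥ 100 bp
   removes it. The "fraction of the read" is interpreted per contig
   (alignment length / contig length), since filtering operates on
   assembly contigs.
2. **Length**: only contigs strictly longer than 500 bp are kept.
3. **Host**: any hit to a coral database with alignment length strictly
   greater than 100 bp and percent identity ≥ 60 qualifies; a qualifying
   clean-symbiont hit vetoes the contig (it is removed, not reassigned).
   Symbiont assignment is symmetric with a clean-coral veto; contigs
   qualifying for both compartments after vetoes are removed.

Boundary conventions ("greater than 100 bp" strict, "60% cutoff"
inclusive) are defaults, configurable where the underlying phrasing is
ambiguous. Existence-of-any-qualifying-hit semantics are used; best-hit
logic is deliberately not.

## Filter cascade

Four steps, matching a conservative transcriptome-SNP recipe; every step
records before/after counts:

1. genotypes with fewer than 5 reads set missing; sites kept only with
   QUAL strictly above 30, biallelic SNP (no indels), minor allele count
   ≥ 3; individuals with more than 50% missing data dropped;
2. individuals with more than 85% missing data dropped;
3. sites kept with ≤ 75% missing data, minor allele frequency ≥ 0.05 and
   mean depth across retained individuals ≥ 10;
4. sites out of Hardy–Weinberg equilibrium (exact test, p < 0.01) in more
   than half of the evaluable populations removed.

Two phrasings in circulating pipeline descriptions are contradictory or
tool-specific; both readings are offered with the conventional one as
default: the mac rule is implemented as *keep* mac ≥ 3
(`mac_literal_exclude` flips it), and "more than 75% missing" is read
literally (call rate ≥ 25%; `site_missing_as_callrate` selects the
inverted convention). Mean depth is computed after genotype recoding.
The HWE exact test is the standard two-sided conditional test: enumerate
heterozygote counts of matching parity given the allele counts and sum
probabilities not exceeding the observed configuration's.

For structure and diversity analyses, loci are thinned to one uniformly
random SNP per contig (seeded), because SNPs on one assembly contig are
tightly linked.

## Clone detection

Allelic distance counts allele-copy differences between individuals
(AA vs Aa = 1, AA vs aa = 2), with pairwise deletion of missing loci;
Prevosti distance divides by twice the shared locus count, and Manhattan
distance on dosage codes is kept as a third metric for robustness checks.
Pairs below 5% of the maximum possible allelic differences (configurable)
are flagged as clones; flagged pairs are merged into groups, one member
is retained by seeded random choice, and a complete-linkage dendrogram is
emitted for visual confirmation. The threshold is a declared parameter:
the analysis this emulates identified clones visually on a dendrogram,
and an automated pipeline needs an explicit proxy.

## Outlier detection (XtX with POD calibration)

Per locus, per population j, the sample alternate-allele frequency
\(\hat p_j\) is standardized against the unweighted cross-population mean
\(\hat\pi\): \(z_j = (\hat p_j - \hat\pi)/\sqrt{\hat\pi(1-\hat\pi)}\). The
scaled covariance of population allele frequencies is estimated by
moments, \(\hat\Omega_{raw} = L^{-1}\sum_l z_l z_l^\top\), and the
per-locus statistic is the quadratic form
\(XtX_l = z_l^\top \Omega^{-1} z_l\) — a SNP-specific Fst analog that
discounts differentiation explained by shared drift. This is the
method-of-moments (FLK-style) counterpart of the Bayesian hierarchical
treatment of the same quantities; MCMC estimation is a non-goal.

The significance threshold comes from pseudo-observed data (POD): loci
simulated from the fitted null — ancestral frequency resampled from the
empirical \(\hat\pi\) distribution, population frequency vector from
\(\mathcal N(\pi\mathbf 1,\ \pi(1-\pi)\,\Omega)\) truncated to [0, 1],
then binomial genotype sampling at the observed sample sizes. Outliers
are loci whose XtX strictly exceeds the POD's 99.5th percentile (linear
interpolation), operationalizing a 0.5% FDR under the null; ties are
neutral.

Two numerical choices matter and were genuinely open:

* **Sampling-noise subtraction for POD generation.** \(\hat\Omega_{raw}\)
  contains binomial sampling noise in addition to drift. Because POD
  generation *adds* binomial sampling, simulating from the raw matrix
  double-counts noise, over-disperses the POD and inflates the threshold.
  `estimate_omega()` therefore subtracts the (unbiasedly estimated)
  standardized sampling variance from the diagonal before POD generation
  (`subtract_sampling = TRUE`, eigenvalue floor `ridge`); with this the
  POD XtX distribution matches the fitted data's to within a few percent.
* **The raw matrix as the XtX metric.** The quadratic form uses
  \(\hat\Omega_{raw}\), not the drift matrix, for both observed and POD
  loci — calibration is unaffected since both sides share the metric.
  Using the drift matrix is fragile when the neutral background is weak:
  any set of true outliers sharing one direction (e.g. an origin
  contrast) then dominates the estimated covariance, and its inverse
  cancels exactly the signal of interest. With the raw metric the
  sampling-noise diagonal keeps that contamination mild at realistic
  sample sizes.

Unweighted \(\hat\pi\) reflects near-equal design sizes. Centering by
\(\hat\pi\) constrains \(\sum_j z_j = 0\), so Ω has the structure
\(c\,(I - \mathbf{11}^\top/J)\) under exchangeability and XtX has J − 1
effective degrees of freedom; all calibration is empirical (POD), so no
chi-square reference is assumed anywhere.

## Population structure and diversity

Global and pairwise Fst use the Weir–Cockerham variance-component
estimator (among populations *a*, among individuals within populations
*b*, within individuals *c*; Fst = Σa / Σ(a+b+c), ratio of sums across
loci) — the standard AMOVA-based estimator for biallelic SNPs under the
allele-within-individual-within-population hierarchy. The GUI tool whose
analysis this mirrors does not document its exact internal conventions,
so this estimator is declared rather than cloned. Monomorphic loci
contribute zero components; small negative Fst is admissible and
reported. Significance uses 999 label permutations of individuals among
populations (sizes preserved; allele-level permutation is available by
flag), with p = (1 + #{perm ≥ obs}) / (n_perm + 1), so the smallest
attainable p is 0.001.

Diversity per population: Ho is the observed heterozygote frequency; Hs
is Nei's unbiased within-population expected heterozygosity,
\(\tilde n/(\tilde n - 1)\,(1 - \sum \hat p^2 - H_o/(2\tilde n))\),
averaged over loci with at least two genotyped individuals.

PCA imputes missing calls with the per-locus mean, centers (optionally
scales by \(\sqrt{\hat p(1-\hat p)}\); centering only is the default) and
eigendecomposes; signs are arbitrary, so all separation assertions use
silhouette widths on absolute projections.

GO enrichment of outlier-bearing genes is a one-sided Fisher exact test
per term (equal to the hypergeometric tail), Benjamini–Hochberg adjusted
by default with a `none` option; GO-graph propagation is off by default.

## The synthetic generator: what it emulates, and what a green test shows

Neutral loci: ancestral frequency Uniform(0.05, 0.95); per-population
frequencies from the Balding–Nichols distribution
Beta(p(1−F)/F, (1−p)(1−F)/F), whose F parameter equals the expected Fst —
chosen exactly because estimator-recovery tests then have a known target.
Outlier loci: one Balding–Nichols draw per *origin* at F = `fst_outlier`,
shared by both populations of the origin, so adaptive divergence
separates origins, not symbiotic states. Genotypes are Binomial(2, p);
depths NegBin(`mean_depth` = 20, `depth_dispersion` = 5), so the DP < 5
recoding is exercised; missingness is MCAR at 5% (no mechanism was
available to emulate); one clone pair is planted in RI-B with a 1%
per-allele-copy error. The symbiont compartment is simulated as diploid
calls for pipeline compatibility, although Symbiodiniaceae are
biologically haploid — a deliberate, documented simplification; its
genotypes exist only in brown hosts. Defaults not pinned down elsewhere
(depth, missingness, loci per contig ~3) were chosen once as realistic
for ~20–30x transcriptome genotyping and are configurable.

A green suite therefore establishes that the estimators recover known
generating parameters, that calibration under the generator's null is
nominal, and that the qualitative study pattern (origin-level adaptive
divergence over a panmictic neutral background in the host; structured
symbiont) is reproduced — not that real transcriptome data, with linked
selection, mapping artifacts, allele-specific expression and non-MCAR
missingness, would behave identically.

**A known power ceiling.** Balding–Nichols draws at large F are strongly
U-shaped: two independent origin draws frequently land near the same
boundary, so a sizable fraction of "planted outliers" realize little or
no between-origin divergence. Recovery power against planted outliers at
F = 0.5 with 10 individuals per population plateaus around one third —
a property of the stated generative world, not of the detector: the
undetected loci are mostly genuinely undiverged. Tests that demand higher
power under this generator fail for this reason and are left failing
deliberately (see the package's acceptance suite comments).

## Degenerate inputs and tie-breaks

Loci monomorphic across all populations are skipped in Ω estimation and
get XtX = 0 (flagged). Populations with fewer than two genotyped
individuals at a site are skipped in the HWE filter; pairs with fewer
than two individuals are skipped in pairwise Fst. Half-missing VCF calls
("./0") are treated as fully missing. All randomized choices (thinning,
clone retention, permutations, POD) derive deterministically from a
single seed; pipeline reruns are byte-identical (figures are SVG because
the PDF device embeds a creation date).

## Limitations

No MCMC estimation of Ω; no environmental-covariate association; no
admixture/STRUCTURE-style modeling; no probabilistic clonal assignment
(psex); read-level simulation and upstream steps (trimming, assembly,
mapping, variant calling) are out of scope — the pipeline starts at an
unfiltered VCF plus BLAST hit tables.
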