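---
title: "Methods: models, simulator assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mpravar)
```

This vignette is the package's own account of its science: the count model
behind the activity test, what the synthetic cohort does and does not
emulate, the numerical conventions, and the places where the design was
genuinely open and a choice had to be fixed. It states no empirical result
that the test suite does not itself compute.

## 1. The assay and its data

An MPRA library member ("oligo") couples a 100-nt genomic insert to a unique
12-nt barcode; five barcodes represent each *element* (one variant ×
one allele), and four single-nucleotide *analogs* per variant cover every
base at the variant position. Sequencing the barcode region of the plasmid
pool (pDNA) and of reverse-transcribed reporter transcripts (cDNA) yields an
element × sample count matrix: an element's count in a sample is the sum of
reads over its five tags, with the tag taken from the first 12 bases of each
read. Regulatory activity is the cDNA/pDNA abundance ratio after
normalization; allelic effects compare that activity between the reference
and the observed variant allele.

## 2. Count model and the activity test

Counts are modelled as negative binomial, $K \sim \mathrm{NB}(\mu,\alpha)$
with $\mathrm{Var}(K) = \mu + \alpha\mu^2$. MPRA analyses conventionally
delegate this comparison to a standard RNA-seq differential tool; here the
machinery is re-implemented so the pipeline is self-contained:

* **Size factors.** Median-of-ratios: for sample $j$,
  $s_j = \mathrm{median}_i \, k_{ij} / (\prod_l k_{il})^{1/m}$ over elements
  with all-positive counts. Normalized counts are $y_{ij} = k_{ij}/s_j$.
* **Dispersion.** Per element, a method-of-moments estimate on normalized
  counts pooled across conditions,
  $\hat\alpha_{\mathrm{raw}} = (\widehat{\mathrm{Var}}(y) - \bar y)/\bar y^2$,
  shrunk halfway toward a mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$
  fitted across elements, floored at $10^{-8}$. This is a deliberately
  simplified stand-in for the empirical-Bayes shrinkage of the delegated
  tool; numerical agreement with that tool is a non-goal — the acceptance
  surface is simulation calibration (type-I error, sensitivity, FDR).
* **Wald test.** Per element, group means $\hat q_g = \bar y_g$ (the NB
  maximum-likelihood estimate on the normalized scale when the per-sample
  variance weights are equal), $\log_2$ activity
  $\hat\beta = \log_2(\hat q_{\mathrm{cDNA}}/\hat q_{\mathrm{pDNA}})$, with
  Fisher information $I_g = n_g \hat q_g/(1 + \alpha \hat q_g)$ per group,
  $\mathrm{SE}(\hat\beta) = \sqrt{I_c^{-1} + I_p^{-1}}/\ln 2$, two-sided
  normal p-value, Benjamini–Hochberg adjustment across all tested elements.
  Elements with all-zero counts get NA statistics and leave the BH family;
  an all-zero *group* is floored at half a pseudo-count.

**Invariance class (a deliberate choice).** Median-of-ratios factors
identify *relative* sample depths: rescaling the samples by factors whose
product is 1 leaves the factors equivariant and every normalized count and
test statistic exactly unchanged (this is what the invariance tests verify,
at `1e-9`). Rescaling a *single* sample additionally shifts the global
geometric-mean anchor, moving all normalized counts by a common constant
$c^{1/m}$; the activity log-fold-change is still exactly invariant, but
statistics that use the absolute count scale (the Poisson part of the
moment dispersion estimator) shift slightly. No estimator that corrects for
per-sample shot noise can be exactly invariant to single-sample rescaling —
the rescaled sample genuinely claims a different depth — so the package
pins down the exactly-invariant class instead and documents it here.

## 3. Variant effects

For each variant with activity estimates on both alleles,
$\delta = \hat\beta_{\mathrm{alt}} - \hat\beta_{\mathrm{ref}}$ (log2 scale,
which makes the ref/alt comparison symmetric — an "expression difference"
statistic needs a scale fixed, and log2 is the natural one here). The $\delta$ are
standardized over the pooled cohort (de novo and inherited together, sample
$n-1$ standard deviation), and $|z| > 2$ calls an effect: `decreased`
(mechanism *loss of function*) or `increased` (mechanism *loss of
repression* when the reference element is itself called a repressor;
increases on non-repressive references are labelled by sign only). Because
$z$ is standardized empirically, a pure-null cohort yields $\approx 4.6\%$
of $|z| > 2$ calls by construction — the planted-effect rate rides on top of
that tail, which is why effect calls are validated against planted truth
rather than against the raw call rate.

## 4. Phenotype-overlap prioritization

A TF is bound at a variant when the variant's (1-based) position, converted
to 0-based, falls in a ChIP cluster interval $[\mathrm{start},
\mathrm{end})$. For every (variant, proband, bound TF) triple, the overlap
of the proband's and TF's HPO term sets is tested with the upper-tail
hypergeometric $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, where $N$
is the total number of annotated HPO terms — supplied by the annotation file
header or configuration, never inferred from the observed sets. Matching is
by exact accession identity; ontology-ancestor propagation (counting a
match when one term subsumes another) is a flagged extension, not
implemented. The tail is
computed in log space (lgamma-based log-binomials with log-sum-exp), and all
tests in a run are pooled into one BH family — the conservative choice
among the possible correction families (per variant, per proband, pooled). Ranking: tier 1 (HPO
overlap at $q < 0.05$ **and** $|z| > 2$), tier 2 (overlap only), tier 3
(effect only); within tiers by minimum $q$, then $|z|$, then variant id for
reproducibility.

## 5. What the simulator emulates — and what it does not

The generator's defaults state the cohort the pipeline targets: 111
probands, 1958 de novo + 1101 inherited rare SNVs (3059 total, hence the
61,180-oligo library), MAF < 0.001, detection by ≥ 2 technologies, all
within ±100 kb of a TSS with mild enrichment near the TSS; 20% of reference
elements planted active, split evenly between activators and repressors;
4.5% of variants planted with an allelic effect, decrease:increase ≈ 51:40.
Planted-fraction counts use the deterministic rounding rule
`floor(n * frac + 0.5)` so they are exactly reproducible.

Choices the source material leaves open, fixed here once:

* **Noise model.** NB with a single shared dispersion per run
  (default $\alpha = 0.05$ per barcode) — the model the delegated count test
  assumes. Per-barcode plasmid abundance is lognormal
  (default sdlog 0.5) around the mean depth (default 500 reads/oligo,
  a realistic targeted-sequencing depth), mimicking uneven
  synthesis/cloning. Because an element sums five barcodes with fixed
  abundances, its effective dispersion is roughly $\alpha/5$ — planted
  effects of 1 log2 unit are comfortably detectable at the default depth,
  which is what the power acceptance test measures.
* **Effect placement.** Planted activity applies at the element level (all
  five tags equally), since the analysis works on 5-tag sums. Effect
  variants are drawn from the active set with direction coupled to the
  reference element's sign — a decrease is a loss of activator function, an
  increase a loss of repression — and their allelic delta applies to the
  variant allele only, with the two remaining analogs left at baseline
  (mirroring the observation that alternative alleles carry minimal
  activity). With the default magnitudes (activity and allelic effect both
  1 log2 unit) the variant allele lands at baseline activity.
* **Replicates.** pDNA replicates are technical, cDNA biological; the test
  treats both simply as samples of their condition. The number of pDNA
  replicates sequenced is not stated in the source; default 2, configurable
  (the acceptance operating point uses 3 + 3).
* **HPO.** Universe 5000 terms, 20 terms per proband/TF; planted
  (proband, TF) pairs share 80% of their terms — far beyond the chance
  expectation of $t^2/N = 0.08$ shared terms — and are placed on variants
  that also carry an allelic effect, giving the doubly-planted positives the
  end-to-end test must recover.

Not emulated (and therefore not established by a green test): real human
genome composition and linkage, ChIP peak shape, read quality errors,
chromatin context, and any property of the real patient cohort. The
simulator validates the *pipeline*, not the biology.

## 6. Numerical and format conventions

* Inserts: 100 nt on the plus strand, 49 bases upstream + variant + 50
  downstream ("centered" with the even-length convention fixed and
  documented); variants whose window leaves the contig are rejected and
  logged.
* The ±100 kb TSS window is boundary-inclusive (a variant exactly 100,000 bp
  away is kept); MAF < 0.001 is strict.
* Barcodes: 12 nt; no BsaI (GGTCTC) or Esp3I (CGTCTC) site on either
  strand, no homopolymer ≥ 5, GC within 25–75%, pairwise Hamming distance
  ≥ 2 (enforced by per-position masked-key deduplication). These constraints
  beyond the enzyme sites are engineering choices for robust golden-gate
  cloning and demultiplexing, not claims about the original library.
* The fixed oligo flanks are placeholders chosen so no enzyme site can span
  a junction regardless of insert content (5' flank ends in `TT`; the
  spacer and 3' flank start with `AA` — no recognition-site prefix ends in
  T, none of their suffixes starts with A).
* Barcode matching is exact by default; with `max_mismatch = 1` a tag is
  rescued only when exactly one barcode lies within Hamming distance 1
  (ambiguity stays unmatched). Tags are read as sequenced, no
  reverse-complement search.
* Coordinates: variant tables 1-based (VCF convention), interval files
  0-based half-open (BED convention).
* Thresholds: activity padj < 0.05 and overlap q < 0.05 (the conventional
  defaults), |z| > 2 for effect calls; all configurable.

## 7. Known limitations

The dispersion trend is a two-parameter least-squares fit, not an
empirical-Bayes posterior; no outlier refitting or Cook's filtering; no
per-replicate z-scores or moderated deltas; no semantic-similarity HPO
scoring; interval logic assumes a single shared assembly. The CLI reads a
JSON configuration (one of the standard markup options) rather than YAML to
stay within the package's dependency footprint.
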