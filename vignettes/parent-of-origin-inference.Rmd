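---
title: "Inferring the parent of origin of haplotypes without parental genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the parent of origin of haplotypes without parental genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pofokit)
library(dplyr)
```

## The problem

A parent-of-origin effect (POE) is present when the phenotypic effect of an
allele depends on which parent transmitted it — the signature of genomic
imprinting and of parental conflict over resource allocation. Detecting POEs
requires, for each study participant, knowing which haplotype is maternal
and which is paternal. Biobanks rarely genotype parents, so `pofokit`
implements a multi-step inference that works from relatives instead:

1. **Relative classification.** Pairwise kinship and IBS0 (the proportion of
   sites sharing zero alleles) are estimated with the robust within-pair
   estimator
   $\hat\varphi = (N_{Aa,Aa} - 2N_{IBS0})/(N_{Aa}^{(a)} + N_{Aa}^{(b)})$.
   Parent–offspring pairs have $\hat\varphi \in [0.1767, 0.3535]$ with
   IBS0 $< 0.0012$ and an age gap above 15 years; siblings the same kinship
   range with IBS0 $> 0.0012$ and an age gap below 15 years; 2nd/3rd/4th
   degree relatives fall in the standard half-interval bins
   (0.0884–0.1767, 0.0442–0.0884, 0.0221–0.0442).
2. **Surrogate-parent clustering.** A target's 2nd–4th-degree relatives are
   clustered by their mutual relatedness: connected components of the
   relatedness graph correspond to the two family sides (groups G1/G2),
   without yet knowing which side is maternal.
3. **Interchromosomal phasing.** IBD segments (≥ 3 cM) between the target's
   haplotypes and each surrogate side anchor the haplotypes: all segments
   shared with one side must descend from one parent, so every G1 anchor is
   forced onto haplotype 0 on every chromosome, simultaneously correcting
   intrachromosomal switch errors between anchors.
4. **Parental-side assignment.** Whether G1 is the maternal or paternal side
   comes from three predictors: X-chromosome sharing (male targets share no
   X transmission path with paternal relatives), mtDNA minor-variant sharing
   (MVS — maternally inherited), and, for siblings, the sex-specific
   crossover score below.
5. **Encoding and scans.** Haplotypes get probability-weighted parental
   dosages, and four association scans (additive, paternal, maternal,
   differential) with a five-way POE classification complete the analysis.

## Probabilistic side assignment

For a predictor value $l$ (X sharing length in cM, or an MVS fraction) the
package uses the empirical-ratio estimator with a uniform prior over sides:

$$\widehat{\Pr}(\text{pat} \mid l(i,j) < l) =
  \frac{N_{pat}^{-1}\sum_i I(l_{pat}(i) < l)}
       {N_{pat}^{-1}\sum_i I(l_{pat}(i) < l) +
        N_{mat}^{-1}\sum_i I(l_{mat}(i) < l)}$$

with the symmetric "$> l$" form for the maternal side. Small values are
evidence for the low-sharing class, large values for the high-sharing class.
The estimator needs a rule for switching between the two forms; the package
places the cut at the training value maximising class separation
(`side_cut()`), oriented so that the "$< l$" form always belongs to the
class with the smaller mean — this keeps the estimator exactly symmetric
under an exchange of the class labels. Indicators are strict, so a query
below every training value returns an uninformative 0.5 rather than an
extrapolated certainty. Because the estimator is a ratio of step functions,
its output is only approximately monotone in $l$ (single training
observations can make it jitter by one step); evaluation is leave-one-out
throughout (`loo_side_predictions()`).

MVS is stratified by relative degree, and the degree used for
stratification is the *kinship-classified* degree, both in training and at
prediction. This matters: a maternal-side cousin reached through a male
uncle carries unrelated mtDNA, so low MVS is common among genuinely
maternal distant relatives. When the training stratum is built with the
same (noisy) degree classification the prediction faces, those broken-line
cases are part of the reference distribution and low MVS values correctly
yield low-confidence calls instead of confident paternal ones.

## The sibling crossover score

IBD segment breakends between siblings are crossovers in one of the four
parental meioses. Around each breakend position $p$ a 1,000-bp window is
converted to genetic lengths $D_f(p)$ and $D_m(p)$ on the female and male
maps, and

$$\Delta(p) = \log_{10} D_f(p) - \log_{10} D_m(p), \qquad
  S_c = \sum_{i \in \text{hap } 0}\Delta(p_i) -
        \sum_{i \in \text{hap } 1}\Delta(p_i), \qquad
  S = \sum_c S_c .$$

A negative $S$ means haplotype 0 is paternally inherited. With
interchromosomal phasing, crossovers aggregate over all autosomes into one
genome-wide score; without it, single chromosomes are called with the hard
thresholds $\pm 2$ and left undetermined in between. Window lengths are
floored at $10^{-8}$ Morgan before the logarithm so map plateaus cannot
produce infinities. Observed crossover counts are QC'd against the cohort
distribution per chromosome (expected Poisson with mean $4\,l_c$ over the
four meioses); individuals more than 10 interquartile ranges out are
dropped, with a Poisson tail test at $10^{-6}$ as the fallback when the
IQR degenerates. Genome-wide scores convert to probabilities by the same
empirical-ratio estimator against validation scores of similar analysed
genomic length ($\pm 3$ Morgans).

## What the simulator emulates

`simulate_cohort()` realises trios, duos, sibling pairs, and families with
2nd/3rd/4th-degree surrogate relatives (one or both sides). Meioses follow
a Poisson crossover process on the sex-specific cM scale — no crossover
interference, which none of the in-scope statistics is sensitive to, since
all of them consume marginal counts or positions. Males carry a single,
maternal X (pseudoautosomal regions are not modelled); mtDNA is copied from
the mother with a small per-meiosis flip rate plus call noise. Observed
data add per-allele genotype errors (default $10^{-3}$), Poisson switch
errors along the cM scale (default 0.005 per cM, i.e. 0.5 per Morgan), and
a random starting haplotype orientation per chromosome — the signature of
statistical phasing that makes interchromosomal phasing necessary at all.
Founder haplotypes are drawn site-independently from a Beta(0.8, 0.8)
frequency spectrum truncated to $[0.05, 0.95]$: no linkage disequilibrium,
which is adequate because no in-scope formula consumes LD except the
pruning utility (exercised on explicitly constructed correlated variants).
Ages are generation-consistent (parents about 28 years older, SD 3), so the
15-year classifier rule operates realistically.

**Genetic maps.** Per-interval cM increments combine a shared fine-scale
hotspot intensity (gamma, shape 0.3) with smooth, independent sex-specific
log-rate fields (cubic spline through 10 knots, SD 1), rescaled to the
requested totals (defaults scale to ≈ 43 female / 26 male Morgans over 22
autosomes). Both parts matter scientifically: hotspots are largely shared
between the sexes, while the female/male rate *ratio* varies on a broad
spatial scale. Detected breakends are displaced from the true crossover by
a few markers (identity runs extend to the next informative site), so if
the sex contrast were spatially incoherent the $\Delta$ signal would
vanish; the smooth fields reproduce the broad-scale differences of real
pedigree maps that the method actually exploits.

**What the simulator does not capture:** real LD and demography, genotype
intensity/clustering artefacts, population structure in kinship, real
hotspot motifs, uniparental disomy, consanguinity, X-inactivation or
pseudoautosomal recombination. Passing tests therefore demonstrate the
statistical machinery under the stated generative model, not performance
on any particular cohort.

## Numerical and design choices

- **IBD scanner.** The HMM-based IBD mapping of production pipelines is
  replaced by an identity-run scanner: maximal match runs, bridging
  isolated single-site mismatches while a block's mismatch rate stays
  ≤ 1/100, splitting at two consecutive mismatches. Segments need ≥ 3 cM
  *and* ≥ 20 markers: at desk-scale marker density a 3-cM span inside a
  hotspot can cover a handful of markers, where chance IBS runs would pass
  the cM floor. Both knobs are exposed (`min_cm`, `min_sites`,
  `max_mismatch_rate`).
- **Censoring by the 3 cM floor.** On truth segments the floor removes
  ~5–10% of true short segments and hence of breakends; the crossover-rate
  validation in `scripts/acceptance.R` therefore measures the rate with
  error-free segments and the floor disabled, while the unit tests pin the
  censored value as well so the trade-off stays visible.
- **Flip points.** Between anchors demanding opposite orientations the
  switch position is unidentifiable; the flip is placed at the physical
  midpoint of the gap. With sparse anchors this can split one true switch
  into two counted switch points; with dense anchors the residual switch
  error falls well below the input rate.
- **Marker support.** Simulated studies use ~15 markers per cM
  (e.g. 12 autosomes × 3,000 markers). Below ~8 markers/cM, chance IBS
  runs start passing both segment guards and contaminate anchors and
  relative discovery; above ~15 the behaviour is stable. Cohort sizes in
  the validation suites (e.g. 120 families; 500–2,000 sibling pairs) were
  chosen so that every Monte-Carlo mean in the tests has a standard error
  at least four times smaller than its asserted tolerance.
- **Ties and boundaries.** Classification degree bins are right-open;
  kinship above 0.3535 is labelled `duplicate`; a first-degree pair with a
  missing age stays `first_degree` (no parent/sibling call). In
  `classify_poe()` the parent-dominant rules are evaluated before the
  asymmetric rules, making the five classes a partition; an exact magnitude
  tie with equal signs resolves to the maternal-asymmetric branch.
- **Regression backend.** Scans are plain least squares (QR, exact t
  tests) and `glm.fit` logistic regression with separation flagged by
  non-convergence or runaway estimates; the whole-genome ridge step of
  biobank GWAS tools is intentionally omitted because simulated cohorts
  carry no polygenic confounding (a polygenic covariate can be added
  through `covariates` for stress tests).
- **Replication contrast.** The differential summary statistic is the
  signed contrast $(\beta_P - \beta_M)/\sqrt{se_P^2 + se_M^2}$; a squared
  numerator cannot produce a signed two-sided statistic, and the worked
  value for rs146982369 (4.574) confirms the signed reading.

## Limitations

Kinship at desk scale has visible sampling noise: realized-kinship variance
on short simulated genomes occasionally misclassifies relationship degrees,
which the classified-degree stratification absorbs but does not eliminate.
The empirical-ratio probabilities are step functions of the training set and
are exactly calibrated only in the leave-one-out sense; very small strata
can still produce overconfident tails. The X predictor is calibrated for
male targets only (females receive paternal X, so sharing is uninformative
about sides in the same way). Sibling-only targets without any surrogate
scaffold receive per-chromosome threshold calls, not genome-wide ones.
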