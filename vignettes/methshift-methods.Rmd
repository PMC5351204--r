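---
title: "Methods: case-control RRBS differential methylation with methshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control RRBS differential methylation with methshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methshift)
```

## The problem

Reduced representation bisulfite sequencing (RRBS) measures DNA methylation
at single-cytosine resolution in CpG-dense regions. In a case-control design
the questions are, in increasing order of aggregation: is any single cytosine
differentially methylated; is any *region* of nearby cytosines
differentially methylated; and is there a *global* shift — an excess of
sites moving in one direction — even when no single site survives
study-wide correction? The last question is the motivating one for this
package: in post-mortem brain tissue, methylation outside the CpG context
(CpH, H = A/C/T) is abundant and developmentally dynamic, and a diffuse
excess of small CpH increases in cases is exactly the kind of signal a
per-site test at stringent thresholds will miss.

methshift implements the full chain — preprocessing, sample QC, per-site
weighted models, a residual-bootstrap empirical null, the global
hypermethylation-shift test, bump-hunting DMR detection with bootstrap FWER,
and Fisher-exact functional enrichment — together with a synthetic RRBS
generator so every stage is testable without external data.

## The per-site model and its empirical null

At each site, percent methylation $y_{ij} = 100\,m_{ij}/c_{ij}$ (methylated
reads over coverage) is regressed on the design

$$y_{ij} = \beta_0 + \beta_d\,\mathrm{dx}_j + \gamma^\top z_j +
  \varepsilon_{ij}, \qquad \mathrm{Var}(\varepsilon_{ij}) \propto 1/w_{ij},$$

with $z_j$ = age, sex, brain bank and $k = 10$ surrogate variables, and
weights $w_{ij} = \log_{10} c_{ij}$: coverage governs the precision of the
percentage estimate, and the $\geq 10\times$ coverage filter guarantees
$w \geq 1$. The diagnosis coefficient $\beta_d$ is the case-minus-control
difference in percentage points. Masked entries carry weight zero, which is
algebraically identical to dropping them; residual degrees of freedom count
only unmasked entries.

Percentages are bounded and their variance is mean-dependent, so nominal
t-distribution p-values are not trusted for study-wide decisions. Instead a
**residual bootstrap** builds an empirical null: fit the full model and the
null model (diagnosis removed) once per site; per bootstrap draw one vector
of sample indices with replacement — *shared across all sites*, preserving
the cross-site correlation that any min-p or proportion statistic depends on
— and form the pseudonull response

$$y^{(b)} = \hat y_{\mathrm{null}} + \hat\varepsilon_{\mathrm{full}}[\pi_b].$$

Because $\hat y_{\mathrm{null}}$ lies in the column space of the null
design, refitting the full model on $y^{(b)}$ yields a diagnosis
coefficient driven purely by resampled residuals: a genuine null, whether
or not the observed data carry effects. Study-wide significance per site
uses the $\alpha$ quantile of the per-bootstrap minimum p-value;
the global test compares the observed hypermethylated proportion among
nominal sites (p below 0.05, 5e-3, 5e-4) to the same proportion recomputed
in every bootstrap, with a one-sided, +1-smoothed empirical p-value.
"Hypermethylated" is operationalized as $\hat\beta_d > 0$; exact zeros are
excluded from both numerator and denominator.

Two numerical notes. First, pseudonull refits reuse the observed weights:
weights describe measurement precision, which resampling does not change.
Second, residuals at masked entries are set to zero before resampling; a
resampled masked residual contributes the null fit at its destination, and
the destination's own mask (weight 0) still removes it from refits. With
mild weight heterogeneity ($\log_{10}$ coverage spans roughly 1–2) the
pooled pseudonull p-values are uniform to Kolmogorov–Smirnov distance
$\approx 0.01$ in the acceptance tests, against a tolerance of 0.05.

## Preprocessing choices

* Coverage $\geq 10\times$ retained; per sample, entries above the 99.9th
  percentile of coverage (linear-interpolation quantile, computed after the
  lower filter) masked as PCR-bias suspects. The DMR branch relaxes the
  lower bound to $\geq 5$ reads.
* Median normalization: each sample scaled to the median of per-sample
  median coverages; counts are rounded back to integers (methylated clipped
  to coverage), so a sample's methylated fraction moves by at most
  $1/c_{\mathrm{out}}$.
* Sites united across $\geq 20$ cases and $\geq 20$ controls.
* The 25% least variable sites (SD of percentages, unweighted) are dropped;
  ties break by genomic order, lower coordinate dropped first.
* Per-site outlier masking is a single pass at 3 SD. The z-score of one
  extreme value among $n$ is bounded by $(n-1)/\sqrt n$, so no masking can
  occur for $n < 11$ at this threshold — a useful analytic sanity check on
  any implementation.

## Surrogate variables and sample QC

`estimate_svs()` implements a deliberately simple iteratively-reweighted
SVA: residualize complete-case sites against the protected design (keeping
case-control status in the design is what "protecting" means here), take the
top-k left singular vectors, reweight sites by evidence of association with
the SVs but not with diagnosis — the weight is $(1 - p_{\mathrm{sv}})\cdot
p_{\mathrm{dx}}$ from two F-tests — and re-decompose; five rounds, k fixed
at 10 rather than estimated. A planted confounder loading on 40% of sites
is recovered by SV1 with $|r| \geq 0.9$ at n = 60 and 5000 sites.

Sample-level QC formalizes three library-failure modes as flags with
configurable thresholds: fraction of cytosines above 50% methylation
(failed bisulfite conversion; flag > 0.99), fraction of CpG sites in the
20–80% mid-range (loss of CpG bimodality; flag > 0.5), and the
Kolmogorov–Smirnov distance between a sample's log-coverage ECDF and the
pooled ECDF (aberrant coverage; flag > 0.3). The KS rule is our
formalization of "does not match the expected distribution"; there is no
canonical definition. Iterative SV-based outlier removal (4 SD on any SV,
column SD including the candidate, all flagged removed, repeat) follows,
and each round can be validated by cis-meQTL recovery: the fraction of
known SNP–site pairs (within 1 Mb, additive dosage, OLS with covariates)
re-detected should not fall when a genuine outlier is removed.

## DMR detection

Sites cluster at `maxgap = 300`; within clusters of at least 7 sites the
diagnosis coefficients are smoothed by a centered 5-site running mean
(truncated at edges; smaller clusters pass through). The cutoff is the
0.99 quantile of |smoothed| — a data-driven stand-in for the reference
engine's pickCutoff — computed once on the observed data and reused for
bootstrap candidates, and picked globally rather than per chromosome (at
the simulated scale a per-chromosome quantile would be estimated from too
few clusters; on genome-scale data the two choices converge). Maximal
runs above the cutoff become candidate regions whose `value` is the mean
raw coefficient and whose FWER is the fraction of bootstraps containing a
null candidate *strictly longer and higher in |value|* — the conjunction
makes single-site spikes cheap to dominate on length and long weak runs
cheap to dominate on value. Significance is `fwer < alpha/n_tests` at the
FWER's printed resolution: 0.05/24 rounds to the operative threshold
0.002, so fwer 0.001 is significant and 0.002 is not.

## Enrichment and power

Hypermethylated sites (nominal p below a cutoff, positive coefficient) are
tested for enrichment in annotation categories by a two-sided Fisher exact
test computed by full hypergeometric enumeration; the background is all
tested sites, which is what a 2×2 table over the analysis implies. Beacon
annotations take "the 200 bp flanking" a CpG as 200 bp total (±100);
`per_side = TRUE` gives the ±200 reading. Replicate histone tracks combine
by genomic intersection.

Power for a two-sample t test with unequal n comes from the noncentral t
with ncp $d\sqrt{n_1 n_2/(n_1+n_2)}$; `min_detectable_diff()` inverts it by
bisection to 1e-6 and scales by a user-supplied per-site SD. The SD is a
property of the data, not the test, and is deliberately a required input:
a published "minimum detectable difference" cannot be recomputed without
it.

## The synthetic generator: what it emulates, and what it does not

Defaults state the world the analysis is designed for: 29 cases / 34
controls; CpG baselines from a two-component beta mixture (weight 0.7 on
Beta(0.9, 29.1), 0.3 on Beta(6.37, 3.63)) with marginal mean ≈ 21.2%
methylation; CpH baselines Beta(0.6, 34.7), mean ≈ 1.7%; negative-binomial
coverage with mean 30 and variance ≈ 3× mean (no coverage distribution is
published; this is a convention, recorded as such); case-only CpH
hypermethylation at 30% of sites with per-site shifts gamma-distributed
around a median of 1.8 percentage points. Effects are planted on the logit
scale so probabilities stay in (0, 1) at any baseline, and are reported in
percentage points measured empirically. Site counts default to 2000 CpG /
6600 CpH — the ~1:3.3 genome-scale ratio at 1/500 scale. Positions are
drawn per MspI-like fragment (runs of 3 + Poisson(9) sites within 180 bp)
rather than uniformly: RRBS cytosines are clumped, and region-level
behavior — cluster sizes, smoothing, the null FWER distribution — is only
meaningful on clumped positions. Age, sex and bank carry small fixed logit
effects; latent confounders load on ~40% of sites. QC failure modes
(hypermethylated, non-bimodal CpG, heavy-tailed coverage) and cis-meQTLs
(Hardy–Weinberg dosages, additive shifts) can be injected with ground truth
recorded.

What the generator does **not** emulate: fragment-level library
preparation, sequencing error, bisulfite non-conversion, 5hmC, spatial
correlation of methylation beyond planted DMRs, and realistic linkage
disequilibrium. A green test therefore establishes that the *statistical
machinery* behaves as specified under the stated world — calibration,
power, recovery, oracle equivalence — not that the biological conclusions
of any particular study are reproduced.

## What the tests establish

`tests/testthat/test-acceptance.R` implements the acceptance surface: (1)
the 0.05/24 threshold reproduces 0.002; (2) under null simulations the
global test rejects at a rate whose 95% binomial CI covers 0.05 (observed
4/100 at B = 99) with mean hypermethylated proportion in [0.45, 0.55];
(3) median +1.8-point shifts on 30% of CpH sites are detected in ≥ 90% of
50 replicates; (4) the WLS fits, Fisher p-values, quantile filters and
clustering match independent brute-force oracles (normal equations to
1e-10; full enumeration; sort; union-find); (5) planted confounders, an
injected fully-methylated sample, and a planted 10-site DMR are recovered
(Jaccard ≥ 0.5, minimal FWER, ≥ 90% of 20 replicates at B = 50); (6)
pooled pseudonull p-values are uniform (KS < 0.05) with and without
planted effects. Bootstrap counts in the tests are the scaled values the
criteria prescribe; pipeline defaults remain B = 1000.

## Known limitations

The IRW-SVA weighting is a simplified heuristic, not the reference
implementation; k is fixed, not estimated. The global test's bootstrap
exchanges residuals across samples with unequal weights, which is only
approximately exchangeable — the acceptance KS bound quantifies the
distortion. FWER dominance uses strict conjunction on length and |value|,
which is conservative for short strong regions. Fisher enrichment uses an
unmatched background; GC- or density-matched backgrounds are out of scope.
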