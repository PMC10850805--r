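---
title: "Prioritizing cancer-type-specific therapeutic vulnerabilities from CRISPR dependency screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing cancer-type-specific therapeutic vulnerabilities from CRISPR dependency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnprior)
```

## The problem and the model

Genome-wide CRISPR loss-of-function screens report, for every cell line
$l$ and gene $g$, a *gene-effect score* $e_{lg}$ — a normalized measure of
how strongly deleting $g$ reduces the viability of $l$. The scale is
anchored so that non-essential genes centre at 0 and pan-essential genes
at $-1$; lower scores mean stronger dependency. A companion *dependency
probability* $p_{lg} \in [0,1]$ measures how likely $e_{lg}$ is to belong
to the essential-score distribution, given the screen quality of line
$l$.

`vulnprior` turns a (effect, probability) matrix pair for one cancer
type's cell-line panel into a ranked list of druggable, cancer-specific
targets, then validates targets against drug-response data and screens
for genetic biomarkers of dependency. The filtration waterfall is:

1. **Essentiality call.** $g$ is essential in $l$ iff $p_{lg} \ge 0.5$
   (inclusive). Per gene, count $n_g = \#\{l : \text{essential}\}$ over
   $N_g$ screened (non-missing) lines; keep genes with $n_g \ge 1$.
2. **Druggability.** Intersect with an externally curated druggable-gene
   list.
3. **Therapeutic window.** Remove the union of *common-essential* genes
   (dependencies in > 90% of all screened cancer lines) and *core
   fitness* genes (essential across normal lineages in independent
   screens): both predict toxicity to normal tissue.
4. **Frequency.** Remove genes with $n_g / N_g < 0.09$. Dependencies
   called in so few lines are dominated by stochastic single-screen
   effects; the cutoff is fractional so it transfers to panels of any
   size (at an 87-line panel it coincides with "fewer than 8 lines").

Survivors are ranked by $n_g$ (descending), then by the median of
$e_{lg}$ *over the dependent lines only* (ascending — more negative
first), then alphabetically. Every stage is recorded in an audit that
enforces $n_{\text{in}} = n_{\text{out}} + |\text{removed}|$; a report
that violates this conservation law cannot be emitted.

### Design choices in the waterfall

* **Dependent-lines median.** "Median gene effect" of a target is taken
  over the lines where the gene is called essential; the median over all
  lines is also computed and selectable (`rank_by = "all"`), because
  published scatter plots of this kind are ambiguous about the
  convention.
* **Inclusive threshold.** $p \ge 0.5$, not $>$; the boundary case is a
  documented behaviour, not an accident.
* **Tie-break.** The three-key sort (frequency, dependent-median,
  symbol) is a total order, so ranking is reproducible across platforms.
* **Mismatched gene universes.** Genes present in the effect matrix but
  absent from the probability matrix are dropped with a warning rather
  than an error — real data releases differ slightly; any other
  misalignment errors out with the symmetric difference.

## Statistical kernels

All p-values are two-sided. The kernels are implemented from their
defining formulas and cross-checked in the test suite against
`stats::t.test`, `stats::wilcox.test`, `stats::oneway.test` and
brute-force enumeration:

* **Welch t** with Satterthwaite df (Student's pooled t by option).
* **Mann–Whitney U**: exact permutation enumeration (all
  $\binom{n_a+n_b}{n_a}$ labelings) when both groups have $\le 8$
  tie-free values; otherwise the normal approximation with midranks,
  tie-corrected variance and continuity correction. Exact mode refuses
  ties and falls back with a warning. Because U is discrete, *any*
  Mann–Whitney variant is conservative at small n — calibration checks
  are run at sizes where the approximation is appropriate.
* **Welch one-way ANOVA** (heteroscedastic F); with two groups it equals
  the squared Welch t.
* **Dunnett many-to-one comparisons** against a designated control,
  adjusted by the family-wise max-|t| distribution under the standard
  Dunnett correlation $\rho_{ij} = \sqrt{\lambda_i\lambda_j}$,
  $\lambda_i = (s_0^2/n_0)/(s_0^2/n_0 + s_i^2/n_i)$. The multivariate-t
  integral is evaluated by *seeded Monte-Carlo* (default $10^5$ draws;
  `mc_seed` isolates the draw from the caller's RNG stream).
  Per-comparison Satterthwaite df use independent chi-square
  denominators: exact for one comparison, a mild approximation for more.
  Adjusted p-values are clipped to `pmax(adjusted, raw)` so the
  monotonicity contract survives MC noise.
* **Holm–Šidák** step-down adjustment with a running maximum for
  monotonicity.
* **Cohen's d** with the pooled-SD denominator.
* **Pearson r** with $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df.
* **Kaplan–Meier / log-rank** are delegated to the `survival` package
  behind `km_logrank()` — standard infrastructure, not re-derived here.

## Drug-response validation

For each prioritized target with inhibitor data, cell lines are split on
the target's gene-effect distribution into **high** (top quartile, most
negative), **intermediate** (middle half) and **low** (bottom quartile)
dependency. Quartiles use linear interpolation on the sorted values
(`quantile` type 7, position $p(n-1)$) with inclusive boundaries; the
convention matters for membership near the cut points and is therefore
fixed and documented. Responses (ln IC50 by default, AUC by option; both
oriented so lower = stronger response) are compared by Welch ANOVA with
Dunnett adjustment, using the **low-dependency stratum as the control**
— the scientific contrast of interest is high vs. low. With only two
populated strata the omnibus falls back to Welch t (or Mann–Whitney by
option). A target is *validated* when the adjusted high-vs-low p is
below $\alpha$ **and** the high stratum responds more strongly. Lines
with drug data but no screen data (or vice versa) are dropped pairwise
with the joined n recorded. Dose–response curves are averaged per
stratum on the union concentration grid (linear interpolation inside
each curve's observed range, flagged when used); the separation score is
the mean high-minus-low viability across concentrations.

## Biomarker discovery

The mutation screen compares gene-effect values between mutant
(any hotspot and/or damaging record) and wildtype lines per
(target, biomarker) pair with a Welch t-test. A pair is significant when
$p < 0.05$ **and** $|d| \ge 1$ — the effect-size gate, not a
multiple-testing correction, controls the screen (a Benjamini–Hochberg
column is emitted for information only). Cohen's d is oriented
mutant-minus-wildtype and the gate uses $|d|$, so the orientation
convention cannot change the hit list. Lines absent from the mutation
table are *unknown* and excluded from both groups rather than defaulted
to wildtype. Biomarkers below 5% mutant prevalence are excluded before
testing.

Copy-number analyses use the discrete 5-level GISTIC code (−2 deep
deletion … +2 amplification; "copy gain" means code ≥ 1).
Co-amplification frequency is the fraction of anchor-amplified tumours
in which a partner is also amplified. Amplicon stratification compares a
per-sample quantity between amplified and non-amplified samples by
Mann–Whitney. When a precomputed absolute-copy-number amplification flag
is unavailable, a threshold on log2 copy number (≥ 1, i.e. ≥ 4 copies)
can substitute — it is a proxy and is labelled as such, since the
original absolute-CN thresholding is not reproducible from summary data.

One phrasing in the source methods is internally inconsistent — a
"t-test comparing the median gene effect score" (t-tests compare means).
We test the per-line gene-effect values directly; the "median" reading
is noted here and nowhere enforced.

## The synthetic panel

`generate_panel()` draws a complete study from a `panel_config`:

| quantity | default | rationale |
|---|---|---|
| lines | 87 (63 primary + 24 related lineage) | mirrors a realistic single-cancer-type panel assembled from two closely related lineages |
| genes | 2000 | large enough for a structured waterfall, small enough for seconds-scale tests |
| planted targets | 20, dependent in 30% of lines, effect $\mathcal N(-0.6, 0.15)$ | clearly above the 9% cutoff, clearly druggable-grade effect sizes |
| exclusion sets | 80 common-essential + 60 core-fitness, 40 shared, effect $\mathcal N(-1, 0.2)$ everywhere | matches the −1 anchoring of pan-essential genes |
| low-frequency targets | 15, dependent in 5% of lines | the population the frequency filter exists to remove |
| non-essential genes | effect $\mathcal N(0, 0.15)$ | the 0-anchoring of the scale |
| probabilities | dependent cells $\mathcal U(0.6, 1)$, others $\mathcal U(0, 0.4)$ | drawn directly, not derived from effects: the probability is treated as an independently supplied input, and direct control makes filter behaviour exactly predictable |
| biomarkers | 5 genes at prevalences 0.79/0.30/0.25/0.18/0.15 | five common cancer genes at ≥ 5% prevalence, one near-ubiquitous |
| amplicon | 1 anchor + 5 partners; 21% of lines amplified; tumour gain rate 0.70, amplification rate 0.123, partner co-amplification 0.95 | a passenger-amplified locus whose amplified lines lose the dependency |
| drugs | ln IC50 $= 2\,e_{lg} + \mathcal N(0, 0.3)$ for 60% of lines | a strong planted pharmacological readout of the dependency |
| tumour cohort | 523 (415 HPV-negative / 72 positive / 36 unknown), exponential survival, equal hazards by default | cohort-subsetting arithmetic plus a null survival contrast |

Gene-class labels are a pure function of the configuration (no RNG), so
the planted truth is known before any value is drawn. Each output file
has its own RNG stream derived from the master seed by a stable integer
hash, so adding an output never perturbs the others, and identical seeds
give byte-identical bundles (verified by content hash).

What the generator does **not** emulate: screen-quality normalization
and copy-number bias correction inside the scoring algorithm,
correlated co-mutation structure beyond the planted blocks, dose–curve
fitting noise models, and real panels' missing-data patterns. A green
planted-recovery test therefore establishes that the filter chain and
statistics behave as specified on data of the stated shape — not that
the defaults reproduce any particular frozen data release, which would
require the original downloads.

## Numerical choices and degenerate inputs

* Missing values are never imputed; every denominator counts non-missing
  entries and operations report their effective n.
* Quartile stratification requires ≥ 4 non-missing, non-constant values;
  fewer (or all-identical) inputs are errors, not silent defaults.
* `associate()` and `stratify_by_amplification()` require ≥ 2 per group;
  in screen mode a failing pair is recorded and skipped, not fatal.
* Exact Mann–Whitney compares $|U - n_a n_b/2|$ with a $10^{-9}$ slack
  so floating-point rank sums cannot flip a boundary labeling.
* Matrix writers serialize doubles at 17 significant digits, making the
  write/read round trip bit-identical.
* Zero-variance groups: Welch t errors when both groups are constant and
  equal, and returns an infinite statistic with p = 0 when constant but
  different; Welch ANOVA and Cohen's d reject zero-variance input.

## Time-budget scaling

Simulation-based checks in the regular unit tests run at 100–200
replicates; the acceptance suite runs the stated sizes (500 simulations,
1000 null replicates, 50 null panels, 20 recovery seeds) and the Dunnett
Monte-Carlo inside the 500-simulation loops uses 4000 draws instead of
the $10^5$ default. At p ≈ 0.05 that MC error is ~0.007, an order of
magnitude inside the acceptance bands, and the default is unchanged for
users.

## Known limitations

* The Dunnett MC draw treats per-comparison chi-square denominators as
  independent; for many comparisons with very unequal group sizes the
  family-wise error can deviate by a few thousandths (covered by a
  simulation test).
* The mutation screen models mutation status as a flat flag; variant
  classes beyond hotspot/damaging are carried but not interpreted.
* Survival analysis is limited to Kaplan–Meier and the log-rank test; no
  hazard regression.
* The pipeline does not re-derive dependency probabilities from effect
  scores, re-compute the common-essential / core-fitness designations,
  or fit dose–response curves: all are treated as upstream inputs, as in
  the study design it implements.
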