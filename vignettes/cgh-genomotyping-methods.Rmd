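---
title: "Methods: presence calling, pan-genome statistics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence calling, pan-genome statistics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghpangenome)
```

This vignette documents the models and numerical choices behind the package:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open.

## The measurement model

A two-color CGH experiment reports, for each probe *g* of a sequenced
reference genome and each hybridized test strain *s*, replicate log ratios
x<sub>g,s,r</sub> = log2(test signal / reference signal). If the test strain
carries an intact copy of the gene, the ratio scatters around 0; if the gene
is deleted or strongly diverged, cross-hybridization fails and the ratio is
strongly negative. The distribution over genes for one strain is therefore a
mixture: a dominant "present" component near 0 and a left-shifted
"absent/diverged" component. The package treats the normalized log ratios as
its input boundary — scanner-level normalization is assumed done upstream.

## Probe quality control

Two filters precede calling:

* **Self-self background filter.** Probes that do not hybridize when
  reference DNA is in both channels are uninformative for every strain. A
  probe is kept iff its mean raw signal across self-self replicates is
  strictly above `mean(background) + k·sd(background)` in *both* channels;
  `k = 3` by default. The strict inequality means a probe exactly at the
  threshold is flagged. When no raw signals are available the stage is
  skipped with a warning rather than guessed.
* **Per-probe ANOVA.** A one-way fixed-effects ANOVA of the replicate log
  ratios across strains, Bonferroni-corrected over all tested probes at
  α = 0.01. The F statistic is computed vectorised from group sums and
  matches `stats::aov` to numerical precision (this is asserted in the
  tests). Degenerate probes with zero within-group variance get p = 1 (no
  between-group difference) or p = 0 (exact separation).

What to *do* with the ANOVA verdict is genuinely ambiguous in the procedure
this package operationalizes: retaining only significant probes (probes that
differ between strains) discards the entire core genome, because a gene
present in every strain shows no strain effect; discarding significant
probes instead removes exactly the informative variable genes. Both readings
are implemented (`anova_policy = "keep_significant"` / `"drop_significant"`),
but the pipeline default is `"none"`: the statistics are computed and
reported, and no probe is removed on their account. This is the only policy
under which core-genome recovery and trait association can both work, and we
regard the filter as a probe-consistency diagnostic rather than a gate.

Replicate spots are then averaged per probe and strain (arithmetic mean over
non-missing replicates; a strain with zero valid replicates yields a missing
value that is treated as uncallable, i.e. absent, downstream).

## The presence model and EPP

Per strain, `fit_presence_model()`:

1. estimates the log-ratio density f̂ by a Gaussian KDE with Silverman's
   rule-of-thumb bandwidth on a 512-point grid spanning the data ± 3
   bandwidths;
2. locates the presence peak *m* as the rightmost local maximum with at
   least 10% of the global maximum height (so massive deletion loads cannot
   hijack the mode), refined to sub-grid accuracy by a parabola on the log
   density across the peak top;
3. estimates the presence-component scale σ̂ from the mirrored right half,
   σ̂² = mean((x − m)²) over x ≥ m, assuming the right flank is free of
   absent genes;
4. forms a Gaussian presence component g centred at *m* and divides by f̂ to
   get the estimated probability of presence, EPP(x) = 1 for x ≥ m and
   min(1, g(x)/f̂(x)) otherwise;
5. regularizes EPP to be non-decreasing in x by isotonic regression left of
   the mode.

Calls are `EPP > 0.95` per gene and strain; the per-strain report includes
the implied log-ratio cutoff x<sub>c</sub> = inf{x : EPP(x) > 0.95}, which is
the quantity a fixed-threshold analysis would have had to guess.

### Numerical choices in step 4 and 5, and why they matter

The density *ratio* near the peak is the fragile part of this construction.
Three facts interact badly: (i) the KDE is kernel-broadened, so the fair
comparison width is σ̂² + bw², not σ̂²; (ii) at realistic n (10³–10⁴ genes
per strain) *no* estimator pins the component variance to better than a few
percent (the sampling error of σ̂² alone is √(2/n)); and (iii) a few percent
of width understatement makes the ratio dip below 0.95 across the entire
present bulk, flipping thousands of clearly-present genes at once. The
asymmetry of the risk dictates the remedy:

* the numerator width is σ̂² + bw² inflated by
  `max(5%, 4·√(2/n_right))` — a few standard errors of the variance
  estimate. Understating the width is catastrophic; overstating it by a few
  percent merely moves x<sub>c</sub> a little further toward the absent
  class, which sits ~5σ away;
* the ratio is credited with two pointwise KDE standard errors
  (SE = √(f·R(K)/(n·h)), R(K) = 1/(2√π) for the Gaussian kernel) before a
  dip counts as evidence of absence. A hovering ratio of 0.94 that is
  statistically indistinguishable from 1 no longer slices the peak, while
  the orders-of-magnitude density drop at the absent class is unaffected;
* monotonization uses isotonic regression rather than a cumulative minimum,
  so an isolated noise dip is averaged with its neighbours instead of being
  propagated across everything to its left.

All of these are exposed (`width_inflation`, `se_z`, `bandwidth`,
`peak_frac`, `grid_n`, `eps`) and all are validated against an analytic
oracle: the same construction evaluated with the *true* mixture densities.
On the reference 85/15 mixture (Normal(0, 0.3) vs Normal(−2.5, 0.5)) the
fitted EPP tracks that oracle to a mean absolute deviation below 0.01 and
calls with balanced accuracy above 0.99; on pure single-component data
essentially every gene gets EPP > 0.95, as it must.

The fit refuses inputs with fewer than 200 finite log ratios (too little
data to estimate a density mode reliably — supply an explicit cutoff
instead) and inputs whose presence-peak scale collapses below 10⁻³, the
automated analog of rejecting a hybridization whose fitted component is
visibly misplaced.

## Pan-genome statistics

With the binary matrix P in hand the partition is set algebra, computed by
matrix operations and cross-checked in tests against per-gene enumeration:
core = genes present in every in-group strain (outgroups excluded from the
scope by default, configurable); reference-specific = present in the
reference and absent everywhere else including outgroups; overlaps
O = PᵀP; dissimilarity d(s) = share of reference-present genes that strain
*s* lacks, reported in percent together with the raw counts. The identity
d(s) = 1 − O(ref, s)/O(ref, ref) is asserted on every partition.

## Dendrogram

Distances are mismatch proportions over kept probes (Jaccard available).
Neighbour joining is the classical Saitou–Nei agglomeration with the
standard branch-length and distance-update formulas; ties in the Q criterion
are broken by lexicographic order of the sorted label pair, which makes the
output invariant to input order. Negative branch-length estimates are
clamped to zero with a warning, per common practice. On additive distances
the tree's path-length matrix reproduces the input to machine accuracy, and
the implementation is cross-checked against an independent NJ implementation
on random matrices in the tests.

Bootstrap supports resample genes (matrix rows) with replacement B = 1000
times by default, rebuild the tree each time, and count bipartitions. Both a
majority-rule (>50%) consensus and the full-data tree are returned with
supports painted as node labels, since a "consensus dendrogram with
supports" can mean either presentation. Only non-trivial bipartitions (2 to
n−2 taxa a side) are tabulated; the split separating a single outgroup tip
is present in every unrooted tree and carries no information.

## Trait association

The filter searches, among strains assigned to phenotype groups A and B
(reference and outgroups excluded), for genes present throughout A and
absent throughout B. The relaxation tolerates one false negative *or* one
false positive — an exclusive-or, so a gene with one of each is rejected
under the default rule (`max_fn = 1`, `max_fp = 1`, `cap_sum = TRUE`); both
caps and the exclusivity are configurable. Only the A-present direction is
searched because all probes derive from the reference genome: genes private
to the B group are unobservable on such an array, so reversing the direction
is a deliberate, separate query (swapping the group labels). The
implementation is exact — tests compare it against brute-force enumeration
over all genes and tolerance settings.

The 16-strain coccolith table and the 16×9 virus-lysis matrix ship as
fixtures. The published design does not state how a 9-virus lysis matrix
collapses to binary susceptibility — one strain is lysed by exactly one
virus, another by seven — so the rule is a parameter (`min_lysed`, default
1: susceptible if lysed by at least one virus) rather than a silent guess.

## The synthetic-data generator

`simulate_pangenome()` + `simulate_arrays()` emulate the structure of the
emulated experiment: 16 in-group strains (the first is the reference and
carries every probe) plus one outgroup, 2,000 gene probes, technical
triplicates, self-versus-self reference arrays, and a planted 2% of probes
whose raw self-self signals sit at background level. Defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `core_fraction` | 0.6 | roughly half the probes core, as in large strain panels |
| `loss_rate_per_branch` | 0.05 | yields ~4–18% per-strain dissimilarity, the published range for intraspecific CGH panels |
| `present_mean/sd` | 0 / 0.3 | clean present peak |
| `absent_mean/sd` | −2.5 / 0.5 | ~5σ separation, the clean bimodality the dynamic-cutoff method assumes |
| `diverged_mean/sd`, `diverged_fraction` | −1.0 / 0.3, 0.1 | a minority grey zone exercising the EPP transition |
| `replicate_sd`, `n_replicates` | 0.1, 3 | technical triplicates with mild extra spot noise |
| `outgroup_absent_fraction` | 0.3 | ~30% content difference to the outgroup species, matching the published outgroup divergence; mostly shared (ancestral) across outgroups, plus one third individually |
| `n_trait_genes` | 20, 7/8 split | planted perfectly trait-matching genes among the variable genes |

Gene loss evolves along a random strain tree (sequential random attachment,
exponential branch lengths) as irreversible per-branch Bernoulli events, so
gene content covaries with phylogeny and the dendrogram stage has signal to
recover; a star-tree mode gives i.i.d. loss when that correlation is
unwanted. "Diverged" entries score as absent when calls are compared with
truth, since a diverged gene is exactly one whose probe no longer
hybridizes.

What the generator does **not** emulate: dye bias, spatial artifacts, probe
cross-hybridization, intensity-dependent variance, or sequence-level
divergence. Passing tests therefore demonstrate that the inference chain is
correct *under its own model assumptions* — a clean mixture with exchangeable
noise — not that it is robust to every artifact of real arrays. The grey
diverged class is the one deliberate stress on the mixture assumption.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 10,000 genes for the
caller's balanced-accuracy check and 50,000 for the analytic-oracle
comparison; 100 random 8-taxon additive matrices for neighbour joining;
B = 200 bootstrap replicates for the support checks; and the full default
16-strain, 2,000-gene experiment for end-to-end recovery. These sizes give
every statistic a comfortable margin over its sampling noise while keeping
a complete validation run in well under a minute.

## Known limitations

* Binary output only: no present/uncertain/absent trinary mode.
* The EPP construction assumes a symmetric, unimodal present component with
  an uncontaminated right flank; heavy right-skew or a present class split
  by copy-number gain would bias σ̂.
* Between-array normalization is out of scope beyond optional
  median-centering; the package trusts its input log ratios.
* Trait hits carry no significance model — the filter is set algebra, and
  with ~600 variable genes and a 7/8 split, chance-matching genes occur and
  are reported as hits exactly as a real screen would report them.
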