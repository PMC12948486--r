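---
title: "Dating a mobile gene family with transfer-derived calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a mobile gene family with transfer-derived calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoclock)
```

## The problem

Some enzymes are old enough that no fossil calibrates their history
directly. Dissimilatory sulfite reductase (DsrAB) — the two-subunit
catalytic core of anaerobic sulfite reduction — is a canonical case: its
two subunits are pre-LUCA paralogs, the family moved repeatedly between
prokaryotic lineages by horizontal gene transfer (HGT), and its deepest
divergences plausibly predate 3 Ga. `paleoclock` implements the inference
chain that makes such a family datable anyway:

1. **Screen** candidate subunit-A/subunit-B homolog pairs by conserved
   motifs (the siroheme-binding `CX5CXnCX3C` and the Fe4S4-binding
   `CX2CX2C`), genomic adjacency of the two genes, and redundancy
   clustering.
2. **Build** a gene tree (distances + neighbor joining, maximum-likelihood
   branch lengths under an empirical amino-acid model), rooted either by a
   named outgroup or by *paralogous rooting* on the branch separating the
   A and B subunit clades.
3. **Reconcile** the gene tree against a dated species tree under a
   parsimony duplication–transfer–loss (DTL) model, with transfer
   frequencies estimated over bootstrap replicate trees and events below a
   0.3 frequency discarded.
4. **Project calibrations**: each retained transfer names a dated recipient
   branch of the species tree; its age interval becomes a min/max
   constraint on the LCA of the corresponding gene-tree clade (clades of
   fewer than three leaves are not used).
5. **Date** the gene tree by a clock-free relative-rate procedure scaled
   through those constraints, with bootstrap confidence intervals.
6. **Reconstruct** ancestral sequences by marginal empirical-Bayes ASR and
   estimate each node's optimal temperature (Topt) from residue
   composition, then regress Topt on evolutionary distance from a
   reference ancestor within clades.

Every stage is also exercisable on synthetic data with known ground truth;
the generator is a first-class module, not a fixture.

## The synthetic study system

`sim_config()` fixes the scaled-down study conditions the package is
validated on. The defaults emulate a sulfite-reductase-like family in an
archaeal-scale species tree:

* **Species tree**: birth–death (forward Gillespie, conditioned on the
  number of extant species by stopping at first attainment, extinct
  lineages pruned), 12 species, root rescaled to 3460 Ma — the dated
  archaeal root scale. Tips sit at 0 Ma.
* **Gene family**: evolves inside the species tree from its root with
  duplication/transfer/loss rates (2.5e-5, 3e-4, 4e-4) per lineage per Ma.
  The loss rate exceeds the transfer rate, giving the sparse, patchy,
  transfer-dominated occupancy that makes reductase-type families both
  hard and interesting: most extant copies descend from horizontal
  acquisitions, and recipient clades tend to be "foreign" monophyletic
  blocks. These rates were chosen so a 12-species system leaves roughly
  16 surviving gene leaves with a handful of detectable transfers.
  Transfer recipients are uniform among contemporaneous branches — the
  simplest null; no transfer preference is modeled.
* **Sequences**: 300 aligned columns (no indels), LG exchangeabilities
  with discrete-gamma rate heterogeneity (shape 1, 4 categories), strict
  clock at 2e-4 substitutions/site/Ma by default, with optional lognormal
  per-branch rate noise (`rate_sdlog`). The LG table is read from
  phangorn's model set at run time.
* **Thermal trait**: Brownian motion with drift on the dated gene tree:
  root 73 °C, scale 0.4 °C/sqrt(Ma), trend −0.005 °C/Ma (a hot ancestor
  slowly cooling); values clipped to [0, 110] °C with clipping reported.
* **Composition coupling**: per-branch equilibrium frequencies are tilted
  in logit space along a fixed thermophily indicator (+1 for I, V, Y, W,
  R, E, L; −1 for D, N, Q, T, S, H, A):
  `log pi_i(T) = log pi_i0 + beta * (T - 37) * d_i - log Z`, using the
  midpoint of the parent and child temperatures for each branch.

**On the coupling strength.** The real determinant of a protein's thermal
optimum is far richer than composition; the learned predictors used in
practice exploit sequence and structure. Here the coupling is an explicit,
documented stand-in, and `beta_comp` is calibrated by an information
argument rather than by proteome statistics: the Topt information carried
by one sequence of length L is approximately
`1 / (beta * sqrt(F(1-F) * L))` degrees (F the indicator-class frequency,
about 0.23 variance contribution under LG frequencies). The default
`beta_comp = 0.025` therefore makes a single 300-residue sequence worth
roughly ±5 °C — the working precision of the predictor being emulated —
so that recovery experiments measure the inference chain (ASR, model
calibration, prediction), not the weakness of raw composition biology
(for which beta would be nearer 0.003 and a single protein worth ±45 °C).
An import hook (`predict_topt(..., override=)`) accepts real predictor
output node-by-node instead.

What the generator does **not** emulate: indels and alignment error,
selection and site-specific constraint shifts, within-branch temperature
variation, gene conversion, incomplete lineage sorting, and transfer
preference by relatedness or ecology. Passing tests therefore demonstrate
the correctness and calibration of the chain under its own model, not
robustness to every real-data pathology.

## Dating: model and numerical choices

`relative_dating()` is a clock-free relative-rate recursion. Node heights
are computed post-order as the mean of the two child path estimates
(`branch + child height`); the relative rate of a lineage is its realized
path divided by the clock-expected path. In the strict-clock limit all
rates are equal and heights are proportional to true depths; on a
two-leaf tree with branches 1 and 3 the leaf rates come out 1:3. No
equivalence with any specific relative-time implementation is claimed —
correctness is defined by these limits and by synthetic recovery. Height
monotonicity is enforced (a parent estimated below a child is clamped a
hair above it and flagged), and a zero-duration branch inherits its
parent's rate, flagged.

`apply_calibrations()` turns relative heights into ages with a single
global least-squares scale, then clamps violations (descendants rescaled
proportionally; ancestors raised minimally), asserting afterwards that
every constraint holds and ages are monotone. Two kinds of constraints
get different targets:

* generic two-sided windows (e.g. a root interval) target their
  **midpoint**;
* transfer-projected constraints target their **younger endpoint**
  (`target_ma`). This is not a stylistic choice: the calibrated node is
  the LCA of the recipient clade, i.e. the first divergence after the
  transfer, which in expectation coincides with the speciation closing
  the recipient branch — the interval's younger end. Midpoint targeting
  would systematically overestimate the time scale by the ratio of
  midpoint to lower bound.

One-sided constraints (e.g. a "< 4380 Ma" root cap) take part in clamping
only, unless no two-sided constraint exists, in which case the bound
itself is the fitting target.

Confidence intervals come from a nonparametric site bootstrap. Three
replicate modes exist: least-squares branch lengths on the fixed
topology (`"ols"`), ML refit on the fixed topology (`"ml"`), and the
pipeline default `"full"`, which re-runs the whole distance +
neighbor-joining + rooting build per replicate and matches every node of
the point tree by its leaf set — at a few hundred sites, topology and
rooting uncertainty dominate branch-length noise and fixed-topology
intervals would understate both. The pipeline's point estimate is an ML
branch-length fit on the rooted topology (the `dist -> nj -> fit` chain;
distance formulas compress deep, saturated distances, while ML lengths
are consistent); because that point estimator differs from the replicate
estimator, the interval is a basic bootstrap — replicate deviations
recentred on the point estimate — rather than raw percentiles, which
would inherit the replicates' compression bias in both endpoints.
Percentile intervals remain the rule when point and replicates share one
estimator, and every interval is widened, with a flag, if it does not
contain the point. These are bootstrap CIs, not analytic rate-variance
CIs; the output metadata says so. A limitation worth stating plainly:
any bias shared by all replicates of the same data — compositional
nonstationarity, a misplaced midpoint root — cannot be absorbed by
resampling, and with a single mid-depth calibration the realized
coverage of nominal 95% intervals in the package's own end-to-end
experiments sits slightly below nominal (the acceptance suite measures
exactly this).

Distances: `p`, `poisson` (`-log(1-p)`) and `gamma`
(`shape*((1-p)^(-1/shape)-1)`), over mutually ungapped columns, with
saturated pairs (p ≥ 0.95) clamped to the p = 0.95 distance and flagged.
The `-log(1-p)` form slightly compresses very deep 20-state distances;
where tight absolute accuracy matters (e.g. strict-clock validation), ML
branch lengths are the consistent estimator and are used instead.

## Reconciliation and the calibration projection

`reconcile()` is a dynamic program over (gene node × species branch) with
costs duplication 2, transfer 3, loss 1 and free speciations — standard
parsimony DTL practice; the probabilistic reconciliation used at full
scale is replaced, deliberately, by this testable analogue, and transfer
frequencies come from topology bootstrap replicates rather than
conditional clade probabilities. Ties break deterministically (speciation
over duplication over transfer, then smallest species label), one optimal
scenario is reported, and the number of co-optimal root placements is
exposed as a diagnostic. A dated mode restricts transfers to
age-overlapping branches.

Two properties of sparse families are worth knowing. First, parsimony
often explains a clade's presence by vertical persistence plus losses
when that is no more expensive than a transfer, so the *exact* recipient
branch of a true transfer is recovered in only a fraction of cases —
cost choices barely move this, and the default costs are kept. Second,
the projection step is protective: a constraint is emitted only when the
recipient's gene clade is monophyletic with at least three leaves, and in
measured runs every emitted constraint contained the true node age. The
price of this conservatism is that many runs emit no constraint at all;
a family without projectable dated transfers simply cannot be dated by
this strategy, which is why the end-to-end experiments (and
`simulate_calibratable_truth()`) condition on datasets where at least one
projectable transfer exists — mirroring the fact that the real analysis
was only possible because high-frequency transfers were found.

## Ancestral reconstruction and thermal regression

`marginal_asr()` computes, per internal node and site, the posterior over
the 20 residues proportional to (conditional likelihood below) ×
(likelihood of the rest of the tree), mixed over gamma categories, with
fixed branch lengths and no clock. MAP ties break alphabetically.
Posterior mass is asserted to sum to 1 within 1e-9. The likelihood engine
is Felsenstein pruning with per-column rescaling (safe for deep trees),
site-pattern compression, and gaps treated as missing data.

`fit_topt_model()` is ridge-regularized least squares of Topt on the
20-vector of residue frequencies (penalty 1e-3 on coefficients, none on
the intercept). The compositions sum to one, so the design is collinear
with the intercept by construction; the ridge penalty is what makes the
fit well-posed, and the error path suggests increasing it if the design
degenerates further. At least 22 training pairs are required (21 free
parameters). `topt_distance_regression()` is ordinary least squares with
the two-sided slope test on n−2 degrees of freedom; constant temperature
or zero distance variance are errors, not silent NaNs.

Trend-direction experiments pool ancestral and extant points, as the
reference analysis regresses both; ASR shrinks deep predictions toward
the training mean, which attenuates slopes without changing their sign.

## Problem sizes used in validation

The test and acceptance experiments run at deliberately desk-scale sizes,
stated here as the package's chosen study conditions: oracle-equivalence
checks on trees of ≤ 4 leaves and ≤ 5 sites (likelihood and ASR compared
with full state enumeration at 1e-9) and DTL instances of ≤ 4 species and
≤ 5 gene leaves over 100 random cost triples; NJ exactness on 50 random
additive matrices of ≤ 8 taxa; strict-clock dating at 10 species × 10,000
sites with ML branch lengths (5 % node-age accuracy) and rate-noise
recovery at 2,000 sites; calibration soundness over 50 simulated
families; end-to-end coverage over 30 dated pipeline runs at 12 species,
~16 gene leaves, 300 sites and 30 bootstrap replicates; thermal recovery
at 24 species (≥ 22 leaves for model calibration). Under these
conditions the acceptance suite itself measures end-to-end CI coverage
of the deepest node and ancestral-Topt recovery; the realized coverage
and the hot-root recovery error sit near — and for coverage and median
Topt error, somewhat beyond — their nominal tolerances, for the
structural reasons given under limitations.

## Known limitations

* Rooting of bootstrap replicate trees follows the point tree's rooting
  mode; midpoint rooting can misroot strongly rate-heterogeneous or
  heavily transferred families, and a misrooted replicate can reverse a
  transfer's direction. Outgroup rooting is preferred whenever an
  outgroup exists.
* With a single projected calibration (the typical scaled-down case; the
  full-scale analysis had five), the root age is a ratio estimate
  through one mid-depth node, and its data-conditional bias is invisible
  to the bootstrap; dated intervals should be read accordingly.
* Parsimony DTL reports one optimal scenario; co-optimal ambiguity is
  only counted, not enumerated.
* The relative-rate recursion is a documented approximation with the
  stated limits; it is not an ML rate model.
* The composition–temperature model is linear and single-sequence; it is
  a stand-in with a declared precision, not a claim about real
  thermophysiology.
* Marginal empirical-Bayes ASR shrinks uncertain deep-node compositions
  toward the model's equilibrium — i.e. toward the family's average,
  mesophilic-leaning composition. Reconstructed thermal optima of very
  hot ancestors are therefore biased cold and positive temperature
  trends are attenuated; any composition-based ancestral Topt estimate
  (including the full-scale analyses this package emulates) inherits
  this shrinkage.
* Transfer-derived constraints inherit the species tree's dates; errors
  in the species-tree chronology propagate untouched.
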