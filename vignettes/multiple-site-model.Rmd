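---
title: "The Multiple-Site ensemble model for SPOT peptide-array binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Multiple-Site ensemble model for SPOT peptide-array binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotms)
```

## The scientific problem

Peptide-binding modules such as SH3 domains recognize proline-rich linear
motifs weakly and transiently, with micromolar affinities and exchange rates
of thousands per second.  SPOT-synthesis arrays measure this binding for
thousands of peptides at once: each spot carries many copies of a 13--14
residue peptide, and the bound-protein signal is quantified as a light
intensity (BLU).  Because the recognition core is only 4--8 residues long,
an array peptide typically contains several overlapping candidate docking
sites, and a transiently binding domain samples all of them.  A model that
assigns the whole measured signal to one fixed site misattributes the
binding energy whenever more than one site contributes.

spotms implements two models of the spot-level signal and the protocol for
comparing them.

## Models

Intensities are converted to pseudo-binding free energies
$G^{SPOT} = -\ln(\mathrm{BLU})$, dimensionless in RT units (multiply by $RT$
for physical units; the package never stores kcal/mol).

**Window energies.**  A window of size $S$ starting at offset $i$ of peptide
$\sigma$ has the additive, position-specific energy
$$G_P(\sigma_i) = \sum_{s=1}^{S} J_{s, a_s},$$
where $a_s$ is the residue at window position $s$ and one *reference*
residue per position carries $J = 0$.  The encoding behind this is a binary
indicator basis: a leading intercept plus, per position, 19 indicators over
the non-reference residues in alphabetical order.

**Multiple-Site (MS) model.**  The domain shuttles among all
$N - S + 1$ windows of an $N$-residue peptide, so the bound-state
configuration integral is the *sum* of per-site Boltzmann factors and the
peptide-level energy is the log-sum-exp ensemble
$$G = \alpha - \ln \sum_{i=1}^{N-S+1} e^{-G_P(\sigma_i)}.$$
$\alpha$ is a fitted additive offset absorbing the imperfect
intensity-to-energy conversion.  Two properties matter scientifically: the
total never exceeds $\alpha$ plus the best window's energy, and every
additional window strictly lowers it — extra nearby sites increase the
bound population.

**Single-Site (SS) baseline.**  Ordinary linear regression of $G^{SPOT}$ on
the indicator encoding of one fixed representative window at offset $r$:
$G = J_0 + \sum_s J_{s,a_s}$.  With a single contributing site the MS model
reduces exactly to this form.

## Identifiability and numerical choices

* In the MS model the window intercept $J_0$ and $\alpha$ are confounded
  ($\alpha - \ln \sum e^{-J_0 - \cdot} = \alpha + J_0 - \ln \sum e^{-\cdot}$),
  so `ms_fit()` pins $J_0 = 0$ and lets $\alpha$ carry the offset.
* $\alpha$ enters additively, not multiplicatively: the conversion error it
  corrects is an affine offset on the energy scale.
* The log-sum-exp is always computed with max-subtraction; window energies
  of 1000 and 1001 RT produce the exact closed form to $10^{-9}$.
* The reference residue per position is not dictated by the data model;
  `ms_fit()` defaults to the modal residue over the training windows
  (`"most_frequent"`, ties broken alphabetically), which centers the
  expansion on the data, and `"fixed_alanine"` is provided for simulations
  and reproducibility work.  The choice is recorded in the model and its
  JSON serialization; models with different references are related by a
  per-position reparameterization plus an $\alpha$ shift.
* The MS objective is non-convex, so `ms_fit()` runs Levenberg--Marquardt
  (analytic Jacobian, `minpack.lm`) from `n_restarts` random starts with
  initial $J \sim \mathrm{Uniform}(-1, 1)$ and $\alpha$ started at the mean
  observed energy, keeping the lowest-SSE solution.  Restart $r$ of a
  $k$-restart run always uses the $r$-th draw under the seed, so the
  best-of-$k$ SSE is non-increasing in $k$ and every fit is exactly
  reproducible from (data, config).
* $J$ is box-bounded to $\pm 20$ RT — far outside plausible single-residue
  contributions — to stop rarely observed features from diverging.
  Features never observed in training are pinned at 0 (in both models), so
  prediction on unseen residues falls back to the reference energy
  deterministically.
* Peptides shorter than the window are skipped with a warning rather than
  failing: real selections mix 13- and 14-mers.

## Evaluation protocol

`crossval()` implements 10-fold cross-validation with the
standard-deviation-normalized RMSE: each test fold's RMS error is divided
by that fold's sample standard deviation (the $n-1$ denominator is our
choice; the mean predictor then scores $\sqrt{(n-1)/n}$, not exactly 1).
A score below 1 beats the trivial predictor.

For the MS model, cross-validation is a two-pass protocol: pass 1 fits each
training set with free $\alpha$; the *median* of the 10 fold $\alpha$'s is
taken (robust to an occasional diverged fold); pass 2 refits each training
set with $\alpha$ fixed at that median before scoring the test folds.

For the SS model, every candidate site offset $r \in \{0, \dots,
N_{\min}-S\}$ is cross-validated and the site with minimal mean RMSE is
selected (ties to smaller $r$); over all window sizes this is the
$N(N+1)/2$-candidate family.  `scan_windows()` repeats either protocol over
a range of $S$ and marks the best size; for the MS scan a full-length
window is excluded from the selection (with one window the ensemble
degenerates to the SS model).  `compare_models()` then evaluates, per fold,
$100\,(RMSE_{SS} - RMSE_{MS})/RMSE_{SS}$ at each model's best size and
reports the fold mean and standard deviation.  We compute the ratio per
fold and then average (rather than the ratio of averages); with 10 folds
the difference is second order.

## The localization statistic

Under the MS model the occupancy of window $i$ is the softmax
$o_i = e^{-G_P(\sigma_i)} / \sum_j e^{-G_P(\sigma_j)}$; the **maximum local
population** (MLP) is $\max_i o_i$, the fraction of the bound population on
the best site.  MLP $= 1$ means fully localized binding; two equal strong
sites give 0.5; $n$ equal sites give $1/n$.  $\alpha$ and any constant
shift of the window energies cancel, so MLP reflects specificity, not
affinity.  `localization_report()` pairs MLP with the predicted energy per
peptide and `scan_fasta()` applies it to tiled protein sequences, which is
how multi-site binders (strong affinity at MLP near 0.5) are distinguished
from single-site binders (MLP near 1).

## The synthetic-data generator

`simulate_spot_array()` is the package's study-condition generator, not a
test fixture: it emulates one domain's array selection with 1000 peptides,
a 50/50 mix of 13- and 14-mers, a `PxxP` core planted uniformly at random
in every peptide, a ground-truth model with a true window size of 6, true
non-reference $J \sim N(0,1)$ RT on an alanine reference, $\alpha = 5$ RT
(placing totals in a plausible small/negative range after the log-sum-exp),
and Gaussian energy-scale noise of 0.1 RT (log-normal on the intensity
scale, matching the additive error term of the fitting equation).  Sizes
and rates not fixed by the array literature (the true BLU noise magnitude
is not published) were chosen once as plausible for SPOT data and are
configurable but not revisited.

What it deliberately does **not** model: spot-density, purity and washing
artifacts beyond the single additive noise term; phage-display-biased
residue composition (an optional non-uniform `aa_freqs` is available);
correlated replicate spots.  Recovery results on this generator therefore
demonstrate the estimator's correctness, not the field performance on any
particular domain.

```{r example}
sim <- simulate_spot_array(n_peptides = 150, lengths = 9, window_size = 3,
                           noise_sd = 0.1, seed = 42)
fit <- ms_fit(sim$records, window_size = 3, profile = "fixed_alanine",
              n_restarts = 3, seed = 1)
fit
correlate(coef(fit)[-1], coef(sim$truth)[-1])
head(mlp(fit, sim$records$sequence[1:5]))
```

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: parameter recovery on
1000 simulated 14-mers at $S = 6$ (with a noiseless variant); a brute-force
grid-search oracle on a two-letter alphabet at 0.01 resolution; and the
MS-vs-SS comparison on 500 peptides with 10 folds, 2 restarts per
cross-validation fit, an iteration cap of 200, and a window scan over
$S \in \{4, 6\}$ — sizes we consider adequate to pin down the direction
and magnitude of the comparison on this generator.  Larger scans behave
the same way, only slower.

## Known limitations

* The expansion is truncated at single-residue terms; pairwise couplings
  (cluster-expansion features) are out of scope.
* The MS fit needs more data than free parameters ($19S$ plus $\alpha$);
  with fewer records the optimizer refuses rather than returning an
  underdetermined solution.
* Comparisons with structure-based (force-field) energies and direct
  re-analysis of published per-domain arrays require external data and
  tooling and are not part of the package.
* An SS-truth world is represented *exactly* by the SS model but only
  approximately by the MS model (its $J$ table is shared across windows),
  so on single-site data the comparison can swing far below zero — the
  qualitative exception seen for domains whose recognition is dominated by
  one anchored position.
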