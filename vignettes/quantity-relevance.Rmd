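---
title: "The quantity-relevance trade-off in mutation-effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quantity-relevance trade-off in mutation-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pottsfocus)
```

## The problem

Statistical models trained on a multiple sequence alignment (MSA) of a
protein family can score the fitness effect of single point mutations of a
wild-type (wt) sequence: residues (and residue pairs) that are rare among
homologs are predicted deleterious. How well this works depends on two
properties of the training alignment that pull in opposite directions:

* **quantity** — the effective number of sequences `B` (after redundancy
  reweighting), which controls the statistical error of every estimated
  parameter;
* **relevance** — how close the training sequences are to the wild type,
  summarized by the weighted mean Hamming distance `D`. Sequences far from
  the wt live in parts of the fitness landscape shaped by epistatic
  interactions that a simple model cannot transfer back to the wt
  neighbourhood.

`pottsfocus` implements this trade-off as an executable theory: the mean
squared prediction error decomposes into a squared bias plus a variance,

* the variance has an analytic estimate from the alignment frequencies,
  `sigma^2 ∝ 1/B` (see `variance_estimate()`, which implements the global
  average over sites and mutations with the `|k_i - 1|` degree factor and
  pair-frequency terms for linked sites);
* the squared bias grows linearly with the distance of the data to the wt,
  `mu^2 ≈ J0 * D`, where the *bias factor* `J0` measures the epistasis the
  model class does **not** capture. `J0` is fitted from data by maximizing
  the absolute Spearman correlation between measured performance `rho` and
  the proxy `J0 * D + sigma^2` across subsampled alignments
  (`fit_bias_factor()`), with a permutation null (`chance_null_rs()`).

The practical payoff is *focusing*: drop the sequences beyond a cutoff
distance `d_cut` from the wt and train on the rest. The package predicts
the best cutoff either from the fitted bias factor
(`predict_cutoff_bv()` — the argmin of `J0 D(d_cut) + sigma^2(d_cut)`) or,
without any experimental input, from a signal-to-noise heuristic
(`predict_cutoff_snr()`, default threshold 3, sensible over roughly 2-4):
keep focusing while the spread of predicted effects still dominates the
statistical noise.

## Models

The predictors are sparse *K-link Potts models* over the `Q = 20` amino
acids: site fields `h_i(a)` everywhere plus couplings `J_ij(a,b)` on `K`
selected site pairs. `K = 0` is the independent-site (profile) model;
`K = N(N-1)/2` would be the fully connected model, with `Q^2 = 400`
parameters per link. Links are chosen by pseudo-likelihood inference of a
fully connected model (`infer_plm()`), ranking pairs by the Frobenius norm
of the zero-sum-gauge coupling blocks (`frobenius_scores()`, no APC
correction), and keeping the top `K` (`select_links()`). The retained
couplings are then re-inferred in a two-site approximation
(`infer_two_site()`): the pointwise-mutual-information form
`J_ij(a,b) = log p_ij(a,b) - log p_i(a) - log p_j(b)`. With this choice a
site with exactly one link scores mutations through pair frequencies
alone, which is what makes the `|k_i - 1|` factor in the variance formula
cancel the single-site noise terms at degree one. The mutation score is
`delta_fitness()`: the difference of log-probabilities between mutant and
wild type, which reduces to a sum of field and coupling differences.

Gaps are a 21st storage state: they count literally in Hamming distances,
are allowed as regression context in the pseudo-likelihood, and are
excluded from all 20-state frequency tables (their weight stays in the
denominator). Frequencies are regularized by uniform pseudocount mixing
with `lambda = 0.01` by default — enough to keep every log finite while
distorting well-observed frequencies by under 1%.

### Numerical choices

* Pseudo-likelihood fitting is per-site ridge multinomial regression
  (L-BFGS-B, analytic gradients), weights applied, asymmetric estimates
  averaged, every block projected to the zero-sum gauge. The one-hot
  context features are weight-centred before fitting; this pins the
  inference gauge so that constant columns carry no coupling mass (an
  alignment of identical sequences yields couplings that are exactly
  zero).
* `fit_bias_factor()` searches 200 log-spaced grid points spanning
  `[1e-6, 1e3] x median(sigma^2)/median(D)` — scale-aware because the
  natural magnitude of `J0` is set by the ratio of the two error terms —
  with a local refinement pass; ties resolve to the smallest maximizing
  grid point.
* Cutoff ties resolve to the *larger* `d_cut` (more data at equal
  predicted error); the SNR rule returns the *smallest* cutoff whose SNR
  still reaches the threshold, i.e. the tightest focus the signal
  supports.
* Biased subsampling (`biased_subsample()`) draws `B0` rows without
  replacement with weight `exp(-alpha d(s, wt))` using the
  exponential-keys method; `alpha` is initialized by bisection on the
  with-replacement expectation and then bisected against the realized
  mean distance until the achieved normalized `D` is within 0.01 of the
  target (the tolerance is interpreted on the normalized scale; one raw
  site would often be unreachable).

## The lattice-protein ground truth

Because real fitness landscapes are unknown, validation uses an *in
silico* protein: a 27-mer folding on the 3x3x3 cube. `enumerate_folds()`
enumerates all compact conformations — Hamiltonian self-avoiding walks —
canonicalized under the 48 cube rotations/reflections: 103,346 folds, each
with exactly 28 non-chain contacts (54 cube edges minus 26 chain bonds),
cross-checked by an independently coded enumerator
(`count_folds_independent()`). Identifying a chain with its reverse would
give 51,704 (the 62 self-reverse folds make the two counts consistent:
2 x 51,704 - 103,346 = 62).

A sequence's fitness cost is `H = -log P_nat`, where `P_nat` is the
Boltzmann weight of the native fold against all competitors, with contact
energies summed over the fold's 28 contacts. The shipped contact-energy
matrix (`contact_energies()`) is a **synthetic stand-in** for the
empirical Miyazawa-Jernigan table, which is not redistributed here: a
rank-one product of the Miyazawa (1985) per-residue contact propensities —
the dominant mode of the empirical matrix — plus a small fixed symmetric
perturbation that provides pair specificity. All geometry and correlation
statements validated on the bench are insensitive to this choice; any
symmetric matrix can be substituted.

The bench world (`lattice_world()`) designs a wild type with
`P_nat ≈ 0.995` — stable, but leaving beneficial mutations available —
computes all 27 x 19 exact mutational effects (`ground_truth_effects()`),
and samples alignments with a Metropolis chain at inverse temperature
`beta = 1000`, recording one sequence every `T = 1000` proposals
(`metropolis_sample()`). A distance bias `gamma in {0, 0.025, 0.05,
0.075}` attracts the chain toward the wild type; the biased term uses the
*normalized* Hamming distance, the same convention as the reweighting
machinery. Empirically these four settings produce mean sampled distances
of about `{0.91, 0.81, 0.64, 0.44} N`, bracketing the `[0.4 N, 0.8 N]`
range that the subsampling grid targets — with raw-count distances the
bias `beta * gamma` would exceed 25 per site and freeze the chain at the
wild type, and with the opposite sign the chain could never come back
below its unbiased equilibrium distance. Mutations with `|E| >= theta = 5`
are masked as unobservable before any bias/variance aggregate.

## What the generator emulates — and what it does not

The bench emulates the full pipeline: families of correlated sequences
concentrated around a viable wild type, with pairwise (structural) and
higher-order (fold-competition) epistasis, and an exactly computable
ground truth. It does **not** emulate phylogenetic correlations beyond
what the Markov chain induces, alignment errors, gaps, or measurement
noise in mutational scans. A green bench therefore establishes the
internal consistency of the estimators and protocol, not their behaviour
on real alignments.

Two desk-scale reductions keep the bench inside minutes (a full-scale
protocol would use the complete fold repertoire and alignments up to 10^6
sequences):

* the competition repertoire is a seeded random sub-sample of 2000 folds
  (including the native). The landscape stays exactly computable over the
  reduced competitor set; the maximal fitness cost drops from
  `log 103346 ≈ 11.5` to `log 2000 ≈ 7.6`, so the `theta = 5` mask
  removes relatively fewer extreme outliers than at full scale;
* the structural-coupling analysis (`structural_coupling_analysis()`)
  trains its fully connected model on 5000 sequences recorded every 200
  proposals instead of ~10^6 every 1000 — enough to separate the variance
  of structural vs non-structural couplings, not to estimate either
  precisely.

At this reduced scale one known artefact appears, documented here because
it is visible in the shipped validation: with `B <= 300` training
sequences, the pointwise-mutual-information couplings of rarely observed
residue pairs are dominated by the pseudocount floor. The resulting
predictions remain rank-informative (the performance `rho` can even
improve with `K`), but their *squared-error* scale grows with `K`, so the
measured squared bias inflates for coupling-rich models and the fitted
`J0(K)` loses the monotone decrease expected when coupling estimates are
accurate. The per-model correlation structure (bias linear in `D`,
variance tracking the analytic estimate, performance anti-correlated with
bias + variance) survives the reduction; the cross-model ordering of
`J0(K)` does not. The effective-theory curve built from the large-`B`
structural analysis — un-modelled couplings counted with their measured
variances, structural couplings incorporated first, constant once all 28
are modelled — is unaffected.

## The bias of the sampler's own couplings

The effective bias curve treats the two coupling classes explicitly:

```
J0_eff(K) = (Nc - min(K, Nc)) * V_struct + (Kmax - Nc) * V_nonstruct
```

with `Nc = 28`. An alternative that kept subtracting non-structural
couplings past `K = Nc` would make the curve decrease forever; the
saturation form above matches the model in which the sparse predictor
acquires structural couplings first, and is exactly constant for
`K >= 28`.

## Reproducibility

Every stochastic step takes a seed; grids and workflows derive per-cell
seeds deterministically from a master seed (kept inside the 32-bit range R
requires), so `run_tradeoff_workflow()` and `run_focus_workflow()` are
bit-reproducible from their arguments. The bench *family* — native fold,
decoy repertoire, wild type — is pinned by a separate `family_seed`
(`lattice_world()`), mirroring a study of one chosen fold: varying the run
seed resamples alignments from the same landscape rather than switching to
a different protein. `scripts/acceptance.R` re-runs the whole bench from a
single `--seed`.

## Known limitations

* Positions are 1-based internally (R convention); scan files use 1-based
  positions in the original, pre-filtering column coordinates.
* The two-site coupling form leaves fields untouched on linked sites; a
  full two-site maximum-likelihood re-fit would also adjust fields.
* `performance()` assumes higher scan score = fitter (flip with
  `sign_convention = -1`).
* No phylogeny-aware subsampling; the relevance descriptor is plain
  Hamming distance.
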