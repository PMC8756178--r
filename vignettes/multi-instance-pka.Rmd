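---
title: "Learning atomic micro-pKa from molecular macro-pKa labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning atomic micro-pKa from molecular macro-pKa labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkamil)
```

## The problem

The acid dissociation constant of a molecule is observable only at the
molecule level: a titration measures the *macro*-pKa for gaining or losing a
proton, regardless of which atom ionizes. Yet the chemistry happens at
individual titratable sites, each with its own *micro*-pKa. For polyprotic
molecules the micro values are rarely measurable, so there is no large
dataset of per-atom labels to train on.

The two scales are, however, tied by an exact algebra. Writing $P$ for the
set of acidic sites of a molecule and $\mathrm{p}K_i$ for the micro-pKa of
site $i$, the most-acidic macro-pKa is

$$\mathrm{p}K^{\mathrm{(acidic)}} = -\log_{10} \sum_{i \in P} 10^{-\mathrm{p}K_i},$$

and symmetrically for the most-basic value over the basic site set $Q$ with
the signs flipped. `pkamil` exploits this: a graph neural network predicts
one raw pKa per atom, non-ionizable atoms are masked (+Inf for the acidic
model, -Inf for the basic model, i.e. they contribute exactly zero to the
sum), and the masked values are pooled through the formula above. The
pooled value is compared against the molecule-level label with a squared
loss. This is multi-instance learning for regression: the molecule is the
bag, its ionizable atoms are the instances, and the pooling formula is the
bag-label function. Because the pooling is a soft minimum (or maximum), its
gradient distributes the molecule-level error over sites in proportion to
$10^{\mp \mathrm{p}K_i}/\sum_j 10^{\mp \mathrm{p}K_j}$ — dominant sites
learn fastest, near-tied sites share the signal.

## Site definitions and standardization

Ionizable sites follow two deliberately simple structural rules: an
*acidic* site is any non-carbon heavy atom bearing at least one hydrogen; a
*basic* site is any nitrogen without a positive formal charge. C–H acidity
is out of scope by construction. Input structures are standardized before
anything else: the largest covalent fragment is kept (salts stripped),
charges are neutralized by adding or removing protons wherever valence
allows, and the result is re-canonicalized. Charges that cannot be
neutralized (a quaternary ammonium, for instance) are kept and the record
is flagged; the basic-site rule then excludes those atoms naturally.
Zwitterions are neutralized on both ends when valence permits — a single
neutral tautomer is the reference form, and tautomer enumeration is a known
limitation, not a goal.

## Model

Each molecule is an undirected graph over heavy atoms; hydrogens are folded
into a per-atom count. Atoms carry 8 descriptors (element, degree, formal
charge, hybridization, aromaticity, hydrogen count, ring membership,
chirality flag), bonds carry 4 (type, conjugation, ring membership, stereo
flag), all one-hot encoded where categorical. Six graph-attention layers
are stacked: in each layer every atom computes attention coefficients over
its incoming neighbors (non-negative, summing to one), aggregates neighbor
messages weighted by those coefficients, and updates its state through a
gated recurrent (GRU) cell. The attention logit is a single linear form in
the destination state, source state and bond features; messages pass the
source state and bond features through an exponential-linear unit. There is
deliberately *no* molecule-level readout: the final atom states feed a
small fully connected head that emits one scalar per atom, and molecule
values exist only through the pooling.

Defaults: hidden width 200, one attention head per layer, dropout 0.1 on
atom states between layers, head width 128. These sizes are configuration,
chosen to train comfortably on a single CPU core; the layer count of six is
the one structural constant. Separate models are trained for the acidic
and the basic task.

The network, its reverse-mode gradients and the Adam optimizer are
implemented inside the package as a small tape-based autodiff over matrix
operations. Every operation's gradient is verified against central finite
differences in the test suite, including the pooling, whose analytic
gradient is exactly the softmin/softmax weight vector.

## Numerical choices

The pooling is computed in shifted form, $m \mp \log_{10} \sum_i
10^{\mp(\mathrm{p}K_i - m)}$ with $m$ the extreme site value, so every
exponent is non-positive and the computation cannot overflow anywhere in
(and far beyond) the chemically occurring range of roughly -10 to 40.
Masking is implemented as exclusion from the sum rather than literal
infinite arithmetic — mathematically identical, since $10^{-\infty} = 0$,
and free of NaN hazards in gradients. Empty site sets yield an explicit
"no-site" result: such molecules are excluded from training for that mode
and reported as unpredictable at inference, because the pooling formula is
undefined on an empty bag.

Two numerical footnotes surface in the tests. Appending a site always
moves the pooled value strictly toward the extreme in exact arithmetic, but
in double precision the change is representable only while the new site is
within about 15 pKa units of the pooled value; the property tests assert
strictness exactly in that regime and monotone non-strictness beyond it.
And dominant-site assignments are set-valued with a tie tolerance
`epsilon` (default 0.1 pKa units, configurable) — far below chemically
meaningful differences, so true ties are captured without inflating the
dominant set.

## Training protocol

Datasets are split 70:15:15 into train/validation/test by a seeded uniform
partition with largest-remainder rounding. Training minimizes the MSE
between pooled predictions and macro labels with Adam (default learning
rate 1e-2, batch 128, up to 500 epochs), early-stops on validation MAE
with patience 30 and a minimum improvement of 1e-3, and returns the
best-validation parameters. All randomness — initialization, batching,
dropout — is derived from explicit seeds, and repeated runs with the same
seeds give bit-identical histories. Multi-run summaries (`train_runs()`)
re-seed both the split and the initialization per run and report mean and
sample standard deviation of the test metrics.

## The synthetic benchmark and what it shows

No public micro-pKa ground truth exists, so the package ships a generator
that builds one. Molecules are assembled from short alkyl backbones (2–8
carbons) carrying one to six ionizable groups — carboxyl, phenol, thiol,
alcohol, sulfonamide for the acidic task; aliphatic amine, aniline,
pyridine for the basic task — plus up to two halogen substituents; aromatic
groups bring their own rings, some with ring halogens. Every site's true
micro-pKa is a deterministic function of the final standardized graph:
a base value per functional group (carboxyl 4.2, phenol 10.0, thiol 8.3,
alcohol 15.5, sulfonamide 10.1, amine 10.6, aniline 4.6, pyridine 5.2 —
rough literature-scale numbers, configurable) minus an
electron-withdrawing shift of weight/distance for each halogen within
graph distance three (F 1.0, Cl 0.8, capped at 1.5 units total). The
macro label is the exact pooled value of the true micro values plus
Gaussian noise. Because the truth is evaluated on the final graph, any
site the assembly creates is covered by construction, and group
frequencies are chosen so that every group type is dominant in a
substantial fraction of molecules — single-group molecules (35% of the
set) pin down each group's scale, multi-group molecules exercise the
pooling, and halogen shifts create within-group variation including
near-ties at the `epsilon` boundary.

`mil_benchmark()` runs the full loop at its defaults — 2000 molecules,
label noise 0.2, hidden width 64, epoch budget 60 with patience 15 —
problem sizes chosen so the whole experiment completes in minutes on one
CPU core. Trained on macro labels only, the model is then asked for
things it never saw: per-atom micro values and dominant sites on held-out
molecules. The test suite gates this at held-out macro MAE at most 0.4,
Spearman correlation at least 0.8 between predicted and true micro values
at the true sites, and a dominant-site consistency rate of at least 0.9
against the generator's ground truth.

What passing does *not* show: the generator's chemistry is a caricature.
Real micro-pKa values depend on resonance, solvation, conformation and
long-range effects that a group-plus-local-shift model does not emulate;
label noise is homoscedastic Gaussian, unlike curated experimental data;
and the molecule distribution is far narrower than a real training corpus.
The benchmark validates the *mechanism* — that bag-level supervision
through the pooling algebra recovers instance-level structure — not
chemical accuracy on real molecules.

## Uncertainty and similarity search

Predictive uncertainty uses Monte-Carlo dropout: 100 stochastic forward
passes (seeded, configurable) with dropout active, summarized by the mean
and the empirical 2.5/97.5 percentiles. The percentile interval is used
rather than a normal approximation because pooled predictions can be
skewed when dominance flips between samples; with dropout 0 the interval
collapses to a point and a warning is raised.

For interpretability, the reference-set search stores, for each labelled
molecule, the last-hidden-layer embedding of its dominant site (under
ties, the lowest atom index). A query molecule returns up to four
reference molecules whose dominant-site embeddings lie within Euclidean
distance 0.05, nearest first, each with its experimental value. The
index carries a fingerprint of the model configuration and parameters, so
querying with a different model is an error rather than a silent
mismatch. A 2-D principal-component projection of embeddings is provided
for visualization, with a deterministic sign convention (the
largest-magnitude loading of each component is positive).

## Known limitations

Beyond those already noted — no C–H acidity, no tautomer handling, one
neutral reference form per molecule — the package predicts only the most
acidic and most basic macro-pKa, not intermediate dissociations; the
similarity threshold 0.05 is meaningful only for embeddings of the model
that built the index; and the synthetic benchmark's passing thresholds are
gates for this package's test suite, not claims about performance on
experimental data.
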