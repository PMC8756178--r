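# pkamil

Multi-instance graph attention networks for aqueous pKa prediction in R.

## The problem

The acid dissociation constant of a molecule is measured at the molecule
level (the **macro-pKa** for gaining or losing a proton), but the underlying
chemistry happens at individual titratable atoms, each with its own
**micro-pKa**. Micro values are rarely measurable, so no per-atom training
labels exist at scale. The two levels are tied by an exact algebra, though:
over the acidic site set *P* of a molecule,

$$\mathrm{p}K^{(\mathrm{acidic})} = -\log_{10} \sum_{i\in P} 10^{-\mathrm{p}K_i},$$

and symmetrically, over the basic site set *Q*,
$\mathrm{p}K^{(\mathrm{basic})} = \log_{10} \sum_{i\in Q} 10^{\mathrm{p}K_i}$.

`pkamil` treats each molecule as a *bag* and its ionizable atoms as
*instances* (multi-instance learning for regression): a six-layer
graph-attention network with a gated recurrent node update predicts one raw
pKa per atom, non-ionizable atoms are masked (+Inf acidic / -Inf basic, i.e.
they contribute exactly zero to the sum), the masked values are pooled
through the formula above, and the pooled value is trained against the
molecule-level label with a squared loss. After training, the network's
per-atom outputs are micro-pKa estimates it was never directly supervised
on, and the argmin/argmax site (with a tie tolerance) is the predicted
dominant ionization site.

Ionizable sites follow two structural rules: **acidic** = non-carbon heavy
atom with at least one hydrogen; **basic** = nitrogen without a positive
formal charge. C–H acidity is out of scope.

The package covers the full workflow: structure standardization (salt
stripping, charge neutralization, canonicalization via OpenBabel through
ChemmineOB), featurized graph construction, site enumeration, the
attention network with its own verified reverse-mode gradients and Adam
(no deep-learning framework required), numerically stable pooling, dataset
splitting and regression metrics, dominant-site consistency analysis
against expert assignments, Tanimoto similarity binning for
applicability-domain assessment, Monte-Carlo-dropout 95% intervals,
atomic-embedding similarity search, and a synthetic group-contribution
generator that makes the weakly supervised mechanism testable with a
knowable ground truth.

## Worked example

```r
library(pkamil)

# Standardization: strip the sodium salt, neutralize, canonicalize
s <- standardize_structure("CC(=O)[O-].[Na+]")
as.character(s)
#> [1] "CC(=O)O"

g <- build_graph(as.character(s))
g
#> <molecule_graph CC(=O)O: 4 atoms, 3 bonds>
enumerate_acidic_sites(g)          # the hydroxyl oxygen, atom 4
#> [1] 4

# The pooling algebra: two identical sites shift the macro by log10(2)
pool_sites(c(4.0, 4.0), "acidic")
#> [1] 3.69897
pool_sites(c(10, 10, 10), "basic") # a triamine-like bag: 10 + log10(3)
#> [1] 10.47712

# End-to-end multi-instance recovery on synthetic data with known truth:
# train on noisy macro labels only, then test micro-level recovery held-out
res <- mil_benchmark(n = 400, seed = 1)
res$metrics
#> <eval_report n=60: MAE 0.2966, RMSE 0.3758, R2 0.9902>
round(res$spearman, 3)             # predicted vs true micro at true sites
#> [1] 0.849
res$consistency
#> <consistency_report: 57/60 consistent (rate 0.950)>
```

The benchmark generates molecules whose per-site micro-pKa is known by
construction (a group-contribution model with halogen perturbations),
computes macro labels exactly through the pooling plus Gaussian noise, and
trains only on those labels. The held-out MAE is the macro regression
error; the Spearman correlation and the consistency rate measure whether
atom-level structure was recovered from molecule-level supervision — the
package's central claim. At the full default size (`n = 2000`, noise 0.2,
hidden width 64) a run on one CPU core finishes in a few minutes and
reaches MAE ≈ 0.18, Spearman ≈ 0.98 and consistency 1.00.

A thin command-line wrapper is installed at `inst/cli/pka` with
subcommands `sites`, `synth`, `train`, `predict`, `eval`, `index`,
`similar`, `consistency`; see its header for usage.

## Vignette

`vignettes/multi-instance-pka.Rmd` documents the model and its
assumptions, the numerical choices (stable pooling, masking semantics,
tie tolerances), the synthetic generator's design and — importantly — what
passing its benchmark does and does not demonstrate about real data.
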