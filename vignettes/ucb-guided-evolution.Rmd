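---
title: "GP/UCB-guided variant ranking: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GP/UCB-guided variant ranking: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucbevolve)
```

## The problem

Directed evolution of an enzyme — here the motivating case is a
biotin-dependent carboxylase engineered to fix CO₂ onto glycolyl-CoA —
screens libraries of sequence variants for two properties at once: the
carboxylation rate, which should go up, and the ATP hydrolyzed per
productive carboxylation, which should come down toward the ideal
stoichiometry of 1. Random mutagenesis finds improvements rarely, so a
surrogate model trained on the screened library is used to rank every
possible single substitution of the parent and concentrate wet-lab
effort on the most promising few percent.

`ucbevolve` implements that loop: sequence handling and single-mutant
enumeration, a sequence-kernel Gaussian process (GP), a combined
multi-objective metric, upper-confidence-bound (UCB) ranking, the
cross-validation protocol used to choose the model, a random-forest
comparison baseline, a synthetic landscape generator with known ground
truth, and the small kinetics computations used when winners are
characterized.

## Model

### Kernel

Two variants of the parent differ at a handful of positions, so
sequences are compared position-wise. The default kernel sums BLOSUM62
log-odds scores over aligned positions,
\[
k_{\mathrm{raw}}(x,y)=\sum_{i=1}^{L} B(x_i,y_i),
\qquad
k(x,y)=\frac{k_{\mathrm{raw}}(x,y)}
{\sqrt{k_{\mathrm{raw}}(x,x)\,k_{\mathrm{raw}}(y,y)}},
\]
the cosine normalization making every sequence's self-similarity 1
regardless of composition or length. The raw, un-normalized form stays
available behind `kernel_spec(normalize = FALSE)`, and a
Hamming-identity kernel (`"hamming"`, the fraction of matching
positions) is provided as the classical alternative. Alignment kernels
are deliberately absent: variant sets are equal-length by
construction, so there is nothing to align.

A position-summed substitution matrix is not guaranteed to be a
positive-semidefinite kernel. On variant sets of a common parent —
the only sets the ranker is meant for — the normalized Gram matrix
plus the default regularization is comfortably positive definite
(this is asserted by Cholesky success in the test suite up to
n = 200). For pathological inputs `psd_repair(mode = "clip")` zeroes
negative eigenvalues; the default mode leaves the matrix untouched
and lets the fit fail loudly if the Cholesky factorization cannot
proceed.

### GP regression

Each target is standardized to zero mean, unit variance on the
training data (sample standard deviation). The GP posterior is exact:
dual weights \(\alpha = (K+\lambda I)^{-1} z\) via Cholesky triangular
solves, predictive mean \(\mu_* = k_*^\top\alpha\) and variance
\(\sigma_*^2 = k(x_*,x_*) - k_*^\top (K+\lambda I)^{-1} k_*\), clamped
at zero before the square root to absorb floating-point noise. The
regularization constant is fixed at \(\lambda = 1\) on the
standardized scale — equivalently, unit observation-noise variance —
and no hyperparameters are searched. The model is multitask in the
minimal sense: one shared kernel, independent dual-weight vectors per
target, so the predictive standard deviation is common to all targets.

### Combined objective and acquisition

The two raw objectives live on incomparable scales, so each is
z-scored with the training statistics, the minimized target (ATP per
carboxylation) is negated, and the z-scores are summed into one
combined performance metric. The combination is invariant under
positive affine rescaling of any raw target. By default a third GP is
fitted directly to the combined training values and its posterior
drives the acquisition; `objective_spec(combined_gp = FALSE)` instead
sums the per-target posteriors (signs applied) at acquisition time.
Candidates are ranked by \( \mathrm{UCB} = \mu + \beta\sigma\) with
\(\beta = 0.5\), a mild exploration bonus; \(\beta\) outside \([0,1]\)
warns rather than fails so the trade-off can be studied. Ties preserve
enumeration order (position-major, mutant residue alphabetical), so a
ranking is reproducible to the byte. Selections take the top
\(\lceil f N\rceil\) rows — the ceiling guarantees a nonempty
selection — and `position_frequency()` counts how often each site
recurs in the selection, the signal used to nominate positions for
saturation mutagenesis.

## Evaluation protocol

`cross_validate()` reproduces the model-selection protocol: a seeded
uniform shuffle chunked into k = 10 folds whose sizes differ by at
most one; per fold, all standardization statistics and the combined
metric are re-estimated from the training split only (no leakage), the
GP is scored by the UCB of the combined metric — the quantity actually
used for ranking — and the RF baseline by its point prediction;
Spearman's ρ (mid-ranks) and Kendall's τ-b (tie-adjusted) are computed
against the held-out combined measurements and averaged across folds.
A pooled-correlation alternative is kept behind
`aggregate = "pooled"` for sensitivity analysis. Correlations are
undefined for constant vectors and are returned as `NA` with a
warning rather than silently coerced.

The baseline mirrors a pretrained-embedding-plus-random-forest
approach through a pluggable embedding interface: by default the
sequences are one-hot encoded (dimension 20·L); an externally computed
embedding table (e.g. averaged language-model hidden states) can be
supplied as TSV via `read_embedding_tsv()`. The forest uses 100 trees,
the default of the regressor settings the baseline protocol describes,
and is scored without an uncertainty term. Both families run through
byte-identical folds, so model comparisons are split-for-split.

## Synthetic landscapes

`simulate_landscape()` generates the data every other module is tested
against, emulating an error-prone-PCR screening campaign:

* a random parent of `parent_length` (default 50) residues;
* one latent effect pair per (position, non-wild-type residue), drawn
  from a zero-mean bivariate normal with sd `effect_sd` (default 1)
  and correlation `task_correlation` (default −0.3, so gains in rate
  tend to cost ATP efficiency, the trade-off seen in real campaigns);
* `library_size` variants (default 200) carrying a truncated-Poisson
  number of substitutions (rate `mean_mutations = 1.5`, at least 1, at
  most 5) at distinct uniform-random positions;
* true values that are exactly additive in the per-substitution
  effects, plus independent Gaussian measurement noise
  (`noise_sd = 0.3` per task, roughly a quarter of the
  between-variant spread).

Epistasis is excluded by default (an optional pairwise term exists
behind `epistasis_sd`) so that the recovery oracle stays
interpretable: with additive truth, the ideal ranking of single
mutants is known exactly. Everything is reproducible from a single
integer seed.

What the generator does *not* emulate matters for interpreting test
results. Real error-prone-PCR libraries concentrate mutations in a
biased spectrum, and real mutational effects correlate across
chemically similar residues at a site; the generator draws effects
independently per (position, residue) and places mutations uniformly.
Two consequences follow. First, a library of 200 variants averaging
fewer than two substitutions observes only a minority of the 19·L
possible substitutions, and under independent effects the unobserved
ones are unpredictable in principle — so rank correlation between
predictions and ground truth over the *complete* single-mutant
candidate set is structurally capped well below 1 even for a perfect
learner, and the BLOSUM smoothing that helps on real data cannot help
here. Second, at realistic construct lengths (hundreds of residues)
held-out variants share almost no substitutions with the training
folds, so cross-validated rank correlations on such synthetic
campaigns sit near zero; observed correlations on real campaigns
reflect structure the generator deliberately omits. The enrichment
property — that the UCB top 1% carries a much higher mean true effect
than a random 1% — is robust to all of this and is the property the
acceptance harness leans on.

## Kinetics

The characterization helpers are small and exact. Michaelis–Menten
saturation data are fitted by Levenberg–Marquardt least squares with
the deterministic start \(V_{max,0}=\max v\), \(K_{M,0}=\mathrm{median}\,S\)
and nonnegativity bounds; a Km estimate at the zero boundary (fully
saturated data) warns. Catalytic efficiency converts mM to M
(\(k_{cat}/(K_M\cdot 10^{-3})\)). Turnover numbers derive from
specific activities by
\(k_{cat}=V_{max}\cdot 10^{-9}\cdot 10^{3}\cdot M_{\mathrm{protomer}}/60\)
for \(V_{max}\) in nmol·min⁻¹·mg⁻¹; the default protomer mass,
1.2973×10⁵ g/mol, is the value consistent with the published
(Vmax, kcat) pairs for this enzyme and is a user parameter. The ATP
stoichiometry of the ATP-limited coupled assay is the quotient of
supplied ATP and consumed NADPH (with a configurable sanity bound),
and `a340_to_nadph()` applies Beer–Lambert with the standard NADPH
extinction coefficient (6220 M⁻¹cm⁻¹) for absorbance-based rates.

## Numerical and design choices

* Positions are 1-based on the full expressed construct; excluded
  regions (affinity tags) are masked, not renumbered, so published
  variant names remain valid.
* Only the 20 canonical amino acids are accepted; FASTA reading is
  strict by default and can instead drop offending records with a
  warning.
* Standardization uses the sample (n−1) standard deviation; every
  rank-based quantity downstream is invariant to that convention.
* Negative predictive variances from floating point are clamped to
  zero; predictive uncertainty is therefore never NaN.
* `kfold_split` gives the remainder observations to the leading
  folds; 161 observations in 10 folds become one fold of 17 and nine
  of 16.
* All stochastic steps (splits, simulations, forests) consume explicit
  integer seeds; repeated calls with equal inputs are identical.

The test suite exercises the problem sizes the package is designed
for: kernel and GP oracles up to n = 50 against dense-inversion linear
algebra, Gram positive-definiteness up to n = 200, recovery and
enrichment on the default 50-residue/200-variant landscape across 100
seeds, and one campaign emulated at a 550-residue construct scale,
where the complete single-mutant library has 10450 candidates and the
top 1% comprises 105 predictions.

## Limitations

The ranker assumes a mostly additive landscape; strong epistasis
violates the kernel's locality and is also excluded from the default
generator. The summed z-score objective is a scalarization, not a
Pareto method, and can favor lopsided trade-offs. The GP's uncertainty
is kernel-geometric only — it knows nothing about assay
heteroscedasticity. And the random-forest baseline here runs on
one-hot features unless a pretrained embedding table is supplied;
conclusions about embedding quality cannot be drawn from the bundled
default.
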