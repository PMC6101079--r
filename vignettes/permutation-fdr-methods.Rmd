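---
title: "Permutation nulls, BH FDR and off-line null inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation nulls, BH FDR and off-line null inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permfdr)
library(dplyr)
```

# The problem

In shotgun proteomics a search engine matches tandem MS spectra to peptides
and a protein-inference tool (e.g. ProteinProphet) assembles them into a
list of proteins, each with a probability-like confidence score in [0, 1].
Deciding how many of those proteins to accept requires an estimate of the
false discovery rate (FDR) — the expected fraction of accepted proteins
that are not actually in the sample. `permfdr` estimates the protein-level
FDR non-parametrically, directly at the protein level, in two stages:

1. **Permutation + BH.** An empirical null distribution of
   false-positive protein scores is built from decoy identifications
   obtained by searching against randomly shuffled protein sequences;
   bin-based p-values are read off the null and the Benjamini–Hochberg
   procedure converts them into q-values and an FDR-versus-count curve.
2. **Off-line null inference.** Because the permutation step is expensive
   (many shuffle + search + inference rounds), previously computed nulls
   are stored in a *feature database* together with a per-sample feature
   and a per-bin logistic coefficient table; the null of a new sample is
   either matched by feature similarity or inferred from the coefficients
   in closed form.

# The permutation null and bin-based p-values

Each target protein sequence is shuffled uniformly at random (Fisher–Yates
over the whole sequence) and appended to the target database with a
`DECOY_` accession prefix, giving a 1:1 concatenated target–decoy database.
Proteins inferred from decoy sequences are false positives by construction.
Because one search yields few decoy proteins, the shuffle-and-search round
is repeated (20 repeats by default in the synthetic harness) and the decoy
scores pooled into a single set of size $M$.

The score domain $[0, 1]$ is partitioned into $K$ bins of width $w$
(default $w = 0.003$, hence $K = \lceil 1/w \rceil = 334$, the last bin
truncated to $[0.999, 1]$). With $y_k$ the decoy count in bin $k$, the
points $(x_k, y_k/M)$ estimate the null density, and the p-value of a
protein whose score falls in bin $\hat k$ is the right tail

$$ p = \frac{\sum_{k=\hat k}^{K} y_k}{M}. $$

Design choices worth knowing:

* **Domain.** Bins cover the fixed unit interval, not the observed score
  range, so every sample shares one bin geometry (and $w = 0.003$ gives
  exactly 334 bins). `lo`/`hi` are configurable for other score types.
* **Bin convention.** Bins are half-open $[l, r)$ with the last bin
  right-closed, so every score in $[0, 1]$ belongs to exactly one bin.
* **Zero p-values.** A score above every decoy score has $p = 0$ under the
  tail formula. That is valid input for BH, but `pvalue(...,
  conservative = TRUE)` substitutes $(c + 1)/(M + 1)$ for a tail count $c$
  when a strictly positive floor is wanted.

The BH step is the canonical step-up procedure: with sorted p-values
$p_{(1)} \le \dots \le p_{(N)}$ over the $N$ *target* proteins (decoy
entries are excluded from $N$), the q-value of rank $i$ is
$\min_{j \ge i} N p_{(j)} / j$, and the estimated FDR after accepting the
top $n$ proteins is the $n$-th sorted q-value. Plain BH is used, no
Benjamini–Yekutieli correction. Ties in $p$ are kept in input order and
accepted together at the boundary.

# The sample feature and similarity

A sample is summarized by the histogram $\Pr_{i,1..10}$ of its target
protein scores in 10 equal bins on $[0, 1]$, and its single feature
($J = 1$) is the Kullback–Leibler divergence to a designated reference
sample:

$$ D_{i,\mathrm{ref}} = \sum_{k=1}^{10} \Pr_{i,k}
   \log \frac{\Pr_{i,k}}{\Pr_{\mathrm{ref},k}} \quad \text{(nats)}. $$

Empty bins make the ratio undefined, so a pseudo-probability
(`eps = 1e-9`) is added to every bin of both histograms before
renormalizing; identical histograms therefore give exactly 0. Both
histograms live on the shared $[0,1]$ domain — KL between histograms
binned on two different per-sample ranges would compare incommensurable
bins. The divergence is deliberately non-symmetric (it measures the sample
against the reference), and the logarithm base is natural by default;
only relative comparisons matter, so the base is a convention.

Similarity matching: with one feature the Pearson correlation of feature
"vectors" is undefined, so a new sample reuses a stored null when the
absolute feature difference to the nearest stored sample is at most
`match_tol` (default 0.05). With $J \ge 2$ features the correlation rule
(best match above `cor_threshold = 0.9`) applies instead.

Note that the KL feature's scale depends on the reference: against a
reference with empty histogram bins the smoothing term dominates and
divergences become large and noisy. A reference whose scores populate all
10 bins keeps the feature scale moderate; this matters when choosing
`match_tol`.

# Per-bin logistic inference of a null

For stored sample $i$ and bin $k$, the cumulative null probability
$\Pr_{i,k}$ (the null mass at or below bin $k$'s upper edge) is linked to
the features through a per-bin logistic model,

$$ \log \frac{\Pr_{i,k}}{1 - \Pr_{i,k}}
   = \beta_{k,0} + \sum_{j=1}^{J} \beta_{k,j} r_{i,j}, $$

fitted **as least squares on the logit scale** — not binomial maximum
likelihood — by minimizing
$\sum_i \mathcal L(\mathrm{logit}(\Pr_{i,k}) - \beta_{k,0} - \sum_j
\beta_{k,j} r_{i,j})$ with $\mathcal L = \|\cdot\|_2$ by default and a
Huber option for robustness. The last bin is never fitted because
$\Pr_{i,K} = 1$ identically, so the coefficient table has $K - 1$ rows.

Numerical choices:

* **Logit clipping.** $\Pr \in \{0, 1\}$ occurs necessarily (empty leading
  bins; the last fitted bin of a sample with no high-scoring decoys), and
  its logit is infinite. Probabilities are clipped into
  $[\varepsilon, 1 - \varepsilon]$ with $\varepsilon = 10^{-6}$ before the
  logit. The clipping epsilon is recorded in the coefficient table's
  metadata.
* **Degenerate designs.** If the features do not vary across training
  samples the fit is rank-deficient: a constant response still yields the
  natural answer (slope 0, intercept at the common logit); a varying
  response raises an error rather than returning arbitrary coefficients.
* **Link overflow.** The linear term is clamped to $\pm 36$ before the
  logistic link, keeping predictions strictly inside $(0, 1)$ in double
  precision.

For a new sample with features $r_0$, each fitted bin's cumulative
probability is predicted through the logistic link, the last bin is forced
to 1 (consistent with skipping it in the fit, rather than extrapolating),
and the density is obtained by first differences with $\Pr_0(\text{bin } 0)
= 0$. Because the per-bin fits are independent, the predicted cumulative
sequence need not be monotone and naive differencing can give negative
densities. The sequence is therefore projected onto the nearest
non-decreasing sequence (isotonic regression, the minimal-$L_2$ repair,
which preserves the total mass) before differencing; the returned density
is non-negative and sums to 1 by construction. Whether and how to repair
non-monotone predictions was genuinely open; isotonic projection was chosen
because it is the canonical minimal correction and leaves already-monotone
predictions untouched.

The inferred null carries a nominal count mass (`nominal_m = 1e6`) spread
over its density so it can be used interchangeably with permutation-built
nulls in `pvalue()`; only the density matters downstream.

# The feature database

`feature_db()` bundles the stored nulls, the feature table, the
coefficient table, the reference sample's 10-bin histogram (so new-sample
feature extraction never re-reads the reference's raw scores) and the
configuration (bin geometry, tolerances, epsilons) into one JSON-serializable
object. `resolve_null()` implements the decision workflow: extract the
feature, match (`"matched:<id>"`) or infer (`"inferred"`), never mutating
the database. Samples are added explicitly with `add_sample()` — nothing is
written back automatically — and adding marks the coefficient table stale
until `refit_db()`.

# The synthetic generator

Real inputs to this framework are protein score tables produced by a
search + protein-inference pipeline on real spectra. The synthetic module
stands in for them with a two-component Beta mixture on $[0, 1]$:

* true-positive targets $\sim \mathrm{Beta}(8, 1)$ (concentrated near 1,
  mimicking confident ProteinProphet probabilities);
* false-positive targets and all decoy scores i.i.d.
  $\sim \mathrm{Beta}(1, 8)$ (a shared low-score distribution — the
  framework's implicit assumption that decoys model false positives holds
  exactly here);
* defaults 300 true + 700 false targets and 20 decoy repeats of
  $n_\mathrm{true} + n_\mathrm{false}$ scores each, i.e. $M = 20{,}000$.

Under this generator the decoy distribution *is* the false-positive
distribution, so estimated and true FDR should agree up to sampling and
binning error; the calibration tests verify mean absolute agreement within
0.05 at $\alpha \in \{0.01, 0.05, 0.1\}$ averaged over 20 seeds, and that
accuracy improves as repeats (hence $M$) grow. What passing these tests
does **not** show: real decoy scores may deviate from the true
false-positive distribution (homologous sequences, shared peptides,
protein-inference artifacts), p-values of different proteins may be
dependent, and score calibration varies across instruments — none of which
the Beta mixture emulates. The synthetic results validate the machinery,
not the target-decoy assumption itself.

`simulate_null_family()` is the analogous harness for the inference model:
it generates nulls whose cumulative bins follow the logit-linear family
exactly (plus optional logit-scale Gaussian noise), then monotonizes by
running maximum. Generating coefficients used in the tests keep the
intercepts on the logit of a strictly increasing base CDF with per-bin
slope variation smaller than the intercept spacing, so every generated CDF
is monotone over the whole feature range and the noiseless round trip
(fit, then infer at a training feature) is exact to floating-point
precision rather than distorted by monotonization.

The true FDR of an accepted set is the fraction of accepted proteins
*outside* the ground-truth set (0 for an empty set by convention) — the
realized counterpart of the estimated FDR.

# Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `bin_width` | 0.003 | null bin width on [0, 1]; gives K = 334 |
| `n_bins` (feature histogram) | 10 | bins of the KL feature histogram |
| `eps` (KL smoothing) | 1e-9 | pseudo-probability for empty bins |
| `clip_eps` | 1e-6 | logit clipping for Pr in {0, 1} |
| `loss` | `"l2"` | per-bin fit loss; `"huber"` for robustness |
| `match_tol` | 0.05 | J = 1 feature-difference matching tolerance |
| `cor_threshold` | 0.9 | J >= 2 correlation matching threshold |
| `nominal_m` | 1e6 | count mass of inferred nulls |
| `n_repeats` | 20 | decoy shuffle/search repeats (synthetic) |

# Problem sizes used in the test suite

The suite runs entirely on generated data: BH and p-value oracle checks on
a thousand random vectors of up to 50 p-values and 200 random decoy/target
configurations; coefficient recovery on a 5-sample, 50-bin noiseless
family; calibration on 20 seeds of the 1,000-protein default mixture; the
repeats-accuracy comparison on 100-protein samples where the null's
resolution is the limiting factor. These sizes make every property
detectable with comfortable margins while keeping the full suite at
desk scale.

# Known limitations

* Protein grouping/parsimony, peptide-level FDR and $\pi_0$-style q-value
  refinements are out of scope; the input is one score per inferred
  protein.
* The shuffle is a whole-sequence permutation; it does not preserve
  enzymatic cleavage sites, and no cleavage-aware variant is provided.
* The single KL feature cannot explain all between-sample variation in
  null shape; the model interface is generic in $J$, but multi-feature
  databases are untested beyond the mechanics.
* Inference quality depends on the stored samples bracketing the new
  sample's feature value; extrapolation outside the training range is not
  prevented, only discouraged.
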