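---
title: "Methods: deep-learning imputation of sparse microbiome counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning imputation of sparse microbiome counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mbsparse)
```

## The problem

Taxonomic count matrices from 16S or shotgun metagenomic sequencing are
extremely sparse: zero fractions up to 90% are common. Some of those zeros
are *biological* (the taxon is genuinely absent and must stay zero); others
are *non-biological* — sampling zeros from limited sequencing depth, or
technical zeros from extraction, PCR or batch effects. Treating all zeros at
face value biases downstream analyses such as differential-abundance
testing. mbsparse imputes likely non-biological zeros while never touching
observed non-zero counts, and deliberately avoids assuming any predefined
count distribution: the conditional structure between samples is learned by
neural networks instead.

## The model

Let `M` be the observed counts for `n` samples by `m` taxa. The working
representation is total-sum scaling followed by a log transform:

* `M'_ij = T * M_ij / sum_j' M_ij'` with target library size `T = 1e6`, then
* `X_ij = log10(M'_ij + 1)`,

so zeros remain zeros, all values are non-negative, and within-sample
abundance ranks are preserved. All model stages operate on `X`; the
normalized-count view of the output is recovered as `10^X - 1`.

The pipeline has three learned stages:

1. **Feature autoencoder.** A dense encoder `m -> 512 -> 128` and mirrored
   decoder `128 -> 512 -> m` are trained to minimize the reconstruction
   mean squared error of `X`. The 128-dimensional bottleneck `Z` is the
   per-sample embedding. Hidden layers use ReLU; the embedding layer uses
   ReLU (embeddings are non-negative) and the output layer softplus, which
   keeps reconstructions non-negative while avoiding dead output units. The
   inner widths (512, 128) are fixed; the outer widths adapt to `m`.
2. **Sample correlation graph.** Each sample is connected to its `k`
   Euclidean nearest neighbours in embedding space (default `k = 5`; a
   small `k` keeps dissimilar samples out of the average). The graph is
   *directed* and not symmetrized: the fill rule below consumes the
   per-target neighbourhood `N_i`, and symmetrizing would give nodes
   unequal neighbour counts. Ties are broken by ascending sample index, so
   the graph is a deterministic function of the embeddings.
3. **Conditional VAE.** For every directed edge `(v, u)` the CVAE learns
   `p(X_u | X_v)`. The recognition network maps `concat(X_u, X_v)` through
   one ReLU layer of width 256 to the mean and log-variance of a diagonal
   Gaussian posterior over a 10-dimensional latent `z`. The decoder
   concatenates `z` with a learned 10-dimensional linear projection of the
   condition `X_v` (decoder input width 20) and maps `20 -> 256 -> m` with a
   softplus output. Training maximizes the ELBO with reparameterized draws
   `z = mu + sigma * eps`. After training, one conditional sample `X^c_v`
   is generated per node by decoding a prior draw `z ~ N(0, I)` under
   condition `X_v`, so conditional neighbours inherit exactly the real
   neighbourhood structure.

**Zero filling.** For every zero entry, with `K = |N_i| = k`:

```
X_ij <- (1 / 2K) * sum_{r in N_i} (X_rj + X^c_rj)
```

Non-zero entries are returned bit-exact. A zero whose real and conditional
neighbours are all zero at that taxon stays zero — that is the mechanism by
which putative biological zeros are left alone. Imputation is attempted at
*every* zero; there is no pre-classification into biological and
non-biological zeros.

### Interpretation choices in the generative model

Three aspects of the CVAE were genuinely open and were resolved as follows:

* **Prior.** A fixed standard-normal prior `N(0, I)` is used rather than a
  learned conditional prior. The generation procedure (condition-only
  input, latent drawn from a parameter-free distribution) and the noise
  term `eps ~ N(0, I)` in the reparameterization are both consistent with a
  fixed prior, which is the simpler model.
* **Likelihood.** The decoder likelihood is Gaussian with fixed unit
  variance in logged space, so the reconstruction term is an MSE and the
  ELBO decomposes as `-KL - SSE/2 - (m/2) log(2*pi)`. Logged abundances are
  continuous and roughly homoscedastic, and this choice avoids imposing a
  count distribution, which is the method's stated philosophy.
* **Monte-Carlo draws.** The reconstruction term averages over
  `n_mc_samples` reparameterized draws; the default is the standard
  single-draw estimator, and the knob is independent of the neighbour
  count `k`.

One latent draw is made per node at generation time (one conditional sample
per sample), not one per edge.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `target_library_size` | 1e6 | total-sum-scaling target (counts/sample) |
| `k` | 5 | neighbours per sample (directed out-degree) |
| `fae$hidden_dim`, `fae$embedding_dim` | 512, 128 | autoencoder widths |
| `cvae$latent_dim`, `cvae$hidden_dim`, `cvae$condition_proj_dim` | 10, 256, 10 | CVAE widths |
| `epochs`, `learning_rate`, `batch_size` | 200, 1e-3, 64 | Adam training (both models) |
| `cvae$n_mc_samples` | 1 | reconstruction-term draws |
| `variant` | `"full"` | `no_fae` / `no_cvae` / `neither` ablations |

The optimizer (Adam), epoch count, learning rate and activation functions
are implementation choices exposed through the configuration objects. The
embedding dimension must be smaller than the number of taxa; for matrices
with fewer than ~130 taxa, pass smaller `hidden_dim`/`embedding_dim`.

Training is implemented as vectorized dense-matrix forward/backward passes
with Adam, in double precision on a single device: two runs with the same
seed are bit-identical, and every stochastic stage receives a seed derived
from the global seed and the stage name by a stable 31-bit hash
(`derive_seed()`), so adding a stage never perturbs another stage's stream.

## The synthetic generator and what passing tests mean

`synthesize_count_matrix()` draws log-means
`log(100) + U V' / sqrt(r)` with standard-normal factors (`r = 5` by
default), negative-binomial counts around them (dispersion 0.5), and then
zeroes entries *independently* with probability `zero_inflation` (default
0.3). This emulates the two features the method actually exploits —
correlated samples through a low-rank structure, and heavy zero inflation —
at the sample sizes typical of microbiome cohorts (defaults 100 samples,
300 taxa).

It does **not** emulate: compositional closure of real relative-abundance
data, mean-dependent (structured) dropout, phylogenetic correlation between
taxa, batch effects, or longitudinal dependence. Consequently the test
suite demonstrates that the pipeline recovers deliberately removed counts
far better than leaving zeros in place *under unstructured zero inflation*;
it does not certify performance on real cohorts, where zeros are structured
and the neighbour signal is typically stronger.

One measured consequence of the unstructured zeros is worth stating
plainly: the mean per-taxon Pearson correlation of the imputed matrix
against the complete matrix can trail the non-imputed baseline even while
the masked-entry MSE improves several-fold and every injected zero is
restored. The fill rule averages neighbour values *including their zeros*,
so fills shrink toward roughly `(1 - zero fraction)` of the true value;
within a taxon the imputed column then mixes unshrunk observed entries with
shrunk fills, and fills at the generator's own (unstructured) zeros add
variance that the all-zero baseline does not have. With structured zeros —
where a zero in one sample predicts zeros in its neighbours — both effects
shrink. The acceptance script reports both correlations so the effect is
visible rather than hidden.

## Corruption protocols

* `inject_dropout()` zeroes `floor(rate * #nonzero)` uniformly chosen
  non-zero entries and records the mask; the mask is sufficient to undo the
  corruption exactly.
* `downsample_depth()` / `depth_experiment()` resample each sample
  multinomially at a fixed depth; the experiment masks the entries newly
  turned to zero. Because *every* entry changes under resampling, depth
  robustness is scored on whole-matrix MSE (`mse_all`), not on the mask
  alone: the masked population itself shifts toward ever-smaller true
  abundances as depth grows, which would make masked-only MSE rise with
  depth even as the imputation gets uniformly better.
* `make_outlier()` rebuilds one sample from low-abundance taxa only (mean
  below the median of taxon means, at least 10 non-zero values), each set
  to a draw from that taxon's top-100 observed values, all other taxa
  zeroed. With fewer than 100 non-zero values, the pool is all of them.
* `make_complete_scheme1()` extracts a zero-free submatrix (the
  `ceiling(p*m)` least-zero taxa, then every sample dense in them);
  `make_complete_scheme2()` adds multinomial resampling at a fixed depth.
  These are documented approximations whose binding contract is the
  zero-free output.

## Numerical choices and degenerate inputs

* Softplus is evaluated as `x + log1p(exp(-x))` for positive `x` to avoid
  overflow; its gradient is the logistic function.
* Samples with zero total count cannot be normalized and are rejected by
  name; imputation of a matrix that contains such samples fails in the
  preprocessing stage with the sample identified.
* KNN ties (identical embeddings) resolve to ascending sample index, making
  every downstream artifact deterministic.
* Per-taxon correlations over constant columns are undefined; they are
  excluded from means and counted, never silently zeroed.
* Imputed rows are *not* re-normalized: filling zeros necessarily breaks
  the exact `1e6` row sum, and rescaling would alter retained entries,
  violating the retention guarantee. Output is offered on both the logged
  and the normalized-count scale; no attempt is made to return to the raw
  count scale.

## Benchmark sizing in the test suite

The stochastic suites use the generator defaults (100 samples, 300 taxa,
30% zero inflation), dropout rate 0.2, and ten replicate seeds, imputed
with a compact network sizing (autoencoder 128/32 hidden/embedding, CVAE
hidden 128, 80 epochs); the depth suite uses 60 x 150 dense matrices at
depths 1000–10000. These sizes keep a full run of the replicated protocols
in the minutes range on one CPU while leaving every architectural element
of the method in place; the defaults above remain the recommended settings
for real data.

## Known limitations

* The method is transductive: models are trained on the matrix being
  imputed, so there is no train/test split and no reusable fitted object
  across datasets.
* Zero filling borrows only across samples (rows); taxon–taxon structure
  enters only indirectly through the learned embeddings and decoder.
* Cross-sectional design: samples are assumed exchangeable; longitudinal
  dependence is not modelled.
* Similarity is Euclidean in embedding space; phylogeny-informed similarity
  is out of scope.
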