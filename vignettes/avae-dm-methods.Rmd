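---
title: "Adversarial variational autoencoders with dual matching for scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial variational autoencoders with dual matching for scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scAVAE)
```

## The problem

Single-cell RNA-seq yields a cells × genes matrix of transcript counts that
is high-dimensional, noisy, and riddled with *dropout events* — zeros that
arise when an expressed transcript goes undetected. Dimensionality
reduction to a small latent space is the first step of most downstream
analyses (clustering, cell-type identification, visualization), and linear
methods such as PCA handle neither the count nature of the data nor the
excess zeros well.

scAVAE reduces count matrices with an *adversarial variational autoencoder
with dual matching* (AVAE-DM). The model combines three ingredients:

1. **A variational autoencoder with a ZINB likelihood.** The encoder maps
   the log-transformed expression vector of each cell to the mean and
   (diagonal) log-variance of a Gaussian variational posterior
   $q(z \mid x)$ over a $K$-dimensional latent code. A latent code drawn by
   the reparameterization trick, $z = \mu_z + e^{\frac{1}{2}\log\sigma_z^2}
   \odot \varepsilon$, is decoded into the parameters of a zero-inflated
   negative binomial (ZINB) distribution over the *raw counts*:
   per gene a mean $\mu > 0$, an inverse-dispersion $\theta > 0$
   (variance $\mu + \mu^2/\theta$), and a dropout probability
   $\pi \in (0, 1)$. The reconstruction loss is the negative ZINB
   log-likelihood, summed over genes and averaged over the cells of a
   minibatch.
2. **Adversarial prior matching instead of a KL term.** A latent-space
   discriminator $D_1$ is trained to tell prior samples
   $z \sim N(0, I)$ from posterior samples; the encoder doubles as the
   generator of that game and is trained to fool $D_1$. At the optimum the
   aggregate posterior matches the prior, which is what the KL term of a
   VAE would otherwise encourage — here the KL objective is background
   only and never used as a training loss.
3. **Dual matching.** A second, data-space discriminator $D_2$ receives
   real expression vectors and the decoder's reconstructions and is
   trained to tell them apart, while the autoencoder is trained to fool
   it. This matches the distribution of reconstructions with that of the
   real data. Disabling $D_2$ (`dual_matching = FALSE`) gives the plain
   AVAE ablation.

## Adversarial objectives

Four interchangeable objectives drive both discriminator games
(`objective =` in `train_config()`):

* `"standard"` — the classic minimax objective. The discriminator
  minimizes $-\mathbb{E}\log D(x) - \mathbb{E}\log(1 - D(G(z)))$; the
  generator uses the non-saturating form $-\mathbb{E}\log D(G(z))$ (the
  minimax generator gradient vanishes early in training, so the
  non-saturating form is the standard practical choice).
* `"wasserstein"` — the critic maximizes
  $\mathbb{E}[D(x)] - \mathbb{E}[D(G(z))]$ with a linear (unbounded)
  output head. No Lipschitz constraint is enforced in this plain variant;
  that is a documented limitation, not an oversight.
* `"wasserstein_gp"` — adds the gradient penalty
  $\lambda\,\mathbb{E}_{\hat x}(\lVert\nabla_{\hat x} D(\hat x)\rVert_2 - 1)^2$
  on random interpolates between real and generated samples
  ($\lambda =$ `gp_weight`, default 10, the conventional coefficient).
* `"bhattacharyya"` — the default, and the variant that defines the
  method. The Bhattacharyya distance between distributions $p, q$ is
  $BD(p,q) = -\ln \sum_x \sqrt{p(x) q(x)}$; for univariate Gaussians it
  has the closed form
  $\tfrac{(\mu_1-\mu_2)^2}{4(\sigma_1^2+\sigma_2^2)} +
  \tfrac{1}{2}\ln\tfrac{\sigma_1^2+\sigma_2^2}{2\sigma_1\sigma_2}$.
  Written as a distance between two scalar expectations of discriminator
  scores, a BD minimax objective is not directly computable — a distance
  between distributions needs distributions. The package's reading: fit a
  Gaussian by moment matching (sample mean, population variance floored
  at $10^{-6}$) to the real-score batch and to the fake-score batch, and
  use $BD$ between those two Gaussians. The discriminator maximizes the
  separation; the generator minimizes it with the real-score moments held
  constant. This preserves the stated intent — measure the similarity of
  the two score populations — while being differentiable; it requires
  batches of at least two on each side, hence `batch_size >= 2`.

Score domains are enforced at model-assembly time: sigmoid heads (scores
in $(0,1)$) for the standard and Bhattacharyya objectives, linear heads
for the Wasserstein variants.

## Networks and training schedule

All networks are fully connected MLPs drawn from a fixed architecture
grid: 1–4 hidden layers with 8–1024 nodes each, LeakyReLU activations
(negative slope 0.2, the GAN-literature default; the activation is
prescribed, the slope is not), and dropout on hidden layers (rate 0.1 by
default, applied to all four networks at training time and disabled at
inference). The decoder's three heads use an exponential link clamped to
$[10^{-8}, 10^8]$ for $\mu$ and $\theta$ and a sigmoid clamped to
$[10^{-8}, 1-10^{-8}]$ for $\pi$, so any finite latent code yields valid
ZINB parameters. Discriminator output heads are initialized with small
weights (sd 0.01) so early scores sit near the decision boundary rather
than in the saturated tails of the sigmoid.

Because no deep-learning framework is available to R in this package's
dependency footprint, forward passes, backpropagation, and Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$; only the optimizer name is
prescribed, so the canonical defaults are used) are implemented directly
in base R matrix code. The WGAN-GP critic update needs the parameter
gradient of a function of the critic's *input* gradient (double
backprop); with LeakyReLU the activation's second derivative vanishes
almost everywhere, so the input-gradient map is the "transpose network"
with frozen slope factors and the penalty gradient follows exactly from
backpropagating through that map. Unit tests verify both backprop paths
against finite differences.

Per minibatch the loop runs: (a) an autoencoder step on the ZINB
reconstruction NLL; (b) one $D_1$ step; (c) two encoder-as-generator
steps against $D_1$ (the generator is updated twice per discriminator
update); and under dual matching (d) one $D_2$ step and (e) two
generator steps against $D_2$. The stated 2:1 ratio is applied to both
discriminators (the protocol states it once, for the latent game; the
package treats it as global and exposes it as
`gen_updates_per_disc`). The sample shown to $D_2$ is the expected
reconstruction $\mu(1-\pi)$ rather than a stochastic ZINB draw —
differentiable and low-variance — and both real and reconstructed
vectors enter $D_2$ on the $\log_2(1+\cdot)$ scale, the same scale the
encoder sees. Generator-side losses are combined with equal unit
weights (reconstruction, latent, data terms); no weighting scheme is
prescribed, and the weights are exposed in `train_config()`.

Epoch counts and stopping rules are not prescribed either: the default
is at most 300 epochs with early stopping once the epoch reconstruction
loss has not improved for 30 epochs. Every source of randomness —
initialization, shuffling, reparameterization noise, dropout masks —
derives from the single `seed` field, so a run is bit-reproducible on a
given platform.

`preset_config()` returns the published per-dataset configurations for
the five reference datasets (Zeisel-3k, Macosko-44k, Zheng-68k,
Zheng-73k, Rosenberg-156k) at $K \in \{2, 10, 20\}$: batch size 128
throughout, the tabulated generator/discriminator widths, and the
tabulated learning rates. The decoder mirrors the encoder's widths in
reverse and both discriminators share the discriminator spec; the
published table lists one generator and one discriminator column, so
this mirroring is the package's interpretation.

## Preprocessing protocol

`select_top_variance_genes()` keeps the 720 genes (default) of largest
across-cell variance of the **raw counts**, using the population variance
(divide by $M$) with ties broken by the lower original gene index —
selection precedes the log transform in the protocol's narrative order,
and whether the ranking should use raw or log counts is not stated; raw
is the default and the choice is configurable by transforming first.
`log_transform()` applies $\log_2(1 + C)$ entrywise. No library-size
normalization is applied — that is outside the protocol. An 80/20
train/test split (`split_train_test()`) uses round-half-up for the
training-set size; models are fit on the training split and evaluated by
projecting the held-out split.

## Evaluation and visualization

`evaluate_embedding()` clusters an embedding with K-means ($k$ = number
of ground-truth cell types, k-means++ seeding, 10 restarts, best
within-cluster sum of squares kept) and scores agreement with the truth
by normalized mutual information,
$\mathrm{NMI} = MI(X;Y)/\sqrt{H(X)H(Y)}$, computed from the joint
contingency table in natural log (the base cancels; a property test
verifies base invariance). A single-class labeling has zero entropy; NMI
is then defined as 0 with a warning. `run_baselines()` embeds the same
matrix with PCA, t-SNE (perplexity 30), and UMAP for comparison; t-SNE
is restricted to $K \le 3$ and reported as `"N/A"` beyond that, as is
any method whose package is unavailable. `two_step_embed()` implements
the two-step visualization recipe — project with a trained $K = 10$
model, then t-SNE to 2-D — and `filter_top_cell_types()` restricts
plots to the most abundant cell types (ties broken lexicographically).
t-SNE settings beyond perplexity follow the library defaults.

## The synthetic-data generator

`generate_zinb_counts()` inverts the model the autoencoder assumes: each
cell is assigned to one of `n_clusters` clusters by the mixing
proportions, and each count is drawn ZINB with the cluster's per-gene
mean, a shared inverse-dispersion $\theta$, and dropout probability
$\pi$ (with probability $\pi$ the count is zeroed). The default study
conditions used throughout the tests are 300 cells × 120 genes, three
equal clusters with block marker profiles (`make_cluster_profiles()`:
each cluster expresses its own third of the genes at mean 10 counts
against a background of 0.5), $\theta = 2$, $\pi = 0.3$ — values typical
of the moderate-depth, strongly-structured regime in which cell types
are recoverable, with roughly 60% zeros. The generator emulates cluster
structure and dropout but deliberately **not** library-size variation,
batch effects, or continuous trajectories; passing tests demonstrate
correct mechanics and cluster recovery under the model's own
assumptions, not robustness to those real-data complications.

Closed forms used in its tests: the ZINB zero mass is
$\pi + (1-\pi)\left(\tfrac{\theta}{\theta+\mu}\right)^{\theta}$, e.g.
$0.3 + 0.7\,(2/7)^2 \approx 0.357$ at $\mu = 5, \theta = 2, \pi = 0.3$.

## Numerical choices and degenerate inputs

* $\mu, \theta$ are clamped to $[10^{-8}, 10^8]$ and $\pi$ to
  $[10^{-8}, 1 - 10^{-8}]$ inside the loss — the likelihood is finite for
  every input the decoder can produce.
* The ZINB zero branch $\ln(\pi + (1-\pi)\,\mathrm{NB}(0))$ is evaluated
  with log-sum-exp; the NB pmf itself is computed entirely in log space
  via `lgamma`.
* Probability-domain scores are clamped to $[10^{-7}, 1-10^{-7}]$ before
  loss evaluation; the BD objective floors per-batch score variances at
  $10^{-6}$.
* A non-finite loss aborts training with a message naming the step; a
  batch size exceeding the cell count is an error; trailing minibatches
  of size 1 are skipped (per-batch variance is undefined for them).
* K-means: `stats::kmeans` rejects $k = M$; that boundary case (singleton
  clusters, inertia 0) is returned directly. Duplicate k-means++ centers
  receive a $10^{-9}$ jitter, as `stats::kmeans` requires distinct
  centers.

## Problem sizes in the test suite

The test suite and the acceptance script train at desk scale, chosen so
the full suite runs comfortably on one CPU: the reference fixture
(300 × 120, three clusters) is trained once for 300 epochs at seed 0
(~1 minute) and ten more times — five seeds × {AVAE-DM, AVAE} — for 150
epochs each for the ablation and random-baseline comparisons.
Mechanical tests (shapes, determinism, gradients) use 60–90 cells and
tiny networks. The published benchmark NMIs on the five real datasets
require external downloads and GPU-scale training and are out of scope;
the synthetic recovery runs stand in for them qualitatively.

## Known limitations

* **BD prior matching is looser than the alternatives.** The BD
  discriminator can increase its objective without bound by driving both
  per-batch score variances toward the floor (sigmoid saturation), after
  which the generator's matching signal weakens. On the reference
  fixture the aggregate posterior under the BD objective ends mildly
  off-prior (per-coordinate means up to ~0.7, variances up to ~4 across
  pilot settings), while the Wasserstein and standard objectives match
  $N(0, I)$ comfortably; cluster recovery (the quantity the method is
  evaluated on) is excellent under all three. The small critic-head
  initialization mitigates but does not remove this. The latent-matching
  property test therefore exercises the mechanism under the Wasserstein
  critic.
* The plain Wasserstein variant enforces no Lipschitz constraint (use
  `wasserstein_gp` when that matters).
* Training is single-threaded base R: suitable for hundreds to a few
  thousand cells at the preset widths, not for atlas-scale matrices.
* ZINB parameters are not identifiable per cell from one draw; the
  decoder's $\theta$ and $\pi$ should be read as distributional fit
  parameters, not per-gene biological estimates.
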