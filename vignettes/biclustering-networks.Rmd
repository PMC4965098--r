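---
title: "Sparse/dense-mixture biclustering and co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse/dense-mixture biclustering and co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicnet)
```

## The model

`bicnet` fits the latent factor model

$$Y = \Lambda X + \epsilon, \qquad
  \epsilon_{\cdot,i} \sim N(0, \Psi),\quad \Psi = \mathrm{diag}(\psi_1,\dots,\psi_p),$$

for a gene-by-sample expression matrix $Y \in \mathbb{R}^{p\times n}$, with
loadings $\Lambda \in \mathbb{R}^{p\times K}$ and factors
$X \in \mathbb{R}^{K\times n}$. Both sides carry a three-level
three-parameter-beta (TPB) shrinkage hierarchy. On the loading side, after
the standard reparameterization of the TPB variables into gamma chains,

$$\gamma \sim \mathrm{Ga}(f,\nu),\;
  \eta \sim \mathrm{Ga}(e,\gamma),\;
  \tau_k \sim \mathrm{Ga}(d,\eta),\;
  \phi_k \sim \mathrm{Ga}(c,\tau_k),\;
  \delta_{jk} \sim \mathrm{Ga}(b,\phi_k),\;
  \theta_{jk} \sim \mathrm{Ga}(a,\delta_{jk}),$$

and $\Lambda_{jk} \sim N(0,\theta_{jk})$. The two local layers integrate to
$\theta_{jk} = \phi_k t$, $t \sim \mathrm{Beta}'(a,b)$; with the default
$a=b=1/2$ this is the horseshoe variance law, so each element gets its own
heavy-tailed local scale while $\phi_k$, $\tau_k$ and the global pair
$(\eta,\gamma)$ shrink whole components and the factorization as a whole.
Each component additionally carries a Bernoulli indicator $z_k$ (loading
side) and $o_k$ (factor side) choosing between this *sparse* branch and a
*dense* branch $\Lambda_{jk}\sim N(0,\phi_k)$, with beta-distributed mixing
proportions. Dense components absorb confounder-like variation that loads
on essentially all genes or all samples; sparse-by-sparse components are
biclusters: a subset of genes co-varying in a subset of samples. The factor
side mirrors this structure with parameters
$(\xi,\varphi,\chi,\kappa_k,\omega_k,\rho_{ki},\sigma_{ki},o_k,\pi_X)$.

Default hyperparameters are $a=b=0.5$, $c=1$, $d=0.5$, $e=f=1$,
$\nu=\xi=1$ and uniform beta priors on the mixing proportions: a horseshoe
at the local level, a Strawderman–Berger prior at the component level, and
a flat-tailed global level. `K` is an overestimate (rule of thumb:
`default_K(p, n)` = $2\min(p,n)$); unsupported components are pruned during
fitting.

## Estimation

`fit_vem()` runs a Gibbs-sampler warm start followed by variational EM.

**Warm start.** The Gibbs sampler (`gibbs_sweep()`) draws every conditional
in closed form: multivariate normal rows/columns for $\Lambda$ and $X$,
generalized-inverse-Gaussian (GIG) conditionals for the local variances and
dense-branch scales, gamma conditionals for the remaining shrinkage chain,
and inverse-gamma for $\Psi$. The GIG sampler is implemented from scratch
(`sample_gig()`): a two-parameter reduction followed by either a
mode-shifted ratio-of-uniforms method or, for $|\lambda|<1$ with small
$\omega=\sqrt{\chi_a\chi_b}$, a three-piece envelope on the $\log x$ scale
where the density is log-concave; it is validated against quadrature
moments and KS tests down to $\omega \approx 10^{-150}$.

Two points in the sampler deviate from a naive transcription of the
conditionals and matter in practice:

* **Indicator draws are collapsed.** Comparing the sparse and dense
  branches' joint densities *at sampled local values* penalizes the sparse
  branch by the conditional entropy of its extra latent layers (about 2
  nats per gene at the defaults), so a chain using that ratio collapses
  into the all-dense state and never leaves it. `bicnet` instead draws each
  indicator with the local variance integrated out: the sparse evidence is
  then a variance-gamma density (Bessel-$K$ closed form), the
  $\delta$-layer is common to both branches and cancels, and the local
  variance is re-imputed from its exact conditional given the new indicator
  (GIG under the sparse branch, its prior under the dense branch). This is
  an exact blocked Gibbs move; joint consistency is verified by a
  Geweke-style prior/chain comparison in the test suite.
* **The warm start pins the indicators sparse for the first 75% of its
  sweeps.** Even with exact moves, the all-dense and structured basins are
  separated by a barrier the chain cannot cross from an unstructured start
  at realistic dimensions. The heavy-tailed sparse hierarchy *nests* dense
  behavior, so running the chain inside the sparse branch loses nothing and
  finds supports freely. The final quarter of the sweeps runs with free
  indicator draws, and their averages (posterior sparse probabilities
  evaluated on honest chain samples) initialize the variational step.
  Initializing from hard indicators instead lets the first sparse-branch
  updates zero out part of a dense column and thereby flip the column's own
  evidence — a self-fulfilling misclassification.

**Variational EM.** Given the warm state, the fit iterates closed-form
updates in a fixed order (loading rows; loading shrinkage, indicators and
mixing; factor columns with their posterior covariances; factor shrinkage;
noise), tracking the number of loading entries above the sparsity
threshold and declaring convergence when that count changes by at most
`convergence_fraction * K * p` (default $Kp/100$) over
`convergence_window` (default 100) iterations.

The one place where this implementation departs from the one-layer-at-a-time
MAP updates is the **local E-step**. At the horseshoe defaults the MAP of
the local rate is degenerate ($a+b-1 = 0$), and any fixed-point through the
$\theta\leftrightarrow\delta$ pair — MAP with a positivity floor, or the
conditional posterior mean — locks the effective local prior precision at
$\approx 2/\Lambda_{jk}^2$ regardless of scale. That penalty is strong
enough to delete roughly a third of genuinely nonzero $N(0,2)$ loading
entries even when the optimizer is started at the ground truth, and it
either freezes ($\phi_k \to 10^{10}$) or collapses ($\phi_k \to 0$,
killing every sparse component at $p \gg m$) the component-level hierarchy,
depending on the variant. `fit_vem()` therefore marginalizes the two local
gamma layers jointly: it uses
$E[1/\theta_{jk} \mid \Lambda_{jk}, \phi_k]$ as the prior precision in the
ridge systems and $\log m(\Lambda_{jk}\mid\phi_k)$, the exact marginal
under the $\mathrm{Beta}'(a,b)$ mixing law, in the indicator updates and
the one-dimensional $\phi_k$ maximization. Both are scale-free functions of
$x = \Lambda^2/(2\phi)$, tabulated once per $(a,b)$ pair by quadrature on a
wide logarithmic grid and spline-interpolated (relative error
$\sim 4\times10^{-5}$; checked against the exponential-integral closed form
available at $a=b=1/2$). This restores the slab behavior of the horseshoe:
supported entries feel a weak $\approx 2/\Lambda^2$ pull (further damped by
a logarithmic factor), while shrinking entries face divergent precision and
reach exactly zero. The printed closed-form updates (`update_theta()`,
`update_delta()`, `update_phi_k()`, ...) remain exported and are verified
against independent numeric maximization of the expected complete log
likelihood; they are what `fit_vem()` would use in a conditional-MAP
variant, and they remain the building blocks of the Gibbs conditionals.

**Numerical choices.** Positive rate/scale parameters are floored at
$10^{-10}$. The local variances use a much smaller floor ($10^{-30}$):
flooring them at $10^{-10}$ caps the prior precision at $10^{10}$, which
leaves dying loadings hovering near $10^{-9}$ — just above the $10^{-10}$
threshold below which elements of sparse-classified components are set to
zero — so supports would never register as sparse. In the Gibbs sweep, GIG
inputs are floored at $10^{-300}$ and variance draws at $10^{-12}$ purely
to keep the chain inside double range. Linear systems use Cholesky solves
with an escalating ridge for transiently rank-deficient systems (duplicated
components inherited from the warm start). Components whose loading column
and factor row are both entirely below threshold are pruned as the fit
proceeds.

## Simulations and what they show

`simulate_biclusters()` generates the two validation designs: sparse
components have supports of `m_min..m_max` positions per side (drawn
independently for the loading and the factor), uniformly placed under a
pairwise-overlap cap enforced by rejection resampling, with nonzero entries
$N(0,2)$ (variance 2); dense components are fully $N(0,2)$; factors are
shuffled across components so sparse loadings may pair with dense factors;
residuals are $N(0,\nu^{-1})$ with $\nu^{-1} = 1$ (low noise) or 2 (high
noise). `sim_preset()` bundles the canonical settings (p = 500, n = 300,
ten sparse components, optionally five dense ones).

The test suite exercises a scaled-down design (p = 100, n = 60, five
sparse components with supports of 5–10, initial K = 30) so that a full
warm start plus fit takes seconds. One property of this design deserves
emphasis: with entry variance 2 and unit noise, the per-cell
signal-to-noise ratio is low enough that a substantial fraction of true
support entries is statistically indistinguishable from noise. An oracle
that is *given* the true factor matrix and chooses the best support
threshold per dataset reaches mean cell-set recovery = relevance
$\approx 0.56$ at these dimensions; no support-exact method can do better,
and the fitted model's Jaccard scores (reported by the acceptance script)
sit below that ceiling. The simulations therefore demonstrate that the
machinery finds the detectable components, classifies sparse against dense
sides, and prunes an overcomplete K — not that bicluster supports are
recoverable exactly at arbitrary noise levels. Real expression data differ
from this generator in having correlated noise, non-Gaussian margins (the
preprocessing maps each gene to standard-normal quantiles, which the
generator skips), and far larger p; passing these tests shows the
estimation machinery behaves as designed, not that real co-expression
networks will be recovered at any particular accuracy.

Small-support components with low realized signal energy
($\sum_j\Lambda_{jk}^2 \sum_i x_{ki}^2$ comparable to the noise floor) are
missed by any method; the surviving-component count correspondingly runs a
few above the planted number because self-sustaining noise micro-components
(one or two cells with $|y| > 2.8\sigma$) are stable fixed points of any
MAP-flavored sparse factorization. The same phenomenon is visible in the
component-count distributions of large real-data analyses with this model
family.

## Networks from fitted components

For a selected subset $A$ of components, the implied gene covariance on the
support (genes with a nonzero loading in some component of $A$) is
$\Omega_A = \Lambda_A \Sigma_{A,A} \Lambda_A^\top + \Psi$, with
$\Sigma = \langle XX^\top\rangle - \langle X\rangle\langle X\rangle^\top$
accumulated from the per-sample posterior covariances during the fit. The
precision matrix $\Delta = \Omega_A^{-1}$ maps to partial correlations
$-\delta_{jj'}/\sqrt{\delta_{jj}\delta_{j'j'}}$. Only the support is ever
inverted, so genes that never share a component cannot gain an edge.

Component selection (`select_components()`) implements three modes:
*ubiquitous* (factor row nonzero for every sample), *context-specific*
(nonzero factor values only at samples with a given label), and
*differential* (two-sided rank-sum test between the two label groups'
factor values). The differential threshold defaults to the Bonferroni rule
$0.05/K$; a fixed $10^{-10}$ is available. The rank test is the two-sample
Mann–Whitney form: the contexts have unequal sizes in every realistic
design, so a paired (signed-rank) test is not applicable, and the quantity
being tested is a difference in mean rank.

Edge calls (`test_edges()`) fit a two-component mixture to the off-diagonal
partial correlations: a Gaussian empirical null on Fisher-transformed
values, whose scale plays the role of an effective-degrees-of-freedom
parameter, against a flat alternative on $(-1,1)$, with the null weight
$\eta_0$ and scale fitted by EM; edges with posterior alternative
probability above 0.8 are kept. With fewer than 20 gene pairs the mixture
is unidentifiable and an absolute rule $|r| \ge 0.8$ is used instead.
Networks from independent restarts are combined by counting each canonical
edge and keeping those replicated in at least $r$ runs
(`aggregate_networks()`); `expected_replicated_edges()` calibrates $r$
against the null expectation
$E \cdot \Pr\{\mathrm{Bin}(R, \hat e/E) \ge r\}$. The complement sum is
computed from $j = 0$; the variant omitting the $j=0$ term (which can go
negative) is available for comparison with the approximate printed form.
Runs are dropped when any component pair has
$\mathrm{cor}(\Lambda_{k_1},\Lambda_{k_2}) \cdot
 \mathrm{cor}(X_{k_1},X_{k_2}) > 0.5$ (signed product, as specified), or
when the fit did not converge.

## Scoring

`recovery_relevance()` computes the Jaccard-based recovery (recall-like)
and relevance (precision-like) scores on bicluster *cell* sets (gene set
times sample set), with the best match taken per true (resp. estimated)
bicluster. `sparse_stability_index()` is a column-matching similarity,
invariant to permutation, sign, and scale: columns are greedily matched on
squared Pearson correlation with deterministic index-order tie-breaking,
and the score is the matched $r^2$ total divided by
$\max(K_\mathrm{true}, K_\mathrm{est})$, so missing and superfluous
components are penalized symmetrically. The exact formula of the
originally-cited index is not reproduced here; this construction pins the
documented properties (1 at perfect recovery up to permutation/sign/scale,
small for unrelated matrices, monotone in the number of corrupted
columns).

## Known limitations

* Inputs must be complete; imputation is out of scope
  (`filter_missing_genes()` + an external imputer first, then
  `quantile_normalize_to_normal()`).
* The likelihood is Gaussian; counts should be transformed upstream.
* No ELBO is computed; convergence is the support-change rule, and a
  non-converged fit is returned with `converged = FALSE` (network
  construction excludes such runs by default).
* One Gibbs chain per restart seed; no cross-chain diagnostics beyond the
  test suite.
* Serialization is plain TSV + JSON per fit directory; no HDF5 container.
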