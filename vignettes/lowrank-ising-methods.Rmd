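---
title: "Full-data-information estimation of low-rank Ising networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-data-information estimation of low-rank Ising networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(isinglr)
```

## The model and why low rank

The Ising model assigns a binary state vector $\sigma \in \{-1,+1\}^n$ the
probability

$$p(\sigma) = \frac{1}{Z}\exp\!\Big(\mathbf b^\top\sigma +
\tfrac12\,\sigma^\top \mathbf A\,\sigma\Big),$$

with main effects $\mathbf b$ and a symmetric connectivity matrix
$\mathbf A$.  Because $\sigma_i^2 = 1$, the diagonal of $\mathbf A$ only
adds a constant: it is not identifiable, and every probability is
invariant under $\mathbf A \mapsto \mathbf A + c\mathbf I$.  The package
fixes the quadratic form with the factor $\tfrac12$ so that $A_{ij}$
appears exactly once per unordered pair; all derived formulas (the
factor-2 log-odds of the full conditionals, the loading construction
$E = Q_r\Lambda_r^{1/2}$) are stated consistently with this convention,
and the test suite verifies their mutual consistency by enumeration to
$10^{-10}$ or better.

Networks from test and questionnaire data are dense — nearly every
variable correlates positively with every other — and their eigenvalue
spectra show a few dominant components followed by a slowly decaying
remainder.  By the Eckart–Young theorem, truncating the
eigendecomposition of the (diagonally shifted) connectivity matrix at
rank $r$ gives the least-squares-optimal rank-$r$ approximation, and the
retained eigenvectors are the leading eigenvectors of the full matrix.
`shift_diagonal()` uses the *minimal* shift $-\lambda_{\min}$ (the
smallest eigenvalue moves exactly to zero): non-negativity is all that is
required for the factorisation, and the minimal shift keeps the spectrum
best conditioned.  Eigenvector signs are fixed by making the
largest-magnitude entry of each column positive; for (near-)tied
eigenvalues any orthonormal basis of the eigenspace is acceptable and
tests compare projectors rather than individual vectors.

## The latent representation

Writing the shifted matrix as $\mathbf E\mathbf E^\top$ and applying the
Gaussian identity
$\exp(\tfrac12\|\mathbf E^\top\sigma\|^2) =
E_{\theta}[\exp(\sigma^\top\mathbf E\theta)]$ with
$\theta \sim N(0, \mathbf I_r)$ linearises the quadratic form.  The
conditional distribution of the state given the latent vector factorises
over nodes,

$$p(\sigma\mid\theta) = \prod_{i=1}^n
\frac{\exp\big(\sigma_i(\mathbf e_i\cdot\theta + b_i)\big)}
     {2\cosh(\mathbf e_i\cdot\theta + b_i)},$$

a multidimensional two-parameter logistic item-response model (with equal
loadings in one dimension, the Rasch model), while the latent density

$$f(\theta) \propto \exp(-\tfrac12\|\theta\|^2)
\prod_i 2\cosh(\mathbf e_i\cdot\theta + b_i)$$

absorbs the partition function into its normalising constant.  The
package's `marginal_prob_quadrature()` verifies the representation
end-to-end: integrating $p(\sigma\mid\theta)$ over $f(\theta)$ on a
64-node-per-dimension Gauss–Hermite grid reproduces the enumerated Ising
probabilities to $10^{-6}$ over all states for $n \le 8$, $r \le 2$.  The
quadrature is deliberately an oracle only: it exists to certify the
algebra at desk scale, while the sampler handles general $r$.

Two exact-computation guards keep the oracle honest: enumeration is
refused beyond $n = 20$ (about $10^6$ states), and the log partition
function is accumulated in log space with max-subtraction so strong
couplings cannot overflow.

## Full-data-information sampling

The joint posterior of $(\mathbf E, \mathbf b, \theta_{1:N})$ has one
tractable full conditional — $\theta_p \mid \sigma_p \sim
N(\mathbf E^\top\sigma_p, \mathbf I_r)$, the main effects cancel — and
one intractable one, because the latent marginal $f(\theta\mid W)$
carries the partition function.  The package therefore samples the
parameters from their *partial* conditionals, which keep the
likelihood-times-prior factors and drop the latent marginal: for a scalar
parameter $w$,

$$\pi(w) \propto f(w)\prod_p F_p(w)^{y_p}\big(1-F_p(w)\big)^{1-y_p},
\qquad y_p = (\sigma_p + 1)/2,$$

with increasing logistic distribution functions $F_p$.  For $w = b_i$ the
curve for replication $p$ has location $-\theta_p\cdot\mathbf e_i$ and
scale $\tfrac12$; for $w = e_{ir}$, location
$-(b_i + \mathrm{rest}_p)/\theta_{pr}$ and scale $1/(2|\theta_{pr}|)$,
with the response flipped when $\theta_{pr} < 0$ so that every curve is
increasing (the product is unchanged; replications with
$\theta_{pr} = 0$ contribute a constant and are dropped).  This scheme
ignores only the information in the latent prior; it never computes $Z$,
which is what lets it scale to arbitrary $n$.

Each scalar update is an independence Metropolis–Hastings step with an
order-statistic proposal: draw $z_0$ from the prior and $z_p \sim F_p$
for each replication, and propose the element whose rank among the
$N + 1$ draws is the total score $y_+ + 1$ — equivalently the unique
column of the indicator matrix $x_{pj} = (z_p < z_j)$ whose total is
$y_+$.  Conditional on its realised indicator pattern the proposal
density is the target with the prior and one observation's curve
interchanged, so the two agree ever more closely as $N$ grows.  The
acceptance ratio is evaluated with the realised pattern,

$$\min\Big\{1,\;
\frac{\tilde\pi(w^\ast)\,\tilde q(w)}{\tilde\pi(w)\,\tilde q(w^\ast)}\Big\},
\qquad
\tilde q(w) = f_{(j)}(w)\prod_{p\ne j} F_p(w)^{x_{pj}}(1-F_p(w))^{1-x_{pj}},$$

a design choice made here (the construction defines the proposal density
but no published acceptance formula): its correctness is certified
empirically rather than assumed, by Kolmogorov–Smirnov comparison of
fixed-$\theta$ chains against grid-normalised partial conditionals
(distance below 0.05 at $10^4$ draws for both main-effect and loading
updates, and for the one-parameter Curie–Weiss chain).

**Priors.**  The model only requires a proper prior.  The default is
independent logistic$(0, 1)$ on every $b_i$ and $e_{ir}$: the logistic
family keeps the prior draw in the same family as the observation curves,
so the prior is exactly the "switched-places" element of the proposal.  A
normal family is available through `ising_prior(family = "normal")`.

**Sweep and seeding.**  One iteration redraws the full latent matrix,
then applies one Metropolis step to each of the $n$ main effects and each
of the $nr$ loadings (sweep order: $\mathbf b$, then $\mathbf E$
row-major), with a fresh draw vector per parameter.  A single master seed
(`withr::with_seed`) makes entire runs bit-reproducible under identical
configurations.

**Warm start.**  The proposal tracks its target only once the latent
spread and the loadings are mutually consistent: from a cold start
(loadings near zero while the data are strongly structured) both
distributions are narrow but mis-centred, and acceptance collapses before
the chain can find the right scale.  `warm_start()` therefore runs a
short damped stochastic-EM pass — exact latent draws alternating with
per-node logistic-regression fits, column norms damped to the geometric
mean of successive passes because the raw map overshoots
multiplicatively — and `fit_lowrank_ising()` starts there by default.
The warm start only chooses the starting point; the chains themselves are
unchanged.

**Identifiability.**  $\mathbf E$ is identified only up to rotation and
sign.  Raw chains are stored unrotated; all reported summaries go through
the rotation-invariant reconstruction $\mathbf E\mathbf E^\top$
(`connectivity_draws()`, `summary()`), and recovery tests compare
connectivity matrices, never raw loadings.

## The Curie–Weiss special case

The fully connected network with equal couplings is the one-parameter
laboratory for the method.  The package adopts the mean-field convention
$A_{ij} = a/n$: the latent representation is then rank one with common
loading $\sqrt{a/n}$, the log-density curvature at the origin is $a - 1$
for *every* $n$, and the unimodal-to-bimodal transition sits at $a = 1$
independent of network size.  (Under the unscaled reading, interaction
$a$ per pair, the transition would move to $a = 1/(n-1)$ and depend on
$n$; the scaled convention is the one consistent with a size-free
critical point.)  `fit_curie_weiss()` runs the chain on the unconstrained
common loading $e$ — every node–replication pair contributes one
observation curve — and reports $a = ne^2$, which is invariant to the
sign of $e$.  Mode counting (`count_modes()`) merges plateaus whose
log-density values differ by less than $10^{-12}$ and never counts
boundary grid points; grids must span at least 8 standard-normal standard
deviations with at least 2001 points.

## Posterior predictive checks

`ppc_check()` selects equally spaced post-burn-in draws, replicates one
dataset from each, and compares the observed sufficient statistic
$\mathbf S = \sum_p \sigma_p\sigma_p^\top$ with the average replicated
$\mathbf S^{\mathrm{rep}}$ through the residual matrix and the
correlation of strictly-lower-triangle entries (the diagonal is the
constant $N$ and is excluded).  At each selected draw the latent matrix
is redrawn from its exact full conditional by default, propagating latent
uncertainty; stored latent draws can be reused instead
(`redraw_theta = FALSE` with `store_theta = TRUE`), since either reading
of "replicate given posterior draws" is defensible.

## Synthetic data: what it emulates and what it does not

`make_lattice()` builds the physics flavour: nearest-neighbour couplings
on a square grid, optionally toroidal, whose spectrum is near-linear —
no low-rank structure to find.  `make_dense_lowrank()` builds the social
science flavour: an all-positive general factor plus zero-sum block
contrasts (sets of nodes interacting positively among themselves and
negatively across sets).  Components are parameterised by their
*eigenvalues* rather than by per-entry coupling bands, so individual
couplings scale as $1/n$ (the same mean-field convention as the
Curie–Weiss model) and the latent geometry of a fixture does not change
with network size.  The defaults — general-factor eigenvalue 1.8,
contrast eigenvalue 0.9 with geometric decay 0.8, main effects uniform in
$\pm 0.05$ — place the general factor moderately above the critical
point, so replications are realistically polarised yet node-level
discordance remains frequent enough that the loadings are identifiable;
the contrasts sit well clear of the residual scree (ratio above 5).

Two things the generator deliberately does not emulate: item-level
artefacts of real test data (guessing, local dependence, missingness),
and very strong magnetisation.  In the latter regime almost every
replication agrees with the majority pattern, the per-node logistic
partial conditionals approach quasi-separation, and loading posteriors
become heavy-tailed upward — chains then drift toward the prior scale.
Passing tests on these fixtures therefore certify the estimator in the
identifiable regime, not under near-separation, and say nothing about
robustness to non-Ising features of real data.

`generate_augmented()` samples exactly through the latent representation
(alternating the two tractable conditionals) and is validated against
full enumeration at small $n$; the default runs one independent chain per
replication, which guarantees exchangeable replications at the cost of a
burn-in per row (a thinned single-chain mode exists).  The exact
enumeration sampler `sample_exact()` remains the oracle below $n = 20$.

## Study sizes and numerical choices

The package's own studies (test suite and acceptance checks) use: exact
oracles at $n \le 8$; quadrature checks over 30 random models; chain
oracles at $10^4$ draws; Curie–Weiss contraction and coverage at
$n = 10$ with $N \in \{100, 500, 1000\}$; rank-2 recovery at $n = 20$,
$N = 2000$, 800 iterations; and rank-1-to-3 predictive checks at
$n = 30$, $N = 2000$, 400 iterations with matched seeds across ranks so
that rank comparisons share their Monte Carlo noise.  These sizes were
chosen as the smallest at which the asymptotic behaviour of the method is
clearly visible.

## Known limitations

* The mixed scheme is not a proper Gibbs sampler for the full posterior:
  the latent-prior information is ignored by construction, so the
  sampled law is the partial posterior.  The package treats that as the
  estimand and verifies finite-sample recovery and coverage empirically.
* Rank selection is a user input; no scree-elbow automation is provided.
* No adaptive tuning, tempering, or convergence diagnostics beyond
  per-parameter acceptance rates and raw chain export.
* Strongly magnetised (near-separated) data leave loadings only weakly
  identified, as described above.
* Missing entries and multi-category (Potts) states are out of scope.
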