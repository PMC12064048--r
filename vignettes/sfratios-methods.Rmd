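---
title: "Estimating the DFE from site frequency ratios: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the DFE from site frequency ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Distribution-of-fitness-effects (DFE) inference from a site frequency
spectrum (SFS) is confounded by everything else that shapes allele
frequencies: demographic history, linked selection, mutation-rate and
gene-conversion heterogeneity, cryptic population structure. The classic
Poisson random field (PRF) treatment assumes a constant-size Wright-Fisher
population; joint selection-plus-demography models help but can only absorb
the factors they parameterize.

This package implements a ratio-based alternative. Suppose a candidate
selected class of biallelic SNPs (say, nonsynonymous sites) and a matched
neutral class (short-intron sites) are sampled from the same `n` genomes.
If the non-selective distortion of frequency bin `i` can be summarized by
a shared factor `a_i`, the expected counts are

- neutral: `a_i * N_i * theta / 2`, with `N_i = 1/i`,
- selected: `a_i * Fg_i * thetaS / 2`,

where `Fg_i` integrates the fixed-`gamma` Wright-Fisher expectation
`F(gamma)_i` over the DFE `g(gamma; phi)` and `gamma = 2Ns` is scaled by
the effective population size. In the per-bin ratio the `a_i` cancel:

```
E[selected_i] / E[neutral_i] = rho * Fg_i / N_i,   rho = thetaS / theta,
```

so the expected ratio profile depends only on the DFE parameters `phi` and
the mutation-rate ratio `rho` — not on demography, and not on the absolute
mutation rates. The package fits `(rho, phi)` by maximum likelihood on the
observed ratios `z_i`, tests for selection, compares DFE families by AIC,
and reports `lambda = rho * Y / X`, the relative probability that a
selected mutation goes unsampled.

## The ratio likelihood

Per-bin counts are Poisson under the PRF; their ratio is a discrete
variable with an awkward law, so both counts are approximated by gaussians
with expectation equal to variance (good for counts of about 10 or more).
The density of the ratio of two independent gaussians (Hinkley 1969;
Díaz-Francés & Rubio 2013), specialized to mean = variance, gives

```
z_i ~ ratio_density(beta_i, delta_i),
beta_i = rho * Fg_i / N_i,  delta_i = M_i^(-1/2),
```

where `M_i` is the mean of the denominator gaussian. For folded spectra
`beta_i = rho (Fg_i + Fg_{n-i}) / (N_i + N_{n-i})`, with the central bin
`i = n/2` unpaired.

Two conventions needed pinning down:

- **The density's internal convention.** `ratio_density(z, beta, delta)`
  is the ratio law of `N(beta*M, beta*M) / N(M, M)` with `M = 1/delta^2`.
  A million-draw Monte-Carlo ratio-of-gaussians check in the test suite
  holds this to Kolmogorov distance < 0.01.
- **The data-facing noise scale.** For a candidate neutral mutation
  parameter `theta`, the neutral count expectation is `N_i * theta / 2`,
  so the package sets `M_i = N_i * theta / 2`. The alternative reading
  (`M_i = N_i * theta`) understates the ratio variance by a factor of two
  and makes the neutrality likelihood-ratio test anticonservative
  (empirical rejection ~0.14 instead of ~0.05 at the 0.05 chi-square
  cutoff in a 200-replicate null calibration); the adopted convention
  calibrates within binomial error.

`theta` is a nuisance. It is integrated out numerically against a uniform
density on `log theta` spanning two orders of magnitude around Watterson's
estimate, `[theta_hat/10, 10*theta_hat]` with `theta_hat = S / a_n` from
the neutral spectrum. Note that under the count convention above
`E[theta_hat] = theta / 2`; the two-decade window comfortably covers the
generating value. The integration uses a composite Simpson rule with 25
log-spaced nodes: a 24-node trapezoid rule was tried first but converges
only to ~3e-3 relative here, while Simpson meets the 1e-4 self-convergence
target (doubling nodes moves the integrated density by < 1e-4).

The log-likelihood sums `log p'(z_i)` over bins with a nonzero neutral
count; zero-denominator bins are masked, not imputed, because the ratio is
undefined there and the gaussian approximation has already failed at count
zero. `make_ratios()` warns about bins with counts below 10.

## Wright-Fisher expectations

`F(gamma)_i` is the integral over population frequency `x` of the sojourn
density times the binomial sampling kernel. The mutation-rate factor is
kept *out* of the sojourn term, so `F(0)_i = 1/i` exactly and the neutral
ratio expectation reduces to `rho`; expected counts are `F_i * thetaS / 2`.
(Keeping the rate factor inside the sojourn density *and* multiplying by
`thetaS/2` would double-count it.)

Numerics:

- The sojourn factor is evaluated through `expm1` with a log-space
  rewriting for `gamma < 0`, stable for `|gamma|` up to `1e5`; the
  `gamma = 0` limit is exact.
- The frequency integral uses composite 24-point Gauss-Legendre panels.
  For strongly deleterious `gamma` the integrand concentrates in a
  boundary layer of width `~1/(2|gamma|)` at `x = 0`, resolved by
  geometrically refined panels; accuracy was checked against dense
  (10^6-point) trapezoid sums and a 50-digit arbitrary-precision
  evaluation of a reference case.
- DFE integration over `gamma` uses a cached grid (`build_grid()`):
  log-spaced nodes in `|gamma|` from `1e-3` out to `-1e5` and `+1`, plus a
  node at 0, trapezoid weights per side. 1501 nodes by default, at which
  the grid-based expectations agree with direct adaptive quadrature to
  ~1e-4 relative for the supported families. The inner window
  `|gamma| < 1e-3` is handled analytically (its CDF mass times `N_i`):
  DFE densities may carry an integrable singularity at their support
  maximum (the gamma family with shape < 1), which a trapezoid across
  zero cannot resolve. The grid is built once per `(n, folded)` layout;
  each optimizer iteration only re-evaluates the DFE density at the nodes
  and takes a weighted matrix-vector product.

## DFE families

All continuous families are "inverted", extending to `-Inf` with an upper
support limit `m` (default 1, so weakly advantageous mutations are
allowed; 0 for the gamma family, matching how externally reported gamma
DFEs are parameterized):

- lognormal: `log(m - gamma) ~ Normal(mu, sigma)`;
- gamma: `m - gamma ~ Gamma(shape, scale)`, constructed from either
  `(mean, shape)` with `scale = (m - mean)/shape`, or `(shape, scale)`
  directly;
- normal: plain gaussian on `gamma`;
- fixed: a single point value (used by the neutrality test).

Any family can carry a point mass at `gamma = 0` (strictly neutral
mutations). The constructor accepts weights up to 1 so that degenerate
pure-point-mass models can be built for identity checks; *fitting* bounds
the point mass at 0.5 of the total density via an affine-logit transform,
reflecting the convention that at most half the density may sit in the
neutral atom.

`dfe_mean()` reports the truncated expectation: the integral of
`gamma * pdf` over `(-1e5, 1e-4)` **without renormalization**, plus point
masses as weight times location. This unnormalized-truncation convention
is what reproduces published summaries of heavy-tailed DFEs (for a
lognormal with `mu = 12.64, sigma = 4.9` the untruncated mean is ~5e10
times larger; the closed-form truncated moment
`exp(mu + sigma^2/2) * Phi((log U - mu - sigma^2)/sigma)` is used as an
independent oracle in the tests).

## Fitting, testing, intervals

Parameters are optimized on unconstrained scales (`log rho`, `log sigma`,
`log shape`, `log(m - mean)`, affine-logit point mass) by Nelder-Mead from
five seeded starts by default; the first start uses the neutral-limit
estimator `rho_0 = X/Y` and family-default shape values, the rest draw
from wide seeded ranges. Each start's simplex is restarted once at its
optimum. Point-mass fits are staged: the point-mass weight is first held
at its starting value while the other parameters are optimized, then all
are freed — the logit boundary at `p_plus = 0` is sticky (the gradient in
the transformed coordinate vanishes there) and a joint simplex can slide
into that basin even when a genuine point mass fits far better. A fit is
flagged converged when the optimizer converged and the
optimum is corroborated — by a second start within 0.01 logL, or, when
wide starts stall on likelihood plateaus (common for strongly deleterious
starting values, where the expected ratios are essentially flat in the
parameters), by a jittered restart returning to the same optimum.

The neutrality test compares the null (`gamma = 0` fixed, `rho` free, one
parameter) with the alternative (single free `gamma`, free `rho`, two
parameters) by twice the log-likelihood ratio against chi-square with 1
df, clipped at zero. Confidence intervals are profile-likelihood at the
chi-square cutoff (1.92 logL units for 95%), endpoints by stepping on the
transformed scale and root finding; an interval that never crosses the
cutoff within the search range is flagged one-sided. Profile likelihood
was chosen because the reference analyses report 95% intervals without
naming a method; it is invariant to the parameter transforms already in
use and needs no second derivatives.

## The simulator and what passing tests mean

`simulate_pair()` draws independent Poisson counts around the model
expectations, with optional shared per-bin distortion factors `a_i`
("expansion-like" enriching singletons, "bottleneck-like" depleting
intermediate frequencies, "smooth" correlated log-gaussian profiles in
[0.2, 5]). This emulates exactly the regime the ratio method assumes:
non-selective effects that multiply both spectra alike. It does **not**
emulate linked selection along chromosomes, real demographic trajectories,
or correlated bins — so the distortion-invariance and calibration results
here validate the method's internal consistency, not its robustness to
violations of the shared-factor assumption (which requires forward
simulation with linkage and is out of scope).

Study conditions used by the acceptance harness, chosen once to match the
method's characterization conditions: null calibration with 500 neutral
pairs at `n = 100`, `theta = thetaS = 500`, folded; rho recovery with 20
pairs at `n = 200`, `theta = 1000`, `rho = 0.35`, weak-selection lognormal
DFE (`mu = 1, sigma = 1`, max 1), folded; coverage with 100 replicates of
a fixed-gamma model at `n = 60`. Folded spectra are the default
throughout (ancestral states are rarely trustworthy, and folding keeps
every neutral bin's expected count at or above 10 in the calibration
conditions, where the gaussian approximation is valid; unfolded bins near
`i = n - 1` would hold only 2-3 sites).

## Neutral-control construction

For VCF input the package reproduces the mutational-context matching
workflow: biallelic SNPs genotyped in at least half the chromosomes are
annotated with the 96 contexts (two flanking reference bases plus the
unordered ref/alt pair — order-insensitive because folded spectra make it
meaningless; reverse complements are *not* merged), and each selected SNP
is greedily paired with the nearest unused short-intron SNP of identical
context on the same chromosome, processing selected sites in genomic
order and breaking distance ties toward the lower coordinate (both
tie-break rules are this package's choices; the procedure is otherwise
underdetermined). Pairs are projected to a uniform sample size by
expected hypergeometric down-sampling and folded. When one member of a
pair fails the sample-size threshold the whole pair is dropped, keeping
the selected and neutral site numbers equal so that `X/Y = 1` and
`lambda_hat = rho_hat` up to projection loss. Short-intron interval
definitions are supplied by the user (annotation tooling is out of
scope).

## Known limitations

- The gaussian approximation degrades below ~10 counts per bin; the
  package warns but does not reweight or merge sparse bins.
- Bins are treated as independent; no covariance correction for linked
  sites.
- The alternative `M_i = N_i * theta` noise convention and the exact
  discrete Poisson-ratio law are not implemented.
- Strong-selection DFEs (mean `2Ns` beyond ~ -1000) are fit but, as with
  any SFS-ratio method, much of their mass lies where expected counts are
  vanishingly small; estimates there lean on the few low-frequency bins.
- Dominance, time-varying selection, and demography-aware expectations
  are deliberately absent — avoiding them is the method's point.
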