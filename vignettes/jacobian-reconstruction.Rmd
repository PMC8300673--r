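---
title: "Reconstructing Jacobians from stationary fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Jacobians from stationary fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jacrecon)
```

## The model behind the method

Consider a dynamical system $\dot{x} = f(x, p)$ resting at a stable
steady state $x^*$ and jostled by weak noise. Linearised about $x^*$,
the fluctuations $X = x - x^*$ form a multivariate Ornstein-Uhlenbeck
process $\dot X = J X + \xi$, where $J$ is the Jacobian
$J_{ij} = \partial \dot x_i / \partial x_j |_{x^*}$ and $\xi$ is white
noise. A classical result for such processes ties together the drift,
the stationary covariance $\Gamma_{ij} = \langle X_i X_j \rangle$, and
the fluctuation matrix $D$ of the noise:

$$ J\,\Gamma + \Gamma\,J^{\mathsf T} = -2\,D . $$

For additive noise of amplitude $\sigma_i$ per variable,
$D = \operatorname{diag}(\sigma_i^2/2)$ under this normalisation
(`fluctuation_from_noise()`); for multiplicative noise the amplitudes
are evaluated at the steady state.

Both sides of the relation are symmetric, so it supplies only
$N(N+1)/2$ constraints on the $N^2$ unknown entries of $J$: covariance
data alone cannot identify the Jacobian for $N > 1$. The missing
information comes from *structure*. In networked systems many pairs of
variables cannot interact directly — non-adjacent patches, or
different species in different patches — and each such pair forces a
Jacobian entry to be exactly zero. With at least $N(N-1)/2$ known
zeros the system becomes determined.

Vectorising the relation (column stacking, `vec()`) with Kronecker
products and the commutation matrix $C$ (`commutation_matrix()`,
$C\,\mathrm{vec}(X) = \mathrm{vec}(X^{\mathsf T})$) gives a single
linear system

$$ \underbrace{\big(\Gamma \otimes I + (I \otimes \Gamma)\,C\big)}_{B}
   \,\mathrm{vec}(J) = -2\,\mathrm{vec}(D), $$

built by `build_design()`. Each structural zero appends one unit row
(`stack_constraints()`), and the stacked system is solved in closed
form by least squares (`solve_reconstruction()`). Because the data
block is consistent at the exact $(\Gamma, D)$ pair, the least-squares
solution recovers $J$ exactly when the zero pattern is sufficient;
with sampled covariances it is the maximum-agreement compromise
between data and structure. The leading eigenvalue of the
reconstructed Jacobian — the quantity whose real part crossing zero
announces a bifurcation — is the early warning signal the package
tracks.

### Numerical choices

* **Right-hand side.** The stacked system carries the factor $-2$ on
  the data block explicitly, so that the unconstrained block is
  exactly the vectorised Lyapunov relation. The closed-form
  pseudo-inverse solution is algebraically insensitive to where the
  factor is written, but the implementation fixes one convention and
  the forward/backward round-trip tests pin it down.
* **Constraint rows** enter with weight 1 by default (the plainly
  stacked system); a scalar `weight` is exposed but untouched
  elsewhere in the package.
* **Zero enforcement.** Least squares on noisy covariances leaves the
  constrained entries small but nonzero; `enforce_zeros = TRUE`
  (default) sets them to exactly zero after the solve, which improves
  the accuracy of the reconstructed eigenvalues.
* **Solver.** Systems up to $N = 40$ go through a rank-revealing dense
  QR (LAPACK, column pivoting), with an SVD minimum-norm fallback for
  rank-deficient stacks. Larger systems use an algebraically
  equivalent normal-equations path,
  $B^{\mathsf T}B = 2(\Gamma^2 \otimes I) + (\Gamma \otimes \Gamma)C +
  C(\Gamma \otimes \Gamma)$, solved by Cholesky without ever
  materialising the $(N^2 + |U|) \times N^2$ stack; a dense QR of the
  60-dimensional stacked system would cost two orders of magnitude
  more time and memory for identical results (the two paths agree to
  $10^{-10}$ in the unit tests, and the 60-dimensional round trip is
  exact to below $10^{-8}$).
* **Asymmetric input.** Sample covariances are symmetric by
  construction, so mild asymmetry (relative magnitude above $10^{-8}$)
  draws a warning and is symmetrised; asymmetry above $10^{-3}$ is
  treated as a user error and fails.
* **Indexing.** All indices — in the R API and in every file format —
  are 1-based, matching the host language. Serialized pattern files
  record this explicitly.
* **Eigenvalue ordering.** Spectra are sorted by descending real
  part, ties by ascending $|\mathrm{Im}|$, conjugates with nonnegative
  imaginary part first, making the "leading eigenvalue" deterministic.
  The leading eigenvalue is tagged `real` (fold-type candidate) or
  `complex-pair` (Hopf-type candidate); finer bifurcation
  classification would need normal-form coefficients and is out of
  scope.

## Structural zeros from topology

`network_zero_pattern()` lists every ordered pair of distinct
non-adjacent nodes. For multilayer metacommunities — $S$ species
replicated over $P$ patches, $N = SP$ —
`multilayer_zero_pattern()` combines three categories:

1. *cross-layer*: a species cannot affect a different species in a
   different patch; always $SP(S-1)(P-1)$ ordered pairs, whatever the
   topology;
2. *spatial*: the same species in non-adjacent patches (dispersal
   moves along edges only);
3. *trophic* (off by default): within-patch species pairs with no
   feeding link. This category is optional because shared predators
   couple unlinked species indirectly (prey switching), so an absent
   link does not guarantee a zero Jacobian entry.

Sufficiency is decided by explicit counting
(`sufficiency_check()`), never by closed-form inequalities in the mean
degree or in $(S, P)$: direct enumeration is cheap and unambiguous on
every topology, while degree-based shortcuts are easy to misapply on
small or irregular graphs.

The count is necessary but the *placement* decides identifiability: a
fully coupled block of variables with no constrained entry inside it
(and none tying it to the rest) keeps its mutual couplings
undetermined no matter how many zeros sit elsewhere — the system then
splits into independent subsystems, and no method could recover the
block from covariance data. `sufficiency_check(structural = TRUE)`
certifies a determined reconstruction by a rank test on the
antisymmetric null-space directions of the Lyapunov design, either at
a generic covariance or at the user's actual $\Gamma$; the stable
sparse Jacobian fixture additionally rejects draws whose interaction
graph is disconnected, since it is meant to emulate one coupled
network.

## The validation test-bed

The ground-truth system is a Rosenzweig-MacArthur predator-prey
metacommunity: logistic prey growth, Holling type-II predation,
linear plus quadratic predator mortality, and diffusive dispersal on a
patch network (`rm_metacommunity_model()`). Default parameters
($r = 1$, $a = 2$, $h = 1$, $\epsilon = 0.5$, $m = 0.2$, $g = 0.05$,
$\delta_b = \delta_c = 0.05$; `inst/extdata/rm_defaults.json`) were
chosen by a numeric scan so that the coexistence state crosses a Hopf
bifurcation inside the scanned range of the carrying capacity
($K_c \approx 1.47$); the same state can also be pushed across the
instability by lowering the predator mortality $m$ or the quadratic
mortality $g$. Equal prey and predator dispersal shifts every
inhomogeneous Laplacian mode by the same amount, so the homogeneous
Hopf mode destabilises first and pattern-forming (Turing/wave)
instabilities stay out of the way of the transect experiments; the
master-stability decomposition (`msf_spectrum()`) is tested against
direct eigendecomposition on both fixture topologies.

The six-patch fixture graph (`fixture_asym6()`, edges 1-2, 2-3, 3-1,
3-4, 4-5, 1-6) is completely asymmetric — its only automorphism is the
identity, checked by brute force over all 720 permutations — so no two
patches are dynamically interchangeable. The 15-patch fixture is a
connected random geometric graph (`fixture_rgg15()`). Both are
documented stand-ins chosen for their qualitative properties, not
reproductions of any particular published topology.

### Simulation scheme

`euler_maruyama()` integrates $x_{k+1} = x_k + f(x_k)\,dt +
\sigma\sqrt{dt}\,\xi_k$, with the two bundled model families running
through a compiled stepper. Positive-orthant trajectories are never
clipped at zero: a run that crosses the floor is rejected and
restarted from a deterministically derived seed, because clipping
would bias exactly the covariance the method feeds on. The validation
experiments use noise amplitudes of 2% of the steady-state biomasses —
strong enough for a clean signal, weak enough that the linearisation
holds and floor rejections never trigger in the stable regime.

The standard series in the validation experiments has $2 \times 10^5$
retained samples with $dt = 0.02$ and one sample kept every 25 steps
(observation span $10^5$ time units, sample spacing 0.5). The spacing
is a compromise: the slow mode near the Hopf point decorrelates over
tens of time units, so denser sampling adds little information per
sample, while a longer span shrinks the covariance error, which decays
with the number of effective (decorrelation-time) windows. At this
span the Euler-Maruyama discretisation bias on the leading eigenvalue
(relative size $\sim dt\,|\lambda|/2$) is far below the statistical
error. Burn-in is 5000 steps from the steady state (or past the
transient onto the limit cycle in the post-Hopf runs).

## Early warning signals and what the tests show

`reconstruct_from_series()` composes covariance estimation (unbiased
$1/(n-1)$ normalisation — immaterial at these lengths, documented for
small windows) with the reconstruction. `sliding_window_ews()` applies
it in windows of $\tau$ samples, each window centred on its own mean so
that the slow drift of the operating point under a parameter ramp does
not contaminate the covariance; window defaults ($\tau = n/10$, stride
$\tau/4$) are package choices, as no standard exists. The fluctuation
matrix is held fixed across windows: estimating a drifting $D$ is out
of scope.

`transect_experiment()` walks a parameter grid towards the
bifurcation, tracking the steady state by continuation, and compares
the reconstructed leading eigenvalue with the exact one at every grid
point. Post-bifurcation points are flagged, not suppressed: there the
analytic eigenvalue describes the now-unstable steady state while the
simulation orbits the new attractor, so disagreement is expected and
informative.

On a stable limit cycle just past the Hopf point the reconstruction
returns a leading real part within a few $10^{-4}$ of zero — the
leading exponent of the cycle — from either side. A literal sign flip
of the estimate is therefore ill-defined at the estimator's
resolution, and `locate_crossing()` estimates the crossing parameter
instead by a one-knot hinge fit (a line rising to zero, then a plateau
at zero, least squares over the knot). For curves that genuinely
change sign, such as the analytic ground truth, it interpolates the
sign change directly. On the six-patch transects the hinge knot lands
within one grid step of the true Hopf point.

Two further empirical properties are locked in by the acceptance
tests: the absolute error of the leading-eigenvalue estimate
*shrinks* as the bifurcation is approached (the critical mode
dominates the covariance, so its geometry is measured best), and an
Ornstein-Uhlenbeck surrogate with the exact 12-dimensional
metacommunity Jacobian placed at $\mathrm{Re}\,\lambda = -0.05$ is
recovered with median relative error below 10% from $2 \times 10^5$
samples.

## What the synthetic data does and does not emulate

The generator covers strong nonlinearity, multiple timescales,
multilayer sparsity, near-critical slowing down, parameter drift, and
state-dependent (multiplicative) noise. It does not emulate
measurement noise, irregular or sparse sampling, missing variables,
misspecified zero patterns, or an unknown fluctuation matrix $D$ — on
real data each of these would degrade the reconstruction, and the
passing tests make no claim about them. Estimating $D$ from data, and
the sensitivity of the method to misplaced zeros, are deliberately out
of scope.

## Worked example

```{r example, eval = FALSE}
library(jacrecon)

# six-patch predator-prey metacommunity near its Hopf point
params <- rm_default_params()
params["K"] <- 1.3
net <- fixture_asym6()
model <- rm_metacommunity_model(params, net)
ss <- find_steady_state(model, rep(c(0.45, 0.6), 6))

# noisy series, 2e5 samples
ns <- noise_spec(0.02 * ss$x)
cfg <- sim_config(dt = 0.02, n_samples = 2e5, stride = 25,
                  burn_in = 5000, seed = 1)
ts <- euler_maruyama(model, ns, cfg, x0 = ss$x)

# structure: cross-layer + spatial zeros of the 2-species, 6-patch system
pattern <- multilayer_zero_pattern(multilayer_index(2, 6), net)
D <- fluctuation_from_noise(ns, n = model$n)
rec <- reconstruct_from_series(ts, pattern, D)

rec$leading_eigenvalue
jacobian_spectrum(numeric_jacobian(model, ss))$leading  # ground truth
```

## Known limitations

* The data demand is intrinsic to the method: tens of thousands of
  decorrelation times of stationary data are needed for percent-level
  eigenvalue accuracy far from the bifurcation (less near it).
* The fluctuation matrix must be known or assumed; errors in $D$
  propagate linearly into $J$.
* The reconstruction assumes stationary fluctuations about a steady
  state; on other attractors the leading-eigenvalue estimate remains
  informative (it finds the cycle's zero exponent) but the full matrix
  has no steady-state interpretation.
* Patterns below $N(N-1)/2$ zeros leave the system underdetermined;
  the minimum-norm solution is returned with a warning, and its
  individual entries should not be over-interpreted.
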