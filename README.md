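# jacrecon

Closed-form reconstruction of a dynamical system's Jacobian matrix from
the covariance of its stationary fluctuations, and its use as an early
warning signal for bifurcations.

## The problem

A system $\dot x = f(x)$ resting at a stable steady state and driven by
weak noise fluctuates in a way that encodes its linear response: the
Jacobian $J$ ($J_{ij} = \partial \dot x_i / \partial x_j$ at the steady
state), the stationary covariance $\Gamma$ of the fluctuations, and the
fluctuation matrix $D$ of the noise obey the Lyapunov relation

$$J\,\Gamma + \Gamma\,J^{\mathsf T} = -2\,D .$$

This relation alone under-determines $J$ (it supplies $N(N+1)/2$
equations for $N^2$ unknowns). In networked systems, however, many
Jacobian entries are *structural zeros* — non-adjacent nodes, or
different species in different habitat patches, cannot interact
directly. Given at least $N(N-1)/2$ such zeros, vectorising the
relation with Kronecker products and the commutation matrix turns the
reconstruction into an overdetermined linear least-squares problem with
a closed-form solution

$$\hat j = (\hat B^{\mathsf T}\hat B)^{-1}\hat B^{\mathsf T}\hat d ,$$

where $\hat B$ stacks the Lyapunov design
$B = \Gamma \otimes I + (I \otimes \Gamma)C$ over one unit row per
structural zero. The real part of the leading eigenvalue of the
reconstructed Jacobian is then tracked as an early warning signal: it
approaches zero as the system nears a bifurcation.

The package is aimed at researchers studying critical transitions in
networked dynamical systems — ecological metacommunities, and by
extension any system whose interaction topology supplies structural
zeros — and provides:

* the reconstruction itself (`reconstruct_jacobian()`,
  `reconstruct_from_series()`) with exact zero enforcement and
  rank/underdeterminacy diagnostics;
* structural-zero patterns from topology (`network_zero_pattern()`,
  `multilayer_zero_pattern()`, `sufficiency_check()`);
* exact oracles: a forward Lyapunov solver (`forward_lyapunov()`) and
  master-stability spectra (`msf_spectrum()`);
* a validation test-bed: Rosenzweig–MacArthur predator–prey
  metacommunities on fixture networks, simulated with a compiled
  Euler–Maruyama stepper (`rm_metacommunity_model()`,
  `euler_maruyama()`, `parameter_ramp()`);
* early-warning tooling: sliding-window eigenvalue trajectories
  (`sliding_window_ews()`), transect experiments against ground truth
  (`transect_experiment()`), and a bifurcation locator
  (`locate_crossing()`).

## Worked example

Reconstruct the Jacobian of a two-species predator–prey metacommunity
on six patches (a 12-dimensional system) from a noisy simulation near
its Hopf bifurcation:

```r
library(jacrecon)

params <- rm_default_params()
params["K"] <- 1.3                      # Hopf crossing sits near K = 1.47
net <- fixture_asym6()
model <- rm_metacommunity_model(params, net)
ss <- find_steady_state(model, rep(c(0.45, 0.6), 6))

ns <- noise_spec(0.02 * ss$x)           # additive noise, 2% of steady state
cfg <- sim_config(dt = 0.02, n_samples = 2e5, stride = 25,
                  burn_in = 5000, seed = 1)
ts <- euler_maruyama(model, ns, cfg, x0 = ss$x)

pattern <- multilayer_zero_pattern(multilayer_index(2, 6), net)
D <- fluctuation_from_noise(ns, n = model$n)
rec <- reconstruct_from_series(ts, pattern, D)

rec$leading_eigenvalue
#> [1] -0.0265815+0.284499i
jacobian_spectrum(numeric_jacobian(model, ss))$leading   # ground truth
#> [1] -0.0261494+0.2883971i
```

The reconstructed leading eigenvalue (−0.0266 ± 0.284i) agrees with the
analytic ground truth (−0.0261 ± 0.288i) to a few times $10^{-3}$: the
system is correctly diagnosed as stable but close to a Hopf
bifurcation (complex leading pair, small negative real part). The
96 structural zeros of the two-species, six-patch topology (60
cross-layer + 36 spatial) are what make the 144-entry Jacobian
recoverable from covariance data alone.

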