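# mesoreplay

Stochastic neural-mass models of metastable population dynamics with
short-term synaptic plasticity, and the statistics of hippocampal-replay-like
events they generate.

## The problem

Population bursts, Up–Down switching, and the spontaneous replay of place-cell
sequences are *metastable* phenomena: discrete activity states that recur
abruptly out of ongoing dynamics. Heuristic rate models explain them either by
slow fatigue (synaptic depression destabilizing an active state) or by noise
(fluctuation-driven escapes), but rarely say where the noise comes from.
`mesoreplay` implements a bottom-up hierarchy in which the noise is derived,
not assumed:

* **microscopic** — networks of `M` populations × `N` linear-nonlinear-Poisson
  (LNP) neurons with Tsodyks–Markram short-term depression (optionally
  facilitation): Bernoulli spiking with hazard `f(h)`, per-neuron resource
  variables `x_j`;
* **mesoscopic** — Langevin equations for the population moments, in two
  flavours: a *jump-diffusion* model driven by hybrid noise (Poisson spike
  counts `Δn ~ Pois(N f(h) Δt)` shared across synapses, plus Gaussian noise
  `√(y f(h)/N) ξ` from the across-synapse spread `y = Q − x²` of the
  depression variables), and a *diffusion* model where both channels collapse
  into a single Gaussian of amplitude `√(Q f(h)/N)`;
* **macroscopic** — the deterministic `N → ∞` mean field
  `τ ḣ = μ − h + τ J U₀ x f(h)`, `τ_D ẋ = 1 − x − τ_D U₀ x f(h)`,
  amenable to phase-plane analysis.

All levels share one transfer function
`f(h) = r·a·log(1 + exp((h − h₀)/a))` and one parameter vocabulary, so every
statistic can be compared across levels. Ring-attractor connectivity
`J_αβ = J₁ cos(θ_α − θ_β) − J₀` (one environment) or its Hopfield-like
superposition over `K` embedded maps turns the same machinery into a model of
hippocampal area CA3, where finite-size fluctuations ignite traveling bumps
of activity — nonlocal replay events — that the analysis battery detects,
decodes (population-vector average), and summarizes (interburst-interval
cumulants, event kinematics, serial correlations, Up–Down segmentation,
environment transition statistics).

## Worked example

Phase-plane anatomy of the bistable single-population regime, then a minute
of fluctuation-driven replay on the ring:

```r
library(mesoreplay)

params <- preset_params("fig3")        # bistable single population
find_fixed_points(params)
#> <fixed_points> 3 fixed point(s)
#>         h        x    eig_re  eig_im classification
#> 1 1.45563 0.990463 -14.60354 0.00000    stable node
#> 2 2.05249 0.888145  23.91711 0.00000         saddle
#> 3 5.69584 0.263570  -1.53827 9.23891   stable focus
```

The low-`h` node is the Down state; the focus at 5.70 mV is the Up state,
whose eigenvalues −1.54 ± 9.24i s⁻¹ predict damped ~1.5 Hz oscillations
that finite-size noise keeps alive.

```r
p <- preset_params("fig45", N = 50)    # ring, fluctuation-driven regime
W <- build_single_env_weights(100, p$J0_tau / p$tau, p$J1_tau / p$tau)
trace <- simulate_jump_diffusion(p, W, T = 65, seed = 1, record = "h")
replay_summary(trace, burn_in = 5)
#> <replay_summary>
#>   T_sim [s]                    60
#>   # bursts                     82
#>   slope(# peaks/duration)      6.99
#>   slope(distance/duration)     16.62
#>   SW rate in bursts [1/s]      9.20
#>   mean(IBI)                    0.600
#>   CV(IBI)                      0.833
#>   ...
#>   # NLE (>1 peak)              14
#>   fraction(NLE/bursts)         17.1%
#>   mean(abs(NLE speed))         12.70
```

82 bursts in 60 s: quiescent stretches of mean length 0.60 s (coefficient of
variation 0.83 — close to the Poissonian 1, the signature of noise-driven
initiation) separate brief bursts; one burst in six carries more than one
activity peak, i.e. a traveling bump — a nonlocal replay event — whose
decoded position moves at ~12.7 rad/s along the ring, each peak corresponding
to one sharp-wave at ~9.2 per second within bursts. Serial correlations over
only 14 events are noise; long runs put them near zero, which distinguishes
this regime from fatigue-driven replay (`mu = -0.9`, `simulate_macroscopic()`),
where direction alternates almost deterministically (lag-1 ≈ −0.56).

The same `replay_summary()` works on `simulate_microscopic()` output, which
is how the package demonstrates that the mesoscopic description matches the
spiking network it was derived from.

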