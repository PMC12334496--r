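# paddleRL

Reinforcement learning of metachronal paddling at zero Reynolds number.

Many swimmers — from *Paramecium* to krill — beat arrays of appendages with
a constant phase lag, propagating a metachronal wave along the body.
`paddleRL` asks whether that rhythm is what an optimizing agent would
discover on its own.  It simulates a two-dimensional Stokes-flow swimmer
(an elongated body with `n` pairs of rigid paddles, for researchers in
low-Reynolds locomotion and learning-based gait optimization) and couples
it to a tabular Q-learning agent that is rewarded by forward displacement.

The pieces:

* **Fluid environment** — the method of regularized Stokeslets (2D Cortez
  kernel, blob width ε = 0.05, points spaced ≤ 0.1) solving the force-free
  mobility problem `MF − U₀ = U_P`, `ΣF = 0` at each instant; the
  displacement reward of a move is `r(s,a) = ∫₀¹ u₀ dt` by 3-point
  Gauss–Legendre quadrature.
* **Deterministic MDP** — states are n-tuples of tilt indices
  `s ∈ {−5,…,5}` (`θ = sπ/20`), actions move each paddle one step or hold
  it; colliding configurations are unavailable.  Every reward is solved
  once and cached (`build_reward_graph()`), so training runs at
  table-lookup speed.
* **Learning** — tabular Q-learning,
  `Q(s,a) ← (1−α)Q(s,a) + α[r + γ max_a' Q(s',a')]`, ε-greedy exploration,
  α and ε decaying geometrically (×0.99) per episode.
* **Exact oracle** — `max_mean_cycle()` (Karp's algorithm) returns the
  provably optimal average-speed stroke on the same reward graph, so
  learned gaits can be checked against the true optimum.
* **Stroke analytics** — stroke length N, speed `U = (1/N)Σr`, per-pair
  phase lag `Δφ = (T_j − T_{j+1})/N ∈ [−0.5, 0.5]`, amplitudes, and
  Lighthill efficiency `η = ζU²/P` with a tank-towed drag coefficient ζ.

## Worked example

Train the two-paddle swimmer at tight spacing (d = 1) with the standard
protocol (γ = 0.99, 50 episodes × 50,000 steps):

```r
library(paddleRL)

geom  <- swimmer_geometry(n_pairs = 2, spacing = 1)
graph <- build_reward_graph(geom)          # ~500 cached fluid solves
fit   <- q_train(graph, train_config(seed = 1))
cycle <- greedy_rollout(fit, graph)
stroke_metrics(cycle, geom, efficiency = FALSE)
#> <stroke_metrics> back_to_front stroke, N = 18, U = 0.03458
#>   phase lags: -0.278
#>   amplitudes (multiples of pi/20): 7, 8
max_mean_cycle(graph)$mean_reward
#> [1] 0.03523153
```

The agent discovers the antiplectic, wave-like stroke: the back paddles
lead the power-stroke sequence by roughly a quarter period (phase lag
−0.278, i.e. back-to-front), the paddles sweep 7 and 8 grid steps (7π/20
and 8π/20 rad), and the stroke advances the swimmer by 0.0346 units per
move —
within 2% of the exact optimum for this geometry (0.0352, from the
oracle).  At wide spacing (`spacing = 4`) the same protocol instead learns
a tilted-in, front-to-back stroke with a short period (N = 7) and a higher
speed (0.0658).

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/paddleRL train --n 2 --spacing 1 --seed 1 --out runs/
Rscript inst/cli/paddleRL sweep --n 2 --spacings 0.5,1,2,4 --replicates 5
Rscript inst/cli/paddleRL oracle --n 2 --spacing 4
```

`train` exits non-zero when the learned stroke is ineffective (U < 0.01),
e.g. with an over-aggressive discount (γ = 0.97).

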