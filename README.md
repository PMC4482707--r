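# scyphodyn

Population dynamics of scyphozoan jellyfish ("true jellyfish") for
theoretical ecologists and modellers studying bloom formation. The
life cycle of most scyphozoans alternates between a benthic, sessile
polyp stage that multiplies asexually (budding, stolons, podocysts)
and releases ephyrae by strobilation, and a pelagic medusa stage that
reproduces sexually via planula larvae which settle and become new
polyps. `scyphodyn` implements a two-stage ordinary-differential-
equation model of this loop and the analysis that goes with it:
equilibria and their stability, the global dynamical trichotomy,
temperature-dependent vital rates, and steady-state sensitivity sweeps
over substrate competition and predation.

## The model

With `P(t)` polyps and `M(t)` medusae (individuals, time in days):

```
dP/dt = α(T) P + s₁ γ M − d₁ P − d₂ P − b₁ P²
dM/dt = s₂ β(T) n P − d₃ M − d₄ M − b₂ M²
```

where `α(T)` is the temperature-dependent budding rate, `s₁ γ M` the
planula recruitment from sexual reproduction, `d₁`/`d₂` polyp natural
and silt/nudibranch mortality, `b₁` substrate competition among
polyps, `s₂ β(T) n P` ephyra recruitment via strobilation, `d₃`/`d₄`
medusa natural and predation mortality, and `b₂` competition among
medusae. Substituting `a = α − d₁ − d₂`, `b = s₁ γ`, `c = s₂ β n`,
`d = d₃ + d₄` gives the planar system the package analyses:

```
dP/dt = aP + bM − b₁P²,   dM/dt = cP − dM − b₂M²
```

Its global behaviour is a trichotomy governed by the discriminant
`ad + bc`:

| condition            | outcome                                      |
|----------------------|----------------------------------------------|
| `ad + bc < 0`        | extinction `E0 = (0, 0)` globally stable     |
| `ad + bc = 0`        | degenerate saddle-node threshold             |
| `ad + bc > 0, c = 0` | polyp-only state `E1 = (a/b₁, 0)` globally stable |
| `ad + bc > 0, c ≠ 0` | coexistence `E* = (P*, M*)` globally stable  |

Two parameter presets are shipped: `V1` (moderate conditions) and
`V2` (high reproduction and survival, low losses and competition — the
bloom-favourable scenario).

## Worked example

```r
library(scyphodyn)

rp <- reduce_params(scypho_preset("V1"))
rp
#> Reduced polyp-medusa system parameters
#>   a = 0.1099, b = 0.8, c = 0.0216, d = 0.086, b1 = 0.0012, b2 = 1e-04
#>   discriminant ad + bc = 0.0267314

classify_regime(rp)
#> Global regime: COEXISTENCE_GAS (ad + bc = 0.0267314)
#>   globally stable attractor: COEXISTENCE equilibrium at
#>   (P, M) = (248.375, 58.4148): stable-node

# a rare invasion (no polyps, two medusae) still reaches the attractor
simulate_dynamics(rp, init = c(P = 0, M = 2), t_end = 3000)
#> Polyp-medusa trajectory: 401 points, t in [0, 3000]
#>   final state (P, M) = (248.375, 58.4148); converged to steady state
```

The discriminant `0.0267 > 0` with `c ≠ 0` places `V1` in the
coexistence regime, so every nonnegative initial state — including the
two-medusa invasion — converges to the equilibrium of about 248 polyps
and 58 medusae. Under `V2` the same invasion reaches about 7490 polyps
and 2683 medusae, a 30–46-fold increase: the signature of a bloom
habitat.

Temperature enters through fitted response curves:

```r
eval_response(strobilation_response(), 16.8108)   # peak rate
#> [1] 0.143
growth_stairs(strobilation_response(), 7, 9)
#>   T_from T_to relative_growth_pct
#> 1      7    8            18.28609
#> 2      8    9            16.17172
```

One degree of warming at the cold end of the range raises ephyra
production by about 18%, tapering as the 16.8 °C peak is approached.
Sweeps over substrate competition (`b1`), predation (`d4`), or
temperature are run with `sweep_steady_state()` and exported as CSV
with `write_sweep()`.

A command-line wrapper with verbs `simulate`, `equilibria`,
`classify`, `fit`, `stairs`, `sweep`, and `fixtures` is installed at
`system.file("cli", "scypho.R", package = "scyphodyn")`.

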