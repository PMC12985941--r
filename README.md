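# glycak

Kinetic models of glycolytic energy metabolism in human erythrocytes and
resting anaerobic skeletal muscle, built around the role of the adenylate
kinase (AK) reaction, ATP + AMP ⇌ 2 ADP (equilibrium constant
K = [ATP][AMP]/[ADP]² ≈ 1), in regulating the glycolytic rate.

## The problem and who this is for

In cells that live on glycolysis, ATP turns over within minutes, so
production must track consumption instant by instant, and the ATP level
must stay put while individual ATP consumers switch on and off. That is
only possible if the steady-state production rate *falls* as ATP rises —
negative feedback of production by its own product. This package is for
systems biologists and biochemists who want a small, fully reproducible
model in which that feedback can be computed, dissected and perturbed.

The models cover upper glycolysis — hexokinase (HK, G6P-inhibited),
glucose-phosphate isomerase (GPI, reversible), and phosphofructokinase
(PFK, allosterically inhibited by ATP and activated by AMP) — against a
lumped linear or hyperbolic ATP-consuming load. The lower pathway enters
through the stoichiometry V_PGK = V_PK = 2·V_PFK, so net glycolytic ATP
production is 3·V_PFK − V_HK (= 2·V_PFK at steady state). The adenine
nucleotide pool A = [ATP] + [ADP] + [AMP] is conserved, and the AK
reaction is treated in two modes:

* **AK at equilibrium** — ATP, ADP, AMP are algebraic functions of the
  composite variable E = 2[ATP] + [ADP], whose balance is free of the AK
  rate. Near K = 1, [AMP] ≈ A·(1 − [ATP]/A)², so AMP is a sensitive
  amplifier of ATP dips and, via PFK activation, the carrier of the
  negative feedback.
* **AK absent** — AMP clamped at its resting value; the feedback is
  severed and the steady-state flux becomes a monotonically increasing
  function of ATP.

The central computed object is the *glycolysis characteristic*: the
steady-state net production rate versus clamped ATP, bell-shaped with AK
(the physiological state sits on the stabilizing descending branch) and
monotone without. On top of it the package locates and classifies steady
states (eigenvalue stability), builds bifurcation diagrams over load
activity with saddle-node bracketing, computes control/stabilization
coefficients (Q = −1/C), decomposes the transient AK contribution to ATP
production after load steps, sweeps the nucleotide pool, and
re-parameterizes the curve by Atkinson's energy charge
φ = ([ATP] + ½[ADP])/A.

## Worked example

```r
library(glycak)

p  <- model_params("erythrocyte")   # published parameter set, mM and hours
st <- find_steady_states(p)         # default linear load, 1.57 1/h
st[, c("ATP", "ADP", "AMP", "G6P", "F6P", "V_PFK",
       "net_production", "stability", "branch")]
#>        ATP       ADP        AMP        G6P        F6P    V_PFK net_production
#> 1 1.498706 0.2496935 0.04160044 0.07033355 0.02300351 1.176484       2.352969
#>   stability     branch
#> 1    stable descending
```

The model finds a single stable steady state on the descending branch at
ATP ≈ 1.50 mM with ADP ≈ 250 µM, AMP ≈ 42 µM, G6P ≈ 70 µM, F6P ≈ 23 µM, a
PFK flux of 1.18 mM h⁻¹ and a net ATP production rate of 2.35 mM h⁻¹ —
the resting erythrocyte operating point.

```r
sr <- step_response(p, "linear", 1.57, 3.24, t_end = 2)
sr
#> ATPase step (linear): 1.57 -> 3.24; max AK share 18.48% at t = 0 h

sc <- steady_atp_change(p)   # twofold load change across the operating point
round(sc$percent_change, 1)
#> [1] 10.3
```

After an instantaneous doubling of the load, the AK reaction briefly
supplies at most ≈ 18% of total ATP production (and nothing at steady
state), while the steady ATP level moves by only ≈ 10% for a twofold load
change — the quantitative signature of AK-mediated ATP homeostasis.

Other entry points: `characteristic()`, `bifurcation_diagram()`,
`pool_sweep()`, `characteristic_vs_charge()`, the linear toy model
(`toy_coefficients()`), the scenario generator (`make_khk2_sweep()`,
`make_regulation_knockouts()`, `make_random_ensemble()`), and a thin
command-line wrapper (`inst/cli/glycak-cli.R`; subcommands
`characteristic`, `steady`, `bifurcation`, `poolsweep`, `charge`, `step`,
`toy`, `scenario`) that writes unit-annotated CSV, JSON summaries and a
run record per invocation.

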