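---
title: "Kinetic modelling of glycolytic ATP homeostasis under adenylate kinase equilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of glycolytic ATP homeostasis under adenylate kinase equilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycak)
```

## The scientific question

Cells that live on glycolysis — human erythrocytes, fast-twitch anaerobic
muscle fibres — keep their ATP concentration nearly constant while the load
imposed by ATP-consuming processes varies severalfold. Stable operation of
such a system requires that the steady-state rate of ATP production
*decrease* with increasing ATP over the physiological range: only then does
a rise in consumption, which depresses ATP, automatically recruit more
production. This package implements kinetic models that locate the origin
of that negative feedback in the adenylate kinase (AK) reaction

$$\mathrm{ATP} + \mathrm{AMP} \;\rightleftharpoons\; 2\,\mathrm{ADP},
\qquad K = \frac{[\mathrm{ATP}][\mathrm{AMP}]}{[\mathrm{ADP}]^2} \approx 1 ,$$

which in vivo is held near equilibrium by an AK activity two to three
orders of magnitude above the glycolytic flux. Near equilibrium and under
conservation of the adenine nucleotide pool
$A = [\mathrm{ATP}] + [\mathrm{ADP}] + [\mathrm{AMP}]$, AMP becomes
approximately a *quadratic* function of the relative ATP concentration,
$[\mathrm{AMP}] \approx A\,(1 - [\mathrm{ATP}]/A)^2$, so small dips in ATP
produce large relative surges in AMP — and AMP is a potent allosteric
activator of phosphofructokinase (PFK). The models quantify how this
AK–PFK–hexokinase interplay shapes the steady-state flux, how strongly it
stabilizes ATP, how much ATP the AK reaction itself transiently
contributes, and why regulation ends up tied to relative rather than
absolute nucleotide concentrations.

## The models

Only upper glycolysis is represented — hexokinase (HK),
glucose-phosphate isomerase (GPI) and PFK — because these three reactions
fix the steady-state flux; the lower pathway is collapsed through the
stoichiometric identity $V_{PGK} = V_{PK} = 2V_{PFK}$, so the lower part
produces $4V_{PFK}$ and the net glycolytic ATP balance is
$3V_{PFK} - V_{HK}$ ($= 2V_{PFK}$ at a hexose-phosphate steady state).
Glucose, orthophosphate and the adenine nucleotide pool are held constant.
The pentose-phosphate pathway, the 2,3-bisphosphoglycerate shunt,
oxidative phosphorylation and the creatine kinase system are outside the
model's scope; for muscle in particular the creatine kinase buffer would
only *reduce* the transient AK contribution computed here.

**With AK at equilibrium** the dynamic state is $(G6P, F6P, E)$ with the
composite variable $E = 2[\mathrm{ATP}] + [\mathrm{ADP}]$, whose balance
$dE/dt = -V_{HK} + 3V_{PFK} - V_{ATPase}$ is free of the AK rate. The
three nucleotides are recovered algebraically at every evaluation
(`split_from_E()`), taking the root of the equilibrium/conservation system
that keeps all concentrations non-negative — the selection is asserted
against a bisection oracle on a grid in the tests. **Without AK** the
state is $(G6P, F6P, ATP)$ with AMP clamped at its resting value, the
model's representation of a cell whose AMP signal is severed.

The AK rate itself never appears in the reduced equations, but because AMP
changes only through AK, it is recovered along trajectories as
$V_{AK} = d[\mathrm{AMP}]/dt = \frac{E - A - Q}{2Q}\,\frac{dE}{dt}$ with
$Q$ the square root appearing in the adenylate split. The five-state
mass-action model (`simulate_mass_action()`), in which AK is an explicit
reaction with a finite rate constant, is kept in the package purely as the
independent oracle for this reduction: at an AK activity $10^4$ times the
glycolytic flux scale its trajectories agree with the reduced model to
better than 0.1%.

### Rate laws

HK is irreversible, saturating in ATP and product-inhibited by G6P; GPI is
a reversible isomerization with equilibrium ratio $[G6P]/[F6P] = 3$; PFK
combines saturable F6P and ATP substrate terms, an AMP activation factor
that at most doubles the rate, a concerted-transition suppression factor
$1 + L_0\,[(1 + ATP/K_4)/((1 + AMP/K_3)(1 + F6P/K_5))]^4$ with
$L_0 = 10^8$, and orthophosphate activation. The transcription of the PFK
law was validated against two independent anchors: the flux at the
erythrocyte operating point (ATP 1.5 mM, F6P 23 µM, AMP 41 µM, Pi 1 mM)
must be ≈ 1.17 mM h⁻¹, and the rate must fall monotonically with ATP
above ~1 mM at fixed F6P 25 µM. Both discriminate sharply between
plausible groupings of the factors (the rejected reading of the GPI
displacement term, for instance, misses the first anchor by a factor of
fifty). "Removing" ATP inhibition of PFK is implemented by *freezing* the
ATP concentration inside the inhibitory term at 1.5 mM rather than
deleting the term, so the normal operating point is untouched and no other
parameter needs re-tuning.

ATP consumption is lumped into a single load, either linear
($a\,[\mathrm{ATP}]$, Michaelis constant far above physiological ATP) or
hyperbolic ($V_{max}[\mathrm{ATP}]/([\mathrm{ATP}] + K_{ATP})$,
$K_{ATP} = 10\ \mu M$ far below it). The published activity of the linear
erythrocyte load is carried as 1.57 h⁻¹: the tabulated unit (mM⁻¹) is
treated as a misprint, since only h⁻¹ makes $a\,[\mathrm{ATP}]$ a rate and
matches the 2.34 mM h⁻¹ production it must balance at 1.5 mM ATP.

### Parameters

The two built-in sets (`model_params("erythrocyte")`,
`model_params("muscle")`) carry the published enzyme activities, pool
sizes and loads; the saturation and allosteric constants are shared
between the cell types, since only activities were published for muscle.
The consistency anchor for that choice is the muscle HK flux at the
resting state (ATP 4.98 mM, G6P 181 µM), which lands on 12.8 mM h⁻¹, the
published resting PFK flux. Everything is stored internally in mM and
hours; quantities conventionally quoted in µM (the HK inhibition constant
5.5 µM, the PFK F6P allosteric site 0.37 µM, the pools, $K_{ATP}$) are
converted at construction. The AK equilibrium constant defaults to exactly
1, which with $A = 1.79$ mM reproduces the resting nucleotide triple
1500/250/40 µM. $K = 1/4$ is rejected at validation: the adenylate
algebra divides by $4K - 1$.

## Steady-state analysis

The *glycolysis characteristic* — net production $2V_{PFK}$ versus clamped
ATP — is computed pointwise by `characteristic()`. At each clamped ATP the
hexose-phosphate steady state $V_{HK} = V_{GPI} = V_{PFK}$ is solved by a
nested monotone scheme rather than a 2-D Newton iteration: for any trial
flux the G6P with $V_{HK} = v$ has a closed form (the HK law is strictly
decreasing in G6P), and $V_{PFK}$ is strictly increasing in F6P, so a
single bracketed root solve on F6P is globally convergent with no initial
guess to tune. A secant polish drives the flux residual below $10^{-11}$
mM h⁻¹ — necessary because bracketing controls the interval width, not the
residual, which matters at muscle's large GPI activity. The default grid
is 400 points on $(0.02A,\ 0.995A)$, ascending so that the natural
continuation in clamped ATP is preserved; points that fail to converge are
flagged, never dropped.

Steady states of the full system are intersections of this characteristic
with the load curve (`find_steady_states()`): bracketed on the grid,
refined by a damped Newton solve on the three dynamic equations, and
classified by the eigenvalues of a forward-difference Jacobian. Forward
(not central) differences are used so that the zero state can be
linearized without probing negative concentrations. The stability
threshold is $\mathrm{Re}\,\lambda < -10^{-9}$ h⁻¹; anything within
$\pm10^{-9}$ of zero is labelled `marginal` rather than silently
classified, because fold points sit exactly at a zero eigenvalue. The
zero state itself is reported only when no nonzero state exists, and it is
*structurally* marginal: at ATP = 0 the pool $G6P + F6P$ is exactly
conserved, and on the AK manifold ATP is quadratic in $E$ near $E = 0$,
so two eigenvalues vanish even though the state attracts nonlinearly.

`bifurcation_diagram()` sweeps the load activity, reusing one
characteristic across the sweep (the characteristic does not depend on the
load), and brackets the saddle-node — the activity beyond which nonzero
states vanish — by bisection to 0.1% relative width. For the hyperbolic
erythrocyte load the fold sits at
$V_{max} \approx \hat V\,(1 + K_{ATP}/\mathrm{ATP}_{peak})$ where
$\hat V$ is the characteristic's peak, a relation the tests verify to 1%.

### Stabilization metrics

The control coefficient of load activity over steady ATP,
$C = d\ln[\mathrm{ATP}]_{ST}/d\ln a$, is computed by a central difference
in log space (half-width 2%), and the stabilization coefficient is
$Q = -1/C$. For the linear toy model of production
$b_1 + b\,[\mathrm{ATP}]$ against consumption $a\,[\mathrm{ATP}]$ the
closed forms $C = a/(b-a)$, $Q = 1 - b/a$ make $Q$ exactly 10 at
$a = 1, b = -9$ and exactly 1 for constant production — the package's
sanity anchors for the numerical differentiation.

For the full erythrocyte model the headline stabilization number is the
steady-ATP response to a *twofold change* in the linear load across the
physiological operating point. The load sweep drawn in the model's
bifurcation view uses 0.5×, 1× and 2× the normal slope, and the twofold
change that ends at the physiological state (0.5× → 1×, referenced to the
1× steady state) moves ATP by ≈ 10%, which is the number
`steady_atp_change()` reports by default. The same function evaluates any
other pair of scalings: the 1× → 2× doubling, which ends deeper on the
flattening part of the descending branch, moves ATP by ≈ 17%. Both
numbers are computed, never assumed; the default was chosen because it is
the reading consistent with the ≈ 10% headline.

### The transient AK contribution

`step_response()` pre-equilibrates the model under the initial load
(100 h of integration with a convergence check, falling back to a Newton
solve), applies an instantaneous activity step, and decomposes ATP
production along the relaxation. The share attributed to AK is
$100\,V_{AK}^{+}/\big[(3V_{PFK} - V_{HK}) + V_{AK}^{+}\big]$ per cent,
with $V_{AK}^{+} = \max(V_{AK}, 0)$: total production counts net
glycolytic production plus the positive part of the AK rate, and episodes
of AK *consuming* ATP are visible in the exported $V_{AK}$ column rather
than netted away. Under the published twofold steps (linear
1.57 → 3.24 h⁻¹; hyperbolic 2.36 → 4.72 mM h⁻¹ — the linear step is taken
literally from its source rather than as exactly 2 × 1.57) the share
peaks immediately after the step at ≈ 18.5% and ≈ 17.5% respectively and
decays to zero at the new steady state. The denominator convention
matters at the level of a point or two — with gross production
$4V_{PFK}$ in the denominator the maxima are smaller — which is why the
package documents the convention and reports the components separately.

### Pool invariance and energy charge

`pool_sweep()` recomputes the characteristic at pool sizes 0.9, 1.79 and
3.58 mM and overlays the curves after normalizing both axes to each
curve's maximum point. The exact mechanism behind the near-invariance is
algebraic and is tested to $10^{-10}$: at $K = 1$ the AMP/ATP ratio
depends only on $[\mathrm{ATP}]/A$. The *curves* themselves collapse only
approximately, because the PFK and HK saturation terms see absolute
concentrations: the measured maximum pairwise deviation is within ~4% of
the peak over the central region spanning the peak and the entire
physiological descending branch, but grows to ~5% at the far left of the
range and to ~12% at the extreme right tail, where the curves terminate
at slightly different normalized abscissae and absolute-AMP effects in
the fourth-power suppression term are largest. `pool_sweep()` reports the
full-range statistic; users comparing against the visual near-coincidence
of normalized experimental curves should be aware that the tails are
where the idealization is weakest.

`characteristic_vs_charge()` re-parameterizes the same curve by Atkinson's
energy charge $\varphi = ([\mathrm{ATP}] + \tfrac12[\mathrm{ADP}])/A$
(equal to $E/2A$ on the AK manifold, 0.95 for the canonical 100:10:1
nucleotide ratio) and by relative ATP. At the erythrocyte operating point
the two abscissae differ by ≈ 8%, converging as the charge rises.

## The scenario module

Scenarios are the package's synthetic experiments: serializable
descriptions (base cell type, parameter overrides, AK mode, the frozen
ATP-inhibition switch, a tag for the expected outcome, and a seed where
randomness is involved) that `run_scenario()` executes and classifies.
The shape classifier calls a curve a *bell* when its interior maximum
exceeds both endpoints by more than 1% of the peak (and any supplied
operating point lies on the descending side), and *monotone* when the
curve is non-decreasing to within $10^{-6}$ of the peak — a rule needed
because the published comparisons classify curves by eye.

The three built-in families emulate the model's own what-if analyses: the
HK-inhibition sweep (four published $(K_{HK2}, A_{HK})$ pairs co-adjusted
to pass through the operating point — three do so within 0.3% in this
implementation, while the 27.5 µM pair's printed activity undershoots by
~13%, consistent with a misprint, and is carried as printed), the
regulation knockouts (baseline / frozen ATP inhibition / no AK, expected
bell / bell / monotone), and log-uniform random ensembles over the three
enzyme activities, driven by a single integer seed through the
Mersenne-Twister generator recorded in the scenario files. The ensembles
probe robustness of the bell shape to parameter uncertainty; they emulate
biological variability in enzyme expression only, not correlated
regulation, measurement noise, or variation in the saturation constants,
so a high bell fraction in an ensemble says nothing about, e.g., cells
with genuinely different PFK isoforms.

What passing tests on these synthetic scenarios do show: the qualitative
claims (bell versus monotone, branch stability, the saddle-node, pool
invariance of the *regulatory ratio*) are properties of the model
structure, robust to moderate parameter perturbation. What they cannot
show: that the rate-law idealizations (constant Pi and glucose, lumped
loads, no 2,3-BPG shunt) hold in any particular real cell.

## Numerical choices and limitations

* Integration: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$ mM. The
  reduced model is non-stiff (the stiffness lives in the eliminated AK
  reaction); the mass-action oracle at large AK rate constants is stiff,
  which lsoda handles by switching methods.
* Feasibility: concentrations in $[-10^{-12}, 0)$ arising from round-off
  at the $E = 2A$ boundary are clamped to zero; anything more negative
  raises an error carrying the offending state.
* Convergence flags: a trajectory is `converged` when all derivative
  magnitudes at its final sample fall below $10^{-6}$ mM h⁻¹; at a solved
  steady state the production/consumption balance closes to the same
  tolerance.
* Test problem sizes: characteristics at 50–400 points, trajectories of
  100–2000 samples over 0.5–10 h, ensembles of 6–8 scenarios — sizes at
  which every quantitative result above is already converged to well
  inside its assertion tolerance; the full suite runs in well under a
  minute.
* Known limitations: no creatine kinase buffering (muscle transients are
  therefore upper bounds on the AK share), no Hopf or two-parameter
  bifurcation analysis (the system exhibits no oscillations in this
  regime), no parameter estimation from data, and no temperature or pH
  corrections. SBML export is not provided; the YAML parameter and
  scenario files plus the CSV/JSON exporters are the interchange surface.
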