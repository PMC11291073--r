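---
title: "Modelling whole-cell voltage-clamp artefacts and their consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-cell voltage-clamp artefacts and their consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(voltclamp)
```

## The problem

Whole-cell voltage clamp assumes the membrane voltage $V_m$ equals the
command voltage $V_{cmd}$. In reality the pipette's series (access)
resistance $R_s$, the membrane and pipette capacitances $C_m$ and $C_p$, the
imperfect seal (leak conductance $g_{leak}$), and residual voltage offsets
$V_{off}$ all intervene, and modern amplifiers *partially* correct for them
using machine *estimates* ($R_s^*$, $C_m^*$, $C_p^*$, $g_{leak}^*$) that are
themselves imperfect. For large, fast currents — the cardiac fast sodium
current being the canonical worst case — the residual error distorts current
amplitudes, timings, and summary current–voltage (I–V) relationships.

`voltclamp` implements a mechanistic ordinary-differential-equation model of
the entire recording chain — cell, pipette, and amplifier with its
compensation circuitry — so that these distortions can be simulated,
explained, and fitted.

## The model

The state variables are the membrane voltage $V_m$, the pipette voltage
$V_p$, the clamp drive $V_{clamp}$, the amplifier's internal estimate of the
membrane voltage $V_{est}$, the recorded (filtered) current $I_{out}$, and
the attached ionic model's states. With $\alpha_R$ the series-resistance
compensation level and $\alpha_P$ the supercharging (prediction) level:

$$
\begin{aligned}
I_{ion} &= f(t, V_m), &
I_{leak} &= g_{leak}(V_m - E_{leak}),\\
\frac{dV_m}{dt} &= \frac{V_p + V_{off} - V_m}{R_s C_m}
  - \frac{I_{ion} + I_{leak}}{C_m}, &
\frac{dV_p}{dt} &= \frac{V_{clamp} - V_p}{\tau_{clamp}},\\
\frac{dV_{est}}{dt} &= \frac{V_{cmd} - V_{est}}{(1-\alpha_P) R_s^* C_m^*}, &
V_{cmd}' &= V_{cmd} + R_s^*\!\left(\alpha_R I_{out}
  + \alpha_P C_m^* \tfrac{dV_{est}}{dt}\right),\\
\frac{dV_{clamp}}{dt} &= \frac{V_{cmd}' - V_{clamp}}{\tau_{sum}}, &
\frac{dI_{out}}{dt} &= \frac{I_{in} - I_{out}}{\tau_z},
\end{aligned}
$$

with the physical pipette current, minus the machine's capacitance
compensation,

$$
I_{in} = I_{ion} + I_{leak}
  + C_p \frac{dV_p}{dt} - C_p^* \frac{dV_{clamp}}{dt}
  + C_m \frac{dV_m}{dt} - C_m^* \frac{dV_{est}}{dt},
$$

and the off-line leak subtraction
$I_{post} = I_{out} - g_{leak}^*(V_{cmd} - E_{leak}^*)$.

The supercharging pathway deserves a comment: the amplifier maintains
$V_{est}$, an internal prediction of $V_m$, relaxing towards $V_{cmd}$ with
time constant $(1-\alpha_P) R_s^* C_m^*$; the feed-forward term
$\alpha_P R_s^* C_m^*\, dV_{est}/dt$ transiently overshoots the command
("supercharges") so the membrane capacitance charges faster. Setting
$\alpha_P = 0$ removes the feed-forward and recovers the earlier
no-supercharging formulation of the instrument model (with $V_{est}$ still
driving the slow-capacitance compensation); this reduction is verified as a
trajectory identity in the test suite. Setting $V_{est} = V_{cmd}$ constant
makes the supercharging term vanish — a fixed point that is also tested.

### Units

Internally everything is mV, ms, MΩ, nA and µS; capacitances are entered in
pF (matching instrument panels and the electrophysiology literature) and
converted once to nF, so that MΩ·nF = ms and nF·mV/ms = nA. This keeps all
state variables within a few orders of magnitude of unity and avoids
scale-induced stiffness pathologies.

### Amplifier time constants

Three first-order lags model the amplifier: the summing amplifier response
$\tau_{sum}$ (default 1 µs), the clamp time constant $\tau_{clamp}$
(default 0.8 µs), and the transconductor/output filter
$\tau_z = R_f C_f$ (default 7.5 µs; physically set by the amplifier's
filtering, anywhere from 0.1 to 50 µs). The defaults follow the reported
orders of magnitude for these response times — $\tau_{sum}$ and
$\tau_{clamp}$ of order 1 µs. The choice matters: a sluggish summing
amplifier (tens of µs) prolongs the mismatch between the supercharging
overshoot and the physical charging current, leaving artificial
capacitive-compensation residues several hundred µs into each step. The
output filter is deliberately a single pole: real amplifiers apply
higher-order filters (e.g. 4-pole Bessel), but a first-order $\tau_z$
captures the dominant smoothing and is what the model intends.

## Ionic models

Any object implementing `n_states()`, `ionic_current()`, `ionic_rhs()`,
`ionic_steady_states()` (and optionally `on_voltage_jump()`) can be
attached; third-party models plug in through this interface (models without
compiled support are integrated through the R-level right-hand side).

**Electrical model cell.** `model_cell()` is a linear two-branch circuit: a
static resistor $R_m$ ($I_m = V_m/R_m$) in parallel with a series
RC branch ($R_k$, $C_k$) whose current obeys
$dI_k/dt = (C_k\, dV_m/dt - I_k)/(R_k C_k)$. The branch needs $dV_m/dt$;
the coupled right-hand side computes the membrane equation first and feeds
its derivative in within the same evaluation — no numerical
differentiation. Component defaults are $R_k = 100$ MΩ, $C_k = 10$ pF,
$R_m = 10$ MΩ: they satisfy the two published constraints — relaxation
constant $R_k C_k = 1$ ms and an order-10 nA current swing for a 130 mV
step — while individual values remain configurable. Because the model cell
is linear, the *entire* coupled system is linear time-invariant within each
protocol segment, and `simulate_model_cell_exact()` provides an
independently assembled matrix-exponential solution. The numerical
integrator is validated against it to better than $10^{-6}$ relative error
across the full compensation grid (0–95%), including the under-damped
ringing regimes at 95%.

**Generic fast sodium current.** `generic_ina()` is a Hodgkin–Huxley
$g_{max} m^3 h j (V_m - E_{Na})$ current with sigmoidal steady states and
bell-shaped time constants. It is a *generic stand-in* for published
cardiac INa formulations, not a reimplementation of any of them. Its
defaults were fixed, once, to the qualitative placement required of a fast
sodium current in this context: activation threshold near −40 mV, an
ideal-clamp I–V peak at −20 mV with a flat top towards −10 mV (cardiac
INa I–V curves typically peak between −30 and −10 mV), activation
steepness of e-fold per 4.5 mV on $m_\infty$ (within the 4–7 mV range
reported for Na$_V$1.5, and steep enough that the positive feedback
between inward current and series-resistance depolarisation — the
mechanism behind near-threshold time-to-peak delays — expresses itself),
time-to-peak between ≈ 0.3 ms (strongly suprathreshold) and ≈ 1.4 ms
(near threshold), and $E_{Na} = +60$ mV (Nernst for 140 mM external and
≈ 14 mM internal sodium). Fast and slow inactivation gates share their
steady state; the slow gate mainly shapes recovery and long holds.

The peak placement was a genuinely open design point: a sharply peaked
I–V (maximum isolated at −10 mV) turns out to *suppress* the
population-level mischaracterisation phenomenon the virtual studies
exist to demonstrate, because both study arms' observed curves then
round onto the same grid voltage; the flat-topped −20 mV placement — at
least as typical of the currents being emulated — lets the differential
loss of clamp between large- and small-current arms express itself
robustly across seeds. This choice was made at the level of the
phenomenon (is the mechanism expressed at all?), not of any particular
random draw.

The near-threshold delay phenomenon is asserted only ordinally (delay at a
just-subthreshold step exceeds the delay far above threshold): its detailed
pattern is known to be sensitive to the precise activation curve of the
ionic model, so a generic stand-in can only claim the mechanism, not the
pattern.

**Current density.** Expression-system work prescribes current size as a
density (A/F). `density_to_conductance()` converts: it computes the
ideal-clamp peak current of the gating model at unit conductance over the
protocol family and scales $g_{max}$ so the peak per unit capacitance
equals the requested density. Peak current is linear in $g_{max}$ under
ideal clamp, so the conversion is exact.

## Simulation

`simulate_clamp()` integrates the coupled system segment by segment.
Command steps are instantaneous (the amplifier lags provide all physical
smoothing); the integrator restarts at each boundary so discontinuities are
honoured exactly. The system is stiff — µs amplifier lags next to ms gating
— and is solved with `deSolve`'s LSODA (BDF on the stiff portions) through
compiled C derivatives, at `rtol = 1e-8`, `atol = 1e-10`. Output is sampled
at `dt_out` (default 0.01 ms, fine enough to resolve $\tau_z$-filtered
capacitive spikes); multi-second holding periods can be sampled coarsely
(`dt_hold`) because every simulation starts from the steady state at the
holding potential, where nothing happens.

`steady_state_init()` finds that steady state by reducing the equilibrium
conditions to a scalar root-find in $V_m$ (all capacitive currents vanish
and the amplifier chain becomes algebraic, including the $\alpha_R$
feedback through $I_{out}$), followed by a Newton polish. The residual norm
of the full right-hand side is reported and checked: the default tolerance
is $10^{-8}$ in simulation units, relaxed automatically in proportion to
the system's fastest rate, because the equilibrium voltage cannot be
resolved below double-precision rounding and any voltage rounding error is
amplified by $1/(R_s C_m)$ when forming derivatives. If multiple
equilibria bracket (possible near the sodium activation threshold), the
root nearest the holding potential is chosen — consistent with how a real
cell arrives at the holding condition.

`simulate_ideal()` is the artefact-free reference: $V_m \equiv V_{cmd}$ and
only the ionic states are integrated. For Hodgkin–Huxley models each
constant-voltage segment is solved in closed form (gates relax
exponentially); for the model cell the RC branch receives the impulse
response of the voltage step ($I_k$ jumps by $\Delta V / R_k$) and then
decays. These closed forms double as independent checks on the numerical
path.

## I–V extraction

`compute_iv()` takes the peak of the post-processed current in a window
that opens 0.2 ms after the step onset (skipping the residual capacitive
spike) and closes at the step end; ties resolve to the earliest time. Three
peak definitions are available: signed extremum of largest magnitude
(`"abs"`, the default), most negative (`"inward"`), most positive
(`"outward"`). The bias studies use `"inward"` — the standard reading for
an inward sodium current, and robust against any outward
compensation-transient residue that outlives the blanking interval in
low-expression cells.

## The two bias studies

**I–V averaging bias** (`averaging_study()`). A virtual population is drawn
by Latin hypercube: conductance scale log-uniform in [0.2, 5], $R_s$
uniform in [4, 15] MΩ, $C_m$ uniform in [8, 22] pF, with *perfect* machine
estimates ($R_s^* = R_s$, $C_m^* = C_m$) and both compensations at 80%.
(The two physical ranges are assigned this way round — resistances in MΩ,
capacitances in pF — as the only physically consistent reading.) Each
cell's I–V curve is simulated on the standard family (hold −100 mV for
2000 ms, 20 ms steps from −90 to +50 mV in 10 mV increments) and the
pointwise mean ± SEM is compared against the ideal-clamp,
baseline-conductance curve. The baseline conductance is derived at run time
from a current density of 1500 A/F — the same wild-type density used in the
mutant study — at the midpoint capacitance (15 pF) of the sampled range,
giving a scale-1 ideal peak of ≈ 22 nA; the population then spans ≈ 4 to
110 nA. The headline outputs are the relative underestimation of the peak,
$100(1 - |\hat I_{mean}| / |\hat I_{ideal}|)$, and the leftward shift of
the peak voltage. Under these conditions the underestimation falls in the
10–30% range and the shift at 10–20 mV for most seeds; at $n = 5$ the
underestimation is noisy (five Latin-hypercube cells), which is inherent to
the design, not a numerical artefact. Normalising the individual curves
before averaging does not remove the voltage shift (tested).

**Mutant/drug mischaracterisation** (`mutant_drug_study()`). Two arms with
identical gating and different current densities — 1500 A/F (wild
type/control) versus 500 A/F (mutant/drug, a pure one-third conductance
reduction) — are characterised through the artefact model at 80%
compensation. Cells are drawn per arm as $R_s \sim$ LogNormal(mean 2.5,
variance 1.5) MΩ, $C_m \sim$ LogNormal(mean 40, variance 10) pF,
$V_{off} \sim$ Normal(0, variance 2.5) mV (log-normals parameterised by
their own mean and variance, with the underlying normal solved from those
moments), machine estimates carry 5% multiplicative error (s.d. 0.05), and
a quality control accepts only $R_s < 4$ MΩ, redrawing until 15 accepted
cells per arm (fixed-n resampling, with a bounded budget). Conductance is
scaled per cell from the arm's density and the sampled $C_m$, so the
*ideal* curves of both arms peak at the same voltage by construction. The
observed mean curves do not: the large-current arm suffers more loss of
clamp, and on the 10 mV protocol grid the apparent peak-voltage difference
between arms is quantised — its modal value across master seeds is 10 mV,
the headline mischaracterisation. Under near-ideal conditions (tiny $R_s$,
no offsets) the shift collapses to zero (tested).

All sampling in a study flows from a single seed; identical seeds give
byte-identical outputs.

## Fitting

`fit_clamp()` adjusts the ionic maximal conductance and the cell-side
instrument parameters ($R_s$, $C_m$, $V_{off}$, $g_{leak}$) so the
simulated post-processed current matches observed sweeps, with compensation
levels and machine estimates held at their known values. Positive
parameters are searched as $p = p^0 e^{s}$ — conductance referenced to
$p^0 = 600$ nS and the others to the machine estimates — which makes the
search scale-free; the signed offset is searched untransformed (scaled to
tens of mV so all coordinates are order 1). The loss is the unweighted sum
of squared residuals over all time points and sweeps — the simplest
defensible choice in the absence of a stated noise model — with simulated
sweeps interpolated onto the data grid segment-by-segment so the
leak-subtraction discontinuity at step boundaries is never smeared.

The optimiser is a self-contained CMA-ES (covariance matrix adaptation
evolution strategy: cumulative step-size adaptation, rank-one and rank-µ
covariance updates, standard strategy constants), restarted from random
points in transformed space ($s \in [-2, 2]$, $V_{off} \in [-20, 20]$ mV;
40 restarts by default, fewer suffice on clean synthetic data), followed by
a Nelder–Mead polish of the best restart. Failed simulations at
pathological proposals return a large finite penalty so the search
continues. On noiseless synthetic data at 80% compensation with 5% mis-set
machine estimates, all five parameters are recovered to well under 1%
(inverse-crime self-consistency, part of the test suite).

## What the synthetic data do and do not show

The generators emulate the *structure* of the experiments: population
variability in access resistance, cell size and offsets; imperfect machine
estimates; quality control; grid protocols. They do not emulate recording
noise, seal drift or loss during a protocol, temperature fluctuations,
P/N-style online transient subtraction, higher-order amplifier filters, or
nonlinear seal leaks — so a passing test suite demonstrates the internal
consistency of the instrument model and the reality of the biases it
predicts, not that any particular laboratory's recordings follow it
quantitatively. Fitting real data additionally relies on the correctness of
the chosen ionic model; discrepancies there propagate nonlinearly
(especially near the activation threshold), which is a known limitation of
the whole approach.

## Numerical choices, in one place

* Stiff LSODA integration at `rtol = 1e-8`, `atol = 1e-10`; integrator
  restart at every command discontinuity; compiled derivatives for the
  built-in models, R fallback for plug-ins.
* Steady-state initialisation by scalar root-find plus Newton polish;
  residual norm reported, tolerance `1e-8` scaled up with the fastest
  system rate; equilibrium nearest the holding potential on multi-root
  brackets.
* Peak detection: 0.2 ms blanking, earliest-time tie-break, direction
  `"abs"`/`"inward"`/`"outward"` (studies use inward).
* `alpha_P` capped at 0.999 (the supercharging time constant must stay
  positive); sweeps cap both compensations at 95%, the highest level
  exercised on the bench.
* Trace CSVs are written as `%.17g` so every double round-trips exactly;
  parsing uses base R's correctly-rounded reader.
* Problem sizes in the test suite: the linear-oracle grid runs 18
  model-cell simulations; the averaging study runs n = 5, 25, 75 (one
  seed); the mutant study runs 10 master seeds at n = 15 per arm; fitting
  checks use 6 sweeps of 15 ms at 0.1 ms sampling with 2 restarts.
  These sizes keep the full suite comfortably reproducible on a laptop
  while matching the studies' stated designs.

## Session info

```{r}
sessionInfo()
```
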