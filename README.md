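# voltclamp

Mechanistic simulation and correction of whole-cell patch-clamp
voltage-clamp artefacts, for electrophysiologists and modellers who need to
know what their amplifier actually did to their current recordings.

Whole-cell voltage clamp assumes the membrane voltage equals the command
voltage. In practice the series (access) resistance Rs, the membrane and
pipette capacitances Cm and Cp, the seal leak, and residual voltage offsets
all intervene; amplifiers *partially* compensate (series-resistance
compensation αR, supercharging/prediction αP, capacitance compensation,
off-line leak subtraction) using imperfect machine estimates Rs\*, Cm\*,
Cp\*, gleak\*. For large fast currents — the cardiac fast sodium current
above all — the residue distorts amplitudes, timings and current–voltage
(I–V) curves, and the distortions do **not** average away across cells.

`voltclamp` implements the full coupled ODE model of cell, pipette and
amplifier:

- membrane: `dVm/dt = (Vp + Voff − Vm)/(Rs·Cm) − (Iion + Ileak)/Cm`
- amplifier chain: `Vcmd → Vcmd′ → Vclamp → Vp` through first-order lags
  (τsum, τclamp), with `Vcmd′ = Vcmd + Rs*·(αR·Iout + αP·Cm*·dVest/dt)` and
  supercharging estimate `dVest/dt = (Vcmd − Vest)/((1 − αP)·Rs*·Cm*)`
- measurement: `Iin = Iion + Ileak + Cp·dVp/dt − Cp*·dVclamp/dt +
  Cm·dVm/dt − Cm*·dVest/dt`, low-pass filtered with τz into `Iout`, and
  leak-subtracted into `Ipost = Iout − gleak*·(Vcmd − Eleak*)`

with pluggable ionic models: a linear electrical **model cell** (validated
against an independently assembled matrix-exponential closed form to 1e−6
across compensation levels 0–95%) and a **generic Hodgkin–Huxley fast
sodium current** (`m³·h·j`). On top sit protocol builders, I–V extraction,
two virtual-population bias studies (I–V averaging bias;
mutant/drug mischaracterisation), and multi-restart CMA-ES fitting of the
coupled model to recorded sweeps.

## Worked example

A sodium current recorded through a realistic instrument (Rs = 10 MΩ,
Cm = 30 pF, both compensations at the typical 80%) versus the artefact-free
ideal clamp:

```r
library(voltclamp)

sett <- amplifier_settings(alpha_R = 0.8, alpha_P = 0.8,
                           Rs_est = 10, Cm_est = 30, Cp_est = 4)
cell <- cell_properties(Rs = 10, Cm = 30, Cp = 4)
ina  <- generic_ina(g_max = 0.6)   # 600 nS
prs  <- iv_protocols(hold = -100, hold_ms = 2000,
                     v_start = -90, v_end = 50, v_inc = 10, step_ms = 20)

obs   <- simulate_iv(sett, cell, ina, prs, direction = "inward")
ideal <- simulate_iv(NULL, NULL, ina, prs, ideal = TRUE,
                     direction = "inward")
iv_peak(obs)
#>   voltage_mV peak_current_nA
#> 1        -30           -9.68
iv_peak(ideal)
#>   voltage_mV peak_current_nA
#> 1        -20           -11.7
```

Even at 80/80% compensation the recorded curve peaks at **−30 mV with
−9.7 nA** where the true current peaks at **−20 mV with −11.7 nA**: a
10 mV leftward shift and a 17% amplitude loss, purely from instrument
physics. `autoplot(obs)` overlays the curves; `averaging_study()` and
`mutant_drug_study()` quantify what happens when such curves are averaged
across cell populations or compared between experimental arms (a pure
conductance reduction acquires an apparent 10 mV activation shift), and
`fit_clamp()` inverts the model to recover conductance, Rs, Cm, Voff and
gleak from compensated recordings.

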