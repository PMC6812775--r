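---
title: "The purse model of bleb filling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The purse model of bleb filling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebflow)
```

## The physical picture

After glaucoma filtration surgery or drainage-device implantation, aqueous
humour is shunted from the anterior chamber into the subconjunctival space,
where it inflates a fluid pocket — a *bleb* — under the conjunctiva. The
bleb's pressure is the quantity clinicians actually care about (it is the
proxy for post-operative intraocular pressure), but it is not directly
observable at the slit lamp; the bleb's geometry is.

`blebflow` implements a minimal mechanical model that links the two. The
conjunctiva is idealised as a clamped thin elastic sheet of Young's modulus
$E$ and thickness $T$ pursing over a fixed circular planform of radius $R$.
Three ingredients close the model:

1. **Mass conservation.** The bleb volume $V$ grows by the difference
   between the constant surgical inflow $Q_{in}$ and the drainage outflow
   $Q_{out}$:
   $$\frac{dV}{dt} = Q_{in} - Q_{out}.$$
2. **Resistive outflow.** Drainage is viscous, so the pressure drop is
   proportional to the flow: $P = K\,Q_{out}$, with $K$ the outflow
   resistance.
3. **Elastic purse law.** The bleb is a shallow spherical cap,
   $V = C_1 \pi R^2 H$ with $C_1 \approx 1/2$, and the static pressure of
   the stretched sheet is cubic in the cap height:
   $$P = C_2\,\frac{E\,T\,H^3}{R^4}, \qquad C_2 = 4.63 .$$

Combining these gives a single autonomous ODE for the height,

$$C_1 \pi R^2 \frac{dH}{dt} = Q_{in} - \frac{C_2 E T}{K R^4} H^3,$$

implemented in `simulate_bleb()`.

## Characteristic scales and the universal curve

The balance point of inflow and outflow defines the equilibrium scales
(`characteristic_scales()`):

$$H_{max} = \left(\frac{Q_{in} K R^4}{C_2 E T}\right)^{1/3},\qquad
  P_{max} = K\,Q_{in},\qquad
  T_c = \frac{C_1 \pi R^2 H_{max}}{Q_{in}} .$$

With $\tau = t/T_c$ and $\hat H = H/H_{max}$ the ODE collapses to the
parameter-free form

$$\frac{d\hat H}{d\tau} = 1 - \hat H^3 ,$$

whose exact solution from $\hat H(0) = 0$ is the antiderivative of
$1/(1-x^3)$:

$$\tau(\hat H) = \frac16 \ln\frac{\hat H^2 + \hat H + 1}{(1-\hat H)^2}
  + \frac{1}{\sqrt3}\left[\arctan\frac{2\hat H + 1}{\sqrt3}
  - \arctan\frac{1}{\sqrt3}\right],$$

implemented as `tau_of_hhat()` with numerical inverse `hhat_of_tau()`. Every
trajectory, at any inflow rate, rescales onto this one curve
(`collapse_series()`); at one time constant the bleb has reached
`hhat_of_tau(1)` $\approx 0.823$ — about 82% — of its final height, and
since $V \propto H$ at fixed planform, of its final volume. Pressure
follows the height cubically along the whole trajectory,
$P/P_{max} = \hat H^3$ (`pressure_ratio()`).

Eliminating $K$ and $Q_{in}$ in favour of $P_{max}$ expresses both
equilibrium ratios as one-third power laws in the load parameter
$P_{max} R/(ET)$ with prefactors $C_2^{-1/3} \approx 0.600$ and
$C_1 C_2^{-1/3} \approx 0.300$ (`scaling_prefactors()`); `scaling_check()`
verifies the exponent and both prefactors empirically across a set of
fitted runs.

## Numerical choices

* **Closed form over quadrature.** `tau_of_hhat()` evaluates the
  antiderivative directly; the test-suite verifies it against adaptive
  quadrature of $\int_0^{\hat H} dx/(1-x^3)$ (1e-8 absolute) and against
  the ODE by numerical differentiation (1e-6 relative). We implement the
  standard antiderivative rather than any typeset rendering of it, and let
  those two independent checks arbitrate.
* **Inversion.** `hhat_of_tau()` uses a safeguarded Newton iteration on the
  closed form — the derivative $d\tau/d\hat H = 1/(1-\hat H^3)$ is exact,
  $\tau(\hat H)$ is convex, and $\hat H \le \tau$ brackets the root, so the
  iteration is monotone after one step. Beyond $\tau \approx 10.46$ the
  residual $1-\hat H = e^{-3(\tau - \tau_0)}$ (with
  $\tau_0 = \ln 3/6 + \pi/(6\sqrt3)$) drops below $10^{-13}$ — under
  double precision the root is no longer distinguishable from 1 and a
  bracketed search degenerates — so the exact exponential asymptote is used
  there. Because $d\tau/d\hat H$ diverges at equilibrium, a $\tau$-side
  round trip $\tau(\hat H(\tau))$ is limited to roughly
  $\varepsilon_{mach}/(1-\hat H^3)$ no matter the algorithm; the tests
  assert 1e-9 accuracy where conditioning allows and the conditioning bound
  beyond.
* **ODE path.** `simulate_bleb()` integrates the dimensional ODE with
  `deSolve` (lsoda, rtol 1e-9, atol $10^{-12} H_{max}$). The analytic
  solution is the accuracy oracle; the ODE route exists to support nonzero
  initial heights — including overfilled blebs $H_0 > H_{max}$, which decay
  to equilibrium — and future model extensions.
* **Filling-curve fit.** `fit_filling_curve()` performs bounded
  Levenberg–Marquardt nonlinear least squares on
  $H(t) = H_{max}\hat H((t + t_0)/T_c)$, with $t_0 \ge 0$ a virtual time
  offset absorbing fluid already present at the start of a recording.
  Starting values: $H_{max}^0 = 1.05\max H$; $T_c^0$ from the first
  crossing of $0.82\max H$ (the one-time-constant level); $t_0^0$ by
  inverting the universal curve at the first sample. Lower bounds are
  $H_{max} > 0$, $T_c > 0$, $t_0 \ge 0$. We deliberately do **not**
  constrain $H_{max} > \max H$: with multiplicative measurement noise the
  largest observed sample on a plateau typically *exceeds* the true
  equilibrium (by about $+3\sigma$), and such a bound would bias the
  estimator upward by construction. Degenerate inputs (constant series, or
  series whose coarse binned trend is not increasing) are rejected with a
  diagnostic rather than fitted.
* **Cubic pressure fit.** `fit_pressure_height_cubic()` is
  origin-constrained least squares of $P$ on $H^3$ (the purse law has no
  intercept); its slope identifies the lumped stiffness
  $ET = k R^4/C_2$, and $K$ then follows from $P_{max} = K Q_{in}$
  (`infer_resistance()`).
* **Units.** Everything internal is SI (m, s, Pa, m³/s); mmHg, mm and
  µl/min exist only at the I/O boundary (1 mmHg = 133.322 Pa,
  1 µl/min = $10^{-9}/60$ m³/s), with units encoded in CSV column
  suffixes. Mixing clinical and laboratory units is the dominant source of
  silent error in this problem, so conversions are confined to
  `R/units.R` and `R/io.R` and tested for involution.
* **Degenerate inflow.** $Q_{in} = 0$ is a decay-only regime with no finite
  equilibrium scales; `characteristic_scales()` and
  `fill_time_estimate()` raise a degenerate-input error rather than
  returning infinities, while `simulate_bleb()` still integrates the decay.
* **Cap constant.** $C_1 = 1/2$ is a shallow-cap approximation, not an
  exact value; it is therefore a configurable argument everywhere it
  enters, with 0.5 as the default.

## The synthetic experiments

No measured trajectories are shipped, so two seeded presets reproduce the
statistical structure of the bench and tissue experiments the model was
built against:

| | `preset_in_vitro()` | `preset_ex_vivo()` |
|---|---|---|
| membrane | silicone, $E$ = 1.24 MPa, $T$ = 0.8 mm | conjunctiva, $E$ = 28 MPa, $T$ = 0.1 mm |
| planform radius | 20 mm (clamped plate) | 4 mm (human-scale convention) |
| outflow resistance | 2.6×10¹⁰ Pa s m⁻³ (set by drainage tube) | 1.6×10¹³ Pa s m⁻³ (convention; $P_{max}$ = 10 mmHg) |
| inflow | 5000 / 8000 / 10000 µl/min | 5 µl/min |
| sampling | 1.875 Hz, 180 s | 1 Hz, 1800 s (≤ 4 h) |
| initial height | 0 (filled from empty) | 0.15 $H_{max}$ (surgical closure leaves fluid) |

The ex vivo planform radius and outflow resistance are *synthetic
conventions*: in the tissue preparation the drainage resistance is a
property of the tissue and can only be inferred from data, so we fix it at
the value that places the equilibrium pressure at the 10 mmHg clinical
target. The 1800 s default duration covers ≈ 20 relaxation times of that
configuration, long enough that the plateau dominates the record the way it
does in practice. Measurement noise defaults to 2% multiplicative Gaussian
on height (photographic extraction) and additive Gaussian on pressure with
SD 2% of $P_{max}$ (transducer); heights are clipped at zero and clip
counts reported. Noise magnitudes are conventions — no noise statistics are
published for the original recordings.

What the generator does *not* emulate: photographic geometry extraction and
its systematic errors, non-circular planforms, tissue porosity and
poroelastic drainage, scarring and encapsulation (which prevent a true
plateau in real tissue), drift or autocorrelated sensor noise, and
leaking/sweating blebs. Passing the recovery tests therefore demonstrates
the estimator's correctness and noise robustness *under the model's own
assumptions*, not the model's validity for real tissue.

`generate_clinical_blebs()` likewise stands in for a clinic population: no
tabulated (radius, height, IOP) triples are published, so geometries are
drawn uniformly over the clinically observed ranges (radius 1–8 mm, height
0.2–4 mm), IOP is the purse-law chart pressure plus Gaussian noise, drop
counts are assigned preferentially above the green band, and a small
fraction is flagged leaking. These are labelled synthetic throughout.

## The traffic-light grading chart

The purse law makes pressure *nonlinear* in the two quantities a clinician
can score — steeply increasing in height (power 3) and decreasing in extent
(power 4) — which is why linear grading scales cannot rank blebs by risk. A
single lumped stiffness $C_2 E T$, calibrated from one reference bleb
(`calibrate_chart()`), turns the (radius, height) plane into a pressure
map: iso-pressure contours $H \propto R^{4/3}$ (`iso_pressure_curve()`)
partition it into a green band around the clinical target, red extremes
(hypotony below, dangerous elevation above, plus a cap on very tall blebs
regardless of pressure), and an orange transition (`classify_bleb()`,
`render_chart()`).

Numerical zone boundaries are conventions of this package — the published
chart is graphical only: green [5, 15] mmHg around the ~10 mmHg target, red
below 2 and above 25 mmHg, height cap 3 mm, all configurable via
`zone_thresholds()`.

Two built-in calibrations are provided and deliberately *not* reconciled:
`"worked_example"` (3 mmHg at $R$ = 4 mm, $H$ = 1 mm, the human fill-time
example) and `"chart"` (10 mmHg at $R$ = 4.5 mm, $H$ = 1 mm, the green-zone
narrative). They differ by a factor ≈ 5 in lumped stiffness; that spread is
real between-eye variability in $C_2 E T$ and hiding it behind an average
would misrepresent the chart's precision.

One subtlety: the "optimum bleb" is often quoted as a *box* — radius
3–6 mm, height 0.5–1.5 mm — but because pressure varies as $H^3/R^4$, the
model pressure spans a factor of ~430 across that box, so no fixed pressure
band can colour all of it green. What is true, and what the tests assert,
is that the 10 mmHg contour of the `"chart"` calibration runs through that
box corner to corner (from $H \approx 0.58$ mm at $R$ = 3 mm to
$H \approx 1.47$ mm at $R$ = 6 mm): the optimum region is a *corridor along
the target contour*, not a rectangle.

Leaking blebs violate the purse assumption (the sheet no longer holds the
pressure); they are still plotted but flagged `pressure_valid = FALSE` and
must not be read as IOP estimates. Very small blebs (low radius *and* low
height) are outside the range over which the model has been confronted with
data; the chart extends there mathematically but should be read with
caution.

## Problem sizes and runtime

The test-suite and worked examples run on deliberately modest problems,
which the physics makes sufficient: bench trajectories of 338 samples
(180 s at 1.875 Hz, ≈ 6 relaxation times), ex vivo trajectories of 1801
samples (1800 s at 1 Hz), 240-sample once-a-minute photographic series for
the noisy-fit check, three-run ensembles for the scaling check, 50-bleb
synthetic clinics, and ~10⁴ samples for the noise-bias check. Noiseless
recovery is verified to 0.1%, seeded 2%-noise recovery to 5%.

## Known limitations

* The model is quasi-static and single-compartment: no tissue porosity, no
  scarring dynamics, no valve mechanics of specific drainage devices.
* $C_2 E T$ enters only as a product; $E$ and $T$ are not separately
  identifiable from a single trajectory.
* The time offset $t_0$ and $T_c$ are weakly coupled for records that
  start far up the filling curve; recovery contracts are stated for the
  preset conditions.
* Chart placement is unreliable for patients on glaucoma drops (the drops
  move IOP independently of bleb geometry) and invalid for leaking blebs;
  both are flagged, not silently graded.
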