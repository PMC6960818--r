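---
title: "Hybrid drift and interference calibration for ISE arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid drift and interference calibration for ISE arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridcal)
```

## The measurement problem

Closed hydroponic systems recirculate their nutrient solution, so the
individual macronutrients — nitrate, potassium, calcium and magnesium —
must be monitored continuously rather than by occasional laboratory
analysis. Ion-selective electrodes (ISEs) are the natural sensor: cheap,
fast, and responsive to a single ion. Two failure modes stand between an
ISE array and routine use:

* **drift** — the electrode's offset (and, more slowly, its sensitivity)
  wanders over hours to days, so a calibration taken yesterday mispredicts
  today; and
* **interference** — a real membrane also responds to chemically similar
  ions, so the measured potential reflects a mixture, not one analyte.

`hybridcal` implements a two-stage treatment: per-measurement **two-point
normalization (TPN)** to cancel drift, and a small **feed-forward neural
network** trained by Levenberg–Marquardt to untangle interference across
the whole array (an electronic-tongue style multivariate calibration). The
hybrid pipeline (TPN-corrected EMFs into the network) is the headline
method; TPN-only and raw-EMF network calibrations are retained as the two
baselines it is compared against.

Because no public data set of raw EMF recordings exists for this kind of
campaign, the package carries a physics-motivated simulator so every stage
is testable end to end without hardware.

## Response model

Each electrode ideally follows the simplified Nernst equation

$$\mathrm{EMF} = E_O + E_J + S \log_{10} a_i,$$

with $E_O + E_J$ the lumped standard and liquid-junction potential (mV),
$S$ the slope in mV/decade ($59.16/z_i$ at 25 °C for charge $z_i$), and
$a_i$ the activity of the target ion. The simulator generates the realistic
departure from this ideal with a Nikolsky–Eisenman response,

$$\mathrm{EMF} = g(s)\,S \log_{10}\!\Big(a_i + \sum_j K_{ij}\, a_j^{z_i/z_j}\Big)
 + E_O + E_J + d(s) + \varepsilon,$$

where $K_{ij}$ are potentiometric selectivity coefficients, $g(s)$ and
$d(s)$ are gain and offset drift trajectories over the measurement step
$s$, and $\varepsilon \sim N(0, \sigma)$ is measurement noise. Activities
are approximated by molar concentrations (ideal-solution assumption); a
Davies-type activity coefficient is available through
`activity_coefficient()` but is off by default, because the calibration
model itself is stated in terms of activity with no ionic-strength
correction.

### Simulator defaults and what they emulate

| Quantity | Default | Why |
|---|---|---|
| Electrode array | 3 × NO3, 3 × K, 2 × Ca + EC probe | replicated ISEs plus conductivity as the 9th channel |
| Slopes | −57.2 / 56.4 / 27.6 mV/decade | slightly sub-Nernstian, as real PVC membranes are |
| Noise | 0.5 mV SD | typical short-term ISE noise |
| Offset drift | 0.15–0.45 mV per measurement step, random sign per electrode | 5–15 mV wander over a ~35-measurement campaign |
| Gain drift | at most 3 × 10⁻⁴ per step | sensitivities stay nearly constant (~1 % per campaign) |
| log K(Ca,Mg) | −0.7 | Mg is chemically close to Ca; this is the channel that lets Mg be inferred at all |
| log K(NO3,Cl) | −1.5; log K(K,NH4) −1.8; others −4 | typical literature magnitudes for these membrane chemistries |
| EC model | Kohlrausch sum of limiting equivalent conductivities | additive, linear at hydroponic dilutions |

Counter-ions are derived stoichiometrically from the preparation salts
(ammonium nitrate, potassium sulfate, calcium chloride, magnesium
sulfate) on top of a fixed half-strength Hoagland + tap-water background,
so the interference and conductivity channels are chemically coherent:
every milligram of Mg drags sulfate into the conductivity signal, every
milligram of Ca drags chloride into the nitrate electrode's field of view.

What the simulator deliberately does **not** model: response-time
kinetics, temperature and pH effects, membrane ageing, electrode death,
and sample-to-sample variation of the background matrix (all field
samples share the training background). Passing tests therefore
demonstrate the algorithmic properties of the methods under controlled,
chemically plausible conditions — not hardware performance on real
greenhouse samples, whose matrices vary in ways this generator holds
fixed.

## Two-point normalization

Before each sample, every electrode reads a low and a high single-salt
standard of its target ion (100/1000, 30/300, 24/240, 10/100 mg/L for
NO3, K, Ca, Mg). With reference EMFs $E^{ref}$ from the stored
calibration curve and measured EMFs $E^{meas}$ from the session, a raw
reading $E$ is corrected in two steps:

1. *sensitivity*: $E' = E \cdot r$ with
   $r = (E^{ref}_{hi} - E^{ref}_{lo})/(E^{meas}_{hi} - E^{meas}_{lo})$;
2. *offset*: $E'' = E' - (E^{meas}_{hi}\, r - E^{ref}_{hi})$, which pins
   the high standard exactly onto the reference curve.

For a Nernstian electrode under any gain $g > 0$ and offset $d$ this is an
algebraic identity: substituting $E^{meas} = g\,E^{true} + d$ gives
$E'' = E^{true}$ exactly. The offset step's direction is stated ambiguously
in words in the field's descriptions; the sign used here is the one that
makes the identity case exact and maps the high standard onto its
reference point (`tpn_correct()`'s documented contract, pinned by tests).
Corrected EMFs are inverted through the Nernst model and converted to
mg/L; replicate electrodes are averaged as concentrations (the
unweighted mean), because concentrations, not EMFs, are the reported
quantity. Predictions are never clamped; values far outside the
calibrated range are flagged. A dead electrode (equal standard readings)
is an error, and can be excluded explicitly, with a warning about the
reduced averaging basis.

TPN has no access to ions without an electrode: magnesium is reported as
*not measurable* by this method.

## The network and its training

The network maps the 9 signals (8 EMFs + EC, min–max scaled to $[0,1]$
by $X_r = (X_s - X_{min})/(X_{max} - X_{min})$) to the 4 concentrations
(also min–max scaled, so all ions weigh comparably in the joint loss).
The default structure is one hidden layer of 14 tansig neurons with a
linear output layer; `structure_search()` reproduces the two-phase
selection protocol — depths {1, 2, 3, 5, 10} at 10 neurons per layer,
then widths 8–16 in steps of 2 at the winning depth, each cell trained in
triplicate, tansig up to 3 layers and ReLU beyond (tanh's bounded output
attenuates signal through deep stacks). Ties go to the smaller structure.

Training is damped Gauss–Newton (Levenberg–Marquardt) on the summed
squared error, with an analytic back-propagated Jacobian of the outputs
with respect to all weights:

* damping $\lambda$ starts at 0.01 — the conventional "learning rate" of
  this optimizer — and is divided by 10 on each accepted step and
  multiplied by 10 on each rejected one, so the accepted-loss trace is
  non-increasing by construction;
* stopping: relative SSE change below 10⁻⁹, 300 accepted epochs
  (campaign default), or $\lambda > 10^{10}$;
* weights initialise uniformly in $[-0.5, 0.5]/\sqrt{fan\_in}$, seeded.

Two guards address the small-sample regime (a 200-parameter network and a
27-solution design): **validation early stopping** and **seeded
restarts**. The campaign runner holds out one full replicate iteration of
the training sweep — the same 27 solutions, fresh noise — as a validation
set. This keeps every design point in the training set (no coverage
loss) while making noise interpolation visible: as the network starts
fitting the training iteration's noise, the held-out iteration's SSE
rises, and the weights at the validation minimum are restored. Without
this guard the network interpolates the lattice and its between-point
oscillations dominate field error. Three seeded initialisations are
trained and the one with the lowest validation SSE kept, because
Gauss–Newton descent on a non-convex loss is sensitive to its starting
point (the same reason the structure search trains each cell in
triplicate).

## The simulated campaign

`run_experiment()` reproduces a full campaign from one master seed
(per-stage streams are derived from it, so stages are independently
reproducible):

1. the 3^(4−1) fractional factorial training design — 27 mixtures, every
   factor level 9 times, main effects orthogonal (generator
   $D = A + B + C \bmod 3$; any regular fraction is equivalent for main
   effects);
2. drift trajectories assigned to the array;
3. the training session, drift on — the raw-EMF network is exposed to
   drift exactly as a real campaign would be — with three replicate
   iterations per solution, normalization standards re-measured before
   every sample under the current drift state;
4. eight field samples drawn uniformly inside the calibrated ranges
   (real hydroponic samples can fall below the calibrated range, where
   log-inversion is unreliable; held-out evaluation stays inside it),
   measured in triplicate with drift continuing where training ended;
5. the three methods: TPN, raw-EMF network, and the hybrid;
6. the evaluation report.

Metrics follow the field's conventions: RMSE with the population-N
denominator; replicate CV as the pooled per-sample SD (N−1 denominator)
over the grand mean × 100, with the per-sample-averaged CV reported
alongside since the aggregation is ambiguous in common usage; and OLS of
*reference on prediction* with a t-based 95 % slope CI, the orientation
in which method biases appear as slopes away from 1.

```{r campaign, eval = FALSE}
ex <- run_experiment(default_config(seed = 7))
ex$report
autoplot(ex)
```

## What the methods are expected to do

The three methods decompose the two error sources:

* the **raw-EMF network** is trained on drifting signals and predicts at
  later drift states, so it degrades badly whenever drift is material;
* **TPN** cancels drift exactly (the algebraic identity above) but
  inherits every interference bias — most visibly for Ca, where the Mg
  cross-sensitivity inflates the apparent Ca activity;
* the **hybrid** sees drift-corrected, distribution-stable inputs and
  learns the interference structure from the designed mixtures.

In this simulator the hybrid's advantage is decisive for Ca (strong,
learnable Mg interference) and for Mg itself; for NO3 and K the
default interference coefficients are mild enough that a well-averaged TPN is
already accurate to ~2–3 % of range, which is at or below the estimation
floor of a network trained on 27 designed solutions — so the hybrid
matches rather than dominates TPN there. `replicate_method_comparison()`
quantifies this over independently seeded campaigns and
`summarize_ordering()` reports how often the hybrid attains the lowest
RMSE.

Magnesium deserves its own demonstration. No Mg electrode exists; the
network infers Mg from the Ca electrodes' Mg response and from the
conductivity Mg (with its sulfate counter-ion) contributes.
`mg_inference_study()` runs the campaign twice — channels enabled and
both zeroed — with 24 field samples rather than 8, so the R² contrast is
estimated stably rather than dominated by small-sample chance
correlation. With the channels enabled the predicted Mg tracks the truth;
with them zeroed no Mg information reaches the array and R² collapses,
confirming that the inference works through the stated physical
mechanism rather than an artifact.

```{r mg, eval = FALSE}
mg_inference_study(seed = 101)
```

## Numerical and design choices

* **Problem sizes.** Campaign: 27 training solutions × 3 iterations,
  8 field samples × 3 iterations; method-comparison studies use 20
  seeded replications; the Mg mechanism study uses 24 field samples.
  The structure search trains 30 networks (10 cells × 3 replicates).
* **Tie-breaks.** Structure search: equal mean RMSE goes to the smaller
  structure. Replicate electrode averaging is unweighted.
* **Degenerate inputs.** Dead electrodes (zero standard span) abort the
  correction with a named error; missing normalization pairs, missing
  signal columns, duplicate standards and constant scaler features are
  all named errors rather than silent NA propagation.
* **Phase-1 width.** The depth scan fixes 10 hidden neurons per layer;
  the architecture has 9 inputs and 4 outputs throughout.
* **Training fit vs held-out fit.** All 27 design solutions are used for
  training (with the replicate-iteration validation split described
  above); generalisation is always reported on separately generated
  field samples.
* **Output scaling.** Outputs are min–max scaled with their own scaler;
  predictions are mapped back to mg/L and reported unclamped.
* **Serialization.** Models round-trip through JSON (weights, biases,
  activations, both scalers, training metadata); sessions and
  predictions through strict-header CSV; configurations through YAML.

## Limitations

The simulator is a controlled analogue, not a digital twin: its drift is
piecewise-linear per measurement step, its interference coefficients are
fixed literature-scale constants, its backgrounds do not vary between
field samples, and its EC model is ideal Kohlrausch mixing. Conclusions
about *relative* method behaviour under drift and interference transfer
to real arrays; absolute RMSE values do not. The TPN inversion assumes
the stored calibration slope remains meaningful (gain drift is corrected,
but a membrane that has lost its log-linear response altogether is out of
scope), and the network methods assume field samples lie inside the
calibrated concentration ranges.
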