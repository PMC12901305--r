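---
title: "Seated whole-body vibration biodynamics: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seated whole-body vibration biodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrobody)
```

## The model

A seated person exposed to vertical seat vibration is represented as a
lumped-parameter system: rigid segment masses $m_i$ connected by linear
spring-damper pairs $(k_i, c_i)$, with one coupling attaching the body
to the vibrating seat. The bundled 10-DOF seated-female model places a
vertical chain head(1)–thorax(2)–abdomen(3)–pelvis(4)–seat and two arm
branches (upper arm–forearm–hand) hanging from the thorax, one per
side. Newton's second law per segment gives
$$M\ddot z + C\dot z + K z = f_z,$$
where $M$ is diagonal, $K$ and $C$ carry the usual coupling stencil
(off-diagonal $-k$ between coupled segments, sums on the diagonal), and
the seat coupling $(k_4, c_4)$ contributes only to the diagonal of the
pelvis row, with the excitation entering through the force vector
$f_z = (k_4 + j\omega c_4)\,Z_0\,e_4$ for harmonic seat motion
$z_0 = Z_0 e^{j\omega t}$. Consequently every row of $K$ sums to zero
except the pelvis row, which sums to $k_4$ — the ground connection is
the only path to the seat. `assemble_system()` builds the matrices from
the coupling list; the stencil is the single source of truth, so
symmetry of $K$ and $C$ holds bitwise by construction.

Assumptions worth keeping in mind: purely vertical motion, linear
elements, rigid segments, constant posture. Fore–aft/lateral axes,
backrest and cushion sub-models, and nonlinear tissue behaviour are out
of scope.

## Biodynamic responses

`biodynamic_curves()` solves
$(-\omega^2 M + j\omega C + K)Z = f_z$
on a frequency grid and reports the three standard seated-body transfer
functions:

* **STHT** $= Z_1/Z_0$ — seat-to-head transmissibility, dimensionless;
* **DPMI** $= F/(j\omega Z_0)$ — driving-point mechanical impedance,
  N·s/m, with $F = (k_4 + j\omega c_4)(Z_0 - Z_4)$ the force
  transmitted through the seat coupling;
* **AM** $= F/(-\omega^2 Z_0)$ — apparent mass, kg.

A genuinely open design point is which motion belongs in the DPMI/AM
denominators. The literal "driving location (pelvis)" reading divides
by the pelvis response $Z_4$; but then the apparent mass loses its
textbook static limit. Dividing by the seat motion $Z_0$ — the
seat–body interface being the driving point — gives
$\mathrm{AM}(f\to 0) = \sum m_i$ exactly (the transmitted force is the
only external force, so quasi-statically it accelerates the whole
mass), which is how apparent-mass data are universally normalized and
gives an analytic limit the tests can pin down. The package defaults to
the seat convention; `driving_point = "pelvis"` exposes the literal
reading. The identity $\mathrm{DPMI} = j\omega\,\mathrm{AM}$ holds at
machine precision under either convention and is asserted as such.

The default grid is 0.5–20 Hz in 0.1 Hz steps (196 points): the band
where seated humans are most vibration-sensitive. The step is this
package's choice; only the span is prescribed by the underlying study.
$\omega = 0$ is never evaluated — the static behaviour is checked as a
limit at low frequency (0.05 Hz, where the apparent mass of any
constrained set is within 1% of the 54 kg total).

## Constraints and their projection

Calibration of the female model operates on a flat 30-vector
$(m_{1..10}, k_{1..10}, c_{1..10})$ under the anthropometric constraint
block: $\sum m_i = 54$ kg, left/right equalities
($m_5{=}m_8$, $m_6{=}m_9$, $m_7{=}m_{10}$, same for $k$ and $c$), and
bounds $k \in (100, 3\times10^5)$ N/m, $c \in (500, 4000)$ N·s/m.
Although the equalities reduce the free dimension to 21, the optimizer
works on the full 30-vector and enforces feasibility by projection
after every move, matching the stated variable size of the original
calibration. `project_constraints()` applies symmetry averaging, then
bound clipping, then multiplicative mass rescaling — rescaling last so
the sum constraint holds exactly on output. Masses have no published
bounds; the package clips them to $[0.1, 54]$ kg before rescaling
(non-physical zero or negative masses are excluded, the sum constraint
stays authoritative). Masses that the rescale would push below the
0.1 kg floor are pinned there and only the free masses rescaled, which
makes the projection idempotent — a property the test suite checks on
random vectors.

## The Firefly Algorithm calibrator

No installed optimizer provides the constrained firefly scheme, so
`firefly_optimize()` implements the canonical formulation: fireflies
live in the unit hypercube (each parameter scaled to its bounds),
brightness is the negated objective, and a dimmer firefly $i$ moves
toward a brighter $j$ as
$$x_i \leftarrow x_i + \beta_0 e^{-\gamma r^2}(x_j - x_i) + \alpha u,
\quad u \sim U(-0.5, 0.5)^d,$$
with $r$ the Euclidean distance in scaled space. Defaults follow the
published setup: swarm 100, 50 iterations, $\alpha = 0.2$ (the
"mutation coefficient", read as the randomization coefficient of the
canonical formulation), $\gamma = 0.8$, and $\beta_0 = 1$ (unstated in
the source; the canonical default). $\alpha$ is held fixed — no decay
schedule. Within an iteration the pairwise pass uses brightness values
frozen at the iteration start, the iteration-best firefly performs a
pure random walk, and each firefly is re-projected and re-evaluated
once per iteration, so a swarm-100, 50-iteration run costs 5100
objective evaluations. The best-so-far solution is tracked, making the
convergence history non-increasing by construction.

Two settings needed interpretation:

* **Stopping.** The published "tolerance limit 0.0001" is implemented
  as a convergence target on the objective: stop once the best
  objective falls to or below it. An improvement-based reading was
  tried first and rejected: a stochastic swarm routinely has an early
  zero-improvement iteration, which would halt runs at a handful of
  iterations and contradicts the 50-iteration convergence behaviour
  the calibration is described with.
* **Objective scale.** The objective is the weighted squared-error sum
  over the frequency grid,
  $F = \sum_i \lambda_1 \Delta\mathrm{STHT}_i^2 +
  \lambda_2 \Delta\mathrm{DPMI}_i^2 + \lambda_3 \Delta\mathrm{AM}_i^2$
  with equal default weights. (The index runs over grid points: the
  residual terms are defined per frequency, and the companion
  goodness-of-fit formulas use $N$ as the number of data points.) On
  raw scales DPMI (thousands of N·s/m) dominates STHT (near 1), so the
  literal equation effectively prioritizes impedance.
  `normalize = TRUE` divides each response's residuals by its mean
  target magnitude; the default is off to match the literal
  definition, and the flag is the documented remedy.

## Goodness of fit

For each response,
$\varepsilon = 1 - \sqrt{\sum(\tau_e - \tau_p)^2/(N-2)} \big/
(\sum \tau_e / N)$: one minus the residual RMS (with an $N-2$
denominator) relative to the mean target level. It is 1 exactly for
identical curves, scale-covariant, and deliberately not clipped below
(historical models score as low as 0.56 on impedance, so negative or
small values are meaningful). The overall score is the weighted sum of
the three $\varepsilon$ values — the arithmetic mean under equal
weights. The report also carries the sample variance ($N-1$
denominator) of the three values as a dispersion indicator; the
source's "variance" column is undefined in its text and matches either
variance definition only to one significant figure, so nothing is
keyed on it. Values are stored on the 0–1 scale and multiplied by 100
for display.

## Synthetic targets and what passing tests show

The experimental curves the original calibration was fitted to are not
published, so `generate_targets()` stands in for them: it
forward-models the magnitude curves from a known constrained parameter
set and multiplies each point by an independent lognormal factor with
unit median and coefficient of variation `noise_cv` (multiplicative,
because magnitude curves are positive and their measurement error
scales with level; the underlying study states no noise model). The
bundled ground truth (`inst/extdata/female_10dof_synthetic.yaml`) uses
the published first-iteration segment masses — the one printed row
consistent with the 54 kg mass constraint — with every stiffness and
damping at the arithmetic midpoint of its bounds (150050 N/m,
2250 N·s/m). That set is illustrative, not fitted; it places the
principal STHT resonance at 5.4 Hz, inside the 3–6 Hz band reported
for seated humans. A second fixture
(`female_10dof_table_iter1.yaml`) preserves a best-effort parse of the
published first-iteration stiffness/damping tables, whose undelimited
digit runs are ambiguous (its $k_4$ reads as 820000 N/m, violating the
source's own bound); it is shipped for reference and used nowhere.

Parameter recovery on noiseless synthetic targets is the package's
closed-loop validation: the truth evaluates to objective 0 and
goodness of fit 1 exactly, and a full seeded swarm run reattains the
response curves (weighted goodness of fit above 0.95; measured 0.973
at seed 1). Two caveats on interpretation. First, the model is only
partially identifiable from magnitude curves — arm parameters barely
influence the vertical responses — so recovery is judged on curves,
not on parameter equality. Second, a fixed-$\alpha$ swarm keeps
jittering by about a tenth of each parameter range and therefore
plateaus: the raw objective settles near $2\times10^4$
(about 2% RMS relative error), not near zero.
Passing these tests shows the pipeline is consistent and the optimizer
effective at curve level; it says nothing about fit quality to real
female subjects, inter-subject variability, or multi-axis excitation.

## Modal analysis and sensitivity

`undamped_modes()` solves $K\varphi = \omega^2 M \varphi$ through the
mass-normalized symmetric form (exact for a diagonal $M$). Mode shapes
are normalized to unit maximum absolute entry with a positive leading
sign — published mode tables are inconsistently scaled, so comparisons
are only meaningful up to scale. Damped complex modes are out of
scope; "natural frequency" here means the undamped value. The
stiffness- and mass-scaling laws ($f \propto \sqrt{s}$ under
$K \to sK$, $f \propto 1/\sqrt{s}$ under $M \to sM$) are asserted to
1e-10 relative as independent oracles.

The sensitivity analysis announced for the original model is never
described there, so `oat_sensitivity()` defines it minimally and
explicitly as this package's own procedure: one-at-a-time perturbation
of each of the 30 parameters by given fractions, re-projection onto
the constraint set (optional, default on), and the relative change of
each response's peak magnitude and the shift of its peak frequency.
Left/right symmetric parameters produce identical rows by model
symmetry, which doubles as a structural test.

## Numerical choices

* Complex linear systems are solved densely per frequency point by
  LAPACK (`solve()`); at 10 DOF there is nothing to gain from
  structure exploitation.
* Peak detection is the grid argmax with ties resolved to the lower
  frequency.
* Eigenvalue noise below $10^{-9}$ relative around the rigid-body zero
  is clamped to zero.
* All randomness (swarm initialization, firefly moves, target noise)
  flows through R's RNG under a caller-supplied seed; identical seeds
  give bit-identical histories, and seeds are echoed into results.
* Test and example problem sizes: the full recovery experiment runs
  swarm 100 for 50 iterations on the 196-point grid (about 5100
  objective evaluations); unit tests use coarser grids (1 Hz step) and
  small swarms, sized to exercise the code paths rather than the
  optimizer's limits.

## Known limitations

Single-axis, linear, posture-fixed model; no cushion/backrest; no
time-domain or random-vibration input; no damped modal analysis. The
calibrator is a plain canonical firefly scheme — no alpha decay,
restarts or hybridization — so its late-stage refinement is limited,
as quantified above. The bundled parameter values are a synthetic
stand-in with published masses and midpoint coupling coefficients, not
a validated female parameter set.
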