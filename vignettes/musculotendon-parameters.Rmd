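---
title: "Musculotendon parameters: derivation, force sensitivity and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Musculotendon parameters: derivation, force sensitivity and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsens)
```

## The model

`mtsens` works with the isometric, rigid-tendon specialization of the
Hill-type muscle contraction dynamics. The force a muscle develops at MTU
(muscle-tendon unit) length $l^{mt}$ and activation $a \in [0,1]$ is

$$F(l^{mt}, a) = F_{iso,max}\,\cos\alpha(l^{mt})\,
  \bigl(f_{pe}(l^f_{norm}) + a\, f_{ce}(l^f_{norm})\bigr),$$

with the four musculotendon parameters: maximal isometric force
$F_{iso,max}$ (N), optimal fiber length $l^f_{opt}$ (m), optimal pennation
angle $\alpha_{opt}$ (rad), and tendon slack length $l^t_{sla}$ (m). Under
the rigid-tendon assumption all MTU length change is absorbed by the fiber,
and under the constant-muscle-thickness assumption the fiber's perpendicular
height $w = l^f_{opt}\sin\alpha_{opt}$ is invariant, so

$$l^f = \sqrt{(l^{mt} - l^t_{sla})^2 + w^2}, \qquad
  \alpha(l^{mt}) = \operatorname{atan2}(w,\; l^{mt} - l^t_{sla}), \qquad
  l^f_{norm} = l^f / l^f_{opt}.$$

We compute the fiber length by this geometric (square-root) form rather than
the equivalent projection form $(l^{mt}-l^t_{sla})/(l^f_{opt}\cos\alpha)$: the
two agree to machine precision wherever the projection is defined, but the
geometric form stays well behaved when a pennated MTU shortens past its slack
length. The force-velocity multiplier is fixed at 1; `muscle_force()` exposes
it as an `f_v` hook, but nothing in this package models velocity dependence.

Tendon slack length is never stored independently. It is always the dependent
quantity

$$l^t_{sla} = l^{mt}_{opt} - l^f_{opt}\cos\alpha_{opt},$$

where $l^{mt}_{opt}$ is the MTU length at the *optimal joint position* — the
joint configuration at which the fiber reaches optimal length. Choosing the
slack length is therefore equivalent to choosing that joint position: the
parameter acts as a phase shift of the expressed force-length curve, not as an
anatomical tendon measurement. This view drives both the sensitivity analysis
and the calibration design below.

## Characteristic curves

The force-length curves are dimensionless, peak-normalized, and pluggable
(`mt_curves()`), with analytic first derivatives because the sensitivity and
calibration modules differentiate through them:

* active: $f_{ce}(l) = \exp(-(l-1)^2/\gamma)$ with width $\gamma = 0.45$ —
  peak 1 at optimal length, zero slope there;
* passive: an exponential anchored at the conventional strain defaults
  (force develops at strain $e_0 = 0$, reaches the maximal isometric value at
  strain $e_{max} = 0.7$): with $x = (l - 1 - e_0)/(e_{max}-e_0)$ and
  $k = 4$,
  $$f_{pe}(l) = \frac{e^{kx} - 1 - kx - (kx)^2/2}{e^{k} - 1 - k - k^2/2},
  \quad x > 0,$$
  and zero below.

Subtracting the linear *and quadratic* terms of the exponential makes the
passive value, slope and curvature all vanish at the slack point, so the
curve is $C^2$ on the working range. This is a numerical design choice, not
cosmetics: the analytic partial derivatives are verified against central
finite differences of the force to a relative tolerance of $10^{-5}$, and a
curvature jump at $l_{norm} = 1$ (as in the plain $(e^{kx}-1)/(e^k-1)$ form)
injects an $O(h)$ artifact into any finite-difference stencil straddling the
slack point, which shows up precisely at the most-used operating point of the
model. The $C^2$ form keeps the same anchors and a nearly identical shape.

Curve shapes differ across published models and are rarely measured per
muscle; every headline quantity in the package that is meant to be
curve-independent (the derivation worked examples, the parameter-consistency
identities) indeed never touches `mt_curves()`.

## Deriving parameters from architecture measurements

Raw muscle-architecture measurements are taken at an arbitrary fixation
position, not at maximal force exertion, so they must be *optimally scaled*
before use as model parameters:

* **Fiber length** scales linearly with sarcomere length (fibers are serial
  chains of sarcomeres): `scale_fiber_length()` multiplies the raw fiber
  length by $l^s_{opt}/l^s_{raw}$. The default optimal sarcomere length is
  2.7 µm (human estimates cluster in 2.6–2.8 µm), configurable within
  2.2–3.2 µm.
* **Pennation** has no linear relation with sarcomere length; the
  constant-thickness model gives
  $\alpha_{opt} = \arcsin(l^s_{meas}\sin\alpha_{meas}/l^s_{opt})$
  (`scale_pennation()`). The classic soleus-style correction takes 28.3°
  measured at 2.12 µm to 21.9° — about a 5% change in the cosine that scales
  transmitted force.
* **PCSA** is volume over optimal fiber length (`pcsa_conventional()`), or
  additionally times $\cos\alpha_{opt}$ (`pcsa_projected()`). Both
  definitions are exposed and neither is declared correct: the choice only
  matters for strongly pennated muscles, and the field has not settled it.
  Note: one printed form of the projected definition multiplies by the angle
  itself rather than its cosine; the accompanying text makes clear the cosine
  is intended, and that is what the implementation uses.
* **Maximal isometric force** is specific tension times PCSA
  (`max_isometric_force()`). Specific tension is per-record, never global: a
  uniform tension is just a constant column, but non-uniform tensions (e.g.
  slow-twitch soleus vs. gastrocnemius) are expressible. A tension tuned
  against raw-length PCSAs must be rescaled by the fiber-length ratio when
  fibers are later scaled to optimality (`rescale_specific_tension()`; the
  classic 61 N/cm² becomes 78 N/cm² under a 2.8/2.2 rescale).
* **Tendon slack length** comes from the optimal-position MTU length via the
  phase-shift relation (`tendon_slack_length()`).

`derive_dataset()` composes these steps over a table of records and writes a
per-muscle derivation log: every applied or omitted scaling step is recorded,
so the simplifications that the provenance audit (below) grades are visible in
the pipeline itself rather than silent. Two policies are worth stating:

* When projected PCSA is requested together with sarcomere scaling, the
  *scaled* pennation angle is used, avoiding the legacy "fixed pennation
  angle" simplification; a compatibility switch
  (`projected_uses_raw_pennation`) reproduces the legacy behavior for audits.
* When both a reported PCSA and a muscle volume are present, the volume-based
  recomputation wins and the discrepancy is logged, mirroring how careful
  model builders have recomputed PCSAs from source volumes.

## Sensitivity: analytic partial derivatives

The package provides closed-form partial derivatives of $F$ with respect to
each parameter, with shared intermediates $E_1 = f_{pe} + a f_{ce}$,
$E_2 = \partial f_{pe}/\partial l_{norm} + a\,\partial f_{ce}/\partial
l_{norm}$, $E_3 = (l^{mt}-l^t_{sla})^2 + w^2$:

* `dF_dlopt_fixed_pcsa()` — w.r.t. $l^f_{opt}$ with $F_{iso,max}$ independent;
* `dF_dlopt_volume_pcsa()` — w.r.t. $l^f_{opt}$ with volume-coupled capacity
  $F_{iso,max} = \sigma V / l^f_{opt}$;
* `dF_dalpha_opt()` — w.r.t. $\alpha_{opt}$; carries an overall
  $\sin\alpha_{opt}$ factor and vanishes at zero pennation (pennation has no
  first-order effect there);
* `dF_dlopt_mt()` — w.r.t. $l^{mt}_{opt}$, the tendon-side parameter; at zero
  pennation it reduces to the pure curve-shift term $-F_{iso,max}E_2/l^f_{opt}$.

**Differentiation convention.** $l^{mt}_{opt}$ is the free tendon-side
parameter and $l^t_{sla}$ is always the dependent quantity; perturbing
$l^f_{opt}$ or $\alpha_{opt}$ therefore also moves the slack length through
the phase-shift relation. This convention is what the printed fixed-PCSA
fiber-length derivative corresponds to, as verified by the finite-difference
oracle.

**A note on expression labelling.** In the source material the two
expressions for the pennation and tendon-side derivatives appear with their
labels interchanged: the expression printed for the pennation derivative has
no $\sin\alpha_{opt}$ prefactor and is nonzero at zero pennation, while the
one printed for the tendon-side derivative carries that prefactor.
Independent symbolic re-derivation and the finite-difference oracle agree:
the prefactor-free expression is the tendon-side derivative and the
$\sin\alpha_{opt}$-prefactored one is the pennation derivative. The
implementation assigns them accordingly, and the test suite pins the
assignment with both the oracle and the zero-pennation symmetry argument.

`fd_gradient()` is the independent oracle: an $O(h^2)$ central difference of
`muscle_force()` honouring the same coupling, with default step
$10^{-7}\times$ the parameter magnitude (floored at $10^{-4}$ rad for the
pennation angle so a zero angle still gets a step that beats round-off), and
an $O(h^2)$ one-sided stencil when the feasible boundary blocks one side. It
is used in tests and diagnostics only, never as a production gradient.

`normalized_derivative()` maps everything to the dimensionless
$(\partial F/\partial\theta)\,\theta / F_{iso,max}$ — the fractional change
in force capacity per fractional parameter change. On this scale the impact
ordering is stark and robust across pennation angles 0–30° and
tendon-to-fiber length ratios 3–10:

$$\Bigl|\frac{\partial F}{\partial l^{mt}_{opt}}\Bigr|_{norm} \;>\;
  \Bigl|\frac{\partial F}{\partial l^f_{opt}}\Bigr|_{norm} \;>\;
  \Bigl|\frac{\partial F}{\partial \alpha_{opt}}\Bigr|_{norm}$$

(maxima over normalized fiber lengths 0.35–1.5). The tendon-side parameter
dominates because its normalized sensitivity is amplified by the large
$l^{mt}_{opt}/l^f_{opt}$ ratio: a 1% error in where fiber optimality sits
shifts the whole expressed force-length curve by a substantial fraction of a
fiber length. Pennation is least impactful: its effect is essentially the
cosine of a small angle. `sensitivity_ranking()` computes this ordering;
`sensitivity_grid()` tabulates normalized sensitivities over a parameter x
length grid for heatmaps (`autoplot()`).

**Sweep coupling.** `sweep_force_curves()` answers a different question from
the derivatives: what happens to the force-length curve when one *model
parameter* is mis-set. The four Hill parameters enter the model as
independent inputs, so the sweep holds tendon slack length fixed while fiber
length or pennation is varied, and only the tendon-side id moves it. (The
derivatives keep the derivation-time convention above; the two conventions
answer different questions and both are tested against the oracle in their
own terms.) Sweeps default to maximal activation over normalized fiber
lengths 0.35–1.50 at 200 points, with ±10%/±20% force-capacity reference
bands — the standard one-at-a-time presentation.

One quantitative caveat surfaced by the tests: for a pennation change from 0°
to 20°, the force change is *not quite* bounded by the cosine gap
$1-\cos 20° = 6.03\%$ of $F_{iso,max}$. Under the constant-thickness model a
pennated fiber at the same MTU length is also slightly longer, and just past
the optimum this compounds with the cosine loss; with the default active
curve width the maximum change is ≈6.9% of $F_{iso,max}$. The size of the
compounding term depends on the curve shape (steeper descending limbs make it
larger), so statements like "pennation errors within 20° are negligible"
should be read as cosine-order, not as an exact 6% ceiling. The package's
acceptance test for this property asserts the stricter cosine-order bound
(6.5%) and is expected to fail at exactly the 20° corner with the default
curves; we left the assertion strict rather than widening it after measuring.

## Calibration

Anatomical measurements alone cannot pin down the parameters — especially the
tendon-side one, which is not anatomically measurable in the modeling sense —
so the derivatives are wired up as calibration gradients against force
observations. `loss_and_gradient()` uses a weighted mean squared force
residual $L = n^{-1}\sum_i w_i (F_i - F^{obs}_i)^2$ (so doubling all weights
doubles the loss but not the minimizer), with the gradient assembled from the
analytic derivatives plus $\partial F/\partial F_{iso,max} = F/F_{iso,max}$.

`calibrate()` is a bounded quasi-Newton scheme: BFGS with Armijo backtracking
in smoothly bounded coordinates — a scaled logit over each parameter's box,
chain-ruled into the gradient — so every iterate is feasible and the accepted
loss trajectory is monotone non-increasing by construction. Defaults: angle
bounds 0–45°, a factor-of-3 box around the initial value for lengths,
factor-of-10 for force capacity, 200 iterations, gradient tolerance
$10^{-8}$ (about the smallest gradient the squared loss resolves in double
precision on noisy data). Reaching the cap yields a non-converged result, not an error; a
run is deterministic given its inputs. The source material prescribes only
"gradient descent"; the specific scheme is this package's choice and these
knobs are the ones that matter. Tendon slack length is never a free parameter
directly — $l^{mt}_{opt}$ is optimized and the slack length follows, which
keeps the phase-shift interpretation intact and the feasible region simple.

Identifiability is reported, not hidden: observations spanning less than 0.1
in normalized fiber length flag the result as near-singular, and free
parameters whose initial gradient is numerically flat relative to the largest
component are flagged as potentially unidentifiable (e.g. force capacity
against purely passive, zero-force data). Observations infeasible at the
initial parameters are excluded with a warning and counted; during the
optimization, steps that would make observations infeasible are rejected by
the line search rather than silently re-weighting the data.

With the synthetic designs below (50 noiseless observations spanning
normalized fiber lengths 0.5–1.4), the recovery experiment over 20 seeded
replicates recovers $l^{mt}_{opt}$ to well under 1% and $l^f_{opt}$ to under
5% median relative error; with 2% multiplicative force noise both stay under
5%. These sizes keep the full suite within a few minutes on one CPU while
leaving the medians far from their thresholds.

## Synthetic data: what it emulates and what it does not

`synth_architecture()` draws ground-truth parameters in adult lower-limb
ranges (optimal fiber length 30–120 mm, pennation 0–30°, volume 50–900 cm³,
specific tension 61 N/cm², optimal-position MTU length at 2.5–8 fiber
lengths, raw sarcomere lengths 2.0–3.2 µm) and *inverse-scales* them into raw
measurements, so the derivation pipeline run with scaling on recovers the
truth exactly — an end-to-end oracle for the derivation code.
`synth_force_observations()` places observations on the model curve at
prescribed normalized fiber lengths and applies seeded multiplicative
Gaussian noise of a given coefficient of variation.

What passing tests on these fixtures shows: the algebra, the units, the
coupling conventions, and the optimizer are correct. What it does not show:
anything about real measurement error structure. Real architecture data have
correlated errors (digitization, fixation state, regional sarcomere
variation), fiber-type-dependent specific tensions, and curve shapes that
differ from the defaults; the generator makes none of these, by design. The
calibration recovery numbers are statements about the estimator under the
stated noise model, not about expected accuracy on cadaveric datasets.

## Provenance auditing

Nine recurring simplifications in how published datasets and models derived
their parameters are encoded as deterministic rules over explicit metadata
(`provenance_metadata()`, `audit()`): optimal-at-rest for fiber length,
pennation, and tendon slack length (three distinct findings), uniform optimal
sarcomere length, fixed pennation angle in projected PCSA, inherited fiber
length (volume and fiber length from different cohorts), inherited and
uniform specific tension, and slack-at-rest (a directly measured tendon
length used as the slack length). Uncertainty grades are
small/considerable/large and impact grades neglectable/considerable/severe;
the verbal qualifiers that escalate them are quantified with explicit,
configurable thresholds (`grade_thresholds()`): pennation is "large" above
20° — where the small-angle cosine argument starts to fail — and a raw
sarcomere is "far from optimal" beyond 10% deviation of the scaling ratio
from unity. Both tendon-side simplifications grade severe for the entire
range of motion: a slack-length error shifts the whole expressed curve, which
is exactly the sensitivity ranking's headline restated as an audit rule.

Where grade cells are merged across related rows in the source taxonomy (the
PCSA sub-rows), the mapping of grades to individual findings follows the
visual grouping; this is an interpretation and is flagged as such here. The
report's scope line states the other honest limitation: findings grade
parameter-derivation uncertainty only, never overall simulation accuracy,
which also depends on muscle paths, moment arms and other components far
outside this package. The shipped YAML packs under
`inst/extdata/provenance/` are illustrative, synthetic examples of derivation
styles — not transcriptions of any published model.

## Degenerate inputs, tie-breaks, numerical choices

* An unpennated fiber at or below slack length has nonpositive length: this
  raises an error rather than clamping (calibration stays feasible via
  bounds and line-search rejection instead).
* Normalized fiber lengths below $\sin\alpha_{opt}$ are geometrically
  unreachable under constant thickness; `mtu_length_at_norm()` returns `NA`
  and grid/sweep code flags or drops such points with a warning.
* Parameter JSON files store the dependent slack length redundantly; on load
  it is recomputed and a relative mismatch above $10^{-6}$ is an error, so
  hand-edited files fail loudly.
* All internal units are SI (m, N, rad); mm, µm, degrees, cm², cm³ and N/cm²
  appear only at file boundaries, matching how the datasets report them.
* Problem sizes in the test suite (a 180-configuration stratified derivative
  grid, 20 + 20 calibration replicates at $n = 50$, $10^4$ random geometry
  checks) were chosen as the smallest sizes that exercise every regime of the
  model; they run in a few minutes on a single CPU.

## Known limitations

* Isometric only: the force-velocity multiplier is a fixed hook, and
  compliant-tendon equilibrium, activation dynamics and musculoskeletal
  geometry (muscle paths, moment arms, joint-angle mapping) are out of scope.
  Calibration is to muscle force, not joint moments.
* The default curves are generic; figure-level reproduction of published
  sensitivity heatmaps is qualitative because the curve parameters behind
  them are not printed anywhere we could verify.
* The audit grades encode a published taxonomy with quantified thresholds;
  the thresholds are configurable precisely because the source gives
  examples, not cutoffs.
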