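---
title: "Methods: a reduced-order model of radioembolization microsphere transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order model of radioembolization microsphere transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resim)
```

## The problem

Radioembolization treats liver tumors by infusing yttrium-90-loaded
microspheres (tens of micrometres, ~50 Bq each) through a microcatheter
placed in the hepatic artery. The spheres are carried by arterial blood
into the liver's Couinaud segments (S1–S8); where they lodge determines
the absorbed dose. Planning the infusion therefore reduces to a transport
question: given the arterial tree, the per-segment perfusion, and the
catheter position and injection protocol, what fraction of the activity
reaches each segment?

`resim` answers this question at desk scale with a reduced-order (0D
network) model: instead of a full 3D Navier–Stokes solve on a
patient-specific geometry, the arterial tree is a graph of straight
cylindrical vessels, each carrying fully developed laminar (Poiseuille)
flow, and spheres are point particles advanced by Newton's second law.
The patient-specific imaging inputs (CT-derived geometry, perfusion maps,
post-treatment PET) are replaced by a synthetic-phantom generator, so the
whole pipeline — boundary conditions, flow, transport, activity
accounting, validation statistics — is testable end to end.

## Perfusion-derived boundary conditions

The arterial flow feeding segment $s$ is

$$q_s = V_{0,s}\,k^*_{1,s} + \sum_i V_{c,i}\,k_{2,i},$$

where $V_{0,s}$ is the healthy parenchyma volume (ml), $k^*_{1,s}$ the
healthy perfusion (ml/min/ml), and each tumor $i$ hosted by the segment
contributes its volume $V_{c,i}$ times its own perfusion $k_{2,i}$. A
tumor spanning several segments is bookkept as one co-located tumor per
host segment. Interfaces accept perfusions in the clinical unit
(ml/min/100 ml) and convert on read; everything internal is ml/min/ml.

Each outlet of the truncated tree irrigates one segment. A segment's
healthy volume is split equally over its outlets; tumor volume is split
by explicit non-negative proximity weights (the clinical assignment is a
judgement call, so the package makes it reproducible and injectable;
the pipeline default is equal weights because the synthetic phantom
carries no tumor coordinates). The outlet flow is then the same
perfusion formula applied to the assigned volumes, and the inlet flow is
the sum of the outlet flows. Conservation ($\sum$ outlet flows = inlet
flow) holds to rounding error by construction and is asserted at 1e-12
relative in the tests.

## Network flow

Because the outlet flows are boundary conditions, the flow in any branch
is fully determined: it is the inlet waveform scaled by the sum of the
flow fractions of the outlets downstream of that branch. No
pressure–resistance solve is needed; mass conservation at every
bifurcation and instant is structural. The inlet waveform is a truncated
Fourier pulse, mean plus two harmonics (default relative amplitudes 0.35
and 0.15, period 1 s); its cycle average equals the prescribed mean
exactly, and the default amplitudes keep the instantaneous flow strictly
positive. The waveform and heart period are configuration, not patient
assumptions.

Within a branch the axial velocity profile is quasi-steady Poiseuille,
$u(r,t) = 2U(t)\,(1-(r/R)^2)$ with $U(t) = Q(t)/\pi R^2$. Blood is
treated as a Carreau shear-thinning fluid,
$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)[1+(\lambda\dot\gamma)^2]^{(n-1)/2}$,
evaluated at the branch mean shear rate $\dot\gamma = 8U/d$. The defaults
($\mu_0 = 0.056$ Pa s, $\mu_\infty = 0.0035$ Pa s, $\lambda = 3.313$ s,
$n = 0.3568$, density 1060 kg/m³) are standard literature blood values —
they are not patient-derived and are fully configurable. No Womersley
correction is applied (quasi-steady closure); this is a documented
limitation of the reduced order.

## Microsphere transport

Spheres (default diameter 32 µm, density 1600 kg/m³ — typical resin
values, configurable) are released during the first cardiac cycle at
times uniform over one period, from the catheter lumen disc (uniform
over the lumen, centred at the tip offset), with the injection velocity
along the vessel axis. The protocol simulates four cardiac cycles at a
2 ms time step by default: one injection cycle plus three cycles for
drainage; a warning (not an error) is raised if fewer than 95% of the
spheres exit.

Each sphere obeys

$$m\,\frac{dv}{dt} = 3\pi\mu d\,(u - v) + (\rho_p - \rho_f)\,V_p\,g,$$

integrated with a drag-implicit Euler step whose still-fluid fixed point
is exactly the Stokes terminal velocity
$(\rho_p-\rho_f) g d^2/18\mu$. The sphere relaxation time
($\approx 2\times10^{-5}$ s) is far below the time step, so spheres track
the local fluid velocity plus the gravitational drift; the integrator is
nevertheless exact in that limit rather than unstable. Coupling is
one-way (dilute suspension); walls clamp the cross position (spheres
slide, no intradomain deposition), matching an exit-based tally.

### The bifurcation closure

The one genuinely 3D effect the reduced model must represent is the
split at a bifurcation: which daughter a sphere enters depends on its
position in the parent cross-section. The parent disc is partitioned by
a chord perpendicular to the projected daughter-separation axis, placed
by bisection (to 1e-10) so that the Poiseuille flux through the
daughter-1 side equals daughter 1's flow fraction. A sphere goes to the
daughter whose region contains it. Two consequences:

- with flux-weighted sphere positions, the expected split equals the
  flow split exactly — the "flow-split limit" in which particle
  distribution is determined by blood flow alone;
- an eccentric catheter tip near a bifurcation shifts the whole release
  cloud across the chord and can change the split dramatically — the
  local-factor sensitivity that distinguishes particle distribution from
  flow distribution.

On entering a daughter, a sphere's cross position is re-seeded
flux-weighted in the daughter cross-section (cross velocity reset; axial
velocity carried). This "remixing" closure was chosen over deterministic
position mapping because no deterministic map of the chord-side region
onto the daughter disc preserves flux weighting exactly; remixing makes
the flow-split limit hold in expectation at every depth, at the price of
not propagating streaming (near-wall spheres stay near-wall) across
bifurcations. Catheter-position sensitivity is therefore resolved at the
first bifurcation the release cloud meets — which is where the clinical
sensitivity lives — and statistically thereafter.

## Activity accounting

The activity reaching a segment is the activity exiting through the
outlets that irrigate it: segment percent = 100 × (segment exit counts)
/ (total exits); spheres still in transit at the end are excluded from
numerator and denominator. Percentages are converted to absolute
activity by the infused GBq and to mean concentration (Bq/ml) by the
total segment volume (healthy + tumor). Two published constants link
counts to activity — 44.48×10⁶ spheres per 3 GBq calibration vial, and
50 Bq per sphere — and they are mutually inconsistent (the vial implies
≈67.4 Bq/sphere). Both are carried independently; 50 Bq/sphere is the
accounting default, and both are echoed in every report and log.
Multiple infusions are simulated separately and combined
activity-weighted.

## Validation statistics

A simulated distribution is compared with an observed one by:

- per-segment absolute percentage-point differences and their mean;
- Spearman rank correlation (Pearson on mid-ranks; ties get average
  ranks — stated explicitly because tie handling is often left implicit);
- Bland–Altman analysis: mean difference, sample SD (n−1 denominator,
  configurable choice documented here because the convention is often
  unstated), limits of agreement mean ± 1.96·SD, and 95% confidence
  intervals — mean ± t·SD/√n for the mean and
  LoA ± t·SD·√(1/n + z²/(2(n−1))) for each limit, the standard
  Bland–Altman CI formulas.

## The synthetic world

The phantom generator replaces imaging-derived inputs with draws from
clinically reported envelopes: eight Couinaud segments with healthy
volumes in 20–400 ml, healthy perfusion 0.02–0.12 ml/min/ml, tumors of
1–70 ml with perfusion 0.35–1.30 ml/min/ml, hosted by one or two
segments. Trees are binary Murray's-law trees (exponent 3, configurable
daughter asymmetry, vessel length = 8 × radius, randomized branching
directions at 20–40°), rooted at a 2 mm-radius artery. The synthetic
"observed" distribution adds independent Gaussian noise (default 2
percentage points) to the true percentages, clamps at zero and
renormalizes — the simplest model that exercises the validation stage.

What the generator does **not** emulate: real arterial tortuosity and
curvature (and the catheter eccentricity curvature induces), anatomical
variants, correlated PET reconstruction noise and co-registration error,
embolization/stasis feedback, hepatopulmonary shunting. A green test
therefore establishes internal correctness of the stated model —
conservation, the flow-split limit, the statistics — not clinical
fidelity; the few-percentage-point agreement the synthetic recovery
experiment recovers at 2 pp injected noise is a property of the stated
noise model, not a prediction about patients.

## Numerical choices and degenerate inputs

- All generators are pure functions of (parameters, seed); the pipeline
  derives one child seed per stage from the master seed, and every
  artifact carries the seed and a configuration hash.
- Bisection for the chord offset runs to 1e-10 on the normalized
  coordinate; the Poiseuille half-plane flux uses the closed-form
  antiderivative of $(1-x^2)^{3/2}$.
- Degenerate daughter directions (parallel projections) fall back to a
  fixed reference axis with a warning; an all-zero outlet-flow phantom
  yields zero flows and flagged undefined fractions; zero exited spheres
  make the distribution undefined (error); activity assigned to a
  zero-volume segment is a hard failure.
- Outlets are processed in lexicographic id order wherever order is
  numerically irrelevant, so serialization is deterministic.
- Time step: the default 2 ms is ~100× the sphere relaxation time; the
  drag-implicit update is unconditionally stable and exact at the
  equilibria, so halving dt moves outlet fractions by less than binomial
  noise (asserted in the tests).

## Known limitations

One-way coupling; no embolization or vessel compliance; quasi-steady
profiles; the injection jet is not resolved (injection velocity enters
only as the spheres' initial velocity, relaxed by drag within one step);
remixing does not propagate near-wall streaming across bifurcations; the
synthetic observation noise is uncorrelated across segments.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 5,
                  infusions = list(list(activity_GBq = 0.5,
                                        n_particles = 5000),
                                   list(activity_GBq = 0.2,
                                        radial_offset_fraction = 0.5,
                                        n_particles = 5000)))
res <- run_pipeline(cfg)
res$report
```

Every number printed by `run_pipeline()` (inlet flow, exit fractions,
average difference, Spearman rho, limits of agreement) is recomputed at
run time; the package reports nothing it does not compute.
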