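---
title: "Membrane prestress and AFM penetration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane prestress and AFM penetration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmindent)
```

# The problem

When an AFM tip is pressed into an adherent cell, the approach force–distance
curve passes through four stages: no contact (O–A), quasi-linear elastic
loading of the cortex (A–B), an abrupt force drop when the tip punctures the
membrane (B; a second drop D can mark the nucleus), and accelerated loading
afterwards as the cytoplasm, nucleus and finally the hard substrate resist
(B–C, up to the preset retract trigger). Two quantities are extracted per
curve: the **insertion force** (force at the pre-drop maximum) and the cell's
elastic response (a Hertz modulus for spherical tips, the A–B slope for
pyramidal tips). Aggregated over repeated indentations per substrate-strain
condition, these give the **insertion rate** and its force/displacement/time
statistics — the quantities that link membrane prestress to how easily a
cell can be pierced.

This package implements that analysis end to end, plus a structural
simulation showing *why* prestress helps: tension stiffens the cytoskeletal
beams (geometric stiffness) and the membrane, so the indenting tip
concentrates stress in a small contact region instead of spreading the load.

# The synthetic-data generator

No instrument data accompany the analysis, so `generate_curve()` produces
seeded curves with exactly the statistical structure the pipeline assumes,
and its ground-truth labels are the oracle for every detector test.

**Stated world.** The five bundled conditions (`strain_conditions()`) use
the published acquisition settings — trigger force 12 nN, approach speed
1 µm/s, pyramidal tip with spring constant 0.02 N/m — and the published
per-condition penetration counts (11, 23, 31, 36, 37 of 60) and
insertion-force distributions (2.0±0.3, 1.8±0.3, 1.5±0.2, 1.0±0.2,
1.0±0.3 nN) for substrate strains of 0, 5, 10, 15, 20 %.

**The slope ties force to displacement.** The A–B stage is modelled as
exactly linear in cantilever-corrected depth, `F = s·δ`, so an event at
insertion force `F₁` occurs at displacement `δ₁ = F₁/s` by construction.
Each condition's slope is therefore fixed at mean force / mean displacement
(1.67, 2.57, 3.0, 5.0, 5.0 nN/µm) — increasing with prestress, as the
experiments report. The consequences are: mean displacement and mean time
(displacement / 1 µm/s) reproduce the published values automatically, but
the *displacement SD* is slaved to the force SD (`sd_δ = sd_F/s`) and is
smaller than the published one. A generator with independent force and
displacement scatter would need curve-to-curve slope variation; we keep the
single-slope world because the published slope trend is the quantity under
test.

**Detectability floor.** An insertion event is scored in an experiment only
when a visible force drop exists. The generator therefore truncates
insertion forces at `max(8·noise_sd, 0.3) + 0.05` nN (0.45 nN at the default
noise) and clamps drop magnitudes into `[max(8·noise_sd, 0.3), 0.95·F₁]`,
sampling them as U(0.3, 0.6)·F₁. Without the floor, a few percent of draws
at the softest conditions produce sub-noise drops that no detector can see
and the published counts become unreproducible in principle. The truncation
shifts condition means by well under 0.1 standard errors. The noise sample
immediately after a planted drop is clamped so the realised step always
exceeds 5·noise_sd, keeping labels consistent with the trace.

**Other choices** (the published account is silent on all of these):
uniform 2 nm piezo grid over a 6 µm range; contact at 1 µm (the "3–5 mm"
cell height in the source text is clearly a typo for µm — either way the
piezo range, not the cell height, bounds the trace); i.i.d. Gaussian force
noise, default SD 0.05 nN (a typical soft-cantilever thermal noise level),
no 1/f drift; post-drop loading is linear with slope
`membrane_slope / post_drop_softening` (softening default 0.7, i.e. the
post-puncture curve rises *faster*, as observed) plus a quadratic substrate
term `2 nN/µm² · (u − u₀)²` beyond `substrate_onset_depth` (default 2 µm of
piezo travel past contact) so the 12 nN trigger is always reached; a second
drop, when drawn, is placed uniformly between the first drop and the trigger.
Exact-count mode assigns the penetrating subset of a batch from a derived
seed so published fractions like 37/60 are reproduced deterministically.

**Not emulated:** retract segments (adhesion, unbinding), thermal or
instrumental drift, hydrodynamic drag, viscoelastic creep, curve-to-curve
slope heterogeneity. A green round-trip test therefore establishes that the
detectors recover what this world plants — not that they are robust to
drifting baselines or viscoelastic rounding of real instruments.

# Single-curve analysis

**Contact point.** Baseline mean and SD come from the leading non-contact
window (10 % of the trace, 50–500 samples). The crossing is the first point
where the 5-sample smoothed force exceeds baseline + 3 SD and stays above
for 10 samples; on noisy traces the estimate is refined by back-extrapolating
a short linear fit of the initial rise (capped 0.3 nN above threshold so it
never spans the first drop) to the baseline level. On noiseless curves the
raw crossing is used directly (exact to one sample); under 0.05 nN noise the
refinement removes the ~3·SD/slope systematic lag, which would otherwise
bias insertion displacements by ~0.1 µm at the softest condition.

**Depth correction.** `δ = (z − z_A) − F/k`, floored at zero. With force in
nN and k in N/m, `F/k` is in nm with no unit juggling.

**Hertz fit.** For spherical tips, `F = 4√R·E/(3(1−ν²))·δ^{3/2}` with
ν = 0.5 is fitted over depths up to 1.5 µm by nonlinear least squares in
(E, z_A). The model is linear in E, so E is profiled out in closed form and
a 1-D golden-section search over z_A (±500 nm around the detected contact)
remains — fast, derivative-free, and immune to E/z_A trade-off divergence.
Fits failing to a non-positive modulus or a boundary contact point raise a
typed error with diagnostics.

**Force drops.** A drop is a decrease of at least
`max(5·baseline SD, 0.05 nN)` completed within 20 nm of piezo travel. The
candidate screen runs on the smoothed trace (noise suppressed ~√5-fold, so
the 5 SD threshold on a genuine step has ~11 SD of headroom against false
positives); the event index is then refined on the raw trace as the steepest
single-sample decrease in the candidate window and the magnitude confirmed
raw. Insertion force is the raw force at the pre-drop sample; displacement
is corrected depth there; time is displacement / approach speed (asserted
exact). Events are ranked membrane-first / nucleus-second in order.

**Segmentation.** The A–B slope is an OLS fit of force against corrected
depth in µm, from contact to the first drop (to the trigger when no drop
occurred). Corrected depth — not raw piezo distance — keeps slopes
comparable across cantilevers; the published curves plot displacement, so
absolute slopes here differ from chart readings by the factor `1/(1 + s/k)`.
Fewer than 5 samples between contact and drop is reported as a degenerate
segmentation error rather than a fit.

# Condition statistics

A curve counts as penetrated iff it has at least one membrane-first event.
Force/displacement/time statistics are computed over the *first* event of
penetrated curves only, as mean ± sample SD (n−1); whether published ±
values are SD or SEM is not stated, and SD is the conservative reading.
Rates are kept as exact fractions and reported rounded to the nearest
integer percent. (The published table prints "19 % (11/60)" although
11/60 = 18.33 % rounds to 18 %; that row is excluded from exact rate
assertions, and this package prints 18 % for 11/60.) Histograms use
half-open bins `[lo, hi)` with a terminal overflow bucket, default edges
0, 1, 2, 3 nN.

# The prestressed-network model

**Geometry.** A square patch (default 2 × 2 µm) of flat membrane
(constant-strain triangles, thickness 5 nm, *no bending stiffness*)
conforming to an orthogonal grid (default 100 nm spacing) of filament beams
(cross-section 38.46 nm², circular, I = A²/4π), with three stress-fibre
lines (400 nm² beams) along x, the cell's long axis, on equally spaced
rows. Membrane, filaments and fibres share the grid nodes — the tie
constraint (no relative motion at junctions) holds identically. Edge nodes
are fully clamped; triangles alternate diagonals in a checkerboard so the
mesh is mirror-symmetric.

**Prestress.** `apply_prestress()` stores σ per component; each beam gets
initial axial force N = σ·A (1.923 pN per filament at 50 kPa) and the
membrane an isotropic tension σ·t (5·10⁻⁷ N/m at 100 Pa), entering assembly
through the standard consistent geometric stiffness of beams and the
`σt·∇Nᵀ∇N` membrane term on all three displacement components. A uniform
prestress with clamped edges is self-equilibrated, so no initial nodal
loads arise and zero travel leaves exactly the prestress state.

**Solution scheme.** Quasi-static increments with a constant
(material + prestress-geometric) stiffness — linearisation about the
prestressed flat state; the published dynamic explicit scheme is replaced
deliberately, since the end-state fields are the target and a direct sparse
solve is deterministic and desk-scale. Contact is unilateral: at each depth,
nodes are prescribed onto the sphere-capped-cone surface (apex radius 50 nm,
default half-angle 20°) only if leaving them free would place the membrane
above the tip surface (growing active set). On the default mesh this reduces
to apex-node contact — a sharp cone on a tense membrane touches in a region
smaller than the grid. After each converged contact solve, one von Kármán
correction pass applies the quadratic deflection-gradient membrane strain
½(∇w)² as an in-plane load and re-solves once; stress recovery then uses the
full quadratic strain plus the prestress baseline, reported both as von
Mises and maximum principal stress. Without the quadratic term a linear
solve would report zero membrane stress change under purely transverse
deflection.

**Material constants.** The source analysis defers its constants to earlier
work without printing them, and the one quantitative anchor it does print
is the membrane stress scale: maxima of 676 Pa (prestressed) vs 410 Pa
(unprestressed) at 100 nm travel. Bulk-actin values (filaments ~GPa) are
inconsistent with that anchor twice over: they put the simulated stress near
30 kPa, and they reduce the *fixed* 50 kPa prestress to a <1 % stiffness
perturbation whose sign at the stress maximum is uncontrolled. The defaults
are therefore coarse-grained effective moduli — membrane 50 kPa, filaments
and fibres 2 MPa — chosen so the stress scale (~1.2–1.6 kPa) and the
prestressed/unprestressed max-stress ratio (1.41 vs the published 1.65) sit
in the published regime. They are configurable, and clearly labelled as
effective values.

**Measures and their caveats.**

* *Max membrane stress* is the element-field maximum (von Mises, Pa). Under
  effectively point-like contact this quantity is mesh-singular (the
  point-loaded tensioned membrane has a logarithmic deflection and diverging
  gradient), so it is compared only *across cases on the same mesh*, never
  across resolutions; the published absolute values are likewise mesh-bound
  and are matched qualitatively only, as the project scope prescribes.
* *Filament spacing is physics, not discretisation.* Halving the spacing
  doubles the network's areal stiffness — it changes the modelled cortex.
  Discretisation convergence is instead demonstrated on the single-beam
  element path (h-refinement against the closed form) and by a domain-size
  study (max-stress changes decay as the clamped boundary recedes). The
  clamped box must stay large relative to the deflection basin: below
  ~800 nm half-width the unprestressed basin is boundary-truncated and the
  prestress contrasts are contaminated.
* *"Centre displacement".* With contact maintained, the apex node follows
  the tip exactly in both cases, so the membrane displacement contrast near
  the contact is measured at the first midline node outside the footprint
  (and as the mean midline |w_z| over free nodes) — both strictly smaller
  with prestress.
* *Stress-peak FWHM* is measured on the nodal-averaged midline profile,
  above its far-field level, with linear interpolation at the half-height
  crossings.
* *Prestress monotonicity* holds for the physically meaningful sweep — the
  full triple (100 Pa, 50 kPa, 50 kPa) scaled jointly (max stress
  1160 → 1431 → 1641 → 1855 Pa at 0/0.5/1/2× on the default mesh). Sweeping
  one component with the others at full strength is *not* monotone:
  stiffening one subsystem redistributes load and can move or lower the
  global maximum. The per-component claim was a conjecture the implemented
  mechanics refutes.

**Tensioned-beam oracle.** The beam-column moment balance
`M(x) = (F₂/2)x − F₁w` for a simply supported span under central load F₂ and
axial tension F₁ integrates to the closed-form midspan deflection
`w = F₂L³/(48EI) · 3(u − tanh u)/u³`, `u = (L/2)√(F₁/EI)` (series expansion
used below u = 10⁻³ to avoid 0/0), with the classical `F₂L³/48EI` and
taut-string `F₂L/(4F₁)` limits. An independent 2000-interval central
finite-difference solve of `EI·w'''' − F₁·w'' = F₂·δ(mid)` agrees to
<10⁻⁵ relative, and the package's own 3-D beam element reproduces the closed
form to <0.5 % with 200 elements — validating exactly the element +
geometric-stiffness path the network assembler uses.

# Numerical conventions

Units: nm, nN, N/m, µm/s, Pa at all interfaces (internally the FE works in
nm–nN, so stresses are in GPa and converted on output). All randomness is
seeded; generators save and restore the caller's RNG state; batch members
and the exact-count subset use derived child seeds below 2³¹. Curve CSVs are
written with 17 significant digits for lossless round trips. Degenerate
inputs raise typed conditions (`afm_invalid_params`, `afm_no_contact`,
`afm_fit_error`, `afm_segmentation_degenerate`, `afm_mesh_error`,
`afm_solver_error`, `afm_trigger_unreachable`, `afm_format_error`,
`afm_pipeline_error`) rather than NA results.

# Known limitations

* The generator's single-slope A–B world ties displacement scatter to force
  scatter (above); published displacement SDs are not reproduced.
* The Hertz path covers spherical tips only; pyramidal curves are analysed
  via slopes and events (no Sneddon conical fit), and retract curves are
  ignored.
* The FE model is linearised about the prestressed flat state: geometric
  nonlinearity beyond the prestress stiffness and the single von Kármán
  recovery pass is omitted, membrane rupture is not modelled, and the
  published absolute stresses (676/410 Pa) are matched in regime and
  ordering, not numerically.
* Intermediate filaments and microtubules are excluded by the model's own
  design; material constants are effective, not molecular.
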