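---
title: "Methods: rules-based 3D simulation of embryoid-body differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rules-based 3D simulation of embryoid-body differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ebsim is a rules-based, center-based (off-lattice) simulator of early
embryoid-body (EB) differentiation. Cells are rigid spheres with a
binary Oct4 state (`POS` = pluripotent, `NEG` = differentiated); they
are packed into a spheroid, exchange state information only through
physical contact, and lose Oct4 irreversibly under one of three
probabilistic neighbour rules. This vignette documents the model, the
parameter choices, the numerical decisions, and the design rationale
for points the underlying scheme leaves open.

## Cell geometry

Single embryonic stem cells are near-spherical: their measured
surface-area-to-volume ratio is within ~10% of the spherical value
(`sphere_sa_v_ratio()` is exactly 3 after normalisation by the radius;
`ellipsoid_sa_v_ratio()` quantifies the excess for deformed shapes and
is used as a numerical control). Cell diameters follow a unimodal,
right-skewed distribution with mean 6.6 µm and SD 0.3287 µm. The
default sampling family is a moment-matched lognormal on the diameter
scale (`radius_distribution()`), which is strictly positive and
right-skewed like Coulter-counter histograms; truncated-normal and
empirical-resampling families are available for sensitivity checks.

## Structure generation

`seed_cells()` places non-overlapping spheres uniformly in a box by
rejection sampling. `aggregate_cells()` then pulls every cell toward a
gravitational point source (default: the seeded centroid): each
iteration every cell advances `step_size` toward the attractor, and
overlapping pairs are pushed apart to exact contact along their centre
line, in randomised order, using a uniform-grid neighbour search in
C++. The step is annealed (halved) when net motion stalls, so the
packing settles into a jammed spheroid; a final settling phase runs
collision sweeps until the worst interpenetration is below
`overlap_tolerance` (1% of the smaller radius).

Two numerical decisions matter here:

* **Translation equivariance.** The solver runs in attractor-local
  coordinates snapped to a 2^-26 µm (~1.5e-8 µm) grid. Without the
  snap, translating the input changes coordinates at the last-ulp
  level, which changes the grid hashing and hence the randomised
  collision order, and the annealing dynamics amplify that chaotically.
  The snap is ~7 orders of magnitude below cell size and makes the
  solver input bit-identical under translation.
* **Determinism.** All randomness is consumed from R's RNG in a fixed
  order (collision shuffles use `unif_rand`), so a seed reproduces a
  packing bit-exactly.

Realism of the generator was checked against closed forms rather than
data: a single cell converges onto the attractor; two cells end
exactly in contact; packings are connected, have ~1% maximum overlap,
projected circularity ≥ 0.85, and centre of mass within one mean
radius of the attractor. The FCC lattice fixture (`fcc_aggregate()`)
pins the contact machinery to exact values: interior degree 12 (the
kissing number) and packing fraction π/√18.

## Contact graph

Cells i and j are connected when their centre distance is at most
(rᵢ + rⱼ)(1 + `contact_slack`), with 5% slack absorbing the residual
gaps relaxation leaves. The graph (tibble of `from`, `to`, `length`)
drives both the rules and all cluster statistics.

## Differentiation rules

All rules act synchronously once per step on Oct4+ cells only;
transitions are irreversible. With β = number of Oct4− contacts and
γ = number of Oct4+ contacts, the per-step transition probability is:

* **random**: α = 0.01 regardless of neighbourhood (the 1% basal
  rate observed for spontaneous differentiation);
* **positive feedback**: `or_gate(α, min(β/ε, 1))` with ε = 12, the
  FCC kissing number used as neighbourhood normaliser;
* **competing feedback**: `or_gate(α, w·β²/(β² + γ²))` with
  `f(0,0) = 0`; `w = 1` in the static model and `w = 0.01` in the
  dynamic model.

`or_gate(p₁, p₂) = 1 − (1−p₁)(1−p₂)` is the probabilistic union of the
two mechanisms. The feedback functional forms are model choices, not
fits to data; their qualitative properties (monotone increasing in β,
decreasing in γ, dominating the basal rate) are enforced by tests. Each step draws
one uniform per Oct4+ cell in `cell_id` order, so a seeded step can be
replayed by hand — a test does exactly that.

## Pattern analytics

UCN and DCN are the numbers of connected components with **two or more
cells** of the same state in the contact graph (isolated cells do not
count). Trajectories are reported on normalised time τ = step / steps
to completion, so runs of different length are comparable;
`summarize_trajectories()` resamples replicates onto a common τ grid
and reports means, variances, and the grid-summed cumulative variance.

`classify_pattern()` assigns one of six classes:

1. `oct4_pos` when ≥ 90% of cells are Oct4+; `oct4_neg` when ≤ 10%.
2. Otherwise a radial-bias test: if the mean normalised radial
   positions of the two states differ by more than 0.15 and each state
   forms at most 2 clusters, the pattern is `inside_out`
   (differentiated core) or `outside_in` (differentiated rim).
3. Otherwise `connected` vs `random` is decided by a join-count
   z-score: the observed number of minority–minority edges is
   standardised by its exact mean and variance under random
   relabelling without replacement (Cliff–Ord moments, closed-form in
   the edge count, degree sequence and minority count), and the
   pattern is `connected` when z > qnorm(0.95).

**Design rationale for step 3** (an open point in the scheme): the
naive criterion "≥ 60% of minority cells sit in clusters" fails on
contact graphs of degree ~10 — under iid labelling nearly every
minority cell has at least one same-state neighbour, so the clustered
fraction is ~1 for *random* patterns too and the criterion classifies
its own checkerboard counter-example as connected. The join-count
z-score conditions on the actual graph and minority count, so "random"
means exactly "indistinguishable from relabelling the same cells".
The closed-form moments were validated against a permutation oracle,
and iid checkerboards classify as `random` in ≥ 80% of seeds while the
two-blob fixture classifies `connected`.

Virtual sections (`virtual_section()`: cells whose centres fall in a
10 µm slab) feed the same classifier and the PNG renderer
(`render_section()`: cyan Oct4+, dark-blue Oct4−, deterministic
output). Circularity is the square root of the minor/major eigenvalue
ratio of the second central moments of the rasterised footprint
(0.25 µm/pixel, with the pixel²/12 moment correction); under this
definition two touching equal disks score 1/√5 ≈ 0.447, which is the
value the test oracle uses.

## Dynamic model

`simulate_growth()` runs the growing-EB model: overdamped mass-spring
mechanics advance every 0.1 h, the rule (if any) is evaluated every
1 h with per-evaluation probabilities, and the run stops at the first
of 144 h, 99% differentiated, or 40 000 cells. Division is symmetric
and unsynchronised: each cell carries an exponential waiting time with
rate ln 2 / T (T = 18 h for Oct4+, 51 h for Oct4−), which makes the
population a Yule process with exactly exponential expected growth —
the property the acceptance fit checks (ln-linear fit recovers ~18 h
within 10%). Daughters inherit state and radius and are placed one
parent radius away in a uniform random direction; the mechanics
resolve the overlap.

Springs act along all pairs within `adhesion_slack` (20%) of rest
length (the sum of radii): compressed pairs push apart, stretched ones
pull back. The capture range is deliberately wider than the 5%
analysis slack — division pushes occasionally nudge a surface cell just
past contact range, and without short-range adhesion it would detach,
whereas real EBs remain cohesive. Hard-sphere overlap projection after
the spring step keeps interpenetration below 1%.

Growth-only controls reproduce the expected invariants: packing
density, mean contact count and mean contact length are stationary
during growth, and ln(count) is linear in time with R² > 0.99.

## Reproducibility and I/O

Every stochastic entry point takes a `seed` and uses an isolated RNG
scope (`withr::with_seed`), so results are bit-reproducible. CSV round
trips are bit-exact: doubles are written with `%.17g` and parsed with
`strtod` via `as.numeric()` (the fast multi-threaded CSV double parser
mis-rounds the last ulp on some values). `run_experiment()` writes all
tables plus a JSON manifest from which a rerun reproduces every file
bit-identically; the default classification grid is rounded to 10
decimals because JSON serialisation does not round-trip
`seq(0.1, 0.9, 0.1)` exactly.

## Limitations

* Cells are rigid spheres: no shape change, no cell death, no
  migration beyond mechanical relaxation, constant cell size across
  divisions.
* The Oct4 state is binary and its loss instantaneous and
  irreversible; there is no intermediate or reversible priming state.
* Signalling is strictly contact-mediated; diffusible morphogens,
  nutrient and oxygen gradients are not modelled, although they likely
  contribute to inside-out/outside-in patterns in real EBs.
* The mechanics are quasi-static and overdamped with a single global
  stiffness; no adhesion heterogeneity between cell states, which is
  one plausible sorting mechanism the model cannot express.
* The feedback functional forms are defaults consistent with the
  qualitative published curves, not fitted to data.
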