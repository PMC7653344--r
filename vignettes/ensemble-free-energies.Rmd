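---
title: "Ensemble binding free energies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble binding free energies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleFE)
```

# The problem

Binding free energies estimated from a single molecular-dynamics
trajectory are neither accurate nor reproducible: independent repeats of
the same simulation, differing only in their initial velocities, scatter by
several kcal/mol. Both protocols implemented here therefore treat the
*replica* — an independent simulation — as the fundamental statistical
unit. The package is MD-engine-independent: it consumes per-frame energy
tables and per-window dV/dλ samples as delimited text and performs all of
the downstream estimation, error analysis and bookkeeping.

# ESMACS: ensemble endpoint free energies

Each species (complex, free receptor, unbound ligand) contributes a
per-frame endpoint free energy

$$G = E_{int} + E_{vdW} + E_{ele} + G_{PB} + G_{SA} \; (-\,T S_{conf}),$$

where the molecular-mechanics terms and the Poisson–Boltzmann polar
solvation term $G_{PB}$ arrive as inputs (the continuum solver is outside
the package's scope), and the nonpolar term is the linear surface-area
model $G_{SA} = \gamma \cdot SASA + b$ with the conventional defaults
$\gamma = 0.00542$ kcal mol$^{-1}$ Å$^{-2}$ and $b = 0.92$ kcal mol$^{-1}$.
The binding free energy is

$$\Delta G = \langle G_{complex}\rangle - \langle G_{receptor}\rangle -
  \langle G_{ligand}\rangle .$$

Aggregation is replica-first: each replica is reduced to its frame-average,
and the ensemble average is the mean of replica means. On a balanced design
this equals the pooled mean, but it gives the bootstrap a clean independent
unit. The SEM is a bootstrap over replicas, scaled by $\sqrt{n/(n-1)}$ — the
plug-in bootstrap standard deviation underestimates the classical SEM by
exactly this factor in expectation, which matters at ensemble sizes of 5–25.

Frame selection follows the tail-window protocol (50 uniformly spaced
frames over the last 10 ns by default, against 25 replicas). The spacing
convention is *endpoint-anchored*: with trajectory length $L$ and window
$W$, times are $L - W + kW/n$, so the final frame is always included and
$n = 1$ degenerates to the final frame. A `window_ns`/`n_frames` pair on
`esmacs_binding_free_energy()` applies the selection; otherwise all frames
given are used.

Two modes are provided. In 1-trajectory mode the receptor and ligand frames
are extracted from the complex trajectory (the function enforces identical
replica/time keys) and the bootstrap resamples replicas *jointly*, which
respects the strong correlation between the three species' energies. In
3-trajectory mode the ensembles are independent and resampled
independently. Point estimates and component breakdowns are identical in
the two modes when fed identical frames; the SEMs deliberately differ
(paired vs independent resampling).

The configurational-entropy term is optional and off by default — endpoint
predictions correlate better with experiment without it — and, when
supplied via the WSAS model, is computed on the selected frames and
averaged per species, like every other term.

# Surface areas and WSAS entropy

Solvent-accessible surface areas are computed natively. The default
backend slices each probe-expanded sphere perpendicular to *z*
(Lee–Richards), measures the accessible arc of each section circle against
all neighbouring section circles, and accumulates arc-angle × R × dz. The
slice thickness (default 0.1 Å) adapts per atom so the slab stack covers
the sphere exactly, making isolated spheres exact to machine precision
rather than to the slicing resolution. A quasi-uniform point-sampling
backend (Fibonacci lattice, default 10⁴ points per atom) provides an
independent cross-check; the two agree within 1% on random overlapping
clusters, and within 0.3% typically.

Degenerate geometry is defined, not accidental: atoms with identical
centres and radii would occlude each other completely under either rule,
so the shared accessible area is computed once and split equally among the
coincident atoms, leaving the total invariant.

The WSAS entropy estimate is
$S_{conf} = \sum_i w_i (SAS_i - k \cdot BSAS_i)$ with
$BSAS_i = 4\pi(r_i + r_{prob})^2 - SAS_i$. The calibration weights $w_i$
and the scaling $k$ are *not* shipped: the original calibration is
external, so the package provides the parameter-file format
(`read_wsas_params()`), a unit-weight default for testing, and a synthetic
example file clearly labelled as such. The probe radius defaults to 1.4 Å,
the standard water probe.

# TIES: ensemble thermodynamic integration

An alchemical transformation from ligand L1 to L2 interpolates the hybrid
potential $V(\lambda) = (1-\lambda)V_1 + \lambda V_2$ and integrates the
ensemble-averaged derivative:

$$\Delta G_{TI} = \int_0^1 \left\langle \frac{\partial V}{\partial
\lambda}\right\rangle_\lambda d\lambda .$$

The default schedule places 13 windows at 0, 0.05, 0.1, 0.2, …, 0.9, 0.95,
1.0, denser near the endpoints, with 5 replicas per window. Disappearing
atoms' electrostatics ramp off linearly over λ ∈ [0, 0.55]; appearing
atoms' ramp on over [0.45, 1]; van der Waals terms use a soft-core form in
the MD engine. The package implements the schedule bookkeeping
(`coupling_scales()`) but not soft-core energy evaluation — dV/dλ arrives
as data.

Numerical choices:

* **Quadrature**: trapezoidal on the λ nodes. It is exact for integrands
  affine in λ (the property the tests pin down) and is the established
  practice on this non-uniform grid.
* **Window statistics**: each replica is reduced to its time-average over
  its whole series; the window mean is the unweighted mean of replica
  averages (replica-mean weighting, not a pooled mean — a replica with ten
  times the samples is still one replica). The window SEM is a bootstrap
  over replica means with the $\sqrt{n/(n-1)}$ correction; with a single
  replica it is `NA`, never a silent zero.
* **Error propagation**: per-leg
  $\sigma_{leg}^2 = \sum_\lambda \sigma_\lambda^2 (\Delta\lambda)^2$. On a
  non-uniform grid $\Delta\lambda$ is read as each node's trapezoidal
  quadrature weight (half the sum of its adjacent intervals), which is the
  weight that actually multiplies that node's mean in the integral; the
  naive forward-interval alternative is selectable
  (`weight_scheme = "interval"`). The combined error is
  $\sigma^2 = \sigma_{aqueous}^2 + \sigma_{bound}^2$.
* **Sign convention**: the thermodynamic cycle gives
  $\Delta G(L2) - \Delta G(L1) = \Delta G_{TI}^{bound} -
  \Delta G_{TI}^{aqueous}$. Part of the literature prints the opposite
  difference under the same name. `ties_ddg()` defaults to
  `"experiment"` (directly comparable to experimental relative-affinity
  tables, which tabulate $\Delta G(L2) - \Delta G(L1)$) and exposes
  `"printed"` for the opposite sign; the choice is explicit because the
  two conventions are genuinely opposed.

# Hybrid (dual) topologies

A transformation needs a hybrid ligand: a common region present in both
end states, a disappearing domain (L1-only atoms) and an appearing domain
(L2-only atoms).

* **Matching** finds the maximum common *connected* subgraph respecting
  element labels and bond topology (induced: two mapped L1 atoms are
  bonded iff their partners are, with equal bond order). The search is an
  exhaustive McGregor-style backtracking over connected mappings with a
  visited-set memo; ties are broken deterministically (larger pairing,
  then lexicographically smallest index sequence). Maximum common
  subgraphs are not unique in general — symmetric molecules admit several
  of equal size — which is why the tests compare sizes and validity
  against an independent exhaustive oracle rather than one arbitrary
  mapping. Hydrogens are matched like heavy atoms.
* **Charge pruning** removes pairs whose partial charges differ by
  strictly more than 0.1 e (a pair at exactly 0.1 e is retained); if that
  disconnects the region the largest connected component is kept, because
  a common "region" is one connected scaffold.
* **Charge assignment** gives each common pair the average of its two
  end-state charges. The charge displaced by averaging is redistributed
  uniformly over the corresponding end state's unique atoms so both end
  states conserve their net charge to 10⁻⁶ e. The original workflow
  re-derives unique-region charges with a constrained quantum refit;
  uniform redistribution is the minimal conservation-preserving
  substitute and is documented as a declared approximation, not a
  reproduction of that refit.

# Affinity statistics

Experimental dissociation constants convert via $\Delta G = RT \ln K_D$
(1 M standard state; the sign is fixed by the physics — tabulated binding
free energies of nanomolar ligands are near −12 kcal/mol). The conversion
temperature defaults to 298.15 K and is configurable (310.15 K
physiological); since the temperature behind published tables is often
unstated, the packaged fixture ships ΔG values as printed rather than raw
K_D. Replicate measurements average unweighted, with uncertainties
combined as $\sqrt{\sum \sigma_i^2}/n$.

The experimental observable of a transformation is
$\Delta\Delta G = \Delta G(L2) - \Delta G(L1)$ with quadrature
uncertainties, reported to 2 decimals (print precision of the packaged
table; `digits = Inf` gives full precision). The packaged
adenosine-receptor tables reproduce every printed transformation value
from the underlying affinities — that is a regression test, not a fit.

Prediction-vs-experiment comparisons use the Pearson correlation, the mean
absolute error, and Cook's-distance outlier screening with the common
$D_i > 4/n$ rule. Cook's distance presupposes a fitted regression, so the
default fits experiment on prediction by OLS with intercept; a
fixed-line $y = x$ variant is provided as a heuristic for the case where
the prediction is itself an estimate of $y$. Exactly collinear data yield
all-zero distances by definition (guarded explicitly; the naive formula
divides rounding noise by a zero residual variance). Missing table entries
are explicit `NA`s, excluded from statistics, never imputed.

# The synthetic-data generators

Every input class can be generated with known ground truth
(`gen_atom_cluster()`, `gen_ti_dataset()`, `gen_energy_frames()`,
`gen_ligand_pair()`, `gen_affinity_table()`), so all estimators are
testable against sidecar truth records with no external data. Defaults
mirror the protocol geometry: 25 replicas × 50 frames for endpoint
ensembles, 5 replicas × 13 windows for TI. Noise is i.i.d. normal
everywhere — the simplest model consistent with ensemble-mean machinery —
with per-frame/per-sample SDs of 2 kcal/mol (endpoint energies) and 0.5
kcal/mol (dV/dλ) as the stated world. The generators emulate none of the
real difficulties: no trajectory autocorrelation, no force-field physics,
no membrane environment, no inter-replica systematic drift. A green
recovery test therefore establishes that the estimators are correct and
calibrated *under the stated noise model*, not that the protocols converge
on real receptors.

Ligand pairs are built so their ground truth is provable: L2 adds a branch
of elements absent from the core, so the true maximum common subgraph is
exactly the shared core, and charge perturbations beyond the 0.1 e
threshold are recorded as prune-expected.

# Worked example

```{r example}
set.seed(1)
aq <- gen_ti_dataset(mu = function(l) 4 * l, sigma = 0.5, seed = 2)
bd <- gen_ti_dataset(mu = function(l) 7 * l, sigma = 0.5,
                     leg = "bound", seed = 3)
ties_ddg(aq$leg, bd$leg, n_boot = 2000, seed = 1)

ge <- gen_energy_frames(seed = 4)
esmacs_binding_free_energy(ge$complex, ge$receptor, ge$ligand,
                           n_boot = 2000, seed = 1)

aff <- adenosine_affinities()
tr <- adenosine_transformations()
head(ddg_table(aff, tr[, c("l1", "l2")], receptors = c("A1", "A2A")))
```

# Known limitations

* $G_{PB}$ is consumed, never computed: no Poisson–Boltzmann or
  Generalized-Born solver is included.
* No trajectory-format readers (DCD/XTC) — energies and derivatives enter
  as delimited text produced by engine-side tooling.
* The running-average convergence diagnostic draws no stopping rule;
  published convergence times (tens of ns for receptor–membrane systems)
  carry no portable criterion.
* WSAS production weights must be supplied by the user.
* Headline correlation/error statistics of any specific study depend on
  that study's per-ligand predictions; the statistics layer is verified by
  oracle equivalence instead.
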