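---
title: "Modelling and inverse design of electrochemical O2 and H2O2 microgradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and inverse design of electrochemical O2 and H2O2 microgradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The physical model

A microwire-array electrode immersed in aerated medium and polarised into
the oxygen-reduction window (0.2–0.6 V vs RHE) consumes dissolved O2 at its
catalytic surface. On Pt the reaction is the 4-electron reduction to water;
on Au a 2-electron channel producing H2O2 runs in parallel with a weak
4-electron channel. Because the array is periodic, a single unit cell with
one centred wire represents the whole electrode, and at steady state the
concentration fields obey Laplace's equation in the electrolyte:

$$ D_i \nabla^2 c_i = 0, \qquad i \in \{\mathrm{O_2}, \mathrm{H_2O_2}\}, $$

with $D_{\mathrm{O_2}} = 2.2\times10^{-9}$ and $D_{\mathrm{H_2O_2}} =
1.5\times10^{-9}\ \mathrm{m^2/s}$. The electrode enters through
concentration-dependent Tafel kinetics: each reaction channel contributes a
cathodic current density

$$ i = -i_0 \, \frac{[\mathrm{O_2}]}{C_{\mathrm{O_2}}}
     \exp\!\left(-\frac{\alpha_c F \eta\, n_{rds}}{RT}\right), $$

where $\eta = E_{appl} - 1.23\ \mathrm{V}$ is the overpotential against the
O2/H2O couple, $\alpha_c = 0.5$, and $(i_0, n_{rds})$ are per-channel
constants: Pt $(3.0\times10^{-6}\ \mathrm{A/m^2},\ 1)$; Au 4e$^-$
$(2.0\times10^{-8},\ 1)$ and Au 2e$^-$ $(8.0\times10^{-7},\ 0.7)$. O2 is
consumed by both channels ($J_{\mathrm{O_2}} = i_{4e}/4F + i_{2e}/2F \le 0$)
and H2O2 is injected by the 2-electron channel ($J_{\mathrm{H_2O_2}} =
-i_{2e}/2F \ge 0$). Both fluxes are *linear* in the local O2 concentration,
which is the key structural fact the solver exploits: the entire boundary
condition reduces to two effective first-order rate constants
$k_{\mathrm{O_2}}(\eta)$ and $k_{gen}(\eta)$ (`effective_rate_constants()`),
and each species solve is a single sparse linear system — no Newton
iteration, no pseudo-time stepping.

Bulk conditions ($[\mathrm{O_2}] = 246\ \mu M$, $[\mathrm{H_2O_2}] = 0$) are
imposed on the plane $z_{bulk} = \min(L + d_D, 200\ \mu m)$, where $d_D$ is
the diffusion-boundary-layer distance above the wire tops (20 µm for Pt,
50 µm for Au, both measured quantities of the reference experiments). We
read "distance from the top of the wire" as vertical distance, giving a flat
Dirichlet plane: for a dense periodic array the diffusion-layer envelope is
planar. The alternative reading (Euclidean distance to the top disc, a
curved cap) is noted but not adopted. The H2O2 bulk value of zero encodes a
continuously refreshed flowing medium.

## Boundary conditions and the active base

The lateral faces of the unit cell are zero-flux mirror planes — exactly
equivalent to periodic conditions for a square lattice with centred wires,
since every unit-cell face is a symmetry plane.

Whether the substrate *between* the wires is catalytically active is a real
modelling choice: the sputtered catalyst film coats the exposed base
conformally, so the package defaults to an active base
(`include_base = TRUE`). This choice is also strongly supported by the
model's own worked examples: with an active base the simulated design
geometries reproduce the targeted amplitudes (a ~100 µM O2 drop for Pt
k = (46, 6, 20) at 0.5 V; a ~15 µM H2O2 peak for Au k = (17, 3, 30) at
0.45 V), while with an inert base both amplitudes come out several-fold too
small for any plausible discretisation. The flag is exposed for users who
pattern the catalyst onto the wires only.

Two further assumptions: temperature is 298.15 K (room-temperature PBS,
never stated otherwise, configurable via `phys_constants()`); and there is
no H2O2 re-oxidation or re-reduction at the electrode — the model has no
H2O2 surface sink, which is a documented simplification. The Au 2-electron
channel uses the same overpotential reference (1.23 V) as the 4-electron
channel, exactly as the rate law is printed; the exchange current densities
absorb the different standard potential of the O2/H2O2 couple.

# Discretisation

The default solver works in cylindrical coordinates on the equal-area disk:
the square $P \times P$ footprint is replaced by a disk of radius
$P/\sqrt{\pi}$ around the centred wire, reducing the solve to an (r, z)
finite-volume problem a few hundred unknowns large (~10 ms per condition).
Grid lines conform exactly to the wire wall ($r = D/2$) and wire top
($z = L$), so electrode patch areas are analytic at any resolution. A full
3-D cartesian mode on the quarter unit cell is retained as a validation
mode; there the voxelised wire surface carries true-area/discretised-area
correction factors per patch group, so the total electrode area — and hence
the total current at uniform concentration — is exact regardless of
spacing (this matters for wires down to D = 0.2 µm, which no practical
uniform grid resolves). The test suite holds the two modes to 5 %
agreement on the laterally averaged profile and the axisymmetric mode to
2 % self-consistency under grid refinement.

Electrode patches couple to the adjacent cell through the half-cell
diffusive resistance in series with the Tafel rate constant (flux
$= c_i / (1/k + \delta h/D)$), which keeps the Robin condition first-order
accurate on coarse cells. The linear systems are solved by sparse LU with
one round of iterative refinement; convergence is asserted on the normwise
backward error ($< 10^{-10}$, in practice $\sim 10^{-16}$), the measure
that remains meaningful when high-aspect-ratio cells make the raw residual
ratio float-noise-limited. The inert-electrode limit (all $i_0 = 0$)
recovers the uniform bulk field to machine precision, and a quasi-1D column
grid (`planar_reference_grid()`) checks the solver against the closed-form
planar solution $c(0) = C_b D/(D + k\, d_D)$.

Profiles are reported the way the reference workflow reports them: 20
laterally averaged concentrations at z = 5, 10, ..., 100 µm above the wire
base, area-weighted over the electrolyte cross-section (wire interior
excluded below the wire top) and interpolated linearly from the grid layers
onto the 5-µm ladder; heights at or above $z_{bulk}$ report the bulk value.

# The synthetic-data generator

Training data are produced by the simulator itself: conditions are drawn
independently and uniformly over $E_{appl} \in [0.2, 0.6]$ V,
$P \in [1, 100]$, $D \in [0.2, 10]$, $L \in [1, 150]$ µm, rejecting draws
with $D \ge P$ (the simplest defensible reading of "random morphologies in
the morphology space"; the sampling distribution is otherwise a free
choice). $E_{appl}$ is sampled rather than fixed so the surrogate learns
its full input space. The generator emulates the *steady-state, diffusion
only* physics of the model: no convection (the flow cell only maintains
bulk conditions), no migration, no H2O2 disproportionation, no transient
switching dynamics. Tests passing on these data therefore validate the
inverse-design machinery against this model of reality, not against
confocal measurements — the reference experiments' own
simulation-vs-experiment AMSEs (~1e-3/5e-6 mM²) bound how literally the
model describes a real device.

# The surrogate

The surrogate is a multilayer perceptron mapping $(E_{appl}, P, D, L)$ to
the 20 profile points: two ReLU hidden layers of 64 units, minibatch Adam
(batch 32, initial rate $10^{-3}$ stepped down 5× at 60 % and 85 % of the
epochs), outputs min-max scaled per column on training statistics. The
geometric inputs span two decades ($P$ 1–100 µm, $D$ 0.2–10 µm, $L$
1–150 µm) and the response depends on them through ratios like the
area-density $DL/P^2$, so $P, D, L$ are log-transformed before
standardisation; this scaler choice alone improves the held-out H2O2 error
roughly seven-fold over raw standardisation. The architecture is deliberately the smallest that
meets the accuracy targets; the target is the held-out AMSE, not the
architecture. Data are split test-first: a random 20 % is held out, the
remainder divided 65 %/15 % (of the whole) into training and validation.
"One epoch" is one full pass over the training rows; the protocol's nominal
10 epochs are a default, and the accuracy-critical runs extend it (200
epochs for O2, 500 for H2O2) since the acceptance surface is the error, not
the epoch count. Training is bit-reproducible from its seed, and the
per-epoch training/validation AMSE curves are logged so overfitting is
visible rather than hidden; at these sizes validation tracks training
closely.

Accuracy is quantified exactly as the reference workflow defines it:
per-profile MSE = mean over the 20 heights of squared error (mM²), AMSE =
mean of per-profile MSEs, SD = population standard deviation of per-profile
MSEs, and $R^2$ pooled over all (profile, height) pairs. At desk scale the
O2 surrogate (2,000 Pt simulations) reaches the reference AMSE bound of
$1.74\times10^{-4}$ mM² with a wide margin; the H2O2 response surface is
harder — its amplitude spans three decades across the morphology block — so
the H2O2 surrogate trains on the reference-scale 10,000 Au simulations
(which the fast solver affords in ~2.5 minutes) to meet its
$1.81\times10^{-6}$ mM² bound. Predictions are clipped to physical bounds
(non-negative; at most 246 µM for O2) at inference.

# Inverse design

A design target fixes the species, the operating potential (0.5 V for the
O2 example, 0.45 V for H2O2) and desired concentrations at seven anchor
heights ($C_O = \{5, 10, 15, 25, 35, 45, 70\}$,
$C_H = \{5, 20, 30, 40, 55, 70, 80\}$ µm). Candidates are scored by

$$ S = 1 - \tfrac{1}{7} \sum_{z \in C}
   \frac{|c_{pred}(z) - c_T(z)|}{c_T(z)}, $$

a pure fraction (1 = perfect; rendered as a percentage only in reports, and
not clamped below zero — score maps may floor the display at 0, but raw
values are preserved). Anchor concentrations must be strictly positive; a
zero target would make the relative error undefined.

The search is the random search of the reference workflow, not a gradient
optimiser: morphologies are drawn uniformly from the block at the target's
fixed potential, scored through the surrogate in one vectorised forward
pass, and the top 10,000 retained with deterministic tie-breaking (score
descending, then P, D, L ascending). Duplicates are possible under random
sampling and retained. Sliced maps aggregate the retained set per
wire-length band (labels 5, 20, 40, 60, 80, 95 µm covering [0,10), [10,30),
[30,50), [50,70), [70,90), [90,100] µm — the slicing recipe is applied to
both species for uniformity) on a (P, D) grid of 2 × 0.5 µm bins; empty
bins stay missing rather than zero. `verify_design()` closes the loop
independently of the surrogate by re-simulating a candidate with the full
solver and reporting its score and MSE against the target.

# Numerical choices and degenerate inputs

* Default grid: 22 cells along the wire, 6 across the boundary layer, 3/14
  radial cells inside/outside the wire (scaled by the `resolution` factor,
  with floors of 20 and 4 enforced); explicit counts below the floors are
  rejected with guidance rather than silently accepted.
* Thin wires: the axisymmetric mesh conforms to any $D \ge 0.2$ µm; the 3-D
  mode guarantees at least one wire voxel column and rescales patch areas.
* $L + d_D$ exceeding the 200 µm domain clips $z_{bulk}$ to the domain top.
* Ladder heights above $z_{bulk}$ report the bulk value exactly.
* Zero-range output columns in the scaler (e.g. H2O2 profile points pinned
  at zero) fall back to unit scale to avoid division by zero.
* Solver failures abort loudly; in batch generation failed rows are logged
  and excluded, and more than 1 % failures aborts the dataset.

# Problem sizes used by the checks

The test suite and the acceptance script rebuild everything from code: the
O2 surrogate from 2,000 Pt simulations (~20 s generation, ~10 s training)
and the H2O2 surrogate from 10,000 Au simulations (~2.5 min generation,
~2 min training); property checks run on dozens of random conditions at the
default resolution. These sizes are the package's desk-scale reference
conditions and are stated here so results are interpreted at the scale that
produced them.

# Known limitations

* Steady state only; the experimental few-second switching transients are
  out of scope.
* Diffusion only: no convective or migrative transport, no homogeneous
  H2O2 chemistry.
* The kinetic constants are taken as printed; no refitting from
  voltammograms is attempted, and whether the Au 2e$^-$ channel's
  $n_{rds} = 0.7$ is device-specific is unknowable from the source.
* The square-lattice unit cell excludes non-square lattices, tilted or
  tapered wires, and multi-wire supercells.
* Surrogate accuracy is certified on held-out *simulated* data; transfer to
  a physical device inherits the simulator-vs-experiment gap noted above.
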