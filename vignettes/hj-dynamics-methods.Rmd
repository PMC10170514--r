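---
title: "Models and methods behind hjdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hjdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjdyn)
```

# The scientific problem

A DNA Holliday junction (HJ) is a four-way branched structure whose
four duplex arms (stems I-IV) interconvert between an extended *open*
conformation and two coaxially *stacked* ("closed") isomers: isomer I
stacks stems I+II and III+IV, isomer II stacks I+IV and II+III. The
open state is the obligatory intermediate between the isomers, and the
open/closed balance is steered by the cation atmosphere around the
strongly charged branch point. Standard fixed-charge force fields
overstabilise the closed state so severely that junctions never open
in plain simulations; a practical remedy is a *structure-specific*
van der Waals correction: the pairwise Lennard-Jones (LJ) well depths
among the branch-point nucleotides are multiplied by a uniform factor
λ ∈ (0, 1] (an NBfix-type pair override), leaving the rest of the
force field untouched. `hjdyn` implements the complete analysis stack
around that idea: building and editing pair tables, the stacking
collective variables and seven-state classification, a desk-scale
well-tempered metadynamics (WT-MetaD) + Hamiltonian replica exchange
(HREX) engine, free-energy analysis with a ΔG(λ) fit, and
ion-atmosphere statistics - all exercisable on synthetic fixtures with
known ground truth.

# Force-field modification

`build_pair_table()` resolves every atom pair through the AMBER
combination rules (`eps_ij = sqrt(eps_i eps_j)`,
`rmin_ij = rmin_half_i + rmin_half_j`) lazily, storing only overrides.
Two override operations exist:

* `apply_lambda_scaling()` multiplies `eps_ij` by λ for pairs whose
  **both** ends lie in the branch-point selection. The both-ends
  convention keeps nucleotide-solvent interactions intact; it is what
  makes the scaled-subset energy *exactly* linear in λ, a property the
  test suite checks against a brute-force pair sum. Watson-Crick
  H-bond donors/acceptors and their polar hydrogens are exempted via a
  configurable per-base template (`wc_atom_templates()`), because the
  correction must not soften base pairing itself. The templates are a
  design choice: the underlying rule names the role of the atoms, not
  an atom list, so the defaults cover the standard bases and can be
  replaced wholesale.
* `apply_cufix()` raises `rmin_ij` for cation x phosphate-oxygen
  pairs by a configurable increment (default 0.1 Å). This emulates
  published cation-phosphate NBfix corrections that weaken
  overestimated ion-phosphate binding; the exact published increments
  differ per ion/oxygen pair, so the default is a single
  representative value and callers supply their own when fidelity to
  a specific parameter set matters.

Scaling touches only ε, the cation fix only `rmin`; bonded/1-4
exclusions are never overridden. Energies stay in kcal/mol and
distances in Å throughout; kJ/mol (exact factor 4.184) and nm appear
only in the GROMACS-style override writer. `write_parm7()` expands a
per-atom-type LJ matrix because pair-specific overrides cannot be
expressed through shared types; the wide `3E24.16` coefficient format
is deliberate so that a round trip reproduces parameters to better
than 1e-10.

# Collective variables and states

Base stacking between two branch-point base pairs is measured by a
coordination number: the sum of the rational switching function

s(r) = (1 − (r/r0)^n) / (1 − (r/r0)^m),  n = 4, m = 2n, r0 = 3 Å

over all inter-group atom pairs (`coordination_number()`). The value
at r = r0 is the removable-singularity limit n/m = 1/2. Four CVs
(s_I-II, s_III-IV, s_I-IV, s_II-III) track the four possible stacks.

States are defined on the **raw** CVs: open when all four are below 5,
a closed isomer when its two CVs exceed 50, and a half-closed
intermediate when exactly one CV exceeds 50 with the other three below
5. We apply the thresholds to raw coordination numbers rather than the
α-normalised values because the state definitions predate the
normalisation in the workflow and 50 is a natural raw contact count;
the normalisation exponents (0.65 for the isomer-I CV pair, 0.4 for
isomer II) exist only to equalise CV fluctuations between open and
closed basins for sampling. `classify_states()` assigns a label only
when exactly one definition matches, which makes the seven labels
mutually exclusive by construction; anything else is `UNASSIGNED`.

`extract_transitions()` walks a label sequence and records reactive
trajectories - complete excursions between two distinct end states
(open, closed I, closed II) - together with the ordered half-closed
intermediates visited, and counts reverted excursions as unsuccessful
attempts. Two policies are ours to set because the state definitions
leave them open: `UNASSIGNED` frames inside a transition are tolerated
up to 50 consecutive frames (longer gaps split the record), and a
single frame in a half-closed state counts as a visit (the
intermediates are short-lived, so no dwell threshold is imposed).

# The toy sampler

The WT-MetaD + HREX engine integrates overdamped Langevin dynamics
(Euler-Maruyama) on a 1D/2D analytic surface given in kT units, with
the bias accumulated on a grid (nearest-node force lookup; walkers
reflect at the grid edges). It is *not* a molecular dynamics engine -
the dynamics is the simplest possible - but the bias and exchange
mathematics are exact: deposit heights follow
w = w0 exp(−V/(kT(γ−1))); swap attempts between neighbouring replicas
every `exchange_stride` steps accept with
min(1, exp(−β[(U_ij + U_ji) − (U_ii + U_jj)])), alternating even/odd
pairs; wall restraints are one-sided parabolas k(s−onset)². Defaults
mirror the junction protocol: w0 = 2.5 kJ/mol, γ = 15, stride 500,
walls from 10 with k = 0.02 kJ/mol, six-replica λ ladder, exchange
stride 2500. A single seed makes every run reproducible.

# Free-energy analysis

`reweight()` converts a biased CV series into a weighted ensemble.
Three estimators are provided. The default `final_bias`
(w ∝ exp(V_final(s)/kT)) is the simplest choice consistent with a
converged bias and is exact in closed-form unit tests. For recovery at
desk-scale run lengths we use `averaged_bias`: the bias is averaged
over the production window (after discarding a burn-in fraction,
default 25%) and only production frames are weighted. The reason is
variance, not correctness: with γ = 15 the hills keep an appreciable
height for a long time, so the instantaneous final bias fluctuates by
the order of one hill (~1 kT), while the time average suppresses that
fluctuation. A `time_dependent` variant evaluates the bias at each
frame's own time.

State free energies integrate the ensemble weight over rectangular CV
regions, ΔG = −kT ln(P_state/P_open), with the open state the exact
zero reference. The default rectangles map the raw thresholds through
the setup's exponent (open below 5^α, closed above 50^α). Errors come
from a circular block bootstrap (default 200 replicates, block length
an autocorrelation-time estimate capped at N/20). The ΔG(λ) points
are fitted with an unweighted least-squares line a·λ + c; the *ideal*
λ is the root −c/a where open and closed are equally stable, and the
expected open-state population is the sigmoid
1/(1 + exp(−(aλ + c)/kT)), which passes through ½ at the ideal λ.

# Ion-atmosphere statistics

All distance work honours minimum image in a general triclinic cell.
`rdf()` normalises shell counts by the ideal-gas expectation at the
target's mean density. `bridging_incidence()` implements the ionic
bridging criterion: a frame is bridged when a single cation sits
within 6 Å of at least one of the three central phosphates of *each*
crossing strand at once (distances to the phosphorus atom; a relaxed
any-ion variant sits behind a flag). `center_ion_count()` counts
cations around the geometric centre of the two branch-point
phosphates (default radius 10 Å, configurable - the canonical choice
is not fixed by the state definitions). `effective_bulk_concentration()`
converts the radial ion/water-oxygen count ratio to molarity via
55.34 mol/L and averages the outermost 10% of sampled radii, the
"near the box edge" estimate that falls below the nominal box
concentration whenever counterions condense on the solute.

# Synthetic data

The generator renders each branch-point base-pair group as a rigid
4 x 6 plate of pseudo-atoms at 1.4 Å spacing - roughly the atom count
of a real two-base pair - stacked plates 3.2 Å apart and isolated
groups ≥ 18 Å from everything. With those distances a stacked pair
scores a raw CV near 100 and an isolated one near 1, so the
generator-classifier round trip is exact for jitter well beyond the
default 0.15 Å; rendering refuses to proceed if any frame would
misclassify. State sequences come from a discrete-time Markov chain
restricted to the opening-closing graph (closed ↔ half-closed ↔ open
plus rare direct edges; geometric dwell times), or from deterministic
scripts with exact per-pathway counts. Ion/water fields place
water-density oxygens and cations uniformly in a cubic box (≥ 56 Å -
smaller cells would fold the junction layout onto itself), with an
optional condensed fraction near the centre.

What the fixtures deliberately do not emulate: real DNA geometry and
sequence effects, force-field energetics, correlated ion motion and
finite water structure. Passing the suite therefore demonstrates the
correctness of the *analysis machinery* (CV algebra, classification,
counting, reweighting, estimators) under known ground truth, not the
biophysics of any particular junction.

# Problem sizes and numerical choices

The recovery studies use a 1D double well with a 3.5 kT barrier and
wells at ±1 on the domain [−1.6, 1.6] (reflecting bounds; the
analytic reference integrates the same domain, so truncation is part
of the model, and the neglected tail mass beyond the bounds is below
e^−8). The tilt is set by a quadrature root so the closed-open gap is
exactly 2 kT. The integrator uses dt = 2·10⁻⁴ with diffusion 1 - at
this step the stationary-distribution discretisation error is a few
hundredths of a kT, checked directly against quadrature with the bias
switched off. Hill widths are 0.15, matching the CV standard deviation
inside a well, following the same rule used to choose the σ values in
the junction protocol. Recovery runs use 6-10·10⁶ steps (one to
two minutes), the six-member λ family 1.5-2.5·10⁶ steps per member; at
those sizes the test suite requires the 2 kT gap back within 0.2 kT,
the bias profile to match −(1 − 1/γ)F within 0.3 kT RMS, and the
ideal λ within 0.03. Bias-grid spacing is 0.02 CV units; the deposit
reads the bias at the nearest grid node.

Ion fixtures use a 60 Å box at 0.15 mol/L (about 20 cations and 7200
water oxygens per frame); the bulk-concentration checks use hundreds
of frames so the edge-shell count noise sits near 3%.

# Known limitations

* The toy sampler's dynamics are overdamped Langevin only; kinetic
  observables (rates, dwell times) are not meaningful beyond ordering.
* Each replica is reweighted independently; no WHAM/MBAR-style
  combined estimator across the λ ladder is attempted.
* Trajectory I/O is multi-model PDB plus in-memory containers; binary
  trajectory formats are out of scope for this implementation.
* The parm7 writer expands one LJ type per atom, which is exact but
  quadratic in atoms; it refuses topologies beyond a configurable
  size.
* Arm-arrangement (parallel vs antiparallel) classification and
  branch migration are out of scope.
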