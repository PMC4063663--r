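---
title: "Pierced lassos: topology detection and folding simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pierced lassos: topology detection and folding simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Every disulphide bridge closes a covalent loop in a polypeptide chain. In
most proteins that loop is empty; occasionally part of the chain threads
through it, producing a knot-like motif — a *pierced lasso* — whose topology
can be switched on and off by the redox state of the bridge. In four-helix
bundle cytokines this motif couples chemistry (oxidation state), topology
(threaded or not), folding mechanism (how the chain gets through the loop),
and function-bearing native-state dynamics.

`plasso` implements the complete computational chain needed to study this
class of systems at Calpha resolution:

1. **Topology**: classify a structure's covalent loops as zero knot, cinch,
   empty lasso, or pierced lasso, with loop size, lasso terminus and the
   threaded segment.
2. **Model building**: a native-centric (Go-type) Calpha force field with
   three disulphide treatments — reduced, oxidized, and a dynamic
   (breakable) bridge.
3. **Sampling**: Langevin dynamics, NVE validation, umbrella sampling along
   the fraction of native contacts Q.
4. **Analysis**: WHAM thermodynamics (specific heat, folding temperature),
   per-segment folding order (q_segment versus Q), threading-mechanism
   classification (slipknot versus plug), and slow-mode native-state
   dynamics (NSD) profiles from principal component analysis.
5. **Synthetic systems**: an idealized four-helix bundle generator covering
   the full lasso taxonomy, so every stage can be exercised and validated
   without any structure download.

## Loop topology as computational geometry

The covalent loop between bridged cysteines `i < j` is realized as the
closed polygon of Calpha positions `i..j` plus the closing chord `j -> i`.
The loop is spanned with a **centroid-fan surface** (one triangle per
boundary edge). A chain tail pierces the loop when its polyline crosses
that surface; each segment-triangle intersection contributes `+1` or `-1`
depending on whether the segment runs along or against the fan orientation
(right-hand rule on the loop's vertex order). The *net* crossing number of
a tail is a topological quantity: for a closed boundary it does not depend
on which spanning surface is used, which is why the cheap fan substitutes
for a true minimal surface. Optional Chaikin corner-cutting (default two
rounds) smooths the boundary; we classify at rounds 0-3 and raise an
`ambiguous` flag whenever the answers disagree rather than silently picking
one.

Numerical safeguards:

* intersections use the Möller–Trumbore predicate with a half-open segment
  parameter, so a crossing exactly at a vertex joint is counted once;
* a deterministic sub-Angstrom jitter (fixed sinusoidal pattern, no RNG) is
  applied to tested chains, removing exact-coplanarity degeneracies without
  being able to change a robust crossing;
* same-sign hits closer than 1e-6 length units are merged (shared-edge
  double counts);
* in trajectory analysis the loop surface is recomputed every frame from
  the instantaneous loop coordinates, and frames whose loop has collapsed
  below a minimal fan area are flagged degenerate and excluded.

Classification conventions:

* **loop size** is the sequence separation `j - i`; with the canonical
  leptin numbering (bridge C96–C146) this gives the familiar 50-residue
  lasso;
* a cysteine within `terminal_margin = 10` residues of a chain end counts
  as terminal: both terminal gives *zero knot*, one gives a *lasso* (N or
  C), none gives a *cinch*;
* *pierced lasso* overrides the other labels whenever a tail has nonzero
  net crossings;
* the two tail bonds adjoining the loop are excluded from crossing traces:
  a pierce that close to the closure can slide off the chord edge and is
  not stable threading;
* the reported threaded segment is the maximal contiguous far-side run of
  tail residues adjacent to a crossing. Published thread lengths use
  unstated conventions that differ between reports, so ours is documented
  but never asserted against them.

Candidate scanning retains pierced lassos with loop size strictly between
40 and 200 residues — the sequence-separation window used when searching
for threaded candidates — and reports every rejection with its reason.

## The structure-based model

Each residue is one bead at the Calpha position. The Hamiltonian has
harmonic virtual bonds and angles, a two-term cosine dihedral, a
Gaussian-well attraction for every native contact, and a generic excluded
volume:

* bonds: `(k_b/2)(r - r0)^2` with `k_b = 2e4` epsilon/nm^2,
* angles: `(k_a/2)(theta - theta0)^2` with `k_a = 40` epsilon/rad^2,
* dihedrals: `k_d1 [1 - cos(phi - phi0)] + k_d2 [1 - cos 3(phi - phi0)]`
  with `k_d1 = 1`, `k_d2 = 0.5` epsilon,
* native contacts: `eps [(1 + (sigma/r)^12)(1 - G(r)) - 1]` with
  `G = exp(-(r - r0)^2 / 2w^2)`; the well is anchored at exactly `-eps` at
  the native separation, decays to zero at large `r`, and keeps a hard
  `(sigma/r)^12` core,
* non-native pairs (`|i - j| >= 3`, not in the contact map):
  `(sigma/r)^12` with `sigma = 4` A for all pairs.

The harmonic constants follow the convention of the MD package this model
family is calibrated for (the `k/2` form); with the unit masses and the
default step this also keeps the stiffest bond mode comfortably inside the
Verlet stability region. Internal units are nm, epsilon, and `k_B = 1`, so
temperatures are quoted in epsilon.

Choices the model leaves open and how we fixed them:

* **contact map**: Calpha cutoff 8 A with `|i - j| >= 4`
  (`method = "ca_cutoff"`); `shadow_approx` additionally removes pairs
  whose connecting segment passes within 1 A of a third residue — a
  Calpha-level approximation of shadow-map screening.
* **Gaussian width** `w = 0.5` A: narrow enough that contact formation is
  cooperative, wide enough that the well is sampled at folding
  temperatures. It is configurable and written into topology headers.
* **excluded-volume cutoff**: the `r^-12` term is truncated at 1.2 nm with
  force-shifting (both the potential and its derivative reach zero at the
  cutoff), so the integrator's neighbour list introduces no energy
  discontinuities; the deviation from the untruncated form is below
  2e-5 epsilon everywhere.
* **angle regularization**: a harmonic-in-theta angle term is singular at a
  straight chain (`1/sin theta` in the force). The force factor is capped
  (`sin theta >= 0.1`), and the bundle generator additionally keeps native
  bend angles at or below 2.6 rad, so in practice the singular region is
  visited only in strongly unfolded states, where the thermostat absorbs
  the bounded error.

### Disulphide oxidation states

The bridge enters the model in one of three ways: **oxidized** — an
unbreakable harmonic bond at the native cysteine separation, with stiffness
`k_ss = 500` epsilon/nm^2 (the covalent link runs through four side-chain
bonds, so its effective Calpha-Calpha stiffness is far below the backbone
virtual bond constant; at backbone stiffness a single cross-link would be
stiffer than a whole helix-helix interface and would visibly distort
global modes, which is not how an all-atom disulphide behaves); **dynamic** —
a breakable Gaussian contact of depth `eps_ss` (default 1 epsilon, the
strength of an ordinary native contact), able to form and break during
folding; **reduced** — plain excluded volume, no closure. The native pair
is removed from the ordinary contact list in the oxidized and dynamic
states so the interaction is not double-counted.

## Dynamics

Production sampling uses **BAOAB Langevin** dynamics with friction
`gamma = 1/coupling`; the stochastic-dynamics time constant defaults to
`coupling = 2` and the step to `dt = 0.005` reduced time. Masses are 1.
Velocity-Verlet NVE is provided for validation: the zero-friction limit of
one Langevin step reproduces it exactly, it is time-reversible to roundoff,
and its energy error scales as `dt^2`. Energy drift is assessed as the
*secular slope* of the total energy (shadow-energy oscillation excluded) in
the small-oscillation regime of a folded bundle; at `dt = 0.005` the
measured slope is of order 1e-5 epsilon per 1e4 steps. The kinetic
temperature estimator at full steps is exact for soft modes but
systematically low for modes with `omega*dt` of order one (a known property
of the BAOAB splitting), so thermostat accuracy is asserted on an
analytically solvable soft subsystem.

Umbrella sampling biases a differentiable contact fraction: each contact
contributes a logistic switch of width `0.1 r0` centred at `lambda r0`, and
the bias `0.5 k_umb (Q_s - Q_center)^2` is recorded per frame for WHAM
unbiasing. The sharp contact-count Q (formed iff `r < lambda r0`,
`lambda = 1.2`) remains the analysis coordinate.

Unfolded starts respect the covalent topology: with an oxidized or dynamic
bridge, the loop residues are laid out as a loose open ring (the covalent
loop exists in the unfolded state too) and the tails extend away from it,
followed by a displacement-capped steepest-descent relaxation of bonds and
overlaps only — contacts stay off so the coil stays unfolded.

## Thermodynamics and folding order

`wham_cv()` runs the standard multi-histogram (Ferrenberg–Swendsen)
iteration on potential-energy samples from a temperature ladder, in log
space to a relative tolerance of 1e-8, and reports the relative density of
states, `Cv(T)` from reweighted energy fluctuations, and `Tf` at the
`Cv` maximum. It refuses non-overlapping histogram sets (printing the
overlap matrix) and is invariant to window order. `wham_fq()` unbiases
umbrella windows into `F(Q)`. Both are validated against closed forms: the
configurational specific heat of a 1-D harmonic oscillator (1/2 in reduced
units) and the curvature of a quadratic free-energy profile.

Folding order is read from `q_segment` versus Q curves. A contact belongs
to a segment when **either** endpoint lies inside it; the alternative
(both-endpoint ownership) would discard exactly the tertiary contacts that
make a terminal helix a late folder, which is the signature of interest.
Transition detection uses two-state assignment with hysteresis
(`q_lo = 0.2`, `q_hi = 0.8`, minimum dwell 100 frames by default). For
marginally stable fixtures whose folded basin sits below Q = 0.8 at the
sampling temperature, the folded threshold is calibrated from a short
native-basin run — the threshold is a property of the basin, not a tuning
knob; the calibrated values used by the tests are stated there.

## Threading mechanisms

Per frame, the crossing state of each tail against the instantaneous loop
surface gives the net crossing number and the positions (along the tail,
counted from the loop attachment) of the crossings. A folding transition is
classified at *establishment* — the first frame where the tail's net
crossing equals the native parity and persists:

* **plug**: the free terminus itself passed through; operationally, some
  frame up to establishment shows the crossing within 3 residues of the
  terminus;
* **slipknot**: a doubled chain (hairpin) inserted; the crossings stay in
  the tail interior throughout;
* **none**: the folded basin was reached with no persistent crossing
  (threading failed or, with a reduced/dynamic bridge, was never required).

The discriminating rule is our operational reconstruction — the original
reports do not state one — and it is exercised against scripted traces with
known answers as well as against generator fixtures whose mechanism is
forced by construction.

## Native-state dynamics

The folded basin is sampled well below the folding temperature (the test
suite uses `0.65 Tf`; ladder estimates of Tf from native-start runs carry a
small upward hysteresis bias, and 0.65 keeps every fixture's retention
above 99.9%); frames with
`Q <= 0.85` are discarded and more than 1% of them aborts the run. Frames
are rigid-body aligned (Kabsch) to their mean, the 3n x 3n displacement
covariance is diagonalized, and the per-residue amplitude is the RMS
displacement within the subspace of the **first four principal components**
(summed over the subspace, reported in Angstrom). Differencing reduced and
oxidized profiles and splitting the trajectory into blocks gives a
permutation test for whether oxidation changes dynamics beyond +/-10
residues around the bridge: an empty loop (cinch) should show nothing
distal, a pierced lasso should.

Both states are sampled at the **same absolute temperature** (0.65 of the
lower of the two folding temperatures): a per-state temperature would scale
all amplitudes with the thermal energy and masquerade as a global
oxidation effect.

This Calpha-resolution NSD stands in for an all-atom treatment; the
assertable surface is the qualitative local-versus-global pattern, never
per-residue amplitudes.

## The synthetic bundle generator

`make_bundle()` produces idealized up-up-down-down four-helix bundles with
ideal helix geometry (rise 1.5 A/residue, radius 2.3 A, 100 deg/residue)
and spline connectors resampled to virtual-bond spacing; a deterministic
repair pass keeps nonconsecutive Calpha pairs at least 3.8 A apart and
bend angles below 2.6 rad while leaving helices exact. Eight kinds cover
the lasso taxonomy. For the pierced kinds the lasso is a helical hairpin
(post up, arc over, post down) whose cysteines meet at a realistic 5.5 A
closure, with the thread helix routed through the aperture perpendicular to
the loop plane — guaranteeing a clean single crossing by construction.
Designed cysteines carry SG pseudo-atoms placed 2.05 A apart.

What the generator emulates: the taxonomy of closed-loop topologies, ideal
secondary structure, a realistic disulphide closure, loop-size control
(helix length 30 gives the 68-residue covalent loop at which threading is
expected to switch mechanism). What it does not: real sequences, side
chains, irregular packing, NMR ensembles, or the contact heterogeneity of
evolved proteins. Passing tests on these fixtures validate the machinery
and the qualitative physics of loop closure and threading — not any
per-protein quantitative prediction.

## Problem sizes used by the test suite

All empirical checks run on desk-scale systems chosen once as study
conditions:

* stability ordering: helix length 12 pierced bundle (67 residues),
  4-temperature ladder at 1.5e5 steps per run, both oxidation states;
* threading mechanisms: small-loop C-lasso (loop 32) quenched at T = 0.7
  for 4e5 steps per run, and the 68-residue-loop N-lasso quenched at
  T = 0.73 for 6e5 steps per run with its folded threshold calibrated to
  that fixture's basin (Q = 0.55); quench batches continue until at least
  30 classified transitions per fixture. The small-loop analog is scaled
  below the canonical 50-residue lasso; smaller loops sit deeper in the
  slipknot regime, so the contrast against the 68-residue fixture is the
  same comparison at sharper statistics;
* folding order and NSD: helix length 18 N-lasso (77 residues) and a
  helix length 16 empty-loop control, ladders of 3e5 and 1.2e5 steps and
  native-basin runs of 2.2e5 steps at 0.65 Tf.

Event counts at this scale make the modal-label and permutation assertions
stable but leave fractions with sampling error of order ten percent; the
package computes Wilson intervals alongside every mechanism fraction for
exactly that reason.

## Known limitations

* Backbone (open-knot) knot invariants are out of scope; a backbone knot
  threaded through nothing would not be detected.
* The classifier refuses loops containing chain breaks instead of
  rebuilding missing residues.
* The Calpha force field has no electrostatics, solvent, or hydrogen
  bonding; threading kinetics in a native-centric model underestimate the
  role of non-native interactions, which are known to assist plugging.
* The discovery-scan half of the original study (structure-bank-wide
  geometric threading searches and sequence alignments) is deliberately
  not reimplemented; `scan_candidates()` classifies user-supplied
  structures instead.

## A worked example

```{r example}
library(plasso)

s <- make_bundle("pierced_C", helix_length = 14, loop_length = 5)
classify_lasso(s)

cm <- build_contact_map(s)
ox <- build_topology(s, cm, attr(s, "cys_pair"), state = "oxidized")
tr <- run_langevin(ox, cfg = run_config(temperature = 0.7, n_steps = 1e5,
                                        stride = 100, seed = 1))
autoplot(tr)

temps <- c(0.65, 0.75, 0.85, 0.95)
runs <- lapply(seq_along(temps), function(k) {
  run_langevin(ox, cfg = run_config(temperature = temps[k], n_steps = 2e5,
                                    stride = 200, seed = k))
})
th <- wham_cv(lapply(runs, function(r) r$e_pot), temps)
glance(th)
autoplot(th)
```
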