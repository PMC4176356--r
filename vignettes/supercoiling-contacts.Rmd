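---
title: "Supercoiled rings and enhancer-promoter contacts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercoiled rings and enhancer-promoter contacts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilsim)
```

## The question and the model

Enhancers activate promoters over genomic distances of up to a megabase,
and contacts between the two are strongly enriched when both sit in the
same supercoiled topological domain. `coilsim` implements a
coarse-grained polymer model for studying how two physical knobs —
torsional stress (the linking-number deficit ΔLk of a closed ring) and a
short-range affinity between two designated beads — jointly control the
fraction of time the two sites spend in contact.

DNA plasmids and chromatin fibres are modelled as closed worm-like bead
chains. All simulation quantities are in reduced units: the bead
diameter $d$ is the unit of length, the thermal energy $k_BT$ the unit
of energy, the translational drag per bead the unit of friction, and
$d^2\gamma/k_BT$ the unit of time. The energy has five terms:

* **Bonds** — harmonic springs, $\tfrac12 k_{bond}(r - d)^2$ with
  $k_{bond} = 200\,k_BT/d^2$ by default, stiff enough to preserve
  topology (length fluctuations ≈ 7 %) while stable at the default
  timestep.
* **Bending** — discrete worm-like chain, $k_{bend}(1-\cos\beta)$ per
  junction. To first order $k_{bend}$ equals the persistence length in
  bond lengths.
* **Twist** — the dihedral potential
  $V(\phi)=\tfrac12 k\,(1-\cos(\phi-\phi_0))$ acting on the
  parallel-transport twist angle $\phi$ of every junction, with
  $k = 65\,k_BT$ for DNA and $50\,k_BT$ for chromatin fibre. $V$ is
  $2\pi$-periodic, zero at $\phi_0$ and maximal ($=k$) half a turn
  away.
* **Excluded volume** — a purely repulsive truncated-shifted 12-6 pair
  term cut at $2^{1/6}d$ between all non-bonded beads, giving the chain
  an effective diameter of one bead (3 nm for DNA, the screened
  physiological value).
* **Affinity** — a truncated 12-6 Lennard-Jones well of depth
  $\varepsilon \in [0, 12]\,k_BT$ and cutoff $2d$, applied **only** to
  designated enhancer-promoter bead pairs. Beyond the cutoff the
  potential is exactly zero; the well is left unshifted so that its
  minimum is exactly $-\varepsilon$.

Two beads count as "in contact" when their centre-to-centre distance is
below two bead diameters (6 nm for 3 nm beads), with minimum-image
distances in periodic boxes. The telegraph of this indicator over time,
reduced to its fraction-on $\Sigma t_{on}/t_{total}$ and mean dwell
times $\langle t_{on}\rangle$, $\langle t_{off}\rangle$, is the central
observable.

## Twist representation and topology bookkeeping

The torsional state is carried by a unit material frame vector on every
edge, kept perpendicular to that edge. The twist angle at a junction is
measured by parallel-transporting the incoming edge's frame onto the
outgoing tangent and reading off the rotation to the outgoing frame —
a scheme that is exact in the twist and remains well defined at
90-degree bends (only an exactly antiparallel pair of consecutive
tangents is degenerate). With transport-measured twist and the exact
Gauss double-sum writhe, the discrete Calugareanu identity

$$ Lk \;=\; Tw + Wr $$

holds to machine precision for every closed ring, so the linking
deficit is conserved by the dynamics unless segments physically cross
(which excluded volume forbids at accessible temperatures). Twist
torques redistribute twist between junctions without changing the
total; twist-writhe interconversion happens only through the
positional gradient of the transport twist, implemented with the
curvature-binormal formula of discrete rod mechanics and verified
against transport-consistent finite differences of the total energy.

ΔLk is imposed through the initial condition rather than through
equilibrium-offset angles: a freshly built ring stores
$2\pi\,\Delta Lk/N$ of material twist per junction (on a flat circle,
$Tw = \Delta Lk$, $Wr = 0$), and the dynamics then partitions the
deficit between twist and writhe. This keeps the bookkeeping invariant
— `topology_state()` recovers ΔLk = Tw + Wr on every frame — which the
equivalent potential-offset formulation would obscure. Supercoiled
production runs start from a pre-built interwound (plectonemic)
conformation carrying most of the deficit as writhe, skipping the slow
buckling transient of a twisted flat circle; the twisted-circle path is
retained (`make_plasmid(start = "circle")`) as a cross-check that both
relax toward the same mean writhe.

Only the magnitude of ΔLk matters: the model is mirror symmetric, so
positive and negative supercoiling of the same extent behave
identically. Signs are kept for bookkeeping.

## Dynamics

Positions follow overdamped Euler-Maruyama steps
$\Delta x = F\,\Delta t + \sqrt{2 k_BT\,\Delta t}\,\xi$ with unit drag;
frame angles follow the analogous update with rotational drag
$\gamma_r = \gamma d^2/3$ (the order of magnitude for a bead-sized
cylinder — only kinetic prefactors, never equilibrium averages, depend
on it). The default timestep is $10^{-4}$ reduced units, chosen for
stability against the stiff bond and excluded-volume terms; runs that
trip the topology-conservation check (|Lk drift| < 0.05) should halve
it. Identical seeds give bit-identical trajectories on one platform
(the noise stream is an own xoshiro256++/polar-method generator, so the
integrator does not touch R's RNG).

Non-bonded pairs are pruned with a Verlet neighbour list (skin 0.7 d,
rebuilt on a half-skin displacement criterion) backed by cell binning
in periodic boxes; results are identical to the all-pairs computation,
which stays available for testing. Equilibration is detected from the
integrated autocorrelation time (Sokal windowing, $c = 5$) of the
writhe for torsionally stressed runs and of the radius of gyration
otherwise; `bd_run()` discards five autocorrelation times (capped at
half the run) before analysis, and run lengths are judged against the
40-fold (DNA) or 10-fold (chromatin) equilibration-time convention via
the schedule's `equilibration_multiple`.

## Scenario generators

The generators in `make_*()` encode the studied conditions and are not
meant to be retuned:

* `make_plasmid()` — a 340-bead DNA ring (3 nm beads at 0.34 nm/bp:
  3000 bp), persistence length 17 beads (51 nm), torsional stiffness
  65 kT, enhancer and promoter diametrically opposed on the circular
  map (beads 1 and 171), ΔLk from 0 to −20.
* `make_chromatin_loop()` — a 200-bead chromatin fibre loop (30 nm
  beads, 4000 bp/bead ≈ 800 kb, the size of a topological domain),
  persistence length 60 nm, torsional stiffness 50 kT, sites 100 beads
  (≈ 400 kb) apart by default.
* `make_crowded_loops()` — 20 loop copies in a periodic cube sized for
  a 20 % bead volume fraction (edge ≈ 21.9 d), random orientations on a
  jittered grid, pushed apart by capped-displacement relaxation with a
  thermal unjamming stage; affinity is strictly intra-loop.
* `make_tethered_pair()` — two loops joined by one permanent harmonic
  bond between border beads; one enhancer with two equidistant,
  equally attractive promoters (ε = 8 kT), one in each domain, contour
  distance measured through the tether for the inter-domain promoter.
  The single-bond tether is the minimal mechanism that keeps the two
  domains topologically independent.
* `make_separation_sweep()` — single loops with genomic separations of
  ≈ 16, 200 and 400 kb (4, 50, 100 beads). These run dilute: the
  enhancement index is a within-scenario ratio, and crowding is
  available separately through `make_crowded_loops()`.
* `make_markov_telegraph()` — exact two-state Markov telegraphs with
  known rates, the ground truth for validating the dwell-time
  estimators (stationary fraction-on $k_{on}/(k_{on}+k_{off})$, mean
  dwells $1/k_{off}$ and $1/k_{on}$).

Supercoiled initial states are built geometrically (two antiparallel
superhelices joined by caps), settled with torsion switched off so that
no torsional driving can force strand passages during the push-off, and
then given exactly the twist remainder $\Delta Lk - Wr$; the builder
retries with less writhed targets until the settled state passes the
chain invariants with its topology intact.

Two further initial-condition conventions make contact statistics
measurable at desk scale. First, plectonemic starts roll the contour
parameterization so the two labelled sites begin juxtaposed
mid-interwound; without this they sit at the two apical loops, and only
quarter-contour slithering — orders of magnitude beyond desk-scale run
lengths — could ever join them. Second, every affinity scenario
($\varepsilon > 0$) starts in the bound state, produced by a temporary
harmonic capture bond that is released before production. The first
diffusive encounter of two sites tens of beads apart is a
cluster-scale event; the binding/unbinding alternation *around* the
bound state, which is what the dwell-time decomposition describes, is
sampled in minutes. Fraction-on values from such runs converge from
above at conditions where rebinding is rare, and comparisons across
ΔLk use identical protocols. In the tethered-domain system only the
intra-domain pair is capture-started; the inter-domain contact is the
measured outcome, and the second domain is oriented so the two
interwounds extend away from their shared tether.

## Parameter mappings and calibrations

**Bending.** For DNA (17 bonds per persistence length) the first-order
mapping $k_{bend} = P/l$ is accurate: equilibrium-sampled chains return
48 nm against the 51 nm target. For chromatin fibre the target
persistence length is only two bond lengths, and there the first-order
mapping over-stiffens the chain — excluded volume between
near-neighbour beads suppresses sharp bends and contributes its own
entropic rigidity, so $k_{bend} = 2$ measures ≈ 74 nm. The default
chromatin bending constant is therefore calibrated numerically to
$k_{bend} = 1.4\,k_BT$, which returns 60-65 nm from the
tangent-correlation estimator.

**Persistence-length estimation.** `persistence_length()` fits
$\langle t(0)\!\cdot\!t(s)\rangle = e^{-s/P}$ over separations up to
two persistence lengths. The window is seeded from the short-range
decrement and deliberately not re-grown from the fitted value: very
flexible self-avoiding chains have a slowly decaying excluded-volume
tail in their tangent correlations, and a window that follows the fit
creeps up that tail without bound. Closed rings use all origins around
the ring (restricted to a quarter of the contour); open-chain
ensembles should pool many independent replicates, because a slowly
rotating chain keeps a coherent overall direction that inflates the
apparent correlation at large separations.

**Twist-writhe partition.** At ΔLk = −15 the DNA parameterization
converts essentially all of the imposed deficit into writhe at
equilibrium (⟨|Wr|⟩/|ΔLk| ≈ 0.93-0.97 rather than the ~0.80 continuum
expectation). Scanning the torsional stiffness from 10 to 65 kT moves
this fraction only weakly: in this discretization — bond length equal
to the excluded-volume diameter, bending soft against kinking at
plectoneme apices — an extra interwound turn costs only a few kT of
bending, far less than the ~11 kT/turn of twist relief available at an
80/20 partition, so writhe wins almost completely regardless of the
torsional stiffness. An independent Metropolis Monte Carlo sampler run
on the same energy function over-writhes at least as much, identifying
this as a property of the energy model rather than of the integrator.
The chromatin parameterization, which is the regime the contact
analyses actually use, sits where it should: a 200-bead loop at
|ΔLk| = 20 equilibrates near ⟨|Wr|⟩ ≈ 18.2-18.5 turns, consistent with
its deliberately high torsional stiffness, so no upward calibration of
the chromatin dihedral constant was needed.

## Contact statistics

`telegraph()` reduces a trajectory to the binary contact signal of a
site pair; `dwell_stats()` run-length encodes it. The first and last
runs touch the observation window and are right/left-censored, so they
are excluded from the mean dwell times but kept in the fraction-on
(which is the exact ratio of on-samples to all samples). A state with
no interior runs reports `NA` dwell statistics rather than a
fabricated value. Off-time distributions under strong supercoiling are
heavy-tailed — the sites occasionally slither far apart — so no
truncation is applied and medians are reported alongside means.
Uncertainties come from a moving-block bootstrap over the telegraph
with block length five integrated autocorrelation times of the signal.

`enhancement_index()` is the fold change of fraction-on against the
torsionally relaxed state; `preference_ratio()` compares the
intra-domain and inter-domain telegraphs of the tethered-pair system
(the two signals are tracked independently — the enhancer may touch
both promoters at once). A zero inter-domain fraction in the sampled
window is reported as a lower bound against the denominator's
confidence ceiling, never as infinity. `phase_diagram()` interpolates
a gridded fraction-on surface bicubically (repeated one-dimensional
natural cubic splines) and extracts isoprobability lines at 0.1, 0.25,
0.5 and 0.75 with `contourLines()`; missing grid cells are masked and
the isolines clipped around them. The default grid spans
ΔLk ∈ {0, −5, −10, −15, −20} × ε ∈ {0, 4, 8, 10, 12} kT.

## What the generators do and do not emulate

The synthetic scenarios reproduce the *mechanical* setting:
torsionally stressed closed chains with persistence lengths, bead
sizes, densities and site placements of the studied systems. They do
not model sequence-dependent bending, nucleosome-scale structure,
topoisomerase action (strand passage), the chirality asymmetry between
positive and negative supercoiling, or competing multi-site affinity
networks. Passing tests therefore demonstrate the statistical
mechanics of the coarse-grained model, not molecular detail of real
chromatin.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
which the package treats as its own design choice of problem sizes:
single chains of 40-400 beads, runs of $10^5$ to $6\times10^6$ steps
(tens to hundreds of reduced time units), and tens of independent
replicates where ensembles are needed. Contact statistics at these
sizes rest on hundreds, not millions, of dwell events; the qualitative
orderings (fraction-on rising with |ΔLk| at ε = 10 while flat at
ε = 0; ⟨t_off⟩ falling while ⟨t_on⟩ stays level; intra/inter
preference growing with supercoiling) are stable at this scale, while
the absolute fold-change bounds of the production-scale study carry
sampling error of order tens of percent. Degenerate inputs fail loudly
by design: zero-length segments, antiparallel consecutive tangents,
non-finite forces (timestep too large), non-decaying tangent
correlations, and telegraphs with no interior events all raise
conditions instead of returning numbers.

## Known limitations

* The twist-writhe partition of the DNA parameterization over-converts
  relative to continuum elasticity (see above); analyses that depend on
  the *absolute* partition at 3 nm resolution should treat the writhe
  fraction as an upper bound. Contact statistics, which depend on the
  plectonemic geometry rather than the exact partition, are unaffected
  in kind.
* Dwell times are in reduced units; mapping them to seconds would
  require a drag coefficient that the coarse-graining does not fix.
* The crowded-box generator relaxes overlaps with capped displacements;
  its output is a valid, topology-exact starting state, but crowded
  systems still need their own equilibration stretch before analysis.
* Writhe evaluation is exact but quadratic in bead number; it is the
  dominant per-sample cost for rings above a few hundred beads.
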