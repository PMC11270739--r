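---
title: "Analysing ligand transport through enzyme tunnel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing ligand transport through enzyme tunnel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Enzymes with buried active sites exchange substrates and products with the
solvent through transport tunnels. Molecular-dynamics simulations of a
ligand binding to and escaping from such an enzyme produce large trajectory
sets in which the interesting questions are coarse: where is the ligand
(active-site cavity, tunnel network, bulk solvent), which tunnel did it use
to get in or out, which metastable ligand states recur across independent
simulation campaigns, and what association/dissociation kinetics does a
Markov state model (MSM) of the data imply. `tunneltransit` implements that
analysis layer. It deliberately does not run or post-process the MD itself:
its inputs are per-frame coordinates (or precomputed distances) of the
ligand and a handful of landmark residue groups.

The geometric picture is a star of tunnels meeting at the catalytic
machinery. Two kinds of landmarks define it: the centre of mass (COM) of
the catalytic residue group, anchoring the bottom of the cavity, and the
COM of each tunnel's bottleneck residues, marking the narrowest point of
that tunnel. For the haloalkane-dehalogenase-type system that motivated the
defaults, four tunnels (`p1a`, `p1b`, `p2`, `p3`) and a three-residue
catalytic group are typical, but any network with at least one tunnel is
accepted.

## Distances and regions

Everything downstream consumes three per-frame distance families, all in
angstrom:

* `d_cat(t)` — ligand COM to catalytic COM;
* `d_bt[T](t)` — ligand COM to the bottleneck COM of tunnel `T`;
* `L[T](t)` — catalytic COM to bottleneck COM of `T`, i.e. the momentary
  tunnel length. `L` is recomputed every frame because the landmark groups
  breathe with the protein; a `static_lengths` mode freezes it at the first
  frame for sensitivity checks.

COMs are mass-weighted when masses are available and geometric otherwise
(`weighting = "auto"`); the two differ negligibly for compact residue
groups, and both modes are exposed because conventions vary between
analysis toolchains.

Region labels partition frames by `d_cat`: cavity for `d_cat <= r_cavity`
(default 5 A), tunnel up to `r_bulk` (default 19 A, of the order of the
average tunnel length in the motivating system), bulk beyond. The
boundaries are half-open above — a frame exactly at 5 A is cavity — so the
three printed ranges 0–5, 5–19, >19 form a true partition. Region labels
are monotone in `d_cat` by construction.

## The transit state machine

Completed crossings between bulk and protein interior are detected in three
stages.

**Position assignment.** Per frame, the closest bottleneck `T*`
(smallest `d_bt`, ties broken by the declaration order of the tunnels —
deterministic and configuration-controlled) sets the reference length
`L = L[T*]`. With `d = d_cat` and band half-width `bt_cutoff_along`
(default 2 A):

* `out_` (bulk side) if `d > L + bt_cutoff_along`;
* `in_` (interior side) if `d < L - bt_cutoff_along`;
* otherwise the frame is in the bottleneck band: `bt_` carrying `T*` when
  `d_bt[T*] <= bt_cutoff_across` (default 5 A), `bt_unknown` when the
  ligand is laterally too far from any bottleneck to attribute the
  passage.

Both band boundaries are inclusive: the strict inequalities of the bulk
and interior rules leave equality to the band. The lateral
(`bt_cutoff_across`) check governs the whole band, above or below the
tunnel length, because its purpose is to decide whether the bottleneck
identity is trustworthy, not where along the tunnel axis the ligand sits.

**Transition detection.** A crossing is complete when the general state
flips between `in_` and `out_`. Band frames in between make the event
`via_bottleneck`, and its category is the band state of the *last* band
frame before the exit (last-write-wins; a band visit that ends
`bt_unknown` yields category `unknown`). A band excursion that returns to
its origin side is no event. Frames before the first general-state frame
carry no memory. A direct flip with no intervening band frame is a
`direct` event categorised by the common closest tunnel of its two end
frames; when the sides disagree, a `dist_tolerance` (default 1 A) may
relabel one side: if the other side's tunnel is within the tolerance of
the closest one on that frame, the sides are reconciled. The destination
side is offered the swap first (so an out-side `p1a` against an in-side
`p1b` with a 0.4 A gap on the in-side resolves to `p1a`); irreconcilable
crossings are `mixed`. Via-bottleneck events never need the tolerance —
the bottleneck that was actually visited wins unconditionally.

**Utilization.** Each completed crossing is counted once, per category
(tunnel id, `mixed`, `unknown`), per trajectory; replicate totals sum
their trajectories; a scheme is summarised as mean ± sample standard
deviation (n−1) over its replicate totals, plus relative fractions. The
sample convention was chosen because three replicates is the typical
campaign size and the replicate totals are the units of replication.

The detector is validated two ways: against an independent brute-force
enumerator that scans all consecutive general-state pairs (property-tested
on thousands of random state sequences), and against the synthetic walk
generator, which returns the exact event list it planted.

## Unified ligand states

Metastable states from independent replicates are matched through distance
fingerprints. Each state's representative ensemble is summarised, per
characteristic distance (`d_cat` plus one `d_bt` per tunnel), by mean and
25th/50th/75th percentiles — 20 numbers for a four-tunnel network.
Percentiles use linear interpolation between order statistics (R's type 7,
the scientific-Python default), stated here because percentile conventions
differ across toolchains in exactly the small-ensemble regime this targets.

Fingerprints are standardised column-wise (the 20 variables share units
but differ in spread by an order of magnitude; a flag disables it),
reduced to three principal components — with each component's sign fixed
so its largest-magnitude loading is positive, making scores reproducible —
and clustered with HDBSCAN at `min_cluster_size = 2`. Two details of the
clustering are deliberate:

* The selection rule may pick the root (all-data) cluster, and points
  attached directly to a selected root are labeled only if they persist to
  the maximal density level. This single-cluster-capable variant behaves
  identically to the standard excess-of-mass rule whenever genuine
  sub-structure exists, and degrades sensibly when it does not: a tight
  pair plus a far outlier gives a pair cluster and an outlier singleton,
  and an ensemble of identical fingerprints gives one cluster rather than
  all noise.
* Density noise becomes singleton unified ligand states (ULSs), so every
  metastable state receives a label; singleton ULSs are meaningful —
  a state sampled in only one replicate is exactly what the presence
  matrix should reveal.

Cluster labels are renumbered by decreasing size, then first-member order.
The presence matrix cross-tabulates ULS × (scheme, replicate) with the
mean stationary probability of the member states (member counts when
probabilities are absent); an empty cell means the ULS was never visited
in that replicate.

## Markov state models and kinetics

The MSM stage is a compact, self-contained re-implementation of the
standard pipeline:

* **TICA** solves the symmetrized time-lagged covariance generalized
  eigenproblem (default lag 2 ns, converted to frames through the frame
  interval). A ridge of 1e-6 on the instantaneous covariance keeps the
  problem well-posed for collinear features; the symmetrized estimator is
  used throughout (no Koopman reweighting). Lagged pairs never span
  trajectory boundaries.
* **Microstates** come from seeded k-means (default 1000, capped by the
  available frames); a fixed seed gives bit-identical assignments.
* **Counting and estimation** use a sliding window at the MSM lag
  (default 20 ns). Count matrices are restricted to their largest strongly
  connected component, with the dropped count mass reported. The default
  estimator symmetrizes counts, `(C + C')/2`, and row-normalises — this
  yields exact detailed balance with the stationary distribution in closed
  form (proportional to symmetrized row sums); the non-reversible
  maximum-likelihood estimator is a flag away, with the stationary
  distribution from the leading left eigenvector.
* **Metastable lumping** replaces PCCA++ with k-means on the leading
  right eigenvectors (eigenvalue-scaled, stationary-weighted). This
  spectral lumping recovers block structure exactly on
  block-dominant matrices and is deterministic given its seed; it does
  not provide PCCA++'s fuzzy memberships, which this package does not
  need. The number of metastable states defaults to the largest spectral
  gap within 2–8 and is flagged as a heuristic; implied-timescale plots
  (`implied_timescales()`) and the Chapman–Kolmogorov test (`ck_test()`,
  macrostate self-transition probabilities of the powered model against
  re-estimation at multiples of the lag, with a trajectory-resampling
  bootstrap band) are provided for the user to confirm the choice.
* **Kinetics.** Mean first-passage times solve the standard linear system
  (zero on the sink set, stationary-weighted over the source set).
  Sink states are those whose representative `d_cat` median lies in the
  cavity; source states those predominantly in the bulk; both are
  automated from the fingerprint medians and overridable. Rates are
  reciprocal MFPTs and the dissociation-constant estimate is their
  dimensionless ratio `k_d = mfpt_on / mfpt_off`. No volume/concentration
  normalisation is applied — converting to a molar constant requires a
  simulation-box standard-state correction that depends on setup details
  the package does not see, so the unit conversion is left to the caller.

## The synthetic generator

Because real campaign data are tens of microseconds of MD, every stage is
validated on synthetic inputs with planted truth:

* `make_toy_network()` builds a star geometry — catalytic COM at the
  origin, bottleneck COMs at `length × direction` — realised as explicit
  atoms whose centroids hit those points to machine precision.
* `simulate_ligand_walk()` executes a planned sequence of crossings along
  tunnel axes with Gaussian positional jitter. Anchor radii keep a safety
  margin of `max(1, 6·noise_sd)` beyond every decision boundary, and
  same-side relocations move at constant safe radius, so in clean mode
  the planted event list is recovered exactly; a `hard` flag removes the
  margins to exercise the tolerance rules. Default jitter is 0.3 A,
  roughly the frame-to-frame COM noise of a small ligand at this scale.
* `simulate_markov_chain()` samples a known transition matrix and embeds
  it as Gaussian blobs, returning exact first-passage times for parameter-
  recovery tests.
* `generate_metastable_ensembles()` draws distance ensembles around
  planted fingerprint profiles with controllable replicate presence.

What the synthetic data do *not* emulate: force-field energetics,
anisotropic and state-dependent noise, landmark breathing (toy landmarks
are rigid), tunnel curvature, and recrossing-dominated boundary dynamics.
Passing the planted-recovery tests therefore demonstrates the correctness
of the bookkeeping and estimators under the model's assumptions, not the
physical fidelity of any MD campaign.

## Numerical choices and problem sizes

Deterministic tie-breaks everywhere: closest-bottleneck ties by canonical
tunnel order, PCA/TICA component signs by largest-magnitude loading,
k-means by explicit seeds, ULS labels by size-then-first-member. The test
suite runs at deliberately desk-scale sizes — 10^4-frame region plants,
10^5-step chains for parameter recovery (transition probabilities within
three standard errors, MFPTs within 5%, `k_d` within 10% of truth),
10^5 Monte-Carlo walkers against the linear MFPT solve, 1000-sequence
property tests of the transit machine — chosen so the whole suite
completes in about a minute while keeping every statistical check
well-powered.

## Limitations

* Inputs are assumed imaged and whole; no periodic-boundary handling, no
  alignment, no geometric tunnel detection.
* The spectral-gap choice of the metastable-state count is a heuristic;
  inspect the implied timescales before trusting it.
* `k_d` is a dimensionless MFPT ratio, comparable across schemes and
  replicates but not directly to a molar experimental constant.
* Reversible estimation by count symmetrization is the standard
  approximation for well-sampled equilibrium data; strongly
  non-equilibrium sampling should use the non-reversible mode and judge
  connectivity carefully.
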