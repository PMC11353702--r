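---
title: "Solvation-shell and ion-interaction analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvation-shell and ion-interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvshell)
```

# Scope

solvshell post-processes molecular-dynamics trajectories of proteins in
electrolyte and ionic-liquid (IL) co-solvents.  The motivating system is a
halophilic, tetrameric alcohol dehydrogenase simulated at 323.15 K in a
100 Å cubic box with 4 M KCl plus 150 mM of one of thirteen IL ion pairs;
the questions the toolkit answers are the ones that matter for such
systems: how strongly do ions pair with each other and with acidic surface
residues (RDF → PMF → binding energies), how long do they stay (survival
probabilities and residence kinetics), where do they sit around
carboxylates (spatial density grids), does the protein leave its native
conformational basin (Cα PCA → free-energy landscapes), and does the
co-solvent rewire the salt-bridge network or park ions between aromatic
gating residues (network diffs, π-stacking event series).

Everything runs on orthorhombic periodic boxes; triclinic cells are
rejected explicitly.  Internal units are Å, ns and kJ/mol throughout, with
conversions only at I/O boundaries (e.g. Bohr in Gaussian cube headers).

# Pair structure

`compute_rdf()` tallies minimum-image reference–selection distances into
bins of width `dr` on (0, r_max] and normalises by the ideal-gas
expectation

$$ g(r) = \frac{\langle n(r) \rangle}{\rho_{\mathrm{sel}}\, V_{\mathrm{shell}}(r)\, n_{\mathrm{ref}}} $$

with exact shell volumes $\frac{4}{3}\pi (r_{i+1}^3 - r_i^3)$ rather than
the $4\pi r^2 \Delta r$ approximation, and the instantaneous per-frame box
volume, so constant-pressure trajectories normalise correctly.  Defaults
`dr = 0.1` Å and `r_max = 15` Å match the window used for combined-shell
energies; `r_max` may never exceed half the smallest box length, where the
minimum-image convention stops being unambiguous.

The potential of mean force is the standard reversible-work transform

$$ W(r) = -k_B T \ln g(r), \qquad k_B = 0.0083144621\ \mathrm{kJ\,mol^{-1}K^{-1}},\ T = 323.15\ \mathrm{K\ by\ default}, $$

with $g = 0$ bins masked rather than clamped.  Shells are detected on a
centred moving average of $g$ (3 bins by default) as local maxima with
prominence ≥ 0.05 over the higher flanking minimum; the smoothing window
and prominence are parameters because noisy desk-scale RDFs otherwise
sprout spurious shells.

**Binding-energy estimator.**  Per-shell binding energy is defined here as
the PMF well depth at the shell peak relative to bulk,
$\Delta G_{\mathrm{shell}} = k_B T \ln g(r_{\mathrm{peak}})$, reported
positive for attractive shells; the `one_shell` mode reports the first
shell, `combined_15A` sums all shells peaking within 15 Å.  This is a
design choice: published per-system tables of this kind do not state their
estimator, and their magnitudes (tens to hundreds of kJ/mol) cannot be
produced by any $k_B T \ln g$ reading — that would require
$\ln g \approx 68$.  The estimator is therefore pluggable
(`binding_energy(..., estimator = )`), absolute cross-study magnitudes are
declared non-comparable, and the quantities this package treats as
meaningful are *relative*: orderings and ratios across systems computed
with one consistent estimator.  Uncertainties come from block averaging
(`binding_energy_blocked()`, ≥ 3 contiguous blocks).

# Residence kinetics

`shell_occupancy()` marks a mobile particle occupied when its
minimum-image distance to any reference atom is ≤ the shell radius (4 Å
default, the coordination criterion used for ion–residue counts).
`survival_probability()` implements the continuous-residence definition

$$ SP(\tau) = \Big\langle \tfrac{N_{\mathrm{cont}}(t, t+\tau)}{N(t)} \Big\rangle_t $$

where a particle survives to $t+\tau$ only if occupied at every
intermediate frame; an `intermittency` window (default 0) tolerates brief
exits by gap-filling the occupancy series first.  Continuous residence is
the default because the scientific contrast of interest is prolonged
versus frequently-exchanging coordination.

**Time origins.**  Origins are every frame (stride configurable) in
$1 \dots n - \tau_{\max}$, i.e. a fixed origin set shared by all lags.
Averaging each lag over whichever origins happen to fit instead makes
$SP$ occasionally non-monotone when a shrinking origin set drops a
low-survival origin; with a fixed set, $SP(0) = 1$ and monotone
non-increase hold by construction, and the default
$\tau_{\max} = n/2$ keeps half the trajectory as origins.  The
implementation is a run-length recursion ($O(\mathrm{frames} \times
\mathrm{particles})$ preprocessing), not a per-origin rescan.

Decay rates come from a least-squares fit of $\ln SP$ versus lag.  The
default fit window keeps lags with $SP \ge 0.1$: beyond that the log
transform amplifies Monte-Carlo noise faster than points add information.
Cross-system ranking uses the area under $SP(\tau)$ (trapezoidal), with
rank 1 for the longest-lived system, ties broken by fitted residence time
and then name; the ranking statistic is swappable to the fitted τ because
the convention behind published ranks of this kind is not stated.

For the two-state Markov binder used as ground truth, the per-frame
release probability $p_{\mathrm{off}}$ maps to a rate
$k = -\ln(1 - p_{\mathrm{off}})/\Delta t$; the distinction matters at
$p_{\mathrm{off}} = 0.2$, where the naive $p/\Delta t$ is 11% off.  A
consequence worth knowing: two binders with a 4× ratio of
$p_{\mathrm{off}}$ have a residence-time ratio of
$\ln(1-p_1)/\ln(1-p_2)$, ≈ 4.35 for 0.05 vs 0.2, which is what the
recovery checks expect around their nominal factor of 4.

# Spatial density grids

A residue-fixed frame is defined by three atoms: origin, +x direction and
plane (z is the plane normal, y completes the right-handed triad).  For
carboxylate-centred maps the natural choice is the carboxylate carbon as
origin with the two oxygens fixing x and the plane; the reference tool
used for such maps in the MD literature does not document its frame atoms,
so ours are explicit parameters and comparisons are qualitative.
Selection positions are folded to the frame origin's central image before
rotation, the grid is a cube (default 12 Å side, 0.5 Å voxels) and
relative density divides the voxel count rate by the whole-box bulk
density of the selection, so bulk voxels read 1.  The conventional
visualisation isovalues (10 for water, 3 for potassium) are carried as
metadata only.  Exports are OpenDX and Gaussian cube, both written z
fastest per their format definitions, cube lengths in Bohr.

# Conformational analysis

Superposition is Kabsch via SVD with the determinant correction that
forbids reflections.  The default reference is the iterative mean
structure (re-fit until the mean moves < 1e-4 Å), because first-frame
referencing biases RMSF toward whatever the first frame happened to be.
PCA is the mass-unweighted eigendecomposition of the covariance of the
aligned Cα coordinates; eigenvalues are in Å² and the report always
includes the cumulative two-component variance so statements like "PC1
and PC2 describe more than half the motion" are checkable.

The landscape is $F = -k_B T \ln(P / P_{\max})$ over a 2-D histogram of
(PC1, PC2), minimum pinned at 0, empty bins masked (no pseudo-counts),
grid spanning the sampled range padded 5%.  `find_minima()` does
persistence merging: bins are flooded in increasing F (ties broken by bin
index, so results are deterministic), and when two basins meet at a
saddle the shallower is absorbed if its depth below the saddle is under
`depth_threshold`.  Masked bins are treated by default as a plateau just
above the highest sampled value — a sampled landscape's sparse tail then
merges into the main basin like any sub-threshold feature instead of
surviving as disconnected "minima"; `connect_masked = FALSE` restores
impassable-wall behaviour.  Minima counts are monotone non-increasing in
the threshold by construction.

The synthetic Gaussian-mode generator draws its random modes orthogonal
to the six rigid-body degrees of freedom at the mean structure.  Without
that projection a random mode overlaps translations/rotations and
superposition silently removes part of the injected variance, so
recovered eigenvalues would be biased low through no fault of the PCA.

# Interaction networks

Salt bridges use the 3.2 Å oxygen–nitrogen criterion between Asp/Glu
carboxylate oxygens and Lys NZ / Arg NE,NH1,NH2 / His ND1,NE2 (His
included by default because protonation at the simulated pH is assigned
externally and is not recoverable from a topology; both His membership
and the atom sets are overridable).  A bridge's occupancy is the fraction
of frames with any qualifying O–N pair; the listing threshold defaults to
0.05 occupancy, a deliberately permissive value because persistence rules
behind published bridge totals are unstated — sensitivity to it should be
checked rather than assumed.  Network diffs partition bridges keyed by
(acidic residue, basic residue, chain pair) into conserved / gained /
lost.

π-stacking is operationalised as the unweighted ring-centroid distance
falling in 3.7–6 Å; no ring-normal angle criterion is applied by default
because the distance-only definition is what the motivating analyses
used.  Contact events are maximal runs of qualifying frames, with runs
separated by ≤ `gap_tolerance` frames merged.  Coordination labels follow
the default thresholds: *prolonged* if any event exceeds 50 ns,
*infrequent_short* if all events are under 5 ns and there are fewer than
10 of them, *intermediate* otherwise; all three numbers are parameters.

# Synthetic systems: what they emulate, and what they do not

Each generator is seed-deterministic and reproduces exactly one
statistical property the corresponding analysis assumes:

* **Ideal gas** — spatial uniformity: $g(r) \equiv 1$, flat SDFs, known
  coordination integrals.
* **Markov binder** — memoryless exchange with a reference site:
  geometric dwell times, known stationary occupancy
  $k_{on}/(k_{on}+k_{off})$, and a ground-truth occupancy matrix the
  shell-detection path must reproduce bit for bit.
* **Gaussian modes** — a low-rank harmonic ensemble with prescribed
  covariance eigenvalues, optionally wrapped in random rigid motion to
  exercise superposition.
* **Contact fixtures** — residues with standard PDB atom names placed so
  O–N or centroid distances are exact: 'on' frames at the requested
  distance, 'off' frames at criterion + 2 Å.

The ion-count helper implements $N = N_A \, c \, V$ with half-up rounding
(90 ions for 150 mM in a 100 Å cube; 2409 for 4 M).  Published
compositions for comparable boxes deviate from this formula (80 and
"around 1800"), presumably via a protein-excluded effective volume that
is not documented; a `volume_fraction` argument reproduces that style of
correction but defaults to the plain formula.

What passing on these generators does **not** show: real trajectories
have correlated dynamics (dwell times are not geometric), anharmonic and
multi-basin conformational ensembles, finite-concentration structure in
the bath, and force-field-dependent energetics.  The generators validate
the *estimators*, not the physics; conclusions about a real system still
require converged sampling of that system.

# Numerical choices and degenerate inputs

* RDF normalisation uses exact shell volumes and per-frame boxes; shared
  ref/sel atoms are excluded from self-pairing.
* $g = 0$ bins are masked in the PMF (never clamped); empty shell sets
  yield a zero binding energy with a warning flag rather than an error.
* Survival fits refuse windows with fewer than 5 positive points;
  all-empty origins are an error ("no occupants").
* Collinear frame-atom triples abort SDF accumulation with the offending
  frame index; zero-length rings and sub-5-atom rings are rejected.
* Alignment requires ≥ 3 fitting atoms; reflection-related structures
  keep a nonzero RMSD by construction.
* Minima tie-breaks are lowest F, then lexicographic bin index.
* Pipeline configs are validated before any computation; unknown keys are
  errors (exit status 2), stage failures are logged and dependants
  skipped (exit status 1).

# Problem sizes used by the test-suite

The suite validates parameter recovery at sizes chosen to put Monte-Carlo
error well inside the asserted tolerances while keeping the whole run in
tens of seconds: ideal-gas nulls at 500 particles × 200 frames (binned at
0.5 Å, where per-bin counting noise sits near 3%), rate recovery at 200
particles × 5000 frames across release probabilities 0.01–0.2 per frame,
rankings over 13 systems at 100 × 1000, PCA recovery at 20 pseudo-atoms ×
5000 frames, landscapes at 10⁵ samples, and brute-force RDF equivalence
on 200-atom frames where the 27-image oracle is exact.  `scripts/acceptance.R`
re-runs the same recoveries from scratch and writes the measured
quantities as JSON.

# Known limitations

* No triclinic cells, no Kirkwood–Buff integrals, no triplet
  correlations.
* No multi-exponential or stretched-exponential residence fits; a single
  rate is meaningful only when $\ln SP$ is near-linear over the window.
* XTC trajectories are recognised but not parsed (no reader available in
  this toolchain); DCD, multi-model PDB and the text fixture format are
  the supported routes.
* Secondary-structure assignment, hydrogen-bond networks and any
  quantum-chemistry-derived descriptor are out of scope; electronic
  descriptors (polarizability, MEP range) are consumed as tabulated
  input, and the bundled table is synthetic, for demonstration only.
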