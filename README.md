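# solvshell

Solvation-shell and ion-interaction analysis of molecular-dynamics
trajectories, for people studying how electrolytes and ionic-liquid (IL)
co-solvents act on protein surfaces — the motivating case being a
halophilic alcohol dehydrogenase simulated at 323.15 K in 4 M KCl plus
150 mM IL ion pairs, where enzyme activity tracks how ions pair with each
other, how long they reside at acidic residues, and whether they wedge
between aromatic gating residues.

## What it computes

* **Pair structure** — radial distribution functions with periodic
  minimum-image counting, g(r) → shells → potential of mean force
  W(r) = −k<sub>B</sub>T ln g(r) → per-shell binding energies
  k<sub>B</sub>T ln g(r<sub>peak</sub>), as a first-shell value or summed
  over all shells within 15 Å; coordination numbers
  N(r) = ρ ∫ 4πr²g(r) dr.
* **Residence kinetics** — shell occupancy, continuous survival
  probability SP(τ) with an optional intermittency window, exponential
  decay fits (k, τ = 1/k), and cross-system ranking with rank 1 for the
  longest-lived shell.
* **Spatial density** — 3-D number-density grids of a species in a
  residue-fixed frame, normalised to bulk, exported as OpenDX or Gaussian
  cube.
* **Conformational analysis** — Kabsch superposition (proper rotations
  only), RMSD/RMSF, Cα PCA, and free-energy landscapes
  F = −k<sub>B</sub>T ln(P/P<sub>max</sub>) over (PC1, PC2) with
  persistence-based minima detection.
* **Interaction networks** — salt bridges at the 3.2 Å O–N cutoff with
  occupancy-annotated native-vs-cosolvent diffs (conserved / gained /
  lost); ring-centroid π-stacking series against the 3.7–6 Å window;
  contact events classified by the 5 ns / 50 ns / 10-event
  duration–frequency rules.
* **Synthetic ground truth** — seed-deterministic generators (uniform
  baths, two-state Markov binders, Gaussian-mode ensembles, exact-distance
  contact fixtures) plus the box-composition formula
  N = N<sub>A</sub>·c·V, so every stage is verifiable against known
  answers at desk scale.
* **Pipeline** — a YAML-configured multi-system driver
  (`run_pipeline()`, or the `inst/cli/solvshell` wrapper) producing
  per-stage CSV/JSON artifacts and a cross-system summary table,
  byte-identical on rerun at a fixed seed.

Trajectory input: multi-model PDB, DCD (via bio3d), and a plain-text
fixture format; topologies from PDB with CRYST1 box parsing.  Only
orthorhombic boxes are supported.

## Worked example

Ions exchanging with a binding site at a known per-frame release
probability of 0.05 (Δt = 0.1 ns), analysed exactly as one would analyse
ions around an acidic residue:

```r
library(solvshell)

b <- generate_markov_binder(n_particles = 200, box = c(60, 60, 60),
                            n_frames = 2000, k_on = 0.05, k_off = 0.05,
                            shell_radius = 4, dt = 0.1, seed = 42)

rdf    <- compute_rdf(b$trajectory, ref = b$site_index,
                      sel = b$mobile_index, r_max = 15, dr = 0.1)
shells <- detect_shells(rdf)
pmf    <- pmf_from_rdf(rdf, temperature = 323.15)
be     <- binding_energy(pmf, shells, mode = "one_shell")

occ <- shell_occupancy(b$trajectory, b$site_index, b$mobile_index,
                       shell_radius = 4)
ft  <- fit_decay(survival_probability(occ))

cat(sprintf("first shell: peak g = %.1f at %.1f A -> %.1f kJ/mol\n",
            shells$peak_g[1], shells$peak_r[1], be$value))
cat(sprintf("coordination number within 4 A: %.1f ions\n",
            coordination_number(rdf, 4)))
cat(sprintf("fitted release rate k = %.2f /ns (true %.2f), tau = %.2f ns\n",
            ft$k, -log(1 - 0.05) / 0.1, ft$tau))
```

This prints:

```
first shell: peak g = 418.1 at 0.4 A -> 16.2 kJ/mol
coordination number within 4 A: 99.9 ions
fitted release rate k = 0.52 /ns (true 0.51), tau = 1.92 ns
```

Half the 200 ions are bound on average (k_on = k_off), so ~100 sit within
the 4 Å shell; the enormous g peak reflects how concentrated the bound
density is relative to bulk; and the fitted release rate matches the
generator's −ln(1 − 0.05)/0.1 = 0.51 /ns ground truth.

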