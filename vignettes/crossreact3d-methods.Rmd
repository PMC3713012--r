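---
title: "Grid-based 3D-QSAR models of peptide-HLA cross-recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based 3D-QSAR models of peptide-HLA cross-recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cytotoxic T lymphocyte (CTL) clone recognizes its cognate peptide presented
by an MHC class I molecule, but also cross-recognizes a halo of other
peptides bound to the same allele. For tumor-antigen-specific clones (here,
Melan-A-specific CTLs recognizing decapeptides on HLA-A2) the extent of that
halo matters both for understanding repertoire selection and for designing
analog peptides for vaccination: a substitution that improves MHC anchoring
must not shift the epitope out of the recognized halo. Sequence similarity
alone does not predict cross-recognition; `crossreact3d` implements a
structure-based alternative: quantitative structure-activity relationship
(QSAR) models built from global three-dimensional field similarities of the
superposed peptide structures.

## The pipeline

1. **Structures** (`molecular_io`). Superposed peptide structures arrive in
   PDB format (dock-style concatenated multi-entry files are split on
   `MODEL`/`END` records). Radii and charges come from a parameter table;
   the built-in table uses element-based (Bondi-type) radii and zero
   charges, with residue/atom-specific CSV tables for force-field-grade
   reproduction work. RMSD between structures is computed *without*
   re-superposition: all structures share the rigid receptor frame, and a
   Kabsch fit would absorb exactly the displacement being measured.
   Backbone means N, CA, C, O; selections are configurable (e.g. adding a
   single side-chain Cβ, or excluding a substitution site).

2. **Conformer selection** (`conformer_selection`). Given per-conformer
   effective energies W (force-field internal energy plus continuum
   solvation, computed upstream — not by this package) and pairwise RMSDs,
   conformers are clustered as connected components of the graph with an
   edge where RMSD ≤ threshold (default 1.0 Å; the original "ad hoc graph
   theory" algorithm is not recoverable from the source, so the simplest
   graph clustering consistent with it is used). Each cluster is scored by
   the conformational free energy G = ⟨W⟩ − T·S with T = 300 K,
   S = −k_B Σ p_i ln p_i, and p_i the Boltzmann weights of the member
   energies (k_B = 0.0019872041 kcal/(mol·K)). The conformation-independent
   constant in G is dropped; rankings are invariant under uniform energy
   shifts. ⟨W⟩ is the probability-weighted mean Σ p_i W_i: the source
   presents the mean-energy and entropy terms only as equation references
   alongside the Boltzmann probabilities, so the ensemble-average reading
   was adopted; for singletons (and in the limit of tight clusters) it
   coincides with the arithmetic mean. The representative structure is the
   best cluster's medoid (smallest RMSD sum to the other members); ties go
   to the lower index.

3. **Fields** (`grid_fields`). One shared grid covers every molecule of the
   analysis with ≥ 6 Å margin at 0.5 Å spacing (defaults). The *shape*
   field is binary occupancy of the closed van der Waals sphere of any
   atom. The *electrostatic* field is the Coulomb energy of a unit positive
   probe under a distance-dependent dielectric ε = 4r, i.e.
   E = Σ_i K q_i / (4 d_i²) with K = 332.0716 kcal·Å/(mol·e²) (CHARMM's
   constant; configurable). Points inside the molecule's own vdW surface
   are zeroed (this also removes singularities), and values are truncated
   to ±5 kcal/mol. The in-range fraction statistic is computed on
   *unclamped* fields (`clamp = NA`). Values are stored x-fastest with the
   origin at the minimum corner, snapped to the global spacing lattice so
   grids with different margins agree on shared points.

4. **Similarity** (`similarity`). Electrostatic entries use the Hodgkin
   index 2ΣP_AP_B/(ΣP_A²+ΣP_B²); shape entries use the Carbó index
   ΣP_AP_B/√(ΣP_A²·ΣP_B²), which for binary fields equals U/√(T_A·T_B)
   (shared over individual interior counts). The Meyer form 2U/(T_A+T_B)
   is available behind `shape_index = "meyer"`: the source asserts the
   binary Carbó and Meyer forms coincide, which is only true when
   T_A = T_B, so the Carbó form is the default and the choice is exposed.
   Two identically-empty fields score 1, one empty field against a
   non-empty one scores 0 (continuity of "identical ⇒ 1" without division
   by zero). Sums run over all grid points, unmasked.

5. **GNN QSAR** (`gnn_qsar`). The descriptor pool holds, for every
   reference molecule, its shape and electrostatic similarity columns (2N
   columns, self-similarity included — models referencing only shape
   columns must be discoverable, not presupposed). A genetic algorithm
   selects 4 distinct columns; fitness is the leave-one-out q² of a 4-1-1
   neural network (one logistic hidden unit, logistic output; 5 weights +
   2 thresholds = 7 parameters), with activities affinely scaled onto
   [0.1, 0.9] for the sigmoid output. q² = 1 − Σ(pred−exp)²/Σ(exp−mean)².
   Networks are trained by scaled conjugate gradient (Møller), capped at
   500 weight updates with gradient tolerance 1e-6 — deliberately generous
   for 7 parameters, and *not* reducible: shorter training systematically
   inflates the LOO q² of junk subsets (less overfitting per fold), so the
   training budget is part of the fitness definition. All folds of one LOO
   evaluation start from the same seeded initial weights (uniform in
   ±0.5), making each subset's fitness a deterministic function.

   GA mechanics (unspecified in the source; standard subset-selection
   choices): 250 individuals, 75 generations, tournament selection of size
   2, uniform crossover with duplicate repair, per-gene mutation rate 0.05
   resampling an unused column, elitism of 1 (best-so-far fitness is
   non-decreasing; asserted in the tests). Within `run_ensemble`, GA seeds
   vary per run while the network-initialization seed is pinned to the
   ensemble's base seed: fitness is then a single well-defined function
   across runs, values are comparable and memoizable, and "keep the higher
   q² on duplicate subsets" cannot reward a lucky initialization.
   Consensus prediction is the arithmetic mean over models.

6. **Validation** (`validation_suite`). Activity-ranked partitioning sorts
   scored actives descending (ties keep table order — this stable
   tie-break is what reproduces the published 17/6 split), chunks them in
   groups of 4, sends the top 3 of each group to training and the rest to
   test; the tied-minimal-score block ("inactives") contributes 3 test
   members, by seeded draw or by an explicit published choice. External
   test statistics report Pearson r and the least-squares line of
   predicted on experimental activities, and refuse models whose training
   set overlaps the test set. Functional dependence scans one descriptor
   over its observed range with the others pinned at training means.
   y-randomization reruns the whole GNN machinery on shuffled activities
   and keeps the 10 best non-negative-q² models per shuffle; "separation"
   is strict dominance of every real model's q² over every retained
   randomized q². The tied minimal-score block weakens shuffling (many
   shuffles move little mass), biasing randomized q² upward — the check is
   therefore conservative.

7. **Synthetic data** (`synthetic_data`). See below.

## The synthetic world

The generator emulates the data regime the pipeline is designed for without
any external structure files:

* a fixed template chain of 10 residues × 7 heavy atoms (≈30 Å span — a
  decapeptide footprint), radius 1.7 Å, small template charges;
* per-molecule Gaussian coordinate jitter with scales on a ladder from
  0.02 Å up to `coordinate_jitter` (default 0.08 Å). The ladder matters: a
  single shared jitter scale makes all pairs roughly equally dissimilar,
  whereas real superposed peptide sets combine a high similarity ceiling
  with a graded spread. The default was calibrated once against the target
  shape-similarity band 0.96–1.0 (realized ≈0.95–0.99 at 0.5 Å spacing)
  and is not tuned per test;
* planted activity a·s^k + b on the realized shape similarity s to the
  first molecule, with (a, k, b) = (82, 40, −26) mapping the realized s
  band onto scores ≈ −16…56, plus Gaussian noise (σ = 1 score unit);
* an 11-of-23 block floored at the tied minimal score −17 (the bimodal
  activity vector of real cross-reactivity panels), applied to the lowest
  noiseless activities so activity remains monotone in s.

What a green recovery test establishes: the full chain (fields →
similarity → GA/NN → validation) can find a planted monotone
structure-activity relationship of realistic narrowness and return its
reference molecule as a descriptor. What it does not establish: anything
about real force fields, real charge distributions, receptor-imposed
conformational constraints, or the adequacy of field similarity for real
TCR recognition — the generator's chemistry is deliberately fake (uniform
radii, random charges, no amino-acid identity).

The conformer-ensemble generator embeds conformers in a 3-D Euclidean
space (cluster centres 6·spread apart, members scattered with sd
spread/3), so its "RMSD" matrix is an exact metric; the clone-profile
generator plants recognition categories first and draws lysis percentages
inside each category's band, so expected scores are known exactly.

## Numerical choices and degenerate inputs

* Sphere membership uses closed spheres (≤, with a 1e-12 slack) so lattice
  points exactly on a surface are inside.
* Boltzmann weights shift energies by their minimum before exponentiation
  (overflow-safe identity).
* Cluster free-energy ties within 1e-9 keep the lower cluster index;
  medoid ties keep the lower conformer index.
* `scale_activities` refuses constant activities; LOO q² refuses
  degenerate variance; Pearson r needs ≥3 pairs and nonzero variances.
* EC50 uses the longest consecutive run of titration points between 20%
  and 80% of the maximal lysis ("linear domain" is undefined in the
  source; this is the conventional operational choice), fits lysis against
  log10(concentration), and errors when 50% of maximal lysis is never
  reached or the domain has fewer than 2 points.
* Lysis-to-category thresholds are strict (a lysis of exactly 10% is
  "lack of significant lysis").

## Run scales in the tests

The acceptance tests state their scales in-line: the GA-vs-exhaustive
comparison runs the GA at the full 250×75 setting against all 10,626
4-subsets of a 24-column pool; the 23-molecule recovery test scales the GA
to 60×30 (10 runs) and the y-randomization to 10 shuffles × 5 runs at
40×15 to fit a CI-sized budget. Thresholds are asserted unchanged at these
scales. Down-scaling the randomized side lowers randomized q² and so could
only make the separation check easier to pass; the negative control (the
same machinery on activity noise, expected to show *no* separation) runs
at the same scale as its real-side comparison so the two sides stay
comparable.

## Known limitations

* The package consumes effective energies and superposed structures; it
  performs no conformational sampling, energy minimization, or
  protonation assignment.
* The built-in parameter table is not a force field; reproduction-grade
  electrostatics require a user-supplied charge table.
* With 2N pool columns and N ≈ 23 molecules, LOO q² remains an optimistic
  estimator; the external test set and y-randomization are the honest
  checks, and both are part of the standard workflow here.
* The reproduction of the original study's numerical endpoints (training
  q² ≈ 0.75, external r ≈ 0.92, field in-range fraction ≈ 90.8%) requires
  the study's deposited structure files, which are not shipped; the
  synthetic property suite covers the machinery instead.
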