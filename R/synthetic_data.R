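#' Specification of a synthetic superposed structure set
#'
#' The generator emulates the data regime of the real pipeline: a set of
#' ~20-25 superposed decapeptide-like molecules whose pairwise shape
#' similarities fall in a narrow high band and whose activities follow a
#' planted nonlinear monotone function of the shape similarity to a
#' reference molecule, with a block of molecules pinned at a tied
#' minimal score (the bimodal activity profile typical of
#' cross-reactivity panels).
#'
#' Defaults state the emulated world: 23 molecules of 10 residues x 7
#' heavy atoms (a decapeptide footprint, ~30 Angstrom span), coordinate
#' jitter ladder chosen so the realized shape-similarity band is about
#' 0.96-1.0, activity = a * s^k + b with (a, k, b) = (82, 40, -26) so
#' noiseless scores span roughly -16 to 56, Gaussian score noise of 1,
#' and an 11-molecule inactive block floored at -17.
#'
#' @param n_molecules number of molecules (default 23).
#' @param n_residues residues per chain (default 10).
#' @param atoms_per_residue heavy atoms per residue (default 7).
#' @param reference_count number of planted reference molecules
#'   (default 1).
#' @param coordinate_jitter largest per-atom Gaussian displacement sd
#'   in Angstrom; molecules get displacement scales on a ladder from
#'   0.02 up to this value (default 0.08).
#' @param charge_jitter per-atom charge noise sd in e (default 0.02).
#' @param activity_a,activity_k,activity_b planted activity model
#'   `a * s^k + b` on the shape similarity s to the first reference.
#' @param noise_sd Gaussian activity noise, in score units (default 1).
#' @param n_inactive molecules floored at `floor_score` (default: the
#'   11-of-23 proportion of the emulated panel, rounded).
#' @param floor_score tied minimal score (default -17).
#' @param similarity_band informational target band for shape entries.
#' @param grid_spacing,grid_margin grid used to realize the planted
#'   similarities (defaults 0.5 and 6 Angstrom).
#' @param seed master seed.
#' @return an object of class `SyntheticSpec` (a list).
#' @export
synthetic_spec <- function(n_molecules = 23, n_residues = 10,
                           atoms_per_residue = 7, reference_count = 1,
                           coordinate_jitter = 0.08, charge_jitter = 0.02,
                           activity_a = 82, activity_k = 40,
                           activity_b = -26, noise_sd = 1,
                           n_inactive = NULL, floor_score = -17,
                           similarity_band = c(0.96, 1.0),
                           grid_spacing = 0.5, grid_margin = 6,
                           seed = 1) {
  if (is.null(n_inactive)) n_inactive <- max(1L, round(n_molecules * 11 / 23))
  stopifnot(n_molecules >= 2, coordinate_jitter >= 0, charge_jitter >= 0,
            reference_count >= 1, n_inactive < n_molecules)
  structure(as.list(environment()), class = "SyntheticSpec")
}

# Fixed decapeptide-like template: 7 heavy atoms per residue around
# residue centres 3.2 A apart along x (~30 A span for 10 residues).
# Deterministic by construction (internal fixed seed, independent of the
# user's RNG state).
#
# Per-molecule jitter scales form a ladder from 0.02 A up to the spec's
# coordinate_jitter: molecules early in the set hug the template (like
# peptides sharing the canonical binding mode) while later ones drift,
# which reproduces both the high ceiling and the graded spread of real
# shape-similarity bands. A single shared jitter would make all pairs
# equally dissimilar instead.
synthetic_template <- function(n_residues, atoms_per_residue) {
  withr::with_seed(20130716L, {
    centers <- cbind(3.2 * (seq_len(n_residues) - 1), 0, 0)
    offsets <- matrix(stats::rnorm(n_residues * atoms_per_residue * 3, 0, 1.1),
                      ncol = 3)
    coords <- centers[rep(seq_len(n_residues), each = atoms_per_residue), ] +
      offsets
    charges <- stats::rnorm(n_residues * atoms_per_residue, 0, 0.15)
    list(coords = coords, charges = charges,
         residue_index = rep(seq_len(n_residues), each = atoms_per_residue))
  })
}

synthetic_molecule <- function(id, template, jitter, charge_jitter,
                               frame_tag) {
  n <- nrow(template$coords)
  xyz <- template$coords + matrix(stats::rnorm(n * 3, 0, jitter), ncol = 3)
  atoms <- data.frame(
    element = "C",
    name = paste0("X", rep(seq_len(n / max(template$residue_index)),
                           times = max(template$residue_index))),
    residue_name = "SYN",
    residue_index = template$residue_index,
    chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = 1.7,
    partial_charge = template$charges + stats::rnorm(n, 0, charge_jitter),
    stringsAsFactors = FALSE)
  new_molecule(id, atoms, frame_tag = frame_tag)
}

#' Generate a synthetic superposed structure set with planted activities
#'
#' Per molecule, the shared template chain is perturbed by Gaussian
#' coordinate jitter; shape fields are then evaluated on the common grid
#' and the realized shape similarity `s` of every molecule to the first
#' reference molecule drives the planted activity
#' `a * s^k + b + N(0, noise_sd)`. The `n_inactive` molecules with the
#' lowest noiseless activity are floored at the tied minimal score (and
#' receive no noise), reproducing the bimodal activity vector of real
#' cross-reactivity panels while keeping activity a monotone function of
#' similarity. Deterministic per seed.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `molecules` (named list), `activities` (named
#'   vector), `grid`, `shape_fields`, `elec_fields`, and `truth`
#'   (class `SyntheticTruth`: reference ids, realized similarities,
#'   noiseless activities, floored ids, model parameters).
#' @export
generate_structure_set <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  template <- synthetic_template(spec$n_residues, spec$atoms_per_residue)
  ids <- sprintf("M%02d", seq_len(spec$n_molecules))
  jitters <- seq(min(0.02, spec$coordinate_jitter), spec$coordinate_jitter,
                 length.out = spec$n_molecules)
  mols <- withr::with_seed(as.integer(spec$seed), {
    ms <- lapply(seq_along(ids), function(i) {
      synthetic_molecule(ids[i], template, jitters[i],
                         spec$charge_jitter, frame_tag = "synthetic")
    })
    names(ms) <- ids
    ms
  })
  grid <- build_common_grid(mols, margin = spec$grid_margin,
                            spacing = spec$grid_spacing)
  shape_fields <- lapply(mols, shape_field, grid = grid)
  elec_fields <- lapply(mols, electrostatic_field, grid = grid)
  ref <- ids[seq_len(spec$reference_count)]
  s <- vapply(shape_fields, carbo, numeric(1), fb = shape_fields[[ref[1]]])
  noiseless <- spec$activity_a * s^spec$activity_k + spec$activity_b
  floored <- ids[order(noiseless)[seq_len(spec$n_inactive)]]
  activities <- withr::with_seed(as.integer(spec$seed) + 1L, {
    a <- noiseless + stats::rnorm(length(noiseless), 0, spec$noise_sd)
    a[floored] <- spec$floor_score
    a
  })
  names(activities) <- ids
  truth <- structure(list(
    reference_ids = ref,
    planted_descriptor = paste0("shape|", ref[1]),
    shape_similarity = s,
    noiseless = noiseless,
    floored_ids = floored,
    params = c(a = spec$activity_a, k = spec$activity_k,
               b = spec$activity_b, noise_sd = spec$noise_sd)),
    class = "SyntheticTruth")
  list(molecules = mols, activities = activities, grid = grid,
       shape_fields = shape_fields, elec_fields = elec_fields,
       truth = truth, spec = spec)
}

#' Generate a conformer ensemble with a planted best cluster
#'
#' Conformers are embedded as points in a 3-D Euclidean space: cluster
#' centres sit `6 * spread` apart and members are scattered with sd
#' `spread / 3`, so within-cluster distances stay below `spread` and
#' between-cluster distances well above it. The pairwise RMSD matrix is
#' the Euclidean distance matrix of the embedding (hence a valid
#' metric). Cluster 1 receives the lowest mean effective energy, lower
#' than the others by `energy_gap` kcal/mol (within-cluster sd 0.5).
#'
#' @param n_conformers total conformers (split evenly over clusters).
#' @param n_clusters planted clusters (>= 1).
#' @param spread within-cluster RMSD scale in Angstrom.
#' @param energy_gap mean-energy advantage of cluster 1 in kcal/mol.
#' @param temperature K (default 300).
#' @param seed master seed.
#' @return list with `ensemble` (a `ConformerEnsemble`) and `truth`
#'   (best cluster members, its medoid index/id).
#' @export
generate_conformer_ensemble <- function(n_conformers = 60, n_clusters = 3,
                                        spread = 0.8, energy_gap = 5,
                                        temperature = 300, seed = 1) {
  stopifnot(n_clusters >= 1, n_conformers >= n_clusters)
  assign_cluster <- rep(seq_len(n_clusters), length.out = n_conformers)
  assign_cluster <- sort(assign_cluster)
  out <- withr::with_seed(as.integer(seed), {
    centers <- cbind(6 * spread * (seq_len(n_clusters) - 1), 0, 0)
    pts <- centers[assign_cluster, , drop = FALSE] +
      matrix(stats::rnorm(n_conformers * 3, 0, spread / 3), ncol = 3)
    W <- -20 + stats::rnorm(n_conformers, 0, 0.5)
    W[assign_cluster == 1L] <- W[assign_cluster == 1L] - energy_gap
    list(pts = pts, W = W)
  })
  D <- as.matrix(stats::dist(out$pts))
  dimnames(D) <- NULL
  ids <- sprintf("c%03d", seq_len(n_conformers))
  ens <- conformer_ensemble(ids, out$W, D, temperature)
  best_members <- which(assign_cluster == 1L)
  sums <- rowSums(D[best_members, best_members, drop = FALSE])
  medoid <- best_members[which.min(sums)]
  truth <- structure(list(
    cluster_assignment = assign_cluster,
    best_cluster_members = best_members,
    best_center_index = medoid,
    best_center_id = ids[medoid]), class = "SyntheticTruth")
  list(ensemble = ens, truth = truth)
}

#' Generate synthetic clone recognition profiles with known scores
#'
#' Per peptide, recognition categories are planted first (driven by an
#' activity level in \[0, 1\]) and lysis percentages are then drawn
#' uniformly inside each category's band, so the category sums — and
#' hence the cross-reactivity scores — are known exactly.
#'
#' @param n_peptides number of peptides.
#' @param n_clones clones per profile (default 17).
#' @param activity_link function mapping peptide index to an activity
#'   level in \[0, 1\] (default: evenly spaced from 1 down to 0).
#' @param seed master seed.
#' @return list with `profiles` (list of `CloneRecognitionProfile`) and
#'   `truth` (planted categories and expected scores).
#' @export
generate_clone_profiles <- function(n_peptides, n_clones = 17,
                                    activity_link = NULL, seed = 1) {
  if (is.null(activity_link)) {
    activity_link <- function(i) {
      if (n_peptides == 1L) 1 else 1 - (i - 1) / (n_peptides - 1)
    }
  }
  bands <- list(`-1` = c(0, 10), `1` = c(10.001, 20), `2` = c(20.001, 40),
                `3` = c(40.001, 60), `4` = c(60.001, 100))
  withr::with_seed(as.integer(seed), {
    profiles <- vector("list", n_peptides)
    cats <- matrix(NA_integer_, n_peptides, n_clones)
    for (i in seq_len(n_peptides)) {
      level <- activity_link(i)
      stopifnot(level >= 0, level <= 1)
      pos <- stats::runif(n_clones) < level
      ci <- ifelse(pos, 1L + findInterval(stats::runif(n_clones) * level,
                                          c(0.25, 0.5, 0.75)), -1L)
      lys <- vapply(ci, function(cc) {
        b <- bands[[as.character(cc)]]
        stats::runif(1, b[1], b[2])
      }, numeric(1))
      cats[i, ] <- ci
      profiles[[i]] <- clone_profile(sprintf("P%02d", i), lysis = lys,
                                     n_clones = n_clones)
      stopifnot(identical(profiles[[i]]$categories, ci))
    }
    truth <- structure(list(categories = cats,
                            expected_scores = rowSums(cats)),
                       class = "SyntheticTruth")
    list(profiles = profiles, truth = truth)
  })
}
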