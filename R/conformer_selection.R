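#' Boltzmann constant in kcal/(mol K)
#' @export
kB_kcal <- 0.0019872041

#' Bundle conformer energies and pairwise RMSDs
#'
#' The effective energy `W` per conformer (force-field internal energy
#' plus continuum solvation free energy) is consumed as input; this
#' package does not compute it. The RMSD matrix must be symmetric with a
#' zero diagonal.
#'
#' @param ids conformer identifiers.
#' @param energies effective energies W in kcal/mol, one per conformer.
#' @param rmsd_matrix symmetric pairwise RMSD matrix in Angstrom.
#' @param temperature absolute temperature in K (default 300).
#' @return an object of class `ConformerEnsemble`.
#' @export
conformer_ensemble <- function(ids, energies, rmsd_matrix, temperature = 300) {
  n <- length(ids)
  rmsd_matrix <- as.matrix(rmsd_matrix)
  stopifnot(length(energies) == n,
            nrow(rmsd_matrix) == n, ncol(rmsd_matrix) == n)
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (max(abs(rmsd_matrix - t(rmsd_matrix))) > 1e-8 ||
      any(abs(diag(rmsd_matrix)) > 1e-8)) {
    stop("rmsd_matrix must be symmetric with zero diagonal")
  }
  structure(list(ids = as.character(ids), energies = as.numeric(energies),
                 rmsd = rmsd_matrix, temperature = temperature),
            class = "ConformerEnsemble")
}

#' Cluster conformers by RMSD threshold graph
#'
#' Two conformers are connected when their pairwise RMSD is at most
#' `threshold`; clusters are the connected components of that graph, so
#' every conformer lands in exactly one cluster.
#'
#' @param ensemble a `ConformerEnsemble`.
#' @param threshold RMSD threshold in Angstrom (default 1.0).
#' @return list of integer membership vectors (indices into the ensemble).
#' @export
cluster_by_rmsd <- function(ensemble, threshold = 1.0) {
  stopifnot(threshold > 0)
  adj <- (ensemble$rmsd <= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  lapply(seq_len(comp$no),
         function(k) unname(which(unname(comp$membership) == k)))
}

#' Boltzmann probabilities of conformer energies
#'
#' `p_i = exp(-W_i / kB T) / Z` with `Z = sum_j exp(-W_j / kB T)`.
#' Energies are shifted by their minimum before exponentiation; this is
#' an algebraic identity that avoids overflow for large |W|.
#'
#' @param W energies in kcal/mol.
#' @param temperature K.
#' @return probability vector summing to 1.
#' @export
boltzmann_weights <- function(W, temperature = 300) {
  if (length(W) == 0L) stop("empty energy vector")
  e <- exp(-(W - min(W)) / (kB_kcal * temperature))
  e / sum(e)
}

#' Conformational entropy of a cluster
#'
#' Gibbs form `S = -kB sum p_i log p_i`, in kcal/(mol K), with
#' `0 log 0 := 0`.
#'
#' @param p probability vector (non-negative, sums to 1).
#' @return entropy in kcal/(mol K).
#' @export
cluster_entropy <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("p must be a probability vector")
  }
  terms <- ifelse(p > 0, p * log(p), 0)
  -kB_kcal * sum(terms)
}

#' Rank conformer clusters by conformational free energy and pick the
#' representative conformer
#'
#' Per cluster, member probabilities are Boltzmann weights of the member
#' energies, the mean energy is the probability-weighted average
#' `<W> = sum p_i W_i`, the entropy is the Gibbs entropy of the member
#' probabilities, and the free energy is `G = <W> - T S` (the
#' conformation-independent constant is dropped). Clusters are ranked
#' ascending in G; the representative is the member of the best cluster
#' with the smallest RMSD sum to the other members (the cluster centre).
#' Ties within 1e-9 go to the lower cluster / conformer index.
#'
#' @param ensemble a `ConformerEnsemble`.
#' @param clusters memberships from [cluster_by_rmsd()]; computed at
#'   `threshold` when omitted.
#' @param threshold RMSD threshold used when `clusters` is `NULL`.
#' @return list with `clusters` (data frame, ranked), `memberships`
#'   (ranked list of index vectors), `representative` (conformer id) and
#'   `representative_index`.
#' @export
rank_and_select <- function(ensemble, clusters = NULL, threshold = 1.0) {
  if (is.null(clusters)) clusters <- cluster_by_rmsd(ensemble, threshold)
  covered <- sort(unname(unlist(clusters)))
  if (!identical(as.integer(covered), seq_along(ensemble$ids))) {
    stop("clusters must cover the ensemble exactly once")
  }
  T <- ensemble$temperature
  info <- lapply(seq_along(clusters), function(k) {
    members <- clusters[[k]]
    W <- ensemble$energies[members]
    p <- boltzmann_weights(W, T)
    S <- cluster_entropy(p)
    meanW <- sum(p * W)
    center <- if (length(members) == 1L) members else {
      sub <- ensemble$rmsd[members, members, drop = FALSE]
      sums <- rowSums(sub)
      members[which(sums <= min(sums) + 1e-9)[1L]]
    }
    data.frame(cluster = k, size = length(members), mean_energy = meanW,
               entropy = S, free_energy = meanW - T * S,
               center_index = center,
               center_id = ensemble$ids[center])
  })
  tab <- do.call(rbind, info)
  # stable sort: equal-G ties keep the lower original cluster index first
  ord <- order(round(tab$free_energy / 1e-9) * 1e-9, tab$cluster)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(clusters = tab,
       memberships = clusters[tab$cluster],
       representative = tab$center_id[1L],
       representative_index = tab$center_index[1L])
}

#' Read a conformer ensemble from CSV files
#'
#' @param energies_path CSV with columns `conformer_id`, `W`.
#' @param rmsd_path CSV holding the square RMSD matrix (header row of
#'   conformer ids, first column of ids).
#' @param temperature K.
#' @return a `ConformerEnsemble`.
#' @export
read_conformer_ensemble <- function(energies_path, rmsd_path,
                                    temperature = 300) {
  en <- utils::read.csv(energies_path, stringsAsFactors = FALSE)
  if (!all(c("conformer_id", "W") %in% names(en))) {
    stop("energies CSV needs columns conformer_id, W")
  }
  rm <- utils::read.csv(rmsd_path, row.names = 1, check.names = FALSE)
  rm <- as.matrix(rm)
  ord <- match(as.character(en$conformer_id), rownames(rm))
  if (any(is.na(ord))) stop("RMSD matrix is missing conformers named in the energy table")
  conformer_ensemble(en$conformer_id, en$W, rm[ord, ord], temperature)
}
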