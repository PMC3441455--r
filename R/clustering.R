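#' Pairwise RMSD matrix over an ensemble
#'
#' Distances are computed on a declared atom selection after a declared
#' superposition. The default for state-ensemble clustering is the peptide
#' backbone RMSD after superposing each frame on the receptor C-alpha
#' reference (no peptide superposition), so distances reflect both binding
#' location and peptide conformation.
#'
#' @param ensemble A `bs_trajectory` (or list of conformations).
#' @param topo A `bs_topology`.
#' @param selection Atom indices over which RMSD is taken; default the
#'   peptide backbone.
#' @param superpose_on `"receptor"` (fit on receptor C-alpha against the
#'   reference), `"peptide"` (pairwise optimal superposition on the
#'   selection itself) or `"none"` (raw coordinates).
#' @param ref A `bs_reference`, required for `superpose_on = "receptor"`.
#' @return Symmetric matrix of distances in Angstrom with zero diagonal.
#' @export
rmsd_matrix <- function(ensemble, topo, selection = NULL,
                        superpose_on = c("receptor", "peptide", "none"),
                        ref = NULL) {
  superpose_on <- match.arg(superpose_on)
  if (!inherits(ensemble, "bs_trajectory")) ensemble <- bs_trajectory(ensemble)
  nf <- n_frames(ensemble)
  if (nf < 2) stop("need at least 2 conformations")
  if (is.null(selection)) selection <- peptide_backbone_indices(topo)
  if (!length(selection)) stop("empty atom selection")
  sel_coords <- vector("list", nf)
  for (f in seq_len(nf)) {
    x <- ensemble$coords[, , f]
    if (superpose_on == "receptor") {
      if (is.null(ref)) stop("receptor superposition requires a reference")
      ca <- receptor_ca_indices(topo)
      x <- superpose(x, rbind_ref_full(ref, topo), fit_idx = ca)$coords
    }
    sel_coords[[f]] <- x[selection, , drop = FALSE]
  }
  d <- matrix(0, nf, nf)
  for (i in 1:(nf - 1)) {
    for (j in (i + 1):nf) {
      d[i, j] <- d[j, i] <- if (superpose_on == "peptide") {
        rmsd_optimized(sel_coords[[i]], sel_coords[[j]])
      } else {
        rmsd_nonoptimized(sel_coords[[i]], sel_coords[[j]])
      }
    }
  }
  d
}

# Full-size reference coordinate target for receptor-CA fitting: only the
# receptor CA rows are used by the fit, the rest are placeholders.
rbind_ref_full <- function(ref, topo) {
  out <- matrix(0, nrow = topo$n_atoms, ncol = 3)
  out[receptor_ca_indices(topo), ] <- ref$receptor_ca_ref
  out
}

#' Complete-linkage clustering at a distance cutoff
#'
#' Agglomerative complete-linkage clustering: repeatedly merge the two
#' clusters with the smallest maximum inter-cluster distance, while that
#' distance is strictly below the cutoff. The result satisfies the
#' guarantee that within every cluster the distance between all pairs of
#' members is less than the cutoff. Ties are broken by the smaller linkage
#' distance, then the smaller lower cluster index, so the partition is
#' deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal (Angstrom).
#' @param cutoff Cluster diameter bound, Angstrom.
#' @return Object of class `bs_clusters`: `assignment` (cluster id per
#'   member, ids ordered by cluster size, largest first), `medoids` (member
#'   index per cluster), `sizes`, `cutoff` and `max_intra` (largest
#'   intra-cluster pairwise distance observed).
#' @export
complete_linkage_cut <- function(d, cutoff) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix must be symmetric")
  }
  link <- d                      # complete-linkage distances between clusters
  diag(link) <- Inf
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  repeat {
    sub <- link
    sub[!active, ] <- Inf
    sub[, !active] <- Inf
    mn <- min(sub)
    if (!is.finite(mn) || mn >= cutoff) break
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    newlink <- pmax(link[i, ], link[j, ])
    link[i, ] <- newlink
    link[, i] <- newlink
    link[i, i] <- Inf
  }
  clusters <- members[active]
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, 1L))
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  medoids <- vapply(clusters, function(m) medoid(m, d), 1L)
  max_intra <- 0
  for (m in clusters) {
    if (length(m) > 1) {
      max_intra <- max(max_intra, max(d[m, m]))
    }
  }
  structure(list(assignment = assignment, medoids = medoids,
                 sizes = as.integer(sizes), cutoff = cutoff,
                 max_intra = max_intra,
                 distance = "complete-linkage on supplied matrix"),
            class = "bs_clusters")
}

#' Medoid of a cluster
#'
#' The member minimising the sum of distances to all other members; ties
#' are broken by the lowest member index.
#'
#' @param members Integer indices of cluster members.
#' @param d Full distance matrix.
#' @return The medoid's member index.
#' @export
medoid <- function(members, d) {
  if (!length(members)) stop("empty cluster")
  if (length(members) == 1) return(as.integer(members))
  sums <- rowSums(d[members, members, drop = FALSE])
  as.integer(members[which.min(sums)])
}

#' @export
print.bs_clusters <- function(x, ...) {
  cat("<bs_clusters> ", length(x$sizes), " clusters at cutoff ", x$cutoff,
      " A; sizes: ", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (length(x$sizes) > 10) ", ...", "\n", sep = "")
  invisible(x)
}

#' Tidy cluster assignments
#' @param x A `bs_clusters`.
#' @param ... Unused.
#' @return Tibble with `member`, `cluster`, `is_medoid`.
#' @method tidy bs_clusters
#' @export
tidy.bs_clusters <- function(x, ...) {
  tibble::tibble(member = seq_along(x$assignment),
                 cluster = x$assignment,
                 is_medoid = seq_along(x$assignment) %in% x$medoids)
}

#' One-row cluster summary
#' @param x A `bs_clusters`.
#' @param ... Unused.
#' @return One-row tibble with cluster count, largest size, cutoff and the
#'   realised maximum intra-cluster distance.
#' @method glance bs_clusters
#' @export
glance.bs_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$sizes),
                 n_members = length(x$assignment),
                 largest = max(x$sizes),
                 cutoff = x$cutoff,
                 max_intra = x$max_intra)
}

#' Cluster a state ensemble of trajectory frames
#'
#' Convenience wrapper: extract the frames of a state, build the RMSD
#' matrix (receptor-superposed peptide backbone by default) and cut at the
#' cutoff.
#'
#' @param traj A `bs_trajectory`.
#' @param topo A `bs_topology`.
#' @param labeled Output of [classify_states()].
#' @param state State label to cluster.
#' @param cutoff Cluster diameter bound, Angstrom.
#' @param ref A `bs_reference` for receptor superposition.
#' @param superpose_on See [rmsd_matrix()].
#' @return List with `clusters` (`bs_clusters`), `frames` (original frame
#'   indices) and `d` (the distance matrix).
#' @export
cluster_state_ensemble <- function(traj, topo, labeled, state, cutoff,
                                   ref = NULL, superpose_on = "receptor") {
  sel <- which(labeled$state == state)
  if (length(sel) < 2) stop("need at least 2 frames in state '", state, "'")
  sub <- bs_trajectory(traj$coords[, , sel, drop = FALSE],
                       box_length = traj$box_length)
  d <- rmsd_matrix(sub, topo, superpose_on = superpose_on, ref = ref)
  cl <- complete_linkage_cut(d, cutoff)
  list(clusters = cl, frames = sel, d = d)
}
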