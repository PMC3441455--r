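#' Reference complex for binding observables
#'
#' Holds everything the binding observables are measured against: the
#' receptor C-alpha reference coordinates (restraint target), the two
#' symmetry-related reference peptide center-of-mass points (one per
#' binding site of the homodimer), the binding-pocket residue set and the
#' bound-state peptide backbone reference.
#'
#' @param receptor_ca_ref M x 3 matrix of receptor C-alpha reference
#'   positions (both monomers, topology order).
#' @param site_com_refs 2 x 3 matrix: reference peptide center of mass for
#'   each symmetric binding site.
#' @param pocket_residues Integer vector of per-monomer residue indices
#'   (1-based `resno`) defining the binding pocket; the same positions on
#'   both monomers form the two pocket copies. Duplicates are an error.
#' @param peptide_ref_backbone K x 3 matrix, bound-state peptide backbone
#'   (N, CA, C per residue, chain order).
#' @return Object of class `bs_reference`.
#' @export
reference_complex <- function(receptor_ca_ref, site_com_refs, pocket_residues,
                              peptide_ref_backbone) {
  site_com_refs <- as.matrix(site_com_refs)
  if (!identical(dim(site_com_refs), c(2L, 3L))) {
    stop("site_com_refs must be a 2 x 3 matrix (two symmetric sites)")
  }
  pocket_residues <- as.integer(pocket_residues)
  if (!length(pocket_residues)) stop("pocket_residues must be non-empty")
  if (anyDuplicated(pocket_residues)) {
    stop("duplicate pocket residue indices: ",
         paste(unique(pocket_residues[duplicated(pocket_residues)]), collapse = ", "))
  }
  structure(list(receptor_ca_ref = as.matrix(receptor_ca_ref),
                 site_com_refs = site_com_refs,
                 pocket_residues = sort(pocket_residues),
                 peptide_ref_backbone = as.matrix(peptide_ref_backbone)),
            class = "bs_reference")
}

validate_reference <- function(ref, topo) {
  ca <- receptor_ca_indices(topo)
  if (length(ca) != nrow(ref$receptor_ca_ref)) {
    stop("receptor CA count (", length(ca), ") does not match reference (",
         nrow(ref$receptor_ca_ref), ")")
  }
  for (role in c("receptor_monomer_1", "receptor_monomer_2")) {
    have <- unique(topo$atoms$resno[topo$atoms$role == role])
    bad <- setdiff(ref$pocket_residues, have)
    if (length(bad)) {
      stop("pocket residues not present in ", role, ": ", paste(bad, collapse = ", "))
    }
  }
  bb <- peptide_backbone_indices(topo)
  if (length(bb) != nrow(ref$peptide_ref_backbone)) {
    stop("peptide backbone reference atom count mismatch")
  }
  invisible(ref)
}

atomic_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

element_mass <- function(element) {
  m <- atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Peptide center-of-mass distance to the nearest binding site
#'
#' The binding-site distance observable: the Euclidean distance between the
#' peptide's (mass-weighted) center of mass and the reference peptide
#' center-of-mass point, minimised over the homodimer's two symmetric
#' binding sites. With a periodic box the displacement to each site is
#' taken under the minimum-image convention.
#'
#' @param conf A `bs_conformation`.
#' @param topo A `bs_topology`.
#' @param ref A `bs_reference`, or `NULL` (returns `NA`).
#' @param heavy_only Use heavy atoms only for the center of mass (default)
#'   or all peptide atoms.
#' @return Distance in Angstrom (`NA_real_` if no reference is supplied).
#' @export
compute_delta <- function(conf, topo, ref, heavy_only = TRUE) {
  if (is.null(ref)) return(NA_real_)
  idx <- atom_indices(topo, role = "peptide", heavy_only = heavy_only)
  if (!length(idx)) stop("empty peptide chain")
  com <- peptide_com(conf$xyz, topo, idx)
  d <- apply(ref$site_com_refs, 1, function(site) {
    sqrt(sum(minimum_image(com - site, conf$box_length)^2))
  })
  min(d)
}

peptide_com <- function(xyz, topo, idx) {
  w <- element_mass(topo$atoms$element[idx])
  colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
}

#' Residue-residue contact rule
#'
#' Two residues are in contact when at least `min_pairs` heavy-atom pairs
#' are separated by strictly less than `threshold` Angstrom.
#'
#' @param xyz_a,xyz_b Heavy-atom coordinate matrices of the two residues.
#' @param threshold Distance threshold in Angstrom (strict inequality).
#' @param min_pairs Minimum number of qualifying atom pairs.
#' @param box_length Optional periodic cube edge.
#' @return Logical scalar.
#' @export
residues_in_contact <- function(xyz_a, xyz_b, threshold = 4.5, min_pairs = 2,
                                box_length = NULL) {
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  n <- pair_count_within(xyz_a, xyz_b, threshold, box_length)
  n >= min_pairs
}

pair_count_within <- function(xyz_a, xyz_b, threshold, box_length = NULL) {
  dx <- outer(xyz_a[, 1], xyz_b[, 1], "-")
  dy <- outer(xyz_a[, 2], xyz_b[, 2], "-")
  dz <- outer(xyz_a[, 3], xyz_b[, 3], "-")
  if (!is.null(box_length)) {
    dx <- minimum_image(dx, box_length)
    dy <- minimum_image(dy, box_length)
    dz <- minimum_image(dz, box_length)
  }
  sum(dx * dx + dy * dy + dz * dz < threshold^2)
}

# Heavy-atom residue-pair contact matrix between the peptide and the two
# pocket copies. Returns an integer matrix n_pep_res x (2 * n_pocket) of
# qualifying-pair counts; contacts are counts >= min_pairs.
pocket_pair_counts <- function(conf, topo, ref, threshold = 4.5) {
  a <- topo$atoms
  pep_idx <- atom_indices(topo, role = "peptide", heavy_only = TRUE)
  pocket <- ref$pocket_residues
  roles <- c("receptor_monomer_1", "receptor_monomer_2")
  rec_keep <- a$is_heavy & a$role %in% roles & a$resno %in% pocket
  rec_idx <- which(rec_keep)
  # column grouping: one group per (monomer, pocket residue)
  rec_group <- paste(a$role[rec_idx], a$resno[rec_idx])
  levels_rec <- as.vector(outer(pocket, roles, function(r, m) paste(m, r)))
  rec_g <- factor(rec_group, levels = levels_rec)
  pep_g <- factor(a$resno[pep_idx], levels = sort(unique(a$resno[pep_idx])))

  xp <- conf$xyz[pep_idx, , drop = FALSE]
  xr <- conf$xyz[rec_idx, , drop = FALSE]
  dx <- outer(xp[, 1], xr[, 1], "-")
  dy <- outer(xp[, 2], xr[, 2], "-")
  dz <- outer(xp[, 3], xr[, 3], "-")
  if (!is.null(conf$box_length)) {
    dx <- minimum_image(dx, conf$box_length)
    dy <- minimum_image(dy, conf$box_length)
    dz <- minimum_image(dz, conf$box_length)
  }
  ind <- (dx * dx + dy * dy + dz * dz < threshold^2) * 1
  mp <- stats::model.matrix(~ g - 1, data.frame(g = pep_g))
  mr <- stats::model.matrix(~ g - 1, data.frame(g = rec_g))
  counts <- t(mp) %*% ind %*% mr
  dimnames(counts) <- list(levels(pep_g), levels_rec)
  counts
}

#' Number of peptide-pocket residue contacts
#'
#' Counts (peptide residue, pocket residue) pairs in contact, summed over
#' the pocket copies of both receptor monomers.
#'
#' @inheritParams compute_delta
#' @param threshold,min_pairs Contact rule parameters (see
#'   [residues_in_contact()]).
#' @return Integer contact count.
#' @export
count_pocket_contacts <- function(conf, topo, ref, threshold = 4.5,
                                  min_pairs = 2) {
  validate_reference(ref, topo)
  counts <- pocket_pair_counts(conf, topo, ref, threshold)
  sum(counts >= min_pairs)
}

#' Helical fraction of the peptide
#'
#' Fraction of peptide residues whose backbone dihedrals fall in the
#' alpha-helical window `phi` in (-100, -30) and `psi` in (-80, -5)
#' degrees. Terminal residues, whose phi or psi is undefined, are excluded
#' from the denominator.
#'
#' @inheritParams compute_delta
#' @param phi_window,psi_window Two-element degree ranges (open intervals).
#' @return Fraction in `[0, 1]`, or `NA_real_` for peptides shorter than 3
#'   residues.
#' @export
helix_fraction <- function(conf, topo, phi_window = c(-100, -30),
                           psi_window = c(-80, -5)) {
  hel <- peptide_dihedrals(conf, topo)
  if (is.null(hel)) return(NA_real_)
  ok <- stats::complete.cases(hel)
  if (!any(ok)) return(NA_real_)
  h <- hel$phi > phi_window[1] & hel$phi < phi_window[2] &
    hel$psi > psi_window[1] & hel$psi < psi_window[2]
  mean(h[ok])
}

# Per-residue (phi, psi) of the peptide; NA at termini. NULL if < 3 residues.
peptide_dihedrals <- function(conf, topo) {
  bb <- peptide_backbone_indices(topo)
  n_res <- length(bb) / 3L
  if (n_res < 3) return(NULL)
  x <- conf$xyz[bb, , drop = FALSE]
  N <- x[seq(1, by = 3, length.out = n_res), , drop = FALSE]
  CA <- x[seq(2, by = 3, length.out = n_res), , drop = FALSE]
  C <- x[seq(3, by = 3, length.out = n_res), , drop = FALSE]
  i <- 2:(n_res - 1)
  phi <- rep(NA_real_, n_res)
  psi <- rep(NA_real_, n_res)
  phi[i] <- dihedral_angle(C[i - 1, , drop = FALSE], N[i, , drop = FALSE],
                           CA[i, , drop = FALSE], C[i, , drop = FALSE])
  psi[i] <- dihedral_angle(N[i, , drop = FALSE], CA[i, , drop = FALSE],
                           C[i, , drop = FALSE], N[i + 1, , drop = FALSE])
  data.frame(resno = seq_len(n_res), phi = phi, psi = psi)
}

#' Optimized (superposed) root-mean-square deviation
#'
#' RMSD after least-squares superposition (proper rotations only; Kabsch).
#'
#' @param x,y K x 3 coordinate matrices, K >= 3.
#' @return RMSD in Angstrom.
#' @export
rmsd_optimized <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("coordinate sets differ in size")
  if (nrow(x) < 3) stop("need at least 3 atoms for superposition")
  xf <- superpose(x, y)$coords
  sqrt(mean(rowSums((xf - y)^2)))
}

#' Non-optimized root-mean-square deviation
#'
#' Plain coordinate RMSD with no superposition; this is the quantity the
#' receptor restraint penalises.
#'
#' @param x,y K x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_nonoptimized <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((x - y)^2)))
}

#' Mean pairwise RMSD of an ensemble (structural diversity)
#'
#' @param ensemble A `bs_trajectory` or list of `bs_conformation`s.
#' @param selection Atom row indices to compare (default: all atoms).
#' @return Mean optimized RMSD over all unordered pairs (Angstrom);
#'   `NA_real_` for fewer than 2 members.
#' @export
ensemble_diversity <- function(ensemble, selection = NULL) {
  if (!inherits(ensemble, "bs_trajectory")) ensemble <- bs_trajectory(ensemble)
  nf <- n_frames(ensemble)
  if (nf < 2) return(NA_real_)
  if (is.null(selection)) selection <- seq_len(dim(ensemble$coords)[1])
  tot <- 0
  for (i in 1:(nf - 1)) {
    xi <- ensemble$coords[selection, , i]
    for (j in (i + 1):nf) {
      tot <- tot + rmsd_optimized(xi, ensemble$coords[selection, , j])
    }
  }
  tot / (nf * (nf - 1) / 2)
}

#' Per-frame binding and folding observables of a trajectory
#'
#' Computes, for every frame: the site distance `delta`, pocket contact
#' count `nc`, `helix_fraction`, the optimized peptide-backbone RMSD to the
#' bound reference (`rmsd_opt`), the receptor C-alpha non-optimized RMSD to
#' its reference (`rmsd_nonopt_receptor`), and carries through per-frame
#' energies when supplied.
#'
#' @param traj A `bs_trajectory`.
#' @param topo A `bs_topology`.
#' @param ref A `bs_reference` or `NULL` (distance/contact columns become `NA`).
#' @param energies Optional data frame with per-frame `energy` and
#'   `restraint_energy`.
#' @param temp_index Integer temperature-ladder index per frame (recycled).
#' @param threshold,min_pairs Contact rule parameters.
#' @param heavy_only Peptide COM atom selection for `delta`.
#' @return A tibble with one row per frame.
#' @export
compute_observables <- function(traj, topo, ref = NULL, energies = NULL,
                                temp_index = 1L, threshold = 4.5,
                                min_pairs = 2, heavy_only = TRUE) {
  nf <- n_frames(traj)
  if (!is.null(ref)) validate_reference(ref, topo)
  bb <- peptide_backbone_indices(topo)
  delta <- nc <- hf <- ro <- rr <- rep(NA_real_, nf)
  ca <- receptor_ca_indices(topo)
  for (f in seq_len(nf)) {
    conf <- get_frame(traj, f)
    if (!is.null(ref)) {
      delta[f] <- compute_delta(conf, topo, ref, heavy_only = heavy_only)
      nc[f] <- sum(pocket_pair_counts(conf, topo, ref, threshold) >= min_pairs)
      ro[f] <- rmsd_optimized(conf$xyz[bb, , drop = FALSE], ref$peptide_ref_backbone)
      rr[f] <- rmsd_nonoptimized(conf$xyz[ca, , drop = FALSE], ref$receptor_ca_ref)
    }
    hf[f] <- helix_fraction(conf, topo)
  }
  out <- tibble::tibble(
    frame = seq_len(nf),
    temp_index = as.integer(rep_len(temp_index, nf)),
    delta = delta,
    nc = nc,
    helix_fraction = hf,
    rmsd_opt = ro,
    energy = NA_real_,
    restraint_energy = NA_real_,
    rmsd_nonopt_receptor = rr)
  if (!is.null(energies)) {
    if (nrow(energies) != nf) stop("energies must have one row per frame")
    out$energy <- energies$energy
    out$restraint_energy <- energies$restraint_energy
  }
  out
}

observable_columns <- c("frame", "temp_index", "delta", "nc", "helix_fraction",
                        "rmsd_opt", "energy", "restraint_energy")

#' Write / read an observable table as TSV
#'
#' Plain-text tab-separated table, one row per frame, fixed leading header
#' columns (`frame`, `temp_index`, `delta`, `nc`, `helix_fraction`,
#' `rmsd_opt`, `energy`, `restraint_energy`); missing values are written as
#' the literal `NA` sentinel. Values round-trip exactly.
#'
#' @param table Observable tibble (as from [compute_observables()]).
#' @param path Output TSV path.
#' @return `read_observables()` returns a tibble.
#' @export
write_observables <- function(table, path) {
  missing_cols <- setdiff(observable_columns, names(table))
  for (m in missing_cols) table[[m]] <- NA_real_
  extra <- setdiff(names(table), observable_columns)
  table <- table[, c(observable_columns, extra)]
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                  col_types = readr::cols(
                    frame = readr::col_integer(),
                    temp_index = readr::col_integer(),
                    .default = readr::col_double()))
}
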