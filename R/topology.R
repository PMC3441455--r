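#' Molecular topology of a receptor-peptide system
#'
#' A topology is an ordered atom table for a system made of exactly two
#' receptor chains (a homodimer) and one peptide chain. Residue numbering is
#' 1-based and strictly increasing within each chain; the original author/PDB
#' numbering is preserved in `orig_resno` so reports can use it.
#'
#' @param atoms A data frame with columns `chain_id`, `role` (one of
#'   `"receptor_monomer_1"`, `"receptor_monomer_2"`, `"peptide"`), `resno`
#'   (1-based within chain), `orig_resno`, `resname` (3-letter code), `atom`
#'   (atom name), `element`, `is_heavy`, `is_ca`.
#' @return An object of class `bs_topology`.
#' @export
bs_topology <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("chain_id", "role", "resno", "resname", "atom", "element",
           "is_heavy", "is_ca")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("topology atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"orig_resno" %in% names(atoms)) atoms$orig_resno <- atoms$resno
  roles <- unique(atoms$role)
  bad <- setdiff(roles, c("receptor_monomer_1", "receptor_monomer_2", "peptide"))
  if (length(bad)) stop("unknown chain roles: ", paste(bad, collapse = ", "))
  if (sum(atoms$role == "peptide" & !duplicated(atoms$chain_id)) != 1) {
    stop("topology must contain exactly one peptide chain")
  }
  n_rec <- sum(c("receptor_monomer_1", "receptor_monomer_2") %in% roles)
  if (n_rec == 1) {
    stop("topology must contain both receptor monomers (or none, for a free peptide)")
  }
  topo <- structure(list(atoms = atoms, n_atoms = nrow(atoms)),
                    class = "bs_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  atoms <- topo$atoms
  for (ch in unique(atoms$chain_id)) {
    res <- atoms$resno[atoms$chain_id == ch]
    if (is.unsorted(res)) stop("residue indices not increasing in chain ", ch)
  }
  by_res <- dplyr::summarise(
    dplyr::group_by(atoms, .data$chain_id, .data$resno, .data$resname),
    n_heavy = sum(.data$is_heavy), n_ca = sum(.data$is_ca), .groups = "drop")
  aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
           "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","UNK","GLX","ASX")
  no_heavy <- by_res[by_res$n_heavy < 1, ]
  if (nrow(no_heavy)) {
    stop("residue without heavy atoms: chain ", no_heavy$chain_id[1],
         " residue ", no_heavy$resno[1])
  }
  bad_ca <- by_res[by_res$resname %in% aa3 & by_res$n_ca != 1, ]
  if (nrow(bad_ca)) {
    stop("amino-acid residue without exactly one CA: chain ", bad_ca$chain_id[1],
         " residue ", bad_ca$resno[1], " (", bad_ca$resname[1], ")")
  }
  invisible(topo)
}

#' @export
print.bs_topology <- function(x, ...) {
  ch <- dplyr::summarise(dplyr::group_by(x$atoms, .data$chain_id, .data$role),
                         residues = dplyr::n_distinct(.data$resno),
                         atoms = dplyr::n(), .groups = "drop")
  cat("<bs_topology> ", x$n_atoms, " atoms\n", sep = "")
  print(as.data.frame(ch), row.names = FALSE)
  invisible(x)
}

# Atom row indices for a chain role, optionally restricted by atom name /
# heavy / CA selections.
atom_indices <- function(topo, role = NULL, atoms = NULL, heavy_only = FALSE,
                         ca_only = FALSE) {
  a <- topo$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(atoms)) keep <- keep & a$atom %in% atoms
  if (heavy_only) keep <- keep & a$is_heavy
  if (ca_only) keep <- keep & a$is_ca
  which(keep)
}

# Backbone (N, CA, C) indices of the peptide chain, in chain order.
peptide_backbone_indices <- function(topo) {
  atom_indices(topo, role = "peptide", atoms = c("N", "CA", "C"))
}

receptor_ca_indices <- function(topo) {
  atom_indices(topo, role = c("receptor_monomer_1", "receptor_monomer_2"),
               ca_only = TRUE)
}

#' A single conformation (coordinate frame)
#'
#' @param xyz N x 3 matrix of Angstrom coordinates in topology atom order.
#' @param box_length Edge of the periodic cube in Angstrom, or `NULL`.
#' @return Object of class `bs_conformation`.
#' @export
bs_conformation <- function(xyz, box_length = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("coordinates must have 3 columns")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!is.null(box_length)) {
    if (!is.numeric(box_length) || length(box_length) != 1 || box_length <= 0)
      stop("box_length must be a single positive number")
  }
  structure(list(xyz = xyz, box_length = box_length), class = "bs_conformation")
}

#' A trajectory: stacked conformations over a fixed topology
#'
#' @param frames List of `bs_conformation` objects or a single N x 3 x F array.
#' @param box_length Periodic cube edge (Angstrom) or `NULL`.
#' @return Object of class `bs_trajectory` with fields `coords`
#'   (N x 3 x F array) and `box_length`.
#' @export
bs_trajectory <- function(frames, box_length = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    coords <- frames
  } else {
    if (!length(frames)) stop("trajectory needs at least one frame")
    n <- nrow(frames[[1]]$xyz)
    if (!all(vapply(frames, function(f) nrow(f$xyz), 1L) == n)) {
      stop("inconsistent atom count across frames")
    }
    if (is.null(box_length)) box_length <- frames[[1]]$box_length
    coords <- array(0, dim = c(n, 3L, length(frames)))
    for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$xyz
  }
  structure(list(coords = coords, box_length = box_length),
            class = "bs_trajectory")
}

#' @export
print.bs_trajectory <- function(x, ...) {
  cat("<bs_trajectory> ", dim(x$coords)[3], " frames x ", dim(x$coords)[1],
      " atoms", if (!is.null(x$box_length)) paste0(", box ", x$box_length, " A"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `bs_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a conformation
#' @param traj A `bs_trajectory`.
#' @param i Frame index (1-based).
#' @return A `bs_conformation`.
#' @export
get_frame <- function(traj, i) {
  bs_conformation(traj$coords[, , i], box_length = traj$box_length)
}

#' Remove residues from a topology (and matching trajectory columns)
#'
#' Deletes whole residues, re-deriving dense 1-based residue numbering while
#' keeping the original numbering in `orig_resno`. The relative order of all
#' surviving atoms is unchanged. Typical use is removing flexible terminal
#' residues before analysis.
#'
#' @param topo A `bs_topology`.
#' @param ranges Named list mapping chain role to an integer vector of
#'   residue indices (current 1-based `resno`) to remove. An empty list is a
#'   no-op.
#' @return List with `topology` (trimmed), `atom_keep` (logical vector over
#'   the old atom order, usable to subset coordinate rows) and `log` (a
#'   tibble recording what was removed).
#' @export
trim_residues <- function(topo, ranges = list()) {
  atoms <- topo$atoms
  keep <- rep(TRUE, nrow(atoms))
  log_rows <- list()
  for (role in names(ranges)) {
    res <- ranges[[role]]
    if (!length(res)) next
    have <- unique(atoms$resno[atoms$role == role])
    missing_res <- setdiff(res, have)
    if (length(missing_res)) {
      stop("trim range outside chain '", role, "': residues ",
           paste(missing_res, collapse = ", "))
    }
    drop <- atoms$role == role & atoms$resno %in% res
    if (role == "peptide" && all(unique(atoms$resno[atoms$role == "peptide"]) %in% res)) {
      stop("refusing to remove every peptide residue")
    }
    keep <- keep & !drop
    log_rows[[role]] <- tibble::tibble(role = role,
                                       resno = sort(unique(res)),
                                       n_atoms = as.integer(sum(drop)))
  }
  new_atoms <- atoms[keep, , drop = FALSE]
  # dense re-indexing per chain, preserving order
  new_atoms <- dplyr::mutate(
    dplyr::group_by(new_atoms, .data$chain_id),
    resno = match(.data$resno, unique(.data$resno)))
  new_atoms <- dplyr::ungroup(new_atoms)
  out <- bs_topology(new_atoms)
  out$provenance <- c(topo$provenance,
                      list(trim = dplyr::bind_rows(log_rows)))
  list(topology = out,
       atom_keep = keep,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
         tibble::tibble(role = character(), resno = integer(), n_atoms = integer()))
}
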