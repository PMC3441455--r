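#' Read a (multi-MODEL) PDB structure into a topology and trajectory
#'
#' Chain roles are never guessed from chain letters: a `chain_map` from
#' chain id to role is required. Hydrogens are kept but flagged not heavy.
#' Alternate locations other than 'A'/blank are dropped (count logged as an
#' attribute). A `CRYST1` record, when present with a cubic cell, provides
#' the periodic box length.
#'
#' @param path Path to a PDB file with one or more MODEL blocks.
#' @param chain_map Named character vector mapping chain ids to roles
#'   (`"receptor_monomer_1"`, `"receptor_monomer_2"`, `"peptide"`).
#' @return List with `topology` (`bs_topology`) and `trajectory`
#'   (`bs_trajectory`, one frame per MODEL).
#' @export
read_structure <- function(path, chain_map) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  alt_drop <- !(is.na(at$alt) | at$alt %in% c("", "A"))
  n_alt_dropped <- sum(alt_drop)
  keep <- !alt_drop & at$type %in% c("ATOM", "HETATM")
  at <- at[keep, , drop = FALSE]

  chains <- unique(at$chain)
  unmapped <- setdiff(chains, names(chain_map))
  if (length(unmapped)) {
    stop("chain_map omits chain id(s): ", paste(unmapped, collapse = ", "))
  }
  role <- unname(chain_map[at$chain])

  element <- at$elesy
  no_el <- is.na(element) | element == ""
  element[no_el] <- substr(trimws(at$elety[no_el]), 1, 1)
  element <- toupper(trimws(element))
  is_heavy <- !(element %in% c("H", "D"))

  atoms <- tibble::tibble(
    chain_id = at$chain,
    role = role,
    orig_resno = at$resno,
    resname = at$resid,
    atom = trimws(at$elety),
    element = element,
    is_heavy = is_heavy,
    is_ca = trimws(at$elety) == "CA")
  # dense 1-based per-chain residue numbering (PDB numbering kept alongside)
  atoms <- dplyr::mutate(
    dplyr::group_by(atoms, .data$chain_id),
    resno = match(.data$orig_resno, unique(.data$orig_resno)))
  atoms <- dplyr::ungroup(atoms)
  topo <- bs_topology(atoms)
  attr(topo, "n_altloc_dropped") <- n_alt_dropped

  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  # bio3d keeps all models' xyz over all original atoms; subset kept atoms
  sel_xyz <- as.vector(t(cbind((which(keep) - 1) * 3 + 1,
                               (which(keep) - 1) * 3 + 2,
                               (which(keep) - 1) * 3 + 3)))
  xyz <- xyz[, sel_xyz, drop = FALSE]
  if (anyNA(xyz)) stop("inconsistent atom count across MODEL blocks in ", path)

  box_length <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                         substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
    if (all(is.finite(abc)) && abc[1] > 1 && diff(range(abc)) < 1e-3) {
      box_length <- abc[1]
    }
  }

  n_frames <- nrow(xyz)
  coords <- array(0, dim = c(nrow(atoms), 3L, n_frames))
  for (i in seq_len(n_frames)) {
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  list(topology = topo,
       trajectory = bs_trajectory(coords, box_length = box_length))
}

#' Write a topology and trajectory as a multi-MODEL PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals). A cubic
#' `CRYST1` record carries the periodic box length when present.
#'
#' @param topo A `bs_topology`.
#' @param traj A `bs_trajectory` (or a single `bs_conformation`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(topo, traj, path) {
  if (inherits(traj, "bs_conformation")) traj <- bs_trajectory(list(traj))
  a <- topo$atoms
  if (dim(traj$coords)[1] != nrow(a)) {
    stop("trajectory atom count does not match topology")
  }
  chain_letters <- a$chain_id
  if (any(nchar(chain_letters) != 1)) {
    chain_letters <- LETTERS[as.integer(factor(a$chain_id, levels = unique(a$chain_id)))]
  }
  atom_field <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                       paste0(" ", formatC(a$atom, width = -3)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(traj$box_length)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box_length, traj$box_length, traj$box_length,
                       90, 90, 90), con)
  }
  nf <- n_frames(traj)
  serial <- seq_len(nrow(a)) %% 100000L
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, atom_field, a$resname, chain_letters, a$orig_resno %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
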