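#' Specification for synthetic ground-truth data
#'
#' Describes a synthetic study: system sizes, the planted state mixture
#' (bound / intermediate / unbound occupancies), per-pair planted contact
#' probabilities for the bound and intermediate states, per-state helicity,
#' coordinate noise and run structure. The generator realises frames
#' i.i.d. from this mixture, with ground truth recorded alongside.
#'
#' @param n_receptor_res Residues per receptor monomer (>= 3).
#' @param n_peptide_res Peptide length (>= 3).
#' @param occupancies Numeric `c(bound, intermediate, unbound)`, summing
#'   to 1.
#' @param bs_contacts,is_contacts Data frames with columns `pep_res`,
#'   `pocket_res`, `prob`: planted contact probabilities per state. Each
#'   peptide residue and each pocket residue may appear at most once per
#'   state (the geometric realisation places one bridge per residue).
#' @param noise Coordinate noise sigma, Angstrom.
#' @param helicity Named numeric: per-state helicity in `[0, 1]`
#'   (`bound`, `intermediate`, `unbound`).
#' @param n_frames Frames per trajectory.
#' @param n_runs Number of independent-run blocks the frames are divided
#'   into (for jackknife errors).
#' @param seed Random seed.
#' @param box_length Periodic cube edge, Angstrom.
#' @param delta_bound,nc_bound,delta_unbound State thresholds the generated
#'   geometry is guaranteed to satisfy (bound frames carry `nc_bound`
#'   always-on core contacts).
#' @return Object of class `bs_synth_spec`.
#' @export
synthetic_spec <- function(n_receptor_res = 20,
                           n_peptide_res = 12,
                           occupancies = c(bound = 0.5, intermediate = 0.3,
                                           unbound = 0.2),
                           bs_contacts = NULL,
                           is_contacts = NULL,
                           noise = 0.15,
                           helicity = c(bound = 0.9, intermediate = 0.5,
                                        unbound = 0.3),
                           n_frames = 2000L,
                           n_runs = 10L,
                           seed = 1L,
                           box_length = 150,
                           delta_bound = 5,
                           nc_bound = 2,
                           delta_unbound = 25) {
  stopifnot(n_receptor_res >= 3, n_peptide_res >= 3)
  if (abs(sum(occupancies) - 1) > 1e-12) stop("occupancies must sum to 1")
  if (any(occupancies < 0 | occupancies > 1)) stop("occupancies must lie in [0, 1]")
  stopifnot(noise >= 0, all(helicity >= 0 & helicity <= 1))
  pocket <- default_pocket_residues(n_receptor_res)
  if (is.null(bs_contacts)) {
    k <- min(6L, n_peptide_res %/% 2, length(pocket))
    bs_contacts <- data.frame(
      pep_res = seq(1L, by = 2L, length.out = k),
      pocket_res = pocket[seq_len(k)],
      prob = c(1, 1, 0.9, 0.6, 0.4, 0.8)[seq_len(k)])
  }
  if (is.null(is_contacts)) {
    k <- min(3L, n_peptide_res %/% 2, length(pocket))
    is_contacts <- data.frame(
      pep_res = seq(2L, by = 2L, length.out = k),
      pocket_res = rev(pocket)[seq_len(k)],
      prob = c(0.5, 0.3, 0.7)[seq_len(k)])
  }
  for (df in list(bs = bs_contacts, is = is_contacts)) {
    if (any(df$prob < 0 | df$prob > 1)) stop("planted probabilities must lie in [0, 1]")
    if (anyDuplicated(df$pep_res) || anyDuplicated(df$pocket_res)) {
      stop("infeasible contact plant: a residue may carry at most one planted partner per state")
    }
    if (!all(df$pocket_res %in% pocket)) {
      stop("planted pocket residues must belong to the pocket set: ",
           paste(pocket, collapse = ", "))
    }
  }
  n_core <- sum(bs_contacts$prob >= 1)
  if (n_core < nc_bound) {
    stop("bound frames carry only ", n_core, " always-on contacts but nc_bound = ",
         nc_bound, "; add probability-1 pairs or lower nc_bound")
  }
  structure(list(n_receptor_res = as.integer(n_receptor_res),
                 n_peptide_res = as.integer(n_peptide_res),
                 occupancies = occupancies, bs_contacts = bs_contacts,
                 is_contacts = is_contacts, noise = noise,
                 helicity = helicity, n_frames = as.integer(n_frames),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 box_length = box_length, delta_bound = delta_bound,
                 nc_bound = nc_bound, delta_unbound = delta_unbound,
                 pocket_residues = pocket),
            class = "bs_synth_spec")
}

# pocket positions spaced two apart in the middle of the monomer, so that
# bridged planted contacts never touch an adjacent pocket member
default_pocket_residues <- function(n_receptor_res) {
  lo <- max(2L, as.integer(round(n_receptor_res / 4)))
  hi <- min(n_receptor_res - 1L, as.integer(round(3 * n_receptor_res / 4)))
  seq(lo, hi, by = 2L)
}

aa_order <- c("N", "CA", "C", "CB")

default_peptide_seq <- function(n) {
  base <- c("THR", "ARG", "THR", "LYS", "ILE", "ASP", "TRP", "ASN", "LYS",
            "ILE", "LEU", "SER")
  rep_len(base, n)
}

chain_atom_table <- function(chain_id, role, resnames) {
  n <- length(resnames)
  tibble::tibble(
    chain_id = chain_id,
    role = role,
    resno = rep(seq_len(n), each = 4L),
    orig_resno = rep(seq_len(n), each = 4L),
    resname = rep(resnames, each = 4L),
    atom = rep(aa_order, n),
    element = rep(c("N", "C", "C", "C"), n),
    is_heavy = TRUE,
    is_ca = rep(c(FALSE, TRUE, FALSE, FALSE), n))
}

# align principal axis of the CA trace to x, centred at the origin
align_chain <- function(coords, ca_rows) {
  ca <- coords[ca_rows, , drop = FALSE]
  ctr <- colMeans(ca)
  x <- sweep(coords, 2, ctr)
  s <- svd(sweep(ca, 2, ctr))
  R <- s$v
  if (det(R) < 0) R[, 3] <- -R[, 3]
  x %*% R
}

c2_about_z <- function(p, center) {
  d <- sweep(as.matrix(p), 2, center)
  sweep(cbind(-d[, 1], -d[, 2], d[, 3]), 2, center, "+")
}

#' Generate a synthetic homodimeric reference complex
#'
#' Builds two identical helical receptor monomers related by an exact
#' two-fold rotation, a bound reference peptide docked alongside monomer 1,
#' the two symmetry-related site reference points (peptide centers of mass),
#' and the pocket residue declaration. By construction the site distance of
#' the bound reference conformation is zero and the two site points are
#' exact images under the generating symmetry.
#'
#' @param spec A `bs_synth_spec`.
#' @param site_offset Distance between monomer and peptide helix axes,
#'   Angstrom.
#' @param monomer_gap Distance between the two monomer helix axes, Angstrom.
#' @return List with `topology`, `reference` (`bs_reference`),
#'   `bound_conformation` (`bs_conformation` of the full complex),
#'   `symmetry` (center and axis of the two-fold operation).
#' @export
make_reference_complex <- function(spec = synthetic_spec(), site_offset = 14,
                                   monomer_gap = 14) {
  n_rec <- spec$n_receptor_res
  n_pep <- spec$n_peptide_res
  rec_seq <- rep_len(c("ALA", "LEU", "SER", "VAL", "GLU", "ILE", "LYS", "PHE"),
                     n_rec)
  pep_seq <- default_peptide_seq(n_pep)

  atoms <- dplyr::bind_rows(
    chain_atom_table("A", "receptor_monomer_1", rec_seq),
    chain_atom_table("B", "receptor_monomer_2", rec_seq),
    chain_atom_table("P", "peptide", pep_seq))
  topo <- bs_topology(atoms)

  helix <- function(n) build_peptide_coords(rep(-57, n), rep(-47, n))
  mono <- helix(n_rec)
  mono <- align_chain(mono, seq(2, by = 4, length.out = n_rec))
  m1 <- sweep(mono, 2, c(0, monomer_gap / 2, 0), "+")

  pep <- helix(n_pep)
  pep <- align_chain(pep, seq(2, by = 4, length.out = n_pep))
  pep <- sweep(pep, 2, c(0, monomer_gap / 2 + site_offset, 0), "+")

  center <- rep(spec$box_length / 2, 3)
  shift <- function(x) sweep(x, 2, center, "+")
  m1 <- shift(m1)
  pep <- shift(pep)
  m2 <- c2_about_z(m1, center)

  coords <- rbind(m1, m2, pep)
  conf <- bs_conformation(coords, box_length = spec$box_length)

  pep_idx <- atom_indices(topo, role = "peptide", heavy_only = TRUE)
  site1 <- peptide_com(conf$xyz, topo, pep_idx)
  site2 <- as.vector(c2_about_z(matrix(site1, 1), center))

  ref <- reference_complex(
    receptor_ca_ref = conf$xyz[receptor_ca_indices(topo), , drop = FALSE],
    site_com_refs = rbind(site1, site2),
    pocket_residues = spec$pocket_residues,
    peptide_ref_backbone = conf$xyz[peptide_backbone_indices(topo), ,
                                    drop = FALSE])
  validate_reference(ref, topo)
  list(topology = topo, reference = ref, bound_conformation = conf,
       symmetry = list(center = center, axis = c(0, 0, 1)))
}

# sample phi/psi for a chain with independent per-residue helicity
sample_dihedrals <- function(n, helicity, noise_deg = 8) {
  hel <- stats::runif(n) < helicity
  phi <- ifelse(hel, -57, -120) + stats::rnorm(n, 0, noise_deg)
  psi <- ifelse(hel, -47, 120) + stats::rnorm(n, 0, noise_deg)
  list(phi = phi, psi = psi, helical = hel)
}

# Build an axis-aligned chain whose atoms stay above the -y "keep-out"
# plane facing the receptor, so docked frames cannot form incidental
# contacts. A chain that dips below is first flipped 180 degrees about its
# own axis (which changes no dihedral) and otherwise resampled.
sample_docked_chain <- function(n, helicity, max_drop = 4) {
  for (try in 1:100) {
    dh <- sample_dihedrals(n, helicity)
    x <- build_peptide_coords(dh$phi, dh$psi)
    x <- align_chain(x, seq(2, by = 4, length.out = n))
    if (min(x[, 2]) > -max_drop) return(x)
    flipped <- cbind(x[, 1], -x[, 2], -x[, 3])
    if (min(flipped[, 2]) > -max_drop) return(flipped)
  }
  x
}

#' Generate a synthetic trajectory with planted states and contacts
#'
#' Frames are drawn i.i.d. from the three-state mixture. Bound frames place
#' the peptide at site 1 or 2 (chosen at random) with the site distance
#' within `delta_bound`; intermediate frames sit in a peripheral zone with
#' the site distance between the two thresholds; unbound frames are uniform
#' in the box beyond `delta_unbound`. Planted contacts are realised by
#' bridging the peptide residue's CB bead onto the partner pocket residue
#' (guaranteeing the two-heavy-atom-pair contact rule) or parking it away.
#' The ground truth (state, site, realised planted contacts, run block) is
#' returned alongside and never needs re-deriving.
#'
#' @param topo Topology from [make_reference_complex()].
#' @param ref Matching `bs_reference`.
#' @param spec A `bs_synth_spec`.
#' @param symmetry Symmetry descriptor from [make_reference_complex()].
#' @return List with `trajectory` (`bs_trajectory`), `truth` (per-frame
#'   tibble: `frame`, `run`, `state`, `site`), `contact_truth` (long tibble
#'   of realised planted contacts per frame and state) and `thresholds`.
#' @export
generate_state_trajectory <- function(topo, ref, spec, symmetry = NULL) {
  set.seed(spec$seed)
  if (is.null(symmetry)) {
    symmetry <- list(center = rep(spec$box_length / 2, 3), axis = c(0, 0, 1))
  }
  nf <- spec$n_frames
  states <- sample(c("bound", "intermediate", "unbound"), nf, replace = TRUE,
                   prob = spec$occupancies)
  n_at <- topo$n_atoms
  coords <- array(0, dim = c(n_at, 3, nf))
  pep_rows <- which(topo$atoms$role == "peptide")
  pep_res <- topo$atoms$resno[pep_rows]
  rec_rows <- which(topo$atoms$role != "peptide")
  a <- topo$atoms
  n_pep <- spec$n_peptide_res

  # receptor: reference coordinates (from the bound reference complex
  # geometry, reconstructed via the restraint target is not enough -- we
  # need all beads, so rebuild the reference complex deterministically)
  refc <- make_reference_complex(spec)
  rec_ref <- refc$bound_conformation$xyz[rec_rows, , drop = FALSE]
  pep_ref <- refc$bound_conformation$xyz[pep_rows, , drop = FALSE]
  center <- symmetry$center

  pep_idx_heavy <- atom_indices(topo, role = "peptide", heavy_only = TRUE)
  site <- integer(nf)
  contact_rows <- list()

  # atom row lookup for pocket bridging: CA and CB of a monomer residue
  rec_atom_row <- function(role, resno, atom) {
    which(a$role == role & a$resno == resno & a$atom == atom)
  }

  receptor_com <- colMeans(rec_ref)

  for (f in seq_len(nf)) {
    fr <- matrix(0, n_at, 3)
    fr[rec_rows, ] <- rec_ref + matrix(stats::rnorm(length(rec_ref), 0, spec$noise),
                                       ncol = 3)
    st <- states[f]
    if (st == "unbound") {
      dh <- sample_dihedrals(n_pep, spec$helicity["unbound"])
      pep <- build_peptide_coords(dh$phi, dh$psi)
      pep <- align_chain(pep, seq(2, by = 4, length.out = n_pep))
      repeat {
        pos <- stats::runif(3, 0, spec$box_length)
        d1 <- sqrt(sum(minimum_image(pos - ref$site_com_refs[1, ], spec$box_length)^2))
        d2 <- sqrt(sum(minimum_image(pos - ref$site_com_refs[2, ], spec$box_length)^2))
        dr <- sqrt(sum(minimum_image(pos - receptor_com, spec$box_length)^2))
        if (min(d1, d2) >= spec$delta_unbound + 2 && dr > 30) break
      }
      pep <- sweep(pep, 2, pos, "+")
      fr[pep_rows, ] <- pep + matrix(stats::rnorm(length(pep), 0, spec$noise), ncol = 3)
    } else {
      s <- sample(1:2, 1)
      site[f] <- s
      hl <- spec$helicity[[if (st == "bound") "bound" else "intermediate"]]
      pep <- sample_docked_chain(n_pep, hl)
      if (st == "bound") {
        # margin below delta_bound: bridged CB beads shift the center of
        # mass by up to ~1.5 A after recentering
        disp <- random_in_ball(0.3 * spec$delta_bound)
      } else {
        # peripheral zone: outward from the receptor along +y of site 1
        dist_is <- stats::runif(1, spec$delta_bound + 2, spec$delta_unbound - 2)
        dir <- c(0, 1, 0)
        disp <- dir * dist_is + random_in_ball(1)
        disp <- disp * (dist_is / sqrt(sum(disp^2))) # keep the drawn distance
      }
      target <- ref$site_com_refs[1, ] + disp
      pep <- sweep(pep, 2, target, "+")
      pep <- pep + matrix(stats::rnorm(length(pep), 0, spec$noise), ncol = 3)
      # recenter heavy-atom COM exactly on the target point
      w <- element_mass(a$element[pep_idx_heavy])
      pep_full <- matrix(0, n_at, 3)
      pep_full[pep_rows, ] <- pep
      com <- colSums(pep_full[pep_idx_heavy, , drop = FALSE] * w) / sum(w)
      pep <- sweep(pep, 2, target - com, "+")
      fr[pep_rows, ] <- pep

      # planted contacts bridged onto monomer 1 (the construction frame);
      # frames docked at site 2 are mapped by the two-fold rotation
      # afterwards, which carries the bridges onto monomer 2
      plant <- if (st == "bound") spec$bs_contacts else spec$is_contacts
      on <- stats::runif(nrow(plant)) < plant$prob
      for (k in seq_len(nrow(plant))) {
        if (!on[k]) next   # an untouched CB stays on the peptide, out of reach
        ca_j <- fr[rec_atom_row("receptor_monomer_1", plant$pocket_res[k], "CA"), ]
        cb_j <- fr[rec_atom_row("receptor_monomer_1", plant$pocket_res[k], "CB"), ]
        cb_i_row <- pep_rows[a$resno[pep_rows] == plant$pep_res[k] &
                               a$atom[pep_rows] == "CB"]
        out_dir0 <- (cb_j - ca_j) / sqrt(sum((cb_j - ca_j)^2))
        # just beyond the pocket CB, collinear with CA->CB: both the
        # CB-CB and CB-CA pairs fall below the contact threshold
        fr[cb_i_row, ] <- cb_j + out_dir0 * 0.8 + stats::rnorm(3, 0, 0.1)
      }
      if (s == 2) {
        fr[pep_rows, ] <- c2_about_z(fr[pep_rows, , drop = FALSE], center)
      }
      contact_rows[[length(contact_rows) + 1L]] <-
        tibble::tibble(frame = f, state = st,
                       pep_res = plant$pep_res,
                       pocket_res = plant$pocket_res,
                       planted_prob = plant$prob,
                       contact = on)
    }
    coords[, , f] <- fr
  }
  truth <- tibble::tibble(
    frame = seq_len(nf),
    run = rep(seq_len(spec$n_runs), length.out = nf,
              each = ceiling(nf / spec$n_runs))[seq_len(nf)],
    state = factor(states, levels = c("bound", "intermediate", "unbound")),
    site = site)
  list(trajectory = bs_trajectory(coords, box_length = spec$box_length),
       truth = truth,
       contact_truth = if (length(contact_rows)) dplyr::bind_rows(contact_rows)
       else tibble::tibble(),
       thresholds = list(delta_bound = spec$delta_bound,
                         nc_bound = spec$nc_bound,
                         delta_unbound = spec$delta_unbound))
}

random_in_ball <- function(radius) {
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v^2) <= 1) return(v * radius)
  }
}

#' Generate a free-peptide ensemble with tunable helicity
#'
#' Each residue is independently helical with the given probability (ideal
#' helix dihedrals plus Gaussian noise), otherwise extended-coil dihedrals;
#' the chain is rebuilt by geometry propagation for every member.
#'
#' @param length Peptide length (>= 3).
#' @param helicity Per-residue helix probability in `[0, 1]`.
#' @param n Ensemble size.
#' @param seed Random seed.
#' @param noise_deg Dihedral noise sigma, degrees.
#' @return List with `topology` (peptide-only), `trajectory`
#'   (`bs_trajectory` of `n` members) and `truth` (per-member realised
#'   helical fraction over interior residues).
#' @export
generate_free_peptide_ensemble <- function(length, helicity, n, seed = 1L,
                                           noise_deg = 8) {
  stopifnot(length >= 3, helicity >= 0, helicity <= 1, n >= 1)
  set.seed(seed)
  topo <- bs_topology(chain_atom_table("P", "peptide",
                                       default_peptide_seq(length)))
  coords <- array(0, dim = c(4L * length, 3L, n))
  frac <- numeric(n)
  for (i in seq_len(n)) {
    dh <- sample_dihedrals(length, helicity, noise_deg)
    coords[, , i] <- build_peptide_coords(dh$phi, dh$psi)
    interior <- 2:(length - 1)
    frac[i] <- mean(dh$helical[interior])
  }
  list(topology = topo,
       trajectory = bs_trajectory(coords),
       truth = tibble::tibble(member = seq_len(n), helical_fraction = frac))
}
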