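#' Toy coarse-grained energy parameters
#'
#' Parameters of the declared toy energy used by the Monte Carlo engine:
#' soft-core excluded volume, a Gaussian-well native-contact (Go) term on an
#' explicit pair list, a helix-propensity bonus per helical peptide residue,
#' a screened Coulomb term between charged side-chain beads, and the
#' quadratic receptor C-alpha restraint. Energies are in reduced units of
#' k_B * T_ref; distances in Angstrom.
#'
#' @param eps_ev Excluded-volume strength (> 0).
#' @param sigma_ev Excluded-volume radius, Angstrom (> 0).
#' @param r_core Hard-core radius below which the repulsion is capped at a
#'   finite value (overlaps are counted, never infinite).
#' @param eps_go Native-contact well depth per pair.
#' @param go_width Gaussian well width, Angstrom.
#' @param eps_helix Energy bonus per helical peptide residue.
#' @param phi_window,psi_window Helical dihedral windows, degrees.
#' @param eps_coulomb Screened-Coulomb prefactor (energy * Angstrom).
#' @param screening_length Debye screening length, Angstrom (> 0).
#' @param coulomb_cutoff Coulomb cutoff distance, Angstrom.
#' @param k_restraint Receptor restraint coefficient, energy * Angstrom^-2.
#' @param move_weights Relative weights of the five move types: peptide
#'   translation, peptide rotation, peptide teleport (box re-insertion),
#'   peptide pivot, receptor residue jiggle.
#' @param step_sizes Numeric vector: translation sigma (Angstrom), rotation
#'   sigma (rad), pivot sigma (degrees), receptor translation sigma
#'   (Angstrom), receptor rotation sigma (rad).
#' @return Object of class `bs_energy_params`.
#' @export
toy_energy_params <- function(eps_ev = 1, sigma_ev = 3, r_core = 1.5,
                              eps_go = 0.55, go_width = 2,
                              eps_helix = 0.5,
                              phi_window = c(-100, -30),
                              psi_window = c(-80, -5),
                              eps_coulomb = 1.5, screening_length = 8,
                              coulomb_cutoff = 25,
                              k_restraint = 2,
                              move_weights = c(translate = 0.25,
                                               rotate = 0.15,
                                               teleport = 0.10,
                                               pivot = 0.25,
                                               receptor = 0.25),
                              step_sizes = c(1.5, 0.25, 25, 0.3, 0.1)) {
  stopifnot(eps_ev > 0, sigma_ev > 0, r_core > 0, r_core < sigma_ev,
            go_width > 0, screening_length > 0, length(move_weights) == 5,
            length(step_sizes) == 5, all(move_weights >= 0))
  structure(list(eps_ev = eps_ev, sigma_ev = sigma_ev, r_core = r_core,
                 eps_go = eps_go, go_width = go_width, eps_helix = eps_helix,
                 phi_window = phi_window, psi_window = psi_window,
                 eps_coulomb = eps_coulomb,
                 screening_length = screening_length,
                 coulomb_cutoff = coulomb_cutoff,
                 k_restraint = k_restraint,
                 move_weights = as.numeric(move_weights),
                 step_sizes = as.numeric(step_sizes)),
            class = "bs_energy_params")
}

residue_charge <- function(resname) {
  ch <- c(LYS = 1, ARG = 1, HIS = 0, ASP = -1, GLU = -1)
  out <- unname(ch[resname])
  out[is.na(out)] <- 0
  out
}

#' Derive a native-contact (Go) pair list from a bound reference pose
#'
#' Pairs every peptide CA/CB bead with receptor CA/CB beads within `cutoff`
#' in the bound reference conformation, recording the reference distance as
#' the well position. Pairs found against one monomer are mirrored onto the
#' symmetry-equivalent atoms of the other monomer (same residue index and
#' bead), so both of the homodimer's binding sites carry identical wells.
#'
#' @param bound_conf `bs_conformation` of the bound reference complex.
#' @param topo `bs_topology` of the complex.
#' @param cutoff Native-contact distance cutoff, Angstrom.
#' @param depth Relative well depth (multiplies `eps_go`).
#' @return Tibble with columns `pep_atom`, `rec_atom` (1-based atom row
#'   indices), `r0` (Angstrom) and `depth`.
#' @export
derive_go_pairs <- function(bound_conf, topo, cutoff = 10, depth = 2,
                            mode = c("anchor", "contact"), n_anchors = 4,
                            anchor_depth = 4, anchor_width = 3,
                            contact_width = 1.2) {
  mode <- match.arg(mode)
  a <- topo$atoms
  if (mode == "anchor") {
    # sparse funnel: a few deep wells between the peptide's central CA and
    # the nearest pocket-region beads. The peptide keeps its orientational
    # and conformational freedom in the bound state, so binding/unbinding
    # stays reversible at equilibrium temperatures.
    rec_idx <- atom_indices(topo, role = "receptor_monomer_1",
                            atoms = c("CA", "CB"))
    xr <- bound_conf$xyz[rec_idx, , drop = FALSE]
    pep_res <- sort(unique(a$resno[a$role == "peptide"]))
    nr <- length(pep_res)
    # two anchor beads near the 1/3 and 2/3 chain positions, each the bead
    # of its neighbourhood closest to the pocket in the reference pose
    # (small r0, so the anchor shells coincide with the bound basin); the
    # pair pins the peptide center of mass at the site while leaving
    # rotation about the anchor axis and tail conformations free
    pick_anchor <- function(res_window) {
      cand <- which(a$role == "peptide" & a$resno %in% res_window &
                      a$atom %in% c("CA", "CB"))
      dmin <- vapply(cand, function(i) {
        min(sqrt(rowSums(sweep(xr, 2, bound_conf$xyz[i, ])^2)))
      }, numeric(1))
      cand[which.min(dmin)]
    }
    a1 <- pick_anchor(pep_res[pep_res <= ceiling(nr / 2)])
    a2 <- pick_anchor(pep_res[pep_res > ceiling(nr / 2)])
    per_bead <- max(1L, n_anchors %/% 2L)
    rows <- lapply(c(a1, a2), function(pi) {
      d <- sqrt(rowSums(sweep(xr, 2, bound_conf$xyz[pi, ])^2))
      near <- order(d)[seq_len(per_bead)]
      tibble::tibble(pep_atom = pi, rec_atom = rec_idx[near], r0 = d[near],
                     depth = anchor_depth, width = anchor_width)
    })
    pairs <- dplyr::bind_rows(rows)
  } else {
    pep_idx <- atom_indices(topo, role = "peptide", atoms = c("CA", "CB"))
    roles <- c("receptor_monomer_1", "receptor_monomer_2")
    rec_idx <- atom_indices(topo, role = roles, atoms = c("CA", "CB"))
    xp <- bound_conf$xyz[pep_idx, , drop = FALSE]
    xr <- bound_conf$xyz[rec_idx, , drop = FALSE]
    d2 <- outer(xp[, 1], xr[, 1], "-")^2 + outer(xp[, 2], xr[, 2], "-")^2 +
      outer(xp[, 3], xr[, 3], "-")^2
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) stop("no native contacts within cutoff; bound reference is not in contact")
    pairs <- tibble::tibble(pep_atom = pep_idx[hit[, 1]],
                            rec_atom = rec_idx[hit[, 2]],
                            r0 = sqrt(d2[hit]),
                            depth = depth,
                            width = contact_width)
  }
  # mirror onto the other monomer: same residue index and bead name
  other_role <- c(receptor_monomer_1 = "receptor_monomer_2",
                  receptor_monomer_2 = "receptor_monomer_1")
  key <- paste(a$role, a$resno, a$atom)
  mirror_key <- paste(other_role[a$role[pairs$rec_atom]],
                      a$resno[pairs$rec_atom], a$atom[pairs$rec_atom])
  mirror_atom <- match(mirror_key, key)
  mirrored <- tibble::tibble(pep_atom = pairs$pep_atom,
                             rec_atom = mirror_atom, r0 = pairs$r0,
                             depth = pairs$depth, width = pairs$width)
  mirrored <- mirrored[!is.na(mirrored$rec_atom), ]
  dplyr::distinct(dplyr::bind_rows(pairs, mirrored))
}

#' Derive the receptor's internal native-contact pair list
#'
#' Wells between receptor CA/CB beads that are close in the reference
#' structure (excluding near-neighbours along the chain). Together with the
#' C-alpha restraint these make up the receptor's internal energy, keeping
#' the homodimer folded while its backbone and side chains stay flexible,
#' and give the physical energy a magnitude against which the restraint
#' share is meaningful.
#'
#' @param bound_conf Reference `bs_conformation`.
#' @param topo A `bs_topology`.
#' @param cutoff Native-contact distance cutoff, Angstrom.
#' @param min_seq_sep Minimum residue separation along the chain.
#' @param depth Relative well depth (multiplies `eps_go`).
#' @return Tibble with `pep_atom` (first atom, receptor), `rec_atom`,
#'   `r0`, `depth` -- same shape [build_system()] consumes.
#' @export
derive_receptor_native_pairs <- function(bound_conf, topo, cutoff = 8,
                                         min_seq_sep = 2, depth = 2) {
  a <- topo$atoms
  roles <- c("receptor_monomer_1", "receptor_monomer_2")
  idx <- atom_indices(topo, role = roles, atoms = c("CA", "CB"))
  x <- bound_conf$xyz[idx, , drop = FALSE]
  d2 <- outer(x[, 1], x[, 1], "-")^2 + outer(x[, 2], x[, 2], "-")^2 +
    outer(x[, 3], x[, 3], "-")^2
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  i1 <- idx[hit[, 1]]; i2 <- idx[hit[, 2]]
  same_chain <- a$chain_id[i1] == a$chain_id[i2]
  sep <- abs(a$resno[i1] - a$resno[i2])
  keep <- !same_chain | sep >= min_seq_sep
  tibble::tibble(pep_atom = i1[keep], rec_atom = i2[keep],
                 r0 = sqrt(d2[hit])[keep], depth = depth, width = -1)
}

#' Assemble a simulation system for the Monte Carlo engine
#'
#' @param topo A `bs_topology`.
#' @param conf Starting `bs_conformation`.
#' @param ref A `bs_reference` (restraint target and, with `go_pairs`
#'   derivable from `bound_conf`, the native wells) or `NULL` for a free
#'   peptide.
#' @param go_pairs Tibble from [derive_go_pairs()] or `NULL`.
#' @param charges Optional per-atom charge vector; by default unit charges
#'   are put on the CB bead of Lys/Arg (+1) and Asp/Glu (-1).
#' @param box_length Periodic cube edge or `NULL` (no periodicity).
#' @param phi,psi Peptide backbone dihedrals consistent with `conf`; when
#'   omitted they are measured from the coordinates.
#' @return Object of class `bs_system` (list consumed by the engine).
#' @export
build_system <- function(topo, conf, ref = NULL, go_pairs = NULL,
                         charges = NULL, box_length = NULL,
                         phi = NULL, psi = NULL) {
  a <- topo$atoms
  chain_code <- c(receptor_monomer_1 = 0L, receptor_monomer_2 = 1L,
                  peptide = 2L)[a$role]
  res_global <- cumsum(!duplicated(paste(a$chain_id, a$resno))) - 1L
  if (is.null(charges)) {
    charges <- ifelse(a$atom == "CB", residue_charge(a$resname), 0)
  }
  pep_rows <- which(a$role == "peptide")
  pep_res <- a$resno[pep_rows]
  pep_nres <- length(unique(pep_res))
  # residue-major N, CA, C, CB ordering for the engine
  ord <- order(pep_res, match(a$atom[pep_rows], c("N", "CA", "C", "CB")))
  pep_atoms <- pep_rows[ord]
  if (length(pep_atoms) != 4L * pep_nres ||
      !all(a$atom[pep_atoms] == rep(c("N", "CA", "C", "CB"), pep_nres))) {
    stop("engine requires 4 beads (N, CA, C, CB) per peptide residue")
  }
  if (is.null(phi) || is.null(psi)) {
    dh <- peptide_dihedrals(conf, topo)
    if (is.null(dh)) {
      phi <- rep(0, pep_nres); psi <- rep(0, pep_nres)
    } else {
      phi <- ifelse(is.na(dh$phi), 0, dh$phi)
      psi <- ifelse(is.na(dh$psi), 0, dh$psi)
    }
  }
  if (!is.null(ref)) {
    ca_atoms <- receptor_ca_indices(topo)
    restr_ref <- ref$receptor_ca_ref
  } else {
    ca_atoms <- integer(0)
    restr_ref <- matrix(0, 0, 3)
  }
  if (is.null(box_length)) box_length <- conf$box_length
  structure(list(
    coords = conf$xyz,
    res_id = as.integer(res_global),
    chain_id = as.integer(chain_code),
    charges = as.numeric(charges),
    restraint_atoms = as.integer(ca_atoms - 1L),
    restraint_ref = restr_ref,
    go_i = if (is.null(go_pairs)) integer(0) else as.integer(go_pairs$pep_atom - 1L),
    go_j = if (is.null(go_pairs)) integer(0) else as.integer(go_pairs$rec_atom - 1L),
    go_r0 = if (is.null(go_pairs)) numeric(0) else as.numeric(go_pairs$r0),
    go_depth = if (is.null(go_pairs)) numeric(0) else if ("depth" %in% names(go_pairs))
      as.numeric(go_pairs$depth) else rep(1, nrow(go_pairs)),
    go_widths = if (is.null(go_pairs)) numeric(0) else if ("width" %in% names(go_pairs))
      as.numeric(go_pairs$width) else rep(-1, nrow(go_pairs)),
    pep_atoms = as.integer(pep_atoms - 1L),
    pep_nres = as.integer(pep_nres),
    phi = as.numeric(phi),
    psi = as.numeric(psi),
    box_length = if (is.null(box_length)) -1 else as.numeric(box_length),
    topology = topo), class = "bs_system")
}

params_for_engine <- function(params, k_restraint = NULL, move_weights = NULL) {
  p <- unclass(params)
  if (!is.null(k_restraint)) p$k_restraint <- k_restraint
  if (!is.null(move_weights)) p$move_weights <- move_weights
  p
}

#' Receptor restraint energy (non-optimized RMSD penalty)
#'
#' The quadratic penalty `k_r * sum_i |r_i - r_i_ref|^2` over receptor
#' C-alpha atoms, equal to `k_r * M * rmsd_nonoptimized^2`. It is applied
#' to the receptor only, never to the peptide.
#'
#' @param conf A `bs_conformation`.
#' @param topo A `bs_topology`.
#' @param ref A `bs_reference` carrying `receptor_ca_ref`.
#' @param k_restraint Coefficient, energy * Angstrom^-2.
#' @return Restraint energy in reduced units.
#' @export
restraint_energy <- function(conf, topo, ref, k_restraint) {
  ca <- receptor_ca_indices(topo)
  if (length(ca) != nrow(ref$receptor_ca_ref)) {
    stop("receptor CA count does not match reference")
  }
  k_restraint * sum((conf$xyz[ca, , drop = FALSE] - ref$receptor_ca_ref)^2)
}

#' Toy energy decomposition of a conformation
#'
#' Evaluates the full toy energy and returns each term separately
#' (excluded volume, screened Coulomb, native wells, helix propensity,
#' restraint) together with the total and the count of capped hard-core
#' overlaps.
#'
#' @param system A `bs_system` from [build_system()].
#' @param params A `bs_energy_params`.
#' @param conf Optional `bs_conformation` overriding the system coordinates.
#' @return Named list of energy components (`total` included).
#' @export
toy_energy <- function(system, params, conf = NULL) {
  if (!is.null(conf)) system$coords <- conf$xyz
  out <- .mc_energy_cpp(system, params_for_engine(params))
  out
}

#' Fixed-temperature Metropolis Monte Carlo run
#'
#' Runs the Metropolis chain at a single reduced temperature in a periodic
#' cube, with the receptor held near its native reference by the
#' non-optimized-RMSD restraint, and returns the saved trajectory together
#' with the per-frame observable table.
#'
#' @param system A `bs_system`.
#' @param ref A `bs_reference` (used for observables), or `NULL`.
#' @param params A `bs_energy_params`.
#' @param config A `bs_run_config`; `config$temperatures[temp_index]` is the
#'   run temperature.
#' @param temp_index Which ladder temperature to run at.
#' @param seed Random seed (defaults to `config$seed`).
#' @param compute_obs Compute the observable table (can be turned off for
#'   speed when only frames are needed).
#' @return List with `trajectory` (`bs_trajectory`), `observables` (tibble),
#'   `acceptance` (tibble per move type), `final_state` and
#'   `energies` (per-frame component matrix).
#' @export
run_fixed_temperature <- function(system, ref, params, config,
                                  temp_index = 1L, seed = NULL,
                                  compute_obs = TRUE) {
  if (all(params$move_weights == 0)) stop("all move weights are zero (non-ergodic)")
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  t_run <- config$temperatures[temp_index]
  res <- .mc_run_cpp(unclass(system), params_for_engine(params),
                     t_run, config$n_steps, config$save_interval,
                     energy_check_interval = max(config$save_interval * 10L, 1L))
  traj <- bs_trajectory(res$frames,
                        box_length = if (system$box_length > 0) system$box_length)
  energies <- tibble::tibble(energy = res$energies[, "total"] -
                               res$energies[, "restraint"],
                             restraint_energy = res$energies[, "restraint"])
  obs <- NULL
  if (compute_obs) {
    obs <- compute_observables(traj, system$topology, ref,
                               energies = energies, temp_index = temp_index)
  }
  move_names <- c("translate", "rotate", "teleport", "pivot", "receptor")
  acc <- tibble::tibble(move = move_names,
                        proposed = as.integer(res$proposed),
                        accepted = as.integer(res$accepted),
                        rate = ifelse(res$proposed > 0,
                                      res$accepted / pmax(res$proposed, 1), NA))
  final_state <- list(coords = res$final_coords, phi = res$phi, psi = res$psi)
  list(trajectory = traj, observables = obs, acceptance = acc,
       energies = res$energies, final_state = final_state,
       overlap_flags = res$overlap_flags, temperature = t_run)
}

#' Simulated-tempering acceptance for a temperature move
#'
#' Metropolis acceptance probability for hopping from inverse temperature
#' `beta_from` to `beta_to` at current energy `energy`, with tempering
#' weights `g_from`, `g_to`.
#'
#' @param energy Current total energy.
#' @param beta_from,beta_to Inverse temperatures.
#' @param g_from,g_to Tempering weights (dimensionless free-energy offsets).
#' @return Acceptance probability in `[0, 1]`.
#' @export
st_acceptance <- function(energy, beta_from, beta_to, g_from, g_to) {
  min(1, exp(-(beta_to - beta_from) * energy + (g_to - g_from)))
}

# Trapezoidal estimate of tempering weights from per-temperature mean
# energies: g_{k+1} - g_k = (beta_{k+1} - beta_k) (E_k + E_{k+1}) / 2.
st_weights_from_energies <- function(betas, mean_energies) {
  k <- length(betas)
  g <- numeric(k)
  for (i in seq_len(k - 1)) {
    g[i + 1] <- g[i] + (betas[i + 1] - betas[i]) *
      (mean_energies[i] + mean_energies[i + 1]) / 2
  }
  g
}

#' Simulated-tempering Monte Carlo run
#'
#' Joint chain over (conformation, temperature index): fixed-temperature
#' engine segments alternate with Metropolis temperature moves on the
#' ladder. Tempering weights are adapted during burn-in from running
#' per-temperature mean energies (trapezoidal free-energy estimate) and
#' frozen for production. Intended for free-peptide systems; with a single
#' ladder temperature it reduces exactly to fixed-temperature sampling.
#'
#' @param system A `bs_system` (typically peptide-only; receptor move weight
#'   is ignored when no receptor atoms are present).
#' @param params A `bs_energy_params`.
#' @param config A `bs_run_config`; `config$temperatures` is the ladder.
#' @param seed Random seed (defaults to `config$seed`).
#' @param segment_steps MC steps between temperature-move attempts.
#' @param burnin_fraction Fraction of segments used for weight adaptation
#'   (discarded from the returned tables).
#' @return List with `observables` (per-frame tibble incl. `temp_index`),
#'   `trajectory`, `weights`, `exchange_rate`, `visits` (production visits
#'   per temperature).
#' @export
run_simulated_tempering <- function(system, params, config, seed = NULL,
                                    segment_steps = 500L,
                                    burnin_fraction = 0.3) {
  if (length(config$temperatures) < 1) stop("empty temperature ladder")
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  betas <- 1 / config$temperatures
  k <- length(betas)
  g <- numeric(k)
  cur <- 1L
  n_segments <- max(1L, config$n_steps %/% segment_steps)
  n_burn <- if (k > 1) max(1L, as.integer(burnin_fraction * n_segments)) else 0L
  segment_steps <- as.integer(segment_steps)
  seg_save <- min(config$save_interval, segment_steps)
  e_sum <- numeric(k); e_n <- numeric(k)
  visits <- integer(k)
  attempts <- 0L; exchanges <- 0L
  frames <- list(); frame_temp <- integer(0); etabs <- list()
  sys <- unclass(system)
  eng_par <- params_for_engine(params)
  check_int <- max(segment_steps * 10L, 1L)
  for (seg in seq_len(n_segments)) {
    res <- .mc_run_cpp(sys, eng_par, config$temperatures[cur],
                       segment_steps, seg_save,
                       energy_check_interval = check_int)
    sys$coords <- res$final_coords
    sys$phi <- res$phi
    sys$psi <- res$psi
    e_now <- res$energies[nrow(res$energies), "total"]
    e_sum[cur] <- e_sum[cur] + e_now
    e_n[cur] <- e_n[cur] + 1
    production <- seg > n_burn
    if (production) {
      visits[cur] <- visits[cur] + 1L
      frames[[length(frames) + 1L]] <- res$frames
      nfr <- dim(res$frames)[3]
      frame_temp <- c(frame_temp, rep(cur, nfr))
      etabs[[length(etabs) + 1L]] <- res$energies
    }
    if (k > 1) {
      if (!production) {
        e_bar <- ifelse(e_n > 0, e_sum / pmax(e_n, 1), e_now)
        g <- st_weights_from_energies(betas, e_bar)
      }
      prop <- cur + sample(c(-1L, 1L), 1L)
      if (prop >= 1L && prop <= k) {
        attempts <- attempts + 1L
        p_acc <- st_acceptance(e_now, betas[cur], betas[prop], g[cur], g[prop])
        if (stats::runif(1) < p_acc) {
          cur <- prop
          exchanges <- exchanges + 1L
        }
      }
    }
  }
  exchange_rate <- if (attempts > 0) exchanges / attempts else NA_real_
  if (k > 1 && isTRUE(exchange_rate < 0.01)) {
    warning(sprintf(paste0("temperature ladder poorly overlapping: ",
                           "exchange acceptance %.2f%% < 1%%"),
                    100 * exchange_rate))
  }
  n_at <- dim(frames[[1]])[1]
  all_frames <- array(unlist(frames), dim = c(n_at, 3, length(frame_temp)))
  traj <- bs_trajectory(all_frames,
                        box_length = if (sys$box_length > 0) sys$box_length)
  obs <- compute_observables(traj, system$topology, ref = NULL,
                             temp_index = frame_temp)
  etab <- do.call(rbind, etabs)
  obs$energy <- etab[, "total"]
  obs$restraint_energy <- etab[, "restraint"]
  list(observables = obs, trajectory = traj, weights = g,
       exchange_rate = exchange_rate, visits = visits,
       final_state = list(coords = sys$coords, phi = sys$phi, psi = sys$psi))
}

#' Metropolis sampling on a discrete state space
#'
#' Uniform-proposal Metropolis chain over states with given energies; used
#' to validate the accept/reject kernel against exact Boltzmann weights.
#'
#' @param energies Numeric vector of state energies (reduced units).
#' @param temperature Reduced temperature.
#' @param n_steps Number of steps.
#' @param seed Random seed.
#' @param init Initial state (1-based).
#' @param thin Record occupancy every `thin` steps (decorrelates tallies).
#' @return List with `counts` (recorded visits per state) and `final_state`
#'   (1-based).
#' @export
metropolis_discrete <- function(energies, temperature, n_steps, seed = 1L,
                                init = 1L, thin = 1L) {
  set.seed(seed)
  res <- .metropolis_discrete_cpp(as.numeric(energies), temperature,
                                  as.integer(n_steps), as.integer(init) - 1L,
                                  as.integer(thin))
  list(counts = as.numeric(res$counts), final_state = res$final_state + 1L)
}

#' Locate the half-bound temperature by a short ladder scan
#'
#' Runs short fixed-temperature chains over a temperature ladder, measures
#' the bound fraction (`delta <= delta_bound`) in each, and interpolates the
#' temperature at which the peptide is bound roughly half of the time.
#'
#' @param system,ref,params,config As in [run_fixed_temperature()].
#' @param scan_steps Steps per scan run.
#' @param target Bound fraction to aim for.
#' @return List with `temperature` (interpolated), `scan` (tibble of ladder
#'   temperature vs bound fraction).
#' @export
find_half_bound_temperature <- function(system, ref, params, config,
                                        scan_steps = 50000L, target = 0.5) {
  scan_cfg <- config
  scan_cfg$n_steps <- as.integer(scan_steps)
  frac <- vapply(seq_along(config$temperatures), function(i) {
    run <- run_fixed_temperature(system, ref, params, scan_cfg,
                                 temp_index = i, seed = config$seed + i)
    mean(run$observables$delta <= config$delta_bound, na.rm = TRUE)
  }, numeric(1))
  scan <- tibble::tibble(temperature = config$temperatures,
                         bound_fraction = frac)
  t_half <- if (all(frac >= target)) {
    config$temperatures[which.min(frac)]
  } else if (all(frac <= target)) {
    # the half-bound condition is approached from below on this landscape:
    # take the ladder temperature whose bound fraction comes closest
    config$temperatures[which.max(frac)]
  } else {
    stats::approx(frac, config$temperatures, xout = target, ties = mean)$y
  }
  list(temperature = t_half, scan = scan)
}
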