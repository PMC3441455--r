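#' Classify frames as bound, intermediate or unbound
#'
#' A frame is bound when `delta <= delta_bound` and `nc >= nc_bound`;
#' unbound when `delta >= delta_unbound`; intermediate otherwise — the
#' intermediate state is everything that is neither unbound nor part of the
#' bound state. The thresholds used are recorded as attributes.
#'
#' @param table Observable tibble with `delta` and `nc` columns.
#' @param delta_bound,nc_bound,delta_unbound State thresholds (Angstrom,
#'   contacts, Angstrom); `delta_bound < delta_unbound` is required. A
#'   `bs_run_config` may be given as `config` instead.
#' @param config Optional `bs_run_config` supplying the thresholds.
#' @return The input tibble with a `state` factor column (levels `bound`,
#'   `intermediate`, `unbound`); thresholds attached as the `thresholds`
#'   attribute.
#' @export
classify_states <- function(table, delta_bound = 5, nc_bound = 20,
                            delta_unbound = 25, config = NULL) {
  if (!is.null(config)) {
    delta_bound <- config$delta_bound
    nc_bound <- config$nc_bound
    delta_unbound <- config$delta_unbound
  }
  if (!(delta_bound < delta_unbound)) {
    stop("delta_bound must be smaller than delta_unbound")
  }
  if (anyNA(table$delta)) {
    stop("missing delta in ", sum(is.na(table$delta)),
         " frame(s); a reference complex is required for state classification")
  }
  nc <- table$nc
  if (is.null(nc)) nc <- rep(Inf, nrow(table))
  state <- ifelse(table$delta >= delta_unbound, "unbound",
                  ifelse(table$delta <= delta_bound & nc >= nc_bound,
                         "bound", "intermediate"))
  out <- table
  out$state <- factor(state, levels = c("bound", "intermediate", "unbound"))
  attr(out, "thresholds") <- list(delta_bound = delta_bound,
                                  nc_bound = nc_bound,
                                  delta_unbound = delta_unbound)
  out
}

#' State populations
#'
#' @param labeled Output of [classify_states()].
#' @return Tibble of state, count and fraction.
#' @export
state_populations <- function(labeled) {
  tab <- table(labeled$state)
  tibble::tibble(state = names(tab),
                 n = as.integer(tab),
                 fraction = as.numeric(tab) / nrow(labeled))
}

#' Probabilistic peptide-pocket contact map for one state
#'
#' For the frames carrying the requested state label, computes the
#' frequency with which each (peptide residue, pocket residue) pair is in
#' contact. The two monomers' symmetric pocket copies are merged into a
#' single pocket-residue row set: a pair counts as in contact in a frame if
#' the peptide residue contacts that pocket position on either monomer.
#'
#' @param traj A `bs_trajectory` aligned with `labeled`.
#' @param topo A `bs_topology`.
#' @param ref A `bs_reference`.
#' @param labeled Output of [classify_states()] with one row per frame.
#' @param state State to map (`"bound"`, `"intermediate"` or `"unbound"`).
#' @param threshold,min_pairs Contact rule parameters.
#' @return Object of class `bs_contact_map`: probability and count matrices
#'   (peptide residue x pocket residue), `n_frames`, and the state mapped.
#'   An empty state yields a missing-flagged map with `n_frames = 0` and a
#'   warning.
#' @export
state_contact_map <- function(traj, topo, ref, labeled, state,
                              threshold = 4.5, min_pairs = 2) {
  validate_reference(ref, topo)
  if (n_frames(traj) != nrow(labeled)) {
    stop("trajectory and labels are not aligned")
  }
  sel <- which(labeled$state == state)
  a <- topo$atoms
  pep_res <- sort(unique(a$resno[a$role == "peptide"]))
  pocket <- ref$pocket_residues
  counts <- matrix(0L, nrow = length(pep_res), ncol = length(pocket),
                   dimnames = list(peptide_residue_labels(topo),
                                   pocket_residue_labels(topo, pocket)))
  if (!length(sel)) {
    warning("no frames in state '", state, "'; returning empty map")
    prob <- matrix(NA_real_, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
    return(structure(list(prob = prob, counts = counts, n_frames = 0L,
                          state = state), class = "bs_contact_map"))
  }
  np <- length(pocket)
  for (f in sel) {
    pc <- pocket_pair_counts(get_frame(traj, f), topo, ref, threshold)
    contact <- pc >= min_pairs
    merged <- contact[, seq_len(np), drop = FALSE] |
      contact[, np + seq_len(np), drop = FALSE]
    counts <- counts + merged
  }
  structure(list(prob = counts / length(sel), counts = counts,
                 n_frames = length(sel), state = state),
            class = "bs_contact_map")
}

peptide_residue_labels <- function(topo) {
  a <- topo$atoms
  p <- a[a$role == "peptide" & !duplicated(paste(a$role, a$resno)), ]
  paste0(p$resname, p$orig_resno)
}

pocket_residue_labels <- function(topo, pocket) {
  a <- topo$atoms
  m1 <- a[a$role == "receptor_monomer_1" &
            !duplicated(paste(a$role, a$resno)), ]
  idx <- match(pocket, m1$resno)
  paste0(m1$resname[idx], m1$orig_resno[idx])
}

#' @export
print.bs_contact_map <- function(x, ...) {
  cat("<bs_contact_map> state '", x$state, "', ", x$n_frames, " frames, ",
      nrow(x$prob), " x ", ncol(x$prob), " residue pairs\n", sep = "")
  invisible(x)
}

#' Tidy a contact map into long format
#' @param x A `bs_contact_map`.
#' @param ... Unused.
#' @return Tibble with `peptide_residue`, `pocket_residue`, `probability`,
#'   `count`, `n_frames`, `state`.
#' @method tidy bs_contact_map
#' @export
tidy.bs_contact_map <- function(x, ...) {
  long <- as.data.frame(as.table(x$prob), stringsAsFactors = FALSE)
  names(long) <- c("peptide_residue", "pocket_residue", "probability")
  long$count <- as.vector(x$counts)
  long$n_frames <- x$n_frames
  long$state <- x$state
  tibble::as_tibble(long)
}

#' Mean number of peptide residues contacted per pocket position
#'
#' For each pocket residue, the mean over frames of the requested state of
#' the number of peptide residues it contacts (either monomer copy). When a
#' `run` column is present in `labeled`, delete-one jackknife errors over
#' runs are attached.
#'
#' @inheritParams state_contact_map
#' @param run Name of the run-id column in `labeled` (optional).
#' @return Tibble with `pocket_residue`, `mean_contacts` and `err`.
#' @export
pocket_involvement <- function(traj, topo, ref, labeled, state,
                               threshold = 4.5, min_pairs = 2, run = "run") {
  validate_reference(ref, topo)
  if (n_frames(traj) != nrow(labeled)) {
    stop("trajectory and labels are not aligned")
  }
  sel <- which(labeled$state == state)
  pocket <- ref$pocket_residues
  labels <- pocket_residue_labels(topo, pocket)
  if (!length(sel)) {
    warning("no frames in state '", state, "'")
    return(tibble::tibble(pocket_residue = labels,
                          mean_contacts = NA_real_, err = NA_real_))
  }
  np <- length(pocket)
  per_frame <- matrix(0L, nrow = length(sel), ncol = np)
  for (i in seq_along(sel)) {
    pc <- pocket_pair_counts(get_frame(traj, sel[i]), topo, ref, threshold)
    contact <- pc >= min_pairs
    merged <- contact[, seq_len(np), drop = FALSE] |
      contact[, np + seq_len(np), drop = FALSE]
    per_frame[i, ] <- colSums(merged)
  }
  err <- rep(NA_real_, np)
  if (!is.null(run) && run %in% names(labeled)) {
    run_id <- labeled[[run]][sel]
    runs <- unique(run_id)
    if (length(runs) >= 2) {
      for (j in seq_len(np)) {
        err[j] <- jackknife_error(
          lapply(runs, function(r) per_frame[run_id == r, j]))
      }
    }
  }
  tibble::tibble(pocket_residue = labels,
                 mean_contacts = colMeans(per_frame),
                 err = err)
}
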