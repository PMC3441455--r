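test_that("state classification implements the threshold definitions", {
  tab <- tibble::tibble(frame = 1:3, delta = c(1, 40, 10), nc = c(30, 0, 5))
  lab <- classify_states(tab, delta_bound = 5, nc_bound = 20,
                         delta_unbound = 25)
  expect_equal(as.character(lab$state), c("bound", "unbound", "intermediate"))
  expect_equal(attr(lab, "thresholds")$nc_bound, 20)
  # a bound-range delta with too few contacts is intermediate, not bound
  lab2 <- classify_states(tibble::tibble(delta = 2, nc = 3), 5, 20, 25)
  expect_equal(as.character(lab2$state), "intermediate")
  expect_error(classify_states(tibble::tibble(delta = NA_real_, nc = 1)),
               "missing delta")
  expect_error(classify_states(tab, delta_bound = 30, delta_unbound = 25),
               "smaller")
})

test_that("raising delta_bound never shrinks the bound set (monotonicity)", {
  set.seed(43)
  tab <- tibble::tibble(delta = runif(300, 0, 40), nc = rpois(300, 10))
  sizes <- vapply(c(2, 5, 8, 12, 20), function(db) {
    sum(classify_states(tab, db, 5, 25)$state == "bound")
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("per-state contact maps recover planted probabilities and merge monomers", {
  spec <- synthetic_spec(n_frames = 1200, seed = 3)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  expect_equal(as.character(lab$state), as.character(gen$truth$state))
  for (st in c("bound", "intermediate")) {
    cm <- state_contact_map(gen$trajectory, rc$topology, rc$reference, lab, st)
    plant <- if (st == "bound") spec$bs_contacts else spec$is_contacts
    truth <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(gen$contact_truth, .data$state == st),
                      .data$pep_res, .data$pocket_res),
      realised = mean(.data$contact), .groups = "drop")
    for (k in seq_len(nrow(truth))) {
      got <- cm$prob[truth$pep_res[k], match(truth$pocket_res[k],
                                             rc$reference$pocket_residues)]
      expect_equal(unname(got), truth$realised[k], tolerance = 1e-9)
    }
  }
  # one-frame state has probabilities in {0, 1}
  one <- lab[, ]
  one$state[] <- "unbound"
  one$state[1] <- "bound"
  cm1 <- state_contact_map(gen$trajectory, rc$topology, rc$reference, one,
                           "bound")
  expect_true(all(cm1$prob %in% c(0, 1)))
  allu <- lab
  allu$state[] <- "unbound"
  expect_warning(
    cmu <- state_contact_map(gen$trajectory, rc$topology, rc$reference, allu,
                             "bound"),
    "no frames")
  expect_equal(cmu$n_frames, 0L)
})

test_that("pocket involvement counts contacted peptide residues per position", {
  spec <- synthetic_spec(n_frames = 800, seed = 13)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  lab$run <- gen$truth$run
  inv <- pocket_involvement(gen$trajectory, rc$topology, rc$reference, lab,
                            "bound")
  # each pocket residue has at most one planted peptide partner, so the
  # expected involvement equals the realised planted contact frequency
  truth <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(gen$contact_truth, .data$state == "bound"),
                    .data$pocket_res),
    realised = mean(.data$contact), .groups = "drop")
  pocket <- rc$reference$pocket_residues
  for (k in seq_len(nrow(truth))) {
    j <- match(truth$pocket_res[k], pocket)
    expect_equal(inv$mean_contacts[j], truth$realised[k], tolerance = 1e-9)
    expect_true(is.finite(inv$err[j]))
  }
  # unplanted pocket positions are never contacted
  unplanted <- setdiff(seq_along(pocket),
                       match(truth$pocket_res, pocket))
  expect_true(all(inv$mean_contacts[unplanted] == 0))
})

test_that("monomer merge is order-independent (site-label swap symmetry)", {
  spec <- synthetic_spec(n_frames = 150, seed = 23)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  cm <- state_contact_map(gen$trajectory, rc$topology, rc$reference, lab,
                          "bound")
  # relabel the monomers by swapping their roles in the topology
  topo2 <- rc$topology
  swap <- c(receptor_monomer_1 = "receptor_monomer_2",
            receptor_monomer_2 = "receptor_monomer_1",
            peptide = "peptide")
  topo2$atoms$role <- unname(swap[topo2$atoms$role])
  cm2 <- state_contact_map(gen$trajectory, topo2, rc$reference, lab, "bound")
  expect_equal(unname(cm$prob), unname(cm2$prob))
})
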