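test_that("reference complex is exactly two-fold symmetric with zero site distance", {
  rc <- make_reference_complex(synthetic_spec(n_receptor_res = 14,
                                              n_peptide_res = 8))
  ctr <- rc$symmetry$center
  map_c2 <- function(p) {
    d <- p - ctr
    c(-d[1], -d[2], d[3]) + ctr
  }
  expect_lt(sqrt(sum((map_c2(rc$reference$site_com_refs[1, ]) -
                        rc$reference$site_com_refs[2, ])^2)), 1e-6)
  # monomer 2 is the exact image of monomer 1
  a <- rc$topology$atoms
  m1 <- rc$bound_conformation$xyz[a$role == "receptor_monomer_1", ]
  m2 <- rc$bound_conformation$xyz[a$role == "receptor_monomer_2", ]
  expect_lt(max(abs(t(apply(m1, 1, map_c2)) - m2)), 1e-9)
  # pocket declarations have equal length per monomer by construction
  expect_true(all(rc$reference$pocket_residues %in%
                    unique(a$resno[a$role == "receptor_monomer_2"])))
  expect_equal(compute_delta(rc$bound_conformation, rc$topology,
                             rc$reference), 0, tolerance = 1e-9)
})

test_that("planted occupancies are recovered within binomial error", {
  spec <- synthetic_spec(n_frames = 5000, seed = 101)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  pops <- state_populations(lab)
  for (i in 1:3) {
    p <- spec$occupancies[i]
    se <- sqrt(p * (1 - p) / spec$n_frames)
    expect_lt(abs(pops$fraction[pops$state == names(spec$occupancies)[i]] - p),
              3 * se)
  }
  # classification agrees with the generator's own labels frame by frame
  expect_equal(as.character(lab$state), as.character(gen$truth$state))
})

test_that("an all-bound mixture classifies fully bound under matching thresholds", {
  spec <- synthetic_spec(occupancies = c(bound = 1, intermediate = 0,
                                         unbound = 0),
                         n_frames = 120, seed = 7)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  expect_true(all(lab$state == "bound"))
})

test_that("free-peptide ensembles hit the planted helicity", {
  ens1 <- generate_free_peptide_ensemble(12, helicity = 1, n = 60, seed = 3)
  hf1 <- vapply(seq_len(60), function(i) {
    helix_fraction(get_frame(ens1$trajectory, i), ens1$topology)
  }, numeric(1))
  expect_gte(mean(hf1), 0.95)
  ens0 <- generate_free_peptide_ensemble(12, helicity = 0, n = 60, seed = 4)
  hf0 <- vapply(seq_len(60), function(i) {
    helix_fraction(get_frame(ens0$trajectory, i), ens0$topology)
  }, numeric(1))
  expect_lte(mean(hf0), 0.05)
  ens <- generate_free_peptide_ensemble(12, helicity = 0.3, n = 2000, seed = 5)
  hf <- vapply(seq_len(2000), function(i) {
    helix_fraction(get_frame(ens$trajectory, i), ens$topology)
  }, numeric(1))
  n_int <- 10            # interior residues of a 12-mer
  se <- sqrt(0.3 * 0.7 / (2000 * n_int))
  expect_lt(abs(mean(hf) - 0.3), 3 * se + 0.01)
  # measured helicity matches the generator's own per-member bookkeeping
  expect_equal(mean(hf), mean(ens$truth$helical_fraction), tolerance = 0.01)
})

test_that("trajectory helicity is linear: trajectory mean equals mean of frames", {
  ens <- generate_free_peptide_ensemble(8, helicity = 0.5, n = 40, seed = 9)
  per_frame <- vapply(seq_len(40), function(i) {
    helix_fraction(get_frame(ens$trajectory, i), ens$topology)
  }, numeric(1))
  obs <- compute_observables(ens$trajectory, ens$topology)
  expect_equal(obs$helix_fraction, per_frame)
  expect_equal(mean(obs$helix_fraction), mean(per_frame))
})

test_that("infeasible contact plants and invalid mixtures are rejected", {
  expect_error(synthetic_spec(occupancies = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(synthetic_spec(
    bs_contacts = data.frame(pep_res = c(1, 1), pocket_res = c(5, 7),
                             prob = c(1, 1))), "infeasible")
  expect_error(synthetic_spec(
    bs_contacts = data.frame(pep_res = c(1, 3), pocket_res = c(5, 7),
                             prob = c(0.5, 1.5))), "probabilities")
  expect_error(synthetic_spec(
    bs_contacts = data.frame(pep_res = 1, pocket_res = 5, prob = 0.5),
    nc_bound = 2), "always-on")
})

test_that("generation is reproducible for a fixed seed", {
  spec <- synthetic_spec(n_frames = 50, seed = 77)
  rc <- make_reference_complex(spec)
  g1 <- generate_state_trajectory(rc$topology, rc$reference, spec, rc$symmetry)
  g2 <- generate_state_trajectory(rc$topology, rc$reference, spec, rc$symmetry)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth, g2$truth)
})
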