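test_that("site distance matches the 27-image brute force on random placements", {
  spec <- synthetic_spec(n_receptor_res = 10, n_peptide_res = 5, n_frames = 1)
  rc <- make_reference_complex(spec)
  topo <- rc$topology
  ref <- rc$reference
  base <- rc$bound_conformation$xyz
  pep <- atom_indices(topo, role = "peptide")
  pep_heavy <- atom_indices(topo, role = "peptide", heavy_only = TRUE)
  w <- bindscape:::element_mass(topo$atoms$element[pep_heavy])
  set.seed(42)
  for (i in 1:120) {
    xyz <- base
    target <- runif(3, 0, 150)     # random placement inside the box
    com0 <- colSums(xyz[pep_heavy, , drop = FALSE] * w) / sum(w)
    xyz[pep, ] <- sweep(xyz[pep, , drop = FALSE], 2, target - com0, "+")
    conf <- bs_conformation(xyz, box_length = 150)
    com <- colSums(xyz[pep_heavy, , drop = FALSE] * w) / sum(w)
    expect_equal(compute_delta(conf, topo, ref),
                 oracle_delta(com, ref$site_com_refs, 150), tolerance = 1e-9)
  }
  # trivial coincidences
  xyz <- base
  conf <- bs_conformation(xyz, box_length = 150)
  expect_equal(compute_delta(conf, topo, ref), 0, tolerance = 1e-9)
  expect_true(is.na(compute_delta(conf, topo, NULL)))
})

test_that("site distance is symmetric under swapping the two site labels", {
  rc <- tiny_complex()
  ref2 <- rc$reference
  ref2$site_com_refs <- ref2$site_com_refs[2:1, ]
  set.seed(8)
  xyz <- rc$bound_conformation$xyz + rnorm(rc$topology$n_atoms * 3, 0, 20)
  conf <- bs_conformation(xyz, box_length = 150)
  expect_equal(compute_delta(conf, rc$topology, rc$reference),
               compute_delta(conf, rc$topology, ref2))
})

test_that("contact rule enforces at least two heavy-atom pairs strictly below threshold", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  # exactly one pair at 4.0, everything else far
  b <- rbind(c(4, 0, 0), c(40, 0, 0))
  expect_false(residues_in_contact(a, b))
  # two pairs at 4.4
  b2 <- rbind(c(4.4, 0, 0), c(10, 4.4, 0))
  expect_true(residues_in_contact(a, b2))
  # a pair at exactly the threshold does not count
  b3 <- rbind(c(4.5, 0, 0), c(10, 4.4, 0))
  expect_false(residues_in_contact(a, b3))
})

test_that("pocket contact count equals the O(N^2) oracle on planted geometries", {
  spec <- synthetic_spec(n_receptor_res = 12, n_peptide_res = 6,
                         n_frames = 40, occupancies = c(bound = 0.6,
                                                        intermediate = 0.3,
                                                        unbound = 0.1),
                         seed = 5)
  rc <- make_reference_complex(spec)
  topo <- rc$topology; ref <- rc$reference
  gen <- generate_state_trajectory(topo, ref, spec, rc$symmetry)
  a <- topo$atoms
  for (f in seq(1, 40, by = 4)) {
    conf <- get_frame(gen$trajectory, f)
    slow <- 0L
    for (pr in unique(a$resno[a$role == "peptide"])) {
      xa <- conf$xyz[a$role == "peptide" & a$resno == pr & a$is_heavy, , drop = FALSE]
      for (role in c("receptor_monomer_1", "receptor_monomer_2")) {
        for (qr in ref$pocket_residues) {
          xb <- conf$xyz[a$role == role & a$resno == qr & a$is_heavy, , drop = FALSE]
          if (oracle_pair_count(xa, xb, 4.5) >= 2) slow <- slow + 1L
        }
      }
    }
    expect_equal(count_pocket_contacts(conf, topo, ref), slow)
  }
  # far-away peptide has no contacts
  far <- rc$bound_conformation$xyz
  pep <- atom_indices(topo, role = "peptide")
  far[pep, ] <- sweep(far[pep, , drop = FALSE], 2, c(60, 0, 0), "+")
  expect_equal(count_pocket_contacts(bs_conformation(far, box_length = 150),
                                     topo, ref), 0)
  # duplicate pocket residues are rejected at construction
  expect_error(reference_complex(ref$receptor_ca_ref, ref$site_com_refs,
                                 c(4, 4, 6), ref$peptide_ref_backbone),
               "duplicate")
})

test_that("helix fraction follows the dihedral window and matches an external oracle", {
  topo <- toy_peptide(8)
  ideal <- bs_conformation(build_peptide_coords(rep(-57, 8), rep(-47, 8)))
  expect_equal(helix_fraction(ideal, topo), 1.0)
  ext <- bs_conformation(build_peptide_coords(rep(-120, 8), rep(120, 8)))
  expect_equal(helix_fraction(ext, topo), 0.0)
  # half the interior helical; verify against bio3d's torsion routine
  phi <- c(0, -57, -57, -57, -120, -120, -120, 0)
  psi <- c(0, -47, -47, -47, 120, 120, 120, 0)
  mix <- bs_conformation(build_peptide_coords(phi, psi))
  expect_equal(helix_fraction(mix, topo), 0.5)
  bb <- bindscape:::peptide_backbone_indices(topo)
  tor <- bio3d::torsion.xyz(as.vector(t(mix$xyz[bb, ])), atm.inc = 1)
  dh <- bindscape:::peptide_dihedrals(mix, topo)
  # torsions along the backbone chain: psi_1 / omega_1 / phi_2 / psi_2 ...
  tor_phi <- tor[seq(4, length(tor), by = 3)]
  expect_equal(dh$phi[2:7], tor_phi[1:6], tolerance = 1e-6)
  # short peptides are missing-flagged
  expect_true(is.na(helix_fraction(
    bs_conformation(build_peptide_coords(c(0, 0), c(0, 0))), toy_peptide(2))))
})

test_that("optimized RMSD agrees with the quaternion oracle and bio3d", {
  set.seed(11)
  for (i in 1:60) {
    x <- matrix(rnorm(30), ncol = 3)
    y <- matrix(rnorm(30), ncol = 3)
    expect_equal(rmsd_optimized(x, y), oracle_rmsd_quaternion(x, y),
                 tolerance = 1e-6)
  }
  x <- matrix(rnorm(30), ncol = 3)
  R <- bindscape:::rotation_about_axis(c(1, 2, 3), 1.1)
  y <- sweep(x %*% t(R), 2, c(4, -2, 9), "+")
  expect_lt(rmsd_optimized(x, y), 1e-6)
  expect_equal(rmsd_optimized(x, x), 0)
  expect_equal(rmsd_optimized(x, y),
               bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE),
               tolerance = 1e-4)
  expect_error(rmsd_optimized(x, y[1:5, ]), "size")
})

test_that("non-optimized RMSD has its closed form and bounds the optimized one", {
  set.seed(12)
  x <- matrix(rnorm(24), ncol = 3)
  expect_equal(rmsd_nonoptimized(x, x), 0)
  expect_equal(rmsd_nonoptimized(x, sweep(x, 2, c(3, 0, 0), "+")), 3)
  for (i in 1:50) {
    a <- matrix(rnorm(18), ncol = 3)
    b <- matrix(rnorm(18), ncol = 3)
    expect_gte(rmsd_nonoptimized(a, b) + 1e-12, rmsd_optimized(a, b))
  }
})

test_that("ensemble diversity equals the pairwise enumeration", {
  set.seed(13)
  frames <- lapply(1:5, function(i) bs_conformation(matrix(rnorm(30), ncol = 3)))
  traj <- bs_trajectory(frames)
  manual <- mean(apply(utils::combn(5, 2), 2, function(p) {
    rmsd_optimized(frames[[p[1]]]$xyz, frames[[p[2]]]$xyz)
  }))
  expect_equal(ensemble_diversity(traj), manual)
  # identical copies give zero, pairs reduce to their own RMSD
  same <- bs_trajectory(frames[c(1, 1, 1)])
  expect_equal(ensemble_diversity(same), 0)
  two <- bs_trajectory(frames[1:2])
  expect_equal(ensemble_diversity(two),
               rmsd_optimized(frames[[1]]$xyz, frames[[2]]$xyz))
  expect_true(is.na(ensemble_diversity(bs_trajectory(frames[1]))))
})

test_that("contact count is invariant under rigid motion of the whole system", {
  spec <- synthetic_spec(n_receptor_res = 10, n_peptide_res = 5, n_frames = 1)
  rc <- make_reference_complex(spec)
  conf <- rc$bound_conformation
  n0 <- count_pocket_contacts(bs_conformation(conf$xyz), rc$topology,
                              rc$reference)
  R <- bindscape:::rotation_about_axis(c(1, 1, 0), 0.7)
  moved <- sweep(conf$xyz %*% t(R), 2, c(5, -3, 2), "+")
  expect_equal(count_pocket_contacts(bs_conformation(moved), rc$topology,
                                     rc$reference), n0)
})
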