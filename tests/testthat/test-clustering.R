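random_distance_matrix <- function(n) {
  x <- matrix(rnorm(n * 2, sd = 3), ncol = 2)
  as.matrix(dist(x))
}

test_that("complete linkage honours the intra-cluster diameter guarantee", {
  set.seed(47)
  for (rep in 1:20) {
    d <- random_distance_matrix(sample(5:15, 1))
    cutoff <- runif(1, 1, 8)
    cl <- complete_linkage_cut(d, cutoff)
    expect_equal(sum(cl$sizes), nrow(d))
    for (k in seq_along(cl$sizes)) {
      members <- which(cl$assignment == k)
      if (length(members) > 1) {
        expect_lt(max(d[members, members]), cutoff)
      }
    }
    expect_lt(cl$max_intra, cutoff)
  }
})

test_that("partitions match the brute-force agglomerative oracle", {
  set.seed(53)
  for (rep in 1:50) {
    d <- random_distance_matrix(sample(5:15, 1))
    cutoff <- runif(1, 1, 9)
    cl <- complete_linkage_cut(d, cutoff)
    oracle <- oracle_complete_linkage(d, cutoff)
    expect_equal(partition_canonical(cl$assignment),
                 partition_canonical(oracle))
  }
})

test_that("partitions agree with stats::hclust complete linkage", {
  set.seed(59)
  for (rep in 1:20) {
    d <- random_distance_matrix(12)
    cutoff <- runif(1, 1, 8)
    cl <- complete_linkage_cut(d, cutoff)
    hc <- stats::cutree(stats::hclust(as.dist(d), method = "complete"),
                        h = cutoff - 1e-9)
    expect_equal(partition_canonical(cl$assignment)[order(cl$assignment)],
                 partition_canonical(unname(hc))[order(cl$assignment)])
    expect_equal(length(cl$sizes), length(unique(hc)))
  }
})

test_that("degenerate geometries cluster as expected", {
  d <- matrix(2, 4, 4); diag(d) <- 0
  one <- complete_linkage_cut(d, 5)
  expect_equal(length(one$sizes), 1L)
  # two tight groups far apart
  x <- c(0, 0.1, 0.2, 50, 50.1)
  d2 <- as.matrix(dist(x))
  two <- complete_linkage_cut(d2, 5)
  expect_equal(length(two$sizes), 2L)
  expect_equal(sort(two$sizes), c(2L, 3L))
  expect_error(complete_linkage_cut(matrix(c(0, 1, 2, 0), 2, 2), 5),
               "symmetric")
})

test_that("lowering the cutoff never merges clusters", {
  set.seed(61)
  d <- random_distance_matrix(14)
  n_prev <- 0
  for (cutoff in c(10, 6, 4, 2, 1)) {
    n_now <- length(complete_linkage_cut(d, cutoff)$sizes)
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("clustering is invariant under input reordering up to relabeling", {
  set.seed(67)
  d <- random_distance_matrix(10)
  perm <- sample(10)
  cl1 <- complete_linkage_cut(d, 4)
  cl2 <- complete_linkage_cut(d[perm, perm], 4)
  # member i in the permuted problem is member perm[i] originally
  back <- integer(10)
  back[perm] <- cl2$assignment
  expect_equal(partition_canonical(cl1$assignment),
               partition_canonical(back))
})

test_that("medoids minimise the summed distance with deterministic ties", {
  d <- as.matrix(dist(c(0, 1, 2)))
  expect_equal(medoid(1:3, d), 2L)          # middle of a line
  expect_equal(medoid(2L, d), 2L)           # singleton
  set.seed(71)
  for (rep in 1:20) {
    dd <- random_distance_matrix(9)
    members <- sort(sample(9, sample(3:9, 1)))
    sums <- vapply(members, function(m) sum(dd[m, members]), numeric(1))
    expect_equal(medoid(members, dd), members[which.min(sums)])
  }
})

test_that("rmsd_matrix agrees with per-pair recomputation via the rmsd routines", {
  spec <- synthetic_spec(n_receptor_res = 8, n_peptide_res = 5, n_frames = 6,
                         seed = 2)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  traj <- gen$trajectory
  bb <- bindscape:::peptide_backbone_indices(rc$topology)
  d <- rmsd_matrix(traj, rc$topology, superpose_on = "none")
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d[i, j],
                   rmsd_nonoptimized(traj$coords[bb, , i], traj$coords[bb, , j]))
    }
  }
  dp <- rmsd_matrix(traj, rc$topology, superpose_on = "peptide")
  for (i in 1:3) {
    expect_equal(dp[i, i + 1],
                 rmsd_optimized(traj$coords[bb, , i], traj$coords[bb, , i + 1]))
  }
  # duplicated members give zero off-diagonal entries
  dup <- bs_trajectory(traj$coords[, , c(1, 1, 2)], box_length = 150)
  d0 <- rmsd_matrix(dup, rc$topology, superpose_on = "none")
  expect_equal(d0[1, 2], 0)
  expect_error(rmsd_matrix(traj, rc$topology, selection = integer(0)),
               "empty")
})

test_that("state ensembles cluster end to end with receptor superposition", {
  spec <- synthetic_spec(n_frames = 400, seed = 31)
  rc <- make_reference_complex(spec)
  gen <- generate_state_trajectory(rc$topology, rc$reference, spec,
                                   rc$symmetry)
  obs <- compute_observables(gen$trajectory, rc$topology, rc$reference)
  lab <- classify_states(obs, spec$delta_bound, spec$nc_bound,
                         spec$delta_unbound)
  res <- cluster_state_ensemble(gen$trajectory, rc$topology, lab,
                                "intermediate", cutoff = 8,
                                ref = rc$reference)
  g <- glance(res$clusters)
  expect_lt(g$max_intra, 8)
  expect_equal(g$n_members, sum(lab$state == "intermediate"))
  # sites are symmetry-related but spatially distinct: frames docked at
  # different sites can never share a cluster at this cutoff
  sites <- gen$truth$site[res$frames]
  for (k in seq_along(res$clusters$sizes)) {
    expect_equal(length(unique(sites[res$clusters$assignment == k])), 1L)
  }
})
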