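test_that("two-bin surface reproduces kT ln 4 exactly", {
  tab <- tibble::tibble(delta = c(rep(0.5, 800), rep(1.5, 200)))
  fes <- fes_from_samples(tab, x = "delta", bins = list(delta = c(0, 1, 2)))
  F <- fes$bins$F
  expect_equal(min(F), 0)
  expect_equal(max(F) - min(F), log(4), tolerance = 1e-12)
})

test_that("uniform occupancy gives a flat surface and probabilities are recovered", {
  set.seed(4)
  tab <- tibble::tibble(delta = rep(seq(0.5, 9.5, by = 1), each = 30))
  fes <- fes_from_samples(tab, x = "delta", bins = list(delta = 0:10))
  expect_true(all(abs(fes$bins$F) < 1e-12))
  # exponentiating -F and renormalising recovers empirical bin probabilities
  tab2 <- tibble::tibble(delta = runif(5000, 0, 10))
  fes2 <- fes_from_samples(tab2, x = "delta", bins = list(delta = 0:10))
  p_emp <- fes2$bins$counts / sum(fes2$bins$counts)
  p_fes <- exp(-fes2$bins$F)
  p_fes <- p_fes / sum(p_fes)
  expect_equal(p_fes, p_emp, tolerance = 1e-12)
})

test_that("planted 3-state occupancies give free-energy gaps at the log ratios", {
  set.seed(19)
  occ <- c(0.5, 0.3, 0.2)
  n_runs <- 10
  draws <- tibble::tibble(
    run = rep(seq_len(n_runs), each = 1e4),
    delta = sample(c(2.5, 12.5, 30.5), n_runs * 1e4, replace = TRUE,
                   prob = occ))
  fes <- profile_1d(draws, "delta", bins = c(0, 5, 25, 40), run = "run")
  occ_bins <- which(fes$bins$occupied)
  F <- fes$bins$F[occ_bins]
  err <- fes$bins$err[occ_bins]
  expect_true(all(is.finite(err)))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    dF <- F[pair[2]] - F[pair[1]]
    expected <- log(occ[pair[1]] / occ[pair[2]])
    tol <- 3 * sqrt(err[pair[1]]^2 + err[pair[2]]^2)
    expect_lt(abs(dF - expected), max(tol, 1e-3))
  }
})

test_that("jackknife of the mean equals the classical standard error exactly", {
  set.seed(23)
  x <- rnorm(12, 5, 2)
  expect_equal(jackknife_error(x), sd(x) / sqrt(length(x)), tolerance = 1e-12)
  expect_equal(jackknife_error(rep(3.3, 8)), 0)
  expect_true(is.na(jackknife_error(3.3)))
})

test_that("jackknife is calibrated against the known sampling error", {
  set.seed(29)
  m <- 8; sigma <- 1
  ses <- replicate(400, jackknife_error(rnorm(m, 0, sigma)))
  expect_lt(abs(mean(ses) - sigma / sqrt(m)) / (sigma / sqrt(m)), 0.2)
})

test_that("jackknife is invariant under run permutation", {
  set.seed(31)
  runs <- lapply(1:6, function(i) rnorm(50, i, 1))
  e1 <- jackknife_error(runs)
  e2 <- jackknife_error(runs[c(4, 2, 6, 1, 5, 3)])
  expect_equal(e1, e2)
})

test_that("1D profiles respect bin refinement and flag single-run errors", {
  set.seed(37)
  tab <- tibble::tibble(delta = runif(2000, 0, 8), run = rep(1:4, each = 500))
  coarse <- profile_1d(tab, "delta", bins = seq(0, 8, by = 2))
  fine <- profile_1d(tab, "delta", bins = seq(0, 8, by = 1))
  agg <- tapply(fine$bins$counts, rep(seq_len(4), each = 2), sum)
  expect_equal(as.numeric(agg), coarse$bins$counts)
  single <- profile_1d(dplyr::mutate(tab, run = 1L), "delta",
                       bins = seq(0, 8, by = 2))
  expect_true(all(is.na(single$bins$err)))
  expect_error(profile_1d(tab, "no_such_observable"), "available")
})

test_that("a plateau planted in the samples stays flat within half a kT", {
  set.seed(41)
  # equal occupancy across a range of bins = flat free energy there
  tab <- tibble::tibble(delta = c(runif(6000, 5, 15), rnorm(3000, 2, 0.5)))
  fes <- profile_1d(tab, "delta", bins = seq(0, 16, by = 1))
  plateau <- fes$bins$F[fes$bins$delta > 5.5 & fes$bins$delta < 14.5]
  expect_lt(diff(range(plateau)), 0.5)
})

test_that("tidy and glance summarise surfaces", {
  tab <- tibble::tibble(delta = runif(500, 0, 5),
                        helix_fraction = runif(500))
  fes <- fes_from_samples(tab, x = "delta", y = "helix_fraction")
  td <- tidy(fes)
  expect_true(all(c("delta", "helix_fraction", "counts", "F") %in% names(td)))
  expect_equal(sum(td$counts), 500)
  g <- glance(fes)
  expect_equal(g$n_samples, 500)
  expect_gte(g$n_bins, g$n_occupied)
})
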