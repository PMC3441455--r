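# Independent brute-force oracles used to validate the package's
# implementations. These deliberately take the slow, obvious route.

# minimum-image site distance by explicit enumeration of all 27 periodic
# images of the displacement, minimised over both sites
oracle_delta <- function(com, sites, box) {
  best <- Inf
  for (s in seq_len(nrow(sites))) {
    d0 <- com - sites[s, ]
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      d <- d0 + c(ix, iy, iz) * box
      best <- min(best, sqrt(sum(d^2)))
    }
  }
  best
}

# O(n^2) loop over heavy-atom pairs
oracle_pair_count <- function(xa, xb, threshold) {
  n <- 0L
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < threshold) n <- n + 1L
    }
  }
  n
}

# Horn's quaternion method for the optimal superposition RMSD
oracle_rmsd_quaternion <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  M <- crossprod(xc, yc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

# brute-force agglomerative complete linkage: recompute the max-linkage
# between every pair of clusters at every merge
oracle_complete_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- Inf; bi <- bj <- 0
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best - 1e-12 ||
            (abs(link - best) <= 1e-12 &&
             (min(clusters[[i]]) < min(clusters[[bi]]) ||
              (min(clusters[[i]]) == min(clusters[[bi]]) &&
               min(clusters[[j]]) < min(clusters[[bj]]))))) {
          best <- link; bi <- i; bj <- j
        }
      }
    }
    if (best >= cutoff) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  assignment
}

# canonical form of a partition for label-free comparison
partition_canonical <- function(assignment) {
  match(assignment, unique(assignment))
}

# simple peptide-only system for geometry tests
toy_peptide <- function(n = 6, seq3 = rep("ALA", n)) {
  bindscape:::bs_topology(bindscape:::chain_atom_table("P", "peptide", seq3))
}

# a tiny complete complex fixture shared across tests (built once)
tiny_complex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_complex(synthetic_spec(n_receptor_res = 12,
                                                      n_peptide_res = 6,
                                                      n_frames = 10))
    }
    cache
  }
})

count_crossing_events <- function(delta, lo, hi) {
  state <- NA_character_; nb <- 0L; nu <- 0L
  for (d in delta) {
    if (is.na(state)) {
      if (d <= lo) state <- "b" else if (d >= hi) state <- "u"
    } else if (state == "u" && d <= lo) {
      nb <- nb + 1L; state <- "b"
    } else if (state == "b" && d >= hi) {
      nu <- nu + 1L; state <- "u"
    }
  }
  c(bind = nb, unbind = nu)
}
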