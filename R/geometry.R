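#' Torsion (dihedral) angles from four point sets
#'
#' Computes the signed dihedral angle defined by four points, vectorised over
#' rows. Sign follows the IUPAC convention (clockwise positive when viewed
#' from `p2` towards `p3`).
#'
#' @param p1,p2,p3,p4 Numeric matrices with one row per angle and 3 columns
#'   (x, y, z), or length-3 vectors.
#' @return Numeric vector of angles in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- cross(b2 / b2n, n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a fourth point D from three anchors (A, B, C), a bond length |C-D|,
# a bond angle B-C-D and a torsion A-B-C-D (NeRF construction).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ta <- torsion_deg * pi / 180
  bc <- c - b
  bc_hat <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc_hat[3] - ab[3] * bc_hat[2],
         ab[3] * bc_hat[1] - ab[1] * bc_hat[3],
         ab[1] * bc_hat[2] - ab[2] * bc_hat[1])
  n_hat <- n / sqrt(sum(n^2))
  m_hat <- c(n_hat[2] * bc_hat[3] - n_hat[3] * bc_hat[2],
             n_hat[3] * bc_hat[1] - n_hat[1] * bc_hat[3],
             n_hat[1] * bc_hat[2] - n_hat[2] * bc_hat[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  c + d2[1] * bc_hat + d2[2] * m_hat + d2[3] * n_hat
}

# Ideal backbone geometry used by the chain builder (Engh-Huber-like values).
backbone_geometry <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_ca_cb = 1.53,
       a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, omega = 180)
}

#' Build peptide coordinates from backbone dihedrals
#'
#' Constructs a 4-bead-per-residue chain (N, CA, C and a CB pseudo-side-chain
#' bead) by geometry propagation with ideal bond lengths and angles and a
#' planar trans peptide bond. `phi[1]` and `psi[n]` are undefined for a chain
#' of length `n` and are ignored.
#'
#' @param phi,psi Numeric vectors of backbone dihedrals in degrees, one per
#'   residue.
#' @return Matrix (4 * n_res) x 3 of coordinates in Angstrom, atom order
#'   N, CA, C, CB within each residue.
#' @export
build_peptide_coords <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- backbone_geometry()
  coords <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  # first residue laid flat in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(th), sin(th), 0)
  coords[1:3, ] <- rbind(N, CA, C)
  for (i in seq_len(n)) {
    base <- (i - 1L) * 4L
    if (i > 1L) {
      pbase <- (i - 2L) * 4L
      Np <- coords[pbase + 1L, ]; CAp <- coords[pbase + 2L, ]; Cp <- coords[pbase + 3L, ]
      N <- place_atom(Np, CAp, Cp, g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      CA <- place_atom(CAp, Cp, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- place_atom(Cp, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
      coords[base + 1L, ] <- N
      coords[base + 2L, ] <- CA
      coords[base + 3L, ] <- C
    }
    N <- coords[base + 1L, ]; CA <- coords[base + 2L, ]; C <- coords[base + 3L, ]
    u1 <- N - CA; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- C - CA; u2 <- u2 / sqrt(sum(u2^2))
    bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
    nrm <- c(u2[2] * u1[3] - u2[3] * u1[2],
             u2[3] * u1[1] - u2[1] * u1[3],
             u2[1] * u1[2] - u2[2] * u1[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    dir <- bis * cos(0.9553) + nrm * sin(0.9553)  # ~54.75 deg out of plane
    coords[base + 4L, ] <- CA + g$b_ca_cb * dir
  }
  coords
}

# Kabsch optimal proper rotation aligning x onto y (both centred K x 3).
kabsch_rotation <- function(x, y) {
  h <- crossprod(x, y)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition of one coordinate set onto another
#'
#' @param x,y K x 3 matrices; `x` is moved onto `y`.
#' @param fit_idx Optional row indices used to compute the fit; the returned
#'   transform is applied to all rows of `x`.
#' @return List with `coords` (transformed `x`), `rotation`, `translation`.
#' @export
superpose <- function(x, y, fit_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(x))
  xf <- x[fit_idx, , drop = FALSE]
  yf <- y[fit_idx, , drop = FALSE]
  cx <- colMeans(xf); cy <- colMeans(yf)
  r <- kabsch_rotation(sweep(xf, 2, cx), sweep(yf, 2, cy))
  moved <- sweep(sweep(x, 2, cx) %*% r, 2, cy, "+")
  list(coords = moved, rotation = r, translation = cy - cx %*% r)
}

# Minimum-image displacement of vector d in a cubic box (NULL box = identity).
minimum_image <- function(d, box_length = NULL) {
  if (is.null(box_length) || !is.finite(box_length)) return(d)
  d - box_length * round(d / box_length)
}

# Rotation matrix for angle (radians) about unit axis.
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
}
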