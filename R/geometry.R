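## Cartesian geometry primitives: distances, angles, dihedrals, NeRF atom
## placement, and the puckering-state -> ring-coordinates constructor.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

.angle3 <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  .deg(acos(pmin(pmax(sum(u * v), -1), 1)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise rotation
#' of the far bond is positive. Result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 Numeric xyz triples.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  .wrap180(.deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

## place atom D bonded to C with distance r, angle (D,C,B) = theta and
## dihedral (D,C,B,A) = phi (degrees); the inverse of dihedral_angle.
.nerf_place <- function(A, B, C, r, theta, phi) {
  th <- .rad(theta)
  ph <- .rad(phi)
  bc <- .unit(C - B)
  n <- .cross3(B - A, bc)
  if (sqrt(sum(n^2)) < 1e-10) {
    ## reference atoms collinear: pick any perpendicular
    n <- .cross3(if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0), bc)
  }
  n <- .unit(n)
  m <- .cross3(n, bc)
  ## the sign of the out-of-plane component matches dihedral_angle(), so
  ## dihedral_angle(D, C, B, A) recovers phi exactly
  d <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build ring Cartesian coordinates from a puckering state
#'
#' Constructs the three-dimensional geometry of a ring whose out-of-plane
#' displacements reproduce a requested puckering state and whose cyclic bond
#' lengths match a template exactly. The in-plane part is solved in closed
#' form: all atoms share one radius rho, each edge subtends the arc
#' 2 asin(chord_j / 2 rho) where chord_j^2 = L_j^2 - (z_(j+1) - z_j)^2, and
#' rho is found by a one-dimensional root solve of the closure condition
#' (arc steps summing to 2 pi). Both the bond lengths and the recovered
#' puckering coordinates are exact to numerical round-off, comfortably inside
#' the documented tolerances (5e-3 Angstrom on bonds, 1e-3 on q/phi).
#'
#' @param template A [ring_template()].
#' @param state A `cp_pucker` object with matching `n_atoms`; total puckering
#'   amplitude at most 0.9 Angstrom (ring-closure feasibility bound).
#' @return A [ring_atom_set()] with the template's element labels; atom 1
#'   starts on the x axis and the mean plane is the z = 0 plane.
#' @export
#' @examples
#' st <- canonical_state("4C1", 0.55, n_atoms = 6)
#' ring <- build_ring_geometry(ring_template(6, "O"), st)
#' cp_pucker(ring)$theta  # 0
build_ring_geometry <- function(template, state) {
  stopifnot(inherits(template, "ring_template"), inherits(state, "cp_pucker"))
  n <- template$n_atoms
  if (state$n_atoms != n) {
    stop("template and state disagree on ring size", call. = FALSE)
  }
  if (state$amplitude > 0.9) {
    stop("puckering amplitude ", signif(state$amplitude, 4),
         " Angstrom exceeds the 0.9 Angstrom closure bound", call. = FALSE)
  }
  z <- inverse_displacements(state)
  L <- template$bond_lengths # edge j joins atoms j and j+1 (cyclic)
  dz <- z[c(2:n, 1L)] - z
  chord2 <- L^2 - dz^2
  if (any(chord2 <= 0)) {
    stop("ring closure failed: amplitude ", signif(state$amplitude, 4),
         " Angstrom leaves edge ", which(chord2 <= 0)[1L],
         " shorter than its out-of-plane rise", call. = FALSE)
  }
  chord <- sqrt(chord2)
  gap_sum <- function(rho) sum(2 * asin(pmin(chord / (2 * rho), 1))) - 2 * pi
  lo <- max(chord) / 2 * (1 + 1e-12)
  if (gap_sum(lo) < 0) {
    stop("ring closure failed for amplitude ", signif(state$amplitude, 4),
         " Angstrom: edges cannot span the ring", call. = FALSE)
  }
  rho <- uniroot(gap_sum, c(lo, 10 * max(L)), tol = 1e-12)$root
  beta <- cumsum(c(0, 2 * asin(chord / (2 * rho))))[seq_len(n)]
  ## clockwise in-plane placement (viewed from +z) makes the puckering mean
  ## plane normal point along +z, so the requested z are recovered with their
  ## signs (not mirrored) by the forward transform
  coords <- cbind(rho * cos(beta), -rho * sin(beta), z)
  ring_atom_set(coords, labels = template$ring_elements)
}

#' Endocyclic dihedral angles of a ring
#'
#' The N - 3 sequential dihedrals D_k over ring atoms (k, k+1, k+2, k+3),
#' k = 1 ... N - 3, which together with bond lengths and angles fully define
#' a ring conformation.
#'
#' @param ring A [ring_atom_set()] or N x 3 coordinate matrix.
#' @return Named numeric vector `D1` ... `D(N-3)`, degrees in (-180, 180].
#' @export
endocyclic_dihedrals <- function(ring) {
  coords <- if (inherits(ring, "ring_atom_set")) ring$coords else as.matrix(ring)
  n <- nrow(coords)
  k <- seq_len(n - 3L)
  out <- vapply(k, function(i) {
    dihedral_angle(coords[i, ], coords[i + 1L, ], coords[i + 2L, ], coords[i + 3L, ])
  }, numeric(1))
  setNames(out, paste0("D", k))
}
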