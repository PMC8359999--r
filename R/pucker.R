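#' Ordered ring-atom coordinates
#'
#' Bundles the Cartesian coordinates of the N ring atoms of a 5-, 6- or
#' 7-membered ring, ordered by the sugar-chemistry convention: position 1 is
#' the anomeric carbon, position N is the ring heteroatom, and intermediate
#' positions are consecutively bonded.
#'
#' @param coords Numeric matrix with one row per ring atom and columns x, y, z
#'   (Angstrom), or a data frame with columns `x`, `y`, `z`.
#' @param labels Optional character vector of element symbols, one per atom.
#'   Defaults to carbons with the last position labelled `"O"`.
#' @param check Validate bonded distances between cyclic neighbours
#'   (window 1.2--2.0 Angstrom)? Default `TRUE`.
#'
#' @return An object of class `ring_atom_set`: a list with elements `n_atoms`,
#'   `coords` (N x 3 matrix) and `labels`.
#' @export
#' @examples
#' hexagon <- ring_atom_set(regular_ring_coords(6))
#' hexagon$n_atoms
ring_atom_set <- function(coords, labels = NULL, check = TRUE) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y", "z") %in% names(coords)))
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  coords <- unname(as.matrix(coords))
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("`coords` must be an N x 3 numeric matrix", call. = FALSE)
  }
  n <- nrow(coords)
  if (!n %in% 5:7) {
    stop("ring size must be 5, 6 or 7 atoms, got ", n, call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- c(rep("C", n - 1L), "O")
  }
  stopifnot(length(labels) == n)
  if (check) {
    d <- sqrt(rowSums((coords - coords[c(2:n, 1L), , drop = FALSE])^2))
    if (any(d < 1.2 | d > 2.0)) {
      stop(
        "consecutive ring atoms must lie within 1.2-2.0 Angstrom; bond ",
        which(d < 1.2 | d > 2.0)[1L], " is ", signif(d[d < 1.2 | d > 2.0][1L], 4),
        call. = FALSE
      )
    }
  }
  structure(
    list(n_atoms = n, coords = coords, labels = as.character(labels)),
    class = "ring_atom_set"
  )
}

#' @export
print.ring_atom_set <- function(x, ...) {
  cat("<ring_atom_set> ", x$n_atoms, " atoms: ",
      paste(x$labels, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Regular planar polygon coordinates
#'
#' Convenience constructor for an ideal planar ring, mostly used to seed
#' examples and tests.
#'
#' @param n Ring size.
#' @param bond Bond length in Angstrom.
#' @return An `n` x 3 coordinate matrix in the z = 0 plane.
#' @export
regular_ring_coords <- function(n, bond = 1.54) {
  rho <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = rho * cos(ang), y = rho * sin(ang), z = 0)
}

## Mean plane through the geometric centre, oriented by the two Cremer-Pople
## orthogonality conditions (first-harmonic sine/cosine projections vanish).
## Returns centre, unit normal and perpendicular displacements.
cp_mean_plane <- function(coords) {
  n <- nrow(coords)
  centred <- sweep(coords, 2, colMeans(coords))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  r1 <- colSums(centred * sin(ang)) # R' of the classic construction
  r2 <- colSums(centred * cos(ang)) # R''
  nrm <- c(
    r1[2] * r2[3] - r1[3] * r2[2],
    r1[3] * r2[1] - r1[1] * r2[3],
    r1[1] * r2[2] - r1[2] * r2[1]
  )
  len <- sqrt(sum(nrm^2))
  if (!is.finite(len) || len < 1e-10) {
    stop("degenerate ring geometry: atoms are collinear or coincident",
         call. = FALSE)
  }
  nrm <- nrm / len
  list(center = colMeans(coords), normal = nrm, z = drop(centred %*% nrm))
}

#' Out-of-plane displacements from the puckering mean plane
#'
#' Projects each ring atom onto the normal of the Cremer-Pople mean plane: the
#' plane through the ring's geometric centre whose orientation makes the
#' first-harmonic sine and cosine projections of the displacements vanish.
#' The result is invariant under rigid translation and rotation of the input.
#'
#' @param ring A [ring_atom_set()], or a bare N x 3 coordinate matrix.
#' @return Numeric vector of N signed displacements z_j (Angstrom), summing to
#'   zero and satisfying both orientation conditions to machine precision.
#' @export
#' @examples
#' mean_plane_displacements(regular_ring_coords(6)) # all zero: planar ring
mean_plane_displacements <- function(ring) {
  coords <- if (inherits(ring, "ring_atom_set")) ring$coords else {
    ring_atom_set(ring, check = FALSE)$coords
  }
  ## reject coincident atoms early (any pair, not only bonded)
  dd <- as.matrix(stats::dist(coords))
  if (any(dd[upper.tri(dd)] < 1e-6)) {
    stop("degenerate ring geometry: two atoms coincide", call. = FALSE)
  }
  cp_mean_plane(coords)$z
}

#' Puckering phase angle from the projections A and B
#'
#' Converts the sine/cosine projections A_m = q_m sin(phi_m) and
#' B_m = q_m cos(phi_m) into a phase angle. Two conventions are available:
#'
#' * `"standard"`: the two-argument arctangent of (A, B) mapped to
#'   \[0, 360). This is the convention the conformer catalog uses.
#' * `"paper"`: the arccos-based reconstruction used by quantum-chemistry
#'   generalized-internal-coordinate interfaces that lack an arctan operator:
#'   `A/sqrt(A^2 + eps) * acos(B/sqrt(A^2 + B^2)) + 180`, with the smoothing
#'   guard `eps` preventing division by zero at A = 0. For non-degenerate
#'   inputs this differs from `"standard"` by a constant 180 degrees.
#'
#' The degenerate input A = B = 0 returns 0 (`"standard"`) or 180 (`"paper"`)
#' by convention.
#'
#' @param A,B Projections in Angstrom (may be vectors).
#' @param epsilon Smoothing guard of the `"paper"` mode, default `1e-6`.
#' @param mode `"standard"` (default) or `"paper"`.
#' @return Phase angle(s) in degrees.
#' @export
#' @examples
#' phase_angle(1, 0)                  # 90
#' phase_angle(1, 0, mode = "paper")  # ~270
phase_angle <- function(A, B, epsilon = 1e-6, mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  if (mode == "standard") {
    out <- .wrap360(.deg(atan2(A, B)))
    out[A == 0 & B == 0] <- 0
    return(out)
  }
  r <- sqrt(A^2 + B^2)
  acos_term <- ifelse(r > 0, .deg(acos(pmin(pmax(B / r, -1), 1))), 0)
  A / sqrt(A^2 + epsilon) * acos_term + 180
}

#' Forward Cremer-Pople transform
#'
#' Computes the puckering amplitudes and phases of a ring from its
#' out-of-plane displacements: the sine/cosine projections A_m and B_m with
#' prefactor sqrt(2/N) for m = 2 ... floor((N-1)/2), q_m = sqrt(A_m^2 + B_m^2),
#' and for even N the alternating-sum coordinate
#' q_(N/2) = N^(-1/2) * sum_j (-1)^(j-1) z_j. For N = 6 the polar coordinates
#' Q = sqrt(q2^2 + q3^2) and theta = acos(q3_signed / Q) are also filled in;
#' the stored q3 is the absolute value and the sign enters theta, so theta = 0
#' is the chair with atom 1 displaced to the positive side of the mean plane.
#'
#' @param z Displacement vector from [mean_plane_displacements()].
#' @param n_atoms Ring size (5, 6 or 7); must match `length(z)`.
#' @param phase_mode Passed to [phase_angle()]; the default `"standard"` is
#'   required for classification against the conformer catalog.
#' @param epsilon Guard for the `"paper"` phase mode.
#'
#' @return A `cp_pucker` object with fields `q` (named amplitudes, Angstrom),
#'   `phi` (named phases, degrees in \[0, 360)), `Q`, `theta` (N = 6 only),
#'   `A`, `B` (projections, kept for testing), `amplitude` (total puckering
#'   amplitude) and `planar` (flag set when all amplitudes vanish).
#' @seealso [inverse_displacements()] for the inverse, [cp_pucker()] for the
#'   one-call wrapper from Cartesian coordinates.
#' @export
#' @examples
#' z <- rep(c(0.25, -0.25), 3) # ideal chair pattern
#' s <- forward_pucker(z, 6)
#' s$q[["q3"]]   # sqrt(6) * 0.25
#' s$theta       # 0
forward_pucker <- function(z, n_atoms,
                           phase_mode = c("standard", "paper"),
                           epsilon = 1e-6) {
  phase_mode <- match.arg(phase_mode)
  if (length(z) != n_atoms) {
    stop("`z` has length ", length(z), " but `n_atoms` is ", n_atoms,
         call. = FALSE)
  }
  if (!n_atoms %in% 5:7) stop("n_atoms must be 5, 6 or 7", call. = FALSE)
  n <- n_atoms
  j <- seq_len(n) - 1
  ms <- 2:floor((n - 1) / 2) # phase-bearing harmonics: 2 (N=5,6) or 2,3 (N=7)
  A <- B <- q <- phi <- setNames(numeric(length(ms)), paste0("m", ms))
  for (k in seq_along(ms)) {
    m <- ms[k]
    B[k] <- sqrt(2 / n) * sum(z * cos(2 * pi * m * j / n))
    A[k] <- -sqrt(2 / n) * sum(z * sin(2 * pi * m * j / n))
    q[k] <- sqrt(A[k]^2 + B[k]^2)
    phi[k] <- if (q[k] < 1e-12) 0 else phase_angle(A[k], B[k], epsilon, phase_mode)
  }
  names(q) <- names(phi) <- paste0("q", ms)
  names(phi) <- sub("q", "phi", names(phi))
  q_half <- NA_real_
  Q <- theta <- NA_real_
  if (n %% 2 == 0) {
    q_half <- sum(z * (-1)^j) / sqrt(n) # signed (Eq. 3 style alternating sum)
    q <- c(q, q3 = abs(q_half))
    Q <- sqrt(q[["q2"]]^2 + q_half^2)
    theta <- if (Q < 1e-12) 0 else .deg(acos(pmin(pmax(q_half / Q, -1), 1)))
  }
  amplitude <- if (n == 6) Q else sqrt(sum(q^2))
  planar <- amplitude < 1e-10
  if (planar) {
    phi[] <- 0
    theta <- if (n %% 2 == 0) 0 else theta
  }
  structure(
    list(
      n_atoms = n, q = q, phi = phi, Q = Q, theta = theta,
      A = A, B = B, q_half_signed = q_half,
      amplitude = amplitude, planar = planar,
      phase_mode = phase_mode, epsilon = epsilon
    ),
    class = "cp_pucker"
  )
}

#' Construct a puckering state directly
#'
#' Builds a `cp_pucker` object from amplitudes and phases, the inverse-lookup
#' companion of [forward_pucker()]. For N = 6 either give (`q2`, `q3_signed`,
#' `phi2`) or (`Q`, `theta`, `phi2`).
#'
#' @param n_atoms Ring size.
#' @param q2,q3 Amplitudes in Angstrom (`q3` is the m = 3 amplitude for N = 7,
#'   ignored for N = 5).
#' @param phi2,phi3 Phases in degrees (standard convention).
#' @param Q,theta Polar coordinates for N = 6 (alternative to `q2`/`q3`).
#' @param q3_signed Signed alternating-sum coordinate for N = 6.
#' @return A `cp_pucker` object.
#' @export
cp_pucker_state <- function(n_atoms, q2 = NULL, q3 = NULL,
                            phi2 = 0, phi3 = 0,
                            Q = NULL, theta = NULL, q3_signed = NULL) {
  n <- n_atoms
  stopifnot(n %in% 5:7)
  if (n == 6) {
    if (!is.null(Q)) {
      stopifnot(!is.null(theta))
      q3_signed <- Q * cos(.rad(theta))
      q2 <- Q * sin(.rad(theta))
    } else {
      if (is.null(q3_signed)) q3_signed <- if (is.null(q3)) 0 else q3
      if (is.null(q2)) q2 <- 0
      Q <- sqrt(q2^2 + q3_signed^2)
      theta <- if (Q < 1e-12) 0 else .deg(acos(pmin(pmax(q3_signed / Q, -1), 1)))
    }
    q <- c(q2 = q2, q3 = abs(q3_signed))
    phi <- c(phi2 = .wrap360(phi2))
    amplitude <- Q
  } else if (n == 5) {
    if (is.null(q2)) q2 <- 0
    q <- c(q2 = q2)
    phi <- c(phi2 = .wrap360(phi2))
    Q <- theta <- NA_real_
    q3_signed <- NA_real_
    amplitude <- q2
  } else {
    if (is.null(q2)) q2 <- 0
    if (is.null(q3)) q3 <- 0
    q <- c(q2 = q2, q3 = q3)
    phi <- c(phi2 = .wrap360(phi2), phi3 = .wrap360(phi3))
    Q <- theta <- NA_real_
    q3_signed <- NA_real_
    amplitude <- sqrt(q2^2 + q3^2)
  }
  if (any(q < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  A <- q[paste0("q", 2:floor((n - 1) / 2))] * sin(.rad(phi))
  B <- q[paste0("q", 2:floor((n - 1) / 2))] * cos(.rad(phi))
  structure(
    list(
      n_atoms = n, q = q, phi = phi, Q = Q, theta = theta,
      A = unname(A), B = unname(B), q_half_signed = q3_signed,
      amplitude = amplitude, planar = amplitude < 1e-10,
      phase_mode = "standard", epsilon = 1e-6
    ),
    class = "cp_pucker"
  )
}

#' @export
print.cp_pucker <- function(x, digits = 4, ...) {
  cat("<cp_pucker> N =", x$n_atoms)
  if (x$planar) cat(" (planar)")
  cat("\n  ", paste(names(x$q), "=", signif(x$q, digits), collapse = ", "), "\n")
  cat("  ", paste(names(x$phi), "=", signif(x$phi, digits), collapse = ", "))
  if (x$n_atoms == 6) {
    cat(", Q =", signif(x$Q, digits), ", theta =", signif(x$theta, digits))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.cp_pucker <- function(x, ...) {
  as.data.frame(tidy.cp_pucker(x))
}

#' Tidy a puckering state into a one-row tibble
#'
#' @param x A `cp_pucker` object.
#' @param ... Unused.
#' @return A tibble with columns `n_atoms`, `q2`, `q3`, `phi2`, `phi3`, `Q`,
#'   `theta`, `amplitude`, `planar` (absent harmonics are `NA`).
#' @method tidy cp_pucker
#' @export
tidy.cp_pucker <- function(x, ...) {
  tibble::tibble(
    n_atoms = x$n_atoms,
    q2 = x$q[["q2"]],
    q3 = if ("q3" %in% names(x$q)) x$q[["q3"]] else NA_real_,
    phi2 = x$phi[["phi2"]],
    phi3 = if ("phi3" %in% names(x$phi)) x$phi[["phi3"]] else NA_real_,
    Q = x$Q,
    theta = x$theta,
    amplitude = x$amplitude,
    planar = x$planar
  )
}

#' Puckering coordinates of a ring in one call
#'
#' Chains [mean_plane_displacements()] and [forward_pucker()].
#'
#' @inheritParams mean_plane_displacements
#' @inheritParams forward_pucker
#' @return A `cp_pucker` object.
#' @export
cp_pucker <- function(ring, phase_mode = c("standard", "paper"),
                      epsilon = 1e-6) {
  n <- if (inherits(ring, "ring_atom_set")) ring$n_atoms else nrow(ring)
  forward_pucker(mean_plane_displacements(ring), n,
                 phase_mode = match.arg(phase_mode), epsilon = epsilon)
}

#' Inverse Cremer-Pople transform
#'
#' Reconstructs the out-of-plane displacement vector of a puckering state:
#' z_j = sqrt(2/N) * sum_m q_m cos(phi_m + 2 pi m (j-1)/N), plus, for even N,
#' the alternating term N^(-1/2) q_(N/2) (-1)^(j-1) with the sign carried by
#' theta. The phase-convention signs are chosen so that
#' `forward_pucker(inverse_displacements(s))` reproduces `s`.
#'
#' @param state A `cp_pucker` object (standard phase mode, or paper mode,
#'   which is converted internally).
#' @return Numeric displacement vector of length `state$n_atoms`.
#' @export
inverse_displacements <- function(state) {
  stopifnot(inherits(state, "cp_pucker"))
  n <- state$n_atoms
  j <- seq_len(n) - 1
  phi <- state$phi
  if (identical(state$phase_mode, "paper")) {
    ## recover the exact standard phases from the stored projections (the
    ## arccos phase itself carries the epsilon smoothing near A = 0)
    phi[] <- .wrap360(.deg(atan2(state$A, state$B)))
  }
  ms <- 2:floor((n - 1) / 2)
  z <- numeric(n)
  for (k in seq_along(ms)) {
    m <- ms[k]
    z <- z + sqrt(2 / n) * state$q[[paste0("q", m)]] *
      cos(.rad(phi[[paste0("phi", m)]]) + 2 * pi * m * j / n)
  }
  if (n %% 2 == 0) {
    q3s <- state$q_half_signed
    if (is.na(q3s)) q3s <- state$Q * cos(.rad(state$theta))
    z <- z + q3s * (-1)^j / sqrt(n)
  }
  z
}

#' Puckering report for a set of structures
#'
#' Computes puckering coordinates (and optionally conformer labels) for many
#' ring structures at once and returns one row per structure, suitable for the
#' delimited puckering report of the command-line `classify` workflow.
#'
#' @param rings A list of [ring_atom_set()] objects (or coordinate matrices),
#'   optionally named.
#' @param classify Add an `label` column by nearest-canonical-conformer
#'   classification? Default `TRUE`.
#' @param min_amplitude Planarity threshold passed to [classify_state()].
#' @return A tibble with columns `id`, the tidy puckering columns and,
#'   if requested, `label`.
#' @export
pucker_report <- function(rings, classify = TRUE, min_amplitude = 0.05) {
  if (inherits(rings, "ring_atom_set") || is.matrix(rings)) rings <- list(rings)
  ids <- names(rings)
  if (is.null(ids)) ids <- sprintf("structure_%03d", seq_along(rings))
  states <- purrr::map(rings, cp_pucker)
  out <- dplyr::bind_cols(
    tibble::tibble(id = ids),
    purrr::map_dfr(states, tidy.cp_pucker)
  )
  if (classify) {
    out$label <- purrr::map_chr(states, classify_state,
                                min_amplitude = min_amplitude)
  }
  out
}
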