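#' Generalized-internal-coordinate definitions for ring puckering
#'
#' Emits a plain-text block of generalized internal coordinate (GIC)
#' definitions that evaluate the ring puckering coordinates inside a
#' quantum-chemistry scan driver. Only the operators such interfaces provide
#' are used: arithmetic, `SQRT`, `ACOS` and the centre-of-geometry functions
#' `XCntr`/`YCntr`/`ZCntr`; there is no arctangent, so the phases use the
#' arccos reconstruction with the smoothing guard `epsilon` embedded
#' (the `"paper"` mode of [phase_angle()]).
#'
#' The definitions assume the ring has been oriented so that the puckering
#' mean plane is normal to the laboratory z axis; the emitted displacements
#' are z coordinates relative to the ring centre of geometry. A header line
#' records this assumption. Output is byte-identical across runs for fixed
#' inputs.
#'
#' @param n_atoms Ring size (5, 6 or 7).
#' @param atom_indices Integer vector of length `n_atoms`: the (1-based)
#'   indices of the ring atoms in the full molecule, in ring order.
#' @param epsilon Smoothing guard of the phase expression, default `1e-6`.
#' @return A single character scalar, one definition per line.
#' @export
#' @examples
#' cat(emit_gic_definitions(5, 1:5))
emit_gic_definitions <- function(n_atoms, atom_indices, epsilon = 1e-6) {
  stopifnot(n_atoms %in% 5:7)
  idx <- as.integer(atom_indices)
  if (length(idx) != n_atoms) {
    stop("`atom_indices` must have length ", n_atoms, call. = FALSE)
  }
  if (anyDuplicated(idx) || any(idx < 1L)) {
    stop("`atom_indices` must be distinct positive integers", call. = FALSE)
  }
  n <- n_atoms
  num <- function(x) sprintf("%.9f", x)
  ilist <- paste(idx, collapse = ",")
  lines <- c(
    sprintf("! ring puckering GICs, N = %d, ring atoms %s", n, ilist),
    "! assumes the ring mean plane is normal to the laboratory z axis",
    sprintf("ZC(Inactive) = ZCntr(%s)", ilist)
  )
  zname <- sprintf("Z%d", seq_len(n))
  lines <- c(lines, sprintf("%s(Inactive) = Z(%d)-ZC", zname, idx))

  pref <- sqrt(2 / n)
  comb <- function(coef) {
    keep <- abs(coef) > 1e-12
    terms <- sprintf("%s*%s", num(coef[keep]), zname[keep])
    paste(terms, collapse = "+")
  }
  j <- seq_len(n) - 1
  ms <- 2:floor((n - 1) / 2)
  for (m in ms) {
    bm <- sprintf("B%d", m)
    am <- sprintf("A%d", m)
    qm <- sprintf("Q%d", m)
    pm <- sprintf("PHI%d", m)
    lines <- c(
      lines,
      sprintf("%s(Inactive) = %s", bm, comb(pref * cos(2 * pi * m * j / n))),
      sprintf("%s(Inactive) = %s", am, comb(-pref * sin(2 * pi * m * j / n))),
      sprintf("%s = SQRT(%s*%s+%s*%s)", qm, am, am, bm, bm),
      sprintf("%s = (%s/SQRT(%s*%s+%s))*ACOS(%s/SQRT(%s*%s+%s*%s))+180.0",
              pm, am, am, am, num(epsilon), bm, am, am, bm, bm)
    )
  }
  if (n %% 2 == 0) {
    alt <- comb((-1)^j / sqrt(n))
    lines <- c(
      lines,
      sprintf("Q3(Inactive) = %s", alt),
      "QTOT = SQRT(Q2*Q2+Q3*Q3)",
      "THETA = ACOS(Q3/QTOT)"
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
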