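# Independent brute-force evaluation of the puckering projections, written
# directly from the summation formulas with explicit loops. Shares no code
# with the package implementation; used as the oracle in equivalence tests.
oracle_pucker <- function(z) {
  n <- length(z)
  out <- list()
  for (m in 2:floor((n - 1) / 2)) {
    B <- 0
    A <- 0
    for (j in 1:n) {
      B <- B + z[j] * cos(2 * pi * m * (j - 1) / n)
      A <- A - z[j] * sin(2 * pi * m * (j - 1) / n)
    }
    B <- sqrt(2 / n) * B
    A <- sqrt(2 / n) * A
    q <- sqrt(A^2 + B^2)
    phi <- atan2(A, B) * 180 / pi
    if (phi < 0) phi <- phi + 360
    out[[paste0("q", m)]] <- q
    out[[paste0("phi", m)]] <- phi
    out[[paste0("A", m)]] <- A
    out[[paste0("B", m)]] <- B
  }
  if (n %% 2 == 0) {
    s <- 0
    for (j in 1:n) s <- s + (-1)^(j - 1) * z[j]
    out$q_half <- s / sqrt(n)
  }
  out
}

# random rigid motion: proper rotation from QR plus a translation
random_rigid_motion <- function(coords) {
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, runif(3, -20, 20), `+`)
}

# random puckered ring built from a jittered polygon (valid bonded geometry)
random_ring_coords <- function(n, max_z = 0.35) {
  base <- regular_ring_coords(n, bond = 1.54)
  base[, 3] <- runif(n, -max_z, max_z)
  base[, 1:2] <- base[, 1:2] + matrix(runif(2 * n, -0.03, 0.03), n)
  base
}

# random non-degenerate puckering state
random_state <- function(n, min_amp = 0.1, max_amp = 0.8) {
  amp <- runif(1, min_amp, max_amp)
  if (n == 5) {
    cp_pucker_state(5, q2 = amp, phi2 = runif(1, 0, 360))
  } else if (n == 6) {
    cp_pucker_state(6, Q = amp, theta = runif(1, 5, 175),
                    phi2 = runif(1, 0, 360))
  } else {
    alpha <- runif(1, 0.1, pi / 2 - 0.1)
    cp_pucker_state(7, q2 = amp * sin(alpha), q3 = amp * cos(alpha),
                    phi2 = runif(1, 0, 360), phi3 = runif(1, 0, 360))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_angle_equal <- function(a, b, tol = 1e-6) {
  d <- abs((a - b + 180) %% 360 - 180)
  expect_lt(max(d), tol)
}

all_templates <- function() {
  het <- c("CH2", "O", "S", "SO2", "NH", "BH", "PH")
  out <- list()
  for (n in 5:7) for (x in het) out[[paste0(n, x)]] <- ring_template(n, x)
  out
}
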