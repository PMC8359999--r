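test_that("planar rings have zero displacements, rigid motions change nothing", {
  hex <- regular_ring_coords(6)
  expect_equal(mean_plane_displacements(hex), rep(0, 6), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    ring <- random_ring_coords(sample(5:7, 1))
    z0 <- mean_plane_displacements(ring)
    z1 <- mean_plane_displacements(random_rigid_motion(ring))
    expect_equal(z1, z0, tolerance = 1e-9)
    # centring and the two orientation conditions
    n <- length(z0)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    expect_lt(abs(sum(z0)), 1e-9)
    expect_lt(abs(sum(z0 * cos(ang))), 1e-9)
    expect_lt(abs(sum(z0 * sin(ang))), 1e-9)
  }
})

test_that("an ideal chair gives alternating +-0.25 displacements", {
  rho <- 1.54 / (2 * sin(pi / 6))
  ang <- -2 * pi * (0:5) / 6 # clockwise from above
  chair <- cbind(rho * cos(ang), rho * sin(ang), rep(c(0.25, -0.25), 3))
  z <- mean_plane_displacements(chair)
  expect_equal(z, rep(c(0.25, -0.25), 3), tolerance = 1e-6)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(seq(0, 6, length.out = 5) * 1.5, 0, 0)
  expect_error(mean_plane_displacements(line), "degenerate|collinear")
  dup <- regular_ring_coords(5)
  dup[2, ] <- dup[1, ]
  expect_error(mean_plane_displacements(dup), "coincide")
})

test_that("forward transform matches hand-derived cases", {
  # planar ring: everything zero, phases zero by convention
  s0 <- forward_pucker(rep(0, 6), 6)
  expect_true(s0$planar)
  expect_equal(unname(s0$q), c(0, 0))
  expect_equal(unname(s0$phi), 0)
  expect_equal(s0$Q, 0)

  # pure chair pattern: q2 = 0, q3 = sqrt(6) t, theta = 0
  t <- 0.25
  s <- forward_pucker(rep(c(t, -t), 3), 6)
  expect_equal(s$q[["q2"]], 0, tolerance = 1e-12)
  expect_equal(s$q[["q3"]], sqrt(6) * t, tolerance = 1e-12)
  expect_equal(s$theta, 0, tolerance = 1e-9)
  # inverted chair: theta = 180
  expect_equal(forward_pucker(rep(c(-t, t), 3), 6)$theta, 180, tolerance = 1e-9)

  # length mismatch
  expect_error(forward_pucker(rep(0, 5), 6), "length")
})

test_that("forward agrees with the brute-force oracle on random rings", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(5:7, 1)
    z <- mean_plane_displacements(random_ring_coords(n))
    got <- forward_pucker(z, n)
    ref <- oracle_pucker(z)
    for (m in 2:floor((n - 1) / 2)) {
      expect_equal(got$q[[paste0("q", m)]], ref[[paste0("q", m)]],
                   tolerance = 1e-6)
      expect_angle_equal(got$phi[[paste0("phi", m)]], ref[[paste0("phi", m)]],
                         tol = 1e-6)
    }
    if (n == 6) {
      expect_equal(got$q[["q3"]], abs(ref$q_half), tolerance = 1e-9)
      # Q^2 = q2^2 + q3^2 conservation
      expect_equal(got$Q^2, got$q[["q2"]]^2 + got$q[["q3"]]^2,
                   tolerance = 1e-9)
      expect_equal(got$theta,
                   acos(ref$q_half / got$Q) * 180 / pi, tolerance = 1e-6)
    }
    # q_m^2 = A_m^2 + B_m^2
    expect_equal(got$q[seq_along(got$A)]^2, got$A^2 + got$B^2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("cyclic relabeling shifts each phase by m * 360 / N", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:7, 1)
    ring <- random_ring_coords(n)
    s0 <- cp_pucker(ring)
    s1 <- cp_pucker(ring[c(2:n, 1), ]) # new atom j = old atom j + 1
    for (m in 2:floor((n - 1) / 2)) {
      expect_equal(s1$q[[paste0("q", m)]], s0$q[[paste0("q", m)]],
                   tolerance = 1e-9)
      expect_angle_equal(s1$phi[[paste0("phi", m)]],
                         s0$phi[[paste0("phi", m)]] + m * 360 / n, tol = 1e-6)
    }
  }
})

test_that("phase_angle reproduces both conventions and their 180 degree offset", {
  # arccos mode hand cases
  expect_equal(phase_angle(0, 1, mode = "paper"), 180)
  expect_equal(phase_angle(1, 0, mode = "paper"), 270, tolerance = 1e-4)
  expect_equal(phase_angle(1, 0, mode = "standard"), 90)
  expect_equal(phase_angle(0, 0, mode = "standard"), 0)
  expect_equal(phase_angle(0, 0, mode = "paper"), 180)

  # the two modes differ by a constant 180 degrees away from the A ~ 0 seam
  # (the smoothed sign A/sqrt(A^2+eps) departs from +-1 when |A| ~ sqrt(eps))
  set.seed(5)
  for (i in 1:200) {
    A <- runif(1, -1, 1)
    if (abs(A) < 0.05) next
    B <- runif(1, -1, 1)
    d <- phase_angle(A, B, mode = "paper") - phase_angle(A, B) - 180
    expect_lt(abs((d + 180) %% 360 - 180), 0.05)
  }
})

test_that("inverse transform round-trips puckering states", {
  # alternating chair from its polar coordinates
  st <- cp_pucker_state(6, Q = 0.25 * sqrt(6), theta = 0, phi2 = 0)
  expect_equal(inverse_displacements(st), rep(c(0.25, -0.25), 3),
               tolerance = 1e-12)
  # zero state
  expect_equal(inverse_displacements(cp_pucker_state(6, Q = 0, theta = 0)),
               rep(0, 6))

  set.seed(47)
  for (i in 1:300) {
    n <- sample(5:7, 1)
    s <- random_state(n)
    s2 <- forward_pucker(inverse_displacements(s), n)
    expect_equal(unname(s2$q), unname(s$q), tolerance = 1e-6)
    expect_angle_equal(unname(s2$phi), unname(s$phi), tol = 1e-6)
    if (n == 6) expect_equal(s2$theta, s$theta, tolerance = 1e-6)
  }
})

test_that("paper-mode states invert correctly too", {
  set.seed(53)
  z <- mean_plane_displacements(random_ring_coords(6))
  sp <- forward_pucker(z, 6, phase_mode = "paper")
  expect_equal(inverse_displacements(sp), z, tolerance = 1e-9)
})

test_that("GIC definition text is structurally sound and deterministic", {
  for (n in 5:7) {
    idx <- seq_len(n) + 1L
    txt <- emit_gic_definitions(n, idx)
    expect_identical(txt, emit_gic_definitions(n, idx)) # byte-identical
    expect_false(grepl("ATAN", txt, ignore.case = TRUE))
    expect_true(grepl("SQRT", txt))
    expect_true(grepl("ACOS", txt))
    expect_true(grepl("ZCntr", txt))
    expect_true(grepl("0.000001", txt, fixed = TRUE)) # epsilon guard embedded
    # balanced parentheses on every line
    for (ln in strsplit(txt, "\n")[[1]]) {
      open <- lengths(regmatches(ln, gregexpr("\\(", ln)))
      close <- lengths(regmatches(ln, gregexpr("\\)", ln)))
      expect_equal(open, close)
    }
    expect_true(grepl("Q2", txt))
    expect_true(grepl("PHI2", txt))
  }
  expect_true(grepl("THETA", emit_gic_definitions(6, 1:6)))
  expect_true(grepl("PHI3", emit_gic_definitions(7, 1:7)))
  expect_error(emit_gic_definitions(6, c(1, 1, 2, 3, 4, 5)), "distinct")
  expect_error(emit_gic_definitions(6, c(0, 1, 2, 3, 4, 5)), "distinct|positive")
})
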