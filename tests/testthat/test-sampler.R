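test_that("library draws are uniform, bounded and deterministic", {
  lib <- build_dihedral_library(ring_template(5, "O"))
  one <- lib[3, ]
  set.seed(1)
  expect_equal(draw_conformer(one)$label, one$label) # single entry: always it
  expect_error(draw_conformer(lib[0, ]), "empty")

  set.seed(2)
  a <- replicate(50, draw_conformer(lib)$label)
  set.seed(2)
  b <- replicate(50, draw_conformer(lib)$label)
  expect_identical(a, b)

  # frequencies within 4 binomial sigma of 1/20 at n = 2e4 (1e5 in acceptance)
  set.seed(3)
  n <- 2e4
  lab <- replicate(n, draw_conformer(lib)$label)
  p <- 1 / nrow(lib)
  tol <- 4 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(table(lab) / n - p) < tol))
})

test_that("rotamer draws are uniform in [-180, 180]", {
  expect_length(draw_rotamers(0), 0)
  set.seed(4)
  x <- draw_rotamers(2e4)
  expect_gte(min(x), -180)
  expect_lte(max(x), 180)
  expect_lt(abs(mean(x)), 4 * (360 / sqrt(12)) / sqrt(2e4))
  set.seed(9); y1 <- draw_rotamers(10)
  set.seed(9); y2 <- draw_rotamers(10)
  expect_identical(y1, y2)
})

test_that("heteroatom flips are exactly +-120 with equal probability", {
  tpl <- ring_template(6, "NH")
  set.seed(6)
  x <- replicate(5e3, draw_het_flip(tpl))
  expect_setequal(unique(x), c(-120, 120))
  expect_lt(abs(mean(x == 120) - 0.5), 4 * sqrt(0.25 / 5e3))
  expect_error(draw_het_flip(ring_template(6, "O")), "flip")
})

test_that("clash detection separates overlap from normal geometry", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0))
  expect_true(clash_check(coords, 0.7))
  expect_false(clash_check(coords, 0))

  tpl <- ring_template(6, "CH2")
  ring <- build_ring_geometry(tpl, canonical_state("4C1", 0.55, 6))
  mol <- zmat_to_cartesian(attach_substituents(ring, tpl, list()))
  expect_false(clash_check(mol, 0.7)) # idealized cyclohexane chair is clean
  # sanity: closest non-excluded pair is well above the threshold
  d <- as.matrix(dist(mol$coords))
  excl <- puckermc:::.bonded_13_pairs(mol$bonds, nrow(mol$coords))
  d[excl] <- Inf; d[excl[, 2:1]] <- Inf; diag(d) <- Inf
  expect_gt(min(d), 1.7)
})

test_that("generated batches satisfy the count and bound contracts", {
  b <- generate_conformers(spec_hydroxy_thf(), n_conformers = 40, seed = 123)
  expect_equal(nrow(b$manifest), 40)
  expect_length(b$molecules, 40)
  expect_true(all(b$manifest$ROT1 >= -180 & b$manifest$ROT1 <= 180))
  expect_true(all(b$manifest$label %in% enumerate_catalog(5)$name))

  # NH ring: flips recorded and exactly +-120
  specN <- ring_spec(6, "NH", list(substituent(2, "OH", "up")))
  bN <- generate_conformers(specN, n_conformers = 30, seed = 5)
  expect_true(all(bN$manifest$het_flip %in% c(-120, 120)))

  # every realized structure starts at the origin with atom 2 on the x axis
  for (mol in b$molecules[1:5]) {
    expect_equal(mol$coords[1, ], c(0, 0, 0))
    expect_equal(mol$coords[2, 2:3], c(0, 0))
    expect_gt(mol$coords[2, 1], 0)
  }
})

test_that("batches are reproducible from the seed", {
  b1 <- generate_conformers(spec_alpha_d_glucose(), n_conformers = 8, seed = 77)
  b2 <- generate_conformers(spec_alpha_d_glucose(), n_conformers = 8, seed = 77)
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$molecules[[8]]$coords, b2$molecules[[8]]$coords)
  b3 <- generate_conformers(spec_alpha_d_glucose(), n_conformers = 8, seed = 78)
  expect_false(identical(b1$manifest, b3$manifest))
  # entropy-seeded runs record their seed and replay exactly
  b4 <- generate_conformers(spec_hydroxy_thf(), n_conformers = 4)
  b5 <- generate_conformers(spec_hydroxy_thf(), n_conformers = 4, seed = b4$seed)
  expect_identical(b4$manifest, b5$manifest)
})

test_that("clash policies flag, keep or drop as documented", {
  spec <- spec_alpha_d_glucose()
  bf <- generate_conformers(spec, n_conformers = 25, seed = 31,
                            clash_policy = "flag")
  expect_equal(nrow(bf$manifest), 25)
  bk <- generate_conformers(spec, n_conformers = 25, seed = 31,
                            clash_policy = "keep")
  expect_false(any(bk$manifest$clash))
  # with an absurd threshold every draw clashes and "drop" must give up
  expect_error(
    generate_conformers(spec, n_conformers = 2, seed = 1,
                        clash_threshold = 10, clash_policy = "drop"),
    "exhausted"
  )
  bd <- generate_conformers(spec, n_conformers = 10, seed = 13,
                            clash_policy = "drop")
  expect_equal(nrow(bd$manifest), 10)
  expect_false(any(bd$manifest$clash))
})

test_that("tidy, glance and autoplot expose the batch", {
  b <- generate_conformers(spec_hydroxy_thf(), n_conformers = 6, seed = 2)
  expect_identical(tidy(b), b$manifest)
  g <- glance(b)
  expect_equal(g$n_conformers, 6L)
  expect_equal(g$seed, 2)
  p <- ggplot2::autoplot(b)
  expect_s3_class(p, "ggplot")
  pm <- plot_mercator(generate_conformers(
    ring_spec(6, "O"), n_conformers = 4, seed = 3))
  expect_s3_class(pm, "ggplot")
})
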