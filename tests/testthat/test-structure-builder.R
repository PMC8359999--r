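test_that("planar closure gives the circumscribed polygon", {
  tpl <- ring_template(6, "CH2") # all bonds 1.54
  ring <- build_ring_geometry(tpl, cp_pucker_state(6, Q = 0, theta = 0))
  bonds <- sqrt(rowSums((ring$coords - ring$coords[c(2:6, 1), ])^2))
  expect_equal(bonds, rep(1.54, 6), tolerance = 5e-3)
  expect_equal(max(abs(ring$coords[, 3])), 0, tolerance = 1e-9)
})

test_that("built rings reproduce the requested puckering state and bonds", {
  tpl <- ring_template(6, "O")
  ring <- build_ring_geometry(tpl, cp_pucker_state(6, Q = 0.55, theta = 0))
  got <- cp_pucker(ring)
  expect_equal(got$theta, 0, tolerance = 0.5)
  expect_equal(got$q[["q3"]], 0.55, tolerance = 5e-3)
  bonds <- sqrt(rowSums((ring$coords - ring$coords[c(2:6, 1), ])^2))
  expect_equal(bonds, tpl$bond_lengths, tolerance = 5e-3)

  # twist-boat plane of a seven-ring stays at q3 ~ 0
  tpl7 <- ring_template(7, "O")
  st7 <- cp_pucker_state(7, q2 = 0.75, q3 = 0, phi2 = 77.14, phi3 = 0)
  expect_lte(cp_pucker(build_ring_geometry(tpl7, st7))$q[["q3"]], 0.01)

  # sampled canonical labels across heteroatoms (full sweep in acceptance)
  set.seed(83)
  for (tpl in all_templates()[c("5O", "6S", "7NH", "6SO2")]) {
    cat_n <- enumerate_catalog(tpl$n_atoms)
    for (i in sample(nrow(cat_n), 5)) {
      st <- canonical_state(cat_n[i, ], 0.5)
      ring <- build_ring_geometry(tpl, st)
      got <- cp_pucker(ring)
      expect_equal(unname(got$q), unname(st$q), tolerance = 1e-3)
      expect_angle_equal(unname(got$phi), unname(st$phi), tol = 1e-3)
    }
  }

  expect_error(
    build_ring_geometry(tpl, cp_pucker_state(6, Q = 0.95, theta = 90)),
    "0.9"
  )
})

test_that("endocyclic dihedrals behave on planar and chair geometries", {
  planar <- build_ring_geometry(ring_template(6, "CH2"),
                                cp_pucker_state(6, Q = 0, theta = 0))
  expect_equal(max(abs(endocyclic_dihedrals(planar))), 0, tolerance = 1e-6)

  chair <- build_ring_geometry(ring_template(6, "CH2"),
                               cp_pucker_state(6, Q = 0.55, theta = 0))
  D <- unname(endocyclic_dihedrals(chair))
  expect_equal(abs(D), rep(abs(D[1]), 3), tolerance = 1e-6) # equal magnitudes
  expect_equal(sign(D), sign(D[1]) * c(1, -1, 1))           # alternating signs
})

test_that("dihedral libraries are complete and consistent", {
  lib5 <- build_dihedral_library(ring_template(5, "CH2"))
  expect_equal(nrow(lib5), 20)
  expect_named(lib5, c("label", "family", "D1", "D2"))

  lib6 <- build_dihedral_library(ring_template(6, "O"))
  expect_equal(nrow(lib6), 38)
  expect_equal(sum(grepl("^D", names(lib6))), 3)

  # chair entry equals the directly built chair's dihedrals
  tpl <- ring_template(6, "O")
  chair <- build_ring_geometry(tpl, canonical_state("4C1", 0.55, 6))
  expect_equal(
    as.numeric(lib6[lib6$label == "4C1", c("D1", "D2", "D3")]),
    unname(endocyclic_dihedrals(chair)), tolerance = 1e-9
  )

  # a ring rebuilt from a library entry returns the entry's D values
  zm <- attach_substituents(chair, tpl, list())
  row <- lib6[lib6$label == "1S3", ]
  mol <- zmat_to_cartesian(zm, c(D1 = row$D1, D2 = row$D2, D3 = row$D3))
  D_back <- endocyclic_dihedrals(mol$coords[1:6, ])
  expect_equal(unname(D_back), as.numeric(row[, c("D1", "D2", "D3")]),
               tolerance = 1e-3)
})

test_that("library text files round-trip through the per-dihedral layout", {
  dir <- withr::local_tempdir()
  lib <- build_dihedral_library(ring_template(5, "O"))
  paths <- write_library_files(lib, dir, "N-5-H-0-Oxy")
  expect_equal(basename(paths), c("N-5-H-0-Oxy-D1.txt", "N-5-H-0-Oxy-D2.txt"))
  back <- read_library_files(paths)
  expect_equal(nrow(back), 20)
  expect_equal(back$D1, round(lib$D1, 4), tolerance = 1e-9)
  expect_equal(back$D2, round(lib$D2, 4), tolerance = 1e-9)

  # validation: mismatched row counts, empty file, bad naming
  short <- readLines(paths[2])[1:10]
  writeLines(short, paths[2])
  expect_error(read_library_files(paths), "row counts")
  writeLines(character(0), paths[2])
  expect_error(read_library_files(paths), "empty|parse")
  expect_error(read_library_files(file.path(dir, "garbage.txt")), "scheme")
  expect_error(read_library_files(paths[2]), "one file per")
  expect_error(read_library_files(character(0)), "no library files")
})

test_that("Z-matrix assembly counts atoms and variables correctly", {
  # bare cyclohexane: C6H12, three endocyclic variables, no rotamers
  tpl <- ring_template(6, "CH2")
  ring <- build_ring_geometry(tpl, canonical_state("4C1", 0.55, 6))
  zm <- attach_substituents(ring, tpl, list())
  expect_equal(nrow(zm$rows), 18)
  expect_equal(sum(zm$var_tags == "endocyclic"), 3)
  expect_equal(sum(zm$var_tags == "rotamer"), 0)

  # tetrahydrofuran + OH at position 2: exactly one rotamer torsion
  tpl5 <- ring_template(5, "O")
  ring5 <- build_ring_geometry(tpl5, canonical_state(enumerate_catalog(5)[1, ], 0.4))
  zm5 <- attach_substituents(ring5, tpl5, list(substituent(2, "OH", "up")))
  expect_equal(sum(zm5$var_tags == "rotamer"), 1)
  expect_equal(nrow(zm5$rows), 14) # C4H8O2

  # alpha-D-glucose: 24 atoms, 4 + 2 rotamer torsions
  spec <- spec_alpha_d_glucose()
  tpl6 <- spec$template
  ring6 <- build_ring_geometry(tpl6, canonical_state("4C1", 0.55, 6))
  zm6 <- attach_substituents(ring6, tpl6, spec$substituents)
  expect_equal(nrow(zm6$rows), 24) # C6H12O6
  expect_equal(sum(zm6$var_tags == "rotamer"), 6)
  # atom count conservation: ring + sum(group atoms) + filling hydrogens
  expect_equal(nrow(zm6$rows), 6 + 4 * 2 + 5 + 5)

  # NH ring: discrete flip variable; SO2 ring: two fixed exocyclic oxygens
  tplN <- ring_template(6, "NH")
  ringN <- build_ring_geometry(tplN, canonical_state("4C1", 0.55, 6))
  zmN <- attach_substituents(ringN, tplN, list())
  expect_true("HF1" %in% names(zmN$variables))
  expect_equal(unname(zmN$var_tags["HF1"]), "hetflip")
  tplS <- ring_template(6, "SO2")
  zmS <- attach_substituents(build_ring_geometry(tplS, canonical_state("4C1", 0.55, 6)),
                             tplS, list())
  expect_equal(sum(zmS$rows$element == "O" & zmS$rows$tag == "het"), 2)

  # errors: valence overflow, unknown group, substitution on O heteroatom
  subs3 <- list(substituent(2, "OH", "up"), substituent(2, "OH", "down"),
                substituent(2, "F", "up"))
  expect_error(attach_substituents(ring6, tpl6, subs3), "valence")
  expect_error(attach_substituents(ring6, tpl6, list(substituent(2, "XX", "up"))),
               "unknown")
  expect_error(attach_substituents(ring6, tpl6, list(substituent(6, "OH", "up"))),
               "heteroatom")
})

test_that("realized Cartesian structures honour the internal coordinates", {
  spec <- spec_alpha_d_glucose()
  tpl <- spec$template
  ring <- build_ring_geometry(tpl, canonical_state("4C1", 0.55, 6))
  zm <- attach_substituents(ring, tpl, spec$substituents)
  mol <- zmat_to_cartesian(zm)
  # ring bond lengths match the template
  rc <- mol$coords[1:6, ]
  bonds <- sqrt(rowSums((rc - rc[c(2:6, 1), ])^2))
  expect_equal(bonds, tpl$bond_lengths, tolerance = 5e-3)
  # endocyclic dihedrals match the variables
  D <- endocyclic_dihedrals(rc)
  expect_equal(unname(D), unname(zm$variables[c("D1", "D2", "D3")]),
               tolerance = 1e-3)
  # substituent orientations: requested up/down sides are realized
  plane <- puckermc:::cp_mean_plane(rc)
  sub_rows <- which(zm$rows$tag == "sub" & zm$rows$element == "O")[1:4]
  sides <- vapply(sub_rows, function(k) {
    j <- zm$rows$i1[k]
    s <- sum((mol$coords[k, ] - plane$center) * plane$normal) - plane$z[j]
    s > 0
  }, TRUE)
  want <- vapply(spec$substituents[1:4], function(s) s$orientation == "up", TRUE)
  expect_equal(sides, want)
})
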