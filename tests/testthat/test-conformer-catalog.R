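test_that("catalog sizes and family breakdowns are exact", {
  c5 <- enumerate_catalog(5)
  expect_equal(nrow(c5), 20)
  expect_equal(sum(c5$family == "E"), 10)
  expect_equal(sum(c5$family == "T"), 10)

  c6 <- enumerate_catalog(6)
  expect_equal(nrow(c6), 38)
  expect_equal(as.list(table(c6$family)),
               list(B = 6L, C = 2L, E = 12L, H = 12L, S = 6L))

  expect_error(enumerate_catalog(8), "5, 6 or 7")
})

test_that("names are unique and the chairs sit at the poles", {
  c6 <- enumerate_catalog(6)
  expect_false(anyDuplicated(c6$name) > 0)
  chairs <- c6[c6$family == "C", ]
  expect_setequal(chairs$theta, c(0, 180))
  expect_equal(chairs$name[chairs$theta == 0], "4C1")
  expect_equal(chairs$name[chairs$theta == 180], "1C4")
  # boats and skews on the equator, standard name set
  expect_true(all(c6$theta[c6$family %in% c("B", "S")] == 90))
  expect_setequal(c6$name[c6$family == "S"],
                  c("1S3", "3S1", "1S5", "5S1", "2SO", "OS2"))
  expect_setequal(c6$name[c6$family == "B"],
                  c("B1,4", "1,4B", "B2,5", "2,5B", "B3,O", "3,OB"))
  for (n in c(5, 7)) {
    expect_false(anyDuplicated(enumerate_catalog(n)$name) > 0)
  }
})

test_that("the seven-ring catalog has three planes at 0.6 / 0.0 / 0.4", {
  c7 <- enumerate_catalog(7)
  expect_equal(sort(unique(c7$q3rel)), c(0, 0.4, 0.6))
  expect_equal(as.integer(table(c7$q3rel)), c(28L, 28L, 28L))
  expect_setequal(unique(c7$family[c7$q3rel == 0.6]), c("C", "TC"))
  expect_setequal(unique(c7$family[c7$q3rel == 0]), c("B", "TB"))
  expect_setequal(unique(c7$family[c7$q3rel == 0.4]), c("S", "TS", "SB"))
})

test_that("classification is idempotent on every canonical state", {
  for (n in 5:7) {
    cat_n <- enumerate_catalog(n)
    for (i in seq_len(nrow(cat_n))) {
      st <- canonical_state(cat_n[i, ], 0.55)
      expect_identical(classify_state(st), cat_n$name[i])
    }
  }
})

test_that("classification is amplitude-invariant above the planar threshold", {
  set.seed(61)
  for (n in c(5, 6)) {
    cat_n <- enumerate_catalog(n)
    rows <- sample(nrow(cat_n), 8)
    for (i in rows) {
      labels <- vapply(c(0.1, 0.3, 0.6, 0.85), function(a) {
        classify_state(canonical_state(cat_n[i, ], a))
      }, "")
      expect_true(all(labels == cat_n$name[i]))
    }
  }
})

test_that("boat/twist-boat labels of seven-rings ignore phi3 (harp property)", {
  c7 <- enumerate_catalog(7)
  strings <- c7[c7$plane == "B/TB", ]
  for (i in c(1, 2, 9, 20)) {
    base <- strings[i, ]
    labels <- vapply(seq(0, 330, by = 30), function(p3) {
      st <- cp_pucker_state(7, q2 = 0.55, q3 = 0, phi2 = base$phi2, phi3 = p3)
      classify_state(st)
    }, "")
    expect_true(all(labels == base$name))
  }
})

test_that("near-planar states get the planar flag, everything else one label", {
  tiny <- cp_pucker_state(6, Q = 1e-9, theta = 90, phi2 = 10)
  expect_identical(classify_state(tiny, min_amplitude = 1e-3), "planar")
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:7, 1)
    lbl <- classify_state(random_state(n))
    expect_length(lbl, 1)
    expect_true(lbl %in% enumerate_catalog(n)$name)
  }
})

test_that("canonical_state errors on unknown labels and scales correctly", {
  expect_error(canonical_state("XYZ", 0.5), "unknown")
  st <- canonical_state("4C1", 0.55, n_atoms = 6)
  expect_equal(st$q[["q2"]], 0, tolerance = 1e-12)
  expect_equal(st$q[["q3"]], 0.55, tolerance = 1e-12)
  boat <- canonical_state("B1,4", 0.55, n_atoms = 6)
  expect_equal(boat$theta, 90)
})

test_that("catalog export writes a parseable table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 20 + 38 + 84)
  expect_true(all(c("name", "family", "phi2") %in% names(tab)))
})
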