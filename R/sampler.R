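## Monte Carlo conformer generation: pick a ring conformation uniformly from
## the dihedral library, draw one uniform torsion in [-180, 180] per rotamer
## and a discrete +-120 flip for an N-H/P-H heteroatom hydrogen, realize the
## Z-matrix, and flag steric overlap. Pure random generation -- there is no
## energy model and no Metropolis acceptance.

#' Sampler configuration
#'
#' @param n_conformers Number of conformers to generate (>= 1).
#' @param seed Integer seed, or `NULL` for an entropy-derived seed (recorded
#'   in the output so any run can be replayed).
#' @param clash_threshold Distance below which two non-bonded atoms count as
#'   clashing, Angstrom (default 0.7 -- catches coincident/overlapping atoms
#'   without rejecting strained but valid conformers).
#' @param clash_policy `"flag"` (default: emit everything, mark clashes),
#'   `"drop"` (resample until clash-free, up to 100 x n attempts) or `"keep"`
#'   (do not even test).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_conformers = 1L, seed = NULL,
                           clash_threshold = 0.7,
                           clash_policy = c("flag", "drop", "keep")) {
  stopifnot(.is_count(n_conformers), clash_threshold >= 0)
  if (!is.null(seed)) stopifnot(.is_count(abs(seed) + 1))
  structure(
    list(n_conformers = as.integer(n_conformers), seed = seed,
         clash_threshold = clash_threshold,
         clash_policy = match.arg(clash_policy)),
    class = "sampler_config"
  )
}

#' Draw one ring conformation from a dihedral library
#'
#' Selects a library entry uniformly at random (uniform over canonical
#' conformations, not over puckering phase space) using R's global random
#' number stream.
#'
#' @param library A `dihedral_library`.
#' @return A list with `label` and the named `D` vector.
#' @export
draw_conformer <- function(library) {
  if (!is.data.frame(library) || nrow(library) == 0) {
    stop("empty dihedral library", call. = FALSE)
  }
  i <- sample.int(nrow(library), 1L)
  dcols <- .lib_d_cols(library)
  list(label = library$label[i],
       D = setNames(as.numeric(library[i, dcols]), dcols))
}

#' Draw uniform rotamer torsions
#'
#' @param k Number of rotatable torsions (>= 0).
#' @return `k` independent uniform draws in \[-180, 180\] degrees.
#' @export
draw_rotamers <- function(k) {
  stopifnot(k >= 0)
  if (k == 0) return(numeric(0))
  runif(k, -180, 180)
}

#' Draw the heteroatom-hydrogen flip
#'
#' The equatorial/axial placement of an N-H or P-H ring hydrogen: -120 or
#' +120 degrees, each with probability one half.
#'
#' @param template The [ring_template()] (must have a flippable heteroatom).
#' @return -120 or 120.
#' @export
draw_het_flip <- function(template) {
  if (!isTRUE(template$het_flip)) {
    stop("heteroatom ", template$heteroatom,
         " has no H-flip degree of freedom", call. = FALSE)
  }
  sample(c(-120, 120), 1L)
}

#' Steric-overlap test
#'
#' `TRUE` when any atom pair not excluded as bonded (1-2) or geminal (1-3)
#' lies closer than the threshold.
#'
#' @param molecule A `molecule` from [zmat_to_cartesian()], or a coordinate
#'   matrix (then `bonds` must be given).
#' @param threshold Distance threshold in Angstrom.
#' @param bonds Two-column bond index matrix (taken from the molecule when
#'   omitted).
#' @return Logical scalar.
#' @export
clash_check <- function(molecule, threshold = 0.7, bonds = NULL) {
  if (inherits(molecule, "molecule")) {
    coords <- molecule$coords
    if (is.null(bonds)) bonds <- molecule$bonds
  } else {
    coords <- as.matrix(molecule)
  }
  if (threshold <= 0) return(FALSE)
  m <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  excl <- matrix(FALSE, m, m)
  if (!is.null(bonds)) {
    p13 <- .bonded_13_pairs(bonds, m)
    excl[p13] <- TRUE
    excl[p13[, c(2, 1)]] <- TRUE
  }
  close <- d < threshold & upper.tri(d) & !excl
  any(close)
}

#' Generate a batch of random conformers
#'
#' The full Monte Carlo workflow: for each requested conformer, draw a ring
#' conformation (N - 3 endocyclic dihedrals) uniformly from the library, one
#' uniform torsion in \[-180, 180\] degrees per rotamer, the discrete +-120
#' heteroatom-hydrogen flip where applicable, realize the Z-matrix in
#' Cartesian coordinates and test for steric overlap. Fully reproducible from
#' the seed.
#'
#' @param spec A [ring_spec()].
#' @param library Optional `dihedral_library` (built from the spec's template
#'   when omitted).
#' @param config A [sampler_config()]; alternatively pass `n_conformers` /
#'   `seed` / `clash_threshold` / `clash_policy` directly.
#' @param n_conformers,seed,clash_threshold,clash_policy Convenience
#'   arguments used when `config` is missing.
#' @return A `conformer_batch`: list with `manifest` (tibble: index, label,
#'   `D#`, `ROT#`, `het_flip`, `clash`), `molecules` (list of realized
#'   structures), `zmatrices`, `spec`, `seed`, `n_dropped`.
#' @export
#' @examples
#' batch <- generate_conformers(spec_hydroxy_thf(), n_conformers = 5, seed = 1)
#' tidy(batch)
generate_conformers <- function(spec, library = NULL, config = NULL,
                                n_conformers = 500L, seed = NULL,
                                clash_threshold = 0.7,
                                clash_policy = "flag") {
  stopifnot(inherits(spec, "ring_spec"))
  if (is.null(config)) {
    config <- sampler_config(n_conformers, seed, clash_threshold, clash_policy)
  }
  template <- spec$template
  if (is.null(library)) library <- build_dihedral_library(template)
  dcols <- .lib_d_cols(library)
  if (length(dcols) != template$n_atoms - 3L) {
    stop("library provides ", length(dcols), " dihedrals but the ring needs ",
         template$n_atoms - 3L, call. = FALSE)
  }

  ## preserve the caller's RNG state; seed the stream explicitly
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  seed <- config$seed
  if (is.null(seed)) {
    seed <- as.integer(Sys.time()) %% .Machine$integer.max
  }
  set.seed(seed)

  ## reference geometry: first library entry (or planar-free canonical state)
  ref_state <- canonical_state(enumerate_catalog(template$n_atoms)[1, ],
                               if (is.na(attr(library, "amplitude"))) 0.55
                               else attr(library, "amplitude"))
  ref_ring <- build_ring_geometry(template, ref_state)
  zm <- attach_substituents(ref_ring, template, spec$substituents)
  rot_vars <- names(zm$var_tags)[zm$var_tags == "rotamer"]
  has_flip <- "HF1" %in% names(zm$var_tags)

  one_draw <- function(idx) {
    pick <- draw_conformer(library)
    rots <- draw_rotamers(length(rot_vars))
    flip <- if (has_flip) draw_het_flip(template) else NA_real_
    vars <- c(pick$D, setNames(rots, rot_vars),
              if (has_flip) c(HF1 = flip))
    mol <- zmat_to_cartesian(zm, vars)
    clash <- if (config$clash_policy == "keep") FALSE else {
      clash_check(mol, config$clash_threshold)
    }
    list(index = idx, label = pick$label, vars = vars, rots = rots,
         flip = flip, clash = clash, mol = mol)
  }

  n <- config$n_conformers
  draws <- vector("list", n)
  n_dropped <- 0L
  attempts <- 0L
  i <- 1L
  while (i <= n) {
    attempts <- attempts + 1L
    if (config$clash_policy == "drop" && attempts > 100L * n) {
      stop("clash policy 'drop' exhausted ", 100L * n, " attempts", call. = FALSE)
    }
    d <- one_draw(i)
    if (config$clash_policy == "drop" && d$clash) {
      n_dropped <- n_dropped + 1L
      next
    }
    draws[[i]] <- d
    i <- i + 1L
  }

  manifest <- purrr::map_dfr(draws, function(d) {
    row <- tibble::as_tibble_row(c(
      list(index = d$index, label = d$label),
      as.list(d$vars[.lib_d_cols(library)]),
      as.list(setNames(d$rots, rot_vars))
    ))
    row$het_flip <- d$flip
    row$clash <- d$clash
    row
  })

  structure(
    list(manifest = manifest,
         molecules = purrr::map(draws, "mol"),
         zmatrix = zm,
         spec = spec,
         library = library,
         config = config,
         seed = seed,
         n_dropped = n_dropped),
    class = "conformer_batch"
  )
}

#' @export
print.conformer_batch <- function(x, ...) {
  cat("<conformer_batch> ", nrow(x$manifest), " conformers, seed ", x$seed,
      ", ", sum(x$manifest$clash), " flagged clashes\n", sep = "")
  invisible(x)
}

#' Tidy a conformer batch
#'
#' @param x A `conformer_batch`.
#' @param ... Unused.
#' @return The batch manifest: one row per conformer with its label,
#'   endocyclic dihedrals, rotamer torsions, heteroatom flip and clash flag.
#' @method tidy conformer_batch
#' @export
tidy.conformer_batch <- function(x, ...) x$manifest

#' One-row summary of a conformer batch
#'
#' @param x A `conformer_batch`.
#' @param ... Unused.
#' @return Tibble with the batch size, seed, number of distinct ring
#'   conformations sampled, clash count and drop count.
#' @method glance conformer_batch
#' @export
glance.conformer_batch <- function(x, ...) {
  tibble::tibble(
    n_conformers = nrow(x$manifest),
    seed = x$seed,
    n_labels = dplyr::n_distinct(x$manifest$label),
    n_clash = sum(x$manifest$clash),
    n_dropped = x$n_dropped,
    n_atoms = length(x$molecules[[1]]$elements)
  )
}
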