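## Ring templates and molecule specifications.

.het_info <- list(
  CH2 = list(element = "C", cx_bond = 1.54, n_h = 2L, flip = FALSE),
  O   = list(element = "O", cx_bond = 1.43, n_h = 0L, flip = FALSE),
  S   = list(element = "S", cx_bond = 1.82, n_h = 0L, flip = FALSE),
  SO2 = list(element = "S", cx_bond = 1.82, n_h = 0L, flip = FALSE),
  NH  = list(element = "N", cx_bond = 1.47, n_h = 1L, flip = TRUE),
  BH  = list(element = "B", cx_bond = 1.57, n_h = 1L, flip = FALSE),
  PH  = list(element = "P", cx_bond = 1.85, n_h = 1L, flip = TRUE)
)

#' Saturated-ring template
#'
#' Describes the covalent frame of a C(N-1)H(2N-2)X ring: size, heteroatom,
#' per-edge target bond lengths and per-vertex target angles. Default bond
#' lengths come from standard covalent-radius values (C-C 1.54, C-O 1.43,
#' C-S 1.82, C-N 1.47, C-B 1.57, C-P 1.85 Angstrom); edges touching the
#' heteroatom (position N) use the carbon-heteroatom length.
#'
#' @param n_atoms Ring size (5, 6 or 7).
#' @param heteroatom One of `"CH2"`, `"O"`, `"S"`, `"SO2"`, `"NH"`, `"BH"`,
#'   `"PH"`.
#' @param bond_lengths Optional numeric vector of N edge lengths (edge j joins
#'   ring atoms j and j+1, cyclically), Angstrom, each in \[1.3, 2.0\].
#' @param bond_angles Optional numeric vector of N target vertex angles,
#'   degrees, each in \[85, 135\]. These are informational targets used for
#'   idealized exocyclic placement; endocyclic angles of built rings follow
#'   from the closure construction.
#' @return An object of class `ring_template`.
#' @export
#' @examples
#' ring_template(6, "O")   # tetrahydropyran frame
ring_template <- function(n_atoms, heteroatom = "CH2",
                          bond_lengths = NULL, bond_angles = NULL) {
  stopifnot(n_atoms %in% 5:7)
  heteroatom <- match.arg(heteroatom, names(.het_info))
  info <- .het_info[[heteroatom]]
  n <- as.integer(n_atoms)
  if (is.null(bond_lengths)) {
    bond_lengths <- rep(1.54, n)
    bond_lengths[c(n - 1L, n)] <- info$cx_bond # edges (N-1,N) and (N,1)
  }
  if (is.null(bond_angles)) {
    bond_angles <- rep(switch(as.character(n), "5" = 105, "6" = 111, "7" = 115), n)
  }
  stopifnot(length(bond_lengths) == n, length(bond_angles) == n)
  if (any(bond_lengths < 1.3 | bond_lengths > 2.0)) {
    stop("bond lengths must lie in [1.3, 2.0] Angstrom", call. = FALSE)
  }
  if (any(bond_angles < 85 | bond_angles > 135)) {
    stop("bond angles must lie in [85, 135] degrees", call. = FALSE)
  }
  structure(
    list(
      n_atoms = n, heteroatom = heteroatom,
      bond_lengths = as.numeric(bond_lengths),
      bond_angles = as.numeric(bond_angles),
      het_element = info$element, het_hydrogens = info$n_h,
      het_flip = info$flip,
      ring_elements = c(rep("C", n - 1L), info$element)
    ),
    class = "ring_template"
  )
}

#' @export
print.ring_template <- function(x, ...) {
  cat("<ring_template> C", x$n_atoms - 1, "H..", x$heteroatom,
      " ring, bonds ", paste(unique(x$bond_lengths), collapse = "/"),
      " Angstrom\n", sep = "")
  invisible(x)
}

#' Substituent specification
#'
#' One exocyclic group on a ring position.
#'
#' @param position Ring position 1 ... N.
#' @param group Group identifier; built-in groups are `"H"`, `"F"`, `"OH"`,
#'   `"CH3"`, `"OCH3"`, `"CH2OH"`, `"NH2"`.
#' @param orientation `"up"` or `"down"` relative to the puckering mean plane
#'   of the reference conformation.
#' @param rotatable Should the group's torsions become random variables?
#'   Default `TRUE` (ignored for groups without torsions).
#' @return A list of class `substituent`.
#' @export
substituent <- function(position, group, orientation = c("up", "down"),
                        rotatable = TRUE) {
  stopifnot(.is_count(position))
  structure(
    list(position = as.integer(position), group = toupper(group),
         orientation = match.arg(orientation), rotatable = isTRUE(rotatable)),
    class = "substituent"
  )
}

#' Molecule specification for conformer generation
#'
#' Bundles the ring template and substituent list that define one
#' multifunctionalized ring molecule (always built neutral, singlet).
#'
#' @param n_atoms Ring size.
#' @param heteroatom Ring heteroatom, see [ring_template()].
#' @param substituents List of [substituent()] objects (possibly empty).
#' @param template Optional pre-built [ring_template()] overriding
#'   `n_atoms`/`heteroatom`.
#' @return An object of class `ring_spec`.
#' @export
#' @examples
#' ## 2-hydroxy-tetrahydrofuran
#' ring_spec(5, "O", list(substituent(2, "OH", "up")))
ring_spec <- function(n_atoms, heteroatom = "CH2", substituents = list(),
                      template = NULL) {
  if (is.null(template)) template <- ring_template(n_atoms, heteroatom)
  stopifnot(inherits(template, "ring_template"))
  substituents <- lapply(substituents, function(s) {
    if (!inherits(s, "substituent")) stop("substituents must be substituent() objects",
                                          call. = FALSE)
    if (s$position > template$n_atoms) {
      stop("substituent position ", s$position, " outside ring of size ",
           template$n_atoms, call. = FALSE)
    }
    s
  })
  structure(
    list(template = template, substituents = substituents,
         charge = 0L, multiplicity = 1L),
    class = "ring_spec"
  )
}

#' Built-in example molecule specifications
#'
#' `spec_hydroxy_thf()` is 2-hydroxy-tetrahydrofuran (one hydroxyl rotamer);
#' `spec_alpha_d_glucose()` is alpha-D-glucose (four hydroxyls and one
#' hydroxymethyl, six rotamer torsions in total).
#'
#' @return A [ring_spec()].
#' @export
spec_hydroxy_thf <- function() {
  ring_spec(5, "O", list(substituent(2, "OH", "up")))
}

#' @rdname spec_hydroxy_thf
#' @export
spec_alpha_d_glucose <- function() {
  ring_spec(6, "O", list(
    substituent(1, "OH", "down"),
    substituent(2, "OH", "down"),
    substituent(3, "OH", "up"),
    substituent(4, "OH", "down"),
    substituent(5, "CH2OH", "up")
  ))
}

## --- exocyclic group parameter tables (*.var files) -----------------------

## Grammar of a group .var file (key = value lines):
##   natoms = <k>
##   atom<i>.element = <symbol>
##   atom<i>.parent  = <earlier group atom index>   (omitted for atom1)
##   atom<i>.dist    = <Angstrom>
##   atom<i>.angle   = <degrees>
##   atom<i>.torsion = rot | +<offset> | <number>   (atom1 has no torsion:
##                                                   it occupies the ring slot)
## "rot" opens a new rotamer torsion; "+<offset>" rides on the latest rotamer
## at a fixed offset; a bare number is a fixed dihedral.

.parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed line in ", basename(path), ": '", lines[bad][1L], "'",
         call. = FALSE)
  }
  setNames(trimws(vapply(kv, `[`, "", 2L)), trimws(vapply(kv, `[`, "", 1L)))
}

#' Read an exocyclic group parameter file
#'
#' Parses one of the plain-text `*.var` group tables (idealized bond lengths,
#' angles and torsion rules for an exocyclic group).
#'
#' @param path Path to a `.var` file.
#' @return A list with the group name and a per-atom parameter tibble.
#' @export
read_group_var <- function(path) {
  kv <- .parse_kv_file(path)
  k <- as.integer(kv[["natoms"]])
  if (is.na(k) || k < 1) stop("invalid natoms in ", basename(path), call. = FALSE)
  get <- function(i, field, default = NA_character_) {
    key <- sprintf("atom%d.%s", i, field)
    if (key %in% names(kv)) kv[[key]] else default
  }
  atoms <- purrr::map_dfr(seq_len(k), function(i) {
    tibble::tibble(
      element = get(i, "element"),
      parent = as.integer(get(i, "parent", "0")),
      dist = as.numeric(get(i, "dist")),
      angle = as.numeric(get(i, "angle")),
      torsion = get(i, "torsion")
    )
  })
  if (anyNA(atoms$dist) || anyNA(atoms$angle) || anyNA(atoms$element)) {
    stop("incomplete atom records in ", basename(path), call. = FALSE)
  }
  list(group = toupper(sub("\\.var$", "", basename(path))), atoms = atoms)
}

.group_cache <- new.env(parent = emptyenv())

.group_params <- function(group) {
  group <- toupper(group)
  if (is.null(.group_cache[[group]])) {
    path <- system.file("extdata", "var", paste0(group, ".var"),
                        package = "puckermc")
    if (!nzchar(path)) {
      stop("unknown substituent group: ", group, call. = FALSE)
    }
    .group_cache[[group]] <- read_group_var(path)
  }
  .group_cache[[group]]
}

#' Supported substituent groups
#'
#' @return Character vector of group identifiers with shipped `.var` tables.
#' @export
supported_groups <- function() {
  files <- list.files(system.file("extdata", "var", package = "puckermc"),
                      pattern = "\\.var$")
  toupper(sub("\\.var$", "", files))
}
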