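## Endocyclic dihedral libraries: one D1...D(N-3) array per canonical ring
## conformation of a given ring template. Libraries are derived here from
## idealized geometry (canonical puckering states realized through
## build_ring_geometry); externally produced libraries in the N-x-H-y-X-D#.txt
## per-dihedral text layout can be imported with read_library_files.

#' Build a dihedral library from a conformer catalog
#'
#' For every canonical conformer of the catalog, builds the idealized ring
#' geometry at the requested amplitude and records its N - 3 endocyclic
#' dihedrals. The library is complete (one entry per catalog label) and
#' deterministic.
#'
#' @param template A [ring_template()].
#' @param catalog Catalog tibble from [enumerate_catalog()] for the same ring
#'   size (default: the full catalog).
#' @param amplitude Total puckering amplitude in Angstrom; defaults to a
#'   ring-size-typical value (0.40 / 0.55 / 0.75 for N = 5 / 6 / 7).
#' @return A `dihedral_library`: a tibble with columns `label`, `family` and
#'   `D1` ... `D(N-3)`, carrying the template key as attributes.
#' @export
#' @examples
#' lib <- build_dihedral_library(ring_template(5, "O"))
#' nrow(lib)  # 20
build_dihedral_library <- function(template, catalog = NULL, amplitude = NULL) {
  stopifnot(inherits(template, "ring_template"))
  n <- template$n_atoms
  if (is.null(catalog)) catalog <- enumerate_catalog(n)
  if (!all(catalog$n_atoms == n)) {
    stop("catalog ring size does not match the template", call. = FALSE)
  }
  if (is.null(amplitude)) {
    amplitude <- switch(as.character(n), "5" = 0.40, "6" = 0.55, "7" = 0.75)
  }
  entries <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    ring <- tryCatch(
      build_ring_geometry(template, canonical_state(row, amplitude)),
      error = function(e) {
        stop("library construction failed for conformer ", row$name, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    tibble::as_tibble_row(c(
      list(label = row$name, family = row$family),
      as.list(endocyclic_dihedrals(ring))
    ))
  })
  structure(entries,
            class = c("dihedral_library", class(entries)),
            template_key = list(n_atoms = n, heteroatom = template$heteroatom,
                                het_hydrogens = template$het_hydrogens),
            amplitude = amplitude)
}

.lib_d_cols <- function(library) grep("^D[0-9]+$", names(library), value = TRUE)

#' Read a dihedral library from per-dihedral text files
#'
#' Imports libraries stored in the `N-x-H-y[-X]-D#.txt` layout: one
#' whitespace-delimited file per endocyclic dihedral index, each row one scan
#' grid point, the last column the dihedral value and any leading columns the
#' scan coordinates. Row counts (and scan coordinates, where present) must
#' agree across files.
#'
#' @param paths Character vector of file paths, one per `D#` index (the index
#'   is taken from the `-D<k>` token of each file name).
#' @return A `dihedral_library` tibble with columns `label` (the scan
#'   coordinates, or the row number when absent) and `D1` ... `Dk`.
#' @export
read_library_files <- function(paths) {
  if (length(paths) == 0) stop("no library files given", call. = FALSE)
  idx <- suppressWarnings(as.integer(sub(".*-D([0-9]+)\\.txt$", "\\1",
                                         basename(paths))))
  if (anyNA(idx)) {
    stop("file names must follow the N-x-H-y-X-D#.txt scheme; offending: ",
         basename(paths)[which(is.na(idx))[1L]], call. = FALSE)
  }
  if (!setequal(idx, seq_len(max(idx))) || anyDuplicated(idx)) {
    stop("library needs one file per dihedral index 1..",
         max(idx), "; got D", paste(sort(idx), collapse = ", D"), call. = FALSE)
  }
  tabs <- lapply(paths, function(p) {
    tab <- tryCatch(utils::read.table(p, header = FALSE),
                    error = function(e) stop("cannot parse ", basename(p), ": ",
                                             conditionMessage(e), call. = FALSE))
    if (nrow(tab) == 0) stop("empty library file: ", basename(p), call. = FALSE)
    if (!all(vapply(tab, is.numeric, TRUE))) {
      stop("non-numeric content in ", basename(p), call. = FALSE)
    }
    tab
  })
  nr <- vapply(tabs, nrow, 1L)
  if (length(unique(nr)) != 1) {
    stop("inconsistent row counts across library files: ",
         paste(nr, collapse = ", "), call. = FALSE)
  }
  ord <- order(idx)
  tabs <- tabs[ord]
  first <- tabs[[1L]]
  label <- if (ncol(first) > 1) {
    apply(first[, -ncol(first), drop = FALSE], 1, paste, collapse = "/")
  } else {
    as.character(seq_len(nrow(first)))
  }
  out <- tibble::tibble(label = label, family = NA_character_)
  for (k in seq_along(tabs)) {
    out[[paste0("D", k)]] <- tabs[[k]][[ncol(tabs[[k]])]]
  }
  structure(out, class = c("dihedral_library", class(out)),
            template_key = NULL, amplitude = NA_real_)
}

#' Write a dihedral library in the per-dihedral text layout
#'
#' Companion of [read_library_files()]: emits one `<stem>-D<k>.txt` file per
#' dihedral column (row number as the scan coordinate, then the dihedral).
#'
#' @param library A `dihedral_library`.
#' @param dir Output directory.
#' @param stem File-name stem, e.g. `"N-5-H-0"`.
#' @return The written paths, invisibly.
#' @export
write_library_files <- function(library, dir, stem) {
  dcols <- .lib_d_cols(library)
  paths <- file.path(dir, sprintf("%s-D%d.txt", stem, seq_along(dcols)))
  for (k in seq_along(dcols)) {
    utils::write.table(
      data.frame(seq_len(nrow(library)), sprintf("%.4f", library[[dcols[k]]])),
      paths[k], row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(paths)
}
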