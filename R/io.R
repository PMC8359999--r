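## Structure writers and workflow I/O. All writers are deterministic (fixed
## formatting) so identical inputs give byte-identical files.

.mol_coords <- function(molecule) {
  if (inherits(molecule, "molecule")) {
    list(coords = molecule$coords, elements = molecule$elements)
  } else if (inherits(molecule, "ring_atom_set")) {
    list(coords = molecule$coords, elements = molecule$labels)
  } else {
    stop("expected a molecule or ring_atom_set", call. = FALSE)
  }
}

## unique PDB-style atom names: element + per-element counter (C1, O1, H1...)
.atom_names <- function(elements) {
  counts <- integer(0)
  vapply(elements, function(el) {
    counts[el] <<- if (is.na(counts[el])) 1L else counts[el] + 1L
    paste0(el, counts[el])
  }, "", USE.NAMES = FALSE)
}

#' Write a Gaussian Z-matrix input file
#'
#' Emits the standard layout: route line, title, `0 1` charge/multiplicity
#' (all molecules are built neutral singlets), symbolic Z-matrix rows, then a
#' `Variables:` block giving every internal coordinate its value. Distances
#' are `B#`, angles `A#`; dihedrals keep their sampling names (`D#`, `ROT#`,
#' `HF1`) where they are free variables and are materialized as `DH#`
#' otherwise.
#'
#' @param zmatrix A [attach_substituents()] Z-matrix.
#' @param path Output path.
#' @param route Gaussian route line.
#' @param title Title line.
#' @param variables Optional variable overrides (as in [zmat_to_cartesian()]).
#' @return `path`, invisibly.
#' @export
write_gjf <- function(zmatrix, path, route = "#P B972/def2SVP Opt",
                      title = "ring conformer", variables = NULL) {
  stopifnot(inherits(zmatrix, "zmatrix"))
  vars <- zmatrix$variables
  if (!is.null(variables)) vars[names(variables)] <- variables
  rows <- zmatrix$rows
  lines <- c(route, "", title, "",
             sprintf("%d %d", zmatrix$charge, zmatrix$multiplicity))
  val_block <- character()
  add_val <- function(name, value) {
    val_block <<- c(val_block, sprintf("  %s=%.6f", name, value))
  }
  ndh <- 0L
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    if (k == 1L) {
      lines <- c(lines, r$element)
    } else if (is.na(r$i2)) {
      bn <- sprintf("B%d", k)
      add_val(bn, r$dist)
      lines <- c(lines, sprintf("%s %d %s", r$element, r$i1, bn))
    } else if (is.na(r$i3)) {
      bn <- sprintf("B%d", k); an <- sprintf("A%d", k)
      add_val(bn, r$dist); add_val(an, r$angle)
      lines <- c(lines, sprintf("%s %d %s %d %s", r$element, r$i1, bn, r$i2, an))
    } else {
      bn <- sprintf("B%d", k); an <- sprintf("A%d", k)
      add_val(bn, r$dist); add_val(an, r$angle)
      if (!is.na(r$dih_var) && r$dih == 0) {
        dn <- r$dih_var
        add_val(dn, .wrap180(vars[[dn]]))
      } else {
        ndh <- ndh + 1L
        dn <- sprintf("DH%d", ndh)
        dval <- if (!is.na(r$dih_var)) vars[[r$dih_var]] + r$dih else r$dih
        add_val(dn, .wrap180(dval))
      }
      lines <- c(lines, sprintf("%s %d %s %d %s %d %s",
                                r$element, r$i1, bn, r$i2, an, r$i3, dn))
    }
  }
  lines <- c(lines, "", "Variables:", unique(val_block), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a Gaussian Z-matrix input written by [write_gjf()]
#'
#' @param path File path.
#' @return A `zmatrix` object (rows + variables; no bond/tag metadata).
#' @export
read_gjf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cm <- grep("^-?[0-9]+ +[0-9]+$", lines)[1L]
  if (is.na(cm)) stop("no charge/multiplicity line found in ", path, call. = FALSE)
  body_end <- cm + 1L
  while (body_end <= length(lines) && nzchar(trimws(lines[body_end]))) {
    body_end <- body_end + 1L
  }
  body <- lines[(cm + 1L):(body_end - 1L)]
  vstart <- grep("^\\s*Variables:", lines)[1L]
  vars <- numeric()
  if (!is.na(vstart)) {
    for (ln in lines[(vstart + 1L):length(lines)]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      vars[trimws(kv[1L])] <- as.numeric(kv[2L])
    }
  }
  val <- function(tok) if (tok %in% names(vars)) vars[[tok]] else as.numeric(tok)
  rows <- purrr::map_dfr(seq_along(body), function(k) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1L]]
    tibble::tibble(
      element = f[1L],
      i1 = if (length(f) >= 3) as.integer(f[2L]) else NA_integer_,
      i2 = if (length(f) >= 5) as.integer(f[4L]) else NA_integer_,
      i3 = if (length(f) >= 7) as.integer(f[6L]) else NA_integer_,
      dist = if (length(f) >= 3) val(f[3L]) else NA_real_,
      angle = if (length(f) >= 5) val(f[5L]) else NA_real_,
      dih = if (length(f) >= 7) val(f[7L]) else NA_real_,
      dih_var = NA_character_,
      tag = "parsed"
    )
  })
  structure(list(rows = rows, variables = vars, var_tags = character(),
                 bonds = NULL, n_ring = NA_integer_, charge = 0L,
                 multiplicity = 1L),
            class = "zmatrix")
}

#' Write / read XYZ coordinate files
#'
#' Standard XYZ: atom count, comment, one `element x y z` line per atom
#' (Angstrom, six decimals).
#'
#' @param molecule A `molecule` or [ring_atom_set()].
#' @param path File path.
#' @param comment Comment line.
#' @return `path` (writer) or a `molecule` (reader).
#' @export
write_xyz <- function(molecule, path, comment = "") {
  m <- .mol_coords(molecule)
  if (length(m$elements) == 0) stop("empty structure", call. = FALSE)
  lines <- c(
    sprintf("%d", length(m$elements)),
    comment,
    sprintf("%-2s %12.6f %12.6f %12.6f", m$elements,
            m$coords[, 1], m$coords[, 2], m$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 2L) stop("malformed XYZ file: ", path,
                                               call. = FALSE)
  f <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  structure(
    list(
      coords = do.call(rbind, lapply(f, function(x) as.numeric(x[2:4]))),
      elements = vapply(f, `[`, "", 1L),
      bonds = NULL, variables = NULL, n_ring = NA_integer_
    ),
    class = "molecule"
  )
}

#' Write a PDB file
#'
#' HETATM records with serial numbers, atom names unique within the residue
#' (element plus per-element counter), occupancy 1.00 and the element column
#' set, terminated by `END`.
#'
#' @param molecule A `molecule` or [ring_atom_set()].
#' @param path File path.
#' @param resname Residue name, default `"LIG"`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(molecule, path, resname = "LIG") {
  m <- .mol_coords(molecule)
  if (length(m$elements) == 0) stop("empty structure", call. = FALSE)
  names <- .atom_names(m$elements)
  recs <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_along(m$elements), names, resname, "A", 1L,
    m$coords[, 1], m$coords[, 2], m$coords[, 3], 1.00, 0.00,
    toupper(m$elements)
  )
  writeLines(c(recs, "END"), path)
  invisible(path)
}

## --- input.dat ------------------------------------------------------------

#' Parse a run-configuration (`input.dat`) file
#'
#' Key = value grammar, one setting per line, `#` comments allowed:
#' ```
#' ring        = 6
#' heteroatom  = O
#' substituent = 2:OH:up          # position:group:orientation[:fixed]
#' calc        = 500
#' seed        = 42
#' format      = xyz              # gjf | pdb | xyz
#' outdir      = conformers
#' receptor_family = MANNO
#' ```
#' `ring` and `heteroatom` are required; `substituent` may repeat. Unknown
#' keys produce a warning with the line number; malformed values an error.
#'
#' @param path File path.
#' @return A `run_config` list: `spec` ([ring_spec()]), `n_conformers`,
#'   `seed`, `format`, `outdir`, `receptor_family`, `clash_policy`.
#' @export
parse_input_dat <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  known <- c("ring", "heteroatom", "substituent", "calc", "seed", "format",
             "outdir", "receptor_family", "clash_policy", "clash_threshold")
  vals <- list(substituent = list())
  for (ln in seq_along(raw)) {
    line <- trimws(sub("#.*$", "", raw[ln]))
    if (!nzchar(line)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop("line ", ln, ": expected 'key = value', got '", line, "'",
           call. = FALSE)
    }
    key <- trimws(kv[1L])
    value <- trimws(kv[2L])
    if (!key %in% known) {
      warning("line ", ln, ": unknown key '", key, "' ignored", call. = FALSE)
      next
    }
    if (key == "substituent") {
      tok <- strsplit(value, ":", fixed = TRUE)[[1L]]
      if (length(tok) < 3L || is.na(suppressWarnings(as.integer(tok[1L])))) {
        stop("line ", ln, ": malformed substituent token '", value,
             "' (want position:group:orientation)", call. = FALSE)
      }
      vals$substituent <- c(vals$substituent, list(substituent(
        as.integer(tok[1L]), tok[2L], tok[3L],
        rotatable = !(length(tok) >= 4L && tok[4L] == "fixed")
      )))
    } else {
      vals[[key]] <- value
    }
  }
  for (req in c("ring", "heteroatom")) {
    if (is.null(vals[[req]])) {
      stop("missing required key '", req, "' in ", path, call. = FALSE)
    }
  }
  fmt <- tolower(vals$format %||% "xyz")
  if (!fmt %in% c("gjf", "pdb", "xyz")) {
    stop("format must be one of gjf, pdb, xyz; got '", fmt, "'", call. = FALSE)
  }
  structure(
    list(
      spec = ring_spec(as.integer(vals$ring), vals$heteroatom, vals$substituent),
      n_conformers = as.integer(vals$calc %||% 1L),
      seed = if (is.null(vals$seed)) NULL else as.integer(vals$seed),
      format = fmt,
      outdir = vals$outdir %||% ".",
      receptor_family = vals$receptor_family,
      clash_policy = vals$clash_policy %||% "flag",
      clash_threshold = as.numeric(vals$clash_threshold %||% 0.7)
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- batch output ----------------------------------------------------------

#' Write all structures of a conformer batch
#'
#' One structure file per conformer (`conf_0001.<ext>` ...), the delimited
#' batch manifest (`manifest.tsv`) and a short run log recording the seed,
#' library source, counts and clash statistics.
#'
#' @param batch A `conformer_batch`.
#' @param dir Output directory (created if needed).
#' @param format `"xyz"`, `"pdb"` or `"gjf"`.
#' @param prefix File-name prefix, default `"conf"`.
#' @return Character vector of written structure paths, invisibly.
#' @export
write_batch <- function(batch, dir, format = c("xyz", "pdb", "gjf"),
                        prefix = "conf") {
  stopifnot(inherits(batch, "conformer_batch"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(batch$manifest)
  paths <- file.path(dir, sprintf("%s_%04d.%s", prefix, seq_len(n), format))
  for (i in seq_len(n)) {
    mol <- batch$molecules[[i]]
    cmt <- sprintf("conformer %d label %s seed %d", i,
                   batch$manifest$label[i], batch$seed)
    switch(format,
      xyz = write_xyz(mol, paths[i], cmt),
      pdb = write_pdb(mol, paths[i]),
      gjf = {
        vars <- mol$variables
        write_gjf(batch$zmatrix, paths[i], title = cmt, variables = vars)
      }
    )
  }
  man <- batch$manifest
  man$seed <- batch$seed
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- glance.conformer_batch(batch)
  writeLines(c(
    sprintf("seed: %d", batch$seed),
    sprintf("library: %d entries (%s)", nrow(batch$library),
            if (is.null(attr(batch$library, "template_key"))) "imported"
            else "idealized geometry"),
    sprintf("conformers written: %d", g$n_conformers),
    sprintf("clashes flagged: %d", g$n_clash),
    sprintf("dropped: %d", g$n_dropped)
  ), file.path(dir, "run.log"))
  invisible(paths)
}

## --- docking preparation ---------------------------------------------------

#' Read a receptor folder tree
#'
#' Expects `root/<FAMILY>/<receptor_id>/` directories each holding a prepared
#' receptor structure (`*.pdbqt`) and a `box.txt` with the docking box
#' (`center_x/y/z`, `size_x/y/z` key = value lines).
#'
#' @param root Receptor tree root.
#' @param family Optional family name (e.g. `"MANNO"`); all families when
#'   omitted.
#' @return Tibble with columns `family`, `receptor_id`, `receptor_file`,
#'   `center_x/y/z`, `size_x/y/z`.
#' @export
read_receptor_folder <- function(root, family = NULL) {
  if (!dir.exists(root)) {
    stop("receptor folder not found: ", root,
         " (docking needs a receptor and the coordinates of the box)",
         call. = FALSE)
  }
  fams <- if (is.null(family)) list.dirs(root, recursive = FALSE) else {
    fp <- file.path(root, family)
    if (!dir.exists(fp)) {
      stop("receptor family folder not found: ", fp,
           " (docking needs a receptor and the coordinates of the box)",
           call. = FALSE)
    }
    fp
  }
  purrr::map_dfr(fams, function(fdir) {
    purrr::map_dfr(list.dirs(fdir, recursive = FALSE), function(rdir) {
      box_path <- file.path(rdir, "box.txt")
      if (!file.exists(box_path)) {
        stop("missing box.txt in ", rdir, call. = FALSE)
      }
      kv <- .parse_kv_file(box_path)
      rec <- list.files(rdir, pattern = "\\.pdbqt$", full.names = TRUE)
      if (length(rec) == 0) stop("no receptor .pdbqt in ", rdir, call. = FALSE)
      sizes <- as.numeric(kv[c("size_x", "size_y", "size_z")])
      if (any(!is.finite(sizes)) || any(sizes <= 0)) {
        stop("box sizes must be positive in ", box_path, call. = FALSE)
      }
      tibble::tibble(
        family = basename(fdir), receptor_id = basename(rdir),
        receptor_file = rec[1L],
        center_x = as.numeric(kv[["center_x"]]),
        center_y = as.numeric(kv[["center_y"]]),
        center_z = as.numeric(kv[["center_z"]]),
        size_x = sizes[1L], size_y = sizes[2L], size_z = sizes[3L]
      )
    })
  })
}

#' Emit serial docking jobs for a batch of ligands
#'
#' For every (ligand, receptor) pair writes an AutoDock-Vina-style
#' configuration file (receptor, ligand, box centre and size, exhaustiveness)
#' and appends one `vina` command to a serial job manifest `jobs.txt`
#' (exactly one line per pair). The ligand-preparation commands
#' (`prepare_ligand`) go to the companion `prepare.txt`, one per ligand.
#' Nothing is executed.
#'
#' @param ligand_paths Character vector of ligand structure files.
#' @param receptors Receptor tibble from [read_receptor_folder()] (or of the
#'   same shape).
#' @param outdir Output directory for config files and manifests.
#' @param exhaustiveness Vina exhaustiveness, default 8.
#' @return Invisibly, a list with `manifest` (path of jobs.txt), `prep` and
#'   `configs` (paths of the per-pair config files).
#' @export
write_vina_jobs <- function(ligand_paths, receptors, outdir,
                            exhaustiveness = 8) {
  if (length(ligand_paths) == 0) stop("no ligand structures given", call. = FALSE)
  if (!is.data.frame(receptors) || nrow(receptors) == 0) {
    stop("empty receptor list", call. = FALSE)
  }
  need <- c("receptor_id", "receptor_file", "center_x", "center_y", "center_z",
            "size_x", "size_y", "size_z")
  if (!all(need %in% names(receptors))) {
    stop("receptor table lacks columns: ",
         paste(setdiff(need, names(receptors)), collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  configs <- character(0)
  jobs <- character(0)
  lig_stem <- sub("\\.[^.]+$", "", basename(ligand_paths))
  for (li in seq_along(ligand_paths)) {
    for (ri in seq_len(nrow(receptors))) {
      r <- receptors[ri, ]
      cfg <- file.path(outdir, sprintf("conf_%s_%s.txt", lig_stem[li],
                                       r$receptor_id))
      writeLines(c(
        sprintf("receptor = %s", r$receptor_file),
        sprintf("ligand = %s.pdbqt", lig_stem[li]),
        sprintf("center_x = %.3f", r$center_x),
        sprintf("center_y = %.3f", r$center_y),
        sprintf("center_z = %.3f", r$center_z),
        sprintf("size_x = %.3f", r$size_x),
        sprintf("size_y = %.3f", r$size_y),
        sprintf("size_z = %.3f", r$size_z),
        sprintf("exhaustiveness = %d", as.integer(exhaustiveness))
      ), cfg)
      configs <- c(configs, cfg)
      jobs <- c(jobs, sprintf("vina --config %s --out %s_%s_out.pdbqt",
                              cfg, lig_stem[li], r$receptor_id))
    }
  }
  manifest <- file.path(outdir, "jobs.txt")
  writeLines(jobs, manifest)
  prep <- file.path(outdir, "prepare.txt")
  writeLines(sprintf("prepare_ligand4.py -l %s -o %s.pdbqt",
                     ligand_paths, lig_stem), prep)
  invisible(list(manifest = manifest, prep = prep, configs = configs))
}
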