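## Z-matrix assembly: ring internal coordinates, exocyclic slot geometry,
## substituent groups, heteroatom hydrogens, filling hydrogens.
##
## Row k of a zmatrix places one atom by a distance to i1, an angle (k,i1,i2)
## and a dihedral (k,i1,i2,i3). Dihedrals may ride on a named variable:
## realized dihedral = variables[[dih_var]] + dih (dih alone when dih_var is
## NA). Exactly N-3 variables are tagged "endocyclic", one per rotatable
## exocyclic torsion is tagged "rotamer", and the N-H/P-H placement uses one
## discrete "hetflip" variable whose value is +120 or -120.

## anchor chain used for exocyclic atoms at ring position j
.ring_anchors <- function(j, n) {
  if (j == 1L) c(1L, 2L, 3L)
  else if (j == 2L) c(2L, 1L, n)
  else c(j, j - 1L, j - 2L)
}

.other_neighbour <- function(j, n) {
  if (j == 1L) n else if (j == n) 1L else j + 1L
}

#' Assemble the Z-matrix of a multifunctionalized ring molecule
#'
#' Takes a reference ring geometry, its template and a substituent list and
#' returns the internal-coordinate description of the full (neutral, singlet)
#' molecule: ring atoms 1 ... N first, then heteroatom hydrogens (or the two
#' sulfone oxygens), then substituents in position order, then the hydrogens
#' filling the remaining valences. The N - 3 endocyclic dihedrals are named
#' variables `D1` ... `D(N-3)`; every rotatable exocyclic torsion gets a
#' `ROT#` variable; an N-H/P-H heteroatom hydrogen gets the discrete `HF1`
#' variable (+120/-120 relative to the ring-neighbour torsion, i.e. the
#' equatorial/axial choice).
#'
#' Substituent positions carry at most the free valences of the ring atom
#' (two per carbon; substitution at the heteroatom position is only possible
#' for the CH2 "heteroatom"). The `"up"`/`"down"` orientation refers to the
#' puckering mean plane of the supplied reference conformation.
#'
#' @param ring Reference [ring_atom_set()] (e.g. built from a canonical
#'   conformer with [build_ring_geometry()]).
#' @param template The matching [ring_template()].
#' @param subs List of [substituent()] specifications.
#' @return An object of class `zmatrix`; see [zmat_to_cartesian()].
#' @export
#' @examples
#' tpl <- ring_template(6, "CH2")
#' ring <- build_ring_geometry(tpl, canonical_state("4C1", 0.55, 6))
#' zm <- attach_substituents(ring, tpl, list())
#' nrow(zm$rows)  # 18 atoms: cyclohexane
attach_substituents <- function(ring, template, subs = list()) {
  stopifnot(inherits(ring, "ring_atom_set"), inherits(template, "ring_template"))
  n <- template$n_atoms
  if (ring$n_atoms != n) stop("ring/template size mismatch", call. = FALSE)
  coords <- ring$coords
  plane <- cp_mean_plane(coords)

  rows <- list()
  vars <- numeric()
  var_tags <- character()
  add_row <- function(element, i1 = NA, i2 = NA, i3 = NA, dist = NA,
                      angle = NA, dih = NA, dih_var = NA_character_, tag) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      element = element, i1 = as.integer(i1), i2 = as.integer(i2),
      i3 = as.integer(i3), dist = dist, angle = angle, dih = dih,
      dih_var = dih_var, tag = tag
    )
    length(rows)
  }

  ## --- ring atoms ---------------------------------------------------------
  D <- endocyclic_dihedrals(ring)
  for (j in seq_len(n)) {
    el <- template$ring_elements[j]
    if (j == 1L) {
      add_row(el, tag = "ring")
    } else if (j == 2L) {
      add_row(el, i1 = 1L, dist = .dist3(coords[2, ], coords[1, ]), tag = "ring")
    } else if (j == 3L) {
      add_row(el, i1 = 2L, i2 = 1L, dist = .dist3(coords[3, ], coords[2, ]),
              angle = .angle3(coords[3, ], coords[2, ], coords[1, ]), tag = "ring")
    } else {
      dk <- paste0("D", j - 3L)
      vars[dk] <- unname(D[dk])
      var_tags[dk] <- "endocyclic"
      add_row(el, i1 = j - 1L, i2 = j - 2L, i3 = j - 3L,
              dist = .dist3(coords[j, ], coords[j - 1L, ]),
              angle = .angle3(coords[j, ], coords[j - 1L, ], coords[j - 2L, ]),
              dih = 0, dih_var = dk, tag = "ring")
    }
  }

  ## --- exocyclic slot geometry --------------------------------------------
  ## each ring position offers up to two tetrahedral slots at +-120 degrees
  ## from the other ring neighbour about the (j, j-1) bond
  slot_info <- vector("list", n)
  for (j in seq_len(n)) {
    anc <- .ring_anchors(j, n)
    nbr <- .other_neighbour(j, n)
    delta <- dihedral_angle(coords[nbr, ], coords[anc[1], ],
                            coords[anc[2], ], coords[anc[3], ])
    slot <- purrr::map_dfr(c(120, -120), function(off) {
      trial <- .nerf_place(coords[anc[3], ], coords[anc[2], ], coords[anc[1], ],
                           1.0, 109.47, .wrap180(delta + off))
      side <- sum((trial - plane$center) * plane$normal) - plane$z[j]
      tibble::tibble(dih = .wrap180(delta + off),
                     orientation = if (side > 0) "up" else "down")
    })
    slot$taken <- FALSE
    slot_info[[j]] <- list(anchors = anc, delta = delta, slots = slot)
  }

  n_slots <- rep(2L, n)
  het <- template$heteroatom
  n_slots[n] <- switch(het, CH2 = 2L, SO2 = 2L, NH = 1L, PH = 1L, BH = 1L, 0L)

  ## --- slot allocation -----------------------------------------------------
  subs <- subs[order(vapply(subs, `[[`, 1L, "position"))]
  claims <- vector("list", length(subs))
  used <- integer(n)
  for (k in seq_along(subs)) {
    s <- subs[[k]]
    j <- s$position
    if (j == n && het != "CH2") {
      stop("substituents at the heteroatom position require heteroatom CH2",
           call. = FALSE)
    }
    if (used[j] >= n_slots[j]) {
      stop("valence overflow: position ", j, " has only ", n_slots[j],
           " free valence(s)", call. = FALSE)
    }
    sl <- slot_info[[j]]$slots
    pick <- which(!sl$taken & sl$orientation == s$orientation)
    if (length(pick) == 0L) pick <- which(!sl$taken) # orientation occupied
    pick <- pick[1L]
    slot_info[[j]]$slots$taken[pick] <- TRUE
    used[j] <- used[j] + 1L
    claims[[k]] <- pick
  }

  bonds <- cbind(seq_len(n), c(2:n, 1L)) # ring edges; exocyclic added below

  ## --- heteroatom block ----------------------------------------------------
  si <- slot_info[[n]]
  anc <- si$anchors
  if (het == "SO2") {
    for (off in c(120, -120)) {
      id <- add_row("O", anc[1], anc[2], anc[3], dist = 1.45, angle = 109.6,
                    dih = .wrap180(si$delta + off), tag = "het")
      bonds <- rbind(bonds, c(id, n))
    }
    slot_info[[n]]$slots$taken[] <- TRUE
  } else if (het %in% c("NH", "PH")) {
    vars["HF1"] <- 120
    var_tags["HF1"] <- "hetflip"
    d <- if (het == "NH") 1.01 else 1.42
    id <- add_row("H", anc[1], anc[2], anc[3], dist = d, angle = 105,
                  dih = si$delta, dih_var = "HF1", tag = "het")
    bonds <- rbind(bonds, c(id, n))
    slot_info[[n]]$slots$taken[] <- TRUE
  } else if (het == "BH") {
    id <- add_row("H", anc[1], anc[2], anc[3], dist = 1.19, angle = 120,
                  dih = .wrap180(si$delta + 180), tag = "het")
    bonds <- rbind(bonds, c(id, n))
    slot_info[[n]]$slots$taken[] <- TRUE
  } else if (het == "CH2") {
    free <- which(!slot_info[[n]]$slots$taken)
    for (p in free) {
      id <- add_row("H", anc[1], anc[2], anc[3], dist = 1.09, angle = 109.47,
                    dih = slot_info[[n]]$slots$dih[p], tag = "het")
      bonds <- rbind(bonds, c(id, n))
      slot_info[[n]]$slots$taken[p] <- TRUE
    }
  }

  ## --- substituent groups --------------------------------------------------
  n_rot <- 0L
  for (k in seq_along(subs)) {
    s <- subs[[k]]
    j <- s$position
    anc <- slot_info[[j]]$anchors
    params <- .group_params(s$group)$atoms
    gidx <- integer(nrow(params))       # group-local -> global row index
    gparent <- integer(nrow(params))    # global parent chain
    latest_rot <- NA_character_
    for (a in seq_len(nrow(params))) {
      p <- params[a, ]
      if (a == 1L) {
        slot <- claims[[k]]
        id <- add_row(p$element, anc[1], anc[2], anc[3], dist = p$dist,
                      angle = p$angle, dih = slot_info[[j]]$slots$dih[slot],
                      tag = "sub")
        gidx[a] <- id
        gparent[a] <- anc[1]
        bonds <- rbind(bonds, c(id, anc[1]))
        next
      }
      par <- p$parent
      i1 <- gidx[par]
      i2 <- gparent[par]
      i3 <- if (par == 1L) anc[2] else gparent[match(gparent[par], gidx)]
      tor <- p$torsion
      dih <- NA_real_
      dih_var <- NA_character_
      if (identical(tor, "rot")) {
        if (s$rotatable) {
          n_rot <- n_rot + 1L
          dih_var <- paste0("ROT", n_rot)
          vars[dih_var] <- 180
          var_tags[dih_var] <- "rotamer"
          dih <- 0
          latest_rot <- dih_var
        } else {
          dih <- 180
          latest_rot <- NA_character_
        }
      } else if (grepl("^\\+", tor)) {
        off <- as.numeric(tor)
        if (s$rotatable && !is.na(latest_rot)) {
          dih_var <- latest_rot
          dih <- off
        } else {
          dih <- .wrap180(180 + off)
        }
      } else {
        dih <- as.numeric(tor)
      }
      id <- add_row(p$element, i1, i2, i3, dist = p$dist, angle = p$angle,
                    dih = dih, dih_var = dih_var, tag = "sub")
      gidx[a] <- id
      gparent[a] <- i1
      bonds <- rbind(bonds, c(id, i1))
    }
  }

  ## --- filling hydrogens ---------------------------------------------------
  for (j in seq_len(n)) {
    if (j == n && het != "CH2") next
    free <- which(!slot_info[[j]]$slots$taken)
    anc <- slot_info[[j]]$anchors
    for (p in free) {
      id <- add_row("H", anc[1], anc[2], anc[3], dist = 1.09, angle = 109.47,
                    dih = slot_info[[j]]$slots$dih[p], tag = "fill")
      bonds <- rbind(bonds, c(id, j))
      slot_info[[j]]$slots$taken[p] <- TRUE
    }
  }

  structure(
    list(
      rows = dplyr::bind_rows(rows),
      variables = vars,
      var_tags = var_tags,
      bonds = bonds,
      n_ring = n,
      charge = 0L,
      multiplicity = 1L,
      template = template,
      substituents = subs
    ),
    class = "zmatrix"
  )
}

#' @export
print.zmatrix <- function(x, ...) {
  tags <- table(x$var_tags)
  cat("<zmatrix> ", nrow(x$rows), " atoms (", x$n_ring, " ring), variables: ",
      paste(names(tags), tags, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Realize a Z-matrix as Cartesian coordinates
#'
#' Sequential natural-extension placement: atom 1 at the origin, atom 2 on
#' the +x axis, atom 3 in the xy plane, every later atom from its distance,
#' angle and dihedral references.
#'
#' @param zm A [attach_substituents()] Z-matrix.
#' @param variables Optional named numeric vector overriding stored variable
#'   values (e.g. sampled `D#`/`ROT#`/`HF1` values).
#' @return A `molecule` object: list with `coords` (matrix), `elements`,
#'   `bonds` and the realized `variables`.
#' @export
zmat_to_cartesian <- function(zm, variables = NULL) {
  stopifnot(inherits(zm, "zmatrix"))
  vars <- zm$variables
  if (!is.null(variables)) vars[names(variables)] <- variables
  rows <- zm$rows
  m <- nrow(rows)
  coords <- matrix(NA_real_, m, 3)
  for (k in seq_len(m)) {
    r <- rows[k, ]
    if (k == 1L) {
      coords[k, ] <- c(0, 0, 0)
    } else if (is.na(r$i2)) {
      coords[k, ] <- c(r$dist, 0, 0)
    } else if (is.na(r$i3)) {
      u <- .unit(coords[r$i2, ] - coords[r$i1, ])
      a <- .rad(r$angle)
      dir <- c(u[1] * cos(a) - u[2] * sin(a), u[1] * sin(a) + u[2] * cos(a), 0)
      coords[k, ] <- coords[r$i1, ] + r$dist * dir
    } else {
      dih <- if (!is.na(r$dih_var)) vars[[r$dih_var]] + r$dih else r$dih
      coords[k, ] <- .nerf_place(coords[r$i3, ], coords[r$i2, ], coords[r$i1, ],
                                 r$dist, r$angle, .wrap180(dih))
    }
  }
  structure(
    list(coords = coords, elements = rows$element, bonds = zm$bonds,
         variables = vars, n_ring = zm$n_ring),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", length(x$elements), " atoms: ",
      paste(names(table(x$elements)), table(x$elements), sep = "", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

## atom pairs separated by one or two bonds (excluded from clash checks)
.bonded_13_pairs <- function(bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  pairs <- bonds
  for (c_at in seq_len(n_atoms)) {
    nb <- adj[[c_at]]
    if (length(nb) >= 2) {
      combs <- utils::combn(sort(nb), 2)
      pairs <- rbind(pairs, t(combs))
    }
  }
  pairs <- t(apply(pairs, 1, sort))
  unique(pairs)
}
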