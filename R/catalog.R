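## Canonical conformer catalogs.
##
## Naming grammar: atoms above the reference plane precede the family letter,
## atoms below follow it, comma-separated, the ring heteroatom (position N)
## rendered by its symbol ("O" by default). "Above" is fixed per ring size:
## for N = 6 and 7 the side convention is chosen so that theta = 0 (atom 1
## displaced to the positive side of the mean plane) is the 4C1 chair, i.e.
## superscript atoms are those with negative mean-plane displacement; for
## N = 5 the E/T parity convention instead makes the superscript atom the one
## with maximal positive displacement ("1E" at phi2 = 0).

.render_pos <- function(pos, n, het_symbol) {
  ifelse(pos == n, het_symbol, as.character(pos))
}

.render_name <- function(sup, sub, family, n, het_symbol) {
  s1 <- paste(.render_pos(sort(sup), n, het_symbol), collapse = ",")
  s2 <- paste(.render_pos(sort(sub), n, het_symbol), collapse = ",")
  paste0(s1, family, s2)
}

.ring_dist <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}

## displacement pattern of a catalog row at unit total amplitude
.catalog_z <- function(row) {
  n <- row$n_atoms
  state <- if (n == 6) {
    cp_pucker_state(6, Q = 1, theta = row$theta, phi2 = row$phi2)
  } else if (n == 5) {
    cp_pucker_state(5, q2 = 1, phi2 = row$phi2)
  } else {
    cp_pucker_state(7, q2 = row$q2rel, q3 = row$q3rel,
                    phi2 = row$phi2, phi3 = row$phi3)
  }
  inverse_displacements(state)
}

## --- constructive labelers ------------------------------------------------

## N = 5: E has one dominant atom, T an adjacent opposite-sign pair.
## Superscript side is positive z here (see header note).
.label5 <- function(z, family) {
  ord <- order(-abs(z), seq_along(z))
  if (family == "E") {
    d <- ord[1L]
    if (z[d] > 0) list(sup = d, sub = integer()) else list(sup = integer(), sub = d)
  } else {
    pair <- sort(ord[1:2])
    list(sup = pair[z[pair] > 0], sub = pair[z[pair] < 0])
  }
}

## N = 6: family-specific rules; superscript side is negative z.
.label6 <- function(z, family) {
  ord <- order(-abs(z), seq_along(z))
  flip <- function(atoms) list(sup = atoms[z[atoms] < 0], sub = atoms[z[atoms] > 0])
  switch(
    family,
    C = flip(c(1L, 4L)), # out-of-plane pair containing the lowest atom
    E = flip(ord[1L]),
    H = flip(sort(ord[1:2])),
    B = flip(sort(ord[1:2])),
    S = {
      ## four extremal atoms: a para pair up and a para pair down; the named
      ## pair is the meta (1,3-related) cross pair containing the lowest
      ## numbered carbon
      top <- ord[1:4]
      up <- top[z[top] > 0]
      dn <- top[z[top] < 0]
      pairs <- expand.grid(a = up, b = dn)
      pairs <- pairs[.ring_dist(pairs$a, pairs$b, 6L) == 2L, , drop = FALSE]
      carbon_rank <- function(a, b) {
        cc <- c(a, b)
        min(cc[cc != 6L]) # position 6 is the heteroatom
      }
      ranks <- mapply(carbon_rank, pairs$a, pairs$b)
      best <- pairs[which.min(ranks), ]
      flip(c(best$a, best$b))
    },
    stop("unknown family ", family)
  )
}

## N = 7: generic extreme-atom rule (package convention, documented):
## per side, atoms within 80% of the overall maximum |z|, at most two,
## superscript side negative z.
.label7 <- function(z, family) {
  thr <- 0.8 * max(abs(z))
  pick <- function(side) {
    cand <- which(side * z >= thr)
    cand[order(-abs(z[cand]), cand)][seq_len(min(2L, length(cand)))]
  }
  list(sup = sort(pick(-1)), sub = sort(pick(1)))
}

.labeler <- function(n) switch(as.character(n), "5" = .label5,
                               "6" = .label6, "7" = .label7)

## --- catalog construction -------------------------------------------------

.build_catalog <- function(n_atoms, het_symbol = "O") {
  n <- n_atoms
  if (n == 5) {
    grid <- tibble::tibble(
      phi2 = 18 * (0:19),
      family = rep(c("E", "T"), 10),
      theta = NA_real_, phi3 = NA_real_,
      q2rel = 1, q3rel = NA_real_, plane = NA_character_
    )
  } else if (n == 6) {
    th_e <- .deg(acos(1 / sqrt(3))) # 54.7356: idealized tetrahedral band
    band <- function(theta, fams) {
      tibble::tibble(
        phi2 = 30 * (0:11), family = rep(fams, 6), theta = theta,
        phi3 = NA_real_, q2rel = sin(.rad(theta)), q3rel = cos(.rad(theta)),
        plane = NA_character_
      )
    }
    grid <- dplyr::bind_rows(
      tibble::tibble(phi2 = 0, family = "C", theta = 0, phi3 = NA_real_,
                     q2rel = 0, q3rel = 1, plane = NA_character_),
      band(th_e, c("E", "H")),
      band(90, c("B", "S")),
      band(180 - th_e, c("E", "H")),
      tibble::tibble(phi2 = 0, family = "C", theta = 180, phi3 = NA_real_,
                     q2rel = 0, q3rel = -1, plane = NA_character_)
    )
  } else {
    tau <- (0:13) * (360 / 14)
    q2_of <- function(q3rel) sqrt(1 - q3rel^2)
    tc_plane <- dplyr::bind_rows(
      tibble::tibble(phi2 = .wrap360(2 * tau), phi3 = .wrap360(3 * tau),
                     family = "C"),
      tibble::tibble(phi2 = .wrap360(2 * tau + 90), phi3 = .wrap360(3 * tau + 90),
                     family = "TC")
    ) |>
      dplyr::mutate(q3rel = 0.6, q2rel = q2_of(0.6), plane = "TC/C")
    b_plane <- tibble::tibble(
      phi2 = (0:27) * (360 / 28),
      phi3 = 0, # harp plane: phi3 does not affect the structure
      family = rep(c("B", "TB"), 14),
      q3rel = 0, q2rel = 1, plane = "B/TB"
    )
    s_plane <- dplyr::bind_rows(
      tibble::tibble(phi2 = .wrap360(2 * tau), phi3 = .wrap360(3 * tau),
                     family = "S"),
      tibble::tibble(phi2 = .wrap360(2 * tau + 90), phi3 = .wrap360(3 * tau + 90),
                     family = rep(c("TS", "SB"), 7))
    ) |>
      dplyr::mutate(q3rel = 0.4, q2rel = q2_of(0.4), plane = "S/TS/SB")
    grid <- dplyr::bind_rows(tc_plane, b_plane, s_plane) |>
      dplyr::mutate(theta = NA_real_)
  }
  grid$n_atoms <- n
  grid$index <- seq_len(nrow(grid))
  lab <- .labeler(n)
  sup <- sub <- vector("list", nrow(grid))
  name <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    z <- .catalog_z(row)
    parts <- lab(z, row$family)
    sup[[i]] <- as.integer(parts$sup)
    sub[[i]] <- as.integer(parts$sub)
    name[i] <- .render_name(parts$sup, parts$sub, row$family, n, het_symbol)
  }
  grid$sup <- sup
  grid$sub <- sub
  grid$name <- name
  if (anyDuplicated(name)) {
    stop("internal error: duplicate conformer names for N = ", n, call. = FALSE)
  }
  grid[, c("n_atoms", "index", "name", "family", "sup", "sub",
           "phi2", "phi3", "theta", "q2rel", "q3rel", "plane")]
}

.catalog_cache <- new.env(parent = emptyenv())

#' Enumerate the canonical conformers of an N-membered ring
#'
#' Returns the catalog of canonical ring conformers with IUPAC-style labels
#' and their reference puckering coordinates:
#'
#' * N = 5: 20 conformers (10 envelopes E, 10 twists T) alternating every 18
#'   degrees around the phi2 pseudorotation circle.
#' * N = 6: 38 conformers (2 chairs C at the theta poles, 6 boats B and 6
#'   skew-boats S on the equator, 12 envelopes E and 12 half-chairs H on the
#'   idealized tetrahedral bands at theta = 54.74 / 125.26 degrees; phi2 on a
#'   30-degree grid with C/B/E on even multiples and S/H on odd ones).
#' * N = 7: three (phi2, phi3) planes at relative q3 amplitudes 0.6
#'   (chair/twist-chair), 0.0 (boat/twist-boat, where the label depends on
#'   phi2 only) and 0.4 (sofa families), 28 grid points each.
#'
#' @param n_atoms Ring size (5, 6 or 7).
#' @param het_symbol Symbol used to render the heteroatom position (ring
#'   position N) inside conformer names; default `"O"`.
#' @return A tibble with one row per conformer: `n_atoms`, `index`, `name`,
#'   `family`, `sup`/`sub` (list columns of ring positions above/below the
#'   reference plane), the grid phases `phi2`/`phi3`, `theta` (N = 6),
#'   relative amplitudes `q2rel`/`q3rel` and, for N = 7, the `plane` tag.
#'   Ordering is deterministic.
#' @export
#' @examples
#' nrow(enumerate_catalog(5))  # 20
#' table(enumerate_catalog(6)$family)
enumerate_catalog <- function(n_atoms, het_symbol = "O") {
  if (!length(n_atoms) == 1 || !n_atoms %in% 5:7) {
    stop("`n_atoms` must be 5, 6 or 7", call. = FALSE)
  }
  key <- paste0("n", n_atoms, "_", het_symbol)
  if (is.null(.catalog_cache[[key]])) {
    .catalog_cache[[key]] <- .build_catalog(n_atoms, het_symbol)
  }
  .catalog_cache[[key]]
}

#' @rdname enumerate_catalog
#' @export
cp_catalog <- enumerate_catalog

#' Reference puckering state of a canonical conformer
#'
#' Looks up a catalog entry and scales its reference coordinates to the
#' requested total puckering amplitude, so that
#' `classify_state(canonical_state(name, a)) == name` for every catalog entry.
#'
#' @param label Conformer name (e.g. `"4C1"`), or a one-row catalog tibble.
#' @param amplitude Total puckering amplitude in Angstrom (> 0).
#' @param n_atoms Ring size; required when `label` is a name that occurs for a
#'   single ring size it can be dropped, otherwise give it explicitly.
#' @param het_symbol Passed to [enumerate_catalog()].
#' @return A `cp_pucker` object.
#' @export
canonical_state <- function(label, amplitude, n_atoms = NULL, het_symbol = "O") {
  stopifnot(is.numeric(amplitude), amplitude > 0)
  if (is.data.frame(label)) {
    row <- label
  } else {
    sizes <- if (is.null(n_atoms)) 5:7 else n_atoms
    hits <- purrr::map(sizes, function(n) {
      cat_n <- enumerate_catalog(n, het_symbol)
      cat_n[cat_n$name == label, ]
    })
    row <- dplyr::bind_rows(hits)
    if (nrow(row) == 0) stop("unknown conformer label: ", label, call. = FALSE)
    if (nrow(row) > 1) {
      stop("label ", label, " is ambiguous; give `n_atoms`", call. = FALSE)
    }
  }
  n <- row$n_atoms
  if (n == 5) {
    cp_pucker_state(5, q2 = amplitude, phi2 = row$phi2)
  } else if (n == 6) {
    cp_pucker_state(6, Q = amplitude, theta = row$theta, phi2 = row$phi2)
  } else {
    cp_pucker_state(7, q2 = amplitude * row$q2rel, q3 = amplitude * row$q3rel,
                    phi2 = row$phi2, phi3 = row$phi3)
  }
}

#' Classify a puckering state to its nearest canonical conformer
#'
#' Finds the catalog label closest to a puckering state: circular distance in
#' phi2 for five-membered rings; great-circle distance on the (theta, phi2)
#' sphere for six-membered rings; for seven-membered rings, nearest relative-
#' q3 plane first (boundaries at the midpoints 0.2 and 0.5 of the 0.0 / 0.4 /
#' 0.6 plane amplitudes), then grid distance in (phi2, phi3) -- with the
#' q3 = 0 plane classified by phi2 alone (its structures do not depend on
#' phi3). States whose total amplitude falls below `min_amplitude` are
#' reported as `"planar"`. Ties are broken by catalog order.
#'
#' @param state A `cp_pucker` object computed with the standard phase mode.
#' @param min_amplitude Planarity threshold in Angstrom, default 0.05.
#' @param het_symbol Passed to [enumerate_catalog()].
#' @return The conformer name as a character scalar, or `"planar"`.
#' @export
#' @examples
#' classify_state(cp_pucker_state(6, Q = 0.55, theta = 0, phi2 = 0)) # "4C1"
classify_state <- function(state, min_amplitude = 0.05, het_symbol = "O") {
  stopifnot(inherits(state, "cp_pucker"))
  if (identical(state$phase_mode, "paper")) {
    stop("classification requires the standard phase mode", call. = FALSE)
  }
  if (state$amplitude < min_amplitude) return("planar")
  cat_n <- enumerate_catalog(state$n_atoms, het_symbol)
  n <- state$n_atoms
  if (n == 5) {
    d <- .circ_dist(state$phi[["phi2"]], cat_n$phi2)
  } else if (n == 6) {
    th <- .rad(state$theta)
    th0 <- .rad(cat_n$theta)
    dphi <- .rad(state$phi[["phi2"]] - cat_n$phi2)
    d <- acos(pmin(pmax(cos(th) * cos(th0) + sin(th) * sin(th0) * cos(dphi),
                        -1), 1))
  } else {
    q3rel <- state$q[["q3"]] / state$amplitude
    plane <- if (q3rel < 0.2) "B/TB" else if (q3rel < 0.5) "S/TS/SB" else "TC/C"
    cat_n <- cat_n[cat_n$plane == plane, ]
    d <- if (plane == "B/TB") {
      .circ_dist(state$phi[["phi2"]], cat_n$phi2)
    } else {
      sqrt(.circ_dist(state$phi[["phi2"]], cat_n$phi2)^2 +
             .circ_dist(state$phi[["phi3"]], cat_n$phi3)^2)
    }
  }
  cat_n$name[which.min(d)]
}

#' Export a conformer catalog table
#'
#' Writes the catalog of one or more ring sizes as a delimited text table
#' (name, family, canonical coordinates).
#'
#' @param path Output file path.
#' @param n_atoms Ring sizes to include, default all three.
#' @param sep Field separator, default tab.
#' @return The path, invisibly.
#' @export
write_catalog <- function(path, n_atoms = 5:7, sep = "\t") {
  tab <- dplyr::bind_rows(purrr::map(n_atoms, enumerate_catalog)) |>
    dplyr::select("n_atoms", "index", "name", "family", "phi2", "phi3",
                  "theta", "q2rel", "q3rel", "plane")
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
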