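# Reaction-center identification from the atom-atom mapping, and its
# stereochemical augmentation.

# Per-atom environment table for one side of a reaction: for every atom, its
# element, charge, aromaticity and the sorted multiset of (bond order,
# neighbour map) pairs.  Unmapped neighbours contribute an element token
# instead of a map (they cannot be tracked across sides).
side_env_table <- function(mols) {
  rows <- list()
  for (si in seq_along(mols)) {
    m <- mols[[si]]
    adj <- mol_adj(m)
    b <- m$bonds
    for (i in seq_len(n_atoms(m))) {
      nb <- character(0)
      for (k in seq_len(nrow(b))) {
        j <- if (b$a1[k] == i) b$a2[k] else if (b$a2[k] == i) b$a1[k] else next
        tag <- if (m$atoms$map[j] > 0L) sprintf("m%d", m$atoms$map[j])
               else sprintf("u%s", m$atoms$symbol[j])
        nb <- c(nb, paste0(b$order[k], tag))
      }
      rows[[length(rows) + 1L]] <- list(
        species = si, atom = i, map = m$atoms$map[i],
        env = paste(m$atoms$symbol[i], m$atoms$charge[i], m$atoms$aromatic[i],
                    paste(sort(nb), collapse = ","), sep = "|"))
    }
  }
  rows
}

#' Identify the reaction center of a mapped reaction
#'
#' The reaction center is the set of atom-map numbers whose bonding
#' environment changes between the two sides: atoms whose incident bond
#' multiset (neighbour map and bond order), formal charge, element or
#' aromaticity differs, plus atoms that appear on one side only.  A change
#' of implicit hydrogen count alone (a consequence of a neighbour's change)
#' does not, by itself, put an atom in the center.
#'
#' @param rxn an \code{rf_reaction}.
#' @return an \code{rf_center}: list with \code{reacting_maps} (sorted
#'   integer vector), \code{stereo_added_maps} (empty here) and
#'   \code{is_stereo_augmented = FALSE}.
#' @export
identify_reaction_center <- function(rxn) {
  envs <- side_env_table(rxn$substrates)
  envp <- side_env_table(rxn$products)
  env_of <- function(rows) {
    maps <- vapply(rows, `[[`, 0L, "map")
    e <- vapply(rows, `[[`, "", "env")
    e <- e[maps > 0L]
    names(e) <- maps[maps > 0L]
    e
  }
  es <- env_of(envs)
  ep <- env_of(envp)
  both <- intersect(names(es), names(ep))
  changed <- both[es[both] != ep[both]]
  one_side <- c(setdiff(names(es), names(ep)), setdiff(names(ep), names(es)))
  reacting <- sort(as.integer(unique(c(changed, one_side))))
  structure(list(reacting_maps = reacting,
                 stereo_added_maps = integer(),
                 is_stereo_augmented = FALSE),
            class = "rf_center")
}

#' @export
print.rf_center <- function(x, ...) {
  cat(sprintf("<reaction center: {%s}%s>\n",
              paste(x$reacting_maps, collapse = ","),
              if (x$is_stereo_augmented)
                sprintf(" (stereo-added: {%s})",
                        paste(x$stereo_added_maps, collapse = ",")) else ""))
  invisible(x)
}

# Locate the (species index, atom index) of a map number on one side.
find_map <- function(mols, map) {
  for (si in seq_along(mols)) {
    i <- which(mols[[si]]$atoms$map == map)
    if (length(i)) return(c(si, i[1]))
  }
  NULL
}

#' Augment a reaction center with stereo-changing atoms
#'
#' Adds (a) every tetrahedral atom whose descriptor is created, inverted or
#' deleted between the two sides, and (b) both atoms of every double bond
#' whose cis/trans configuration changes (including creation or deletion of
#' the descriptor).  Because the atom-atom mapping identifies each
#' substituent across the reaction, descriptors are compared in a
#' map-normalised frame, which detects exactly the R/S and E/Z changes
#' without a full CIP assignment.
#'
#' @param rxn an \code{rf_reaction}.
#' @param center the centre returned by \code{\link{identify_reaction_center}}.
#' @return an \code{rf_center} with \code{is_stereo_augmented = TRUE}; the
#'   added maps are recorded in \code{stereo_added_maps}.
#' @export
augment_stereo <- function(rxn, center) {
  added <- integer()

  map_parity_side <- function(mols, map) {
    loc <- find_map(mols, map)
    if (is.null(loc)) return(NULL)
    p <- parity_by_map(mols[[loc[1]]], loc[2])
    if (is.na(p))
      stop(sprintf("unperceivable stereo at atom map %d of %s",
                   map, rxn$reaction_id), call. = FALSE)
    p
  }

  all_maps <- function(mols) {
    m <- unlist(lapply(mols, function(x) x$atoms$map))
    m[m > 0L]
  }
  shared <- intersect(all_maps(rxn$substrates), all_maps(rxn$products))

  # Tetrahedral creation / inversion / deletion.
  for (mp in shared) {
    ps <- map_parity_side(rxn$substrates, mp)
    pp <- map_parity_side(rxn$products, mp)
    if (!identical(ps, pp)) added <- c(added, mp)
  }

  # E/Z switches on double bonds present (between the same mapped pair) on
  # both sides.  Reference substituents are chosen on the substrate side and
  # looked up by map on the product side, so the same physical substituents
  # are compared.
  for (m in rxn$substrates) {
    b <- m$bonds
    for (k in which(b$order == "=")) {
      a1 <- b$a1[k]; a2 <- b$a2[k]
      m1 <- m$atoms$map[a1]; m2 <- m$atoms$map[a2]
      if (m1 == 0L || m2 == 0L) next
      loc1 <- find_map(rxn$products, m1)
      loc2 <- find_map(rxn$products, m2)
      if (is.null(loc1) || is.null(loc2) || loc1[1] != loc2[1]) next
      pm <- rxn$products[[loc1[1]]]
      kb <- bond_between(pm, loc1[2], loc2[2])
      if (is.na(kb) || pm$bonds$order[kb] != "=") next
      rs <- ez_relation_by_map(m, a1, a2)
      if (is.null(rs)) next
      rp <- ez_relation_by_map(pm, loc1[2], loc2[2],
                               ref_map_a = rs$ref_map_a,
                               ref_map_b = rs$ref_map_b)
      rel_s <- rs$rel
      rel_p <- if (is.null(rp)) NA_integer_ else rp$rel
      same <- (is.na(rel_s) && is.na(rel_p)) ||
        (!is.na(rel_s) && !is.na(rel_p) && rel_s == rel_p)
      if (!same) added <- c(added, m1, m2)
    }
  }

  added <- sort(setdiff(unique(added), center$reacting_maps))
  structure(list(reacting_maps = sort(unique(c(center$reacting_maps, added))),
                 stereo_added_maps = added,
                 is_stereo_augmented = TRUE),
            class = "rf_center")
}
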