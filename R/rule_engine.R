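# Mono-substrate decomposition, diameter-truncated rule extraction,
# canonicalization and single-step rule application.

#' Decompose a reaction into mono-substrate components
#'
#' One component is produced per non-cofactor substrate in the forward
#' direction and per non-cofactor product in the reverse direction (rules
#' are generated for both directions, which doubles their number).  The
#' products of each component are restricted to species sharing at least one
#' mapped atom with the component substrate; cofactor species are dropped
#' from the product lists when removal is on.
#'
#' @param rxn an accepted \code{rf_reaction}.
#' @param center its \code{rf_center} (stereo-augmented when the policy has
#'   stereo enabled).
#' @param cofactors an \code{rf_cofactors} list or NULL.
#' @param policy an \code{rf_policy}.
#' @return list of \code{rf_component} objects.
#' @export
decompose <- function(rxn, center, cofactors = NULL, policy = rf_policy()) {
  if (!length(center$reacting_maps))
    stop("cannot decompose a reaction with an empty center", call. = FALSE)
  removal <- policy$cofactor_removal
  one_direction <- function(subs, sub_st, prods, prod_st, direction) {
    sub_cof <- vapply(subs, function(m) removal && is_cofactor(m, cofactors),
                      logical(1))
    prod_cof <- vapply(prods, function(m) removal && is_cofactor(m, cofactors),
                       logical(1))
    seeds <- which(!sub_cof)
    if (!length(seeds))
      stop(sprintf("no primary substrate in %s (%s direction): all substrates are cofactors",
                   rxn$reaction_id, direction), call. = FALSE)
    out <- list()
    for (s in seeds) {
      smol <- subs[[s]]
      smaps <- smol$atoms$map
      keep_p <- which(!prod_cof & vapply(prods, function(p) {
        any(p$atoms$map %in% smaps[smaps > 0L])
      }, logical(1)))
      # reacting atoms: centre maps plus unmapped atoms (present on one side)
      sub_center <- which(smaps %in% center$reacting_maps | smaps == 0L)
      comp <- structure(list(
        parent_reaction_id = rxn$reaction_id,
        direction = direction,
        substrate = smol,
        products = prods[keep_p],
        prod_stoich = prod_st[keep_p],
        removed_cofactors = unique(vapply(prods[prod_cof],
          function(m) canonical_smiles(strip_maps(m)), "")),
        center = center,
        sub_center_idx = sub_center,
        ec = rxn$ec,
        sequence_ids = rxn$sequence_ids), class = "rf_component")
      out[[length(out) + 1L]] <- comp
    }
    out
  }
  c(one_direction(rxn$substrates, rxn$sub_stoich, rxn$products, rxn$prod_stoich,
                  "forward"),
    one_direction(rxn$products, rxn$prod_stoich, rxn$substrates, rxn$sub_stoich,
                  "reverse"))
}

#' @export
print.rf_component <- function(x, ...) {
  cat(sprintf("<component of %s (%s): %s >> %d product(s)>\n",
              x$parent_reaction_id, x$direction,
              canonical_smiles(strip_maps(x$substrate)), length(x$products)))
  invisible(x)
}

# Reacting atoms of one product molecule: centre maps plus incoming unmapped
# atoms.
product_center_idx <- function(pmol, center) {
  which(pmol$atoms$map %in% center$reacting_maps | pmol$atoms$map == 0L)
}

# Atom set of one product retained at radius r: atoms whose map is in
# `kept_sub_maps` (they ride along with the substrate pattern) plus incoming
# atoms (map not on the substrate side, or unmapped) within r bonds of a
# reacting atom in the product graph.
product_keep_idx <- function(pmol, center, kept_sub_maps, sub_maps_all, r) {
  seeds <- product_center_idx(pmol, center)
  d <- mol_dist(pmol, seeds)
  maps <- pmol$atoms$map
  incoming <- maps == 0L | !(maps %in% sub_maps_all)
  which((maps %in% kept_sub_maps) | (incoming & d <= r))
}

# Subset a molecule into a pattern fragment, attaching the reacting/interior
# flag columns used by matching and SMARTS emission.
make_pattern <- function(mol, keep, reacting_idx, stereo) {
  if (!stereo) mol <- stereo_strip(mol)
  mol$atoms$reacting <- seq_len(n_atoms(mol)) %in% reacting_idx
  full_nbrs <- mol_adj(mol)
  keep <- sort(unique(keep))
  mol$atoms$interior <- vapply(seq_len(n_atoms(mol)), function(i) {
    all(full_nbrs[[i]] %in% keep)
  }, logical(1))
  subset_mol(mol, keep)
}

#' Extract a reaction rule from a mono-substrate component
#'
#' Truncates the component at the given diameter: the substrate pattern
#' keeps the atoms within \code{diameter/2} bonds of any reacting atom;
#' product patterns keep the atoms mapped to retained substrate atoms plus
#' incoming atoms within the same radius of a reacting atom in the product
#' graph.  Bonds crossing the boundary are cut.  With \code{stereo = TRUE},
#' tetrahedral and E/Z descriptors of retained atoms are written into the
#' patterns (a tetrahedral descriptor is kept only when all of the atom's
#' neighbours are retained).  The rule is returned canonicalized; a rule
#' whose left and right patterns are identical is flagged degenerate.
#'
#' @param component an \code{rf_component}.
#' @param diameter even integer \eqn{\ge 0}, in bonds; \code{Inf} keeps the
#'   full structures.
#' @param stereo logical.
#' @return an \code{rf_rule}, or \code{NULL} when every product vanishes at
#'   this diameter.
#' @export
extract_rule <- function(component, diameter, stereo = FALSE) {
  if (!is.numeric(diameter) || length(diameter) != 1L || is.na(diameter) ||
      diameter < 0 || (is.finite(diameter) && diameter %% 2 != 0))
    stop("diameter must be an even integer >= 0, or Inf", call. = FALSE)
  r <- diameter / 2
  smol <- component$substrate
  dsub <- mol_dist(smol, component$sub_center_idx)
  keep_s <- which(dsub <= r)
  sub_pat <- make_pattern(smol, keep_s, component$sub_center_idx, stereo)
  kept_sub_maps <- smol$atoms$map[keep_s]
  kept_sub_maps <- kept_sub_maps[kept_sub_maps > 0L]
  sub_maps_all <- smol$atoms$map[smol$atoms$map > 0L]

  prod_pats <- list()
  prod_st <- integer()
  for (pi in seq_along(component$products)) {
    pmol <- component$products[[pi]]
    keep_p <- product_keep_idx(pmol, component$center, kept_sub_maps,
                               sub_maps_all, r)
    if (!length(keep_p)) next
    ppat <- make_pattern(pmol, keep_p, product_center_idx(pmol, component$center),
                         stereo)
    prod_pats[[length(prod_pats) + 1L]] <- ppat
    prod_st <- c(prod_st, component$prod_stoich[pi])
  }
  if (!length(prod_pats)) return(NULL)

  rule <- structure(list(
    reaction_id = component$parent_reaction_id,
    substrate_id = canonical_smiles(strip_maps(component$substrate)),
    direction = component$direction,
    diameter = diameter,
    is_stereo = isTRUE(stereo),
    sub_pattern = sub_pat,
    prod_patterns = prod_pats,
    prod_stoich = prod_st,
    ec = component$ec,
    rule_smarts = NA_character_,
    rule_smiles = NA_character_,
    degenerate = NA), class = "rf_rule")
  canonicalize_rule(rule)
}

#' Canonicalize a reaction rule
#'
#' Rewrites the rule's patterns in canonical atom order with consecutive
#' atom-map numbers (substrate atoms first, in canonical emission order;
#' incoming product atoms follow), so that two rules describing the same
#' transformation compare string-equal.  Idempotent.
#'
#' @param rule an \code{rf_rule}.
#' @return the rule with \code{rule_smarts} / \code{rule_smiles} strings and
#'   renumbered patterns; \code{degenerate} is TRUE when the left and right
#'   sides are identical.
#' @export
canonicalize_rule <- function(rule) {
  sub <- rule$sub_pattern
  stereo <- rule$is_stereo

  # canonical emission order of the substrate pattern (fragments sorted by
  # their map-free emitted string)
  frags <- mol_split(sub)
  comp <- mol_components(sub)
  frag_atom_idx <- lapply(seq_along(frags), function(k) which(comp == k))
  es <- lapply(seq_along(frags), function(k) {
    f <- frags[[k]]
    rk <- canonical_ranks(f, extra = mol_extra_invariant(f))
    e <- write_mol_single(f, ranks = rk, format = "smiles", with_maps = FALSE,
                          with_stereo = stereo)
    list(key = e$s, order = e$order, cid = k)
  })
  es <- es[order(vapply(es, `[[`, "", "key"),
                 vapply(es, `[[`, 0L, "cid"))]
  newmap_of_subidx <- integer(n_atoms(sub))
  counter <- 0L
  for (e in es) {
    idx <- frag_atom_idx[[e$cid]]
    for (o in e$order) {
      counter <- counter + 1L
      newmap_of_subidx[idx[o]] <- counter
    }
  }
  k_sub <- counter
  oldmaps <- sub$atoms$map
  old2new <- structure(newmap_of_subidx, names = oldmaps)

  sub$atoms$map <- newmap_of_subidx

  # products: inherit map numbers through the AAM, then number incoming atoms
  prods <- rule$prod_patterns
  inh <- lapply(prods, function(p) {
    m <- p$atoms$map
    new <- integer(length(m))
    hit <- m > 0L & m %in% oldmaps[oldmaps > 0L]
    new[hit] <- old2new[as.character(m[hit])]
    new
  })
  pkeys <- vapply(seq_along(prods), function(i) {
    paste(canonical_smiles(strip_maps(prods[[i]]), stereo = stereo),
          paste(sort(inh[[i]]), collapse = ","))
  }, "")
  porder <- order(pkeys)
  next_map <- k_sub
  out_prods <- list()
  out_st <- integer()
  for (i in porder) {
    p <- prods[[i]]
    new <- inh[[i]]
    # assign incoming maps in canonical emission order
    frag_list <- mol_split(p)
    compp <- mol_components(p)
    emitted <- lapply(frag_list, function(f) {
      rkf <- canonical_ranks(f, extra = mol_extra_invariant(f))
      write_mol_single(f, ranks = rkf, format = "smiles", with_maps = FALSE,
                       with_stereo = stereo)
    })
    fkeys <- vapply(emitted, `[[`, "", "s")
    for (fi in order(fkeys)) {
      idx <- which(compp == fi)
      for (o in emitted[[fi]]$order) {
        ai <- idx[o]
        if (new[ai] == 0L) {
          next_map <- next_map + 1L
          new[ai] <- next_map
        }
      }
    }
    p$atoms$map <- new
    out_prods[[length(out_prods) + 1L]] <- p
    out_st <- c(out_st, rule$prod_stoich[i])
  }

  side_string <- function(mols, stoich, format) {
    ss <- unlist(mapply(function(m, k) {
      rep(write_mol(m, format = format, with_maps = TRUE, with_stereo = stereo), k)
    }, mols, stoich, SIMPLIFY = FALSE))
    paste(ss, collapse = ".")
  }
  sub_smiles <- write_mol(sub, format = "smiles", with_maps = TRUE,
                          with_stereo = stereo)
  sub_smarts <- write_mol(sub, format = "smarts_query", with_maps = TRUE,
                          with_stereo = stereo)
  rule$sub_pattern <- sub
  rule$prod_patterns <- out_prods
  rule$prod_stoich <- out_st
  rule$rule_smiles <- paste0(sub_smiles, ">>",
                             side_string(out_prods, out_st, "smiles"))
  rule$rule_smarts <- paste0(sub_smarts, ">>",
                             side_string(out_prods, out_st, "smarts_template"))
  prod_side <- side_string(out_prods, out_st, "smiles")
  rule$degenerate <- identical(sub_smiles, prod_side)
  rule
}

#' @export
print.rf_rule <- function(x, ...) {
  cat(sprintf("<rule %s / %s d=%s%s%s>\n  %s\n", x$reaction_id,
              substr(x$substrate_id, 1, 40),
              ifelse(is.finite(x$diameter), x$diameter, "max"),
              if (x$is_stereo) " stereo" else "",
              if (isTRUE(x$degenerate)) " DEGENERATE" else "",
              x$rule_smarts))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rule application (single-step product enumeration)

#' Apply a reaction rule to a substrate
#'
#' Matches the rule's substrate pattern onto the given molecule and, for
#' every embedding, rewrites the matched atoms and bonds according to the
#' rule's product patterns: mapped atoms change charge/hydrogen counts and
#' bonds, atoms whose map disappears are removed, and incoming product atoms
#' (co-substrate-derived) are instantiated from the pattern.  Chemically
#' invalid rewrites (valence overflow) are discarded with a warning.  Stereo
#' rules only match substrates with compatible stereo descriptors and write
#' the product-side descriptors into the result.
#'
#' @param rule an \code{rf_rule}.
#' @param substrate a SMILES string or molecule object (atom maps, if any,
#'   are ignored).
#' @return a list of distinct product multisets, each a sorted character
#'   vector of canonical product SMILES; empty list when the rule does not
#'   match.
#' @export
apply_rule <- function(rule, substrate) {
  tgt <- if (is_mol(substrate)) substrate else parse_smiles(substrate)
  tgt <- strip_maps(tgt)
  if (!rule$is_stereo) tgt <- stereo_strip(tgt)
  matches <- match_pattern(rule$sub_pattern, tgt, stereo = rule$is_stereo)
  out <- list()
  seen <- character(0)
  for (m in matches) {
    res <- tryCatch(rewrite_once(rule, tgt, m), error = function(e) NULL)
    if (is.null(res)) next
    key <- paste(res, collapse = " + ")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

# One embedding -> product multiset (sorted canonical SMILES), or error when
# the rewrite is chemically invalid.
rewrite_once <- function(rule, tgt, m) {
  sub <- rule$sub_pattern
  submaps <- sub$atoms$map                      # canonical maps 1..k
  sub_idx_of_map <- integer(max(submaps))
  sub_idx_of_map[submaps] <- seq_along(submaps)

  # expand product instances by stoichiometry
  instances <- list()
  for (i in seq_along(rule$prod_patterns)) {
    for (rep_i in seq_len(rule$prod_stoich[i])) {
      instances[[length(instances) + 1L]] <- rule$prod_patterns[[i]]
    }
  }
  prod_maps_all <- unlist(lapply(instances, function(p) p$atoms$map))
  k_sub <- max(submaps)
  deleted_maps <- setdiff(submaps, prod_maps_all)

  atoms <- tgt$atoms
  bonds <- tgt$bonds
  touched <- integer(0)

  resolve <- vector("list", length(instances))  # product atom -> output index
  # 1. update mapped atoms, instantiate incoming atoms
  for (ii in seq_along(instances)) {
    p <- instances[[ii]]
    res <- integer(n_atoms(p))
    for (j in seq_len(n_atoms(p))) {
      mp <- p$atoms$map[j]
      if (mp > 0L && mp <= k_sub && sub_idx_of_map[mp] > 0L) {
        si <- sub_idx_of_map[mp]
        t <- m[si]
        atoms$symbol[t] <- p$atoms$symbol[j]
        atoms$aromatic[t] <- p$atoms$aromatic[j]
        atoms$charge[t] <- p$atoms$charge[j]
        # hydrogens move by the rule's own H delta: the matcher asserts H
        # counts only on reacting atoms, so a boundary atom of a promiscuous
        # match may carry more hydrogens than the source substrate did
        atoms$hcount[t] <- max(0L, atoms$hcount[t] +
                                 (p$atoms$hcount[j] - sub$atoms$hcount[si]))
        res[j] <- t
        touched <- c(touched, t)
      } else {
        atoms <- rbind(atoms, data.frame(
          symbol = p$atoms$symbol[j], aromatic = p$atoms$aromatic[j],
          charge = p$atoms$charge[j], hcount = p$atoms$hcount[j],
          map = 0L, parity = 0L, stringsAsFactors = FALSE))
        res[j] <- nrow(atoms)
        touched <- c(touched, res[j])
      }
    }
    resolve[[ii]] <- res
  }

  bond_df_find <- function(df, i, j) {
    which((df$a1 == i & df$a2 == j) | (df$a1 == j & df$a2 == i))
  }

  # 2. remove substrate-pattern bonds that do not persist
  persists <- function(map1, map2) {
    for (p in instances) {
      i1 <- which(p$atoms$map == map1)
      i2 <- which(p$atoms$map == map2)
      if (length(i1) && length(i2) && !is.na(bond_between(p, i1[1], i2[1])))
        return(TRUE)
    }
    FALSE
  }
  sb <- sub$bonds
  drop_rows <- integer(0)
  for (k in seq_len(nrow(sb))) {
    m1 <- submaps[sb$a1[k]]; m2 <- submaps[sb$a2[k]]
    if (m1 %in% deleted_maps || m2 %in% deleted_maps) next  # atom removal
    if (!persists(m1, m2)) {
      t1 <- m[sb$a1[k]]; t2 <- m[sb$a2[k]]
      drop_rows <- c(drop_rows, bond_df_find(bonds, t1, t2))
      touched <- c(touched, t1, t2)
    }
  }
  if (length(drop_rows)) bonds <- bonds[-unique(drop_rows), , drop = FALSE]

  # 3. add / update product-pattern bonds
  for (ii in seq_along(instances)) {
    p <- instances[[ii]]
    res <- resolve[[ii]]
    pb <- p$bonds
    for (k in seq_len(nrow(pb))) {
      t1 <- res[pb$a1[k]]; t2 <- res[pb$a2[k]]
      hit <- bond_df_find(bonds, t1, t2)
      if (length(hit)) {
        bonds$order[hit[1]] <- pb$order[k]
        bonds$a1[hit[1]] <- t1; bonds$a2[hit[1]] <- t2
        bonds$dir[hit[1]] <- if (rule$is_stereo) pb$dir[k] else 0L
      } else {
        bonds <- rbind(bonds, data.frame(a1 = t1, a2 = t2, order = pb$order[k],
                                         dir = if (rule$is_stereo) pb$dir[k] else 0L,
                                         stringsAsFactors = FALSE))
      }
      touched <- c(touched, t1, t2)
    }
  }

  out <- new_mol(atoms, bonds)

  # 4. stereo descriptors on the product side
  reacting_sub <- which(isTRUE_vec(sub$atoms$reacting))
  for (i in reacting_sub) out$atoms$parity[m[i]] <- 0L
  if (rule$is_stereo) {
    odeg <- mol_degree(out)
    for (ii in seq_along(instances)) {
      p <- instances[[ii]]
      res <- resolve[[ii]]
      for (j in seq_len(n_atoms(p))) {
        t <- res[j]
        pp <- p$atoms$parity[j]
        if (pp == 0L) {
          if (isTRUE(p$atoms$interior[j])) out$atoms$parity[t] <- 0L
          next
        }
        frame_p <- parity_frame_idx(p, j)
        heavy_p <- frame_p[frame_p != 0L]
        image <- c(res[heavy_p], if (0L %in% frame_p) 0L)
        # only set when the output neighbourhood is exactly the pattern's
        if (odeg[t] != length(heavy_p)) { out$atoms$parity[t] <- 0L; next }
        frame_t <- parity_frame_idx(out, t)
        if (!setequal(image, frame_t)) { out$atoms$parity[t] <- 0L; next }
        out$atoms$parity[t] <- parity_rel(pp, image, frame_t)
      }
    }
  }
  out <- clean_bond_dirs(out)

  # 5. delete disappearing atoms
  if (length(deleted_maps)) {
    del_t <- m[sub_idx_of_map[deleted_maps]]
    out <- subset_mol(out, setdiff(seq_len(n_atoms(out)), del_t))
  }

  # 6. valence sanity check on touched atoms (indices shifted by deletion:
  # recheck every atom; molecules are small)
  bs <- mol_bondsum(out)
  for (i in seq_len(n_atoms(out))) {
    cap <- max_valence(out$atoms$symbol[i], out$atoms$charge[i])
    if (ceiling(bs[i]) + out$atoms$hcount[i] > cap) {
      warning(sprintf("discarding match: valence overflow at %s (%d bonds + %dH > %s)",
                      out$atoms$symbol[i], ceiling(bs[i]), out$atoms$hcount[i],
                      format(cap)), call. = FALSE)
      stop("invalid rewrite", call. = FALSE)
    }
  }

  frags <- mol_split(out)
  sort(vapply(frags, function(f) {
    canonical_smiles(strip_maps(f), stereo = rule$is_stereo)
  }, ""))
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else which_safe(x)
which_safe <- function(x) { x[is.na(x)] <- FALSE; x }
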