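# Canonical SMILES / SMARTS emission.
#
# Molecules are written fragment by fragment (connected components), each by
# depth-first traversal from its lowest-ranked atom visiting neighbours in
# canonical-rank order; fragments are joined with "." after sorting by their
# emitted string.  Three token dialects share the same traversal:
#   "smiles"          minimal-bracket concrete SMILES
#   "smarts_query"    substrate-side query atoms: element/aromaticity and
#                     charge always, D<n> (explicit degree) on interior
#                     atoms, H<n> on reacting atoms
#   "smarts_template" product-side template atoms: concrete bracket atoms
# Tetrahedral descriptors are emitted only for atoms whose full neighbour
# set (3 heavy + 1 H, or 4 heavy) is present in the fragment.

mol_extra_invariant <- function(mol) {
  if (!is.null(mol$atoms$reacting)) {
    paste(mol$atoms$reacting, mol$atoms$interior)
  } else NULL
}

# E/Z direction marks admit a global flip per conjugation cluster (flipping
# every mark around a double bond encodes the same geometry).  Canonical
# emission therefore re-orients each cluster so that its representative
# marked bond -- the one with the lowest (min rank, max rank) endpoint key --
# points "up" from its lower-ranked atom.
normalize_dirs <- function(mol, ranks) {
  b <- mol$bonds
  marked <- which(b$dir != 0L)
  if (!length(marked)) return(mol)
  complete <- stereo_double_bonds(mol)
  uf <- seq_along(marked)
  find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  for (k in complete) {
    ends <- c(b$a1[k], b$a2[k])
    touch <- which(b$a1[marked] %in% ends | b$a2[marked] %in% ends)
    if (length(touch) > 1L) {
      r0 <- find(touch[1])
      for (t in touch[-1]) uf[find(t)] <- r0
    }
  }
  roots <- vapply(seq_along(marked), find, 0L)
  for (cl in unique(roots)) {
    members <- marked[roots == cl]
    key <- vapply(members, function(k) {
      r <- sort(c(ranks[b$a1[k]], ranks[b$a2[k]]))
      r[1] * (n_atoms(mol) + 1L) + r[2]
    }, 0)
    rep_k <- members[which.min(key)]
    low_first <- ranks[b$a1[rep_k]] < ranks[b$a2[rep_k]]
    s <- if (low_first) b$dir[rep_k] else -b$dir[rep_k]
    if (s < 0L) mol$bonds$dir[members] <- -mol$bonds$dir[members]
  }
  mol
}

# Emit one *connected* molecule. Returns list(s = string, order = atom
# indices in emission order).
write_mol_single <- function(mol, ranks = NULL, format = "smiles",
                             with_maps = TRUE, with_stereo = TRUE) {
  n <- n_atoms(mol)
  if (is.null(ranks)) ranks <- canonical_ranks(mol, extra = mol_extra_invariant(mol))
  if (with_stereo) mol <- normalize_dirs(mol, ranks)
  adj <- mol_adj(mol)
  adjr <- lapply(adj, function(v) v[order(ranks[v])])
  deg <- mol_degree(mol)

  start <- which.min(ranks)
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  disc <- integer(n)
  children <- rep(list(integer()), n)
  cnt <- 0L
  stack_dfs <- list(list(u = start, nexti = 1L))
  visited[start] <- TRUE; cnt <- cnt + 1L; disc[start] <- cnt
  while (length(stack_dfs)) {
    fr <- stack_dfs[[length(stack_dfs)]]
    u <- fr$u
    nbrs <- adjr[[u]]
    if (fr$nexti > length(nbrs)) {
      stack_dfs[[length(stack_dfs)]] <- NULL
      next
    }
    v <- nbrs[fr$nexti]
    stack_dfs[[length(stack_dfs)]]$nexti <- fr$nexti + 1L
    if (!visited[v]) {
      visited[v] <- TRUE
      cnt <- cnt + 1L; disc[v] <- cnt
      parent[v] <- u
      children[[u]] <- c(children[[u]], v)
      stack_dfs[[length(stack_dfs) + 1L]] <- list(u = v, nexti = 1L)
    }
  }
  if (!all(visited)) stop("write_mol_single called on a disconnected molecule")

  # Ring-closure (back) edges: every bond that is not a tree edge.
  b <- mol$bonds
  is_tree <- vapply(seq_len(nrow(b)), function(k) {
    identical(parent[b$a1[k]], b$a2[k]) || identical(parent[b$a2[k]], b$a1[k])
  }, logical(1))
  back <- which(!is_tree)
  if (length(back)) {
    op <- vapply(back, function(k) min(disc[b$a1[k]], disc[b$a2[k]]), 0L)
    cl <- vapply(back, function(k) max(disc[b$a1[k]], disc[b$a2[k]]), 0L)
    back <- back[order(op, cl)]
  }
  ring_label <- function(i) if (i <= 9L) as.character(i) else sprintf("%%%02d", i)
  rings_at <- rep(list(integer()), n)   # back-edge seq numbers per atom
  for (i in seq_along(back)) {
    k <- back[i]
    rings_at[[b$a1[k]]] <- c(rings_at[[b$a1[k]]], i)
    rings_at[[b$a2[k]]] <- c(rings_at[[b$a2[k]]], i)
  }

  bond_sym <- function(u, v, krow) {
    ord <- b$order[krow]
    if (with_stereo && ord == "-" && b$dir[krow] != 0L) {
      s <- if (b$a1[krow] == u) b$dir[krow] else -b$dir[krow]
      return(if (s > 0L) "/" else "\\")
    }
    both_arom <- mol$atoms$aromatic[u] && mol$atoms$aromatic[v]
    switch(ord,
           "-" = if (both_arom) "-" else "",
           "=" = "=",
           "#" = "#",
           ":" = if (both_arom) "" else ":")
  }

  order_out <- integer(0)

  emit <- function(u) {
    order_out <<- c(order_out, u)
    ring_ids <- rings_at[[u]]
    ring_partners <- vapply(ring_ids, function(i) {
      k <- back[i]
      if (b$a1[k] == u) b$a2[k] else b$a1[k]
    }, 0L)
    # chirality frame in emission order
    chir_emitted <- with_stereo && mol$atoms$parity[u] != 0L &&
      mol$atoms$hcount[u] <= 1L &&
      (deg[u] + (mol$atoms$hcount[u] == 1L)) == 4L
    chir <- ""
    if (chir_emitted) {
      frame_em <- c(if (!is.na(parent[u])) parent[u],
                    if (mol$atoms$hcount[u] == 1L) 0L,
                    ring_partners,
                    children[[u]])
      frame_n <- parity_frame_idx(mol, u)
      p <- tryCatch(parity_rel(mol$atoms$parity[u], frame_n, frame_em),
                    error = function(e) 0L)
      chir <- c("", "@", "@@")[p + 1L]
      if (p == 0L) chir_emitted <- FALSE
    }
    token <- atom_token(mol, u, format, with_maps, chir, chir_emitted)
    ring_str <- ""
    for (i in ring_ids) {
      k <- back[i]
      pre <- ""
      if (disc[u] == max(disc[b$a1[k]], disc[b$a2[k]])) {
        v <- if (b$a1[k] == u) b$a2[k] else b$a1[k]
        pre <- bond_sym(u, v, k)
      }
      ring_str <- paste0(ring_str, pre, ring_label(i))
    }
    kids <- children[[u]]
    kid_str <- ""
    for (j in seq_along(kids)) {
      v <- kids[j]
      krow <- bond_between(mol, u, v)
      piece <- paste0(bond_sym(u, v, krow), emit(v))
      kid_str <- paste0(kid_str,
                        if (j < length(kids)) paste0("(", piece, ")") else piece)
    }
    paste0(token, ring_str, kid_str)
  }

  s <- emit(start)
  list(s = s, order = order_out)
}

atom_token <- function(mol, u, format, with_maps, chir, chir_emitted) {
  a <- mol$atoms
  sym <- a$symbol[u]
  disp <- if (a$aromatic[u]) tolower(sym) else sym
  mp <- if (with_maps && a$map[u] > 0L) paste0(":", a$map[u]) else ""
  charge_str <- function(ch) {
    if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
    else sprintf("%+d", ch)
  }
  if (format == "smarts_query") {
    parts <- paste0(disp, chir)
    parts <- paste0(parts, ";", if (a$charge[u] >= 0L) "+" else "",
                    a$charge[u])
    if (isTRUE(a$interior[u])) parts <- paste0(parts, ";D", mol_degree(mol)[u])
    if (isTRUE(a$reacting[u])) parts <- paste0(parts, ";H", a$hcount[u])
    return(paste0("[", parts, mp, "]"))
  }
  if (format == "smarts_template") {
    h <- if (a$hcount[u] > 0L) paste0("H", if (a$hcount[u] > 1L) a$hcount[u]) else ""
    return(paste0("[", disp, chir, h, charge_str(a$charge[u]), mp, "]"))
  }
  # concrete SMILES
  bs <- mol_bondsum(mol)[u]
  need <- (nzchar(mp)) || a$charge[u] != 0L || chir_emitted ||
    !(sym %in% c(ORGANIC_SUBSET, "*")) ||
    (a$aromatic[u] && !(tolower(sym) %in% AROMATIC_SYMBOLS)) ||
    (sym != "*" && a$hcount[u] != default_hcount(sym, bs)) ||
    (sym == "*" && a$hcount[u] != 0L)
  if (!need) return(disp)
  h <- if (a$hcount[u] > 0L) paste0("H", if (a$hcount[u] > 1L) a$hcount[u]) else ""
  paste0("[", disp, chir, h, charge_str(a$charge[u]), mp, "]")
}

# Write a possibly multi-fragment molecule; fragments sorted by string.
write_mol <- function(mol, format = "smiles", with_maps = TRUE,
                      with_stereo = TRUE) {
  if (n_atoms(mol) == 0L) return("")
  frags <- mol_split(mol)
  ss <- vapply(frags, function(f) {
    write_mol_single(f, format = format, with_maps = with_maps,
                     with_stereo = with_stereo)$s
  }, "")
  paste(sort(ss), collapse = ".")
}

#' Canonical SMILES of a molecule
#'
#' Re-writes a SMILES string (or internal molecule object) in the package's
#' canonical form: deterministic atom ordering by iterative neighbourhood
#' refinement, so any two atom-order permutations of the same molecule give
#' the same string.
#'
#' @param x a SMILES string or an internal molecule object.
#' @param stereo keep tetrahedral and E/Z descriptors (default TRUE).
#' @param maps keep atom-map numbers (default FALSE).
#' @return a character scalar.
#' @examples
#' canonical_smiles("OC(=O)C")          # acetic acid
#' canonical_smiles("C(C)(=O)O")        # same molecule, same string
#' @export
canonical_smiles <- function(x, stereo = TRUE, maps = FALSE) {
  mol <- if (is_mol(x)) x else parse_smiles(x)
  if (!stereo) mol <- stereo_strip(mol)
  write_mol(mol, format = "smiles", with_maps = maps, with_stereo = stereo)
}
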