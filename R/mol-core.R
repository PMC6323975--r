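# Molecular graph container used throughout the package.
#
# An rf_mol holds an atom table and a bond table:
#   atoms: symbol (element, "*" = wildcard), aromatic (flag), charge (e),
#          hcount (attached hydrogens), map (atom-map number, 0 = unmapped),
#          parity (tetrahedral descriptor normalised to neighbours in
#          ascending atom-index order with the implicit-H slot last;
#          0 = none, 1 = "@", 2 = "@@")
#   bonds: a1, a2 (atom indices, oriented as written), order in
#          {"-", "=", "#", ":"}, dir (directional single-bond mark for E/Z:
#          0 none, +1 "/", -1 "\", read from a1 towards a2)
#
# Pattern molecules (truncated rule fragments) carry two extra logical atom
# columns: reacting (atom belongs to the reaction center) and interior
# (every neighbour of the atom was retained at the current diameter).

BOND_ORDER_VALUE <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5)

new_mol <- function(atoms = NULL, bonds = NULL) {
  if (is.null(atoms)) {
    atoms <- data.frame(symbol = character(), aromatic = logical(),
                        charge = integer(), hcount = integer(),
                        map = integer(), parity = integer(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(bonds)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                        dir = integer(), stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds), class = "rf_mol")
}

is_mol <- function(x) inherits(x, "rf_mol")

n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.rf_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds> %s\n",
              n_atoms(x), nrow(x$bonds), write_mol(x)))
  invisible(x)
}

# Adjacency list (heavy atoms only; hydrogens live in hcount).
mol_adj <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(integer()), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

mol_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    d[b$a1[k]] <- d[b$a1[k]] + 1L
    d[b$a2[k]] <- d[b$a2[k]] + 1L
  }
  d
}

# Row index of the bond between i and j, or NA.
bond_between <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  if (length(k)) k[1] else NA_integer_
}

# Breadth-first bond-graph distance from a seed set (Inf = unreachable).
mol_dist <- function(mol, sources) {
  n <- n_atoms(mol)
  d <- rep(Inf, n)
  if (!length(sources) || n == 0L) return(d)
  adj <- mol_adj(mol)
  d[sources] <- 0
  queue <- as.integer(sources)
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in adj[[u]]) {
      if (d[v] > d[u] + 1) {
        d[v] <- d[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  d
}

# Connected-component id per atom.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      reach <- which(is.finite(mol_dist(mol, s)))
      comp[reach] <- cid
    }
  }
  comp
}

mol_split <- function(mol) {
  comp <- mol_components(mol)
  lapply(seq_len(max(comp, 0L)), function(k) subset_mol(mol, which(comp == k)))
}

# Sum of bond orders at each atom (aromatic counts 1.5).
mol_bondsum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    v <- BOND_ORDER_VALUE[[b$order[k]]]
    s[b$a1[k]] <- s[b$a1[k]] + v
    s[b$a2[k]] <- s[b$a2[k]] + v
  }
  s
}

# Normal valence set used for implicit hydrogen filling (organic subset).
default_valences <- function(symbol) {
  switch(symbol,
         B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
         F = 1, Cl = 1, Br = 1, I = 1, 0)
}

# Implicit H count a bare (unbracketed, uncharged) organic-subset atom gets.
default_hcount <- function(symbol, bondsum) {
  v <- default_valences(symbol)
  b <- ceiling(bondsum)
  v <- v[v >= b]
  if (!length(v)) return(0L)
  as.integer(v[1] - b)
}

# Upper bond-capacity bound used to discard chemically invalid rewrites.
max_valence <- function(symbol, charge) {
  base <- switch(symbol,
                 B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                 F = 1, Cl = 1, Br = 1, I = 1, Inf)
  if (!is.finite(base)) return(Inf)
  if (charge < 0) return(max(0, base - abs(charge)))
  if (charge > 0 && symbol %in% c("N", "O", "S", "P")) return(base + charge)
  if (charge > 0) return(max(0, base - charge))
  base
}

# Element counts including hydrogens, scaled by a stoichiometric factor.
mol_formula <- function(mol, stoich = 1L) {
  if (n_atoms(mol) == 0L) return(integer())
  tab <- table(mol$atoms$symbol) * stoich
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  h <- sum(mol$atoms$hcount) * stoich
  if (h > 0) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h
  counts[order(names(counts))]
}

add_formulas <- function(a, b) {
  keys <- sort(unique(c(names(a), names(b))))
  out <- vapply(keys, function(k) {
    (if (k %in% names(a)) a[[k]] else 0L) + (if (k %in% names(b)) b[[k]] else 0L)
  }, integer(1))
  out
}

# Net charge of one molecule.
mol_charge <- function(mol) sum(mol$atoms$charge)

# Keep a subset of atoms; indices are remapped, tetrahedral descriptors of
# atoms that lost a heavy neighbour are cleared (the parity has no meaning
# once an anchor is missing), and orphaned E/Z direction marks are swept.
subset_mol <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  old2new <- rep(NA_integer_, n_atoms(mol))
  old2new[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  sel <- !is.na(old2new[b$a1]) & !is.na(old2new[b$a2])
  bonds <- b[sel, , drop = FALSE]
  bonds$a1 <- old2new[bonds$a1]
  bonds$a2 <- old2new[bonds$a2]
  rownames(bonds) <- NULL
  out <- new_mol(atoms, bonds)
  olddeg <- mol_degree(mol)
  newdeg <- mol_degree(out)
  lost <- which(out$atoms$parity != 0L & newdeg < olddeg[keep])
  if (length(lost)) out$atoms$parity[lost] <- 0L
  clean_bond_dirs(out)
}

# Strip all stereochemical information (tetrahedral parities and E/Z marks).
stereo_strip <- function(mol) {
  mol$atoms$parity <- rep(0L, n_atoms(mol))
  if (nrow(mol$bonds)) mol$bonds$dir <- rep(0L, nrow(mol$bonds))
  mol
}

strip_maps <- function(mol) {
  mol$atoms$map <- rep(0L, n_atoms(mol))
  mol
}
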