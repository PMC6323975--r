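# Canonical atom ranking by iterative neighbourhood refinement.
#
# Initial invariant: (element, aromaticity, charge, H count, heavy degree,
# caller-supplied extras such as pattern-constraint flags).  Ranks are then
# refined with the sorted multiset of (bond order, neighbour rank) until the
# partition is stable; remaining ties are broken by artificially promoting
# the lowest-index member of the smallest tied class and re-refining.  Tied
# atoms that survive full refinement are (in ordinary chemical graphs)
# automorphic, so the tie-break does not affect the emitted string; the rare
# regular-graph counterexamples do not arise in this package's domain.
# Atom-map numbers are deliberately excluded so that canonical forms are
# mapping-independent.

canonical_ranks <- function(mol, extra = NULL) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  deg <- mol_degree(mol)
  if (is.null(extra)) extra <- rep("", n)
  key <- paste(mol$atoms$symbol, mol$atoms$aromatic, mol$atoms$charge,
               mol$atoms$hcount, deg, extra, sep = "|")
  r <- match(key, sort(unique(key)))

  b <- mol$bonds
  nb_atoms <- rep(list(integer()), n)
  nb_orders <- rep(list(character()), n)
  for (k in seq_len(nrow(b))) {
    nb_atoms[[b$a1[k]]] <- c(nb_atoms[[b$a1[k]]], b$a2[k])
    nb_orders[[b$a1[k]]] <- c(nb_orders[[b$a1[k]]], b$order[k])
    nb_atoms[[b$a2[k]]] <- c(nb_atoms[[b$a2[k]]], b$a1[k])
    nb_orders[[b$a2[k]]] <- c(nb_orders[[b$a2[k]]], b$order[k])
  }

  refine <- function(r) {
    repeat {
      keys <- vapply(seq_len(n), function(i) {
        nbr <- sprintf("%s%04d", nb_orders[[i]], r[nb_atoms[[i]]])
        paste(sprintf("%04d", r[i]), paste(sort(nbr), collapse = ","),
              sep = "|")
      }, "")
      nr <- match(keys, sort(unique(keys)))
      if (length(unique(nr)) == length(unique(r))) return(nr)
      r <- nr
    }
  }

  r <- refine(r)
  while (length(unique(r)) < n) {
    dup <- r[duplicated(r)]
    t <- min(dup)
    i <- which(r == t)[1]
    r <- ifelse(r > t | (r == t & seq_len(n) != i), r + 1L, r)
    # atom i keeps rank t alone; everything at or above t (except i) shifted
    r <- match(r, sort(unique(r)))
    r <- refine(r)
  }
  r
}
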