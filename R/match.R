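# Substructure (monomorphism) matching of rule patterns onto target
# molecules, with the pattern-atom constraint semantics used by the emitted
# SMARTS: element, aromaticity and formal charge always; explicit heavy
# degree on interior atoms; exact hydrogen count on reacting atoms; and, for
# stereo rules, tetrahedral parity / double-bond cis-trans compatibility.

# All embeddings of `pat` (possibly disconnected) into `tgt`.
# Returns a list of integer vectors m, with m[pattern index] = target index.
match_pattern <- function(pat, tgt, stereo = FALSE, max_matches = 1000L) {
  np <- n_atoms(pat)
  nt <- n_atoms(tgt)
  if (np == 0L || np > nt) return(list())
  pa <- pat$atoms
  ta <- tgt$atoms
  pdeg <- mol_degree(pat)
  tdeg <- mol_degree(tgt)
  interior <- if (!is.null(pa$interior)) pa$interior else rep(FALSE, np)
  reacting <- if (!is.null(pa$reacting)) pa$reacting else rep(FALSE, np)

  cand <- vector("list", np)
  for (i in seq_len(np)) {
    ok <- (pa$symbol[i] == "*" | ta$symbol == pa$symbol[i]) &
      ta$aromatic == pa$aromatic[i] &
      ta$charge == pa$charge[i] &
      tdeg >= pdeg[i]
    if (interior[i]) ok <- ok & tdeg == pdeg[i]
    if (reacting[i]) ok <- ok & ta$hcount == pa$hcount[i]
    cand[[i]] <- which(ok)
    if (!length(cand[[i]])) return(list())
  }

  padj <- mol_adj(pat)
  # bond order lookup tables keyed "i|j"
  bond_key <- function(b) {
    k1 <- paste(b$a1, b$a2, sep = "|")
    k2 <- paste(b$a2, b$a1, sep = "|")
    ord <- c(b$order, b$order)
    names(ord) <- c(k1, k2)
    ord
  }
  pord <- bond_key(pat$bonds)
  tord <- bond_key(tgt$bonds)

  # Placement order: per pattern component, start from the most constrained
  # atom and grow so each later atom touches an already-placed one.
  comp <- mol_components(pat)
  ordering <- integer(0)
  for (cid in unique(comp)) {
    atoms_c <- which(comp == cid)
    seed <- atoms_c[which.min(vapply(atoms_c, function(i) length(cand[[i]]), 0L))]
    placed <- seed
    rest <- setdiff(atoms_c, seed)
    while (length(rest)) {
      nxt <- rest[vapply(rest, function(i) any(padj[[i]] %in% placed), logical(1))]
      if (!length(nxt)) nxt <- rest  # disconnected within component: impossible
      pick <- nxt[which.min(vapply(nxt, function(i) length(cand[[i]]), 0L))]
      placed <- c(placed, pick)
      rest <- setdiff(rest, pick)
    }
    ordering <- c(ordering, placed)
  }

  results <- list()
  m <- rep(NA_integer_, np)
  used <- logical(nt)

  consistent <- function(p, t) {
    for (q in padj[[p]]) {
      if (!is.na(m[q])) {
        po <- pord[[paste(p, q, sep = "|")]]
        to <- tord[paste(t, m[q], sep = "|")]
        if (is.na(to) || to != po) return(FALSE)
      }
    }
    TRUE
  }

  recurse <- function(pos) {
    if (length(results) >= max_matches) return()
    if (pos > np) {
      if (!stereo || stereo_compatible(pat, tgt, m)) {
        results[[length(results) + 1L]] <<- m
      }
      return()
    }
    p <- ordering[pos]
    for (t in cand[[p]]) {
      if (!used[t] && consistent(p, t)) {
        m[p] <<- t
        used[t] <<- TRUE
        recurse(pos + 1L)
        m[p] <<- NA_integer_
        used[t] <<- FALSE
      }
    }
  }
  recurse(1L)
  results
}

# Tetrahedral and E/Z agreement between a fully-placed pattern and the
# target.  Pattern descriptors are only present on atoms/bonds whose full
# stereo environment was retained at extraction time, so each check can be
# anchored through the embedding.
stereo_compatible <- function(pat, tgt, m) {
  pa <- pat$atoms
  # tetrahedral
  for (i in which(pa$parity != 0L)) {
    t <- m[i]
    if (tgt$atoms$parity[t] == 0L) return(FALSE)
    if (tgt$atoms$hcount[t] != pa$hcount[i]) return(FALSE)
    frame_p <- parity_frame_idx(pat, i)
    heavy_p <- frame_p[frame_p != 0L]
    image <- c(m[heavy_p], if (0L %in% frame_p) 0L)
    frame_t <- parity_frame_idx(tgt, t)
    if (!setequal(image, frame_t)) return(FALSE)
    translated <- tryCatch(parity_rel(pa$parity[i], image, frame_t),
                           error = function(e) 0L)
    if (translated != tgt$atoms$parity[t]) return(FALSE)
  }
  # E/Z
  pb <- pat$bonds
  for (k in stereo_double_bonds(pat)) {
    a <- pb$a1[k]; b <- pb$a2[k]
    ra <- heavy_neighbors(pat, a, exclude = b)
    rb <- heavy_neighbors(pat, b, exclude = a)
    ra <- ra[vapply(ra, function(x) dir_toward(pat, x, a) != 0L, logical(1))][1]
    rb <- rb[vapply(rb, function(x) dir_toward(pat, x, b) != 0L, logical(1))][1]
    if (is.na(ra) || is.na(rb)) next
    rel_p <- ez_relation(pat, a, b, ra, rb)
    rel_t <- ez_relation(tgt, m[a], m[b], m[ra], m[rb])
    if (is.na(rel_t) || is.na(rel_p) || rel_t != rel_p) return(FALSE)
  }
  TRUE
}
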