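# Stereodescriptor bookkeeping.
#
# Tetrahedral parity is stored in a *normalised frame*: the neighbour list is
# taken in ascending atom-index order with the implicit-hydrogen slot last
# (sentinel 0).  Parity 1 means: looking from the first neighbour of that
# list, the remaining three appear counterclockwise ("@"); parity 2 is the
# mirror image ("@@").  Any re-ordering of the neighbour list flips the
# parity when the permutation is odd.
#
# E/Z configuration is carried by directional marks on single bonds flanking
# a double bond ("/" = +1, "\" = -1, read along the stored bond orientation
# a1 -> a2).  The *relation* of a double bond a=b w.r.t. reference
# substituents x (on a) and y (on b) is sign(x->a) * sign(b->y):
# +1 = trans (E-like), -1 = cis (Z-like).

perm_sign <- function(p) {
  s <- 1L
  n <- length(p)
  if (n < 2L) return(s)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) if (p[i] > p[j]) s <- -s
  }
  s
}

flip_parity <- function(parity) {
  if (parity == 0L) 0L else 3L - parity
}

# Parity expressed in frame A, re-expressed in frame B (both orderings of
# the same identifiers; the implicit-H sentinel must appear in both or
# neither).
parity_rel <- function(parity, frame_a, frame_b) {
  if (parity == 0L) return(0L)
  stopifnot(length(frame_a) == length(frame_b))
  p <- match(frame_b, frame_a)
  if (anyNA(p)) stop("incompatible stereo frames")
  if (perm_sign(p) == 1L) parity else flip_parity(parity)
}

# The stored (index-normalised) frame of atom i: heavy neighbours ascending,
# implicit-H sentinel (0) last when the atom carries a hydrogen.
parity_frame_idx <- function(mol, i, adj = NULL) {
  nb <- if (is.null(adj)) {
    b <- mol$bonds
    c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  } else adj[[i]]
  frame <- sort(nb)
  if (mol$atoms$hcount[i] > 0L) frame <- c(frame, 0L)
  frame
}

# Parity of atom i re-normalised so neighbours are ordered by their atom-map
# number (H sentinel last).  NA when the descriptor cannot be anchored
# (unmapped or duplicated neighbour maps) -- callers treat that as
# unperceivable stereo.
parity_by_map <- function(mol, i) {
  par <- mol$atoms$parity[i]
  if (par == 0L) return(0L)
  frame <- parity_frame_idx(mol, i)
  heavy <- frame[frame != 0L]
  maps <- mol$atoms$map[heavy]
  if (any(maps == 0L) || anyDuplicated(maps)) return(NA_integer_)
  keys <- c(maps, if (0L %in% frame) Inf)
  frame_b <- frame[order(keys)]
  parity_rel(par, frame, frame_b)
}

# Directional sign from atom x towards atom a (0 when the bond carries no
# mark or does not exist).
dir_toward <- function(mol, x, a) {
  k <- bond_between(mol, x, a)
  if (is.na(k) || mol$bonds$dir[k] == 0L) return(0L)
  if (mol$bonds$a1[k] == x) mol$bonds$dir[k] else -mol$bonds$dir[k]
}

heavy_neighbors <- function(mol, i, exclude = integer()) {
  b <- mol$bonds
  nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  setdiff(nb, exclude)
}

# sign(x -> a) with fallback through the opposite substituent on a.
ez_arm_sign <- function(mol, x, a, partner) {
  s <- dir_toward(mol, x, a)
  if (s != 0L) return(s)
  others <- setdiff(heavy_neighbors(mol, a, exclude = partner), x)
  for (o in others) {
    so <- dir_toward(mol, o, a)
    if (so != 0L) return(-so)
  }
  0L
}

# Relation (+1 trans / -1 cis / NA undefined) of double bond a=b with respect
# to reference substituents ref_a (neighbour of a) and ref_b (neighbour of b).
ez_relation <- function(mol, a, b, ref_a, ref_b) {
  s1 <- ez_arm_sign(mol, ref_a, a, partner = b)
  s2 <- -ez_arm_sign(mol, ref_b, b, partner = a)  # orient b -> ref_b
  if (s1 == 0L || s2 == 0L) return(NA_integer_)
  as.integer(s1 * s2)
}

# Relation of double bond a=b keyed by atom maps: reference substituents are
# the lowest-mapped heavy neighbour on each end.  Returns list(rel, ref_map_a,
# ref_map_b) or NULL when no substituent exists; rel is NA when undefined.
ez_relation_by_map <- function(mol, a, b, ref_map_a = NULL, ref_map_b = NULL) {
  na <- heavy_neighbors(mol, a, exclude = b)
  nb <- heavy_neighbors(mol, b, exclude = a)
  if (!length(na) || !length(nb)) return(NULL)
  pick <- function(nbrs, want) {
    maps <- mol$atoms$map[nbrs]
    if (!is.null(want)) {
      hit <- nbrs[maps == want]
      if (!length(hit)) return(NA_integer_)
      return(hit[1])
    }
    if (any(maps > 0L)) nbrs[maps > 0L][which.min(maps[maps > 0L])] else nbrs[1]
  }
  ra <- pick(na, ref_map_a)
  rb <- pick(nb, ref_map_b)
  if (is.na(ra) || is.na(rb)) return(NULL)
  list(rel = ez_relation(mol, a, b, ra, rb),
       ref_map_a = mol$atoms$map[ra], ref_map_b = mol$atoms$map[rb])
}

# Double bonds that carry a *complete* E/Z specification: at least one
# direction-marked single bond on each end.
stereo_double_bonds <- function(mol) {
  b <- mol$bonds
  dbl <- which(b$order == "=")
  keep <- logical(length(dbl))
  for (t in seq_along(dbl)) {
    k <- dbl[t]
    a1 <- b$a1[k]; a2 <- b$a2[k]
    arm <- function(a, partner) {
      any(vapply(heavy_neighbors(mol, a, exclude = partner),
                 function(x) dir_toward(mol, x, a) != 0L, logical(1)))
    }
    keep[t] <- arm(a1, a2) && arm(a2, a1)
  }
  dbl[keep]
}

# Remove direction marks that no longer flank a completely specified double
# bond (e.g. after truncation or a rewrite); iterated to a fixed point.
clean_bond_dirs <- function(mol) {
  b <- mol$bonds
  if (!nrow(b) || !any(b$dir != 0L)) return(mol)
  repeat {
    complete <- stereo_double_bonds(mol)
    anchors <- unique(unlist(lapply(complete, function(k) {
      c(mol$bonds$a1[k], mol$bonds$a2[k])
    })))
    marked <- which(mol$bonds$dir != 0L)
    drop <- marked[!(mol$bonds$a1[marked] %in% anchors |
                       mol$bonds$a2[marked] %in% anchors)]
    if (!length(drop)) break
    mol$bonds$dir[drop] <- 0L
  }
  mol
}
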