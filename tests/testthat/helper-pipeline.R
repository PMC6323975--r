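# Shared, lazily-memoised heavy fixtures: the toy corpus and the two rule
# datasets at the standard diameter grid are computed once per test run.

.rf_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .rf_cache)) assign(key, expr, envir = .rf_cache)
  get(key, envir = .rf_cache)
}

test_corpus <- function() memo("corpus", generate_corpus(42L, n_variants = 3L))

test_cofactors <- function() memo("cofactors", default_cofactors())

# stereo + non-stereo datasets at diameters 2..16, scored
test_datasets <- function() {
  memo("datasets", {
    corpus <- test_corpus()
    suppressWarnings(build_rule_datasets(
      corpus, diameters = seq(2, 16, by = 2),
      annotations = corpus_annotations(corpus)))
  })
}

# components of the accepted reactions, per stereo mode
test_components <- function(stereo) {
  memo(paste0("components_", stereo), {
    corpus <- test_corpus()
    pol <- rf_policy("strict", stereo = stereo)
    out <- list()
    for (rxn in corpus$reactions) {
      if (!validate_reaction(rxn, pol)$accepted) next
      ctr <- identify_reaction_center(rxn)
      if (stereo) ctr <- augment_stereo(rxn, ctr)
      out <- c(out, decompose(rxn, ctr, test_cofactors(), pol))
    }
    out
  })
}

# Apply an atom permutation to a molecule (perm[new_position] = old index),
# recomputing the index-normalised tetrahedral frames -- used to check that
# canonicalization is invariant under input atom order.
permute_mol <- function(mol, perm) {
  old2new <- order(perm)            # old index -> new index
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$a1 <- old2new[bonds$a1]
  bonds$a2 <- old2new[bonds$a2]
  out <- structure(list(atoms = atoms, bonds = bonds), class = "rf_mol")
  for (new_i in which(out$atoms$parity != 0L)) {
    old_i <- perm[new_i]
    frame_old <- ruleforge:::parity_frame_idx(mol, old_i)
    frame_old_in_new <- ifelse(frame_old == 0L, 0L, old2new[frame_old])
    frame_new <- ruleforge:::parity_frame_idx(out, new_i)
    out$atoms$parity[new_i] <-
      ruleforge:::parity_rel(mol$atoms$parity[old_i], frame_old_in_new, frame_new)
  }
  out
}

# Fixed pseudo-random permutations without touching the RNG stream.
fixed_perms <- function(n, k = 5L) {
  lapply(seq_len(k), function(s) {
    key <- (seq_len(n) * (7L + s) + s * 13L) %% (n * 4L + 1L)
    order(key, seq_len(n))
  })
}
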