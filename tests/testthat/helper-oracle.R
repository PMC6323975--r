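# Independent oracles.

# Brute-force reaction-center oracle: tabulates, per mapped atom, the full
# (element, charge, aromaticity, incident (order, neighbour-map) multiset)
# record on each side and diffs the tables; atoms present on one side only
# count as reacting.  Kept deliberately free of the package's environment
# machinery.
brute_force_center <- function(rxn) {
  tabulate_side <- function(mols) {
    recs <- character(0)
    for (m in mols) {
      b <- m$bonds
      for (i in seq_len(nrow(m$atoms))) {
        mp <- m$atoms$map[i]
        if (mp == 0L) next
        inc <- character(0)
        for (k in seq_len(nrow(b))) {
          if (b$a1[k] == i) j <- b$a2[k]
          else if (b$a2[k] == i) j <- b$a1[k]
          else next
          inc <- c(inc, paste0(b$order[k], ">", m$atoms$map[j]))
        }
        recs[as.character(mp)] <- paste(
          m$atoms$symbol[i], m$atoms$charge[i], m$atoms$aromatic[i],
          paste(sort(inc), collapse = "/"))
      }
    }
    recs
  }
  s <- tabulate_side(rxn$substrates)
  p <- tabulate_side(rxn$products)
  shared <- intersect(names(s), names(p))
  diff <- shared[s[shared] != p[shared]]
  lone <- c(setdiff(names(s), names(p)), setdiff(names(p), names(s)))
  sort(as.integer(unique(c(diff, lone))))
}

# Run a python/RDKit snippet; returns its stdout lines.  RDKit serves as the
# independent cheminformatics oracle for string validity and substructure
# matching.
run_python <- function(code) {
  res <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(res, collapse = "\n"))
  res
}
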