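# End-to-end driver: validation -> centre -> decomposition -> extraction ->
# canonical rule set, for one stereo dataset or both.

#' Extract the full rule set from a collection of reactions
#'
#' Runs the complete generation procedure for one dataset (stereo on or off,
#' as set in the policy): every reaction is validated, its reaction centre
#' identified (and stereo-augmented when the policy asks for it), decomposed
#' into direction-specific mono-substrate components, and truncated at every
#' policy diameter.  Degenerate rules (identical left and right patterns)
#' are suppressed and reported.
#'
#' @param reactions list of \code{rf_reaction} (e.g. from
#'   \code{\link{read_reactions_tsv}} or \code{\link{generate_corpus}}).
#' @param policy an \code{rf_policy}.
#' @param cofactors an \code{rf_cofactors} list (default: built-in list);
#'   ignored in DIY mode.
#' @return an \code{rf_ruleset}: list with \code{rules} (list of
#'   \code{rf_rule}), \code{table} (one row per rule), \code{components},
#'   \code{rejected} and \code{suppressed} data.frames, and the policy.
#' @export
extract_rules <- function(reactions, policy = rf_policy(),
                          cofactors = default_cofactors()) {
  if (inherits(reactions, "rf_corpus")) reactions <- reactions$reactions
  if (inherits(reactions, "rf_reaction")) reactions <- list(reactions)
  if (policy$mode == "diy" || !policy$cofactor_removal) cofactors <- NULL
  rules <- list()
  components <- list()
  rejected <- list()
  suppressed <- list()
  for (rxn in reactions) {
    v <- validate_reaction(rxn, policy)
    if (!v$accepted) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(reaction_id = rxn$reaction_id, reason = v$reason,
                   stringsAsFactors = FALSE)
      next
    }
    center <- identify_reaction_center(rxn)
    if (policy$stereo_enabled) center <- augment_stereo(rxn, center)
    comps <- decompose(rxn, center, cofactors, policy)
    components <- c(components, comps)
    for (comp in comps) {
      for (d in policy$diameters) {
        rule <- extract_rule(comp, d, stereo = policy$stereo_enabled)
        if (is.null(rule)) next
        if (rule$degenerate) {
          suppressed[[length(suppressed) + 1L]] <- data.frame(
            reaction_id = rule$reaction_id, substrate_id = rule$substrate_id,
            diameter = d, is_stereo = rule$is_stereo, stringsAsFactors = FALSE)
          next
        }
        rules[[length(rules) + 1L]] <- rule
      }
    }
  }
  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  tab <- if (length(rules)) {
    do.call(rbind, lapply(rules, function(r) data.frame(
      reaction_id = r$reaction_id, substrate_id = r$substrate_id,
      direction = r$direction, diameter = r$diameter, is_stereo = r$is_stereo,
      rule_smarts = r$rule_smarts, rule_smiles = r$rule_smiles,
      n_products = length(r$prod_patterns),
      ec = paste(r$ec, collapse = ";"), stringsAsFactors = FALSE)))
  } else {
    data.frame(reaction_id = character(), substrate_id = character(),
               direction = character(), diameter = numeric(),
               is_stereo = logical(), rule_smarts = character(),
               rule_smiles = character(), n_products = integer(),
               ec = character(), stringsAsFactors = FALSE)
  }
  ord <- order(tab$reaction_id, tab$substrate_id, tab$diameter, tab$is_stereo)
  structure(list(rules = rules[ord], table = tab[ord, , drop = FALSE],
                 components = components,
                 rejected = bind(rejected, data.frame(reaction_id = character(),
                                                      reason = character())),
                 suppressed = bind(suppressed, data.frame(
                   reaction_id = character(), substrate_id = character(),
                   diameter = numeric(), is_stereo = logical())),
                 policy = policy), class = "rf_ruleset")
}

#' @export
print.rf_ruleset <- function(x, ...) {
  cat(sprintf("<rule set: %d rules (%d distinct SMARTS) from %d components; %d rejected, %d degenerate suppressed>\n",
              nrow(x$table), length(unique(x$table$rule_smarts)),
              length(x$components), nrow(x$rejected), nrow(x$suppressed)))
  invisible(x)
}

#' Combine the stereo and non-stereo datasets for a reaction collection
#'
#' Convenience wrapper running \code{\link{extract_rules}} twice (stereo off
#' and on) with otherwise identical settings, then scoring both datasets.
#'
#' @param reactions reactions or corpus.
#' @param diameters diameter grid.
#' @param mode \code{"strict"} or \code{"diy"}.
#' @param cofactors cofactor list.
#' @param annotations named list reaction_id -> accessions (NULL = none).
#' @return list with elements \code{nonstereo} and \code{stereo}
#'   (scored \code{rf_ruleset}s).
#' @export
build_rule_datasets <- function(reactions, diameters = seq(2, 16, by = 2),
                                mode = "strict",
                                cofactors = default_cofactors(),
                                annotations = NULL) {
  out <- list()
  for (st in c(FALSE, TRUE)) {
    pol <- rf_policy(mode = mode, stereo = st, diameters = diameters)
    rs <- extract_rules(reactions, pol, cofactors)
    if (!is.null(annotations)) rs <- score_rules(rs, annotations)
    out[[if (st) "stereo" else "nonstereo"]] <- rs
  }
  out
}

#' Write a rule table as TSV
#'
#' Deterministic row order (reaction, substrate, diameter, stereo flag);
#' used for run-to-run reproducibility digests.
#'
#' @param ruleset an \code{rf_ruleset} (scored or not).
#' @param path output path.
#' @export
write_rules_tsv <- function(ruleset, path) {
  tab <- ruleset$table
  tab$diameter <- ifelse(is.finite(tab$diameter), tab$diameter, -1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Expected products of a rule at diameter d applied back to its *own* source
# substrate: every substrate-derived atom of each recorded product survives
# (the unmatched part of the substrate rides along), while incoming
# (co-substrate-derived) atoms survive only within the truncation sphere.
# Used by the round-trip tests as an independently-constructed oracle.
expected_products_at <- function(component, diameter, stereo = FALSE) {
  r <- diameter / 2
  smol <- component$substrate
  sub_maps_all <- smol$atoms$map[smol$atoms$map > 0L]
  dsub <- mol_dist(smol, component$sub_center_idx)
  kept_sub_maps <- smol$atoms$map[dsub <= r]
  kept_sub_maps <- kept_sub_maps[kept_sub_maps > 0L]
  out <- character(0)
  for (pi in seq_along(component$products)) {
    pmol <- component$products[[pi]]
    if (!stereo) pmol <- stereo_strip(pmol)
    maps <- pmol$atoms$map
    seeds <- product_center_idx(pmol, component$center)
    d <- mol_dist(pmol, seeds)
    incoming <- maps == 0L | !(maps %in% sub_maps_all)
    keep <- which(!incoming | d <= r)
    if (!length(keep)) next
    if (stereo) {
      # A rule only carries the stereo descriptors that survive inside its
      # own (truncated) product pattern; descriptors of atoms/bonds whose
      # stereo anchors fall outside that pattern cannot be regenerated, so
      # the expectation masks them the same way.
      k_pat <- sort(product_keep_idx(pmol, component$center, kept_sub_maps,
                                     sub_maps_all, r))
      pat_sub <- subset_mol(pmol, k_pat)
      pmol$atoms$parity[k_pat] <- pat_sub$atoms$parity
      in_pat <- seq_len(n_atoms(pmol)) %in% k_pat
      new_idx <- match(seq_len(n_atoms(pmol)), k_pat)
      for (k in seq_len(nrow(pmol$bonds))) {
        a1 <- pmol$bonds$a1[k]; a2 <- pmol$bonds$a2[k]
        if (in_pat[a1] && in_pat[a2]) {
          kk <- bond_between(pat_sub, new_idx[a1], new_idx[a2])
          pmol$bonds$dir[k] <- if (is.na(kk)) 0L else {
            if (pat_sub$bonds$a1[kk] == new_idx[a1]) pat_sub$bonds$dir[kk]
            else -pat_sub$bonds$dir[kk]
          }
        }
      }
      # double bonds inside the pattern whose E/Z did not survive truncation
      # also lose the flanking marks that sit partly outside the pattern
      complete_pat <- stereo_double_bonds(pat_sub)
      complete_orig <- stereo_double_bonds(pmol)
      for (k in intersect(which(pmol$bonds$order == "="), complete_orig)) {
        a1 <- pmol$bonds$a1[k]; a2 <- pmol$bonds$a2[k]
        if (!(in_pat[a1] && in_pat[a2])) next
        kk <- bond_between(pat_sub, new_idx[a1], new_idx[a2])
        if (!is.na(kk) && !(kk %in% complete_pat)) {
          flank <- which(pmol$bonds$order == "-" &
                           (pmol$bonds$a1 %in% c(a1, a2) |
                              pmol$bonds$a2 %in% c(a1, a2)))
          pmol$bonds$dir[flank] <- 0L
        }
      }
    }
    frag <- subset_mol(pmol, keep)
    pieces <- mol_split(frag)
    ss <- vapply(pieces, function(f) canonical_smiles(strip_maps(f), stereo = stereo), "")
    out <- c(out, rep(ss, component$prod_stoich[pi]))
  }
  sort(out)
}
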