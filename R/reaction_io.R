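# Parsing, normalisation and validation of atom-mapped reactions, cofactor
# lists and run policies.

#' Parse an atom-mapped reaction string
#'
#' Reads a reaction in the \code{substrates>>products} convention with
#' dot-separated species and bracketed atom-map numbers
#' (e.g. \code{"[CH3:1][OH:2]>>[CH3:1][O-:2]"}).  Repeated byte-identical
#' species on one side are aggregated into a stoichiometry count.
#'
#' @param text reaction string.
#' @param reaction_id opaque identifier attached to the reaction.
#' @param ec character vector of EC numbers (may be empty).
#' @param sequence_ids character vector of enzyme sequence accessions.
#' @param direction_label \code{"forward"} or \code{"reverse"}.
#' @return an object of class \code{rf_reaction}.
#' @export
parse_mapped_reaction <- function(text, reaction_id = "R1",
                                  ec = character(), sequence_ids = character(),
                                  direction_label = "forward") {
  sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    parse_error("reaction '%s' must contain exactly one '>>'", reaction_id)
  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(list(mols = list(), stoich = integer()))
    pieces <- strsplit(s, ".", fixed = TRUE)[[1]]
    tab <- table(factor(pieces, levels = unique(pieces)))
    mols <- lapply(names(tab), parse_smiles)
    list(mols = mols, stoich = as.integer(tab))
  }
  left <- parse_side(sides[1])
  right <- parse_side(sides[2])
  check_maps <- function(mols, side) {
    maps <- unlist(lapply(mols, function(m) m$atoms$map))
    maps <- maps[maps > 0L]
    if (anyDuplicated(maps)) {
      d <- unique(maps[duplicated(maps)])
      stop(sprintf("mapping error: atom map %s duplicated on %s side of %s",
                   paste(d, collapse = ","), side, reaction_id), call. = FALSE)
    }
    maps
  }
  check_maps(left$mols, "substrate")
  check_maps(right$mols, "product")
  structure(list(reaction_id = reaction_id,
                 substrates = left$mols, sub_stoich = left$stoich,
                 products = right$mols, prod_stoich = right$stoich,
                 ec = as.character(ec), sequence_ids = as.character(sequence_ids),
                 direction_label = direction_label),
            class = "rf_reaction")
}

#' @export
print.rf_reaction <- function(x, ...) {
  cat(sprintf("<reaction %s: %d substrate(s) >> %d product(s)>\n",
              x$reaction_id, length(x$substrates), length(x$products)))
  cat(" ", write_reaction(x), "\n")
  invisible(x)
}

# Serialise back to a mapped reaction string (canonical per-species form).
write_reaction <- function(rxn, canonical = TRUE) {
  side <- function(mols, stoich) {
    ss <- mapply(function(m, k) {
      s <- if (canonical) write_mol(m, with_maps = TRUE) else write_mol(m)
      rep(s, k)
    }, mols, stoich, SIMPLIFY = FALSE)
    paste(unlist(ss), collapse = ".")
  }
  paste0(side(rxn$substrates, rxn$sub_stoich), ">>",
         side(rxn$products, rxn$prod_stoich))
}

# Swap the two sides (used for reverse-direction decomposition and for the
# centre-symmetry property).
reverse_reaction <- function(rxn) {
  out <- rxn
  out$substrates <- rxn$products
  out$sub_stoich <- rxn$prod_stoich
  out$products <- rxn$substrates
  out$prod_stoich <- rxn$sub_stoich
  out$direction_label <- if (identical(rxn$direction_label, "forward"))
    "reverse" else "forward"
  out
}

#' Run policy for rule generation
#'
#' @param mode \code{"strict"} (balanced, fully characterised reactions only,
#'   cofactors removable) or \code{"diy"} (on-the-fly mode: every structure is
#'   a primary compound, unbalanced reactions are allowed, cofactor removal is
#'   forced off).
#' @param stereo logical; generate the stereochemistry-expressing dataset
#'   (tetrahedral R/S and double-bond E/Z changes join the reacting-atom set
#'   and descriptors are written into the rules).
#' @param diameters even bond-diameters at which rules are emitted; \code{Inf}
#'   means the untruncated (full-structure) rule.
#' @param cofactor_removal drop cofactor species before decomposition.
#' @return an object of class \code{rf_policy}.
#' @export
rf_policy <- function(mode = c("strict", "diy"), stereo = FALSE,
                      diameters = seq(2, 16, by = 2), cofactor_removal = TRUE) {
  mode <- match.arg(mode)
  diameters <- sort(unique(as.numeric(diameters)))
  fin <- diameters[is.finite(diameters)]
  if (any(fin < 0) || any(fin %% 2 != 0))
    stop("diameters must be even integers >= 0 (Inf allowed)", call. = FALSE)
  if (mode == "diy") cofactor_removal <- FALSE
  structure(list(mode = mode, stereo_enabled = isTRUE(stereo),
                 diameters = diameters,
                 cofactor_removal = isTRUE(cofactor_removal)),
            class = "rf_policy")
}

#' @export
print.rf_policy <- function(x, ...) {
  cat(sprintf("<policy: %s mode, stereo %s, diameters %s, cofactor removal %s>\n",
              x$mode, if (x$stereo_enabled) "on" else "off",
              paste(x$diameters, collapse = ","),
              if (x$cofactor_removal) "on" else "off"))
  invisible(x)
}

#' Load a cofactor structure list
#'
#' One SMILES per line; blank lines and \code{#} comments are ignored.
#' Entries are canonicalised (atom maps stripped) and de-duplicated;
#' membership tests against reaction species use canonical-structure
#' equality, never names.
#'
#' @param path file path.
#' @return character vector of canonical structure strings
#'   (class \code{rf_cofactors}).
#' @export
load_cofactors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- which(nzchar(lines))
  entries <- character(0)
  for (i in keep) {
    mol <- tryCatch(parse_smiles(lines[i]), error = function(e) {
      stop(sprintf("cofactor file %s line %d: %s", path, i, conditionMessage(e)),
           call. = FALSE)
    })
    entries <- c(entries, canonical_smiles(strip_maps(mol)))
  }
  structure(unique(entries), class = "rf_cofactors")
}

#' Built-in default cofactor list
#'
#' A desk-scale stand-in covering water, carbon dioxide, phosphate species,
#' common nucleotide cofactors (ATP/ADP/AMP, NAD(P)+/NAD(P)H) and a few ions.
#' Override it by supplying your own file to \code{\link{load_cofactors}}.
#'
#' @return object of class \code{rf_cofactors}.
#' @export
default_cofactors <- function() {
  path <- system.file("extdata", "cofactors.smi", package = "ruleforge")
  if (!nzchar(path)) stop("built-in cofactor list not found")
  load_cofactors(path)
}

is_cofactor <- function(mol, cofactors) {
  if (is.null(cofactors) || !length(cofactors)) return(FALSE)
  canonical_smiles(strip_maps(mol)) %in% cofactors
}

#' Validate an atom-mapped reaction against a run policy
#'
#' Applies the input filters used before rule generation: reactions with a
#' missing/empty side are rejected (\code{missing-structure}); reactions
#' containing wildcard R-group atoms or unmapped heavy atoms in strict mode
#' are rejected (\code{underspecified}); strict mode rejects reactions whose
#' element multisets (including hydrogens) differ between sides
#' (\code{unbalanced}; a charge imbalance alone only raises a warning); and
#' reactions that change nothing -- no bond, charge or (in stereo mode)
#' stereodescriptor change, e.g. passive transport -- are rejected
#' (\code{no-change}).  In DIY mode the balance check never fires.
#'
#' @param rxn an \code{rf_reaction}.
#' @param policy an \code{rf_policy}.
#' @return an \code{rf_verdict}: list with \code{accepted} (logical) and
#'   \code{reason} (one of \code{ok}, \code{no-change}, \code{unbalanced},
#'   \code{underspecified}, \code{missing-structure}).
#' @export
validate_reaction <- function(rxn, policy = rf_policy()) {
  verdict <- function(ok, reason) {
    structure(list(accepted = ok, reason = reason,
                   reaction_id = rxn$reaction_id), class = "rf_verdict")
  }
  if (!is.null(rxn$defect))
    return(verdict(FALSE, rxn$defect))
  if (!length(rxn$substrates) || !length(rxn$products))
    return(verdict(FALSE, "missing-structure"))
  all_mols <- c(rxn$substrates, rxn$products)
  if (any(vapply(all_mols, function(m) any(m$atoms$symbol == "*"), logical(1))))
    return(verdict(FALSE, "underspecified"))
  if (policy$mode == "strict") {
    unmapped <- vapply(all_mols, function(m) any(m$atoms$map == 0L), logical(1))
    if (any(unmapped))
      return(verdict(FALSE, "underspecified"))
    f <- function(mols, stoich) {
      out <- integer()
      for (i in seq_along(mols)) out <- add_formulas(out, mol_formula(mols[[i]], stoich[i]))
      out
    }
    fs <- f(rxn$substrates, rxn$sub_stoich)
    fp <- f(rxn$products, rxn$prod_stoich)
    if (!identical(fs, fp))
      return(verdict(FALSE, "unbalanced"))
    qs <- sum(vapply(seq_along(rxn$substrates), function(i)
      mol_charge(rxn$substrates[[i]]) * rxn$sub_stoich[i], numeric(1)))
    qp <- sum(vapply(seq_along(rxn$products), function(i)
      mol_charge(rxn$products[[i]]) * rxn$prod_stoich[i], numeric(1)))
    if (qs != qp)
      warning(sprintf("reaction %s: charge imbalance (%+d vs %+d)",
                      rxn$reaction_id, qs, qp), call. = FALSE)
  }
  center <- identify_reaction_center(rxn)
  if (policy$stereo_enabled) center <- augment_stereo(rxn, center)
  if (!length(center$reacting_maps))
    return(verdict(FALSE, "no-change"))
  verdict(TRUE, "ok")
}

#' @export
print.rf_verdict <- function(x, ...) {
  cat(sprintf("<%s: %s (%s)>\n", x$reaction_id,
              if (x$accepted) "accepted" else "rejected", x$reason))
  invisible(x)
}

#' Read a reaction table
#'
#' Tab-separated, one reaction per line:
#' \code{id<TAB>mapped-reaction<TAB>ec;ec<TAB>seq;seq} (the last two fields
#' optional).  \code{#} comment lines are skipped.  Rows whose reaction
#' string is empty or unparseable become stub reactions carrying a
#' \code{missing-structure} defect so that validation reports them instead
#' of the reader aborting the whole run.
#'
#' @param path TSV file path.
#' @return list of \code{rf_reaction} objects.
#' @export
read_reactions_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    id <- f[1]
    smi <- if (length(f) >= 2) f[2] else ""
    ec <- if (length(f) >= 3 && nzchar(f[3])) strsplit(f[3], ";")[[1]] else character()
    sq <- if (length(f) >= 4 && nzchar(f[4])) strsplit(f[4], ";")[[1]] else character()
    out[[i]] <- tryCatch(
      parse_mapped_reaction(smi, reaction_id = id, ec = ec, sequence_ids = sq),
      error = function(e) {
        structure(list(reaction_id = id, substrates = list(),
                       sub_stoich = integer(), products = list(),
                       prod_stoich = integer(), ec = ec, sequence_ids = sq,
                       direction_label = "forward",
                       defect = "missing-structure"),
                  class = "rf_reaction")
      })
  }
  out
}

# Write reactions in the same TSV dialect.
write_reactions_tsv <- function(reactions, path, raw_strings = NULL) {
  lines <- vapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    smi <- if (!is.null(raw_strings)) raw_strings[i] else write_reaction(r)
    paste(r$reaction_id, smi, paste(r$ec, collapse = ";"),
          paste(r$sequence_ids, collapse = ";"), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
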