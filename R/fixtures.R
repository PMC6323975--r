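# Deterministic toy reaction corpus.
#
# The corpus emulates, at desk scale, the reaction classes that matter for
# rule generation: an aminotransferase pair (keto/amino group swap between
# two substrates, 4 reacting atoms), a racemase and a cis-trans isomerase
# (rules exist only when stereochemistry is expressed), a hydratase with
# water as cofactor, a two-substrate addition, a passive-transport identity,
# an R-group reaction and an unbalanced reaction (rejection cases), plus
# ring-substituted analogs of the transamination substrate placed *outside*
# the maximal-diameter sphere of its reaction centre, so that low-diameter
# rules must match them and full-diameter rules must not.
#
# All reactions are hand-mapped; accepted ones are balanced and fully
# mapped.  Enzyme-sequence accessions are laid out to exercise the scoring
# closed forms: n = 10 (penalty 1), n = 1 (penalty 0), overlapping accession
# sets that merge when analog rules collapse onto the parent rule at low
# diameter, and an unannotated reaction (worst-case fallback).

TYR_MAPPED <- paste0("[NH2:1][C@@H:2]([CH2:3][c:4]1[cH:5][cH:6][c:7]([OH:8])",
                     "[cH:9][cH:10]1)[C:11](=[O:12])[OH:13]")
OXOGLUTARATE_MAPPED <- paste0("[O:14]=[C:15]([C:16](=[O:17])[OH:18])",
                              "[CH2:19][CH2:20][C:21](=[O:22])[OH:23]")
HPP_MAPPED <- paste0("[O:12]=[C:11]([OH:13])[C:2](=[O:14])[CH2:3][c:4]1",
                     "[cH:5][cH:6][c:7]([OH:8])[cH:9][cH:10]1")
GLU_MAPPED <- paste0("[NH2:1][C@@H:15]([C:16](=[O:17])[OH:18])[CH2:19]",
                     "[CH2:20][C:21](=[O:22])[OH:23]")

# para-substituent variants of the transamination pair (position is 6 bonds
# from the nearest reacting atom; the default diameter grid tops out at 16,
# i.e. radius 8, so the full rule sees the substituent while d <= 10 does
# not)
VARIANT_SUBSTITUENTS <- list(
  list(tag = "F",   from = "[c:7]([OH:8])", to = "[c:7]([F:8])"),
  list(tag = "H",   from = "[c:7]([OH:8])", to = "[cH:7]"),
  list(tag = "CH3", from = "[c:7]([OH:8])", to = "[c:7]([CH3:8])"),
  list(tag = "Cl",  from = "[c:7]([OH:8])", to = "[c:7]([Cl:8])"),
  list(tag = "Br",  from = "[c:7]([OH:8])", to = "[c:7]([Br:8])")
)

#' Generate the deterministic fixture corpus
#'
#' Builds the toy, pre-mapped reaction corpus used by the test-suite and the
#' acceptance script, together with a table of expected outcomes (verdict,
#' non-stereo centre size, component count, stereo-only flag).  The corpus
#' is a pure function of its arguments: the same seed always yields a
#' byte-identical corpus (the seed is recorded; nothing in the construction
#' is sampled).
#'
#' @param seed integer, recorded in the corpus.
#' @param n_variants number of substituted transamination analogs (1--5).
#' @return an \code{rf_corpus}: list with \code{seed}, \code{reactions}
#'   (list of \code{rf_reaction}), \code{table} (the TSV view) and
#'   \code{expected} (data.frame of per-reaction expectations).
#' @export
generate_corpus <- function(seed = 42L, n_variants = 3L) {
  stopifnot(n_variants >= 1L)
  if (n_variants > length(VARIANT_SUBSTITUENTS))
    stop(sprintf("at most %d analog variants are available",
                 length(VARIANT_SUBSTITUENTS)), call. = FALSE)
  rows <- list()
  add <- function(id, smi, ec, seqs, verdict, reason, center_size, n_comp,
                  stereo_only) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, smiles = smi, ec = ec, seqs = seqs, verdict = verdict,
      reason = reason, center_size = center_size, n_components = n_comp,
      stereo_only = stereo_only, stringsAsFactors = FALSE)
  }

  # (1) transamination, EC 2.6.1.5-like: 10 supporting sequences
  add("TX1", paste0(TYR_MAPPED, ".", OXOGLUTARATE_MAPPED, ">>",
                    HPP_MAPPED, ".", GLU_MAPPED),
      "2.6.1.5", paste(sprintf("S%02d", 1:10), collapse = ";"),
      "accepted", "ok", 4L, 4L, FALSE)

  # analogs of (1): substituent swapped at the ring para position
  variant_seqs <- c("S02;S11", "S12", "S13;S14", "S15", "S16")
  for (v in seq_len(n_variants)) {
    sub <- VARIANT_SUBSTITUENTS[[v]]
    tyr_v <- sub(sub$from, sub$to, TYR_MAPPED, fixed = TRUE)
    hpp_v <- sub(sub$from, sub$to, HPP_MAPPED, fixed = TRUE)
    add(sprintf("TX1_V%d", v),
        paste0(tyr_v, ".", OXOGLUTARATE_MAPPED, ">>", hpp_v, ".", GLU_MAPPED),
        "2.6.1.5", variant_seqs[v], "accepted", "ok", 4L, 4L, FALSE)
  }

  # (2) racemization (alanine racemase, EC 5.1.1.1): 1 sequence; the rule
  # exists only in the stereo dataset
  add("RC1", paste0("[NH2:1][C@@H:2]([CH3:3])[C:4](=[O:5])[OH:6]>>",
                    "[NH2:1][C@H:2]([CH3:3])[C:4](=[O:5])[OH:6]"),
      "5.1.1.1", "S20", "accepted", "ok", 0L, 2L, TRUE)

  # (3) cis-trans isomerization (maleate isomerase, EC 5.2.1.1)
  add("CT1", paste0("[OH:1][C:2](=[O:3])/[CH:4]=[CH:5]\\[C:6](=[O:7])[OH:8]>>",
                    "[OH:1][C:2](=[O:3])/[CH:4]=[CH:5]/[C:6](=[O:7])[OH:8]"),
      "5.2.1.1", "S21;S22", "accepted", "ok", 0L, 2L, TRUE)

  # (4) hydration with water as cofactor (fumarase, EC 4.2.1.2): the water
  # never seeds a component; its oxygen enters the product
  add("HY1", paste0("[OH:1][C:2](=[O:3])/[CH:4]=[CH:5]/[C:6](=[O:7])[OH:8].",
                    "[OH2:9]>>",
                    "[OH:1][C:2](=[O:3])[CH2:4][C@H:5]([OH:9])[C:6](=[O:7])[OH:8]"),
      "4.2.1.2", paste(sprintf("S%02d", 30:39), collapse = ";"),
      "accepted", "ok", 3L, 2L, FALSE)

  # (5) two-substrate addition (cyanohydrin formation, EC 4.1.2.10-like);
  # no sequence annotation -> worst-case scoring path
  add("CN1", paste0("[CH3:1][CH:2]=[O:3].[CH:4]#[N:5]>>",
                    "[CH3:1][CH:2]([OH:3])[C:4]#[N:5]"),
      "4.1.2.10", "", "accepted", "ok", 3L, 3L, FALSE)

  # (6) passive transport: nothing changes
  add("TR1", "[OH2:1]>>[OH2:1]", "", "", "rejected", "no-change", 0L, 0L, FALSE)

  # (7) R-group reaction: not fully characterised
  add("RG1", "[*:1][CH2:2][CH2:3][OH:4]>>[*:1][CH:2]([CH3:3])[OH:4]",
      "", "", "rejected", "underspecified", NA_integer_, 0L, FALSE)

  # (8) unbalanced (decarboxylation with the CO2 omitted): rejected in
  # strict mode, accepted in DIY mode
  add("UB1", paste0("[CH3:1][C:2](=[O:3])[C:4](=[O:5])[OH:6]>>",
                    "[CH3:1][CH:2]=[O:3]"),
      "4.1.1.1", "", "rejected", "unbalanced", 4L, 0L, FALSE)

  # (9) missing structure: empty product side
  add("MS1", "[CH4:1]>>", "", "", "rejected", "missing-structure",
      NA_integer_, 0L, FALSE)

  tab <- do.call(rbind, rows)
  reactions <- lapply(seq_len(nrow(tab)), function(i) {
    if (tab$id[i] == "MS1") {
      structure(list(reaction_id = "MS1", substrates = list(),
                     sub_stoich = integer(), products = list(),
                     prod_stoich = integer(), ec = character(),
                     sequence_ids = character(), direction_label = "forward",
                     defect = "missing-structure"), class = "rf_reaction")
    } else {
      parse_mapped_reaction(tab$smiles[i], reaction_id = tab$id[i],
                            ec = if (nzchar(tab$ec[i])) strsplit(tab$ec[i], ";")[[1]] else character(),
                            sequence_ids = if (nzchar(tab$seqs[i])) strsplit(tab$seqs[i], ";")[[1]] else character())
    }
  })
  structure(list(seed = as.integer(seed), reactions = reactions,
                 table = tab[, c("id", "smiles", "ec", "seqs")],
                 expected = tab[, c("id", "verdict", "reason", "center_size",
                                    "n_components", "stereo_only")]),
            class = "rf_corpus")
}

#' @export
print.rf_corpus <- function(x, ...) {
  cat(sprintf("<fixture corpus: %d reactions (seed %d)>\n",
              length(x$reactions), x$seed))
  print(x$expected, row.names = FALSE)
  invisible(x)
}

#' Write a corpus in the reaction-TSV dialect
#'
#' @param corpus an \code{rf_corpus}.
#' @param path output file.
#' @export
write_corpus_tsv <- function(corpus, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", corpus$table$id, corpus$table$smiles,
                   corpus$table$ec, corpus$table$seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Sequence-accession annotations of a corpus
#'
#' @param corpus an \code{rf_corpus}.
#' @return named list reaction_id -> character vector of accessions.
#' @export
corpus_annotations <- function(corpus) {
  out <- lapply(corpus$reactions, function(r) r$sequence_ids)
  names(out) <- vapply(corpus$reactions, function(r) r$reaction_id, "")
  out
}
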