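# SQLite persistence of rule sets.
#
# Schema (keys follow the published layout): the central `rules` table has
# primary key (reaction_id, substrate_id, diameter, isStereo) and references
# one row each in `smarts` and `smiles`; `smarts_smiles` links the two
# string tables bidirectionally; `rule_products` holds (product_id,
# stoichiometry) per rule against `chemical_species`; reaction
# meta-information lives in `reactions`, `chemical_species`,
# `reaction_substrates`, `reaction_products`, `reaction_ec` and
# `reaction_sequences`; `cofactor_log` and `run_metadata` record the run.
# The symbolic full-structure diameter (Inf) is stored as -1 (INTEGER
# column; documented sentinel).

diameter_to_db <- function(d) ifelse(is.finite(d), as.integer(d), -1L)
diameter_from_db <- function(d) ifelse(d < 0, Inf, as.numeric(d))

db_connect <- function(db) {
  if (inherits(db, "DBIConnection")) db
  else DBI::dbConnect(RSQLite::SQLite(), db)
}
db_disconnect <- function(con, db) {
  if (!inherits(db, "DBIConnection")) DBI::dbDisconnect(con)
}

DB_SCHEMA <- c(
  "CREATE TABLE smarts (smarts_id INTEGER PRIMARY KEY, smarts_string TEXT UNIQUE NOT NULL)",
  "CREATE TABLE smiles (smiles_id INTEGER PRIMARY KEY, smiles_string TEXT UNIQUE NOT NULL)",
  "CREATE TABLE smarts_smiles (smarts_id INTEGER NOT NULL REFERENCES smarts(smarts_id),
     smiles_id INTEGER NOT NULL REFERENCES smiles(smiles_id),
     PRIMARY KEY (smarts_id, smiles_id))",
  "CREATE TABLE chemical_species (species_id INTEGER PRIMARY KEY, smiles TEXT UNIQUE NOT NULL)",
  "CREATE TABLE reactions (reaction_id TEXT PRIMARY KEY, mapped_smiles TEXT,
     direction_label TEXT)",
  "CREATE TABLE reaction_substrates (reaction_id TEXT NOT NULL REFERENCES reactions(reaction_id),
     species_id INTEGER NOT NULL REFERENCES chemical_species(species_id),
     stoichiometry INTEGER NOT NULL)",
  "CREATE TABLE reaction_products (reaction_id TEXT NOT NULL REFERENCES reactions(reaction_id),
     species_id INTEGER NOT NULL REFERENCES chemical_species(species_id),
     stoichiometry INTEGER NOT NULL)",
  "CREATE TABLE reaction_ec (reaction_id TEXT NOT NULL REFERENCES reactions(reaction_id),
     ec TEXT NOT NULL)",
  "CREATE TABLE reaction_sequences (reaction_id TEXT NOT NULL REFERENCES reactions(reaction_id),
     sequence_id TEXT NOT NULL)",
  "CREATE TABLE rules (reaction_id TEXT NOT NULL,
     substrate_id TEXT NOT NULL,
     diameter INTEGER NOT NULL,
     isStereo BOOLEAN NOT NULL,
     direction TEXT NOT NULL,
     smarts_id INTEGER NOT NULL REFERENCES smarts(smarts_id),
     smiles_id INTEGER NOT NULL REFERENCES smiles(smiles_id),
     score REAL, n_sequences INTEGER, score_provenance TEXT,
     PRIMARY KEY (reaction_id, substrate_id, diameter, isStereo))",
  "CREATE TABLE rule_products (reaction_id TEXT NOT NULL,
     substrate_id TEXT NOT NULL,
     diameter INTEGER NOT NULL,
     isStereo BOOLEAN NOT NULL,
     product_id INTEGER NOT NULL REFERENCES chemical_species(species_id),
     stoichiometry INTEGER NOT NULL,
     FOREIGN KEY (reaction_id, substrate_id, diameter, isStereo)
       REFERENCES rules(reaction_id, substrate_id, diameter, isStereo))",
  "CREATE TABLE cofactor_log (smiles TEXT NOT NULL)",
  "CREATE TABLE run_metadata (key TEXT PRIMARY KEY, value TEXT)"
)

#' Export rule sets to an SQLite database
#'
#' Writes rules (with their scores), rule products, the SMARTS/SMILES string
#' tables with their bidirectional link, and reaction/species
#' meta-information into a single SQLite file.
#'
#' @param rulesets one scored \code{rf_ruleset} or a list of them (e.g. the
#'   stereo and non-stereo datasets of \code{\link{build_rule_datasets}}).
#' @param path output file; overwritten if present.
#' @param reactions optional list of \code{rf_reaction} (or an
#'   \code{rf_corpus}) supplying the meta tables.
#' @param cofactors optional \code{rf_cofactors} recorded in
#'   \code{cofactor_log}.
#' @param metadata optional named character vector for \code{run_metadata}.
#' @return the path, invisibly.
#' @export
export_db <- function(rulesets, path, reactions = NULL, cofactors = NULL,
                      metadata = NULL) {
  if (inherits(rulesets, "rf_ruleset")) rulesets <- list(rulesets)
  rules_list <- unlist(lapply(rulesets, `[[`, "rules"), recursive = FALSE)
  tabs <- lapply(rulesets, `[[`, "table")
  for (i in seq_along(tabs)) {
    if (is.null(tabs[[i]]$score)) {
      n <- nrow(tabs[[i]])
      tabs[[i]]$n_sequences <- rep(NA_integer_, n)
      tabs[[i]]$score <- rep(NA_real_, n)
      tabs[[i]]$score_provenance <- rep(NA_character_, n)
    }
  }
  tab <- do.call(rbind, tabs)

  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (stmt in DB_SCHEMA) DBI::dbExecute(con, stmt)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  DBI::dbBegin(con)
  ok <- FALSE
  tryCatch({
    key <- paste(tab$reaction_id, tab$substrate_id, tab$diameter,
                 tab$is_stereo, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop(sprintf("duplicate rule primary key: %s",
                   gsub("\r", " / ", dup)), call. = FALSE)
    }

    insert_strings <- function(table, col, idcol, values) {
      values <- sort(unique(values))
      if (length(values)) {
        DBI::dbExecute(con,
          sprintf("INSERT INTO %s (%s) VALUES (?)", table, col),
          params = list(values))
      }
      got <- DBI::dbGetQuery(con, sprintf("SELECT %s, %s FROM %s", idcol, col, table))
      structure(got[[idcol]], names = got[[col]])
    }
    smarts_ids <- insert_strings("smarts", "smarts_string", "smarts_id",
                                 tab$rule_smarts)
    smiles_ids <- insert_strings("smiles", "smiles_string", "smiles_id",
                                 tab$rule_smiles)
    link <- unique(data.frame(smarts_id = smarts_ids[tab$rule_smarts],
                              smiles_id = smiles_ids[tab$rule_smiles]))
    if (nrow(link))
      DBI::dbExecute(con,
        "INSERT INTO smarts_smiles (smarts_id, smiles_id) VALUES (?, ?)",
        params = list(link$smarts_id, link$smiles_id))

    # chemical species: full substrates/products plus rule product fragments
    species <- character(0)
    if (!is.null(reactions)) {
      if (inherits(reactions, "rf_corpus")) reactions <- reactions$reactions
      for (r in reactions) {
        species <- c(species,
                     vapply(r$substrates, function(m) canonical_smiles(strip_maps(m)), ""),
                     vapply(r$products, function(m) canonical_smiles(strip_maps(m)), ""))
      }
    }
    rule_prod_rows <- list()
    for (r in rules_list) {
      for (i in seq_along(r$prod_patterns)) {
        s <- canonical_smiles(strip_maps(r$prod_patterns[[i]]),
                              stereo = r$is_stereo)
        species <- c(species, s)
        rule_prod_rows[[length(rule_prod_rows) + 1L]] <- data.frame(
          reaction_id = r$reaction_id, substrate_id = r$substrate_id,
          diameter = diameter_to_db(r$diameter),
          isStereo = as.integer(r$is_stereo), smiles = s,
          stoichiometry = r$prod_stoich[i], stringsAsFactors = FALSE)
      }
    }
    species <- c(species, tab$substrate_id)
    species_ids <- insert_strings("chemical_species", "smiles", "species_id",
                                  species)

    if (nrow(tab))
      DBI::dbExecute(con, paste(
        "INSERT INTO rules (reaction_id, substrate_id, diameter, isStereo,",
        "direction, smarts_id, smiles_id, score, n_sequences, score_provenance)",
        "VALUES (?,?,?,?,?,?,?,?,?,?)"),
        params = list(tab$reaction_id, tab$substrate_id,
                      diameter_to_db(tab$diameter), as.integer(tab$is_stereo),
                      tab$direction,
                      unname(smarts_ids[tab$rule_smarts]),
                      unname(smiles_ids[tab$rule_smiles]),
                      tab$score, tab$n_sequences, tab$score_provenance))

    if (length(rule_prod_rows)) {
      rp <- do.call(rbind, rule_prod_rows)
      rp <- stats::aggregate(stoichiometry ~ reaction_id + substrate_id +
                               diameter + isStereo + smiles, data = rp, FUN = sum)
      DBI::dbExecute(con, paste(
        "INSERT INTO rule_products (reaction_id, substrate_id, diameter,",
        "isStereo, product_id, stoichiometry) VALUES (?,?,?,?,?,?)"),
        params = list(rp$reaction_id, rp$substrate_id, rp$diameter,
                      rp$isStereo, unname(species_ids[rp$smiles]),
                      rp$stoichiometry))
    }

    if (!is.null(reactions)) {
      DBI::dbExecute(con,
        "INSERT INTO reactions (reaction_id, mapped_smiles, direction_label) VALUES (?,?,?)",
        params = list(vapply(reactions, `[[`, "", "reaction_id"),
                      vapply(reactions, function(r) {
                        if (length(r$substrates) || length(r$products))
                          write_reaction(r) else ""
                      }, ""),
                      vapply(reactions, `[[`, "", "direction_label")))
      for (r in reactions) {
        add_side <- function(mols, stoich, table) {
          if (!length(mols)) return()
          sm <- vapply(mols, function(m) canonical_smiles(strip_maps(m)), "")
          DBI::dbExecute(con, sprintf(
            "INSERT INTO %s (reaction_id, species_id, stoichiometry) VALUES (?,?,?)",
            table),
            params = list(rep(r$reaction_id, length(sm)),
                          unname(species_ids[sm]), stoich))
        }
        add_side(r$substrates, r$sub_stoich, "reaction_substrates")
        add_side(r$products, r$prod_stoich, "reaction_products")
        if (length(r$ec))
          DBI::dbExecute(con,
            "INSERT INTO reaction_ec (reaction_id, ec) VALUES (?,?)",
            params = list(rep(r$reaction_id, length(r$ec)), r$ec))
        if (length(r$sequence_ids))
          DBI::dbExecute(con,
            "INSERT INTO reaction_sequences (reaction_id, sequence_id) VALUES (?,?)",
            params = list(rep(r$reaction_id, length(r$sequence_ids)),
                          r$sequence_ids))
      }
    }
    if (!is.null(cofactors) && length(cofactors))
      DBI::dbExecute(con, "INSERT INTO cofactor_log (smiles) VALUES (?)",
                     params = list(sort(unique(unclass(cofactors)))))
    meta <- c(schema_version = "1", metadata)
    DBI::dbExecute(con, "INSERT INTO run_metadata (key, value) VALUES (?,?)",
                   params = list(names(meta), unname(meta)))
    DBI::dbCommit(con)
    ok <- TRUE
  }, finally = if (!ok) DBI::dbRollback(con))
  invisible(path)
}

#' Integrity and referential checks of a rule database
#'
#' Runs SQLite's integrity check plus referential checks: no rules row
#' without its smarts/smiles strings, no orphan rule_products or
#' smarts_smiles rows.
#'
#' @param db path or connection.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
db_check <- function(db) {
  con <- db_connect(db)
  on.exit(db_disconnect(con, db), add = TRUE)
  ic <- DBI::dbGetQuery(con, "PRAGMA integrity_check")
  if (!identical(ic[[1]], "ok")) stop("SQLite integrity check failed")
  checks <- c(
    orphan_rule_smarts = "SELECT COUNT(*) FROM rules r LEFT JOIN smarts s ON s.smarts_id = r.smarts_id WHERE s.smarts_id IS NULL",
    orphan_rule_smiles = "SELECT COUNT(*) FROM rules r LEFT JOIN smiles s ON s.smiles_id = r.smiles_id WHERE s.smiles_id IS NULL",
    orphan_rule_products = "SELECT COUNT(*) FROM rule_products p LEFT JOIN rules r
       ON r.reaction_id = p.reaction_id AND r.substrate_id = p.substrate_id
       AND r.diameter = p.diameter AND r.isStereo = p.isStereo
       WHERE r.reaction_id IS NULL",
    orphan_product_species = "SELECT COUNT(*) FROM rule_products p LEFT JOIN chemical_species c ON c.species_id = p.product_id WHERE c.species_id IS NULL",
    orphan_link = "SELECT COUNT(*) FROM smarts_smiles l LEFT JOIN smarts s ON s.smarts_id = l.smarts_id LEFT JOIN smiles t ON t.smiles_id = l.smiles_id WHERE s.smarts_id IS NULL OR t.smiles_id IS NULL",
    ruleless_smarts = "SELECT COUNT(*) FROM smarts s LEFT JOIN rules r ON r.smarts_id = s.smarts_id WHERE r.smarts_id IS NULL")
  for (nm in names(checks)) {
    cnt <- DBI::dbGetQuery(con, checks[[nm]])[[1]]
    if (cnt != 0L) stop(sprintf("referential check '%s' failed (%d rows)", nm, cnt))
  }
  invisible(TRUE)
}

#' Query rules from a database, ranked by penalty
#'
#' Rows matching every supplied filter are returned sorted by penalty
#' ascending (best first), ties broken by the rule key.
#'
#' @param db path or connection.
#' @param ec EC-number prefix filter (e.g. \code{"2.6.1"} matches
#'   \code{2.6.1.x}).
#' @param reaction_id exact reaction id.
#' @param substrate substrate structure (SMILES; canonicalized and matched
#'   by structure-string equality).
#' @param min_diameter,max_diameter diameter range (Inf allowed).
#' @param is_stereo logical filter on the stereo flag.
#' @return data.frame of rules with scores.
#' @export
query_rules <- function(db, ec = NULL, reaction_id = NULL, substrate = NULL,
                        min_diameter = NULL, max_diameter = NULL,
                        is_stereo = NULL) {
  con <- db_connect(db)
  on.exit(db_disconnect(con, db), add = TRUE)
  sql <- paste(
    "SELECT r.reaction_id, r.substrate_id, r.diameter, r.isStereo,",
    "r.direction, sa.smarts_string AS rule_smarts,",
    "si.smiles_string AS rule_smiles, r.score, r.n_sequences,",
    "r.score_provenance FROM rules r",
    "JOIN smarts sa ON sa.smarts_id = r.smarts_id",
    "JOIN smiles si ON si.smiles_id = r.smiles_id")
  where <- character(0)
  params <- list()
  if (!is.null(ec)) {
    sql <- paste(sql, "JOIN reaction_ec e ON e.reaction_id = r.reaction_id")
    where <- c(where, "(e.ec = ? OR e.ec LIKE ?)")
    params <- c(params, list(ec, paste0(ec, ".%")))
  }
  if (!is.null(reaction_id)) {
    where <- c(where, "r.reaction_id = ?")
    params <- c(params, list(reaction_id))
  }
  if (!is.null(substrate)) {
    canon <- tryCatch(canonical_smiles(substrate),
                      error = function(e) stop(sprintf(
                        "malformed structure query: %s", conditionMessage(e)),
                        call. = FALSE))
    where <- c(where, "r.substrate_id = ?")
    params <- c(params, list(canon))
  }
  if (!is.null(min_diameter) && is.finite(min_diameter)) {
    where <- c(where, "(r.diameter < 0 OR r.diameter >= ?)")
    params <- c(params, list(as.integer(min_diameter)))
  }
  if (!is.null(max_diameter)) {
    if (is.finite(max_diameter)) {
      where <- c(where, "(r.diameter >= 0 AND r.diameter <= ?)")
      params <- c(params, list(as.integer(max_diameter)))
    }
  }
  if (!is.null(is_stereo)) {
    where <- c(where, "r.isStereo = ?")
    params <- c(params, list(as.integer(is_stereo)))
  }
  if (length(where)) sql <- paste(sql, "WHERE", paste(where, collapse = " AND "))
  sql <- paste(sql, "ORDER BY r.score ASC, r.reaction_id, r.substrate_id,",
               "r.diameter, r.isStereo")
  out <- DBI::dbGetQuery(con, sql, params = if (length(params)) params else NULL)
  unique(out)
}

#' Read the rules table back from a database
#'
#' @param db path or connection.
#' @return data.frame with one row per rule (diameter -1 decoded to Inf).
#' @export
db_rules <- function(db) {
  out <- query_rules(db)
  out$diameter <- diameter_from_db(out$diameter)
  out
}

#' Export a query result as CSV or JSON
#'
#' @param result data.frame from \code{\link{query_rules}}.
#' @param path output file.
#' @param format \code{"csv"} (RFC 4180, UTF-8, header row) or \code{"json"}
#'   (one object per rule).
#' @export
export_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(result, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(result, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

# Content digest of a database: md5 over the ordered dump of every table
# (used by the determinism checks; file-level bytes can differ through page
# layout, content must not).
db_digest <- function(db) {
  con <- db_connect(db)
  on.exit(db_disconnect(con, db), add = TRUE)
  tabs <- sort(DBI::dbListTables(con))
  dump <- character(0)
  for (t in tabs) {
    d <- DBI::dbReadTable(con, t)
    if (nrow(d)) d <- d[do.call(order, as.list(d)), , drop = FALSE]
    dump <- c(dump, t, utils::capture.output(utils::write.csv(d, stdout(),
                                                              row.names = FALSE)))
  }
  f <- tempfile()
  writeLines(dump, f)
  on.exit(unlink(f), add = TRUE)
  unname(tools::md5sum(f))
}
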