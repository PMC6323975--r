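# SQLite persistence: schema, integrity, queries, determinism.

test_that("export creates the named tables and passes integrity checks", {
  ds <- test_datasets()
  db <- withr::local_tempfile(fileext = ".sqlite")
  export_db(ds, db, reactions = test_corpus(), cofactors = test_cofactors(),
            metadata = c(seed = "42"))
  expect_true(db_check(db))
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  expect_true(all(c("rules", "rule_products", "smarts", "smiles",
                    "smarts_smiles", "reactions", "chemical_species",
                    "reaction_substrates", "reaction_products") %in% tabs))
  # primary key of the rules table
  pk <- DBI::dbGetQuery(con, "PRAGMA table_info(rules)")
  expect_equal(pk$name[pk$pk > 0][order(pk$pk[pk$pk > 0])],
               c("reaction_id", "substrate_id", "diameter", "isStereo"))
  expect_equal(pk$type[pk$name == "isStereo"], "BOOLEAN")
  # every rule has at least one product row
  orphans <- DBI::dbGetQuery(con, paste(
    "SELECT COUNT(*) AS n FROM rules r LEFT JOIN rule_products p ON",
    "p.reaction_id = r.reaction_id AND p.substrate_id = r.substrate_id AND",
    "p.diameter = r.diameter AND p.isStereo = r.isStereo",
    "WHERE p.product_id IS NULL"))
  expect_equal(orphans$n, 0L)
})

test_that("read-back is lossless for strings, flags, diameters and scores", {
  ds <- test_datasets()
  db <- withr::local_tempfile(fileext = ".sqlite")
  export_db(ds, db, reactions = test_corpus())
  back <- db_rules(db)
  orig <- rbind(ds$nonstereo$table, ds$stereo$table)
  expect_equal(nrow(back), nrow(orig))
  key <- function(d, st) paste(d$reaction_id, d$substrate_id, d$diameter, st)
  m <- match(key(orig, orig$is_stereo), key(back, as.logical(back$isStereo)))
  expect_false(anyNA(m))
  expect_equal(back$rule_smarts[m], orig$rule_smarts)
  expect_equal(back$rule_smiles[m], orig$rule_smiles)
  expect_equal(back$score[m], orig$score)
  expect_equal(back$n_sequences[m], orig$n_sequences)
})

test_that("duplicate rule keys are rejected, empty exports are valid", {
  ds <- test_datasets()
  dup <- ds$nonstereo
  dup2 <- list(dup, dup)          # same rules twice -> PK violation
  db <- withr::local_tempfile(fileext = ".sqlite")
  expect_error(export_db(dup2, db), "duplicate rule primary key")

  empty <- extract_rules(list(), rf_policy())
  db2 <- withr::local_tempfile(fileext = ".sqlite")
  export_db(empty, db2)
  expect_true(db_check(db2))
  expect_equal(nrow(db_rules(db2)), 0L)
})

test_that("queries filter by key, EC prefix, structure and diameter, ranked by penalty", {
  ds <- test_datasets()
  db <- withr::local_tempfile(fileext = ".sqlite")
  export_db(ds, db, reactions = test_corpus())

  all_rc <- query_rules(db, reaction_id = "RC1")
  expect_true(all(all_rc$reaction_id == "RC1"))
  expect_equal(nrow(all_rc), sum(test_datasets()$stereo$table$reaction_id == "RC1"))

  q <- query_rules(db, ec = "2.6.1", min_diameter = 6)
  expect_true(all(q$diameter >= 6))
  expect_true(all(grepl("^TX1", q$reaction_id)))
  expect_false(is.unsorted(q$score))

  q2 <- query_rules(db, substrate = "OC(=O)C[C@H](O)C(=O)O")  # the malate fixture
  expect_true(all(q2$reaction_id == "HY1"))
  expect_gt(nrow(q2), 0L)
  expect_equal(nrow(query_rules(db, substrate = "CCCC")), 0L)
  expect_error(query_rules(db, substrate = "C((C"), "malformed structure")

  # ranking is a total order: penalty, then the rule key
  expect_false(is.unsorted(query_rules(db)$score))

  # CSV / JSON export round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  export_results(q, f, "csv")
  expect_equal(nrow(utils::read.csv(f)), nrow(q))
  fj <- withr::local_tempfile(fileext = ".json")
  export_results(q, fj, "json")
  expect_equal(length(jsonlite::read_json(fj)), nrow(q))
})

test_that("repeated runs give identical rule TSVs and database digests", {
  ds1 <- test_datasets()
  corpus2 <- generate_corpus(42L, n_variants = 3L)
  ds2 <- suppressWarnings(build_rule_datasets(
    corpus2, diameters = seq(2, 16, by = 2),
    annotations = corpus_annotations(corpus2)))
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_rules_tsv(ds1$nonstereo, t1)
  write_rules_tsv(ds2$nonstereo, t2)
  expect_identical(readLines(t1), readLines(t2))

  db1 <- withr::local_tempfile(fileext = ".sqlite")
  db2 <- withr::local_tempfile(fileext = ".sqlite")
  export_db(ds1, db1, reactions = test_corpus(), cofactors = test_cofactors())
  export_db(ds2, db2, reactions = corpus2, cofactors = test_cofactors())
  expect_identical(ruleforge:::db_digest(db1), ruleforge:::db_digest(db2))
})
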