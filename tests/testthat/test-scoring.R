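# Penalty scoring: log10 of the number of distinct supporting sequences.

test_that("closed forms and the accession union over collapsed rules", {
  ds <- test_datasets()
  ns <- ds$nonstereo$table
  st <- ds$stereo$table

  # n = 10 distinct sequences -> penalty 1 (transamination at full grid top)
  tx16 <- ns[ns$reaction_id == "TX1" & ns$diameter == 16, ]
  expect_true(all(tx16$n_sequences == 10L))
  expect_true(all(tx16$score == 1))
  expect_true(all(tx16$score_provenance == "computed"))

  # n = 1 -> penalty 0 (racemase, stereo dataset only)
  rc <- st[st$reaction_id == "RC1", ]
  expect_gt(nrow(rc), 0L)
  expect_true(all(rc$n_sequences == 1L))
  expect_true(all(rc$score == 0))

  # at low diameter the parent and analog rules collapse onto one canonical
  # rule, so n is the union of their accession sets:
  # {S01..S10} u {S02,S11} u {S12} u {S13,S14} = 14
  fam <- ns[ns$diameter == 2 & grepl("^TX1", ns$reaction_id), ]
  expect_true(all(fam$n_sequences == 14L))
  expect_equal(unique(fam$score), log10(14))
  # while at diameter 16 the analogs separate and keep their own counts
  v2 <- ns[ns$diameter == 16 & ns$reaction_id == "TX1_V2", ]
  expect_true(all(v2$n_sequences == 1L))

  # unannotated reaction: worst observed penalty at that diameter
  cn <- ns[ns$reaction_id == "CN1", ]
  expect_true(all(cn$score_provenance == "worst-case"))
  for (d in unique(cn$diameter)) {
    worst <- max(ns$score[ns$diameter == d & ns$score_provenance == "computed"])
    expect_equal(unique(cn$score[cn$diameter == d]), worst)
  }

  # penalties are never negative and never decrease with extra sequences
  expect_true(all(ns$score >= 0) && all(st$score >= 0))
})

test_that("adding sequences never lowers a rule's penalty", {
  ds <- test_datasets()
  corpus <- test_corpus()
  ann <- corpus_annotations(corpus)
  # extend only reactions that already have annotations: an unannotated rule
  # sits on the worst-case fallback, and giving it its first annotations can
  # legitimately *lower* its penalty below that ceiling
  ann_more <- lapply(ann, function(a)
    if (length(a)) unique(c(a, paste0("EXTRA", 1:3))) else a)
  s1 <- score_rules(ds$nonstereo, ann)$table
  s2 <- score_rules(ds$nonstereo, ann_more)$table
  expect_true(all(s2$score >= s1$score - 1e-12))
})

test_that("custom rules inherit stored scores or fall back to the worst case", {
  ds <- test_datasets()
  db <- withr::local_tempfile(fileext = ".sqlite")
  export_db(ds, db, reactions = test_corpus(), cofactors = test_cofactors())

  # fixed point: a rule used to build the db returns its own stored score
  i <- which(ds$stereo$table$reaction_id == "RC1")[1]
  rule <- ds$stereo$rules[[i]]
  sc <- score_custom_rule(rule, db)
  expect_equal(sc$provenance, "inherited")
  expect_equal(sc$penalty, ds$stereo$table$score[i])

  # novel rule: worst stored penalty at the considered diameter
  novel <- rule
  novel$rule_smarts <- "[N;+0;H2:1][C;+0;H3:2]>>[N;+0;H1:1]=[C;+0;H2:2]"
  sc2 <- score_custom_rule(novel, db)
  expect_equal(sc2$provenance, "worst-case")
  all_scores <- db_rules(db)
  expect_equal(sc2$penalty,
               max(all_scores$score[all_scores$diameter == rule$diameter]))

  # diameter absent from the reference: an error, not a guess
  novel$diameter <- 20
  expect_error(score_custom_rule(novel, db), "no reference scores")
})
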