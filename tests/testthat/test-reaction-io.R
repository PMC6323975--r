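# Reaction parsing, validation filters and cofactor handling.

test_that("mapped reactions parse with aggregated stoichiometry and map checks", {
  r <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1][O-:2]")
  expect_length(r$substrates, 1L)
  expect_length(r$products, 1L)
  expect_setequal(unlist(lapply(r$substrates, function(m) m$atoms$map)), 1:2)

  r2 <- parse_mapped_reaction("[C:1](=[O:2])C.[NH3:3]>>[C:1](=[NH2:3])C.[OH2:2]")
  expect_length(r2$substrates, 2L)
  expect_length(r2$products, 2L)
  expect_setequal(unlist(lapply(r2$substrates, function(m) m$atoms$map)), 0:3)

  expect_error(
    parse_mapped_reaction("[CH3:1][OH:2].[CH3:1]O>>[CH3:1][O-:2]"),
    "map 1 duplicated on substrate")
})

test_that("serialise / re-parse is a canonical round trip", {
  corpus <- test_corpus()
  for (rxn in corpus$reactions) {
    if (!is.null(rxn$defect)) next
    s1 <- ruleforge:::write_reaction(rxn)
    r2 <- parse_mapped_reaction(s1, reaction_id = rxn$reaction_id)
    expect_identical(ruleforge:::write_reaction(r2), s1, info = rxn$reaction_id)
  }
})

test_that("validation applies the input filters in both modes", {
  strict <- rf_policy("strict")
  diy <- rf_policy("diy")

  transport <- parse_mapped_reaction("[OH2:1]>>[OH2:1]", "T")
  expect_equal(validate_reaction(transport, strict)$reason, "no-change")

  rgroup <- parse_mapped_reaction("[*:1][CH2:2][OH:3]>>[*:1][CH:2]=[O:3]", "R")
  expect_equal(validate_reaction(rgroup, strict)$reason, "underspecified")

  # C2 -> C1: rejected in strict mode, accepted on-the-fly
  shrink <- parse_mapped_reaction("[CH3:1][CH3:2]>>[CH4:1]", "U")
  expect_equal(validate_reaction(shrink, strict)$reason, "unbalanced")
  expect_true(validate_reaction(shrink, diy)$accepted)

  # verdicts are pure: same input, same verdict
  expect_identical(validate_reaction(transport, strict),
                   validate_reaction(transport, strict))

  # element-balanced but charge-imbalanced: warning, not rejection, and the
  # strict verdict agrees with the diy verdict
  redox <- parse_mapped_reaction("[Fe+2:1][OH:2]>>[Fe+3:1][OH:2]", "OK")
  expect_warning(v1 <- validate_reaction(redox, strict), "charge imbalance")
  v2 <- validate_reaction(redox, diy)
  expect_equal(v1$reason, v2$reason)
  expect_true(v1$accepted)
})

test_that("diy policy forces cofactor removal off and allows odd inputs", {
  p <- rf_policy("diy", cofactor_removal = TRUE)
  expect_false(p$cofactor_removal)
  expect_error(rf_policy(diameters = c(1, 2)), "even")
  expect_identical(rf_policy(diameters = c(4, 2, 4))$diameters, c(2, 4))
})

test_that("cofactor lists canonicalise, deduplicate and honour comments", {
  f <- withr::local_tempfile(lines = c(
    "O          # water", "", "# a comment", "O=C=O", "OCO>>bad" , "O"))
  expect_error(load_cofactors(f), "line 5")
  f2 <- withr::local_tempfile(lines = c("O  # water", "C(=O)=O", "O"))
  cof <- load_cofactors(f2)
  expect_length(cof, 2L)
  expect_true(canonical_smiles("O") %in% cof)
  f3 <- withr::local_tempfile(lines = character(0))
  expect_length(load_cofactors(f3), 0L)
})

test_that("reaction tables read back with annotations and defect stubs", {
  f <- withr::local_tempfile(lines = c(
    "# corpus",
    "A\t[CH3:1][OH:2]>>[CH3:1][O-:2]\t1.1.1.1;2.2.2.2\tP1;P2",
    "B\t[CH4:1]>>",
    "C\tnot_a_smiles>>either"))
  rs <- read_reactions_tsv(f)
  expect_length(rs, 3L)
  expect_equal(rs[[1]]$ec, c("1.1.1.1", "2.2.2.2"))
  expect_equal(rs[[1]]$sequence_ids, c("P1", "P2"))
  expect_equal(validate_reaction(rs[[2]], rf_policy())$reason, "missing-structure")
  expect_equal(validate_reaction(rs[[3]], rf_policy())$reason, "missing-structure")
})
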