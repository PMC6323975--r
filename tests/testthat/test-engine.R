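# Decomposition, rule extraction, canonicalization and application.

test_that("decomposition yields one component per non-cofactor species and direction", {
  corpus <- test_corpus()
  cof <- test_cofactors()
  pol <- rf_policy("strict")
  byid <- function(id) corpus$reactions[[which(corpus$expected$id == id)]]

  # 2 substrates + 2 products -> 4 components
  tx1 <- byid("TX1")
  comps <- decompose(tx1, identify_reaction_center(tx1), cof, pol)
  expect_length(comps, 4L)
  expect_equal(sum(vapply(comps, `[[`, "", "direction") == "forward"), 2L)

  # hydration with water as cofactor: 1 forward + 1 reverse, and the water
  # never seeds a component
  hy <- byid("HY1")
  comps_hy <- decompose(hy, identify_reaction_center(hy), cof, pol)
  expect_length(comps_hy, 2L)
  subs <- vapply(comps_hy, function(cp)
    canonical_smiles(ruleforge:::strip_maps(cp$substrate)), "")
  expect_false(canonical_smiles("O") %in% subs)
  # the dropped water is logged on the reverse component
  rev <- comps_hy[[which(vapply(comps_hy, `[[`, "", "direction") == "reverse")]]
  expect_equal(rev$removed_cofactors, canonical_smiles("O"))

  # every retained product shares a mapped atom with its substrate
  for (cp in comps) {
    smaps <- cp$substrate$atoms$map
    for (p in cp$products)
      expect_true(any(p$atoms$map %in% smaps[smaps > 0L]))
  }

  # all-cofactor substrate side is an error
  expect_error(suppressWarnings(
    decompose(parse_mapped_reaction("[OH2:9]>>[OH2:9]", "WW"),
              structure(list(reacting_maps = 9L), class = "rf_center"),
              cof, pol)),
    "no primary substrate")
})

test_that("diameter truncation keeps nested atom sets down to the bare center", {
  comp <- test_components(FALSE)[[1]]   # TX1 forward, tyrosine substrate
  sizes <- integer(0)
  prev_maps <- NULL
  for (d in c(0, 2, 4, 8, 16, Inf)) {
    rule <- extract_rule(comp, d, stereo = FALSE)
    maps_d <- sort(rule$sub_pattern$atoms$map)
    sizes <- c(sizes, ruleforge:::n_atoms(rule$sub_pattern))
    if (!is.null(prev_maps)) expect_true(length(prev_maps) <= length(maps_d))
    prev_maps <- maps_d
  }
  expect_true(!is.unsorted(sizes))
  # diameter 0: exactly the reacting atoms of the substrate
  r0 <- extract_rule(comp, 0, stereo = FALSE)
  expect_equal(ruleforge:::n_atoms(r0$sub_pattern),
               length(intersect(comp$substrate$atoms$map,
                                comp$center$reacting_maps)))
  expect_error(extract_rule(comp, 3), "even")
  expect_error(extract_rule(comp, -2), "even")
})

test_that("canonicalization is deterministic, permutation-invariant and idempotent", {
  comp <- test_components(FALSE)[[1]]
  r1 <- extract_rule(comp, 4, stereo = FALSE)
  r2 <- extract_rule(comp, 4, stereo = FALSE)
  expect_identical(r1$rule_smarts, r2$rule_smarts)
  expect_identical(r1$rule_smiles, r2$rule_smiles)
  expect_identical(canonicalize_rule(r1)$rule_smarts, r1$rule_smarts)

  # permuting the input atom order of the reaction leaves the rule unchanged
  rxn <- test_corpus()$reactions[[1]]
  perm_smiles <- ruleforge:::write_reaction(rxn)     # canonical re-serialisation
  rxn2 <- parse_mapped_reaction(perm_smiles, "TX1")
  ctr2 <- identify_reaction_center(rxn2)
  comps2 <- decompose(rxn2, ctr2, test_cofactors(), rf_policy("strict"))
  sub_id <- r1$substrate_id
  comp2 <- comps2[[which(vapply(comps2, function(cp)
    canonical_smiles(ruleforge:::strip_maps(cp$substrate)), "") == sub_id &
    vapply(comps2, `[[`, "", "direction") == "forward")]]
  r1b <- extract_rule(comp2, 4, stereo = FALSE)
  expect_identical(r1b$rule_smarts, r1$rule_smarts)
})

test_that("applying a rule back to its source substrate regenerates the products", {
  # spot checks here; the full diameter sweep lives in the acceptance tests
  for (stereo in c(FALSE, TRUE)) {
    comps <- test_components(stereo)
    for (comp in comps[c(1, length(comps))]) {
      for (d in c(2, Inf)) {
        rule <- extract_rule(comp, d, stereo = stereo)
        if (is.null(rule) || rule$degenerate) next
        expected <- ruleforge:::expected_products_at(comp, d, stereo = stereo)
        got <- suppressWarnings(apply_rule(rule, comp$substrate))
        expect_true(any(vapply(got, function(g) identical(sort(g), expected),
                               logical(1))),
                    info = sprintf("%s %s d=%s stereo=%s",
                                   comp$parent_reaction_id, comp$direction,
                                   format(d), stereo))
      }
    }
  }
})

test_that("rules do not match unrelated substrates", {
  comp <- test_components(FALSE)[[1]]
  rule <- extract_rule(comp, 4, stereo = FALSE)
  expect_length(apply_rule(rule, "C"), 0L)       # methane
  expect_length(apply_rule(rule, "c1ccccc1"), 0L)
})

test_that("smaller diameters are more permissive on a substrate panel", {
  comp <- test_components(FALSE)[[1]]   # tyrosine transamination
  panel <- c("N[C@@H](Cc1ccc(O)cc1)C(=O)O",    # source
             "N[C@@H](Cc1ccc(F)cc1)C(=O)O",    # para-F analog
             "NC(Cc1ccccc1)C(=O)O",            # des-hydroxy analog
             "NCC(=O)O",                       # glycine
             "CCO")
  prev <- NULL
  for (d in c(2, 6, 10, 16, Inf)) {
    rule <- extract_rule(comp, d, stereo = FALSE)
    hits <- vapply(panel, function(s)
      length(suppressWarnings(apply_rule(rule, s))) > 0, logical(1))
    if (!is.null(prev)) expect_true(all(which(hits) %in% which(prev)))
    prev <- hits
  }
  # low diameter matches the analogs, the full rule only the source
  r2 <- extract_rule(comp, 2, stereo = FALSE)
  rmax <- extract_rule(comp, Inf, stereo = FALSE)
  hit2 <- vapply(panel, function(s)
    length(suppressWarnings(apply_rule(r2, s))) > 0, logical(1))
  hitmax <- vapply(panel, function(s)
    length(suppressWarnings(apply_rule(rmax, s))) > 0, logical(1))
  expect_true(hit2[[2]] && hit2[[3]])
  expect_equal(unname(hitmax), c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("racemization is degenerate without stereo and a parity flip with it", {
  corpus <- test_corpus()
  rc <- corpus$reactions[[which(corpus$expected$id == "RC1")]]
  # without stereo the reaction does not even validate (nothing changes)
  expect_equal(validate_reaction(rc, rf_policy("strict", stereo = FALSE))$reason,
               "no-change")
  # with stereo: a valid rule that inverts the alpha-carbon parity
  ctr <- augment_stereo(rc, identify_reaction_center(rc))
  comps <- decompose(rc, ctr, test_cofactors(), rf_policy("strict", stereo = TRUE))
  rule <- extract_rule(comps[[1]], 2, stereo = TRUE)
  expect_false(rule$degenerate)
  sides <- strsplit(rule$rule_smiles, ">>", fixed = TRUE)[[1]]
  expect_false(identical(sides[1], sides[2]))
  got <- apply_rule(rule, "N[C@@H](C)C(=O)O")
  expect_equal(got, list(canonical_smiles("N[C@H](C)C(=O)O")))
  # and it does not fire on the achiral substrate
  expect_length(apply_rule(rule, "NC(C)C(=O)O"), 0L)
  # the non-stereo truncation of the same component is degenerate
  rule_ns <- extract_rule(comps[[1]], 2, stereo = FALSE)
  expect_true(rule_ns$degenerate)
})
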