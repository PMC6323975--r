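# Cross-validation of emitted strings and the substructure matcher against
# RDKit (independent cheminformatics oracle, driven through python).

test_that("every emitted SMARTS and rule-SMILES fragment parses in RDKit", {
  ds <- test_datasets()
  tab <- rbind(ds$nonstereo$table, ds$stereo$table)
  smarts_file <- withr::local_tempfile(lines = unique(tab$rule_smarts))
  smiles_file <- withr::local_tempfile(lines = unique(tab$rule_smiles))
  out <- run_python(sprintf(paste0(
    "from rdkit import Chem\n",
    "import sys\n",
    "bad = 0\n",
    "for line in open(%s):\n",
    "    for side in line.strip().split('>>'):\n",
    "        for frag in side.split('.'):\n",
    "            if Chem.MolFromSmarts(frag) is None: bad += 1\n",
    "for line in open(%s):\n",
    "    for side in line.strip().split('>>'):\n",
    "        for frag in side.split('.'):\n",
    "            if Chem.MolFromSmiles(frag, sanitize=False) is None: bad += 1\n",
    "print('BAD', bad)\n"),
    shQuote(smarts_file), shQuote(smiles_file)))
  expect_true(any(grepl("^BAD 0$", out)))
})

test_that("the embedded matcher agrees with RDKit substructure counts", {
  ds <- test_datasets()
  rules <- ds$nonstereo$rules
  rules <- rules[ds$nonstereo$table$diameter %in% c(2, 8, 16)]
  panel <- c("N[C@@H](Cc1ccc(O)cc1)C(=O)O", "N[C@@H](Cc1ccc(F)cc1)C(=O)O",
             "NC(Cc1ccccc1)C(=O)O", "CC(=O)C(=O)O", "OC(=O)/C=C/C(=O)O",
             "OC(=O)C[C@@H](O)C(=O)O", "CC=O", "C")
  cases <- list()
  for (r in rules) {
    sub_smarts <- strsplit(r$rule_smarts, ">>", fixed = TRUE)[[1]][1]
    for (p in panel) {
      n <- length(ruleforge:::match_pattern(
        r$sub_pattern, ruleforge:::stereo_strip(ruleforge:::parse_smiles(p))))
      cases[[length(cases) + 1L]] <- c(sub_smarts, p, n)
    }
  }
  df <- unique(do.call(rbind, cases))
  f <- withr::local_tempfile(lines = apply(df, 1, paste, collapse = "\t"))
  out <- run_python(sprintf(paste0(
    "from rdkit import Chem\n",
    "mism = 0; tot = 0\n",
    "for line in open(%s):\n",
    "    smarts, smi, n = line.rstrip('\\n').split('\\t')\n",
    "    patt = Chem.MolFromSmarts(smarts)\n",
    "    tgt = Chem.MolFromSmiles(smi)\n",
    "    k = len(tgt.GetSubstructMatches(patt, uniquify=False, useChirality=False))\n",
    "    tot += 1\n",
    "    if k != int(n): mism += 1\n",
    "print('AGREE', tot - mism, 'OF', tot)\n"), shQuote(f)))
  line <- grep("^AGREE", out, value = TRUE)
  expect_length(line, 1L)
  parts <- strsplit(line, " ")[[1]]
  expect_equal(parts[2], parts[4])
})

test_that("canonical equivalence classes match RDKit's", {
  mols <- c("N[C@@H](Cc1ccc(O)cc1)C(=O)O", "OC(=O)[C@@H](N)Cc1ccc(cc1)O",
            "N[C@H](Cc1ccc(O)cc1)C(=O)O",
            "OC(=O)/C=C\\C(=O)O", "C(\\C=C/C(O)=O)(=O)O",
            "OC(=O)/C=C/C(=O)O",
            "OC(=O)C[C@@H](O)C(=O)O", "OC(=O)C[C@H](O)C(=O)O",
            "CC(N)=O", "O=C(C)N")
  ours <- unname(vapply(mols, canonical_smiles, ""))
  f <- withr::local_tempfile(lines = mols)
  out <- run_python(sprintf(paste0(
    "from rdkit import Chem\n",
    "for line in open(%s): print(Chem.CanonSmiles(line.strip()))\n"),
    shQuote(f)))
  theirs <- out[nzchar(out)]
  expect_length(theirs, length(mols))
  # same partition into equivalence classes
  for (i in seq_along(mols)) {
    for (j in seq_along(mols)) {
      expect_equal(ours[i] == ours[j], theirs[i] == theirs[j],
                   info = sprintf("%s vs %s", mols[i], mols[j]))
    }
  }
})
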