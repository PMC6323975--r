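Package: ruleforge
Title: Stereochemistry-Aware Reaction Rule Extraction from Atom-Mapped
    Biochemical Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates generic, diameter-parameterized reaction rules from
    atom-mapped biochemical reactions for retrosynthesis and enzyme-promiscuity
    modelling. Reactions are validated, their reaction centers identified from
    the atom-atom mapping (optionally augmented with atoms undergoing
    tetrahedral R/S or double-bond E/Z changes), decomposed into
    direction-specific mono-substrate components with optional cofactor
    removal, and truncated at a series of even bond-diameters around the
    reacting atoms to yield transformation patterns in SMARTS and reaction
    SMILES form. Rules are canonicalized, deduplicated, scored by the number
    of distinct supporting enzyme sequences (log10 penalty), applied back to
    substrates for single-step product enumeration, and exported to an SQLite
    database with ranked query utilities. A deterministic built-in corpus of
    toy reactions (transamination, racemization, cis-trans isomerization,
    hydration with cofactor, condensation, and rejection cases) exercises the
    full pipeline without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
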