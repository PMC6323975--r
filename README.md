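# ruleforge

Stereochemistry-aware reaction rules from atom-mapped biochemical reactions.

## The problem

Retrosynthesis tools and enzyme-promiscuity models do not operate on whole
reactions: they operate on *reaction rules* — generic, substructure-level
descriptions of a chemical transformation that can fire on molecules other
than the substrate they were learned from. A rule is obtained from an
atom-mapped reaction by (i) locating the **reaction center** (the atoms whose
bonds, charges or stereodescriptors change between the two sides of the
atom-atom mapping), (ii) decomposing the reaction into direction-specific
**mono-substrate components** (one per non-cofactor substrate, in both
directions; ubiquitous co-substrates such as water, CO2, ATP or NAD(P) are
set aside), and (iii) keeping only the atoms within a bond-graph radius
*d*/2 of the reacting atoms, for a series of even **diameters** *d*. The
diameter is the specificity dial: *d* = 16 reproduces nearly the exact
substrate; *d* = 2 keeps little more than the reacting atoms and lets the
rule fire on distant analogs, which is exactly how promiscuous enzyme
activity is modelled. Each rule is emitted as reaction SMARTS (a matchable
transformation pattern) and reaction SMILES (the concrete fragments), with a
Boolean `isStereo` flag controlling whether tetrahedral (R/S) and
double-bond (E/Z) changes are encoded — racemases and *cis-trans* isomerases
only yield rules at all when they are.

Every rule is scored by a **biochemical-uncertainty penalty**
log10(*n*), where *n* is the number of distinct enzyme-sequence accessions
supporting the (deduplicated, canonical) rule: 0 for a rule backed by a
single sequence, 1 for ten. Custom (on-the-fly, "DIY") rules inherit the
stored score when they coincide with a database rule and otherwise take the
worst score at their diameter. Rules, products, SMARTS/SMILES strings and
reaction metadata are persisted to a single SQLite file keyed by
`(reaction_id, substrate_id, diameter, isStereo)`.

The package is written for metabolic engineers and cheminformaticians who
need a self-contained, deterministic rule-generation engine: atom-mapped
reactions in, a scored and queryable rule database out. Atom-atom mapping
itself is required input, not computed.

## Worked example

An alanine racemase (EC 5.1.1.1). Nothing changes in the bonding graph, so
the plain center is empty; stereo augmentation finds the inverting
alpha-carbon:

```r
library(ruleforge)

rxn <- parse_mapped_reaction(
  "[NH2:1][C@@H:2]([CH3:3])[C:4](=[O:5])[OH:6]>>[NH2:1][C@H:2]([CH3:3])[C:4](=[O:5])[OH:6]",
  reaction_id = "racemase", ec = "5.1.1.1", sequence_ids = "Q8X8R2")
center <- augment_stereo(rxn, identify_reaction_center(rxn))
center
#> <reaction center: {2} (stereo-added: {2})>

policy <- rf_policy("strict", stereo = TRUE, diameters = c(2, 4, Inf))
comps  <- decompose(rxn, center, default_cofactors(), policy)
rule   <- extract_rule(comps[[1]], diameter = 2, stereo = TRUE)
rule
#> <rule racemase / C([C@H](C)N)(=O)O d=2 stereo>
#>   [C;+0:1][C@;+0;D3;H1:2]([C;+0;D1:3])[N;+0;D1:4]>>[C:1][C@@H:2]([CH3:3])[NH2:4]
```

The diameter-2 rule retains one bond around the alpha-carbon: the carboxyl
carbon survives only as an unconstrained boundary atom `[C;+0:1]`. It
therefore also fires on alaninol, a substrate the reaction never mentioned,
inverting its stereocenter — while the full-diameter rule matches nothing
but alanine itself:

```r
apply_rule(rule, "OC[C@@H](N)C")      # L-alaninol, promiscuous match
#> [[1]]
#> [1] "[C@H](CO)(C)N"
apply_rule(extract_rule(comps[[1]], Inf, stereo = TRUE), "OC[C@@H](N)C")
#> list()
```

At corpus scale: the built-in deterministic fixture corpus (a
transamination pair with ring-substituted analogs, a racemization, a
*cis-trans* isomerization, a hydration with water as cofactor, a
condensation, and one rejection case per filter) runs through both stereo
datasets and into SQLite:

```r
corpus <- generate_corpus(seed = 42, n_variants = 3)
ds <- build_rule_datasets(corpus, annotations = corpus_annotations(corpus))
ds$stereo
#> <rule set: 200 rules (51 distinct SMARTS) from 25 components; 4 rejected, 0 degenerate suppressed>

export_db(ds, "rules.sqlite", reactions = corpus, cofactors = default_cofactors())
head(query_rules("rules.sqlite", ec = "2.6.1", min_diameter = 6)[,
     c("reaction_id", "diameter", "isStereo", "score")])
#>   reaction_id diameter isStereo score
#> 1      TX1_V2       10        0     0
#> 2      TX1_V2       10        1     0
#> 3      TX1_V2       12        0     0
#> 4      TX1_V2       12        1     0
#> 5      TX1_V2       14        0     0
#> 6      TX1_V2       14        1     0
```

Queries are ranked by penalty (best-supported rules first) and export to
CSV or JSON with `export_results()`. A thin command-line front end with
`validate` / `extract` / `score` / `export` / `query` / `fixtures`
subcommands is installed under `exec/ruleforge`.

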