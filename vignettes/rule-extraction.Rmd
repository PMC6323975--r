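---
title: "Diameter-parameterized reaction rules: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diameter-parameterized reaction rules: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleforge)
```

## The model

A reaction rule is a transformation pattern cut out of an atom-mapped
reaction. The pipeline has five conceptual steps, each exposed as one
user-facing function:

1. **Validation** (`validate_reaction`). Reactions that change nothing
   (passive transport), that are element-unbalanced (hydrogens included),
   that contain wildcard R-group atoms or unmapped heavy atoms, or that
   miss a structure entirely, are rejected with a reason code rather than
   an error. In DIY (on-the-fly) mode the balance check is disabled and
   every species is treated as a primary compound.
2. **Reaction center** (`identify_reaction_center`). An atom is reacting
   when its formal charge, element, aromaticity, or incident bond multiset
   — each bond recorded as (order, neighbour map number) — differs between
   the two sides, or when it exists on one side only. A change of hydrogen
   count alone does not recruit an atom: it is always the shadow of a
   neighbour's change, and including it would inflate centers without
   adding information.
3. **Stereo augmentation** (`augment_stereo`). With stereo enabled, every
   tetrahedral atom whose descriptor is created, inverted or deleted, and
   both atoms of every double bond whose cis/trans relation changes, join
   the reacting set. E/Z augmentation adds only the two double-bond atoms,
   not the stereo-determining substituents; substituents enter through the
   diameter sphere. This is the smallest set consistent with descriptor
   change, and it keeps diameter-0 centers minimal.
4. **Decomposition** (`decompose`). One component per non-cofactor
   substrate, in both directions, each keeping only products that share a
   mapped atom with its substrate. Cofactors are matched by canonical
   structure string (maps stripped), never by name.
5. **Truncation and emission** (`extract_rule`). Diameter *d* keeps atoms
   within *d*/2 bonds of a reacting atom (`Inf` keeps everything); bonds
   crossing the boundary are cut; patterns are canonicalized, renumbered
   and emitted as SMARTS and fragment SMILES.

## Tunable parameters

* **diameters** (even integers, bonds; default 2–16, `0` and `Inf`
  accepted). The only scientifically meaningful dial: *d*/2 is the retained
  bond-graph radius. Rule sets at successive diameters are nested by
  construction, which is why distinct-rule counts can only grow with *d*.
* **stereo** (default off, run both ways by `build_rule_datasets`).
  Racemizations and cis-trans isomerizations have empty bonding centers and
  exist only in the stereo dataset; every stereo rule additionally carries
  descriptors on its retained atoms.
* **mode** (`strict`/`diy`). DIY forces cofactor removal off and skips the
  balance check; atoms present on one side only are treated as reacting, so
  unbalanced custom reactions still give usable (if lossy) rules.
* **cofactor list** (canonical SMILES, user-overridable). The shipped
  default covers water, CO2, phosphates, the adenosine cofactors and common
  ions; it is a desk-scale stand-in, not a curated inventory, and any
  serious corpus should supply its own file.

## Atom-query content of emitted patterns

Each pattern atom always asserts element, aromaticity and formal charge.
Explicit degree (`D`) is asserted only on *interior* atoms — atoms whose
complete neighbourhood was retained — and hydrogen counts (`H`) only on
*reacting* atoms, where the H change encodes the transformation itself.
Boundary atoms carry no degree constraint, which is what lets a truncated
rule embed into larger substrates while the round-trip onto its own
substrate stays exact. Note the corollary: a terminal atom (e.g. a methyl
carbon) inside the sphere is vacuously interior and keeps its `D1`, so
rules learned from small substrates stay conservative at such positions.
During application, hydrogen counts on matched non-reacting atoms move by
the rule's own H *delta* rather than being overwritten, so a promiscuous
match on a more substituted atom keeps its extra hydrogens.

## Stereochemistry conventions

Tetrahedral parity is stored relative to a fixed neighbour frame
(ascending atom index, implicit-H slot last) and compared across the
reaction in a *map-normalised* frame: because the atom-atom mapping
identifies every substituent across the two sides, a change of the
normalised parity is equivalent to a CIP R/S creation, inversion or
deletion — without implementing CIP priorities. The same holds for E/Z,
compared as the cis/trans relation of map-identified reference
substituents. Two consequences are deliberate:

* A descriptor is only written into a rule when all of the atom's
  neighbours (or, for E/Z, a marked reference bond on each end) survive
  truncation; a parity with a missing anchor is meaningless. The
  racemization rule therefore first appears at diameter 2, and its
  diameter-0 truncation is degenerate and suppressed.
* Defined-versus-undefined counts as a change (creation/deletion), so
  hydration creating a stereocenter recruits that atom in stereo mode even
  when the bonding change already did.

Axial and planar chirality are out of scope. E/Z direction marks admit a
global flip per conjugation cluster; canonical emission re-orients each
cluster from its lowest-ranked marked bond so equivalent inputs give
byte-identical strings.

## Canonicalization and determinism

Canonical atom ranks come from iterative neighbourhood refinement seeded
with (element, aromaticity, charge, H count, degree, pattern flags), with
remaining ties broken by deterministically promoting the lowest-index
member of the smallest tied class. Atoms still tied after full refinement
are automorphic in ordinary chemical graphs, so the tie-break cannot leak
input order into the output string; the pathological regular-graph
counterexamples do not occur in this chemistry. Atom maps are excluded
from the invariants and reassigned from the canonical emission order
(substrate first, incoming product atoms after), so two rules describing
the same transformation compare string-equal — that string equality *is*
the deduplication and scoring key. Everything downstream (TSV export, the
SQLite content digest) is byte-reproducible; the fixture corpus itself is a
pure function of its seed, with nothing sampled.

## Rule application and round-trip closure

`apply_rule` performs monomorphic embedding of the substrate pattern
(element/aromaticity/charge everywhere, degree on interior atoms, H on
reacting atoms, stereo compatibility for stereo rules) and rewrites matched
atoms and bonds; valence-violating rewrites are discarded with a warning.
The invariant the test-suite enforces on every fixture component and every
diameter: applying the rule to its own substrate regenerates each recorded
product *up to co-substrate truncation* — substrate-derived atoms all
survive (the unmatched part of the molecule rides along), while
co-substrate-derived atoms appear exactly as far as the rule's sphere
recorded them, including their stereo descriptors. At unbounded diameter
this reduces to strict equality with the recorded products and nothing
else. The mirrored expectation is constructed independently from the full
product graphs (`expected_products_at`), not read back from the rule.

## What the fixture corpus does and does not show

The corpus covers the behaviourally distinct reaction classes —
two-substrate group transfer with distant-analog promiscuity probes placed
outside the largest sphere, stereo-only reactions, cofactor handling, a
condensation, and one representative per rejection reason — with
hand-verified mappings, balanced equations and accession sets hitting the
scoring closed forms (n = 1, n = 10, overlapping unions, unannotated).
It is deliberately tiny: molecules stay under ~25 heavy atoms and the full
two-dataset pipeline at diameters 2–16 runs in seconds. Passing tests
demonstrate the engine's algebra (closure, monotonicity, determinism,
persistence), not coverage of metabolic chemistry: real corpora bring
tautomers, ambiguous protonation, partial mappings and aromaticity-model
mismatches that this corpus intentionally excludes, and mapping quality
itself — assumed as input here — dominates rule quality in practice.

## Numerical and degenerate-input choices

* Diameters must be even (`extract_rule` rejects odd values); `Inf` is the
  symbolic full-structure diameter, stored as `-1` in the SQLite artifact.
* Degenerate rules (identical canonical left and right sides, e.g. a
  racemization truncated without stereo) are suppressed and reported, not
  exported.
* Scoring with *n* = 0 (no annotation) takes the worst computed penalty at
  that diameter; if a diameter has no computed penalty at all the fallback
  is 0. `score_custom_rule` inherits on exact (SMARTS, diameter, stereo)
  identity and errors when the reference database is empty at the queried
  diameter.
* Charge imbalance alone warns rather than rejects — the balance filter is
  about atoms; electron bookkeeping is left to the curator.
* Substrate-structure queries against the database use canonical-string
  equality, not substructure search: at desk scale exact lookup is what is
  wanted, and it keeps the query layer free of a second matching engine.

## Known limitations

Aromaticity is taken as written (lowercase/bond symbols), not re-perceived,
so corpora must be consistently aromatized; implicit-H filling follows
fixed normal valences; no isotopes, no explicit [H] atoms, no axial
chirality; rule SMARTS chirality follows the package's own matcher
semantics (RDKit parses every emitted string, and substructure-match counts
agree with RDKit on the achiral query content, but cross-toolkit *stereo*
matching of 3-connected chiral SMARTS atoms is toolkit-dependent). The
scoring module counts distinct accession strings; sequence-identity
clustering ("non-redundant" in the strong sense) is out of scope.
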