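---
title: "Connectivity-level compound cross-referencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-level compound cross-referencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inchilink)
```

## The problem

Public chemistry resources depict what a pharmacologist would call "the same
molecule" in many forms: the free acid and its sodium salt, a racemate and a
resolved enantiomer, a labelled isotopologue, a different protonation state,
or the molecule embedded in a mixture. Every one of these forms has a
different Standard InChI and a different Standard InChIKey, so
cross-references built on exact key identity miss them. `inchilink` is a
registry and search engine that links compound identifiers across sources at
the level of *atom connectivity*, while annotating exactly which structural
layers differ between the query and each hit, so each user can apply their
own definition of molecular equivalence downstream.

## The structural model

A Standard InChI is a layered string: a molecular formula followed by
`/`-prefixed layers in the fixed order `c` (connections), `h` (hydrogens),
`q` (charge), `p` (protons added or removed), `b`, `t`, `m`, `s`
(stereochemistry), and `i` (isotopes). In a salt or mixture, each layer is
subdivided into `;`-separated per-component sublayers, with `N*` shorthand
for repeated components and a leading count in the formula. The package
parses these strings losslessly (`parse_inchi()` / `serialize_inchi()` are
exact inverses), expands components (`expand_components()`), and reassembles
single-component InChIs from a multi-component one (`split_components()`).

The first 14 letters of the Standard InChIKey — the first InChIKey hash
block, FIKHB — hash exactly the formula, connectivity, hydrogen and charge
layers (the basic, Mobile-H layer set). Two structures share a FIKHB
precisely when they share atom connectivity, which makes the FIKHB a compact,
fixed-length join key for connectivity-level lookup. The registry stores
each structure's FIKHB and, for every multi-component structure, the
parent–child edges between its FIKHB and its components' FIKHBs
(`children_of()`, `parents_of()`). Edges are computed once per novel parent
FIKHB at load time: a later salt with the same connectivity but new
stereochemistry reuses the existing edges and is never re-split.

### Decisions at the edges of the format

Several splitting rules are underdetermined by the format and were fixed as
follows:

* **Proton layer (`/p`)** is never propagated to split children. It encodes
  a whole-structure proton balance, contributes only to the final InChIKey
  character, and participates in neither the FIKHB nor the
  key-minus-proton-flag pattern, so no downstream comparison can observe it
  on a child.
* **Stereo parity (`/m`)**: after multiplier expansion the k-th character of
  `/m` belongs to the k-th component; `.` means no parity and yields no `/m`
  in that child. A child that receives a parity character also receives an
  `/s` layer — the parent's own value for relative/unknown stereo types
  (`/s2`, `/s3`), otherwise `/s1` — because a lone parity without a stereo
  type marker is not a well-formed single-component string.
* **Isotopic parents**: the `/i` block (including any internal isotopic
  hydrogen sublayer) is treated as one opaque unit. Splitting a
  multi-component isotopic block is out of scope; such parents generate
  children from their non-isotopic layers only, with a warning.
* **Absent versus empty layers** normalize to "no layer" everywhere,
  including difference flags.

Per-layer difference annotation (`layer_diff()`) covers the six columns
`p, b, t, m, s, i`. The charge layer is deliberately not a column: charge is
part of the hashed basic layer, so two structures retrieved through the same
FIKHB can never differ in it.

## Key providers

Key generation is a pluggable contract with one non-negotiable property:
determinism, plus basic-layer consistency (identical formula + `c` + `h` +
`q` layers must give identical first blocks).

* The **toolkit provider** wraps Open Babel's InChI implementation and
  produces real Standard InChIKeys, interoperable with keys published by
  public databases.
* The **surrogate provider** is a pure-R construction: the basic-layer
  string is hashed into the 14-letter first block and the remaining layers
  into the 8-letter second block, using one 32-bit FNV-1a pass per output
  letter (position-prefixed), with flags `SA` and a proton character offset
  from `N` by the `/p` count. It makes no attempt to reproduce the official
  truncated-SHA construction; its purpose is to key *synthetic* structures
  that no chemistry toolkit would accept, so the entire engine — including
  properties such as "FIKHB equality if and only if basic-layer equality" —
  can be exercised hermetically. Collisions are possible in principle
  (26^-14 per pair per block) but are negligible at test scale.

A registry records which provider keyed it and refuses to open under any
other, because hash blocks from different providers are incomparable.

## The search engine

Searches are qualified by eight user criteria, all defaulting to 0:

| criterion | meaning |
|---|---|
| A | restrict results to one source (0 = all) |
| B | match pattern: 0 = FIKHB, 1 = key minus proton flag (first 25 characters) |
| C | component mapping: 0 matches, 1 matches a component of, 2 has a component which matches, 3 has a component which matches a component of, 4 = all four |
| D | frequency block level for component sub-queries |
| E | connectivity-length block for component sub-queries |
| F | 0 = attach component labels, 1 = off |
| G | 0 = current assignments only, 1 = current + obsolete |
| H | 0 = flat output, 1 = grouped by source (JSON serialization only) |

Both entry points — `key_search` (a full key or a bare FIKHB) and
`cpd_search` (a source identifier pair) — resolve to the same query context.
A query runs only when a query InChI can be recovered from the registry;
keys known only from a keys-only source have none, so the query returns
empty with an explanatory status rather than guessing. A bare-FIKHB query
runs, but its hits carry no difference flags rather than inventing a
representative query InChI.

Component sub-queries (the per-component searches behind relations 2 and 3)
are skipped for components occurring in more than `freq_threshold(D)`
distinct multi-component structures — 200 by default, rising tenfold per
increment of D to a hard cap of 100,000 that cannot be overridden — or whose
connectivity length (formula through the end of the `c` layer) is at most E.
The direction of E was chosen so that short connectivity strings — water,
chloride, and other trivial components — are the ones blocked; `E = 0`
blocks nothing. The decade progression and the cap are this package's own
calibration of "can be varied but not fully overridden". The query standing
in as its own single component (see below) is never blocked: blocking exists
to stop a counter-ion buried in a query from enumerating every salt in the
registry, not to refuse a user who queries that counter-ion directly.

Two further semantics were genuinely open and are fixed as package policy:

* **Degenerate single-component queries.** When the query has one component,
  relation 2 coincides with relation 0 and relation 3 with relation 1; at
  `C = 4` the duplicate records collapse onto the lower relation code. When
  only the higher code was requested, its records keep that code.
* **Record identity.** A structure reachable through several relations
  yields one record per (assignment, relation); ordering is deterministic by
  (relation, src_id, src_compound_id), since a sortable results table
  implies no canonical server-side order.

For speed, relation matching runs entirely on indexed FIKHB/key-prefix
columns and the hierarchy table; retrieved InChIs are parsed only for the
annotation stage, and each unique retrieved InChI is parsed exactly once per
query (the instrumented count is exposed as the `parse_count` attribute and
asserted in the test suite). Hits whose structure lacks an InChI are
skipped, because per-layer comparison requires both sides.

Every search path has a verification twin, `oracle_search()`, which ignores
the hierarchy table and all hash blocks: it splits every registered
structure at query time and compares layer strings directly (basic layer for
FIKHB-level equality; the string minus `/p` for the B = 1 pattern). The test
suite asserts engine–oracle identity over the criteria grid
{A, B, G} × {C = 0..4} on twenty seeded synthetic registries.

## The synthetic-data generator

`generate_fixture()` emulates the catalogue of "essentially similar
structural forms" the engine exists to connect: for each of `n_skeletons`
parent skeletons it emits the skeleton, stereoisomers, isotopologues,
protonation variants, one salt/mixture form per configured counter-ion
(Na, HCl, K, hydrate templates), and a stereo form of the first salt
(exercising the known-parent reuse path). Three sources are written — a
primary source with every structure, a partial second source, and a
keys-only source containing both resolvable and unresolvable keys — plus a
counter-ion label table and a manifest with the expected hierarchy edge set
and a probe query's expected hit set computed by the brute-force reference.

Default family sizes (4 skeletons, Na and HCl counter-ions, one variant of
each kind, roughly 30 structures per registry) keep a full criteria-grid
comparison against the brute-force reference tractable; the frequency-block
boundary is exercised separately with single-counter-ion families of 200 and
201 salts, the sizes at which the default threshold flips.

Generated layers are *syntactically* valid Standard InChI — random but
well-formed connection tables and hydrogen lists — not real chemistry, which
is exactly what the surrogate provider requires and no more. Consequences to
keep in mind: passing the synthetic suites demonstrates the parsing,
hierarchy, blocking and annotation logic, but says nothing about InChI
normalization quality on real molecules. Real-chemistry behaviour is pinned
instead by the literature pair of worked examples (p-aminobenzoic acid with
its sodium salt, which connect at the connectivity level; 5-methyltetrazole
with its sodium salt, which do not, because the InChI software cannot
protonate the tetrazolide anion and the two forms differ within the hashed
basic layer) run under the real toolkit provider. That second example is
also the engine's honest limitation: connectivity linking inherits every
protonation-normalization gap of the InChI software itself, and structures
the InChI cannot represent (polymers, Markush, non-classical stereo) are out
of scope entirely.

## Degenerate inputs and numerical choices

* Loading the same records twice is a no-op; reloading a source marks
  vanished assignments obsolete (rows are kept) and reactivates returning
  ones, keeping at most one current assignment per identifier and source.
* A supplied key that contradicts the provider-computed key rejects that
  record; keys-only records are trusted (their key is all they have).
* A keys-only structure whose key is later matched by an InChI-bearing load
  is merged by `registry_backfill_keys_only()`; key uniqueness holds among
  InChI-bearing structures at all times and across all structures after
  backfill.
* Mixtures of identical components split to one child with a multiplicity
  attribute, so hierarchy edges stay unique under the (parent, child)
  composite key.

## A worked example

```{r}
acid <- "InChI=1S/C7H7NO2/c8-6-3-1-5(2-4-6)7(9)10/h1-4H,8H2,(H,9,10)"
salt <- "InChI=1S/C7H7NO2.Na/c8-6-3-1-5(2-4-6)7(9)10;/h1-4H,8H2,(H,9,10);/q;+1/p-1"

reg <- registry_create(surrogate_provider())
registry_add_source(reg, 1, "chemdb")
registry_load_source(reg, 1, data.frame(
  src_compound_id = c("A1", "S1"), standardinchi = c(acid, salt)))

ctx <- resolve_key_query(reg, key_for(acid, reg$provider))
execute_search(reg, ctx, search_criteria(C = 4))[
  c("src_compound_id", "relation", "p", "b", "t", "m", "s", "i")]
```

The acid matches itself (relation 0) and is identified as a component of its
sodium salt (relation 1); the salt record differs from the query only in the
proton layer, hence the single `p` flag.
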