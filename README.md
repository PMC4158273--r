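# inchilink

Connectivity-level compound cross-referencing for cheminformatics and drug
discovery: a self-contained registry that links compound identifiers across
data sources when the underlying molecules share **atom connectivity**, even
when they differ as salts, mixtures, stereoisomers, isotopologues or
protonation states — with every hit annotated by the exact Standard InChI
layers in which it differs from the query.

## The method

A Standard InChI encodes a molecule in ordered layers
(`formula /c /h /q /p /b /t /m /s /i`), with `;`-separated per-component
sublayers for salts and mixtures. The first 14 letters of the Standard
InChIKey — the first InChIKey hash block (FIKHB) — hash exactly the basic
(Mobile-H) layers: formula, connectivity, hydrogens, charge. `inchilink`

* parses and splits Standard InChIs losslessly at the layer level
  (`parse_inchi()`, `split_components()`);
* keys structures through a pluggable provider — an Open Babel wrapper for
  real InChIKeys, or a hermetic deterministic surrogate for synthetic test
  structures (`toolkit_provider()`, `surrogate_provider()`);
* maintains a registry of sources, structures and identifier assignments
  plus a FIKHB parent–child hierarchy, built incrementally at load time:
  each multi-component structure with a novel FIKHB is split once and its
  component edges stored (`registry_load_source()`);
* answers `key_search` / `cpd_search` queries under eight user criteria
  A–H: source filter, match pattern (FIKHB vs key-minus-proton-flag),
  component-mapping relation (exact / component-of / has-component /
  component-to-component, or all four at once), sub-query blocking by
  component frequency and connectivity length, labels, assignment scope and
  output shape (`execute_search()`);
* verifies itself against a brute-force reference (`oracle_search()`) that
  splits every structure at query time and compares layer strings directly.

## A worked example

p-Aminobenzoic acid and its sodium salt have different InChIs and InChIKeys,
but the salt's acid component carries the acid's exact basic layers:

```r
library(inchilink)

acid <- "InChI=1S/C7H7NO2/c8-6-3-1-5(2-4-6)7(9)10/h1-4H,8H2,(H,9,10)"
salt <- "InChI=1S/C7H7NO2.Na/c8-6-3-1-5(2-4-6)7(9)10;/h1-4H,8H2,(H,9,10);/q;+1/p-1"

vapply(split_components(parse_inchi(salt)), serialize_inchi, "")
#> [1] "InChI=1S/C7H7NO2/c8-6-3-1-5(2-4-6)7(9)10/h1-4H,8H2,(H,9,10)"
#> [2] "InChI=1S/Na/q+1"

reg <- registry_create(surrogate_provider())
registry_add_source(reg, 1, "chemdb")
registry_load_source(reg, 1, data.frame(
  src_compound_id = c("A1", "S1"), standardinchi = c(acid, salt)))
#> load report (src_id 1): 2 records, 0 rejected, 2 new structures,
#> 2 new hierarchy edges, 2 current assignments, 0 obsoleted

ctx <- resolve_key_query(reg, key_for(acid, reg$provider))
execute_search(reg, ctx, search_criteria(C = 4))[
  c("src_compound_id", "relation", "p", "b", "t", "m", "s", "i")]
#>   src_compound_id relation p b t m s i
#> 1              A1        0 0 0 0 0 0 0
#> 2              S1        1 1 0 0 0 0 0
```

The acid matches itself (relation 0, "Matches") and is found as a component
of its salt (relation 1, "Matches a component of"); the salt differs from
the query only in the proton layer (`p = 1`). Under the real toolkit
provider the acid keys to `ALYNCZNDIQEVRV-UHFFFAOYSA-N`, and the salt's acid
child shares its FIKHB `ALYNCZNDIQEVRV`. The converse limitation is equally
visible: 5-methyltetrazole and its sodium salt do *not* connect, because the
InChI software cannot re-protonate the tetrazolide anion, so the two forms
differ inside the hashed basic layer.

A thin command-line wrapper is installed under `exec/`:

```sh
inchilink load --config inchilink.conf --src 1
inchilink search key ALYNCZNDIQEVRV-UHFFFAOYSA-N --config inchilink.conf --C 4
inchilink search cpd A1 --src 1 --config inchilink.conf --format json --H 1
```

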