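# Literature InChIs used throughout the suite: p-aminobenzoic acid and its
# sodium salt (a case where the InChI normalization connects acid and salt at
# the connectivity level), and 5-methyltetrazole and its sodium salt (a case
# where it cannot).
ACID <- "InChI=1S/C7H7NO2/c8-6-3-1-5(2-4-6)7(9)10/h1-4H,8H2,(H,9,10)"
ACID_SALT <- "InChI=1S/C7H7NO2.Na/c8-6-3-1-5(2-4-6)7(9)10;/h1-4H,8H2,(H,9,10);/q;+1/p-1"
TETRAZOLE <- "InChI=1S/C2H4N4/c1-2-3-5-6-4-2/h1H3,(H,3,4,5,6)"
TETRAZOLE_SALT <- "InChI=1S/C2H3N4.Na/c1-2-3-5-6-4-2;/h1H3;/q-1;+1"
PRINTED <- c(ACID, ACID_SALT, TETRAZOLE, TETRAZOLE_SALT)

# registry holding the acid + its sodium salt under one source
pair_registry <- function(provider = surrogate_provider()) {
  reg <- registry_create(provider)
  registry_add_source(reg, 1L, "chemdb")
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "S1"),
    standardinchi = c(ACID, ACID_SALT),
    stringsAsFactors = FALSE))
  reg
}

hit_set <- function(hits) {
  out <- unique(hits[c("src_compound_id", "src_id", "relation", "current")])
  rownames(out) <- NULL
  out
}

oracle_set <- function(o) { rownames(o) <- NULL; o }
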