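test_that("loading a salt records its parent-child FIKHB edges once", {
  reg <- registry_create(surrogate_provider())
  registry_add_source(reg, 1L, "chemdb")
  rep <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("T1", "T2"),
    standardinchi = c(TETRAZOLE, TETRAZOLE_SALT),
    stringsAsFactors = FALSE))
  expect_equal(rep$n_new_structures, 2L)
  expect_equal(rep$n_new_edges, 2L)

  salt_fikhb <- reg$structures$fikhb[reg$structures$standardinchi == TETRAZOLE_SALT]
  kids <- children_of(reg, salt_fikhb)
  expect_length(kids, 2L)
  # the neutral tetrazole's FIKHB appears in no edge: its anion form differs
  neutral <- reg$structures$fikhb[reg$structures$standardinchi == TETRAZOLE]
  expect_false(neutral %in% c(reg$hierarchy$parent, reg$hierarchy$child))
})

test_that("a known parent FIKHB with novel stereochemistry adds no edges", {
  reg <- pair_registry()
  n_edges <- nrow(reg$hierarchy)
  stereo_salt <- paste0(ACID_SALT, "/t5-;/m0./s1")
  rep <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "S1", "S2"),
    standardinchi = c(ACID, ACID_SALT, stereo_salt),
    stringsAsFactors = FALSE))
  expect_equal(rep$n_new_structures, 1L)
  expect_equal(rep$n_new_edges, 0L)
  expect_equal(nrow(reg$hierarchy), n_edges)
})

test_that("reloading identical records is idempotent", {
  reg <- pair_registry()
  before <- list(nrow(reg$structures), nrow(reg$hierarchy), nrow(reg$assignments))
  rep <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "S1"),
    standardinchi = c(ACID, ACID_SALT), stringsAsFactors = FALSE))
  expect_equal(rep$n_new_structures, 0L)
  expect_equal(rep$n_new_edges, 0L)
  expect_equal(rep$n_obsoleted, 0L)
  expect_identical(list(nrow(reg$structures), nrow(reg$hierarchy),
                        nrow(reg$assignments)), before)
})

test_that("reloading versions assignments: vanished obsolete, returning current", {
  reg <- pair_registry()
  rep <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = "A1", standardinchi = ACID, stringsAsFactors = FALSE))
  expect_equal(rep$n_obsoleted, 1L)
  a <- reg$assignments
  expect_equal(a$current[a$src_compound_id == "S1"], 0L)  # row retained
  rep2 <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "S1"),
    standardinchi = c(ACID, ACID_SALT), stringsAsFactors = FALSE))
  expect_equal(rep2$n_new_structures, 0L)
  a <- reg$assignments
  expect_equal(a$current[a$src_compound_id == "S1"], 1L)
  expect_equal(nrow(a), 2L)  # reactivated, not duplicated
  # at most one current assignment per (src_compound_id, src_id)
  cur <- a[a$current == 1L, ]
  expect_false(any(duplicated(cur[c("src_compound_id", "src_id")])))
})

test_that("split children are never stored as structures", {
  reg <- registry_create(surrogate_provider())
  registry_add_source(reg, 1L, "chemdb")
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = "S1", standardinchi = ACID_SALT, stringsAsFactors = FALSE))
  expect_equal(nrow(reg$structures), 1L)   # only the salt itself
  expect_equal(nrow(reg$hierarchy), 2L)    # but both edges exist
})

test_that("contradictory supplied keys and misplaced records are rejected", {
  reg <- registry_create(surrogate_provider())
  registry_add_source(reg, 1L, "chemdb")
  registry_add_source(reg, 2L, "keydb", keys_only = TRUE)
  wrong <- "AAAAAAAAAAAAAA-AAAAAAAASA-N"
  rep <- registry_load_source(reg, 1L, data.frame(
    src_compound_id = "A1", standardinchi = ACID,
    standardinchikey = wrong, stringsAsFactors = FALSE))
  expect_equal(rep$n_rejected, 1L)
  expect_match(rep$rejects, "contradicts")
  expect_equal(nrow(reg$structures), 0L)
  # an InChI-bearing record cannot enter through a keys-only source
  rep2 <- registry_load_source(reg, 2L, data.frame(
    src_compound_id = "K1", standardinchi = ACID, stringsAsFactors = FALSE))
  expect_equal(rep2$n_rejected, 1L)
  expect_match(rep2$rejects, "keys-only")
})

test_that("keys-only structures are backfilled from matching InChI sources", {
  sp <- surrogate_provider()
  reg <- registry_create(sp)
  registry_add_source(reg, 1L, "keydb", keys_only = TRUE)
  registry_add_source(reg, 2L, "chemdb")
  acid_key <- key_for(ACID, sp)
  orphan_key <- key_for("InChI=1S/Xe", sp)
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("K1", "K2"),
    standardinchikey = c(acid_key, orphan_key), stringsAsFactors = FALSE))
  expect_equal(sum(is.na(reg$structures$standardinchi)), 2L)
  registry_load_source(reg, 2L, data.frame(
    src_compound_id = "A1", standardinchi = ACID, stringsAsFactors = FALSE))
  missing <- registry_backfill_keys_only(reg)
  expect_equal(missing, 1L)  # the orphan key persists without an InChI
  # one merged structure, both assignments pointing at it
  srow <- which(reg$structures$standardinchikey == acid_key)
  expect_length(srow, 1L)
  expect_false(is.na(reg$structures$standardinchi[srow]))
  uci <- reg$structures$uci[srow]
  a <- reg$assignments
  expect_setequal(a$src_compound_id[a$uci == uci], c("K1", "A1"))
  # keys are unique across structures after backfill
  expect_false(any(duplicated(reg$structures$standardinchikey)))
  # no keys-only sources at all: nothing to do
  reg2 <- pair_registry()
  expect_equal(registry_backfill_keys_only(reg2), 0L)
})

test_that("hierarchy lookups are inverse relations with brute-force counts", {
  d <- tempfile()
  m <- generate_fixture(family_spec(n_skeletons = 4, seed = 3), d)
  reg <- fixture_registry(d)
  # children_of and parents_of expose the same edge set
  for (p in unique(reg$hierarchy$parent))
    for (ch in children_of(reg, p))
      expect_true(p %in% parents_of(reg, ch))
  # component_frequency equals a brute-force split of every multi-component
  # InChI at query time (no hierarchy table involved)
  sp <- surrogate_provider()
  inchis <- reg$structures$standardinchi[!is.na(reg$structures$standardinchi)]
  parsed <- lapply(inchis, parse_inchi)
  multi <- vapply(parsed, function(p) sum(p$formula$count) >= 2L, TRUE)
  parent_fikhb <- substr(key_for(inchis[multi], sp), 1, 14)
  child_sets <- lapply(parsed[multi], function(p) {
    kids <- suppressWarnings(split_components(p))
    unique(substr(key_for(vapply(kids, serialize_inchi, ""), sp), 1, 14))
  })
  for (ch in unique(reg$hierarchy$child)) {
    n <- length(unique(parent_fikhb[vapply(child_sets, function(cs) ch %in% cs, TRUE)]))
    expect_identical(component_frequency(reg, ch), n)
  }
  expect_identical(component_frequency(reg, "ZZZZZZZZZZZZZZ"), 0L)
  expect_identical(parents_of(reg, "ZZZZZZZZZZZZZZ"), character(0))
})

test_that("the FIKHB column always mirrors the key and edges are unique", {
  d <- tempfile()
  generate_fixture(family_spec(seed = 8), d)
  reg <- fixture_registry(d)
  expect_identical(reg$structures$fikhb,
                   substr(reg$structures$standardinchikey, 1, 14))
  expect_false(any(duplicated(reg$hierarchy)))
})

test_that("a registry round-trips through its directory representation", {
  reg <- pair_registry()
  registry_set_labels(reg, c(AAAABBBBCCCCDD = "Na"))
  d <- tempfile()
  registry_write(reg, d)
  back <- registry_read(d, surrogate_provider())
  expect_identical(back$structures, reg$structures)
  expect_identical(back$assignments, reg$assignments)
  expect_identical(back$hierarchy, reg$hierarchy)
  expect_identical(back$sources, reg$sources)
  expect_identical(back$labels, reg$labels)
  # providers must not be mixed over one registry
  expect_error(registry_read(d, toolkit_provider()), "refusing")
})
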