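test_that("acid query at C=4 finds itself and its sodium salt", {
  reg <- pair_registry()
  ctx <- resolve_key_query(reg, key_for(ACID, reg$provider))
  hits <- execute_search(reg, ctx, search_criteria(C = 4))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$src_compound_id, c("A1", "S1"))
  expect_equal(hits$relation, c(0L, 1L))  # itself; "matches a component of"
  # the salt record differs from the query only in the proton layer
  expect_equal(unlist(hits[2, c("p", "b", "t", "m", "s", "i")], use.names = FALSE),
               c(1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("salt query at C=4 maps onto components and sibling salts", {
  reg <- pair_registry()
  other_salt <- "InChI=1S/C7H7NO2.K/c8-6-3-1-5(2-4-6)7(9)10;/h1-4H,8H2,(H,9,10);/q;+1/p-1"
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "S1", "S2"),
    standardinchi = c(ACID, ACID_SALT, other_salt), stringsAsFactors = FALSE))
  ctx <- resolve_key_query(reg, key_for(ACID_SALT, reg$provider))
  hits <- execute_search(reg, ctx, search_criteria(C = 4))
  hs <- hit_set(hits)
  expect_equal(hs$relation[hs$src_compound_id == "S1"], c(0L, 3L))
  expect_equal(hs$relation[hs$src_compound_id == "A1"], 2L)
  expect_identical(hs$relation[hs$src_compound_id == "S2"], 3L)  # sibling salt
  # agrees with the brute-force reference
  o <- oracle_search(reg, resolve_key_query(reg, key_for(ACID_SALT, reg$provider)),
                     search_criteria(C = 4))
  expect_identical(hit_set(hits), oracle_set(o))
})

test_that("cpd_search resolves to the same context as key_search", {
  reg <- pair_registry()
  k1 <- execute_search(reg, resolve_cpd_query(reg, "A1", 1L), search_criteria(C = 4))
  k2 <- execute_search(reg, resolve_key_query(reg, key_for(ACID, reg$provider)),
                       search_criteria(C = 4))
  expect_identical(hit_set(k1), hit_set(k2))
  bad <- resolve_cpd_query(reg, "NOPE", 1L)
  expect_identical(bad$status, "unknown src_compound_id")
  expect_equal(nrow(execute_search(reg, bad)), 0L)
})

test_that("keys without InChIs cannot run a query and are never retrieved", {
  sp <- surrogate_provider()
  reg <- pair_registry(sp)
  registry_add_source(reg, 2L, "keydb", keys_only = TRUE)
  orphan <- key_for("InChI=1S/Xe", sp)
  registry_load_source(reg, 2L, data.frame(
    src_compound_id = "K1", standardinchikey = orphan, stringsAsFactors = FALSE))
  registry_backfill_keys_only(reg)
  ctx <- resolve_key_query(reg, orphan)
  expect_identical(ctx$status, "no query InChI")
  hits <- execute_search(reg, ctx, search_criteria(C = 4))
  expect_equal(nrow(hits), 0L)
  expect_identical(attr(hits, "status"), "no query InChI")
  # an InChI-less structure is skipped even when its key pattern matches
  ctx2 <- resolve_key_query(reg, key_for(ACID, sp))
  hits2 <- execute_search(reg, ctx2, search_criteria(C = 4))
  expect_false("K1" %in% hits2$src_compound_id)
  # a key entirely absent from the registry cannot run either
  absent <- key_for("InChI=1S/Kr", sp)
  expect_identical(resolve_key_query(reg, absent)$status, "no query InChI")
})

test_that("bare FIKHB queries run without diff annotation", {
  reg <- pair_registry()
  ctx <- resolve_key_query(reg, fikhb_of(key_for(ACID, reg$provider)))
  expect_null(ctx$query_inchi)
  hits <- execute_search(reg, ctx, search_criteria(C = 1))
  expect_equal(hits$src_compound_id, "S1")
  expect_true(all(is.na(hits[c("p", "b", "t", "m", "s", "i")])))
  expect_error(execute_search(reg, ctx, search_criteria(B = 1)),
               "pattern requires full key")
})

test_that("criterion B=1 restricts to identical stereo and isotopic layers", {
  sp <- surrogate_provider()
  reg <- registry_create(sp)
  registry_add_source(reg, 1L, "chemdb")
  iso <- paste0(ACID, "/i1+1")
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = c("A1", "I1", "S1"),
    standardinchi = c(ACID, iso, ACID_SALT), stringsAsFactors = FALSE))
  ctx0 <- resolve_key_query(reg, key_for(ACID, sp))
  b0 <- execute_search(reg, ctx0, search_criteria(C = 4, B = 0))
  b1 <- execute_search(reg, resolve_key_query(reg, key_for(ACID, sp)),
                       search_criteria(C = 4, B = 1))
  # B=1 results are a subset of B=0 results
  expect_true(all(do.call(paste, hit_set(b1)) %in% do.call(paste, hit_set(b0))))
  expect_true("I1" %in% b0$src_compound_id)
  expect_false("I1" %in% b1$src_compound_id)   # isotopic variant excluded
  expect_true("S1" %in% b1$src_compound_id)    # but its salt still found via C=4
  # every B=1 exact/component-exact record has zero stereo/isotope flags
  r02 <- b1[b1$relation %in% c(0L, 2L), ]
  expect_true(all(r02[c("b", "t", "m", "s", "i")] == 0L))
})

test_that("frequency thresholds step by decades up to a hard cap", {
  expect_identical(freq_threshold(0), 200L)
  expect_identical(freq_threshold(1), 2000L)
  expect_identical(freq_threshold(2), 20000L)
  expect_identical(freq_threshold(3), 100000L)
  expect_identical(freq_threshold(9), 100000L)  # cap is never exceeded
  expect_error(freq_threshold(-1))
})

test_that("criterion E blocks sub-queries for trivially short components", {
  reg <- pair_registry()
  ctx <- resolve_key_query(reg, key_for(ACID_SALT, reg$provider))
  # Na has connectivity length 2: blocked at E=2, acid sub-query unaffected
  hits <- execute_search(reg, ctx, search_criteria(C = 4, E = 2))
  expect_true("A1" %in% hits$src_compound_id[hits$relation == 2L])
  expect_false(any(hits$relation == 3L & hits$src_compound_id != "S1"))
  # E large enough blocks the acid component as well
  acid_len <- connectivity_length(parse_inchi(ACID))
  hits2 <- execute_search(reg, resolve_key_query(reg, key_for(ACID_SALT, reg$provider)),
                          search_criteria(C = 4, E = acid_len))
  expect_false(any(hits2$relation %in% c(2L, 3L)))
})

test_that("labels flag common counter-ions unless criterion F disables them", {
  sp <- surrogate_provider()
  reg <- pair_registry(sp)
  na_fikhb <- fikhb_of(key_for("InChI=1S/Na/q+1", sp))
  registry_set_labels(reg, stats::setNames("Na", na_fikhb))
  ctx <- resolve_key_query(reg, key_for(ACID, sp))
  hits <- execute_search(reg, ctx, search_criteria(C = 4))
  expect_identical(hits$labels[[which(hits$src_compound_id == "S1")]], "Na")
  expect_identical(hits$labels[[which(hits$src_compound_id == "A1")]], character(0))
  off <- execute_search(reg, resolve_key_query(reg, key_for(ACID, sp)),
                        search_criteria(C = 4, F = 1))
  expect_true(all(lengths(off$labels) == 0L))
  # annotate_labels in isolation
  expect_identical(annotate_labels(c("X", na_fikhb),
                                   stats::setNames("Na", na_fikhb)), "Na")
  expect_identical(annotate_labels("X", character(0)), character(0))
})

test_that("criteria A and G filter by source and assignment scope", {
  reg <- pair_registry()
  registry_add_source(reg, 2L, "altdb")
  registry_load_source(reg, 2L, data.frame(
    src_compound_id = "X1", standardinchi = ACID, stringsAsFactors = FALSE))
  # obsolete the salt assignment in source 1
  registry_load_source(reg, 1L, data.frame(
    src_compound_id = "A1", standardinchi = ACID, stringsAsFactors = FALSE))
  ctx <- function() resolve_key_query(reg, key_for(ACID, reg$provider))
  all_hits <- execute_search(reg, ctx(), search_criteria(C = 4, G = 1))
  expect_true("S1" %in% all_hits$src_compound_id)
  expect_equal(all_hits$current[all_hits$src_compound_id == "S1"], 0L)
  cur_hits <- execute_search(reg, ctx(), search_criteria(C = 4, G = 0))
  expect_false("S1" %in% cur_hits$src_compound_id)
  only2 <- execute_search(reg, ctx(), search_criteria(C = 4, A = 2))
  expect_identical(unique(only2$src_id), 2L)
  expect_identical(only2$src_compound_id, "X1")
})

test_that("each unique retrieved InChI is parsed exactly once per query", {
  d <- tempfile()
  m <- generate_fixture(family_spec(seed = 21), d)
  reg <- fixture_registry(d)
  ctx <- resolve_key_query(reg, m$probe$term)
  hits <- execute_search(reg, ctx, search_criteria(C = 4))
  n_unique <- length(unique(hits$standardinchi))
  expect_gt(n_unique, 1L)
  expect_lte(attr(hits, "parse_count"), n_unique + 1L)  # hits + the query itself
})

test_that("records are deterministically ordered by relation, source, id", {
  d <- tempfile()
  m <- generate_fixture(family_spec(seed = 31), d)
  reg <- fixture_registry(d)
  hits <- execute_search(reg, resolve_key_query(reg, m$probe$term),
                         search_criteria(C = 4))
  key <- order(hits$relation, hits$src_id, hits$src_compound_id)
  expect_identical(key, seq_len(nrow(hits)))
})
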