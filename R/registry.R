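# The compound cross-reference registry: four relational tables mirroring the
# classic schema (sources, structures, assignments, plus the FIKHB
# parent-child hierarchy) held as data frames inside an environment, so loader
# operations mutate in place. Persistence is a directory of TSV tables plus a
# JSON meta file recording the key provider, because keys minted by different
# providers are incomparable and must never be mixed in one registry.

#' Create an empty compound registry
#'
#' @param provider the key provider every load into this registry will use
#'   (see [surrogate_provider()], [toolkit_provider()]).
#' @return An environment of class `inchilink_registry` holding the tables
#'   `sources`, `structures`, `assignments` and `hierarchy`, plus an optional
#'   FIKHB label table.
#' @export
registry_create <- function(provider = surrogate_provider()) {
  stopifnot(inherits(provider, "key_provider"))
  reg <- new.env(parent = emptyenv())
  reg$sources <- data.frame(src_id = integer(0), name = character(0),
                            keys_only = integer(0), stringsAsFactors = FALSE)
  reg$structures <- data.frame(uci = integer(0), standardinchi = character(0),
                               standardinchikey = character(0),
                               fikhb = character(0), stringsAsFactors = FALSE)
  reg$assignments <- data.frame(src_compound_id = character(0),
                                src_id = integer(0), uci = integer(0),
                                current = integer(0), stringsAsFactors = FALSE)
  reg$hierarchy <- data.frame(parent = character(0), child = character(0),
                              stringsAsFactors = FALSE)
  reg$labels <- character(0)      # named: FIKHB -> label text
  reg$provider <- provider
  reg$next_uci <- 1L
  class(reg) <- "inchilink_registry"
  reg
}

#' @export
print.inchilink_registry <- function(x, ...) {
  cat(sprintf("<inchilink_registry: %d sources, %d structures (%d without InChI), %d assignments, %d hierarchy edges; provider=%s>\n",
              nrow(x$sources), nrow(x$structures),
              sum(is.na(x$structures$standardinchi)),
              nrow(x$assignments), nrow(x$hierarchy), x$provider$name))
  invisible(x)
}

#' Register a data source
#'
#' @param reg a registry.
#' @param src_id positive integer source identifier, unique in the registry.
#' @param name source name.
#' @param keys_only `TRUE` for a source that contributes only Standard
#'   InChIKeys (its InChIs are inferred from other sources sharing a key).
#' @return The registry, invisibly.
#' @export
registry_add_source <- function(reg, src_id, name, keys_only = FALSE) {
  stopifnot(inherits(reg, "inchilink_registry"))
  src_id <- as.integer(src_id)
  stopifnot(length(src_id) == 1L, src_id > 0L)
  if (src_id %in% reg$sources$src_id)
    stop(sprintf("src_id %d already registered", src_id))
  reg$sources <- rbind(reg$sources,
                       data.frame(src_id = src_id, name = as.character(name),
                                  keys_only = as.integer(keys_only),
                                  stringsAsFactors = FALSE))
  invisible(reg)
}

#' Attach a FIKHB label table
#'
#' Labels are short text tags for frequently occurring components (common
#' salts and mixture partners such as HCl); search results flag any hit whose
#' components carry a label.
#'
#' @param reg a registry.
#' @param labels named character vector, names are FIKHBs.
#' @return The registry, invisibly.
#' @export
registry_set_labels <- function(reg, labels) {
  stopifnot(inherits(reg, "inchilink_registry"),
            is.character(labels), !is.null(names(labels)) || length(labels) == 0L)
  reg$labels <- labels
  invisible(reg)
}

.find_structure_by_key <- function(reg, key) which(reg$structures$standardinchikey == key)

.insert_structure <- function(reg, inchi, key) {
  uci <- reg$next_uci
  reg$next_uci <- uci + 1L
  reg$structures <- rbind(reg$structures,
                          data.frame(uci = uci, standardinchi = inchi,
                                     standardinchikey = key,
                                     fikhb = substr(key, 1L, 14L),
                                     stringsAsFactors = FALSE))
  uci
}

# Insert hierarchy edges for a multi-component InChI whose FIKHB is not yet a
# parent. Children's single-component InChIs are never stored as structures.
.maybe_insert_edges <- function(reg, parsed, parent_fikhb) {
  if (sum(parsed$formula$count) < 2L) return(0L)
  if (parent_fikhb %in% reg$hierarchy$parent) return(0L)
  children <- withCallingHandlers(split_components(parsed),
                                  warning = function(w) invokeRestart("muffleWarning"))
  child_inchis <- vapply(children, serialize_inchi, "")
  child_keys <- key_for(child_inchis, reg$provider)
  child_fikhbs <- unique(substr(child_keys, 1L, 14L))
  reg$hierarchy <- rbind(reg$hierarchy,
                         data.frame(parent = parent_fikhb, child = child_fikhbs,
                                    stringsAsFactors = FALSE))
  length(child_fikhbs)
}

#' Load (or reload) a source's assignment records into the registry
#'
#' Records for an ordinary source carry a Standard InChI and optionally a
#' Standard InChIKey; the key is always recomputed with the registry's
#' provider and a contradictory supplied key rejects the record. Records for
#' a keys-only source carry only a key, which is trusted. New structures are
#' inserted with their key and FIKHB; every multi-component InChI whose FIKHB
#' is not yet a hierarchy parent is split and its parent-child FIKHB edges
#' inserted (the split children themselves are never stored as structures).
#' Reloading a source marks assignments that vanished from the record stream
#' obsolete (`current = 0`, rows retained) and reactivates returning ones.
#'
#' @param reg a registry.
#' @param src_id a registered source id.
#' @param records data frame with columns `src_compound_id`, `standardinchi`
#'   (ordinary sources), and/or `standardinchikey`.
#' @return A `load_report` list: counts of records read, rejected, new
#'   structures, new hierarchy edges, current and obsoleted assignments, and
#'   a character vector of rejection messages.
#' @export
registry_load_source <- function(reg, src_id, records) {
  stopifnot(inherits(reg, "inchilink_registry"))
  src_id <- as.integer(src_id)
  srow <- match(src_id, reg$sources$src_id)
  if (is.na(srow)) stop(sprintf("src_id %d is not registered", src_id))
  keys_only <- reg$sources$keys_only[srow] == 1L
  stopifnot(is.data.frame(records), "src_compound_id" %in% names(records))

  rejects <- character(0)
  n_new_structures <- 0L
  n_new_edges <- 0L
  seen_ids <- character(0)
  kept <- data.frame(src_compound_id = character(0), uci = integer(0),
                     stringsAsFactors = FALSE)

  get_col <- function(col, i) {
    if (!col %in% names(records)) return(NA_character_)
    v <- records[[col]][i]
    if (is.na(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
  }

  for (i in seq_len(nrow(records))) {
    id <- get_col("src_compound_id", i)
    inchi <- get_col("standardinchi", i)
    key <- get_col("standardinchikey", i)
    if (is.na(id)) {
      rejects <- c(rejects, sprintf("row %d: missing src_compound_id", i)); next
    }
    if (id %in% seen_ids) {
      rejects <- c(rejects, sprintf("row %d: duplicate src_compound_id '%s' in load", i, id)); next
    }
    if (keys_only) {
      if (!is.na(inchi)) {
        rejects <- c(rejects, sprintf("row %d (%s): InChI supplied for keys-only source", i, id)); next
      }
      if (is.na(key) || !is_inchikey(key)) {
        rejects <- c(rejects, sprintf("row %d (%s): missing or malformed InChIKey", i, id)); next
      }
      hit <- .find_structure_by_key(reg, key)
      if (length(hit)) {
        # prefer an InChI-bearing row when both exist pre-backfill
        with_inchi <- hit[!is.na(reg$structures$standardinchi[hit])]
        uci <- reg$structures$uci[if (length(with_inchi)) with_inchi[1] else hit[1]]
      } else {
        uci <- .insert_structure(reg, NA_character_, key)
        n_new_structures <- n_new_structures + 1L
      }
    } else {
      if (is.na(inchi)) {
        rejects <- c(rejects, sprintf("row %d (%s): missing Standard InChI", i, id)); next
      }
      parsed <- tryCatch(parse_inchi(inchi), error = function(e) e)
      if (inherits(parsed, "error")) {
        rejects <- c(rejects, sprintf("row %d (%s): %s", i, id, conditionMessage(parsed))); next
      }
      computed <- key_for(inchi, reg$provider)
      if (!is.na(key) && key != computed) {
        rejects <- c(rejects, sprintf(
          "row %d (%s): supplied key %s contradicts computed key %s", i, id, key, computed)); next
      }
      hit <- .find_structure_by_key(reg, computed)
      with_inchi <- hit[!is.na(reg$structures$standardinchi[hit])]
      if (length(with_inchi)) {
        uci <- reg$structures$uci[with_inchi[1]]
      } else {
        uci <- .insert_structure(reg, inchi, computed)
        n_new_structures <- n_new_structures + 1L
        n_new_edges <- n_new_edges +
          .maybe_insert_edges(reg, parsed, substr(computed, 1L, 14L))
      }
    }
    seen_ids <- c(seen_ids, id)
    kept <- rbind(kept, data.frame(src_compound_id = id, uci = uci,
                                   stringsAsFactors = FALSE))
  }

  # assignment versioning: one current row per (src_compound_id, src_id)
  a <- reg$assignments
  mine <- a$src_id == src_id
  n_obsoleted <- 0L
  keep_key <- paste(kept$src_compound_id, kept$uci)
  old_key <- paste(a$src_compound_id, a$uci)
  vanish <- mine & a$current == 1L & !(old_key %in% keep_key)
  n_obsoleted <- sum(vanish)
  a$current[vanish] <- 0L
  for (j in seq_len(nrow(kept))) {
    rows <- which(mine & a$src_compound_id == kept$src_compound_id[j] &
                    a$uci == kept$uci[j])
    if (length(rows)) {
      a$current[rows[1]] <- 1L
    } else {
      a <- rbind(a, data.frame(src_compound_id = kept$src_compound_id[j],
                               src_id = src_id, uci = kept$uci[j],
                               current = 1L, stringsAsFactors = FALSE))
      mine <- c(mine, TRUE)
    }
  }
  reg$assignments <- a

  structure(list(src_id = src_id, n_records = nrow(records),
                 n_rejected = length(rejects),
                 n_new_structures = n_new_structures,
                 n_new_edges = n_new_edges,
                 n_current = sum(a$src_id == src_id & a$current == 1L),
                 n_obsoleted = n_obsoleted,
                 rejects = rejects),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf(
    "load report (src_id %d): %d records, %d rejected, %d new structures, %d new hierarchy edges, %d current assignments, %d obsoleted\n",
    x$src_id, x$n_records, x$n_rejected, x$n_new_structures, x$n_new_edges,
    x$n_current, x$n_obsoleted))
  for (r in x$rejects) cat("  rejected: ", r, "\n", sep = "")
  invisible(x)
}

#' Resolve InChI-less structures against InChI-bearing ones
#'
#' A keys-only source contributes structures known only by their InChIKey.
#' When another source later supplies an InChI whose key matches, the two
#' structure rows are merged: assignments are repointed at the InChI-bearing
#' row and the empty row is dropped, so the key's InChI is taken to be the
#' correct InChI for the keys-only source.
#'
#' @param reg a registry.
#' @return Integer: the number of structures still lacking an InChI.
#' @export
registry_backfill_keys_only <- function(reg) {
  stopifnot(inherits(reg, "inchilink_registry"))
  s <- reg$structures
  empty <- which(is.na(s$standardinchi))
  drop <- integer(0)
  for (i in empty) {
    donor <- which(s$standardinchikey == s$standardinchikey[i] &
                     !is.na(s$standardinchi))
    if (length(donor)) {
      reg$assignments$uci[reg$assignments$uci == s$uci[i]] <- s$uci[donor[1]]
      drop <- c(drop, i)
    }
  }
  if (length(drop)) reg$structures <- s[-drop, , drop = FALSE]
  sum(is.na(reg$structures$standardinchi))
}

#' Hierarchy lookups
#'
#' `children_of()` returns the single-component FIKHBs recorded for a
#' multi-component parent FIKHB; `parents_of()` the inverse;
#' `component_frequency()` the number of distinct parents containing a child
#' (the quantity criterion D's sub-query blocking is based on).
#'
#' @param reg a registry.
#' @param fikhb a 14-character FIKHB.
#' @return `children_of`/`parents_of`: character vector (possibly empty);
#'   `component_frequency`: a non-negative integer.
#' @export
children_of <- function(reg, fikhb) {
  stopifnot(inherits(reg, "inchilink_registry"))
  reg$hierarchy$child[reg$hierarchy$parent == fikhb]
}

#' @rdname children_of
#' @export
parents_of <- function(reg, fikhb) {
  stopifnot(inherits(reg, "inchilink_registry"))
  reg$hierarchy$parent[reg$hierarchy$child == fikhb]
}

#' @rdname children_of
#' @export
component_frequency <- function(reg, fikhb) {
  length(unique(parents_of(reg, fikhb)))
}

# ---- persistence -----------------------------------------------------------

#' Write / read a registry directory
#'
#' The registry is persisted as four TSV tables plus `meta.json` recording
#' the key provider and the label table. Reading refuses a provider other
#' than the one the registry was built with, because FIKHBs from different
#' providers are incomparable.
#'
#' @param reg a registry.
#' @param dir directory path.
#' @param provider provider object to attach on read; must match the recorded
#'   provider name.
#' @return `registry_write`: `dir` invisibly; `registry_read`: a registry.
#' @export
registry_write <- function(reg, dir) {
  stopifnot(inherits(reg, "inchilink_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  wt(reg$sources, "sources.tsv")
  wt(reg$structures, "structures.tsv")
  wt(reg$assignments, "assignments.tsv")
  wt(reg$hierarchy, "hierarchy.tsv")
  meta <- list(provider = reg$provider$name, next_uci = reg$next_uci,
               labels = as.list(reg$labels))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname registry_write
#' @export
registry_read <- function(dir, provider = NULL) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (is.null(provider)) provider <- get_provider(meta$provider)
  if (!identical(provider$name, meta$provider))
    stop(sprintf("registry was built with provider '%s'; refusing to open with '%s'",
                 meta$provider, provider$name))
  rd <- function(f, col) utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE, colClasses = col,
    quote = "", comment.char = "", na.strings = "", stringsAsFactors = FALSE)
  reg <- registry_create(provider)
  reg$sources <- rd("sources.tsv", c("integer", "character", "integer"))
  reg$structures <- rd("structures.tsv",
                       c("integer", "character", "character", "character"))
  reg$assignments <- rd("assignments.tsv",
                        c("character", "integer", "integer", "integer"))
  reg$hierarchy <- rd("hierarchy.tsv", c("character", "character"))
  reg$next_uci <- as.integer(meta$next_uci)
  reg$labels <- unlist(meta$labels) %||% character(0)
  if (is.null(reg$labels)) reg$labels <- character(0)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a source assignment TSV
#'
#' Columns are `src_compound_id`, `standard_inchi` and optionally
#' `standard_inchikey` (keys-only dialect: `src_compound_id`,
#' `standard_inchikey`). A header line is optional and detected by the
#' literal prefix `src_compound_id`.
#'
#' @param path file path.
#' @param keys_only whether the file uses the keys-only two-column dialect.
#' @return A records data frame suitable for [registry_load_source()].
#' @export
read_source_file <- function(path, keys_only = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) && startsWith(lines[1], "src_compound_id"))
    lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  if (keys_only) {
    data.frame(src_compound_id = get(1), standardinchikey = get(2),
               stringsAsFactors = FALSE)
  } else {
    df <- data.frame(src_compound_id = get(1), standardinchi = get(2),
                     stringsAsFactors = FALSE)
    if (any(vapply(parts, length, 1L) >= 3)) df$standardinchikey <- get(3)
    df
  }
}
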