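# Connectivity search: key_search / cpd_search under the eight user criteria.
#
# Criteria (all default 0):
#   A source filter (0 = all sources, otherwise a src_id)
#   B pattern (0 = match on FIKHB, 1 = match on key minus proton flag)
#   C component mapping (0 matches, 1 matches a component of, 2 has a
#     component which matches, 3 has a component which matches a component
#     of, 4 = run 0-3 simultaneously)
#   D frequency block level for component sub-queries
#   E connectivity-length block for component sub-queries
#   F labels (0 = attach, 1 = off)
#   G assignment scope (0 = current only, 1 = current + obsolete)
#   H output shape (0 = flat, 1 = grouped by source; serialization concern)

#' Construct a search criteria vector
#'
#' @param A,B,C,D,E,F,G,H integers; see the package vignette for the meaning
#'   and range of each criterion. All default to 0.
#' @return A `search_criteria` list.
#' @export
search_criteria <- function(A = 0L, B = 0L, C = 0L, D = 0L, E = 0L,
                            F = 0L, G = 0L, H = 0L) {
  crit <- lapply(list(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H),
                 as.integer)
  stopifnot(crit$A >= 0L, crit$B %in% 0:1, crit$C %in% 0:4, crit$D >= 0L,
            crit$E >= 0L, crit$F %in% 0:1, crit$G %in% 0:1, crit$H %in% 0:1)
  structure(crit, class = "search_criteria")
}

#' Frequency threshold for component sub-query blocking
#'
#' Sub-queries for a single component are skipped when the component occurs
#' in more than this many distinct multi-component structures. The default
#' (`D = 0`) is 200; each increment of D raises the threshold tenfold, up to
#' a hard cap of 100000 that cannot be overridden.
#'
#' @param D non-negative integer, criterion D.
#' @return Integer threshold.
#' @export
freq_threshold <- function(D) {
  D <- as.integer(D)
  stopifnot(length(D) == 1L, D >= 0L)
  as.integer(min(200 * 10^D, 100000))
}

#' Labels for a hit's component FIKHBs
#'
#' @param component_fikhbs FIKHBs of the hit's components, in component order.
#' @param label_table named character vector mapping FIKHB to label text.
#' @return Character vector of label texts for the labelled components.
#' @export
annotate_labels <- function(component_fikhbs, label_table) {
  if (length(label_table) == 0L) return(character(0))
  unname(label_table[component_fikhbs[component_fikhbs %in% names(label_table)]])
}

# ---- query resolution ------------------------------------------------------

.new_context <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$status <- "ok"
  ctx$query_inchi <- NULL    # parsed_inchi or NULL
  ctx$query_key <- NULL      # full 27-char key or NULL
  ctx$query_fikhb <- NULL
  ctx$components <- NULL     # lazily: list(parsed=, key=, fikhb=)
  ctx$parse_count <- 0L
  class(ctx) <- "query_context"
  ctx
}

.ctx_parse <- function(ctx, inchi) {
  ctx$parse_count <- ctx$parse_count + 1L
  parse_inchi(inchi)
}

#' Resolve a key_search term into a query context
#'
#' A full 27-character Standard InChIKey is looked up in the registry: the
#' query runs only if the key is present and its structure carries an InChI
#' (a key known only from a keys-only source has no query InChI, so the
#' query cannot run and the context status is set accordingly). A bare
#' 14-letter FIKHB yields a context without a query InChI; hits are then
#' returned without per-layer difference flags.
#'
#' @param reg a registry.
#' @param term full key or 14-letter FIKHB.
#' @return A `query_context`.
#' @export
resolve_key_query <- function(reg, term) {
  stopifnot(inherits(reg, "inchilink_registry"))
  ctx <- .new_context()
  if (grepl(.FIKHB_RE, term)) {
    ctx$query_fikhb <- term
    return(ctx)
  }
  validate_inchikey(term)
  hit <- .find_structure_by_key(reg, term)
  inchi <- if (length(hit)) reg$structures$standardinchi[hit[1]] else NA_character_
  if (!length(hit) || is.na(inchi)) {
    ctx$status <- "no query InChI"
    return(ctx)
  }
  ctx$query_key <- term
  ctx$query_fikhb <- substr(term, 1L, 14L)
  ctx$query_inchi <- .ctx_parse(ctx, inchi)
  ctx
}

#' Resolve a cpd_search term into a query context
#'
#' Looks up the current assignment of `src_compound_id` within source
#' `src_id` and continues as [resolve_key_query()] with that structure's key.
#'
#' @param reg a registry.
#' @param src_compound_id the source's native compound identifier.
#' @param src_id the numeric source identifier (required to disambiguate).
#' @return A `query_context`.
#' @export
resolve_cpd_query <- function(reg, src_compound_id, src_id) {
  stopifnot(inherits(reg, "inchilink_registry"))
  ctx <- .new_context()
  if (!src_id %in% reg$sources$src_id) {
    ctx$status <- "unknown src_id"
    return(ctx)
  }
  a <- reg$assignments
  row <- which(a$src_compound_id == src_compound_id & a$src_id == src_id &
                 a$current == 1L)
  if (!length(row)) {
    ctx$status <- "unknown src_compound_id"
    return(ctx)
  }
  srow <- match(a$uci[row[1]], reg$structures$uci)
  inchi <- reg$structures$standardinchi[srow]
  if (is.na(inchi)) {
    ctx$status <- "no query InChI"
    return(ctx)
  }
  ctx$query_key <- reg$structures$standardinchikey[srow]
  ctx$query_fikhb <- reg$structures$fikhb[srow]
  ctx$query_inchi <- .ctx_parse(ctx, inchi)
  ctx
}

# query components: the split children of a multi-component query, or the
# query itself (degenerate single-component case).
.ctx_components <- function(ctx, reg) {
  if (!is.null(ctx$components)) return(ctx$components)
  p <- ctx$query_inchi
  if (is.null(p)) stop("component mapping requires a query InChI")
  if (sum(p$formula$count) >= 2L) {
    ch <- withCallingHandlers(split_components(p),
                              warning = function(w) invokeRestart("muffleWarning"))
    keys <- key_for(vapply(ch, serialize_inchi, ""), reg$provider)
    ctx$components <- lapply(seq_along(ch), function(i)
      list(parsed = ch[[i]], key = keys[i], fikhb = substr(keys[i], 1L, 14L),
           self = FALSE))
  } else {
    ctx$components <- list(list(parsed = p, key = ctx$query_key,
                                fikhb = ctx$query_fikhb, self = TRUE))
  }
  ctx$components
}

# ---- execution -------------------------------------------------------------

.empty_hits <- function(status = "ok", parse_count = 0L) {
  out <- data.frame(src_compound_id = character(0), src_id = integer(0),
                    source_name = character(0), standardinchi = character(0),
                    standardinchikey = character(0), relation = integer(0),
                    current = integer(0),
                    p = integer(0), b = integer(0), t = integer(0),
                    m = integer(0), s = integer(0), i = integer(0),
                    stringsAsFactors = FALSE)
  out$labels <- vector("list", 0L)
  attr(out, "status") <- status
  attr(out, "parse_count") <- parse_count
  out
}

#' Execute a connectivity search
#'
#' Runs the component-mapping relations requested by criterion C against the
#' registry and assembles one result record per matching
#' src_compound_id-to-structure assignment and relation:
#' \describe{
#'   \item{0 "Matches"}{structures whose pattern (criterion B) equals the
#'     query's pattern.}
#'   \item{1 "Matches a component of"}{structures whose FIKHB is a hierarchy
#'     parent of the query FIKHB.}
#'   \item{2 "Has a component which matches"}{structures matching the pattern
#'     of one of the query's components.}
#'   \item{3 "Has a component which matches a component of"}{structures whose
#'     FIKHB is a hierarchy parent of one of the query's component FIKHBs.}
#' }
#' `C = 4` runs all four simultaneously. Component sub-queries (relations 2
#' and 3) are skipped for components occurring in more than
#' [freq_threshold()]`(D)` distinct multi-component structures or whose
#' [connectivity_length()] is at most E; the query itself, standing in as its
#' own single component in the degenerate single-component case, is never
#' blocked, and records a degenerate component would duplicate are collapsed
#' onto the lower relation code. Hits whose structure lacks an InChI are
#' skipped, because per-layer comparison requires both a query and a
#' retrieved InChI. Each unique retrieved InChI is parsed exactly once per
#' query; the count is exposed as the `"parse_count"` attribute.
#'
#' @param reg a registry.
#' @param ctx a `query_context` from [resolve_key_query()] or
#'   [resolve_cpd_query()].
#' @param crit a [search_criteria()] vector.
#' @return A data frame of hit records ordered by (relation, src_id,
#'   src_compound_id), with columns `src_compound_id`, `src_id`,
#'   `source_name`, `standardinchi`, `standardinchikey`, `relation`,
#'   `current`, the six layer-difference flags `p,b,t,m,s,i` (NA for a bare
#'   FIKHB query), and a `labels` list column. Attributes: `status`,
#'   `parse_count`.
#' @export
execute_search <- function(reg, ctx, crit = search_criteria()) {
  stopifnot(inherits(reg, "inchilink_registry"), inherits(ctx, "query_context"),
            inherits(crit, "search_criteria"))
  if (ctx$status != "ok") return(.empty_hits(ctx$status))
  if (crit$B == 1L && is.null(ctx$query_key))
    stop("pattern requires full key (criterion B = 1 with a bare FIKHB query)")

  S <- reg$structures
  relations <- if (crit$C == 4L) 0:3 else crit$C
  pairs <- data.frame(uci = integer(0), relation = integer(0))
  add <- function(ucis, rel) {
    if (length(ucis))
      pairs <<- rbind(pairs, data.frame(uci = ucis, relation = rel))
  }

  q_pattern <- if (crit$B == 0L) ctx$query_fikhb else substr(ctx$query_key, 1L, 25L)
  s_pattern <- if (crit$B == 0L) S$fikhb else substr(S$standardinchikey, 1L, 25L)

  comps <- if (any(relations %in% c(2L, 3L))) .ctx_components(ctx, reg) else list()
  thr <- freq_threshold(crit$D)
  blocked <- vapply(comps, function(cp) {
    if (cp$self) return(FALSE)  # a direct query is never blocked
    component_frequency(reg, cp$fikhb) > thr ||
      connectivity_length(cp$parsed) <= crit$E
  }, TRUE)

  degenerate <- length(comps) == 1L && isTRUE(comps[[1]]$self)

  for (rel in relations) {
    if (rel == 0L) {
      add(S$uci[s_pattern == q_pattern], 0L)
    } else if (rel == 1L) {
      add(S$uci[S$fikhb %in% parents_of(reg, ctx$query_fikhb)], 1L)
    } else if (rel == 2L) {
      if (degenerate && 0L %in% relations) next  # collapses onto relation 0
      for (k in seq_along(comps)) {
        if (blocked[k]) next
        cp_pattern <- if (crit$B == 0L) comps[[k]]$fikhb else substr(comps[[k]]$key, 1L, 25L)
        add(S$uci[s_pattern == cp_pattern], 2L)
      }
    } else if (rel == 3L) {
      if (degenerate && 1L %in% relations) next  # collapses onto relation 1
      for (k in seq_along(comps)) {
        if (blocked[k]) next
        add(S$uci[S$fikhb %in% parents_of(reg, comps[[k]]$fikhb)], 3L)
      }
    }
  }
  pairs <- unique(pairs)
  if (!nrow(pairs)) return(.empty_hits("ok", ctx$parse_count))

  srows <- match(pairs$uci, S$uci)
  ok <- !is.na(S$standardinchi[srows])  # skip hits without a retrieved InChI
  pairs <- pairs[ok, , drop = FALSE]
  srows <- srows[ok]
  if (!nrow(pairs)) return(.empty_hits("ok", ctx$parse_count))

  # join assignments, applying G (scope) and A (source filter)
  a <- reg$assignments
  if (crit$G == 0L) a <- a[a$current == 1L, , drop = FALSE]
  if (crit$A != 0L) a <- a[a$src_id == crit$A, , drop = FALSE]
  arows <- lapply(pairs$uci, function(u) which(a$uci == u))
  nrep <- vapply(arows, length, 1L)
  if (!sum(nrep)) return(.empty_hits("ok", ctx$parse_count))
  arows <- unlist(arows)
  srows <- rep(srows, nrep)
  rel <- rep(pairs$relation, nrep)

  # parse-once: each unique retrieved InChI parsed a single time per query
  u_inchi <- unique(S$standardinchi[unique(srows)])
  parsed_cache <- lapply(u_inchi, function(x) .ctx_parse(ctx, x))
  names(parsed_cache) <- u_inchi

  if (!is.null(ctx$query_inchi)) {
    diffs <- lapply(u_inchi, function(x) layer_diff(ctx$query_inchi, parsed_cache[[x]]))
    names(diffs) <- u_inchi
  }

  hit_inchi <- S$standardinchi[srows]
  out <- data.frame(
    src_compound_id = a$src_compound_id[arows],
    src_id = a$src_id[arows],
    source_name = reg$sources$name[match(a$src_id[arows], reg$sources$src_id)],
    standardinchi = hit_inchi,
    standardinchikey = S$standardinchikey[srows],
    relation = rel,
    current = a$current[arows],
    stringsAsFactors = FALSE)

  if (!is.null(ctx$query_inchi)) {
    dm <- do.call(rbind, lapply(hit_inchi, function(x) diffs[[x]]))
    out <- cbind(out, as.data.frame(dm))
  } else {
    out[c("p", "b", "t", "m", "s", "i")] <- NA_integer_
  }

  if (crit$F == 0L && length(reg$labels)) {
    out$labels <- lapply(srows, function(sr) {
      comp_fikhbs <- children_of(reg, S$fikhb[sr])
      if (!length(comp_fikhbs)) comp_fikhbs <- S$fikhb[sr]
      annotate_labels(comp_fikhbs, reg$labels)
    })
  } else {
    out$labels <- rep(list(character(0)), nrow(out))
  }

  ord <- order(out$relation, out$src_id, out$src_compound_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  attr(out, "parse_count") <- ctx$parse_count
  out
}
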