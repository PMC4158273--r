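# Verification twin of execute_search(): recomputes a query's hit set by
# splitting every registered structure at query time and comparing layer
# strings directly -- no FIKHB hashes, no hierarchy table, no parse cache.
# Equality of hashed patterns is replaced by equality of the strings they
# hash: the basic layer (formula + /c + /h + /q) for FIKHB-level matching,
# and the whole InChI minus its proton layer for key-minus-proton-flag
# matching.

.basic_string <- function(p) {
  paste0(.formula_string(p), "/c", .layer(p, "c"), "/h", .layer(p, "h"),
         "/q", .layer(p, "q"))
}

.nonp_string <- function(p) {
  paste0(.basic_string(p), "/b", .layer(p, "b"), "/t", .layer(p, "t"),
         "/m", .layer(p, "m"), "/s", .layer(p, "s"), "/i", .layer(p, "i"))
}

.oracle_components <- function(p) {
  if (sum(p$formula$count) >= 2L) {
    withCallingHandlers(split_components(p),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else {
    list(p)
  }
}

#' Brute-force reference search
#'
#' Computes the same (assignment, relation) set as [execute_search()] by
#' direct structural comparison of every InChI-bearing structure in the
#' registry, independently of the FIKHB hierarchy and the key provider's
#' hashes. Intended for testing: slow but self-evidently correct.
#'
#' @param reg a registry (only its `structures`, `assignments` and `sources`
#'   tables are consulted).
#' @param ctx a `query_context` carrying a query InChI.
#' @param crit a [search_criteria()] vector.
#' @return Data frame with columns `src_compound_id`, `src_id`, `relation`,
#'   `current`, ordered like [execute_search()] output.
#' @export
oracle_search <- function(reg, ctx, crit = search_criteria()) {
  stopifnot(inherits(ctx, "query_context"), inherits(crit, "search_criteria"))
  empty <- data.frame(src_compound_id = character(0), src_id = integer(0),
                      relation = integer(0), current = integer(0),
                      stringsAsFactors = FALSE)
  if (ctx$status != "ok") return(empty)
  if (is.null(ctx$query_inchi))
    stop("oracle_search() requires a query InChI")

  q <- ctx$query_inchi
  S <- reg$structures
  keep <- !is.na(S$standardinchi)
  S <- S[keep, , drop = FALSE]
  parsed <- lapply(S$standardinchi, parse_inchi)
  basics <- vapply(parsed, .basic_string, "")
  nonps <- vapply(parsed, .nonp_string, "")
  multi <- vapply(parsed, function(p) sum(p$formula$count) >= 2L, TRUE)
  comps <- lapply(parsed, .oracle_components)
  comp_basics <- lapply(comps, function(cc) vapply(cc, .basic_string, ""))

  q_multi <- sum(q$formula$count) >= 2L
  q_comps <- if (q_multi) .oracle_components(q) else list(q)
  q_self <- !q_multi
  q_basic <- .basic_string(q)
  q_nonp <- .nonp_string(q)
  qc_basic <- vapply(q_comps, .basic_string, "")
  qc_nonp <- vapply(q_comps, .nonp_string, "")

  # blocking: frequency = distinct parent basic layers containing the
  # component, counted by scanning every multi-component structure
  thr <- freq_threshold(crit$D)
  blocked <- vapply(seq_along(q_comps), function(k) {
    if (q_self) return(FALSE)
    freq <- length(unique(basics[multi][vapply(
      comp_basics[multi], function(cb) qc_basic[k] %in% cb, TRUE)]))
    freq > thr || connectivity_length(q_comps[[k]]) <= crit$E
  }, TRUE)

  relations <- if (crit$C == 4L) 0:3 else crit$C
  degenerate <- q_self
  pairs <- data.frame(idx = integer(0), relation = integer(0))
  add <- function(idx, rel) {
    if (length(idx)) pairs <<- rbind(pairs, data.frame(idx = idx, relation = rel))
  }
  for (rel in relations) {
    if (rel == 0L) {
      hitm <- if (crit$B == 0L) basics == q_basic else nonps == q_nonp
      add(which(hitm), 0L)
    } else if (rel == 1L) {
      hitm <- multi & vapply(comp_basics, function(cb) q_basic %in% cb, TRUE)
      add(which(hitm), 1L)
    } else if (rel == 2L) {
      if (degenerate && 0L %in% relations) next
      for (k in seq_along(q_comps)) {
        if (blocked[k]) next
        hitm <- if (crit$B == 0L) basics == qc_basic[k] else nonps == qc_nonp[k]
        add(which(hitm), 2L)
      }
    } else if (rel == 3L) {
      if (degenerate && 1L %in% relations) next
      for (k in seq_along(q_comps)) {
        if (blocked[k]) next
        hitm <- multi & vapply(comp_basics, function(cb) qc_basic[k] %in% cb, TRUE)
        add(which(hitm), 3L)
      }
    }
  }
  pairs <- unique(pairs)
  if (!nrow(pairs)) return(empty)

  a <- reg$assignments
  if (crit$G == 0L) a <- a[a$current == 1L, , drop = FALSE]
  if (crit$A != 0L) a <- a[a$src_id == crit$A, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    rows <- which(a$uci == S$uci[pairs$idx[j]])
    if (!length(rows)) return(NULL)
    data.frame(src_compound_id = a$src_compound_id[rows],
               src_id = a$src_id[rows], relation = pairs$relation[j],
               current = a$current[rows], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  out <- unique(out)
  out <- out[order(out$relation, out$src_id, out$src_compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
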