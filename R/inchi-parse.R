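#' @title Standard InChI layer parsing
#' @description Internal grammar notes: a Standard InChI is
#'   `InChI=1S/<formula>/c<...>/h<...>/q<...>/p<...>/b<...>/t<...>/m<...>/s<...>/i<...>`
#'   where every layer after the formula is optional, layer codes appear at
#'   most once and in that canonical order, and the isotopic block (`/i`) runs
#'   to the end of the string (it may itself contain an isotopic mobile-H
#'   sublayer introduced by a further `/h`, which is kept opaque here).
#' @name inchi-parse
NULL

.LAYER_ORDER <- c("c", "h", "q", "p", "b", "t", "m", "s", "i")

inchi_error <- function(msg, segment = NULL) {
  if (!is.null(segment)) msg <- sprintf("%s [segment: %s]", msg, segment)
  stop(errorCondition(msg, class = c("inchi_parse_error", "error")))
}

#' Parse a Standard InChI string into its named layers
#'
#' Decomposes a Standard InChI into a molecular-formula table (with leading
#' multiplicities expanded, so `2ClH` becomes count 2 of segment `ClH`) and an
#' ordered map of layer code to raw layer text. Only Standard InChIs (version
#' tag `1S`) are accepted. The isotopic layer, including any of its own
#' sublayers, is stored as a single opaque unit under code `i`.
#'
#' @param x a single character string beginning `InChI=`.
#' @return An object of class `parsed_inchi`: a list with elements `version`
#'   (always `"1S"`), `formula` (data frame with integer `count` and character
#'   `segment`), and `layers` (named character vector keyed by layer code).
#' @seealso [serialize_inchi()] for the inverse operation.
#' @examples
#' p <- parse_inchi("InChI=1S/C7H7NO2/c8-6-3-1-5(2-4-6)7(9)10/h1-4H,8H2,(H,9,10)")
#' p$layers[["c"]]
#' @export
parse_inchi <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    inchi_error("input must be a single character string")
  if (!startsWith(x, "InChI="))
    inchi_error("malformed prefix: string must begin 'InChI='", substr(x, 1, 8))
  body <- substring(x, 7L)
  slash <- regexpr("/", body, fixed = TRUE)
  if (slash < 0L) inchi_error("missing formula: no '/' after version tag", body)
  version <- substr(body, 1L, slash - 1L)
  if (!identical(version, "1S"))
    inchi_error("non-standard version tag (only Standard InChI '1S' accepted)", version)
  toks <- strsplit(substring(body, slash + 1L), "/", fixed = TRUE)[[1]]
  if (length(toks) == 0L || toks[1] == "")
    inchi_error("empty formula layer")
  formula <- .parse_formula(toks[1])

  layers <- character(0)
  last_idx <- 0L
  k <- 2L
  while (k <= length(toks)) {
    tk <- toks[k]
    if (tk == "") inchi_error("empty layer segment ('//')")
    code <- substr(tk, 1L, 1L)
    if (code == "i") {
      # isotopic block swallows the remainder of the string as one unit
      itxt <- paste(c(substring(tk, 2L), toks[seq_along(toks) > k]), collapse = "/")
      if (itxt == "") inchi_error("empty isotopic layer", tk)
      layers[["i"]] <- itxt
      last_idx <- length(.LAYER_ORDER)
      break
    }
    idx <- match(code, .LAYER_ORDER)
    if (is.na(idx)) inchi_error(sprintf("unknown layer code '%s'", code), tk)
    if (code %in% names(layers))
      inchi_error(sprintf("duplicated layer '%s'", code), tk)
    if (idx <= last_idx)
      inchi_error(sprintf("layer '%s' out of canonical order c,h,q,p,b,t,m,s,i", code), tk)
    txt <- substring(tk, 2L)
    if (txt == "") inchi_error(sprintf("empty '%s' layer", code), tk)
    layers[[code]] <- txt
    last_idx <- idx
    k <- k + 1L
  }
  structure(list(version = "1S", formula = formula, layers = layers),
            class = "parsed_inchi")
}

.parse_formula <- function(txt) {
  segs <- strsplit(txt, ".", fixed = TRUE)[[1]]
  if (length(segs) == 0L || any(segs == ""))
    inchi_error("malformed formula layer", txt)
  m <- regmatches(segs, regexec("^([0-9]*)([A-Za-z][A-Za-z0-9]*)$", segs))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) inchi_error("malformed formula segment", segs[bad][1])
  count <- vapply(m, function(g) if (g[2] == "") 1L else as.integer(g[2]), 1L)
  segment <- vapply(m, `[`, "", 3L)
  if (any(count < 1L)) inchi_error("formula multiplicity must be positive", txt)
  if (any(vapply(m, function(g) g[2] == "1", TRUE)))
    inchi_error("redundant explicit multiplicity '1' in formula", txt)
  data.frame(count = count, segment = segment, stringsAsFactors = FALSE)
}

.formula_string <- function(p) {
  paste(ifelse(p$formula$count > 1L,
               paste0(p$formula$count, p$formula$segment),
               p$formula$segment),
        collapse = ".")
}

#' Serialize a parsed InChI back to its canonical string
#'
#' Exact inverse of [parse_inchi()]: `serialize_inchi(parse_inchi(x))` is
#' byte-identical to `x` for every syntactically valid Standard InChI.
#'
#' @param p a `parsed_inchi` object.
#' @return A single character string.
#' @export
serialize_inchi <- function(p) {
  stopifnot(inherits(p, "parsed_inchi"))
  out <- paste0("InChI=", p$version, "/", .formula_string(p))
  codes <- intersect(.LAYER_ORDER, names(p$layers))
  present <- codes[p$layers[codes] != ""]
  if (length(present))
    out <- paste0(out, paste0("/", present, p$layers[present], collapse = ""))
  out
}

#' @export
format.parsed_inchi <- function(x, ...) serialize_inchi(x)

#' @export
print.parsed_inchi <- function(x, ...) {
  cat("<parsed_inchi> ", serialize_inchi(x), "\n", sep = "")
  invisible(x)
}

.layer <- function(p, code) {
  v <- unname(p$layers[code])
  if (length(v) == 0L || is.na(v)) "" else v
}
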