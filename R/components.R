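# Multi-component (salt/mixture) handling: per-component sublayers are
# ';'-separated within a layer, repeated components are abbreviated 'N*text'
# in layers and by a leading count in the formula. Trailing empty sublayers
# may be omitted entirely in the printed string.

.SUBLAYER_CODES <- c("c", "h", "q", "b", "t")

#' Expand a parsed InChI into its per-component sublayer table
#'
#' Splits every sublayer-bearing layer (`c`, `h`, `q`, `b`, `t`) on `;`,
#' expands `N*` repetition shorthand and formula multiplicities, and pads
#' omitted trailing sublayers with empty text, so that every layer carries
#' exactly one entry per component. The stereo-parity layer `/m` is split one
#' character per component (`.` meaning "no parity for this component"), the
#' `/s` layer is kept as a single global value, and the isotopic block is kept
#' opaque.
#'
#' @param p a `parsed_inchi` object.
#' @return An object of class `component_table`: a list with
#'   `n_components`, `per_layer` (list of character vectors keyed by layer
#'   code), `m_chars`, `s_value` and `i_text`.
#' @export
expand_components <- function(p) {
  stopifnot(inherits(p, "parsed_inchi"))
  n <- sum(p$formula$count)
  per_layer <- lapply(.SUBLAYER_CODES, function(code) {
    txt <- .layer(p, code)
    if (txt == "") return(rep("", n))
    toks <- strsplit(txt, ";", fixed = TRUE)[[1]]
    if (length(toks) == 0L) toks <- ""
    expanded <- unlist(lapply(toks, function(tk) {
      m <- regmatches(tk, regexec("^([0-9]+)\\*(.*)$", tk))[[1]]
      if (length(m)) rep(m[3], as.integer(m[2])) else tk
    }), use.names = FALSE)
    if (length(expanded) > n)
      inchi_error(sprintf(
        "layer '%s' has %d sublayers after expansion but only %d components",
        code, length(expanded), n), txt)
    c(expanded, rep("", n - length(expanded)))
  })
  names(per_layer) <- .SUBLAYER_CODES

  mtxt <- .layer(p, "m")
  if (mtxt == "") {
    m_chars <- rep(".", n)
  } else {
    m_chars <- strsplit(mtxt, "", fixed = TRUE)[[1]]
    if (!all(m_chars %in% c("0", "1", ".")))
      inchi_error("m layer may contain only '0', '1' and '.'", mtxt)
    if (length(m_chars) != n)
      inchi_error(sprintf("m layer has %d characters for %d components",
                          length(m_chars), n), mtxt)
  }
  structure(list(n_components = n,
                 per_layer = per_layer,
                 m_chars = m_chars,
                 s_value = .layer(p, "s"),
                 i_text = .layer(p, "i")),
            class = "component_table")
}

#' Split a multi-component InChI into single-component InChIs
#'
#' Each expanded component is reassembled into a stand-alone Standard InChI
#' from its formula segment and its `c`, `h`, `q`, `b`, `t` sublayers. A
#' component with a stereo parity character receives that character as its
#' `/m` layer together with an `/s` layer (the parent's value for relative or
#' unknown stereo, `/s2` / `/s3`, otherwise `/s1`). The proton layer `/p` is
#' never propagated to children: it encodes a whole-structure proton balance
#' and contributes only to the final InChIKey character, never to the
#' connectivity hash. An isotopic parent has its `/i` block dropped from the
#' children (with a warning): children are generated from the non-isotopic
#' layers only.
#'
#' Duplicate components (from `N*` or formula multiplicities, or identical
#' sublayers) are returned once each, with their multiplicity recorded in the
#' `"multiplicity"` attribute.
#'
#' @param p a `parsed_inchi` with at least two components.
#' @return A list of `parsed_inchi` children, in first-appearance order, with
#'   an integer `"multiplicity"` attribute of the same length.
#' @examples
#' salt <- parse_inchi(
#'   "InChI=1S/C7H7NO2.Na/c8-6-3-1-5(2-4-6)7(9)10;/h1-4H,8H2,(H,9,10);/q;+1/p-1")
#' vapply(split_components(salt), serialize_inchi, "")
#' @export
split_components <- function(p) {
  stopifnot(inherits(p, "parsed_inchi"))
  ct <- expand_components(p)
  if (ct$n_components < 2L)
    stop("split_components() requires a multi-component InChI")
  if (ct$i_text != "")
    warning("isotopic layer dropped: children generated from non-isotopic layers only")
  segs <- rep(p$formula$segment, p$formula$count)
  children <- vector("list", ct$n_components)
  for (k in seq_len(ct$n_components)) {
    layers <- character(0)
    for (code in .SUBLAYER_CODES) {
      v <- ct$per_layer[[code]][k]
      if (v != "") layers[[code]] <- v
    }
    if (ct$m_chars[k] %in% c("0", "1")) {
      layers[["m"]] <- ct$m_chars[k]
      layers[["s"]] <- if (ct$s_value %in% c("2", "3")) ct$s_value else "1"
    }
    children[[k]] <- structure(
      list(version = "1S",
           formula = data.frame(count = 1L, segment = segs[k],
                                stringsAsFactors = FALSE),
           layers = layers),
      class = "parsed_inchi")
  }
  strs <- vapply(children, serialize_inchi, "")
  keep <- !duplicated(strs)
  out <- children[keep]
  attr(out, "multiplicity") <- as.integer(table(factor(strs, levels = strs[keep])))
  out
}

#' Length of an InChI up to the end of its connection layer
#'
#' Counts characters of the serialized string from the first formula character
#' through the last character of the `/c` layer (formula alone when there is
#' no connection layer). Used by search criterion E to identify trivially
#' small components such as water or chloride.
#'
#' @param p a `parsed_inchi`.
#' @return An integer character count.
#' @export
connectivity_length <- function(p) {
  stopifnot(inherits(p, "parsed_inchi"))
  n <- nchar(.formula_string(p))
  ctxt <- .layer(p, "c")
  if (ctxt != "") n <- n + 2L + nchar(ctxt)
  as.integer(n)
}

#' Per-layer difference flags between two InChIs
#'
#' Compares the raw text of the `p`, `b`, `t`, `m`, `s` and `i` layers of two
#' parsed InChIs: a flag is 1 when the layer text differs and 0 when it is
#' identical (a layer absent from both counts as identical). These are the
#' six annotation columns of a connectivity-search result row; the charge
#' layer is not compared because structures retrieved through the
#' connectivity hash can never differ in it.
#'
#' @param query,hit `parsed_inchi` objects.
#' @return A named integer vector with elements `p`, `b`, `t`, `m`, `s`, `i`,
#'   each 0 or 1.
#' @export
layer_diff <- function(query, hit) {
  stopifnot(inherits(query, "parsed_inchi"), inherits(hit, "parsed_inchi"))
  codes <- c("p", "b", "t", "m", "s", "i")
  flags <- vapply(codes, function(code) {
    as.integer(!identical(.layer(query, code), .layer(hit, code)))
  }, 1L)
  names(flags) <- codes
  flags
}
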