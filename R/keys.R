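# Standard InChIKey handling and key providers.
#
# A Standard InChIKey is 27 characters: a 14-letter first hash block (FIKHB)
# encoding molecular formula + connectivity + charge (the basic, Mobile-H
# layer), a hyphen, an 8-letter second block encoding the remaining layers,
# the standard flag pair "SA", a hyphen, and a final protonation-flag letter
# encoding the /p layer ("N" for zero).

.KEY_RE   <- "^[A-Z]{14}-[A-Z]{8}SA-[A-Z]$"
.FIKHB_RE <- "^[A-Z]{14}$"

#' Validate a Standard InChIKey
#'
#' @param s a character string.
#' @return `s` invisibly classed as validated; errors name the violated rule
#'   (length, hyphen placement, letter alphabet, or non-standard flag pair).
#' @export
validate_inchikey <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("InChIKey must be a single character string")
  if (nchar(s) != 27L)
    stop(sprintf("InChIKey must be 27 characters, got %d: '%s'", nchar(s), s))
  if (substr(s, 15, 15) != "-" || substr(s, 26, 26) != "-")
    stop(sprintf("InChIKey must have hyphens at positions 15 and 26: '%s'", s))
  if (substr(s, 24, 25) != "SA")
    stop(sprintf("non-standard InChIKey (flag pair '%s', expected 'SA'): '%s'",
                 substr(s, 24, 25), s))
  if (!grepl(.KEY_RE, s))
    stop(sprintf("InChIKey blocks must be uppercase letters: '%s'", s))
  invisible(s)
}

#' Is a string a well-formed Standard InChIKey?
#' @param s character vector.
#' @return logical vector.
#' @export
is_inchikey <- function(s) grepl(.KEY_RE, s)

#' First InChIKey hash block (FIKHB)
#'
#' Extracts the 14-letter connectivity hash block from a full Standard
#' InChIKey; idempotent on a bare 14-letter block. Two structures share a
#' FIKHB exactly when they share molecular formula and atom connectivity
#' (the layers of the basic Mobile-H InChI).
#'
#' @param k a full 27-character Standard InChIKey or a bare 14-letter block.
#' @return The 14-character FIKHB.
#' @export
fikhb_of <- function(k) {
  if (!is.character(k) || length(k) != 1L || is.na(k))
    stop("fikhb_of() expects a single string")
  if (grepl(.FIKHB_RE, k)) return(k)
  validate_inchikey(k)
  substr(k, 1L, 14L)
}

#' Search pattern for a key under criterion B
#'
#' Criterion B selects the match pattern: `b = 0` matches on the FIKHB
#' (connectivity only); `b = 1` matches on the Standard InChIKey minus its
#' proton flag, i.e. the first 25 characters, so stereochemistry and isotopic
#' composition must also agree.
#'
#' @param k a Standard InChIKey (a bare FIKHB is accepted only for `b = 0`).
#' @param b 0 or 1.
#' @return The 14- or 25-character match pattern.
#' @export
pattern_of <- function(k, b) {
  stopifnot(b %in% c(0L, 1L))
  if (b == 0L) return(fikhb_of(k))
  if (grepl(.FIKHB_RE, k)) stop("pattern requires full key")
  validate_inchikey(k)
  substr(k, 1L, 25L)
}

# ---- key providers ---------------------------------------------------------

#' Generate Standard InChIKeys for InChI strings
#'
#' @param inchi character vector of Standard InChI strings.
#' @param provider a key provider from [surrogate_provider()] or
#'   [toolkit_provider()].
#' @return Character vector of 27-character Standard InChIKeys.
#' @export
key_for <- function(inchi, provider) {
  stopifnot(inherits(provider, "key_provider"))
  keys <- provider$key_for(inchi)
  ok <- is_inchikey(keys)
  if (!all(ok))
    stop(sprintf("key provider '%s' returned an invalid key for: %s",
                 provider$name, inchi[!ok][1]))
  keys
}

#' Hermetic surrogate key provider
#'
#' A deterministic, pure-R provider that hashes the basic layer string
#' (formula + `/c` + `/h` + `/q`) into the 14-letter first block and the
#' remaining layers (`b`, `t`, `m`, `s`, `i`) into the 8-letter second block,
#' with standard flags `SA` and a proton character derived from `/p` (`N`
#' for none, offset up or down the alphabet by the proton count). It
#' preserves the structural equalities that matter to connectivity search --
#' identical basic layers give identical first blocks, identical stereo and
#' isotopic layers give identical second blocks -- without reproducing the
#' official truncated-SHA construction, so the whole engine can be exercised
#' on synthetic structures that no chemistry toolkit would accept.
#'
#' @return A `key_provider` object.
#' @export
surrogate_provider <- function() {
  structure(list(
    name = "surrogate",
    deterministic = TRUE,
    key_for = function(inchi) {
      vapply(inchi, .surrogate_key, "", USE.NAMES = FALSE)
    }), class = "key_provider")
}

.surrogate_key <- function(inchi) {
  p <- parse_inchi(inchi)
  basic <- paste0(.formula_string(p),
                  "/c", .layer(p, "c"), "/h", .layer(p, "h"), "/q", .layer(p, "q"))
  rest <- paste0("/b", .layer(p, "b"), "/t", .layer(p, "t"),
                 "/m", .layer(p, "m"), "/s", .layer(p, "s"), "/i", .layer(p, "i"))
  first  <- .hash_letters(basic, 14L)
  second <- .hash_letters(rest, 8L)
  ptxt <- .layer(p, "p")
  proton <- if (ptxt == "") {
    "N"
  } else {
    v <- suppressWarnings(as.integer(ptxt))
    if (is.na(v)) v <- 0L
    LETTERS[max(1L, min(26L, 14L + v))]  # N = neutral; O = +1, M = -1, ...
  }
  paste0(first, "-", second, "SA-", proton)
}

# FNV-1a 32-bit over the UTF-8 bytes, in double arithmetic (all intermediates
# stay below 2^53). One independent pass per output letter, distinguished by
# a position prefix; letters are the hash mod 26.
.hash_letters <- function(text, n) {
  bytes <- utf8ToInt(text)
  out <- character(n)
  for (i in seq_len(n)) {
    h <- 2166136261
    for (b in c(utf8ToInt(sprintf("%d:", i)), bytes)) {
      lo <- h %% 256
      h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
      # h * 16777619 mod 2^32, split to avoid exceeding 2^53
      hlo <- h %% 65536
      hhi <- (h - hlo) / 65536
      h <- (hlo * 16777619 + ((hhi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    out[i] <- LETTERS[(h %% 26) + 1]
  }
  paste(out, collapse = "")
}

#' InChI-toolkit key provider (Open Babel)
#'
#' Wraps the Open Babel command-line InChI implementation (`obabel`) to
#' produce real Standard InChIKeys, interoperable with keys found in public
#' compound databases. Inputs are batched through a temporary file, one InChI
#' per line.
#'
#' @param command path to the `obabel` executable (found on `PATH` by
#'   default).
#' @return A `key_provider` object.
#' @export
toolkit_provider <- function(command = "obabel") {
  if (Sys.which(command) == "")
    stop(sprintf("InChI toolkit executable '%s' not found on PATH", command))
  force(command)
  structure(list(
    name = "toolkit",
    deterministic = TRUE,
    key_for = function(inchi) {
      if (length(inchi) == 0L) return(character(0))
      inf <- tempfile(fileext = ".inchi")
      on.exit(unlink(inf))
      writeLines(inchi, inf)
      out <- suppressWarnings(
        system2(command, c("-iinchi", shQuote(inf), "-oinchikey"),
                stdout = TRUE, stderr = FALSE))
      out <- out[nzchar(out)]
      if (length(out) != length(inchi))
        stop(sprintf("toolkit produced %d keys for %d InChIs (offending batch starts: %s)",
                     length(out), length(inchi), inchi[1]))
      out
    }), class = "key_provider")
}

#' Look up a key provider by name
#' @param name `"surrogate"` or `"toolkit"`.
#' @return A `key_provider`.
#' @export
get_provider <- function(name) {
  switch(name,
         surrogate = surrogate_provider(),
         toolkit = toolkit_provider(),
         stop(sprintf("unknown key provider '%s' (use 'surrogate' or 'toolkit')", name)))
}

#' @export
print.key_provider <- function(x, ...) {
  cat(sprintf("<key_provider: %s>\n", x$name)); invisible(x)
}
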