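# Deterministic synthetic-data generator. Emits families of related
# structures -- a parent skeleton plus its salt/mixture forms, stereoisomers,
# isotopic and protonation variants -- as source assignment TSVs with a
# ground-truth manifest, so the whole engine is testable without any external
# data. Generated InChIs are syntactically valid Standard InChIs built from
# templated layers; they are chemically meaningful only to the surrogate key
# provider (real-chemistry coverage comes from a small set of literature
# InChIs exercised with the toolkit provider in the tests).

.COUNTER_IONS <- list(
  Na  = list(formula = "Na",  h = "",    q = "+1", p = "-1", label = "Na"),
  ClH = list(formula = "ClH", h = "1H",  q = "",   p = "",   label = "HCl"),
  K   = list(formula = "K",   h = "",    q = "+1", p = "-1", label = "K"),
  H2O = list(formula = "H2O", h = "1H2", q = "",   p = "",   label = "hydrate"))

#' Describe a synthetic structure family
#'
#' @param n_skeletons number of distinct parent skeletons.
#' @param counter_ions names of counter-ion / mixture-partner fragments
#'   (subset of `"Na"`, `"ClH"`, `"K"`, `"H2O"`); each skeleton gets one
#'   salt/mixture form per counter-ion.
#' @param stereo_variants stereoisomers generated per skeleton (and one
#'   stereo form of its first salt, exercising the known-parent-FIKHB path).
#' @param isotope_variants isotopically labelled forms per skeleton.
#' @param proton_variants protonation-state forms per skeleton.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_skeletons = 4L, counter_ions = c("Na", "ClH"),
                        stereo_variants = 1L, isotope_variants = 1L,
                        proton_variants = 1L, seed = 1L) {
  stopifnot(n_skeletons >= 1L, all(counter_ions %in% names(.COUNTER_IONS)),
            stereo_variants >= 0L, isotope_variants >= 0L,
            proton_variants >= 0L)
  structure(list(n_skeletons = as.integer(n_skeletons),
                 counter_ions = counter_ions,
                 stereo_variants = as.integer(stereo_variants),
                 isotope_variants = as.integer(isotope_variants),
                 proton_variants = as.integer(proton_variants),
                 seed = as.integer(seed)),
            class = "family_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# one random skeleton: formula + connection + hydrogen layers
.gen_skeleton <- function() {
  nc <- sample(5:9, 1)
  nn <- sample(0:2, 1)
  no <- sample(0:2, 1)
  nh <- nc + sample(1:4, 1)
  fmt_el <- function(sym, n) if (n == 0L) "" else if (n == 1L) sym else paste0(sym, n)
  formula <- paste0("C", nc, "H", nh, fmt_el("N", nn), fmt_el("O", no))
  heavy <- nc + nn + no
  ord <- sample(heavy)
  if (heavy >= 5 && runif(1) < 0.7) {
    ctxt <- paste0(paste(ord[1:2], collapse = "-"), "(", ord[3], ")",
                   paste(ord[4:heavy], collapse = "-"))
  } else {
    ctxt <- paste(ord, collapse = "-")
  }
  hh <- sample(2:(heavy - 1), 1)
  htxt <- sprintf("1-%dH,%dH%d", hh, min(hh + 1, heavy), sample(1:2, 1))
  list(formula = formula, c = ctxt, h = htxt)
}

.mk_inchi <- function(formula, layers) {
  layers <- layers[nzchar(layers)]
  paste0("InChI=1S/", formula,
         if (length(layers)) paste0("/", names(layers), layers, collapse = ""))
}

.salt_inchi <- function(sk, ion) {
  q <- if (ion$q != "") paste0(";", ion$q) else ""
  h <- if (ion$h != "") paste0(sk$h, ";", ion$h) else sk$h
  .mk_inchi(paste0(sk$formula, ".", ion$formula),
            c(c = sk$c, h = h, q = q, p = ion$p))
}

#' Generate a synthetic fixture: source TSVs plus ground truth
#'
#' Writes three source files into `out_dir` -- `source_1.tsv` (a primary
#' source holding every structure), `source_2.tsv` (a second source covering
#' a subset under its own identifiers), and `source_3_keys.tsv` (a keys-only
#' source: keys of a few loaded structures plus one key unique to it) --
#' together with a counter-ion label table and `manifest.json` holding the
#' expected FIKHB hierarchy edge set and, for a designated probe query (the
#' first salt, all-default criteria with C = 4), the expected hit set
#' computed by the built-in brute-force [oracle_search()].
#'
#' @param spec a [family_spec()].
#' @param out_dir output directory (created if needed).
#' @param provider key provider used for ground-truth keys (the surrogate by
#'   default; the generated structures are synthetic, so only the surrogate
#'   can key them).
#' @return The manifest, invisibly (also written as JSON).
#' @export
generate_fixture <- function(spec, out_dir, provider = surrogate_provider()) {
  stopifnot(inherits(spec, "family_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(spec$seed, {
    skels <- list()
    basics <- character(0)
    while (length(skels) < spec$n_skeletons) {
      sk <- .gen_skeleton()
      b <- paste(sk$formula, sk$c, sk$h)
      if (b %in% basics) next   # skeleton basic layers must be distinct
      skels[[length(skels) + 1L]] <- sk
      basics <- c(basics, b)
    }

    inchis <- character(0)
    for (k in seq_along(skels)) {
      sk <- skels[[k]]
      base <- .mk_inchi(sk$formula, c(c = sk$c, h = sk$h))
      fam <- base
      heavy <- length(strsplit(gsub("[()]", "-", sk$c), "-")[[1]])
      for (v in seq_len(spec$stereo_variants)) {
        tpos <- 1 + (v %% max(heavy - 1, 1))
        fam <- c(fam, .mk_inchi(sk$formula, c(
          c = sk$c, h = sk$h, t = sprintf("%d-", tpos + 1),
          m = as.character(v %% 2), s = "1")))
      }
      for (v in seq_len(spec$isotope_variants))
        fam <- c(fam, .mk_inchi(sk$formula, c(c = sk$c, h = sk$h,
                                              i = sprintf("%d+1", v))))
      for (v in seq_len(spec$proton_variants))
        fam <- c(fam, .mk_inchi(sk$formula, c(c = sk$c, h = sk$h,
                                              p = sprintf("%+d", -v))))
      for (ionname in spec$counter_ions) {
        ion <- .COUNTER_IONS[[ionname]]
        fam <- c(fam, .salt_inchi(sk, ion))
      }
      # a stereo form of the first salt: same parent FIKHB, novel stereo
      if (spec$stereo_variants > 0L && length(spec$counter_ions) > 0L) {
        ion <- .COUNTER_IONS[[spec$counter_ions[1]]]
        q <- if (ion$q != "") paste0(";", ion$q) else ""
        h <- if (ion$h != "") paste0(sk$h, ";", ion$h) else sk$h
        fam <- c(fam, .mk_inchi(paste0(sk$formula, ".", ion$formula),
                                c(c = sk$c, h = h, q = q, p = ion$p,
                                  t = "2-", m = "0.", s = "1")))
      }
      inchis <- c(inchis, fam)
    }
    inchis <- unique(inchis)
    keys <- key_for(inchis, provider)
    fikhbs <- substr(keys, 1L, 14L)

    # ground-truth hierarchy: split every distinct multi-component FIKHB once
    parsed <- lapply(inchis, parse_inchi)
    multi <- vapply(parsed, function(p) sum(p$formula$count) >= 2L, TRUE)
    edges <- do.call(rbind, lapply(which(multi & !duplicated(fikhbs)), function(j) {
      ch <- withCallingHandlers(split_components(parsed[[j]]),
                                warning = function(w) invokeRestart("muffleWarning"))
      ck <- key_for(vapply(ch, serialize_inchi, ""), provider)
      data.frame(parent = fikhbs[j], child = unique(substr(ck, 1L, 14L)),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
      edges <- data.frame(parent = character(0), child = character(0),
                          stringsAsFactors = FALSE)
    edges <- unique(edges)

    # source files
    main <- data.frame(src_compound_id = sprintf("MOL%04d", seq_along(inchis)),
                       standardinchi = inchis, standardinchikey = keys,
                       stringsAsFactors = FALSE)
    sub <- main[seq_len(nrow(main)) %% 3L == 1L, , drop = FALSE]
    sub$src_compound_id <- sub("MOL", "ALT", sub$src_compound_id)
    extra_key <- key_for("InChI=1S/Xe", provider)  # unique to the keys-only source
    keysrc <- data.frame(
      src_compound_id = c(sprintf("KEY%04d", seq_len(min(3L, nrow(main)))), "KEY9999"),
      standardinchikey = c(main$standardinchikey[seq_len(min(3L, nrow(main)))],
                           extra_key),
      stringsAsFactors = FALSE)

    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(main, "source_1.tsv")
    wt(sub, "source_2.tsv")
    wt(keysrc, "source_3_keys.tsv")

    ion_labels <- vapply(spec$counter_ions, function(nm) {
      ion <- .COUNTER_IONS[[nm]]
      fikhb_of(key_for(.mk_inchi(ion$formula, c(h = ion$h, q = ion$q)), provider))
    }, "")
    labels <- data.frame(fikhb = unname(ion_labels),
                         label = vapply(spec$counter_ions,
                                        function(nm) .COUNTER_IONS[[nm]]$label, ""),
                         stringsAsFactors = FALSE)
    wt(labels, "labels.tsv")

    # components blocked at default criteria (frequency over 200 parents)
    freq <- table(edges$child)
    blocked <- names(freq)[freq > freq_threshold(0L)]

    # probe expectation via the brute-force oracle on an ad-hoc table set
    probe <- NULL
    first_salt <- which(multi)[1]
    if (!is.na(first_salt)) {
      fake <- list(structures = data.frame(uci = seq_along(inchis),
                                           standardinchi = inchis,
                                           standardinchikey = keys,
                                           fikhb = fikhbs,
                                           stringsAsFactors = FALSE),
                   assignments = rbind(
                     data.frame(src_compound_id = main$src_compound_id,
                                src_id = 1L, uci = seq_along(inchis),
                                current = 1L, stringsAsFactors = FALSE),
                     data.frame(src_compound_id = sub$src_compound_id,
                                src_id = 2L,
                                uci = match(sub$standardinchikey, keys),
                                current = 1L, stringsAsFactors = FALSE),
                     # keys-only assignments that resolve to a loaded InChI
                     local({
                       u <- match(keysrc$standardinchikey, keys)
                       data.frame(src_compound_id = keysrc$src_compound_id[!is.na(u)],
                                  src_id = 3L, uci = u[!is.na(u)],
                                  current = 1L, stringsAsFactors = FALSE)
                     })))
      ctx <- .new_context()
      ctx$query_key <- keys[first_salt]
      ctx$query_fikhb <- fikhbs[first_salt]
      ctx$query_inchi <- parse_inchi(inchis[first_salt])
      exp_hits <- oracle_search(fake, ctx, search_criteria(C = 4L))
      probe <- list(term = keys[first_salt],
                    criteria = list(C = 4L),
                    expected = exp_hits)
    }

    manifest <- list(
      spec = unclass(spec),
      provider = provider$name,
      files = list(source_1 = "source_1.tsv", source_2 = "source_2.tsv",
                   source_3_keys = "source_3_keys.tsv", labels = "labels.tsv"),
      n_structures = length(inchis),
      expected_edges = edges,
      blocked_components = blocked,
      probe = probe)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", null = "null"),
               file.path(out_dir, "manifest.json"))
    invisible(manifest)
  })
}

#' Build a registry from a generated fixture directory
#'
#' Registers the three fixture sources (the third as keys-only), loads their
#' files, runs the keys-only backfill and attaches the counter-ion label
#' table.
#'
#' @param dir a directory written by [generate_fixture()].
#' @param provider key provider (must match the fixture's).
#' @return An `inchilink_registry`.
#' @export
fixture_registry <- function(dir, provider = surrogate_provider()) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(provider$name, manifest$provider))
    stop(sprintf("fixture was keyed with provider '%s'", manifest$provider))
  reg <- registry_create(provider)
  registry_add_source(reg, 1L, "moldb")
  registry_add_source(reg, 2L, "altdb")
  registry_add_source(reg, 3L, "keydb", keys_only = TRUE)
  registry_load_source(reg, 1L, read_source_file(file.path(dir, "source_1.tsv")))
  registry_load_source(reg, 2L, read_source_file(file.path(dir, "source_2.tsv")))
  registry_load_source(reg, 3L,
                       read_source_file(file.path(dir, "source_3_keys.tsv"),
                                        keys_only = TRUE))
  registry_backfill_keys_only(reg)
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  registry_set_labels(reg, stats::setNames(lab$label, lab$fikhb))
  reg
}
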