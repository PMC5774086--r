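#' An in-memory RDF triple store
#'
#' `rdf_graph()` creates an empty, environment-backed set of RDF triples.
#' Subjects are IRIs or blank nodes (a leading `"_:"` marks a blank node),
#' predicates are IRIs, and objects are IRIs, blank nodes or literals with an
#' optional datatype or language tag. Predicates and IRI positions may be
#' written as CURIEs (`"skos:Concept"`) against the graph's namespace table;
#' they are stored expanded.
#'
#' The store is a *set*: duplicate triples are collapsed. Triples are held in
#' a plain data frame (columns `s`, `p`, `o`, `o_type`, `o_dt`, `o_lang`)
#' retrievable with [rdf_triples()].
#'
#' @param namespaces Named character vector of prefix-to-IRI mappings used
#'   for CURIE expansion and for prefix compression when serializing.
#' @return An object of class `rdf_graph`.
#' @seealso [rdf_add()], [rdf_serialize()], [rdf_parse()], [rdf_isomorphic()]
#' @export
#' @examples
#' g <- rdf_graph()
#' rdf_add(g, "openbiodiv:x", "rdf:type", "skos:Concept")
#' rdf_size(g)
rdf_graph <- function(namespaces = default_namespaces()) {
  env <- new.env(parent = emptyenv())
  env$chunks <- list()
  env$cache <- empty_triples()
  env$dirty <- FALSE
  env$namespaces <- namespaces
  structure(list(env = env), class = "rdf_graph")
}

empty_triples <- function() {
  data.frame(
    s = character(), p = character(), o = character(),
    o_type = character(), o_dt = character(), o_lang = character(),
    stringsAsFactors = FALSE
  )
}

is_bnode <- function(x) startsWith(x, "_:")

#' Add triples with IRI or blank-node objects
#'
#' Vectorized over `s`, `p`, `o`. Terms may be CURIEs; a leading `"_:"`
#' denotes a blank node.
#'
#' @param g An [rdf_graph()].
#' @param s,p,o Character vectors (recycled to common length).
#' @return `g`, invisibly (the graph is modified in place).
#' @export
rdf_add <- function(g, s, p, o) {
  stopifnot(inherits(g, "rdf_graph"))
  n <- max(length(s), length(p), length(o))
  ns <- g$env$namespaces
  df <- data.frame(
    s = expand_term(rep_len(s, n), ns),
    p = ns_expand(rep_len(p, n), ns),
    o = expand_term(rep_len(o, n), ns),
    o_type = ifelse(is_bnode(rep_len(o, n)), "bnode", "iri"),
    o_dt = NA_character_, o_lang = NA_character_,
    stringsAsFactors = FALSE
  )
  push_triples(g, df)
}

#' Add triples with literal objects
#'
#' @inheritParams rdf_add
#' @param text Character vector of literal lexical forms.
#' @param datatype Optional datatype IRI or CURIE (e.g. `"xsd:integer"`).
#' @param lang Optional language tag. At most one of `datatype`/`lang`.
#' @return `g`, invisibly.
#' @export
rdf_add_literal <- function(g, s, p, text, datatype = NULL, lang = NULL) {
  stopifnot(inherits(g, "rdf_graph"))
  if (!is.null(datatype) && !is.null(lang)) {
    stop("a literal cannot carry both a datatype and a language tag")
  }
  n <- max(length(s), length(p), length(text))
  ns <- g$env$namespaces
  df <- data.frame(
    s = expand_term(rep_len(s, n), ns),
    p = ns_expand(rep_len(p, n), ns),
    o = as.character(rep_len(text, n)),
    o_type = "literal",
    o_dt = if (is.null(datatype)) NA_character_ else ns_expand(datatype, ns),
    o_lang = if (is.null(lang)) NA_character_ else lang,
    stringsAsFactors = FALSE
  )
  push_triples(g, df)
}

expand_term <- function(x, ns) ifelse(is_bnode(x), x, ns_expand(x, ns))

push_triples <- function(g, df) {
  g$env$chunks[[length(g$env$chunks) + 1L]] <- df
  g$env$dirty <- TRUE
  invisible(g)
}

#' Retrieve the triples of a graph
#'
#' @param g An [rdf_graph()].
#' @return Data frame with columns `s`, `p`, `o`, `o_type` (`"iri"`,
#'   `"bnode"` or `"literal"`), `o_dt`, `o_lang`; one row per distinct triple.
#' @export
rdf_triples <- function(g) {
  stopifnot(inherits(g, "rdf_graph"))
  if (g$env$dirty) {
    all <- rbind(g$env$cache, do.call(rbind, g$env$chunks))
    g$env$cache <- unique(all)
    rownames(g$env$cache) <- NULL
    g$env$chunks <- list()
    g$env$dirty <- FALSE
  }
  g$env$cache
}

#' Number of distinct triples
#' @param g An [rdf_graph()].
#' @return Integer count.
#' @export
rdf_size <- function(g) nrow(rdf_triples(g))

#' Match triples by pattern
#'
#' `NULL` positions are wildcards. `s`, `p`, `o` accept CURIEs.
#'
#' @param g An [rdf_graph()].
#' @param s,p,o Optional term filters (`o` matches IRI/bnode objects or, for
#'   literals, the exact lexical form).
#' @return Data frame of matching triples (same shape as [rdf_triples()]).
#' @export
rdf_match <- function(g, s = NULL, p = NULL, o = NULL) {
  tr <- rdf_triples(g)
  ns <- g$env$namespaces
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(s)) keep <- keep & tr$s %in% expand_term(s, ns)
  if (!is.null(p)) keep <- keep & tr$p %in% ns_expand(p, ns)
  if (!is.null(o)) keep <- keep & tr$o %in% c(expand_term(o, ns), o)
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Objects of matching triples
#' @inheritParams rdf_match
#' @return Character vector of object terms.
#' @export
rdf_objects <- function(g, s = NULL, p = NULL) unique(rdf_match(g, s = s, p = p)$o)

#' Subjects of matching triples
#' @inheritParams rdf_match
#' @return Character vector of subject terms.
#' @export
rdf_subjects <- function(g, p = NULL, o = NULL) unique(rdf_match(g, p = p, o = o)$s)

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", rdf_size(x), " triples, ",
      length(x$env$namespaces), " namespaces\n", sep = "")
  invisible(x)
}

#' Copy a graph
#'
#' Graphs are environment-backed; `rdf_clone()` yields an independent copy.
#' @param g An [rdf_graph()].
#' @return A new `rdf_graph` with the same triples and namespaces.
#' @export
rdf_clone <- function(g) {
  out <- rdf_graph(namespaces = g$env$namespaces)
  tr <- rdf_triples(g)
  if (nrow(tr)) push_triples(out, tr)
  out
}

# ---------------------------------------------------------------------------
# N-Triples-style canonical lines (used for comparison and hashing)

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  stringi::stri_replace_all_regex(
    x,
    c("\\\\n", "\\\\r", "\\\\t", "\\\\\"", "\\\\\\\\"),
    c("\n", "\r", "\t", "\"", "\\\\"),
    vectorize_all = FALSE
  )
}

term_object_str <- function(tr) {
  ifelse(
    tr$o_type == "literal",
    paste0(
      "\"", escape_literal(tr$o), "\"",
      ifelse(is.na(tr$o_lang), "", paste0("@", tr$o_lang)),
      ifelse(is.na(tr$o_dt), "", paste0("^^<", tr$o_dt, ">"))
    ),
    ifelse(tr$o_type == "bnode", tr$o, paste0("<", tr$o, ">"))
  )
}

canonical_lines <- function(tr) {
  subj <- ifelse(is_bnode(tr$s), tr$s, paste0("<", tr$s, ">"))
  sort(paste(subj, paste0("<", tr$p, ">"), term_object_str(tr), "."))
}

# ---------------------------------------------------------------------------
# Turtle serialization

pname_ok <- function(local) grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)

compress_iri <- function(iri, ns) {
  # longest-prefix compression to a CURIE when the local part is PN-safe;
  # NAs pass through (they arise when a vectorized caller mixes term kinds)
  nas <- is.na(iri)
  iri[nas] <- ""
  ord <- order(nchar(ns), decreasing = TRUE)
  for (i in ord) {
    base <- ns[[i]]
    hit <- startsWith(iri, base)
    if (any(hit)) {
      loc <- substring(iri[hit], nchar(base) + 1L)
      ok <- pname_ok(loc) | loc == ""
      iri[hit][ok] <- paste0(names(ns)[i], ":", loc[ok])
      iri[hit][!ok] <- paste0("<", iri[hit][!ok], ">")
      # mark done by protecting with angle brackets below
    }
  }
  miss <- (!grepl("^[A-Za-z]", iri) | grepl("^https?://", iri)) & !nas
  iri[miss & !startsWith(iri, "<")] <- paste0("<", iri[miss & !startsWith(iri, "<")], ">")
  iri[nas] <- NA_character_
  iri
}

turtle_term <- function(x, type, dt, lang, ns) {
  out <- character(length(x))
  lit <- type == "literal"
  bn <- type == "bnode"
  res <- !lit & !bn
  if (any(res)) out[res] <- compress_iri(x[res], ns)
  if (any(bn)) out[bn] <- x[bn]
  if (any(lit)) {
    base <- paste0("\"", escape_literal(x[lit]), "\"")
    tag <- ifelse(!is.na(lang[lit]), paste0("@", lang[lit]),
      ifelse(!is.na(dt[lit]), paste0("^^", compress_iri(dt[lit], ns)), "")
    )
    out[lit] <- paste0(base, tag)
  }
  out
}

serialize_turtle <- function(g) {
  tr <- rdf_triples(g)
  ns <- g$env$namespaces
  header <- paste0("@prefix ", names(ns), ": <", ns, "> .")
  if (!nrow(tr)) return(paste0(c(header, ""), collapse = "\n"))
  tr <- tr[order(tr$s, tr$p, tr$o), , drop = FALSE]
  subj_str <- ifelse(is_bnode(tr$s), tr$s, compress_iri(tr$s, ns))
  pred_str <- compress_iri(tr$p, ns)
  pred_str[tr$p == ns_expand("rdf:type")] <- "a"
  obj_str <- turtle_term(tr$o, tr$o_type, tr$o_dt, tr$o_lang, ns)
  blocks <- vapply(split(seq_len(nrow(tr)), factor(tr$s, levels = unique(tr$s))),
    function(idx) {
      lines <- character(0)
      preds <- split(idx, factor(pred_str[idx], levels = unique(pred_str[idx])))
      for (k in seq_along(preds)) {
        objs <- paste(obj_str[preds[[k]]], collapse = " , ")
        lines <- c(lines, paste0("    ", names(preds)[k], " ", objs))
      }
      paste0(subj_str[idx[1]], "\n", paste(lines, collapse = " ;\n"), " .")
    }, character(1)
  )
  paste0(paste(header, collapse = "\n"), "\n\n", paste(blocks, collapse = "\n\n"), "\n")
}

# ---------------------------------------------------------------------------
# Turtle parsing (the subset the package emits: prefixes, CURIEs, IRIs,
# blank-node labels, quoted literals with @lang / ^^datatype, ';' ',' '.')

ttl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    i <- 1L
    n <- nchar(line)
    while (i <= n) {
      ch <- substr(line, i, i)
      if (grepl("^\\s$", ch)) { i <- i + 1L; next }
      if (ch == "#") break
      if (ch == "<") {
        j <- regexpr(">", substring(line, i), fixed = TRUE)
        if (j < 0) stop("line ", ln, ": unterminated IRI")
        toks[[length(toks) + 1L]] <- list(t = "iri",
          v = substr(line, i + 1L, i + j - 2L), line = ln)
        i <- i + j
      } else if (ch == "\"") {
        j <- i + 1L
        while (j <= n) {
          cj <- substr(line, j, j)
          if (cj == "\\") { j <- j + 2L; next }
          if (cj == "\"") break
          j <- j + 1L
        }
        if (j > n) stop("line ", ln, ": unterminated string literal")
        val <- unescape_literal(substr(line, i + 1L, j - 1L))
        i <- j + 1L
        dt <- NA_character_; lang <- NA_character_
        rest <- substring(line, i)
        if (startsWith(rest, "@")) {
          m <- regmatches(rest, regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest))
          lang <- substring(m, 2L)
          i <- i + nchar(m)
        } else if (startsWith(rest, "^^")) {
          toks[[length(toks) + 1L]] <- list(t = "lit_pending", v = val, line = ln)
          i <- i + 2L
          toks[[length(toks) + 1L]] <- list(t = "dt_marker", v = "", line = ln)
          next
        }
        toks[[length(toks) + 1L]] <- list(t = "literal", v = val, dt = dt,
          lang = lang, line = ln)
      } else if (ch %in% c(".", ";", ",")) {
        toks[[length(toks) + 1L]] <- list(t = ch, v = ch, line = ln)
        i <- i + 1L
      } else {
        m <- regmatches(substring(line, i),
          regexpr("^[^\\s;,\"<>#]+", substring(line, i), perl = TRUE))
        if (!length(m) || !nzchar(m)) stop("line ", ln, ": unparsable character '", ch, "'")
        word <- m
        # a bare word may end with the statement terminator '.'
        if (grepl("\\.$", word) && !grepl("^(@prefix|@base)$", word) &&
            !grepl("^[0-9.]+$", word) && !grepl(":.*\\.[A-Za-z0-9_-]", word)) {
          word <- sub("\\.$", "", word)
          toks[[length(toks) + 1L]] <- list(t = "word", v = word, line = ln)
          toks[[length(toks) + 1L]] <- list(t = ".", v = ".", line = ln)
          i <- i + nchar(m)
          next
        }
        toks[[length(toks) + 1L]] <- list(t = "word", v = word, line = ln)
        i <- i + nchar(m)
      }
    }
  }
  toks
}

parse_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  # resolve pending datatype literals: lit_pending dt_marker <iri-or-word>
  resolved <- list()
  i <- 1L
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (identical(tk$t, "lit_pending")) {
      if (i + 2L > length(toks) || !identical(toks[[i + 1L]]$t, "dt_marker")) {
        stop("line ", tk$line, ": malformed datatype literal")
      }
      dtk <- toks[[i + 2L]]
      resolved[[length(resolved) + 1L]] <- list(t = "literal", v = tk$v,
        dt_raw = dtk, lang = NA_character_, line = tk$line)
      i <- i + 3L
    } else {
      resolved[[length(resolved) + 1L]] <- tk
      i <- i + 1L
    }
  }
  toks <- resolved

  ns <- character(0)
  g <- rdf_graph(namespaces = default_namespaces())
  rows <- list()
  resolve_res <- function(tk) {
    if (identical(tk$t, "iri")) return(tk$v)
    w <- tk$v
    if (identical(w, "a")) return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    if (startsWith(w, "_:")) return(w)
    if (grepl("^[A-Za-z][A-Za-z0-9_-]*:", w)) {
      pfx <- sub(":.*$", "", w)
      if (!pfx %in% names(ns)) stop("line ", tk$line, ": undeclared prefix '", pfx, "'")
      return(paste0(ns[[pfx]], sub("^[^:]*:", "", w)))
    }
    stop("line ", tk$line, ": expected IRI, CURIE or blank node, got '", w, "'")
  }

  i <- 1L
  xsd <- "http://www.w3.org/2001/XMLSchema#"
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (identical(tk$t, "word") && tk$v %in% c("@prefix", "PREFIX")) {
      pfx_tok <- toks[[i + 1L]]
      iri_tok <- toks[[i + 2L]]
      if (!identical(iri_tok$t, "iri")) stop("line ", tk$line, ": malformed @prefix")
      pfx <- sub(":$", "", pfx_tok$v)
      ns[[pfx]] <- iri_tok$v
      i <- i + 3L
      if (i <= length(toks) && identical(toks[[i]]$t, ".")) i <- i + 1L
      next
    }
    if (identical(tk$t, "word") && tk$v %in% c("@base", "BASE")) {
      stop("line ", tk$line, ": @base is not supported")
    }
    # subject
    subj <- resolve_res(tk)
    i <- i + 1L
    repeat {
      if (i > length(toks)) stop("line ", tk$line, ": statement not terminated with '.'")
      pred <- resolve_res(toks[[i]])
      i <- i + 1L
      repeat {
        if (i > length(toks)) stop("line ", tk$line, ": object expected before end of input")
        ot <- toks[[i]]
        if (identical(ot$t, "literal")) {
          dt <- NA_character_
          if (!is.null(ot$dt_raw)) dt <- resolve_res(ot$dt_raw)
          rows[[length(rows) + 1L]] <- data.frame(s = subj, p = pred, o = ot$v,
            o_type = "literal", o_dt = dt,
            o_lang = if (is.null(ot$lang)) NA_character_ else ot$lang,
            stringsAsFactors = FALSE)
        } else if (identical(ot$t, "word") && grepl("^[+-]?[0-9]+$", ot$v)) {
          rows[[length(rows) + 1L]] <- data.frame(s = subj, p = pred, o = ot$v,
            o_type = "literal", o_dt = paste0(xsd, "integer"),
            o_lang = NA_character_, stringsAsFactors = FALSE)
        } else if (identical(ot$t, "word") && ot$v %in% c("true", "false")) {
          rows[[length(rows) + 1L]] <- data.frame(s = subj, p = pred, o = ot$v,
            o_type = "literal", o_dt = paste0(xsd, "boolean"),
            o_lang = NA_character_, stringsAsFactors = FALSE)
        } else {
          res <- resolve_res(ot)
          rows[[length(rows) + 1L]] <- data.frame(s = subj, p = pred, o = res,
            o_type = if (is_bnode(res)) "bnode" else "iri", o_dt = NA_character_,
            o_lang = NA_character_, stringsAsFactors = FALSE)
        }
        i <- i + 1L
        if (i > length(toks)) stop("line ", ot$line, ": statement not terminated with '.'")
        sep <- toks[[i]]
        if (identical(sep$t, ",")) { i <- i + 1L; next }
        break
      }
      sep <- toks[[i]]
      if (identical(sep$t, ";")) {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= length(toks) && identical(toks[[i]]$t, ".")) { i <- i + 1L; break }
        next
      }
      if (identical(sep$t, ".")) { i <- i + 1L; break }
      stop("line ", sep$line, ": expected ',', ';' or '.', got '", sep$v, "'")
    }
  }
  if (length(ns)) {
    merged <- g$env$namespaces
    merged[names(ns)] <- unname(ns)
    g$env$namespaces <- merged
  }
  if (length(rows)) push_triples(g, do.call(rbind, rows))
  g
}

# ---------------------------------------------------------------------------
# RDF/XML serialization via xml2

serialize_rdfxml <- function(g) {
  tr <- rdf_triples(g)
  ns <- g$env$namespaces
  rdfns <- ns[["rdf"]]
  doc <- xml2::xml_new_root("rdf:RDF")
  for (p in names(ns)) xml2::xml_set_attr(doc, paste0("xmlns:", p), ns[[p]])
  split_pred <- function(p) {
    # QName split: namespace must be a declared prefix
    ord <- order(nchar(ns), decreasing = TRUE)
    for (i in ord) {
      if (startsWith(p, ns[[i]])) {
        loc <- substring(p, nchar(ns[[i]]) + 1L)
        if (pname_ok(loc)) return(c(names(ns)[i], loc))
      }
    }
    stop("cannot QName-split predicate for RDF/XML: ", p)
  }
  for (s in unique(tr$s)) {
    node <- xml2::xml_add_child(doc, "rdf:Description")
    if (is_bnode(s)) {
      xml2::xml_set_attr(node, "rdf:nodeID", substring(s, 3L))
    } else {
      xml2::xml_set_attr(node, "rdf:about", s)
    }
    rows <- tr[tr$s == s, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      qp <- split_pred(rows$p[k])
      child <- xml2::xml_add_child(node, paste0(qp[1], ":", qp[2]))
      if (rows$o_type[k] == "iri") {
        xml2::xml_set_attr(child, "rdf:resource", rows$o[k])
      } else if (rows$o_type[k] == "bnode") {
        xml2::xml_set_attr(child, "rdf:nodeID", substring(rows$o[k], 3L))
      } else {
        if (!is.na(rows$o_lang[k])) xml2::xml_set_attr(child, "xml:lang", rows$o_lang[k])
        if (!is.na(rows$o_dt[k])) xml2::xml_set_attr(child, "rdf:datatype", rows$o_dt[k])
        xml2::xml_set_text(child, rows$o[k])
      }
    }
  }
  as.character(doc)
}

parse_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
    error = function(e) stop("RDF/XML parse error: ", conditionMessage(e)))
  g <- rdf_graph()
  rows <- list()
  for (desc in xml2::xml_children(doc)) {
    about <- xml2::xml_attr(desc, "about")
    nodeid <- xml2::xml_attr(desc, "nodeID")
    s <- if (!is.na(about)) about else if (!is.na(nodeid)) paste0("_:", nodeid) else
      stop("RDF/XML parse error: description without rdf:about or rdf:nodeID")
    # a typed node element (<pfx:Class rdf:about=...>) asserts rdf:type
    nsmap <- xml2::xml_ns(doc)
    qn <- xml2::xml_name(desc, ns = nsmap)
    if (!qn %in% c("rdf:Description", "Description")) {
      cls <- paste0(nsmap[[sub(":.*$", "", qn)]], sub("^.*:", "", qn))
      rows[[length(rows) + 1L]] <- data.frame(s = s,
        p = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
        o = cls, o_type = "iri",
        o_dt = NA_character_, o_lang = NA_character_, stringsAsFactors = FALSE)
    }
    for (el in xml2::xml_children(desc)) {
      p <- paste0(xml2::xml_ns(doc)[[sub(":.*$", "", xml2::xml_name(el, ns = xml2::xml_ns(doc)))]],
                  sub("^.*:", "", xml2::xml_name(el, ns = xml2::xml_ns(doc))))
      res <- xml2::xml_attr(el, "resource")
      oid <- xml2::xml_attr(el, "nodeID")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- data.frame(s = s, p = p, o = res, o_type = "iri",
          o_dt = NA_character_, o_lang = NA_character_, stringsAsFactors = FALSE)
      } else if (!is.na(oid)) {
        rows[[length(rows) + 1L]] <- data.frame(s = s, p = p, o = paste0("_:", oid),
          o_type = "bnode", o_dt = NA_character_, o_lang = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        dt <- xml2::xml_attr(el, "datatype")
        lang <- xml2::xml_attr(el, "lang")
        rows[[length(rows) + 1L]] <- data.frame(s = s, p = p, o = xml2::xml_text(el),
          o_type = "literal", o_dt = dt, o_lang = lang, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) push_triples(g, do.call(rbind, rows))
  g
}

# ---------------------------------------------------------------------------
# Public serialization surface

#' Serialize a graph to Turtle or RDF/XML
#'
#' @param g An [rdf_graph()].
#' @param file Optional path; when `NULL` the serialization is returned as a
#'   single string.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return The serialization (invisibly when written to `file`).
#' @export
rdf_serialize <- function(g, file = NULL, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  text <- switch(format, turtle = serialize_turtle(g), rdfxml = serialize_rdfxml(g))
  if (is.null(file)) return(text)
  writeLines(text, file, useBytes = TRUE)
  invisible(text)
}

#' Parse Turtle or RDF/XML into a graph
#'
#' Errors carry line diagnostics from the underlying reader.
#'
#' @param file Path to a file, or `NULL` when `text` is given.
#' @param text Serialization as a single string (alternative to `file`).
#' @param format `"turtle"` or `"rdfxml"`.
#' @return An [rdf_graph()].
#' @export
rdf_parse <- function(file = NULL, text = NULL, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be supplied")
    text <- paste(readLines(file, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  switch(format, turtle = parse_turtle(text), rdfxml = parse_rdfxml(text))
}

#' Serialize-and-reparse round trip
#'
#' @param g An [rdf_graph()].
#' @param format `"turtle"` or `"rdfxml"`.
#' @return The reparsed [rdf_graph()]; [rdf_isomorphic()] to `g` by contract.
#' @export
rdf_roundtrip <- function(g, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  rdf_parse(text = rdf_serialize(g, format = format), format = format)
}

# ---------------------------------------------------------------------------
# Isomorphism (exact on ground graphs; signature refinement + bounded
# backtracking over blank nodes)

#' Test two graphs for isomorphism
#'
#' Ground triples must match exactly; blank nodes may be renamed. Blank-node
#' matching uses iterative signature refinement and, if signatures tie, a
#' bounded permutation search (ample for the small blank-node counts this
#' package produces).
#'
#' @param g1,g2 [rdf_graph()] objects.
#' @return Logical.
#' @export
rdf_isomorphic <- function(g1, g2) {
  t1 <- rdf_triples(g1); t2 <- rdf_triples(g2)
  if (nrow(t1) != nrow(t2)) return(FALSE)
  b1 <- unique(c(t1$s[is_bnode(t1$s)], t1$o[t1$o_type == "bnode"]))
  b2 <- unique(c(t2$s[is_bnode(t2$s)], t2$o[t2$o_type == "bnode"]))
  if (length(b1) != length(b2)) return(FALSE)
  if (!length(b1)) return(setequal(canonical_lines(t1), canonical_lines(t2)))

  sig <- function(tr, lab) {
    # one refinement round: signature of each bnode from its incident triples
    vapply(names(lab), function(b) {
      as_s <- tr[tr$s == b, , drop = FALSE]
      as_o <- tr[tr$o == b & tr$o_type == "bnode", , drop = FALSE]
      oo <- ifelse(as_s$o_type == "bnode", unname(lab[as_s$o]), term_object_str(as_s))
      ss <- ifelse(is_bnode(as_o$s), unname(lab[as_o$s]), paste0("<", as_o$s, ">"))
      paste(c(sort(paste("S", as_s$p, oo)), sort(paste("O", as_o$p, ss))), collapse = "|")
    }, character(1))
  }
  refine <- function(tr, bn) {
    lab <- stats::setNames(rep("b", length(bn)), bn)
    for (k in 1:4) {
      s <- sig(tr, lab)
      lab <- stats::setNames(as.character(match(s, sort(unique(s)))), bn)
    }
    lab
  }
  l1 <- refine(t1, b1); l2 <- refine(t2, b2)
  class_sizes <- function(l) {
    tt <- table(l)
    stats::setNames(as.integer(tt), names(tt))[order(names(tt))]
  }
  if (!identical(class_sizes(l1), class_sizes(l2))) return(FALSE)

  rename <- function(tr, map) {
    tr$s <- ifelse(is_bnode(tr$s), map[tr$s], tr$s)
    tr$o <- ifelse(tr$o_type == "bnode", map[tr$o], tr$o)
    tr
  }
  # group bnodes by signature class and try permutations within classes
  classes <- sort(unique(l1))
  groups1 <- lapply(classes, function(cl) names(l1)[l1 == cl])
  groups2 <- lapply(classes, function(cl) names(l2)[l2 == cl])
  total_perms <- prod(vapply(groups1, function(gr) factorial(length(gr)), numeric(1)))
  if (total_perms > 40320) {
    warning("blank-node structure too symmetric; isomorphism check may be incomplete")
    total_perms <- 40320
  }
  target <- canonical_lines(rename(t2, stats::setNames(
    paste0("_:c", seq_along(unlist(groups2))), unlist(groups2))))
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  group_perms <- lapply(groups1, perms_of)
  idx <- rep(1L, length(groups1))
  tried <- 0
  repeat {
    ordered <- unlist(mapply(function(ps, i) ps[[i]], group_perms, idx,
                             SIMPLIFY = FALSE))
    map <- stats::setNames(paste0("_:c", seq_along(ordered)), ordered)
    if (setequal(canonical_lines(rename(t1, map)), target)) return(TRUE)
    tried <- tried + 1
    if (tried >= total_perms) return(FALSE)
    # advance mixed-radix counter
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= length(group_perms[[k]])) break
      idx[k] <- 1L
      k <- k + 1L
      if (k > length(idx)) return(FALSE)
    }
  }
}
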