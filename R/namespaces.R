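#' Default namespace table
#'
#' Prefix-to-IRI map used by the term registry, the serializers and the
#' vocabularies. The unprefixed base namespace is `http://openbiodiv.net/`;
#' the remaining prefixes are the external ontologies the model aligns to
#' (SPAR's FaBiO and DEO for publishing, FRBR for work/expression, SKOS for
#' concept schemes, Darwin Core for the taxon alignment).
#'
#' @return Named character vector mapping prefixes to namespace IRIs.
#' @export
#' @examples
#' default_namespaces()[["skos"]]
default_namespaces <- function() {
  c(
    openbiodiv = "http://openbiodiv.net/",
    rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
    owl     = "http://www.w3.org/2002/07/owl#",
    xsd     = "http://www.w3.org/2001/XMLSchema#",
    skos    = "http://www.w3.org/2004/02/skos/core#",
    dcterms = "http://purl.org/dc/terms/",
    foaf    = "http://xmlns.com/foaf/0.1/",
    fabio   = "http://purl.org/spar/fabio/",
    deo     = "http://purl.org/spar/deo/",
    doco    = "http://purl.org/spar/doco/",
    po      = "http://www.essepuntato.it/2008/12/pattern#",
    frbr    = "http://purl.org/vocab/frbr/core#",
    dwc     = "http://rs.tdwg.org/dwc/terms/",
    dwciri  = "http://rs.tdwg.org/dwc/iri/",
    envo    = "http://purl.obolibrary.org/obo/",
    prism   = "http://prismstandard.org/namespaces/basic/2.0/"
  )
}

# Expand "prefix:local" against a namespace table; full IRIs pass through.
ns_expand <- function(x, ns = default_namespaces()) {
  out <- x
  hit <- grepl("^[A-Za-z][A-Za-z0-9]*:", x) & !grepl("^(https?|urn|file|mailto):", x)
  if (any(hit)) {
    pfx <- sub(":.*$", "", x[hit])
    loc <- sub("^[^:]*:", "", x[hit])
    base <- ns[pfx]
    if (anyNA(base)) {
      stop("unknown namespace prefix: ", paste(unique(pfx[is.na(base)]), collapse = ", "))
    }
    out[hit] <- paste0(base, loc)
  }
  out
}

# Shorthand builders for the model's own terms.
obn <- function(local) paste0("http://openbiodiv.net/", local)
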