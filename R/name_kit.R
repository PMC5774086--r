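#' @title Scientific-name parsing and formatting
#' @name name_kit
#' @description
#' A small grammar for latinized scientific names as they appear in
#' taxonomic articles:
#'
#' ```
#' name  = Genus [epithet] [marker epithet]
#'         [ "(" Author ["," year] ")"  |  Author [","] [year] ]
#' ```
#'
#' The genus is a capitalized latinized token; epithets are lower-case;
#' the infraspecific marker is one of `var.`, `subsp.`, `ssp.`, `f.`,
#' `subvar.`, `forma`. Authorship is kept as an opaque string (no splitting
#' of author teams); the year is a four-digit integer. Parenthesized
#' authorship (zoological recombinations) is recorded as a flag. Strings are
#' NFC-normalized and whitespace-collapsed before parsing.
NULL

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("taxograph_parse_error", "error", "condition")))
}

infraspecific_markers <- function() c("var.", "subsp.", "ssp.", "f.", "subvar.", "forma")

new_scientific_name <- function(genus, specificEpithet = NA_character_,
                                infraspecificMarker = NA_character_,
                                infraspecificEpithet = NA_character_,
                                authorship = NA_character_, year = NA_integer_,
                                parenthesizedAuthorship = FALSE,
                                yearComma = FALSE, verbatim) {
  structure(
    list(genus = genus, specificEpithet = specificEpithet,
         infraspecificMarker = infraspecificMarker,
         infraspecificEpithet = infraspecificEpithet,
         authorship = authorship, year = year,
         parenthesizedAuthorship = parenthesizedAuthorship,
         yearComma = yearComma, verbatim = verbatim),
    class = "scientific_name"
  )
}

#' @export
print.scientific_name <- function(x, ...) {
  cat("<scientific_name> ", format_name(x), "\n", sep = "")
  invisible(x)
}

squish <- function(s) trimws(gsub("\\s+", " ", s))

#' Parse a latinized scientific name
#'
#' @param s A non-empty string, e.g. `"Heser stoevi Deltschev 2016"` or
#'   `"Harmonia manillana (Mulsant, 1866)"`.
#' @return A `scientific_name` object with fields `genus`,
#'   `specificEpithet`, `infraspecificMarker`, `infraspecificEpithet`,
#'   `authorship`, `year`, `parenthesizedAuthorship` and `verbatim`.
#' @export
#' @examples
#' parse_scientific_name("Andropogon virginicus var. tenuispatheus")
parse_scientific_name <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s))) {
    stop_parse("`s` must be a single non-empty string")
  }
  verbatim <- squish(stringi::stri_trans_nfc(s))
  toks <- strsplit(verbatim, " ", fixed = TRUE)[[1]]

  if (!grepl("^[A-Z][a-zäëïöü-]+$", toks[1])) {
    stop_parse("no capitalized latinized head token in '", verbatim, "'")
  }
  genus <- toks[1]
  i <- 2L
  specificEpithet <- NA_character_
  infraMarker <- NA_character_
  infraEpithet <- NA_character_
  if (i <= length(toks) && grepl("^[a-z][a-z-]+$", toks[i]) &&
      !toks[i] %in% infraspecific_markers()) {
    specificEpithet <- toks[i]
    i <- i + 1L
  }
  if (i <= length(toks) && toks[i] %in% infraspecific_markers()) {
    if (is.na(specificEpithet)) {
      stop_parse("infraspecific marker without a specific epithet in '", verbatim, "'")
    }
    infraMarker <- toks[i]
    i <- i + 1L
    if (i > length(toks) || !grepl("^[a-z][a-z-]+$", toks[i])) {
      stop_parse("infraspecific marker not followed by an epithet in '", verbatim, "'")
    }
    infraEpithet <- toks[i]
    i <- i + 1L
  }

  authorship <- NA_character_
  year <- NA_integer_
  paren <- FALSE
  yearComma <- FALSE
  if (i <= length(toks)) {
    rest <- paste(toks[i:length(toks)], collapse = " ")
    if (startsWith(rest, "(")) {
      if (!endsWith(rest, ")")) stop_parse("unbalanced parenthesis in '", verbatim, "'")
      paren <- TRUE
      rest <- substr(rest, 2L, nchar(rest) - 1L)
    }
    if (grepl("^sec\\.?$|^sec\\. ", rest)) {
      stop_parse("'sec.' is a concept-label keyword, not an authorship: '", verbatim, "'")
    }
    if (grepl(",\\s*[0-9]{4}$", rest)) {
      year <- as.integer(sub("^.*?([0-9]{4})$", "\\1", rest))
      yearComma <- TRUE
      rest <- trimws(sub(",\\s*[0-9]{4}$", "", rest))
    } else if (grepl("(^|\\s)[0-9]{4}$", rest)) {
      year <- as.integer(sub("^.*?([0-9]{4})$", "\\1", rest))
      rest <- trimws(sub("\\s*[0-9]{4}$", "", rest))
    }
    if (nzchar(rest)) {
      if (!grepl("^[A-ZÀ-Þ(]", rest)) {
        stop_parse("unexpected token where authorship was expected: '", rest, "'")
      }
      authorship <- rest
    } else if (is.na(year)) {
      stop_parse("empty authorship in '", verbatim, "'")
    }
  }
  new_scientific_name(genus, specificEpithet, infraMarker, infraEpithet,
                      authorship, year, paren, yearComma, verbatim)
}

#' Render a scientific name canonically
#'
#' One-line canonical rendering; [parse_scientific_name()] of the result
#' reproduces the structured fields (`parse %∘% format` is the identity on
#' fields).
#'
#' @param n A `scientific_name`.
#' @return A single string.
#' @export
#' @examples
#' format_name(parse_scientific_name("Harmonia manillana (Mulsant, 1866)"))
format_name <- function(n) {
  stopifnot(inherits(n, "scientific_name"))
  parts <- c(n$genus,
             if (!is.na(n$specificEpithet)) n$specificEpithet,
             if (!is.na(n$infraspecificMarker)) c(n$infraspecificMarker, n$infraspecificEpithet))
  auth <- NULL
  if (!is.na(n$authorship) || !is.na(n$year)) {
    core <- if (!is.na(n$authorship)) n$authorship else ""
    if (!is.na(n$year)) {
      sep <- if (isTRUE(n$yearComma)) ", " else " "
      core <- if (nzchar(core)) paste0(core, sep, n$year) else as.character(n$year)
    }
    auth <- if (isTRUE(n$parenthesizedAuthorship)) paste0("(", core, ")") else core
  }
  paste(c(parts, auth), collapse = " ")
}

#' Parse a taxonomic name usage
#'
#' A taxonomic name usage is a scientific name optionally followed by a
#' taxonomic status abbreviation, e.g.
#' `"Heser stoevi Deltschev 2016, sp. n."`. The trailing status (comma- or
#' whitespace-delimited) is recognized via [classify_status()]; tokens that
#' do not classify are left with the name, so years and authorships are
#' never consumed.
#'
#' @param s A non-empty string.
#' @param extra Passed to [classify_status()] to extend the mapping.
#' @return A `name_usage_parse` list: `name` (a `scientific_name`),
#'   `status` (status class or `NA`), `statusVerbatim` (raw trailing text or
#'   `NA`).
#' @export
#' @examples
#' parse_taxonomic_name_usage("Heser stoevi Deltschev 2016, sp. n.")$status
parse_taxonomic_name_usage <- function(s, extra = NULL) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s))) {
    stop_parse("`s` must be a single non-empty string")
  }
  txt <- squish(stringi::stri_trans_nfc(s))
  status <- NA_character_
  statusVerbatim <- NA_character_
  namePart <- txt

  comma_at <- gregexpr(",", txt, fixed = TRUE)[[1]]
  if (comma_at[1] > 0) {
    last <- comma_at[length(comma_at)]
    cand <- trimws(substring(txt, last + 1L))
    if (nzchar(cand) && classify_status(cand, extra) != "Unclassified") {
      status <- classify_status(cand, extra)
      statusVerbatim <- cand
      namePart <- trimws(substr(txt, 1L, last - 1L))
    }
  }
  if (is.na(status)) {
    toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
    for (k in rev(seq_len(min(4L, length(toks) - 1L)))) {
      cand <- paste(toks[(length(toks) - k + 1L):length(toks)], collapse = " ")
      if (classify_status(cand, extra) != "Unclassified") {
        status <- classify_status(cand, extra)
        statusVerbatim <- cand
        namePart <- paste(toks[seq_len(length(toks) - k)], collapse = " ")
        break
      }
    }
  }
  structure(
    list(name = parse_scientific_name(namePart), status = status,
         statusVerbatim = statusVerbatim, verbatim = txt),
    class = "name_usage_parse"
  )
}

#' @export
print.name_usage_parse <- function(x, ...) {
  cat("<name_usage> ", format_name(x$name),
      if (!is.na(x$status)) paste0(" [", x$status, "]"), "\n", sep = "")
  invisible(x)
}

#' Parse a taxonomic concept label
#'
#' A taxonomic concept label is a Linnaean name plus a reference to the
#' circumscribing publication, joined by the keyword `sec.` (Latin
#' *secundum*), e.g.
#' `"Andropogon virginicus var. tenuispatheus sec. Blomquist (1948)"`.
#' The keyword is matched case-sensitively as an exact token.
#'
#' @param s A string containing the token `sec.`.
#' @return A `concept_label_parse` list: `name` (a `scientific_name`),
#'   `secReference` (non-empty citation string), `verbatim`.
#' @export
#' @examples
#' parse_concept_label("Casuarinicola australis Taylor, 2010 sec. Thorpe")
parse_concept_label <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s))) {
    stop_parse("`s` must be a single non-empty string")
  }
  txt <- squish(stringi::stri_trans_nfc(s))
  toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
  at <- which(toks == "sec.")
  if (!length(at)) {
    stop(errorCondition(
      paste0("not a taxonomic concept label (no 'sec.' keyword): '", txt, "'"),
      class = c("taxograph_not_a_concept_label", "taxograph_parse_error",
                "error", "condition")
    ))
  }
  at <- at[1]
  if (at == 1L) stop_parse("concept label lacks a name before 'sec.'")
  secReference <- paste(toks[-seq_len(at)], collapse = " ")
  if (!nzchar(secReference)) stop_parse("concept label lacks a reference after 'sec.'")
  structure(
    list(name = parse_scientific_name(paste(toks[seq_len(at - 1L)], collapse = " ")),
         secReference = secReference, verbatim = txt),
    class = "concept_label_parse"
  )
}

#' @export
print.concept_label_parse <- function(x, ...) {
  cat("<concept_label> ", format_name(x$name), " sec. ", x$secReference, "\n", sep = "")
  invisible(x)
}

#' Render a concept label canonically
#' @param cl A `concept_label_parse`.
#' @return `"<name> sec. <reference>"`.
#' @export
format_concept_label <- function(cl) {
  stopifnot(inherits(cl, "concept_label_parse"))
  paste(format_name(cl$name), "sec.", cl$secReference)
}
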