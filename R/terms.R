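# RDF term handling.
#
# Triples live in a plain data.frame ("triple table") with columns
#   s     subject IRI (blank nodes are skolemised to urn:skolem:... IRIs)
#   p     predicate IRI
#   o     object: IRI, or the lexical form when o_lit is TRUE
#   o_lit logical, TRUE for literal objects
#   o_dt  datatype IRI for literals (xsd:string for plain/lang-tagged), NA for IRIs
#
# All sorting in the package is byte-order ("radix") so results do not
# depend on the locale.

RDF_TYPE    <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
OWL_SAMEAS  <- "http://www.w3.org/2002/07/owl#sameAs"
XSD_NS      <- "http://www.w3.org/2001/XMLSchema#"
XSD_STRING  <- "http://www.w3.org/2001/XMLSchema#string"
RDF_LANGSTRING <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#langString"
SKOLEM_PREFIX <- "urn:skolem:"

SCHEMA_PREDICATES <- c(RDF_TYPE, RDFS_SUBCLASS, OWL_SAMEAS)

#' Construct a triple table
#'
#' Builds the plain-data.frame triple representation used throughout the
#' package. Objects are either IRIs (`o_lit = FALSE`) or literals
#' (`o_lit = TRUE`) carrying a datatype IRI; plain literals default to
#' `xsd:string`.
#'
#' @param s,p character vectors of subject and predicate IRIs.
#' @param o character vector of object IRIs or literal lexical forms.
#' @param o_lit logical vector flagging literal objects.
#' @param o_dt datatype IRIs for literals; `NA` for IRI objects.
#' @return a `data.frame` with columns `s, p, o, o_lit, o_dt`, deduplicated
#'   and sorted in byte order.
#' @export
rdf_triples <- function(s = character(), p = character(), o = character(),
                        o_lit = logical(length(s)), o_dt = rep(NA_character_, length(s))) {
  stopifnot(length(s) == length(p), length(p) == length(o),
            length(o) == length(o_lit), length(o) == length(o_dt))
  o_dt[o_lit & is.na(o_dt)] <- XSD_STRING
  o_dt[!o_lit] <- NA_character_
  df <- data.frame(s = as.character(s), p = as.character(p), o = as.character(o),
                   o_lit = as.logical(o_lit), o_dt = as.character(o_dt),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  sort_triples(df)
}

sort_triples <- function(df) {
  key <- object_key(df$o, df$o_lit, df$o_dt)
  df[order(df$s, df$p, key, method = "radix"), , drop = FALSE] |> reset_rownames()
}

reset_rownames <- function(df) { rownames(df) <- NULL; df }

# Canonical N-Triples-style key for an object term; used for dedup and sorting.
object_key <- function(o, o_lit, o_dt) {
  ifelse(o_lit, paste0('"', escape_ntriples(o), '"^^<', o_dt, ">"),
         paste0("<", o, ">"))
}

escape_ntriples <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_ntriples <- function(x) {
  # handles \\ \" \n \r \t \uXXXX \UXXXXXXXX
  vapply(x, function(one) {
    if (!grepl("\\\\", one)) return(one)
    out <- character(0)
    chars <- strsplit(one, "", fixed = TRUE)[[1]]
    i <- 1L; n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (ch == "\\" && i < n) {
        nx <- chars[i + 1L]
        rep2 <- switch(nx, n = "\n", r = "\r", t = "\t", "\"" = "\"",
                       "\\" = "\\", "'" = "'", NULL)
        if (!is.null(rep2)) { out <- c(out, rep2); i <- i + 2L; next }
        if (nx == "u" && i + 5L <= n) {
          code <- paste(chars[(i + 2L):(i + 5L)], collapse = "")
          out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 6L; next
        }
        if (nx == "U" && i + 9L <= n) {
          code <- paste(chars[(i + 2L):(i + 9L)], collapse = "")
          out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 10L; next
        }
      }
      out <- c(out, ch); i <- i + 1L
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Namespace prefix of an IRI
#'
#' The namespace of an IRI is everything up to and including the last `#`,
#' or failing that the last `/`; IRIs with neither are their own namespace.
#'
#' @param iri character vector of IRIs.
#' @return character vector of namespace prefixes.
#' @export
namespace_of <- function(iri) {
  hash <- regexpr("#", iri, fixed = TRUE)
  out <- character(length(iri))
  has_hash <- hash > 0
  out[has_hash] <- substr(iri[has_hash], 1L, hash[has_hash])
  rest <- !has_hash
  if (any(rest)) {
    # last slash, but not the ones in the scheme's "//"
    out[rest] <- vapply(iri[rest], function(u) {
      m <- gregexpr("/", u, fixed = TRUE)[[1]]
      m <- m[m > 8L | !grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", u)]
      if (length(m) == 0 || m[1] == -1) u else substr(u, 1L, max(m))
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

iri_in_namespaces <- function(iri, namespaces) {
  if (length(namespaces) == 0) return(rep(FALSE, length(iri)))
  res <- startsWith(iri, SKOLEM_PREFIX)  # skolemised blank nodes are internal
  for (ns in namespaces) res <- res | startsWith(iri, ns)
  res
}

local_name <- function(iri) {
  sub("^.*[#/]", "", iri)
}

# FNV-1a 32-bit hash of a UTF-8 string, returned as a decimal string.
# Used for stable node/link identifiers in exports. Arithmetic is done on
# 16-bit halves so every intermediate stays exactly representable.
fnv1a32 <- function(x) {
  vapply(x, function(one) {
    bytes <- as.integer(charToRaw(enc2utf8(one)))
    h <- 2166136261
    for (b in bytes) {
      lo <- h %% 65536; hi <- h %/% 65536
      lo <- bitwXor(as.integer(lo), b)
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    sprintf("%.0f", h)
  }, character(1), USE.NAMES = FALSE)
}
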