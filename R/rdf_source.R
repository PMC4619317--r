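# Uniform access to the analysed RDF resource.
#
# A "queryable graph" answers a small set of introspection operations with
# deterministic (byte-sorted) iteration order, independently of whether it
# is backed by parsed local files or by a SPARQL 1.1 endpoint. The SPARQL
# text sent by the endpoint backend is an implementation detail; any
# backend satisfying the operations' postconditions is conformant.

#' Describe an RDF resource to analyse
#'
#' @param input character vector of file paths (Turtle/.ttl, N-Triples/.nt,
#'   RDF-XML/.rdf/.owl). Mutually exclusive with `endpoint`.
#' @param endpoint SPARQL 1.1 endpoint URL (plain http).
#' @param namespaces character vector of IRI prefixes considered internal to
#'   the resource; needed to tell external references from invalid
#'   (untyped, in-resource) ones. At least one is required.
#' @param limit_per_predicate optional cap (>= 1) on the statements
#'   retrieved per predicate. Hitting the cap marks the predicate's links
#'   as truncated and their multiplicities as not determined.
#' @param timeout seconds per endpoint query.
#' @return a `resource_handle` object.
#' @export
resource_handle <- function(input = NULL, endpoint = NULL, namespaces,
                            limit_per_predicate = NULL, timeout = 60) {
  if (is.null(input) == is.null(endpoint)) {
    stop("exactly one of 'input' (files) or 'endpoint' (URL) must be given", call. = FALSE)
  }
  if (missing(namespaces) || length(namespaces) == 0 || !all(nzchar(namespaces))) {
    stop("at least one internal namespace prefix is required", call. = FALSE)
  }
  if (!is.null(limit_per_predicate)) {
    limit_per_predicate <- as.integer(limit_per_predicate)
    if (is.na(limit_per_predicate) || limit_per_predicate < 1L) {
      stop("limit_per_predicate must be a positive integer", call. = FALSE)
    }
  }
  structure(list(input = input, endpoint = endpoint,
                 namespaces = as.character(namespaces),
                 limit_per_predicate = limit_per_predicate,
                 timeout = as.numeric(timeout)),
            class = "resource_handle")
}

#' @export
print.resource_handle <- function(x, ...) {
  origin <- if (!is.null(x$input)) paste("files:", paste(x$input, collapse = ", "))
            else paste("endpoint:", x$endpoint)
  cat("<resource_handle> ", origin, "\n  namespaces: ",
      paste(x$namespaces, collapse = ", "), "\n", sep = "")
  if (!is.null(x$limit_per_predicate))
    cat("  limit per predicate:", x$limit_per_predicate, "\n")
  invisible(x)
}

#' Open a queryable graph for a resource
#'
#' File handles are parsed into an in-memory triple table; endpoint handles
#' are probed with an `ASK {}` query and queried lazily.
#'
#' @param handle a [resource_handle()].
#' @return an object of class `rdf_graph` (backend subclass `memory_graph`
#'   or `endpoint_graph`).
#' @export
rdf_load <- function(handle) {
  stopifnot(inherits(handle, "resource_handle"))
  if (!is.null(handle$input)) {
    parts <- lapply(handle$input, parse_rdf_file)
    triples <- if (length(parts) == 1L) parts[[1]] else {
      # re-skolemise per file so blank labels cannot collide across files
      for (i in seq_along(parts)) {
        for (col in c("s", "o")) {
          sk <- startsWith(parts[[i]][[col]], SKOLEM_PREFIX) &
                (col == "s" | !parts[[i]]$o_lit)
          parts[[i]][[col]][sk] <- sub(SKOLEM_PREFIX,
                                       paste0(SKOLEM_PREFIX, "f", i, "."),
                                       parts[[i]][[col]][sk], fixed = TRUE)
        }
      }
      sort_triples(unique(do.call(rbind, parts)))
    }
    memory_graph(triples, handle$namespaces, handle)
  } else {
    ok <- tryCatch(sparql_ask(handle$endpoint, "ASK {}", timeout = handle$timeout),
                   error = function(e) {
                     stop(sprintf("cannot reach SPARQL endpoint %s: %s",
                                  handle$endpoint, conditionMessage(e)), call. = FALSE)
                   })
    if (!isTRUE(ok)) stop(sprintf("endpoint %s did not answer ASK {}", handle$endpoint),
                          call. = FALSE)
    structure(list(url = handle$endpoint, namespaces = handle$namespaces,
                   handle = handle, cache = new.env(parent = emptyenv())),
              class = c("endpoint_graph", "rdf_graph"))
  }
}

#' Construct an in-memory queryable graph from a triple table
#'
#' @param triples a triple table ([rdf_triples()]).
#' @param namespaces internal namespace prefixes.
#' @param handle optional originating [resource_handle()].
#' @return a `memory_graph`.
#' @export
memory_graph <- function(triples, namespaces, handle = NULL) {
  if (is.null(handle)) {
    handle <- resource_handle(input = "<memory>", namespaces = namespaces)
    handle$input <- NULL; handle$memory <- TRUE
  }
  structure(list(triples = sort_triples(unique(triples)),
                 namespaces = as.character(namespaces), handle = handle),
            class = c("memory_graph", "rdf_graph"))
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<%s> %d triples\n", class(x)[1], graph_size(x)))
  invisible(x)
}

#' Number of triples in a queryable graph
#' @param g an `rdf_graph`.
#' @return integer triple count.
#' @export
graph_size <- function(g) UseMethod("graph_size")
#' @export
graph_size.memory_graph <- function(g) nrow(g$triples)
#' @export
graph_size.endpoint_graph <- function(g) {
  res <- ep_query(g, "SELECT (COUNT(*) AS ?n) WHERE { ?s ?p ?o }")
  as.integer(res$n)
}

#' Enumerate classes and their direct instance counts
#'
#' A class is any IRI used as the object of `rdf:type` or on either side of
#' `rdfs:subClassOf`. The count is the number of distinct subjects directly
#' typed with the class (0 allowed).
#'
#' @param g an `rdf_graph`.
#' @return `data.frame(class, instances)` sorted by class IRI.
#' @export
enumerate_classes <- function(g) UseMethod("enumerate_classes")
#' @export
enumerate_classes.memory_graph <- function(g) {
  tr <- g$triples
  typed <- tr[tr$p == RDF_TYPE & !tr$o_lit, c("s", "o")]
  sub <- tr[tr$p == RDFS_SUBCLASS & !tr$o_lit, c("s", "o")]
  cls <- sort(unique(c(typed$o, sub$s, sub$o)), method = "radix")
  typed <- unique(typed)
  counts <- table(factor(typed$o, levels = cls))
  data.frame(class = cls, instances = as.integer(counts), stringsAsFactors = FALSE)
}
#' @export
enumerate_classes.endpoint_graph <- function(g) {
  cls <- ep_query(g, paste0(
    "SELECT DISTINCT ?c WHERE { { [] <", RDF_TYPE, "> ?c } UNION { ?c <",
    RDFS_SUBCLASS, "> [] } UNION { [] <", RDFS_SUBCLASS, "> ?c } }"))
  counts <- ep_query(g, paste0(
    "SELECT ?c (COUNT(DISTINCT ?s) AS ?n) WHERE { ?s <", RDF_TYPE,
    "> ?c } GROUP BY ?c"))
  cl <- sort(unique(cls$c), method = "radix")
  n <- integer(length(cl))
  if (nrow(counts)) n[match(counts$c, cl)] <- as.integer(counts$n)
  n[is.na(n)] <- 0L
  data.frame(class = cl, instances = n, stringsAsFactors = FALSE)
}

#' Enumerate subclass links (with sameAs folded in)
#'
#' Every `rdfs:subClassOf` pair is returned once; every `owl:sameAs` pair
#' between IRIs used as classes is returned twice, once in each direction,
#' which is how class equivalence is folded into the hierarchy.
#'
#' @param g an `rdf_graph`.
#' @return `data.frame(child, parent)` sorted.
#' @export
enumerate_subclass_links <- function(g) UseMethod("enumerate_subclass_links")
#' @export
enumerate_subclass_links.memory_graph <- function(g) {
  tr <- g$triples
  sub <- tr[tr$p == RDFS_SUBCLASS & !tr$o_lit, c("s", "o")]
  same <- tr[tr$p == OWL_SAMEAS & !tr$o_lit, c("s", "o")]
  cls <- enumerate_classes(g)$class
  same <- same[same$s %in% cls & same$o %in% cls, , drop = FALSE]
  out <- rbind(
    data.frame(child = sub$s, parent = sub$o, stringsAsFactors = FALSE),
    data.frame(child = same$s, parent = same$o, stringsAsFactors = FALSE),
    data.frame(child = same$o, parent = same$s, stringsAsFactors = FALSE))
  out <- unique(out)
  reset_rownames(out[order(out$child, out$parent, method = "radix"), , drop = FALSE])
}
#' @export
enumerate_subclass_links.endpoint_graph <- function(g) {
  sub <- ep_query(g, paste0("SELECT ?a ?b WHERE { ?a <", RDFS_SUBCLASS, "> ?b }"))
  same <- ep_query(g, paste0("SELECT ?a ?b WHERE { ?a <", OWL_SAMEAS, "> ?b }"))
  cls <- enumerate_classes(g)$class
  keep <- same$a %in% cls & same$b %in% cls
  same <- same[keep, , drop = FALSE]
  out <- unique(rbind(
    data.frame(child = sub$a, parent = sub$b, stringsAsFactors = FALSE),
    data.frame(child = same$a, parent = same$b, stringsAsFactors = FALSE),
    data.frame(child = same$b, parent = same$a, stringsAsFactors = FALSE)))
  reset_rownames(out[order(out$child, out$parent, method = "radix"), , drop = FALSE])
}

#' Enumerate the non-schema predicates of a graph
#'
#' `rdf:type`, `rdfs:subClassOf` and `owl:sameAs` are excluded.
#'
#' @param g an `rdf_graph`.
#' @return sorted character vector of predicate IRIs.
#' @export
enumerate_predicates <- function(g) UseMethod("enumerate_predicates")
#' @export
enumerate_predicates.memory_graph <- function(g) {
  p <- setdiff(unique(g$triples$p), SCHEMA_PREDICATES)
  sort(p, method = "radix")
}
#' @export
enumerate_predicates.endpoint_graph <- function(g) {
  res <- ep_query(g, "SELECT DISTINCT ?p WHERE { [] ?p [] }")
  sort(setdiff(res$p, SCHEMA_PREDICATES), method = "radix")
}

#' Fetch the (subject, object) statements of one predicate
#'
#' Results are distinct pairs in byte-sorted order; with `limit` set the
#' sorted prefix is returned and `truncated` reports whether statements
#' were dropped (truncation invalidates multiplicity calculations
#' downstream).
#'
#' @param g an `rdf_graph`.
#' @param predicate predicate IRI.
#' @param limit optional positive integer.
#' @return `list(statements = data.frame(s, o, o_lit, o_dt), truncated = flag)`.
#' @export
fetch_statements <- function(g, predicate, limit = NULL) UseMethod("fetch_statements")
#' @export
fetch_statements.memory_graph <- function(g, predicate, limit = NULL) {
  tr <- g$triples
  st <- tr[tr$p == predicate, c("s", "o", "o_lit", "o_dt"), drop = FALSE]
  st <- unique(st)
  st <- st[order(st$s, object_key(st$o, st$o_lit, st$o_dt), method = "radix"), , drop = FALSE]
  truncated <- FALSE
  if (!is.null(limit) && nrow(st) > limit) { st <- st[seq_len(limit), , drop = FALSE]; truncated <- TRUE }
  list(statements = reset_rownames(st), truncated = truncated)
}
#' @export
fetch_statements.endpoint_graph <- function(g, predicate, limit = NULL) {
  q <- paste0("SELECT ?s ?o WHERE { ?s <", predicate, "> ?o }")
  if (!is.null(limit)) q <- paste0(q, " LIMIT ", as.integer(limit) + 1L)
  res <- ep_query(g, q, terms = "o")
  st <- data.frame(s = res$s, o = res$o, o_lit = res$o_lit, o_dt = res$o_dt,
                   stringsAsFactors = FALSE)
  st <- unique(st)
  st <- st[order(st$s, object_key(st$o, st$o_lit, st$o_dt), method = "radix"), , drop = FALSE]
  truncated <- FALSE
  if (!is.null(limit) && nrow(st) > limit) { st <- st[seq_len(limit), , drop = FALSE]; truncated <- TRUE }
  list(statements = reset_rownames(st), truncated = truncated)
}

# rdf:type assertions (s, type) with IRI objects; used by object
# classification and the integrity report.
type_assertions <- function(g) UseMethod("type_assertions")
#' @export
type_assertions.memory_graph <- function(g) {
  tr <- g$triples
  ty <- unique(tr[tr$p == RDF_TYPE & !tr$o_lit, c("s", "o"), drop = FALSE])
  names(ty) <- c("s", "type")
  reset_rownames(ty[order(ty$s, ty$type, method = "radix"), , drop = FALSE])
}
#' @export
type_assertions.endpoint_graph <- function(g) {
  if (is.null(g$cache$types)) {
    res <- ep_query(g, paste0("SELECT ?s ?o WHERE { ?s <", RDF_TYPE, "> ?o }"),
                    terms = "o")
    ty <- unique(data.frame(s = res$s[!res$o_lit], type = res$o[!res$o_lit],
                            stringsAsFactors = FALSE))
    g$cache$types <- reset_rownames(ty[order(ty$s, ty$type, method = "radix"), , drop = FALSE])
  }
  g$cache$types
}

# distinct subject IRIs of the graph
subject_iris <- function(g) UseMethod("subject_iris")
#' @export
subject_iris.memory_graph <- function(g) sort(unique(g$triples$s), method = "radix")
#' @export
subject_iris.endpoint_graph <- function(g) {
  if (is.null(g$cache$subjects)) {
    res <- ep_query(g, "SELECT DISTINCT ?s WHERE { ?s ?p ?o }")
    g$cache$subjects <- sort(unique(res$s), method = "radix")
  }
  g$cache$subjects
}

graph_namespaces <- function(g) g$namespaces

graph_limit <- function(g) {
  h <- g$handle
  if (is.null(h)) NULL else h$limit_per_predicate
}
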