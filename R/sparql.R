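# Minimal SPARQL 1.1 protocol support over plain HTTP.
#
# The client sends GET requests with a url-encoded `query` parameter and
# parses application/sparql-results+json. Everything is built on base-R
# sockets: libcurl-based transports are deliberately avoided so the code
# runs in network-restricted environments where only loopback traffic is
# possible.
#
# The package also ships a fixture endpoint server that serves a local RDF
# file over this protocol. It is a test double, not a SPARQL engine: it
# evaluates exactly the documented query templates the endpoint backend
# emits (ASK, class/predicate/subject enumeration, per-predicate statement
# dumps with LIMIT) against its loaded triple table.

parse_http_url <- function(url) {
  m <- regmatches(url, regexec("^http://([^:/]+)(?::([0-9]+))?(/.*)?$", url))[[1]]
  if (length(m) == 0) stop(sprintf("unsupported URL (plain http only): %s", url), call. = FALSE)
  list(host = m[2],
       port = if (nzchar(m[3])) as.integer(m[3]) else 80L,
       path = if (nzchar(m[4])) m[4] else "/")
}

http_get <- function(url, timeout = 60) {
  u <- parse_http_url(url)
  con <- tryCatch(
    socketConnection(u$host, u$port, blocking = TRUE, open = "r+b", timeout = timeout),
    error = function(e) stop(sprintf("connection error contacting %s: %s",
                                     url, conditionMessage(e)), call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("GET %s HTTP/1.1", u$path),
               sprintf("Host: %s:%d", u$host, u$port),
               "Accept: application/sparql-results+json",
               "Connection: close", ""), con, sep = "\r\n")
  flush(con)
  status <- readLines(con, n = 1)
  if (length(status) == 0) stop(sprintf("empty response from %s", url), call. = FALSE)
  code <- as.integer(strsplit(status, " ")[[1]][2])
  len <- NA_integer_
  repeat {
    h <- readLines(con, n = 1)
    if (length(h) == 0 || !nzchar(h)) break
    if (grepl("^content-length:", h, ignore.case = TRUE)) {
      len <- as.integer(trimws(sub("^[^:]+:", "", h)))
    }
  }
  body <- if (!is.na(len) && len > 0) {
    rawToChar(readBin(con, "raw", n = len))
  } else {
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }
  if (is.na(code) || code >= 400) {
    stop(sprintf("HTTP %s from %s: %s", code, url, substr(body, 1, 200)), call. = FALSE)
  }
  body
}

sparql_request <- function(url, query, timeout = 60) {
  full <- paste0(url, if (grepl("\\?", url)) "&" else "?", "query=",
                 utils::URLencode(query, reserved = TRUE))
  jsonlite::fromJSON(http_get(full, timeout = timeout), simplifyVector = FALSE)
}

# Run an ASK query; returns TRUE/FALSE.
sparql_ask <- function(url, query = "ASK {}", timeout = 60) {
  res <- sparql_request(url, query, timeout)
  isTRUE(res$boolean)
}

# Run a SELECT query, returning one character column per variable. Variables
# named in `terms` additionally get `<var>_lit` / `<var>_dt` columns so
# literal objects survive with their datatype.
sparql_select <- function(url, query, timeout = 60, terms = character()) {
  res <- sparql_request(url, query, timeout)
  vars <- unlist(res$head$vars)
  bindings <- res$results$bindings
  cols <- list()
  for (v in vars) {
    vals <- vapply(bindings, function(b) {
      t <- b[[v]]; if (is.null(t)) NA_character_ else as.character(t$value)
    }, character(1))
    cols[[v]] <- vals
    if (v %in% terms) {
      cols[[paste0(v, "_lit")]] <- vapply(bindings, function(b) {
        t <- b[[v]]; !is.null(t) && identical(t$type, "literal")
      }, logical(1))
      cols[[paste0(v, "_dt")]] <- vapply(bindings, function(b) {
        t <- b[[v]]
        if (is.null(t) || !identical(t$type, "literal")) return(NA_character_)
        if (!is.null(t$datatype)) as.character(t$datatype) else XSD_STRING
      }, character(1))
    }
  }
  if (length(bindings) == 0) {
    cols <- c(stats::setNames(lapply(vars, function(v) character(0)), vars),
              if (length(terms)) stats::setNames(
                rep(list(logical(0), character(0)), length(terms))[
                  order(rep(seq_along(terms), 2))],
                as.vector(rbind(paste0(terms, "_lit"), paste0(terms, "_dt")))))
    cols <- cols[!duplicated(names(cols))]
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# endpoint-graph query helper with per-handle timeout and retriable timeout
# errors carrying the query
ep_query <- function(g, query, terms = character()) {
  tryCatch(sparql_select(g$url, query, timeout = g$handle$timeout, terms = terms),
           error = function(e) {
             stop(sprintf("SPARQL query failed against %s: %s\nquery: %s",
                          g$url, conditionMessage(e), query), call. = FALSE)
           })
}

# ---------------------------------------------------------------------------
# fixture endpoint server

json_term <- function(o, lit, dt) {
  if (isTRUE(lit)) {
    if (identical(dt, XSD_STRING)) list(type = "literal", value = o)
    else list(type = "literal", value = o, datatype = dt)
  } else list(type = "uri", value = o)
}

sparql_answer <- function(triples, query) {
  q <- gsub("\\s+", " ", trimws(query))
  if (grepl("^ASK", q, ignore.case = TRUE)) {
    return(list(head = list(), boolean = TRUE))
  }
  mk <- function(vars, rows) {
    list(head = list(vars = as.list(vars)),
         results = list(bindings = rows))
  }
  if (grepl("SELECT \\(COUNT\\(\\*\\) AS \\?n\\)", q)) {
    return(mk("n", list(list(n = list(
      type = "literal", value = as.character(nrow(triples)),
      datatype = paste0(XSD_NS, "integer"))))))
  }
  if (grepl("^SELECT DISTINCT \\?c WHERE", q)) {
    typed <- triples[triples$p == RDF_TYPE & !triples$o_lit, ]
    sub <- triples[triples$p == RDFS_SUBCLASS & !triples$o_lit, ]
    cls <- sort(unique(c(typed$o, sub$s, sub$o)), method = "radix")
    return(mk("c", lapply(cls, function(v) list(c = list(type = "uri", value = v)))))
  }
  if (grepl("SELECT \\?c \\(COUNT\\(DISTINCT \\?s\\) AS \\?n\\)", q)) {
    typed <- unique(triples[triples$p == RDF_TYPE & !triples$o_lit, c("s", "o")])
    if (nrow(typed) == 0) return(mk(c("c", "n"), list()))
    tab <- table(typed$o)
    cls <- sort(names(tab), method = "radix")
    return(mk(c("c", "n"), lapply(cls, function(v) list(
      c = list(type = "uri", value = v),
      n = list(type = "literal", value = as.character(tab[[v]]),
               datatype = paste0(XSD_NS, "integer"))))))
  }
  m <- regmatches(q, regexec("^SELECT \\?a \\?b WHERE \\{ \\?a <([^>]+)> \\?b \\}$", q))[[1]]
  if (length(m)) {
    rows <- unique(triples[triples$p == m[2] & !triples$o_lit, c("s", "o")])
    rows <- rows[order(rows$s, rows$o, method = "radix"), , drop = FALSE]
    return(mk(c("a", "b"), lapply(seq_len(nrow(rows)), function(i) list(
      a = list(type = "uri", value = rows$s[i]),
      b = list(type = "uri", value = rows$o[i])))))
  }
  if (grepl("^SELECT DISTINCT \\?p WHERE", q)) {
    p <- sort(unique(triples$p), method = "radix")
    return(mk("p", lapply(p, function(v) list(p = list(type = "uri", value = v)))))
  }
  if (grepl("^SELECT DISTINCT \\?s WHERE \\{ \\?s \\?p \\?o \\}$", q)) {
    s <- sort(unique(triples$s), method = "radix")
    return(mk("s", lapply(s, function(v) list(s = list(type = "uri", value = v)))))
  }
  m <- regmatches(q, regexec(
    "^SELECT \\?s \\?o WHERE \\{ \\?s <([^>]+)> \\?o \\}(?: LIMIT ([0-9]+))?$", q))[[1]]
  if (length(m)) {
    rows <- unique(triples[triples$p == m[2], c("s", "o", "o_lit", "o_dt")])
    rows <- rows[order(rows$s, object_key(rows$o, rows$o_lit, rows$o_dt),
                       method = "radix"), , drop = FALSE]
    if (nzchar(m[3])) rows <- utils::head(rows, as.integer(m[3]))
    return(mk(c("s", "o"), lapply(seq_len(nrow(rows)), function(i) list(
      s = list(type = "uri", value = rows$s[i]),
      o = json_term(rows$o[i], rows$o_lit[i], rows$o_dt[i])))))
  }
  stop(sprintf("fixture endpoint cannot answer query: %s", q), call. = FALSE)
}

#' Serve a local RDF file as a SPARQL fixture endpoint
#'
#' Blocks and answers the query templates used by the package's endpoint
#' backend on `http://127.0.0.1:port/sparql` until `max_requests` requests
#' have been served, a request to `/shutdown` arrives, or `idle_timeout`
#' seconds pass without a connection. Intended for tests and for demoing
#' endpoint mode against local data; it is not a general SPARQL engine.
#'
#' @param path RDF file to serve.
#' @param port TCP port on 127.0.0.1.
#' @param max_requests stop after this many requests.
#' @param idle_timeout seconds of inactivity before the server exits.
#' @return invisibly, the number of requests served.
#' @export
sparql_fixture_server <- function(path, port, max_requests = 10000, idle_timeout = 120) {
  triples <- parse_rdf_file(path)
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0L
  idle <- 0
  while (served < max_requests && idle < idle_timeout) {
    con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 1),
                    error = function(e) NULL)
    if (is.null(con)) { idle <- idle + 1; next }
    idle <- 0
    req <- tryCatch(readLines(con, n = 1), error = function(e) character(0))
    while (length(h <- tryCatch(readLines(con, n = 1), error = function(e) character(0))) &&
           nzchar(h)) {}
    shutdown <- FALSE
    body <- tryCatch({
      target <- strsplit(req, " ")[[1]][2]
      if (is.na(target)) stop("bad request")
      if (startsWith(target, "/shutdown")) { shutdown <- TRUE; '{"status":"bye"}' }
      else {
        qpos <- regexpr("query=", target, fixed = TRUE)
        if (qpos < 0) stop("missing query parameter")
        query <- utils::URLdecode(substr(target, qpos + 6L, nchar(target)))
        as.character(jsonlite::toJSON(sparql_answer(triples, query), auto_unbox = TRUE))
      }
    }, error = function(e) paste0('{"error":', jsonlite::toJSON(conditionMessage(e)), "}"))
    status <- if (startsWith(body, '{"error"')) "HTTP/1.1 400 Bad Request" else "HTTP/1.1 200 OK"
    tryCatch({
      writeLines(c(status, "Content-Type: application/sparql-results+json",
                   sprintf("Content-Length: %d", nchar(body, type = "bytes")),
                   "Connection: close", ""), con, sep = "\r\n")
      writeChar(body, con, eos = NULL, useBytes = TRUE)
      flush(con)
    }, error = function(e) NULL)
    close(con)
    served <- served + 1L
    if (shutdown) break
  }
  invisible(served)
}

#' Pick a free loopback TCP port
#' @return an integer port number.
#' @export
pick_free_port <- function() {
  for (i in 1:50) {
    port <- sample(20000:60000, 1)
    s <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(s)) { close(s); return(port) }
  }
  stop("no free port found", call. = FALSE)
}

#' Start a background fixture endpoint for a local RDF file
#'
#' Launches `sparql_fixture_server()` in a separate `Rscript` process and
#' waits until it answers `ASK {}`.
#'
#' @param path RDF file to serve.
#' @param port port; a free one is picked when `NULL`.
#' @param timeout seconds to wait for readiness.
#' @return `list(url, port)`; pass `url` to [resource_handle()] and the
#'   whole value to [stop_fixture_endpoint()].
#' @export
start_fixture_endpoint <- function(path, port = NULL, timeout = 20) {
  if (is.null(port)) port <- pick_free_port()
  rscript <- file.path(R.home("bin"), "Rscript")
  code <- sprintf("rdfstruct::sparql_fixture_server(%s, %d, idle_timeout = 60)",
                  deparse(normalizePath(path)), port)
  system2(rscript, c("-e", shQuote(code)), wait = FALSE,
          stdout = FALSE, stderr = FALSE)
  url <- sprintf("http://127.0.0.1:%d/sparql", port)
  deadline <- Sys.time() + timeout
  while (Sys.time() < deadline) {
    ok <- suppressWarnings(tryCatch(sparql_ask(url, timeout = 2), error = function(e) FALSE))
    if (isTRUE(ok)) return(list(url = url, port = port))
    Sys.sleep(0.2)
  }
  stop(sprintf("fixture endpoint on port %d did not come up within %ds", port, timeout),
       call. = FALSE)
}

#' Stop a background fixture endpoint
#' @param ep value returned by [start_fixture_endpoint()].
#' @return invisibly `TRUE`.
#' @export
stop_fixture_endpoint <- function(ep) {
  tryCatch(http_get(sub("/sparql$", "/shutdown", ep$url), timeout = 2),
           error = function(e) NULL)
  invisible(TRUE)
}
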