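# ShEx compact syntax (ShExC, ShEx 2.x) export.
#
# One shape per class with instances; one triple constraint per class
# property, with an OR group when the class property holds several links.
# Cardinality tokens from the forward multiplicity: 1..1 none, 0..1 `?`,
# 1..N `+`, 0..N `*`; not_determined is emitted permissively as `*` with a
# warning comment (undetermined links are an integrity signal, not absent
# structure).

MULT_TO_SHEX <- c("1..1" = "", "0..1" = "?", "1..N" = "+", "0..N" = "*",
                  "not_determined" = "*")

#' Export a structure graph as ShEx compact syntax
#'
#' Datatype targets become literal datatype constraints; class targets with
#' instances become shape references; classes without instances, external
#' and invalid targets become `IRI` node-kind constraints with a comment
#' noting the kind.
#'
#' @param s a `structure_graph`.
#' @param path output file; `NULL` returns the text lines.
#' @return invisibly, a character vector of ShExC lines.
#' @export
export_shex <- function(s, path = NULL) {
  stopifnot(inherits(s, "structure_graph"))
  nodes <- s$class_tree$nodes
  with_inst <- nodes$class[nodes$instances > 0]
  links <- s$links
  out <- c(sprintf("PREFIX xsd: <%s>", XSD_NS), "")
  constraint <- function(link) {
    pred <- sprintf("<%s>", link$predicate)
    value <- switch(link$object_kind,
      datatype = {
        if (startsWith(link$object_type, XSD_NS))
          paste0("xsd:", substr(link$object_type, nchar(XSD_NS) + 1L, nchar(link$object_type)))
        else sprintf("<%s>", link$object_type)
      },
      class = if (link$object_type %in% with_inst) sprintf("@<%s>", link$object_type) else "IRI",
      external = "IRI",
      invalid = "IRI")
    card <- MULT_TO_SHEX[[link$forward]]
    note <- c()
    if (link$object_kind == "external") note <- sprintf("external reference into %s", link$object_type)
    if (link$object_kind == "invalid") note <- sprintf("invalid: untyped subject in %s", link$object_type)
    if (link$object_kind == "class" && !(link$object_type %in% with_inst))
      note <- sprintf("class <%s> has no instances", link$object_type)
    if (link$forward == "not_determined") note <- c(note, "multiplicity not determined")
    txt <- trimws(paste(pred, value, card))
    list(text = txt, note = if (length(note)) paste(note, collapse = "; ") else NULL)
  }
  for (cl in sort(with_inst, method = "radix")) {
    lc <- links[links$subject_type == cl, , drop = FALSE]
    out <- c(out, sprintf("<%s> {", cl))
    preds <- sort(unique(lc$predicate), method = "radix")
    body <- character(0)
    for (p in preds) {
      lp <- lc[lc$predicate == p, , drop = FALSE]
      lp <- lp[order(lp$object_type, method = "radix"), , drop = FALSE]
      cons <- lapply(seq_len(nrow(lp)), function(i) constraint(lp[i, ]))
      notes <- unlist(lapply(cons, `[[`, "note"))
      line <- if (length(cons) == 1) {
        cons[[1]]$text
      } else {
        paste0("( ", paste(vapply(cons, `[[`, character(1), "text"), collapse = " | "), " )")
      }
      if (length(notes)) line <- paste0(line, "  # ", paste(notes, collapse = "; "))
      body <- c(body, line)
    }
    if (length(body)) {
      # ';' separates triple constraints; comments must stay at line end
      sep <- c(rep(" ;", length(body) - 1L), "")
      with_sep <- mapply(function(b, s_) {
        if (grepl("#", b, fixed = TRUE) && nzchar(s_)) sub("  #", paste0(s_, "  #"), b)
        else paste0(b, s_)
      }, body, sep, USE.NAMES = FALSE)
      out <- c(out, paste0("  ", with_sep))
    }
    out <- c(out, "}", "")
  }
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Structural-integrity report
#'
#' Summarizes the findings recorded during recovery: unique type links
#' whose multiplicity could not be determined because they reference an
#' untyped in-resource subject, subjects bearing properties without a type,
#' and IRIs used both as class and predicate.
#'
#' @param s a `structure_graph`.
#' @param path optional text-file destination.
#' @return the findings `data.frame(kind, subject, detail)` in stable
#'   sorted order; the text report is written when `path` is given.
#' @export
integrity_report <- function(s, path = NULL) {
  stopifnot(inherits(s, "structure_graph"))
  f <- s$findings
  f <- reset_rownames(f[order(f$kind, f$subject, method = "radix"), , drop = FALSE])
  lines <- c(sprintf("%d issue%s", nrow(f), if (nrow(f) == 1) "" else "s"))
  if (nrow(f)) {
    counts <- table(f$kind)
    lines <- c(lines,
               sprintf("  %s: %d", names(counts), as.integer(counts)),
               "",
               sprintf("[%s] %s", f$kind, f$detail))
  }
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  attr(f, "report") <- lines
  f
}
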