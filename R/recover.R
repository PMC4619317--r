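# Structure recovery: from raw statements to the recovered structure graph
# with class tree, unique type links, occurrence counts, forward/reverse
# multiplicities and concept-class flags.

MULTIPLICITIES <- c("1..1", "1..N", "0..1", "0..N", "not_determined")
OBJECT_KINDS <- c("class", "datatype", "external", "invalid")

#' Classify one object term
#'
#' Literals map to their datatype (plain and language-tagged literals to
#' `xsd:string`). A typed IRI yields one `class` classification per
#' declared type. An untyped IRI inside one of the resource's namespaces
#' (or a skolemised blank node) is `invalid` - a structural defect - and is
#' represented by its namespace; an untyped IRI outside every configured
#' namespace is `external`, represented by its own namespace prefix.
#'
#' @param o object value: IRI or literal lexical form.
#' @param o_lit logical; literal object?
#' @param o_dt datatype IRI for literals.
#' @param g an `rdf_graph` used to look up declared types.
#' @param namespaces internal namespace prefixes.
#' @return `data.frame(object_type, object_kind)`, one row per
#'   classification.
#' @export
classify_object <- function(o, o_lit = FALSE, o_dt = NA_character_, g, namespaces) {
  if (isTRUE(o_lit)) {
    dt <- if (is.na(o_dt) || identical(o_dt, RDF_LANGSTRING)) XSD_STRING else o_dt
    return(data.frame(object_type = dt, object_kind = "datatype", stringsAsFactors = FALSE))
  }
  ty <- type_assertions(g)
  types <- ty$type[ty$s == o]
  if (length(types)) {
    return(data.frame(object_type = sort(types, method = "radix"),
                      object_kind = "class", stringsAsFactors = FALSE))
  }
  if (iri_in_namespaces(o, namespaces)) {
    marker <- if (startsWith(o, SKOLEM_PREFIX)) SKOLEM_PREFIX else {
      hits <- namespaces[startsWith(o, namespaces)]
      hits[which.max(nchar(hits))]
    }
    return(data.frame(object_type = unname(marker), object_kind = "invalid",
                      stringsAsFactors = FALSE))
  }
  data.frame(object_type = namespace_of(o), object_kind = "external",
             stringsAsFactors = FALSE)
}

# Vectorised object classification for a statement batch. `st` must carry
# columns o, o_lit, o_dt and an integer row id `sid`; returns one row per
# (sid, classification).
classify_objects_batch <- function(st, types_df, namespaces) {
  out <- list()
  lit <- st[st$o_lit, , drop = FALSE]
  if (nrow(lit)) {
    dt <- ifelse(is.na(lit$o_dt) | lit$o_dt == RDF_LANGSTRING, XSD_STRING, lit$o_dt)
    out$lit <- data.frame(sid = lit$sid, object_type = dt, object_kind = "datatype",
                          stringsAsFactors = FALSE)
  }
  iri <- st[!st$o_lit, , drop = FALSE]
  if (nrow(iri)) {
    m <- merge(iri[, c("sid", "o")], types_df, by.x = "o", by.y = "s")
    if (nrow(m)) {
      out$cls <- data.frame(sid = m$sid, object_type = m$type, object_kind = "class",
                            stringsAsFactors = FALSE)
    }
    untyped <- iri[!(iri$o %in% types_df$s), , drop = FALSE]
    if (nrow(untyped)) {
      internal <- iri_in_namespaces(untyped$o, namespaces)
      if (any(internal)) {
        io <- untyped$o[internal]
        marker <- vapply(io, function(one) {
          if (startsWith(one, SKOLEM_PREFIX)) return(SKOLEM_PREFIX)
          hits <- namespaces[startsWith(one, namespaces)]
          unname(hits[which.max(nchar(hits))])
        }, character(1), USE.NAMES = FALSE)
        out$inv <- data.frame(sid = untyped$sid[internal], object_type = marker,
                              object_kind = "invalid", stringsAsFactors = FALSE)
      }
      if (any(!internal)) {
        out$ext <- data.frame(sid = untyped$sid[!internal],
                              object_type = namespace_of(untyped$o[!internal]),
                              object_kind = "external", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sid = integer(), object_type = character(),
                      object_kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(out))
}

#' Extract type links and their statement registries
#'
#' For every non-schema statement (s, p, o), one type link is emitted per
#' declared type of s crossed with every classification of o. The registry
#' keeps the contributing (s, o) pairs per unique tuple; multiplicity
#' classification needs them.
#'
#' @param g an `rdf_graph`.
#' @param handle the originating [resource_handle()] (for the per-predicate
#'   limit); defaults to the graph's own handle.
#' @return a list with elements `links` (unique type links with counts),
#'   `registry` (contributing pairs), `truncated` (predicates whose fetch
#'   hit the limit) and `untyped_subjects` (subjects bearing properties but
#'   no type).
#' @export
extract_type_links <- function(g, handle = g$handle) {
  limit <- if (!is.null(handle)) handle$limit_per_predicate else NULL
  namespaces <- graph_namespaces(g)
  types_df <- type_assertions(g)
  preds <- enumerate_predicates(g)
  reg_parts <- list()
  truncated <- character(0)
  untyped <- character(0)
  for (p in preds) {
    fs <- fetch_statements(g, p, limit)
    st <- fs$statements
    if (fs$truncated) truncated <- c(truncated, p)
    if (nrow(st) == 0) next
    st$sid <- seq_len(nrow(st))
    subj_types <- merge(st[, c("sid", "s")], types_df, by = "s")
    untyped <- c(untyped, unique(st$s[!(st$s %in% types_df$s)]))
    if (nrow(subj_types) == 0) next
    obj_cls <- classify_objects_batch(st, types_df, namespaces)
    pairs <- merge(subj_types, obj_cls, by = "sid")
    if (nrow(pairs) == 0) next
    st_key <- st[, c("sid", "o", "o_lit", "o_dt")]
    st_key$o_key <- object_key(st_key$o, st_key$o_lit, st_key$o_dt)
    pairs <- merge(pairs, st_key[, c("sid", "o_key")], by = "sid")
    reg <- unique(data.frame(subject_type = pairs$type, predicate = p,
                             object_type = pairs$object_type,
                             object_kind = pairs$object_kind,
                             s = pairs$s, o_key = pairs$o_key,
                             stringsAsFactors = FALSE))
    reg_parts[[p]] <- reg
  }
  registry <- if (length(reg_parts)) do.call(rbind, unname(reg_parts)) else {
    data.frame(subject_type = character(), predicate = character(),
               object_type = character(), object_kind = character(),
               s = character(), o_key = character(), stringsAsFactors = FALSE)
  }
  registry <- reset_rownames(registry[order(registry$subject_type, registry$predicate,
                                            registry$object_type, registry$object_kind,
                                            registry$s, registry$o_key,
                                            method = "radix"), , drop = FALSE])
  links <- aggregate_registry(registry)
  links$truncated <- links$predicate %in% truncated
  list(links = links, registry = registry,
       truncated = sort(unique(truncated), method = "radix"),
       untyped_subjects = sort(unique(untyped), method = "radix"))
}

aggregate_registry <- function(registry) {
  if (nrow(registry) == 0) {
    return(data.frame(subject_type = character(), predicate = character(),
                      object_type = character(), object_kind = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(registry)
  agg <- dt[, list(count = .N),
            by = c("subject_type", "predicate", "object_type", "object_kind")]
  data.table::setorderv(agg, c("subject_type", "predicate", "object_type", "object_kind"))
  as.data.frame(agg)
}

#' Classify a forward multiplicity from reference counts
#'
#' @param total_instances direct instance count of the source class.
#' @param refcounts per participating source instance, the number of
#'   distinct references to the target (all >= 1).
#' @return one of `"1..1"`, `"1..N"`, `"0..1"`, `"0..N"`.
#' @export
classify_forward <- function(total_instances, refcounts) {
  participating <- length(refcounts)
  if (participating == 0) {
    stop("contract violation: a unique type link with zero participating subjects", call. = FALSE)
  }
  if (any(refcounts < 1)) stop("refcounts must all be >= 1", call. = FALSE)
  if (participating > total_instances) {
    stop("participating subjects exceed the class instance total", call. = FALSE)
  }
  all_participate <- participating == total_instances
  single <- max(refcounts) == 1
  if (all_participate && single) "1..1"
  else if (all_participate) "1..N"
  else if (single) "0..1"
  else "0..N"
}

#' Classify a reverse multiplicity
#'
#' The roles of target and source are inverted: the target class's direct
#' instance total against per-object distinct-subject counts. Only links to
#' classes have a reverse multiplicity; datatype, external and invalid
#' targets yield `"not_determined"` (no instance total exists for them).
#'
#' @param object_kind the link's object kind.
#' @param target_total direct instance count of the target class.
#' @param subject_counts per participating target instance, the number of
#'   distinct referring subjects.
#' @return a multiplicity string.
#' @export
classify_reverse <- function(object_kind, target_total, subject_counts) {
  if (!identical(object_kind, "class")) return("not_determined")
  classify_forward(target_total, subject_counts)
}

# Compute forward/reverse multiplicities for every link from the registry.
compute_multiplicities <- function(links, registry, class_instances) {
  if (nrow(links) == 0) {
    links$forward <- character(0); links$reverse <- character(0)
    return(links)
  }
  inst <- stats::setNames(class_instances$instances, class_instances$class)
  reg <- data.table::as.data.table(registry)
  key <- c("subject_type", "predicate", "object_type", "object_kind")
  fwd <- reg[, list(participating = data.table::uniqueN(s),
                    maxref = max(table(s))), by = key]
  # per-object distinct subject counts for the reverse direction
  rev <- reg[, list(targets = data.table::uniqueN(o_key),
                    maxsubj = max(table(o_key))), by = key]
  links_dt <- data.table::as.data.table(links)
  links_dt <- merge(links_dt, fwd, by = key, all.x = TRUE)
  links_dt <- merge(links_dt, rev, by = key, all.x = TRUE)
  mult_from <- function(total, participating, maxref) {
    ifelse(participating == total & maxref == 1, "1..1",
    ifelse(participating == total, "1..N",
    ifelse(maxref == 1, "0..1", "0..N")))
  }
  s_tot <- inst[links_dt$subject_type]
  links_dt$forward <- mult_from(s_tot, links_dt$participating, links_dt$maxref)
  t_tot <- inst[links_dt$object_type]
  links_dt$reverse <- ifelse(links_dt$object_kind == "class",
                             mult_from(t_tot, links_dt$targets, links_dt$maxsubj),
                             "not_determined")
  und <- links_dt$object_kind == "invalid" | links_dt$truncated
  links_dt$forward[und] <- "not_determined"
  links_dt$reverse[und] <- "not_determined"
  out <- as.data.frame(links_dt)
  out$participating <- NULL; out$maxref <- NULL
  out$targets <- NULL; out$maxsubj <- NULL
  data.table::setDF(out)
  reset_rownames(out[order(out$subject_type, out$predicate, out$object_type,
                           out$object_kind, method = "radix"), , drop = FALSE])
}

#' Recover the structure of an RDF resource
#'
#' Runs the full recovery: class and hierarchy enumeration, type-link
#' extraction, multiplicity classification, concept-class detection and the
#' structural-integrity findings.
#'
#' @param x a [resource_handle()] or an already-loaded `rdf_graph`.
#' @return a `structure_graph`.
#' @export
recover_structure <- function(x) {
  g <- if (inherits(x, "resource_handle")) rdf_load(x) else x
  stopifnot(inherits(g, "rdf_graph"))
  classes <- enumerate_classes(g)
  sub <- enumerate_subclass_links(g)
  tree <- detect_concept_classes(build_class_tree(classes, sub))
  ex <- extract_type_links(g)
  links <- compute_multiplicities(ex$links, ex$registry, classes)
  findings <- derive_findings(g, links, ex$untyped_subjects)
  structure_graph(tree, links, findings, simplified = FALSE,
                  namespaces = graph_namespaces(g))
}

derive_findings <- function(g, links, untyped_subjects) {
  f <- list()
  und <- links[links$object_kind == "invalid", , drop = FALSE]
  if (nrow(und)) {
    f$und <- data.frame(
      kind = "undetermined_multiplicity",
      subject = paste(und$subject_type, und$predicate, und$object_type, sep = " "),
      detail = sprintf("multiplicity of <%s> --<%s>--> %s not determined: target is an untyped in-resource subject",
                       und$subject_type, und$predicate, und$object_type),
      stringsAsFactors = FALSE)
  }
  if (length(untyped_subjects)) {
    f$unt <- data.frame(
      kind = "untyped_subject_with_properties",
      subject = untyped_subjects,
      detail = sprintf("subject <%s> has properties but no rdf:type", untyped_subjects),
      stringsAsFactors = FALSE)
  }
  cls <- enumerate_classes(g)$class
  preds <- enumerate_predicates(g)
  both <- sort(intersect(cls, preds), method = "radix")
  if (length(both)) {
    f$both <- data.frame(
      kind = "predicate_also_class",
      subject = both,
      detail = sprintf("IRI <%s> is used both as a class and as a predicate", both),
      stringsAsFactors = FALSE)
  }
  out <- if (length(f)) do.call(rbind, unname(f)) else {
    data.frame(kind = character(), subject = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
  reset_rownames(out[order(out$kind, out$subject, method = "radix"), , drop = FALSE])
}

#' Construct a structure graph
#'
#' The container every exporter consumes: the class tree, the unique type
#' links (each owned by exactly one class property), and the integrity
#' findings.
#'
#' @param class_tree a `class_tree`.
#' @param links unique-type-link data frame.
#' @param findings integrity findings data frame.
#' @param simplified has the hierarchy merge run?
#' @param namespaces internal namespace prefixes of the source resource.
#' @param links_before_simplify link count before simplification, for the
#'   summary.
#' @return a `structure_graph`.
#' @export
structure_graph <- function(class_tree, links, findings = NULL, simplified = FALSE,
                            namespaces = character(), links_before_simplify = NULL) {
  if (is.null(findings)) {
    findings <- data.frame(kind = character(), subject = character(),
                           detail = character(), stringsAsFactors = FALSE)
  }
  if (!"truncated" %in% names(links)) links$truncated <- FALSE
  structure(list(class_tree = class_tree, links = reset_rownames(links),
                 findings = findings, simplified = simplified,
                 namespaces = namespaces,
                 links_before_simplify = links_before_simplify),
            class = "structure_graph")
}

#' Class properties of a structure graph
#'
#' Groups the unique type links per (owner class, predicate); occurrences
#' are the summed link counts.
#'
#' @param s a `structure_graph`.
#' @return `data.frame(owner_class, predicate, n_links, occurrences)`.
#' @export
class_properties <- function(s) {
  if (nrow(s$links) == 0) {
    return(data.frame(owner_class = character(), predicate = character(),
                      n_links = integer(), occurrences = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(s$links)
  agg <- dt[, list(n_links = .N, occurrences = sum(count)),
            by = c("subject_type", "predicate")]
  data.table::setnames(agg, "subject_type", "owner_class")
  data.table::setorderv(agg, c("owner_class", "predicate"))
  data.table::setDF(agg)
  agg
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("<structure_graph>%s %d classes, %d unique type links, %d findings\n",
              if (x$simplified) " (simplified)" else "",
              nrow(x$class_tree$nodes), nrow(x$links), nrow(x$findings)))
  invisible(x)
}

#' @export
summary.structure_graph <- function(object, ...) {
  nodes <- object$class_tree$nodes
  hist <- table(factor(object$links$forward, levels = MULTIPLICITIES))
  out <- list(
    classes_with_instances = sum(nodes$instances > 0),
    classes_without_instances = sum(nodes$instances == 0),
    links = nrow(object$links),
    links_before_simplify = if (!is.null(object$links_before_simplify))
      object$links_before_simplify else nrow(object$links),
    multiplicity = as.list(stats::setNames(as.integer(hist), names(hist))),
    findings = nrow(object$findings))
  class(out) <- "summary.structure_graph"
  out
}

#' @export
print.summary.structure_graph <- function(x, ...) {
  cat("classes with instances:    ", x$classes_with_instances, "\n")
  cat("classes without instances: ", x$classes_without_instances, "\n")
  cat("unique type links before simplification:", x$links_before_simplify, "\n")
  cat("unique type links after simplification: ", x$links, "\n")
  cat("forward multiplicity histogram:\n")
  for (m in names(x$multiplicity)) cat(sprintf("  %-14s %d\n", m, x$multiplicity[[m]]))
  cat("integrity findings:", x$findings, "\n")
  invisible(x)
}
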