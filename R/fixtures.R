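# Programmatic generation of RDF test graphs with known structure. The
# generator emits both the graph and the ground-truth structure it
# realizes, so recovery tests are exact rather than statistical.

EX_NS <- "http://example.org/"

#' Describe a synthetic RDF fixture
#'
#' @param tree_depth depth of the class hierarchy below the root (0 = flat).
#' @param branching subclasses per class.
#' @param instances_per_class an integer, or `c(min, max)` sampled per
#'   class; classes sampled at 0 become concept candidates.
#' @param predicates list of `list(name, target, forward)` with `target`
#'   one of `"class"`, `"datatype"`, `"external"` and `forward` one of the
#'   four multiplicities. Source classes rotate over classes with at least
#'   3 instances.
#' @param fraction_untyped fraction of a source class's instances that
#'   additionally reference a fresh untyped in-resource IRI (each such IRI
#'   also bears a property, making it an untyped subject with properties).
#' @param fraction_external like `fraction_untyped` but referencing untyped
#'   IRIs outside the resource's namespace.
#' @param seed RNG seed; the same seed yields byte-identical Turtle.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(tree_depth = 1, branching = 2, instances_per_class = 5,
                         predicates = list(list(name = "p1", target = "class",
                                                forward = "1..1")),
                         fraction_untyped = 0, fraction_external = 0, seed = 1L) {
  stopifnot(tree_depth >= 0, branching >= 1,
            fraction_untyped >= 0, fraction_untyped <= 1,
            fraction_external >= 0, fraction_external <= 1)
  for (p in predicates) {
    stopifnot(p$target %in% c("class", "datatype", "external"),
              p$forward %in% setdiff(MULTIPLICITIES, "not_determined"))
  }
  structure(list(tree_depth = tree_depth, branching = branching,
                 instances_per_class = instances_per_class,
                 predicates = predicates, fraction_untyped = fraction_untyped,
                 fraction_external = fraction_external, seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mult_of_counts <- function(total, refcounts) {
  if (length(refcounts) == 0) return(NA_character_)
  if (length(refcounts) == total) { if (max(refcounts) == 1) "1..1" else "1..N" }
  else { if (max(refcounts) == 1) "0..1" else "0..N" }
}

#' Generate a synthetic RDF graph and its ground-truth structure
#'
#' @param spec a [fixture_spec()].
#' @return a list with `triples` (triple table), `turtle` (text lines),
#'   `namespaces`, `graph` (a ready `memory_graph`) and `truth` (the
#'   expected unsimplified `structure_graph`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    # --- class hierarchy -----------------------------------------------
    cls <- data.frame(class = paste0(EX_NS, "Class1"), parent = NA_character_,
                      depth = 0L, stringsAsFactors = FALSE)
    frontier <- cls$class
    for (d in seq_len(spec$tree_depth)) {
      nxt <- character(0)
      for (pa in frontier) {
        kids <- paste0(pa, "_", seq_len(spec$branching))
        cls <- rbind(cls, data.frame(class = kids, parent = pa, depth = d))
        nxt <- c(nxt, kids)
      }
      frontier <- nxt
    }
    ipc <- spec$instances_per_class
    cls$n <- if (length(ipc) == 2) {
      sample(ipc[1]:ipc[2], nrow(cls), replace = TRUE)
    } else rep(as.integer(ipc), nrow(cls))

    S <- P <- O <- character(0); LIT <- logical(0); DT <- character(0)
    add <- function(s, p, o, lit = FALSE, dt = NA_character_) {
      S <<- c(S, s); P <<- c(P, p); O <<- c(O, o); LIT <<- c(LIT, lit); DT <<- c(DT, dt)
    }
    inst <- list()
    for (i in seq_len(nrow(cls))) {
      if (cls$n[i] == 0) { inst[[cls$class[i]]] <- character(0); next }
      ids <- paste0(cls$class[i], "/i", seq_len(cls$n[i]))
      inst[[cls$class[i]]] <- ids
      for (id in ids) add(id, RDF_TYPE, cls$class[i])
    }
    for (i in seq_len(nrow(cls))) {
      if (!is.na(cls$parent[i])) add(cls$class[i], RDFS_SUBCLASS, cls$parent[i])
    }

    # --- predicates ----------------------------------------------------
    eligible <- cls$class[cls$n >= 3]
    if (length(eligible) == 0) stop("fixture needs at least one class with >= 3 instances")
    links_truth <- list()
    for (k in seq_along(spec$predicates)) {
      ps <- spec$predicates[[k]]
      pred <- paste0(EX_NS, ps$name)
      src_cls <- eligible[((k - 1) %% length(eligible)) + 1]
      srcs <- inst[[src_cls]]
      n <- length(srcs)
      tgt_cls <- NA_character_
      if (ps$target == "class") {
        others <- cls$class[cls$n >= 2 & cls$class != src_cls]
        tgt_cls <- if (length(others)) others[(k %% length(others)) + 1] else src_cls
      }
      targets <- switch(ps$target,
        class = inst[[tgt_cls]],
        datatype = NULL,
        external = paste0("http://otherres.org/id/", seq_len(max(3, n))))
      mk_obj <- function(j) {
        if (ps$target == "datatype") {
          list(o = paste0("value-", k, "-", j), lit = TRUE, dt = XSD_STRING)
        } else {
          list(o = targets[((j - 1) %% length(targets)) + 1], lit = FALSE, dt = NA_character_)
        }
      }
      # realize the requested forward multiplicity
      assign_counts <- switch(ps$forward,
        "1..1" = rep(1L, n),
        "1..N" = c(2L, rep(1L, n - 1L)),
        "0..1" = c(0L, rep(1L, n - 1L)),
        "0..N" = c(0L, 2L, rep(1L, n - 2L)))
      oi <- 0L
      rows <- list()
      for (si in seq_len(n)) {
        if (assign_counts[si] == 0) next
        for (r in seq_len(assign_counts[si])) {
          oi <- oi + 1L
          ob <- mk_obj(oi)
          add(srcs[si], pred, ob$o, ob$lit, ob$dt)
          rows[[length(rows) + 1L]] <- data.frame(s = srcs[si], o = ob$o,
                                                  o_lit = ob$lit, o_dt = ob$dt,
                                                  stringsAsFactors = FALSE)
        }
      }
      st <- unique(do.call(rbind, rows))
      object_type <- switch(ps$target,
        class = tgt_cls,
        datatype = XSD_STRING,
        external = "http://otherres.org/id/")
      fwd <- mult_of_counts(n, as.integer(table(st$s)))
      rev <- if (ps$target == "class") {
        tgt_total <- cls$n[cls$class == object_type]
        mult_of_counts(tgt_total, as.integer(table(st$o)))
      } else "not_determined"
      links_truth[[length(links_truth) + 1L]] <- data.frame(
        subject_type = src_cls, predicate = pred, object_type = object_type,
        object_kind = if (ps$target == "class") "class" else ps$target,
        count = nrow(st), forward = fwd, reverse = rev, stringsAsFactors = FALSE)
    }

    # --- untyped / external noise --------------------------------------
    src_cls <- eligible[1]
    srcs <- inst[[src_cls]]
    n_unt <- round(spec$fraction_untyped * length(srcs))
    untyped_subjects <- character(0)
    if (n_unt > 0) {
      pred <- paste0(EX_NS, "brokenRef")
      orphans <- paste0(EX_NS, "orphan", seq_len(n_unt))
      for (j in seq_len(n_unt)) {
        add(srcs[j], pred, orphans[j])
        add(orphans[j], paste0(EX_NS, "note"), paste0("orphan-", j), TRUE, XSD_STRING)
      }
      untyped_subjects <- orphans
      links_truth[[length(links_truth) + 1L]] <- data.frame(
        subject_type = src_cls, predicate = pred, object_type = EX_NS,
        object_kind = "invalid", count = n_unt,
        forward = "not_determined", reverse = "not_determined",
        stringsAsFactors = FALSE)
    }
    n_ext <- round(spec$fraction_external * length(srcs))
    if (n_ext > 0) {
      pred <- paste0(EX_NS, "externalRef")
      for (j in seq_len(n_ext)) add(srcs[j], pred, paste0("http://elsewhere.org/e", j))
      links_truth[[length(links_truth) + 1L]] <- data.frame(
        subject_type = src_cls, predicate = pred,
        object_type = "http://elsewhere.org/", object_kind = "external",
        count = n_ext,
        forward = mult_of_counts(length(srcs), rep(1L, n_ext)),
        reverse = "not_determined", stringsAsFactors = FALSE)
    }

    triples <- rdf_triples(S, P, O, LIT, DT)
    turtle <- write_turtle(triples, prefixes = c(ex = EX_NS, xsd = XSD_NS))

    # --- ground truth structure ----------------------------------------
    classes <- data.frame(class = cls$class, instances = cls$n, stringsAsFactors = FALSE)
    classes <- classes[order(classes$class, method = "radix"), ]
    edges <- cls[!is.na(cls$parent), c("class", "parent")]
    tree <- detect_concept_classes(build_class_tree(
      classes, data.frame(child = edges$class, parent = edges$parent,
                          stringsAsFactors = FALSE)))
    links <- do.call(rbind, links_truth)
    links$truncated <- FALSE
    links <- reset_rownames(links[order(links$subject_type, links$predicate,
                                        links$object_type, method = "radix"), , drop = FALSE])
    findings <- list()
    inv <- links[links$object_kind == "invalid", , drop = FALSE]
    if (nrow(inv)) {
      findings$und <- data.frame(
        kind = "undetermined_multiplicity",
        subject = paste(inv$subject_type, inv$predicate, inv$object_type, sep = " "),
        detail = sprintf("multiplicity of <%s> --<%s>--> %s not determined: target is an untyped in-resource subject",
                         inv$subject_type, inv$predicate, inv$object_type),
        stringsAsFactors = FALSE)
    }
    if (length(untyped_subjects)) {
      findings$unt <- data.frame(
        kind = "untyped_subject_with_properties", subject = untyped_subjects,
        detail = sprintf("subject <%s> has properties but no rdf:type", untyped_subjects),
        stringsAsFactors = FALSE)
    }
    fdf <- if (length(findings)) do.call(rbind, unname(findings)) else {
      data.frame(kind = character(), subject = character(), detail = character(),
                 stringsAsFactors = FALSE)
    }
    fdf <- reset_rownames(fdf[order(fdf$kind, fdf$subject, method = "radix"), , drop = FALSE])
    truth <- structure_graph(tree, links, fdf, simplified = FALSE, namespaces = EX_NS)
    list(triples = triples, turtle = turtle, namespaces = EX_NS,
         graph = memory_graph(triples, EX_NS), truth = truth)
  })
}

#' A random fixture specification
#'
#' Draws hierarchy shape, instance counts, predicates and noise fractions
#' from modest ranges (graphs stay well under 500 triples); used by the
#' oracle-equivalence and property tests.
#'
#' @param seed RNG seed.
#' @return a `fixture_spec`.
#' @export
random_fixture_spec <- function(seed) {
  with_seed(seed, {
    kinds <- c("class", "datatype", "external")
    mults <- c("1..1", "1..N", "0..1", "0..N")
    n_pred <- sample(1:4, 1)
    preds <- lapply(seq_len(n_pred), function(i) {
      list(name = paste0("p", i), target = sample(kinds, 1), forward = sample(mults, 1))
    })
    fixture_spec(tree_depth = sample(0:2, 1), branching = sample(1:3, 1),
                 instances_per_class = c(3, 8), predicates = preds,
                 fraction_untyped = sample(c(0, 0.2), 1),
                 fraction_external = sample(c(0, 0.2), 1),
                 seed = sample.int(2^30, 1))
  })
}

#' The worked-example graphs
#'
#' Small hand-built graphs exercising the canonical situations: the
#' gene/chromosome one-to-one link with one-or-many reverse, the
#' person/hasSon zero-or-many link, the three hierarchy-merge cases
#' (sibling targets, sibling sources, both), and a graph using one IRI as
#' both class and predicate.
#'
#' @return a named list; each element has `triples`, `namespaces` and a
#'   `description`.
#' @export
example_graphs <- function() {
  ex <- EX_NS
  g <- list()

  # (a) gene/chromosome: 10 genes, each on exactly one of 2 chromosomes,
  # every chromosome carrying at least 2 genes
  genes <- paste0(ex, "gene", 1:10)
  chrs <- paste0(ex, "chr", 1:2)
  on_chr <- rep(chrs, c(6, 4))
  g$gene_chromosome <- list(
    triples = rdf_triples(
      s = c(genes, chrs, genes),
      p = c(rep(RDF_TYPE, 12), rep(paste0(ex, "locatedOn"), 10)),
      o = c(rep(paste0(ex, "Gene"), 10), rep(paste0(ex, "Chromosome"), 2), on_chr)),
    namespaces = ex,
    description = "every gene on exactly one chromosome; chromosomes hold many genes")

  # (b) person/hasSon: four persons; two have two sons each, sons sonless
  p <- paste0(ex, c("adam", "eve", "bob", "dave"))
  g$person_hasSon <- list(
    triples = rdf_triples(
      s = c(p, p[1], p[1], p[2], p[2]),
      p = c(rep(RDF_TYPE, 4), rep(paste0(ex, "hasSon"), 4)),
      o = c(rep(paste0(ex, "Person"), 4), p[3], p[4], p[3], p[4])),
    namespaces = ex,
    description = "no limit on sons; not every person has one; sons have two parents")

  two_inst <- function(cls) paste0(cls, c("/i1", "/i2"))
  hier <- function(spec_edges, typed, stmts, pred = "p") {
    s <- c(); pp <- c(); o <- c()
    for (e in spec_edges) { s <- c(s, paste0(ex, e[1])); pp <- c(pp, RDFS_SUBCLASS); o <- c(o, paste0(ex, e[2])) }
    for (t in typed) {
      for (i in two_inst(paste0(ex, t))) { s <- c(s, i); pp <- c(pp, RDF_TYPE); o <- c(o, paste0(ex, t)) }
    }
    for (st in stmts) {
      s <- c(s, two_inst(paste0(ex, st[1])))
      pp <- c(pp, rep(paste0(ex, pred), 2))
      o <- c(o, two_inst(paste0(ex, st[2])))
    }
    rdf_triples(s, pp, o)
  }

  # Fig.-2-style cases: links between instance pairs, 2 instances per class
  g$merge_case_a <- list(
    triples = hier(list(c("Y1", "Y"), c("Y2", "Y")), c("X", "Y1", "Y2"),
                   list(c("X", "Y1"), c("X", "Y2"))),
    namespaces = ex,
    description = "one class linking to two sibling subclasses; merges to the parent target")
  g$merge_case_b <- list(
    triples = hier(list(c("X1", "X"), c("X2", "X")), c("X1", "X2", "Y"),
                   list(c("X1", "Y"), c("X2", "Y"))),
    namespaces = ex,
    description = "two sibling subclasses linking to one class; merges to the parent source")
  g$merge_case_c <- list(
    triples = hier(list(c("X1", "X"), c("X2", "X"), c("Y1", "Y"), c("Y2", "Y")),
                   c("X1", "X2", "Y1", "Y2"),
                   list(c("X1", "Y1"), c("X2", "Y2"))),
    namespaces = ex,
    description = "sibling subclasses on both ends; merges to parent-to-parent")

  cds <- paste0(ex, "CDS")
  g$cds_collision <- list(
    triples = rdf_triples(
      s = c(paste0(ex, "g1"), paste0(ex, "g1"), paste0(ex, "r1"), paste0(ex, "r1")),
      p = c(RDF_TYPE, paste0(ex, "partOf"), RDF_TYPE, cds),
      o = c(cds, paste0(ex, "r1"), paste0(ex, "Region"), paste0(ex, "g1"))),
    namespaces = ex,
    description = "one IRI used both as a class and as a predicate")

  g
}
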