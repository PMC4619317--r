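# The class tree: a directed graph of child -> parent subClassOf edges
# (owl:sameAs pairs arrive already folded in as one edge per direction).
# Cycles are allowed; each strongly connected component behaves as a single
# equivalence group for ancestor queries, represented by its
# lexicographically smallest member.

#' Build the class tree
#'
#' @param classes `data.frame(class, instances)` from [enumerate_classes()].
#' @param subclass_links `data.frame(child, parent)` from
#'   [enumerate_subclass_links()].
#' @return a `class_tree` object.
#' @export
build_class_tree <- function(classes, subclass_links) {
  stopifnot(all(c("class", "instances") %in% names(classes)))
  nodes <- data.frame(class = classes$class,
                      instances = as.integer(classes$instances),
                      concept = rep(NA, length(classes$class)),
                      stringsAsFactors = FALSE)
  nodes <- reset_rownames(nodes[order(nodes$class, method = "radix"), , drop = FALSE])
  edges <- unique(data.frame(child = subclass_links$child,
                             parent = subclass_links$parent,
                             stringsAsFactors = FALSE))
  edges <- edges[edges$child != edges$parent, , drop = FALSE]
  edges <- reset_rownames(edges[order(edges$child, edges$parent, method = "radix"), , drop = FALSE])
  extra <- setdiff(unique(c(edges$child, edges$parent)), nodes$class)
  if (length(extra)) {
    nodes <- rbind(nodes, data.frame(class = extra, instances = 0L, concept = NA))
    nodes <- reset_rownames(nodes[order(nodes$class, method = "radix"), , drop = FALSE])
  }
  gr <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(child = character(), parent = character()),
    directed = TRUE, vertices = nodes$class)
  # equivalence groups: strongly connected components (mutual sameAs edges)
  comp <- igraph::components(gr, mode = "strong")
  member <- split(nodes$class, comp$membership[nodes$class])
  rep_of <- stats::setNames(nodes$class, nodes$class)
  for (grp in member) {
    if (length(grp) > 1) rep_of[grp] <- min(grp)
  }
  # ancestors: all vertices reachable along child -> parent edges (excluding
  # the class itself unless it sits in a cycle with others)
  anc <- lapply(nodes$class, function(cl) {
    r <- names(igraph::subcomponent(gr, cl, mode = "out"))
    sort(setdiff(r, cl), method = "radix")
  })
  names(anc) <- nodes$class
  # depth of each ancestor (shortest directed path) for nearest-ancestor ties
  dist <- igraph::distances(gr, mode = "out")
  structure(list(nodes = nodes, edges = edges, ancestors = anc,
                 rep_of = rep_of, dist = dist, graph = gr),
            class = "class_tree")
}

#' @export
print.class_tree <- function(x, ...) {
  cat(sprintf("<class_tree> %d classes, %d subclass edges, %d with instances\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$instances > 0)))
  invisible(x)
}

tree_has <- function(tree, cl) cl %in% tree$nodes$class

tree_ancestors <- function(tree, cl) {
  if (!tree_has(tree, cl)) return(character(0))
  tree$ancestors[[cl]]
}

tree_children <- function(tree, cl) {
  sort(tree$edges$child[tree$edges$parent == cl], method = "radix")
}

tree_roots <- function(tree) {
  # classes with no parent outside their own equivalence group
  has_parent <- vapply(tree$nodes$class, function(cl) {
    p <- tree$edges$parent[tree$edges$child == cl]
    any(!(tree$rep_of[p] == tree$rep_of[cl]))
  }, logical(1))
  sort(tree$nodes$class[!has_parent], method = "radix")
}

#' Is class K a child of class L?
#'
#' True when K equals L, when K is a (transitive) subclass of L, or when the
#' two sit in the same sameAs equivalence group.
#'
#' @param tree a `class_tree`.
#' @param k,l class IRIs.
#' @return logical.
#' @export
child_of <- function(tree, k, l) {
  if (identical(k, l)) return(TRUE)
  if (!tree_has(tree, k) || !tree_has(tree, l)) return(FALSE)
  if (identical(unname(tree$rep_of[k]), unname(tree$rep_of[l]))) return(TRUE)
  l %in% tree$ancestors[[k]]
}

#' Nearest shared ancestor of two types
#'
#' Two types are shared when they are identical, when one is an ancestor of
#' the other (the ancestor is returned), or when they have a common ancestor
#' in the class tree - then the nearest one (smallest maximum distance to
#' the pair) is returned, ties broken lexicographically. Non-class targets
#' (datatypes, external and invalid markers) are shared only when identical.
#'
#' @param tree a `class_tree`.
#' @param t1,t2 type IRIs.
#' @param kinds optional object kinds of `t1`/`t2`; when given, both must
#'   equal `"class"` for hierarchy lookups to apply.
#' @return the shared type IRI or `NULL` when the types are not shared.
#' @export
shared_type <- function(tree, t1, t2, kinds = NULL) {
  if (identical(t1, t2) && (is.null(kinds) || kinds[1] == kinds[2])) return(t1)
  if (!is.null(kinds) && !(identical(kinds[1], "class") && identical(kinds[2], "class"))) {
    return(NULL)
  }
  if (!tree_has(tree, t1) || !tree_has(tree, t2)) return(NULL)
  if (child_of(tree, t1, t2)) return(t2)
  if (child_of(tree, t2, t1)) return(t1)
  common <- intersect(tree$ancestors[[t1]], tree$ancestors[[t2]])
  if (length(common) == 0) return(NULL)
  d <- pmax(tree$dist[t1, common], tree$dist[t2, common])
  best <- common[d == min(d)]
  sort(best, method = "radix")[1]
}

#' Flag concept classes
#'
#' A concept class has no direct instances and no transitive descendant
#' with instances; GO-term-style vocabularies are the typical case. The
#' flag drives their optional exclusion from the network export.
#'
#' @param tree a `class_tree` with instance counts populated.
#' @return the tree with the `concept` flag set on every node.
#' @export
detect_concept_classes <- function(tree) {
  desc_instances <- vapply(tree$nodes$class, function(cl) {
    below <- names(igraph::subcomponent(tree$graph, cl, mode = "in"))
    sum(tree$nodes$instances[tree$nodes$class %in% below])
  }, numeric(1))
  tree$nodes$concept <- desc_instances == 0
  tree
}
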