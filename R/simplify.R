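# Hierarchy-aware simplification of the recovered structure.
#
# Per predicate, five steps run over the class tree: (1) seed temporary
# links from the unique type links; (2) copy every temporary link to all
# ancestor classes and repeatedly merge, two at a time and in sorted
# order, pairs on the same class whose targets are shared, replacing them
# with a link to the nearest common ancestor; (3) breadth-first from the
# roots, drop a temporary link when exactly one direct child holds a
# covering link; (4) depth-first, drop a temporary link whose target is
# covered by a link on any ancestor class; (5) emit the survivors, each
# original link assigned to exactly one survivor so that provenance
# partitions the originals and counts are conserved.

#' Widen a set of multiplicities into one
#'
#' Conservative combination used when merged links are emitted: the result
#' never promises more than every constituent guarantees.
#' `not_determined` absorbs.
#'
#' @param ms character vector of multiplicities.
#' @return a single multiplicity string.
#' @export
aggregate_multiplicity <- function(ms) {
  stopifnot(length(ms) >= 1, all(ms %in% MULTIPLICITIES))
  if (any(ms == "not_determined")) return("not_determined")
  lower0 <- any(startsWith(ms, "0"))
  upperN <- any(endsWith(ms, "N"))
  paste0(if (lower0) "0" else "1", "..", if (upperN) "N" else "1")
}

# --- temporary-link bookkeeping --------------------------------------------
# temp links are a list of records: list(class, target, kind, prov = integer ids)

tl_key <- function(t) paste(t$class, t$target, t$kind, sep = "\r")

tl_dedupe <- function(temps) {
  keys <- vapply(temps, tl_key, character(1))
  out <- list()
  for (i in seq_along(temps)) {
    k <- keys[i]
    if (is.null(out[[k]])) out[[k]] <- temps[[i]]
    else out[[k]]$prov <- sort(unique(c(out[[k]]$prov, temps[[i]]$prov)))
  }
  unname(out[sort(names(out), method = "radix")])
}

#' Simplify the unique type links of a single predicate
#'
#' @param links_p data frame of unique type links sharing one predicate
#'   (columns `subject_type, predicate, object_type, object_kind, count,
#'   forward, reverse`, optionally `truncated`).
#' @param tree the `class_tree`.
#' @return the surviving links as a data frame of the same shape.
#' @export
simplify_predicate <- function(links_p, tree) {
  n <- nrow(links_p)
  if (n == 0) return(links_p)
  stopifnot(length(unique(links_p$predicate)) == 1)
  if (!"truncated" %in% names(links_p)) links_p$truncated <- FALSE

  # Step 1: seed
  temps <- lapply(seq_len(n), function(i) {
    list(class = links_p$subject_type[i], target = links_p$object_type[i],
         kind = links_p$object_kind[i], prov = i)
  })
  temps <- tl_dedupe(temps)

  # Step 2: copy upwards and merge shared targets, to fixpoint
  repeat {
    before <- vapply(temps, tl_key, character(1))
    copies <- list()
    for (t in temps) {
      for (a in tree_ancestors(tree, t$class)) {
        copies[[length(copies) + 1L]] <- list(class = a, target = t$target,
                                              kind = t$kind, prov = t$prov)
      }
    }
    temps <- tl_dedupe(c(temps, copies))
    temps <- merge_within_classes(temps, tree)
    after <- vapply(temps, tl_key, character(1))
    if (length(before) == length(after) && all(before == after)) break
  }

  # Step 3: breadth first from the roots; remove a link when exactly one
  # direct child holds a covering link. Removal applies to lifted copies
  # only: a link whose provenance contains an original seeded at this class
  # is that original's sole guaranteed representation and must stay, or the
  # merge would lose coverage and drop counts.
  seed_rep <- unname(tree$rep_of[links_p$subject_type])
  order3 <- bfs_order(tree)
  for (cl in order3) {
    idx <- which(vapply(temps, function(t) t$class == cl, logical(1)))
    idx <- idx[order(vapply(temps[idx], function(t) t$target, character(1)), method = "radix")]
    for (i in idx) {
      t <- temps[[i]]
      if (any(seed_rep[t$prov] == unname(tree$rep_of[cl]))) next
      kids <- tree_children(tree, cl)
      kids <- kids[tree$rep_of[kids] != tree$rep_of[cl]]
      covering <- vapply(kids, function(k) {
        any(vapply(temps, function(u) {
          !is.null(u) && u$class == k && covers(tree, t, u)
        }, logical(1)))
      }, logical(1))
      if (length(covering) && sum(covering) == 1L) temps[i] <- list(NULL)
    }
    temps <- temps[!vapply(temps, is.null, logical(1))]
  }

  # Step 4: ancestors first; remove a link covered by any ancestor link
  order4 <- topo_order(tree)
  for (cl in order4) {
    idx <- which(vapply(temps, function(t) t$class == cl, logical(1)))
    if (length(idx) == 0) next
    anc <- tree_ancestors(tree, cl)
    anc <- anc[tree$rep_of[anc] != tree$rep_of[cl]]
    if (length(anc) == 0) next
    anc_links <- temps[vapply(temps, function(t) t$class %in% anc, logical(1))]
    if (length(anc_links) == 0) next
    drop <- vapply(idx, function(i) {
      any(vapply(anc_links, function(u) covers(tree, u, temps[[i]]), logical(1)))
    }, logical(1))
    temps[idx[drop]] <- list(NULL)
    temps <- temps[!vapply(temps, is.null, logical(1))]
  }

  # Step 5: assign each original to exactly one survivor and emit
  if (length(temps) == 0) return(links_p[0, , drop = FALSE])
  skeys <- vapply(temps, function(t) paste(t$class, t$target, sep = "\r"), character(1))
  ord <- order(skeys, method = "radix")
  temps <- temps[ord]
  assigned <- rep(NA_integer_, n)
  for (j in seq_along(temps)) {
    free <- temps[[j]]$prov[is.na(assigned[temps[[j]]$prov])]
    assigned[free] <- j
  }
  out <- list()
  for (j in seq_along(temps)) {
    ids <- which(assigned == j)
    if (length(ids) == 0) next
    t <- temps[[j]]
    out[[length(out) + 1L]] <- data.frame(
      subject_type = t$class, predicate = links_p$predicate[1],
      object_type = t$target, object_kind = t$kind,
      count = sum(links_p$count[ids]),
      forward = aggregate_multiplicity(links_p$forward[ids]),
      reverse = aggregate_multiplicity(links_p$reverse[ids]),
      truncated = any(links_p$truncated[ids]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  extra <- setdiff(names(links_p), names(res))
  for (e in extra) res[[e]] <- links_p[[e]][1]
  res <- res[, names(links_p), drop = FALSE]
  reset_rownames(res[order(res$subject_type, res$object_type, method = "radix"), , drop = FALSE])
}

# does temp link `upper` cover temp link `lower`: same kind and the lower
# target is a child of (or identical to) the upper target
covers <- function(tree, upper, lower) {
  if (upper$kind == "class" && lower$kind == "class") {
    child_of(tree, lower$target, upper$target)
  } else {
    upper$kind == lower$kind && identical(upper$target, lower$target)
  }
}

merge_within_classes <- function(temps, tree) {
  repeat {
    classes <- sort(unique(vapply(temps, function(t) t$class, character(1))), method = "radix")
    merged_any <- FALSE
    for (cl in classes) {
      repeat {
        idx <- which(vapply(temps, function(t) t$class == cl, logical(1)))
        if (length(idx) < 2) break
      idx <- idx[order(vapply(temps[idx], function(t) t$target, character(1)), method = "radix")]
        done <- FALSE
        for (ai in seq_along(idx)) {
          for (bi in seq_along(idx)) {
            if (bi <= ai) next
            t1 <- temps[[idx[ai]]]; t2 <- temps[[idx[bi]]]
            sh <- shared_type(tree, t1$target, t2$target, kinds = c(t1$kind, t2$kind))
            if (is.null(sh)) next
            kind <- if (t1$kind == "class") "class" else t1$kind
            newt <- list(class = cl, target = sh, kind = kind,
                         prov = sort(unique(c(t1$prov, t2$prov))))
            temps[idx[c(ai, bi)]] <- list(NULL, NULL)
            temps <- temps[!vapply(temps, is.null, logical(1))]
            temps[[length(temps) + 1L]] <- newt
            temps <- tl_dedupe(temps)
            done <- TRUE; merged_any <- TRUE
            break
          }
          if (done) break
        }
        if (!done) break
      }
    }
    if (!merged_any) break
  }
  temps
}

# classes in breadth-first order from the hierarchy roots (group-condensed,
# ties byte-sorted)
bfs_order <- function(tree) {
  ord <- topo_order(tree)
  ord
}

# ancestors-before-descendants order over the condensation of the tree
topo_order <- function(tree) {
  nodes <- tree$nodes$class
  if (length(nodes) == 0) return(character(0))
  # depth = longest path from a root, over the group condensation
  depth <- stats::setNames(rep(0L, length(nodes)), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(tree$edges))) {
      ch <- tree$edges$child[i]; pa <- tree$edges$parent[i]
      if (tree$rep_of[ch] == tree$rep_of[pa]) next
      if (depth[ch] < depth[pa] + 1L) { depth[ch] <- depth[pa] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  nodes[order(depth[nodes], nodes, method = "radix")]
}

#' Simplify a structure graph
#'
#' Applies the per-predicate merge to every predicate in sorted order. The
#' class tree and the integrity findings are unchanged; class properties
#' regroup around the surviving links. Running it twice is a no-op.
#'
#' @param s a `structure_graph`.
#' @return the simplified `structure_graph`.
#' @export
simplify_structure <- function(s) {
  stopifnot(inherits(s, "structure_graph"))
  links <- s$links
  before <- if (!is.null(s$links_before_simplify)) s$links_before_simplify else nrow(links)
  parts <- list()
  for (p in sort(unique(links$predicate), method = "radix")) {
    parts[[p]] <- simplify_predicate(links[links$predicate == p, , drop = FALSE],
                                     s$class_tree)
  }
  out <- if (length(parts)) do.call(rbind, unname(parts)) else links[0, , drop = FALSE]
  out <- reset_rownames(out[order(out$subject_type, out$predicate, out$object_type,
                                  out$object_kind, method = "radix"), , drop = FALSE])
  structure_graph(s$class_tree, out, s$findings, simplified = TRUE,
                  namespaces = s$namespaces, links_before_simplify = before)
}
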