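#' Build a validated brain structure tree
#'
#' A structure tree is the hierarchical region ontology (Allen-style) through
#' which voxel-level measurements roll up to parent structures. It is stored
#' as a data frame with one row per node and columns `id`, `acronym`, `name`
#' and `parent_structure_id` (`NA` for the root).
#'
#' Validation enforces: unique ids, unique acronyms, exactly one root, every
#' parent reference resolvable, and no cycles (checked by traversal from the
#' root; any node unreachable from the root is an orphan or part of a cycle).
#'
#' @param nodes data frame with columns `id` (integer), `acronym` (character),
#'   `name` (character), `parent_structure_id` (integer, `NA` for the root).
#' @return A `structure_tree` (validated data frame).
#' @examples
#' tr <- structure_tree(data.frame(
#'   id = c(1, 2, 3), acronym = c("root", "A", "B"),
#'   name = c("root", "region A", "region B"),
#'   parent_structure_id = c(NA, 1, 2)
#' ))
#' descendants(tr, 1)
#' @export
structure_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  required <- c("id", "acronym", "name", "parent_structure_id")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("ontology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_structure_id <- as.integer(nodes$parent_structure_id)
  nodes$acronym <- as.character(nodes$acronym)
  nodes$name <- as.character(nodes$name)

  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (anyDuplicated(nodes$acronym)) {
    stop("duplicate acronym: ",
         paste(unique(nodes$acronym[duplicated(nodes$acronym)]), collapse = ", "))
  }
  root <- nodes$id[is.na(nodes$parent_structure_id)]
  if (length(root) != 1L) {
    stop("tree must have exactly one root (found ", length(root), ")")
  }
  has_parent <- !is.na(nodes$parent_structure_id)
  unknown <- setdiff(nodes$parent_structure_id[has_parent], nodes$id)
  if (length(unknown) > 0L) {
    stop("unknown parent id: ", paste(unknown, collapse = ", "))
  }
  self_parent <- nodes$id[has_parent & nodes$parent_structure_id == nodes$id]
  if (length(self_parent) > 0L) {
    stop("cycle: node ", self_parent[1L], " is its own parent")
  }
  # reachability from root detects cycles / orphan subtrees
  children <- split(nodes$id[has_parent], nodes$parent_structure_id[has_parent])
  seen <- root
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  stranded <- setdiff(nodes$id, seen)
  if (length(stranded) > 0L) {
    stop("cycle or orphaned subtree involving node ",
         paste(stranded, collapse = ", "))
  }
  rownames(nodes) <- NULL
  class(nodes) <- c("structure_tree", "data.frame")
  nodes
}

#' Load a structure tree from an Allen-style JSON ontology
#'
#' Accepts either a path to a JSON file or an already-parsed list/data frame.
#' The document must carry `id`, `acronym`, `name` and `parent_structure_id`
#' fields per node (flat array form, as exported by [write_tree_json()]).
#'
#' @param ontology path to a JSON file, or a data frame / list of nodes.
#' @return A validated [structure_tree()].
#' @export
load_tree <- function(ontology) {
  if (is.character(ontology) && length(ontology) == 1L) {
    ontology <- jsonlite::fromJSON(ontology)
  }
  if (!is.data.frame(ontology)) {
    ontology <- do.call(rbind, lapply(ontology, function(n) {
      data.frame(
        id = n$id, acronym = n$acronym, name = n$name,
        parent_structure_id = if (is.null(n$parent_structure_id)) NA_integer_
                              else n$parent_structure_id
      )
    }))
  }
  structure_tree(ontology)
}

#' Write a structure tree as an Allen-style JSON ontology
#'
#' @param tree a [structure_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "structure_tree"))
  jsonlite::write_json(as.data.frame(tree), path, na = "null", digits = NA)
  invisible(path)
}

tree_root_id <- function(tree) {
  tree$id[is.na(tree$parent_structure_id)]
}

tree_children <- function(tree) {
  has_parent <- !is.na(tree$parent_structure_id)
  split(tree$id[has_parent], tree$parent_structure_id[has_parent])
}

#' Descendants of a node
#'
#' Returns the ids of all nodes in the subtree rooted at `id`, including `id`
#' itself.
#'
#' @param tree a [structure_tree()].
#' @param id node id (integer) or acronym (character).
#' @return Integer vector of node ids.
#' @export
descendants <- function(tree, id) {
  stopifnot(inherits(tree, "structure_tree"))
  id <- resolve_node(tree, id)
  children <- tree_children(tree)
  out <- id
  frontier <- id
  while (length(frontier) > 0L) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Leaf nodes of a structure tree
#'
#' @param tree a [structure_tree()].
#' @param id optional subtree root (id or acronym); default whole tree.
#' @return Integer vector of leaf ids.
#' @export
tree_leaves <- function(tree, id = NULL) {
  stopifnot(inherits(tree, "structure_tree"))
  parents <- unique(tree$parent_structure_id[!is.na(tree$parent_structure_id)])
  leaves <- setdiff(tree$id, parents)
  if (!is.null(id)) leaves <- intersect(descendants(tree, id), leaves)
  leaves
}

# map acronym -> id, pass ids through; errors on unknown nodes
resolve_node <- function(tree, x) {
  if (is.character(x)) {
    idx <- match(x, tree$acronym)
    if (anyNA(idx)) stop("unknown acronym: ", paste(x[is.na(idx)], collapse = ", "))
    return(tree$id[idx])
  }
  x <- as.integer(x)
  if (!all(x %in% tree$id)) {
    stop("unknown node id: ", paste(setdiff(x, tree$id), collapse = ", "))
  }
  x
}

#' Roll leaf values up the structure tree
#'
#' Each node's value is the sum of the values of its descendant leaves; the
#' root's value is the sum over all leaves. Leaves absent from `leaf_values`
#' contribute 0, so rolling up an empty map yields all zeros.
#'
#' @param tree a [structure_tree()].
#' @param leaf_values named numeric vector keyed by leaf id (names coercible
#'   to integer ids).
#' @return Named numeric vector over all node ids in `tree`.
#' @export
rollup <- function(tree, leaf_values) {
  stopifnot(inherits(tree, "structure_tree"))
  leaves <- tree_leaves(tree)
  if (length(leaf_values) > 0L) {
    ids <- as.integer(names(leaf_values))
    if (anyNA(ids)) stop("leaf_values must be keyed by integer leaf ids")
    bad <- setdiff(ids, leaves)
    if (length(bad) > 0L) {
      stop("not a leaf of the tree: ", paste(bad, collapse = ", "))
    }
  } else {
    ids <- integer(0)
  }
  vals <- stats::setNames(numeric(length(tree$id)), tree$id)
  vals[as.character(ids)] <- as.numeric(leaf_values)
  # accumulate leaves-to-root: process nodes in decreasing depth
  depth <- node_depths(tree)
  for (id in tree$id[order(depth, decreasing = TRUE)]) {
    p <- tree$parent_structure_id[match(id, tree$id)]
    if (!is.na(p)) {
      vals[as.character(p)] <- vals[as.character(p)] + vals[as.character(id)]
    }
  }
  vals
}

node_depths <- function(tree) {
  depth <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$id)
  depth[as.character(tree_root_id(tree))] <- 0L
  children <- tree_children(tree)
  frontier <- tree_root_id(tree)
  while (length(frontier) > 0L) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    if (length(nxt) > 0L) {
      for (n in nxt) {
        p <- tree$parent_structure_id[match(n, tree$id)]
        depth[as.character(n)] <- depth[as.character(p)] + 1L
      }
    }
    frontier <- nxt
  }
  depth[match(tree$id, as.integer(names(depth)))]
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("structure_tree:", nrow(x), "nodes,", length(tree_leaves(x)),
      "leaves, root =", x$acronym[is.na(x$parent_structure_id)], "\n")
  invisible(x)
}
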