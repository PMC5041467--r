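## Taxonomy representation and per-iteration search scopes.
##
## The taxonomy is a rooted tree given by parent links: one node is its own
## parent (the root).  Iterative family expansion ascends one level per round
## and excludes the sub-tree already searched in the previous round, so the
## per-round taxon sets partition the tree.

#' Construct a taxonomy tree from a node table
#'
#' @param nodes data frame with columns `taxid`, `parent`, `rank`, `name`
#'   (first two coercible to integer).
#' @return a `taxonomy_tree` object.
#' @details The root is the unique self-parented node.  Validation rejects
#'   duplicate ids, parents that do not exist, zero or multiple roots, and
#'   parent-link cycles.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(nodes)))
  taxid <- as.integer(nodes$taxid)
  parent <- as.integer(nodes$parent)
  if (anyDuplicated(taxid)) stop("duplicate taxon ids in taxonomy")
  if (!all(parent %in% taxid)) {
    stop("taxonomy reference error: parent id(s) ",
         paste(setdiff(parent, taxid), collapse = ", "), " not present")
  }
  roots <- taxid[taxid == parent]
  if (length(roots) != 1L) {
    stop("taxonomy root error: expected exactly one self-parented node, found ",
         length(roots))
  }
  parent_map <- setNames(parent, as.character(taxid))
  ## Cycle check: every node must reach the root by parent links.
  for (t in taxid) {
    seen <- integer(0)
    cur <- t
    while (cur != roots) {
      if (cur %in% seen) stop("taxonomy structural error: cycle at node ", t)
      seen <- c(seen, cur)
      cur <- parent_map[[as.character(cur)]]
      if (length(seen) > length(taxid)) {
        stop("taxonomy structural error: cycle at node ", t)
      }
    }
  }
  non_root <- taxid != roots
  children <- split(taxid[non_root], as.character(parent[non_root]))
  structure(
    list(
      nodes = tibble(taxid = taxid, parent = parent,
                     rank = as.character(nodes$rank),
                     name = as.character(nodes$name)),
      parent_map = parent_map,
      children = children,
      root = roots
    ),
    class = "taxonomy_tree"
  )
}

#' Read a taxonomy from a TSV file
#'
#' Four tab-separated columns: taxon id, parent id, rank, name.  A header row
#' is detected (first field non-numeric) and skipped.
#'
#' @param path path to the TSV file.
#' @return a [taxonomy_tree()] object.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (length(readLines(path, warn = FALSE)) == 0L) {
    stop("taxonomy file is empty: ", path)
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("taxonomy file is empty: ", path)
  if (ncol(raw) < 4L) stop("taxonomy file needs 4 columns (taxid, parent, rank, name)")
  if (is.na(suppressWarnings(as.integer(raw[1, 1])))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop("taxonomy file has no data rows: ", path)
  taxonomy_tree(tibble(taxid = raw[[1]], parent = raw[[2]],
                       rank = raw[[3]], name = raw[[4]]))
}

#' Write a taxonomy tree to TSV
#'
#' @param tree a `taxonomy_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " taxa, root = ", x$root, "\n", sep = "")
  invisible(x)
}

#' Parent of a taxonomy node
#'
#' The root is its own parent; callers detect `parent_of(tree, n) == n` as the
#' termination condition of the taxonomic ascent.
#'
#' @param tree a `taxonomy_tree`.
#' @param node taxon id.
#' @return the parent taxon id.
#' @export
parent_of <- function(tree, node) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  key <- as.character(as.integer(node))
  if (!key %in% names(tree$parent_map)) stop("unknown taxon id: ", node)
  unname(tree$parent_map[[key]])
}

descendants_of <- function(tree, node) {
  ## node itself plus all transitive children (iterative BFS).
  out <- integer(0)
  frontier <- as.integer(node)
  while (length(frontier)) {
    out <- c(out, frontier)
    kids <- unlist(tree$children[as.character(frontier)], use.names = FALSE)
    frontier <- kids
  }
  sort(unique(out))
}

#' Search scope for one expansion round
#'
#' A scope is the sub-tree of `current` minus (optionally) the sub-tree of
#' `previous`, the node searched in the preceding round.  Excluding the
#' previous sub-tree makes successive rounds disjoint: for example, with
#' current node Enterobacteriaceae and previous node Enterobacter, all taxa
#' that belong to Enterobacteriaceae but not to Enterobacter are searched.
#'
#' @param tree a `taxonomy_tree`.
#' @param current taxon id whose sub-tree is searched.
#' @param previous optional taxon id excluded with its sub-tree; must be a
#'   strict descendant of `current`.
#' @return a `search_scope` object with fields `include` and `exclude`.
#' @export
scope_for_iteration <- function(tree, current, previous = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  current <- as.integer(current)
  if (!as.character(current) %in% names(tree$parent_map)) {
    stop("unknown taxon id: ", current)
  }
  if (!is.null(previous)) {
    previous <- as.integer(previous)
    desc <- descendants_of(tree, current)
    if (!(previous %in% desc) || previous == current) {
      stop("scope error: previous node ", previous,
           " is not a strict descendant of current node ", current)
    }
  }
  structure(list(include = current, exclude = previous), class = "search_scope")
}

#' Materialize the taxon set of a search scope
#'
#' @param tree a `taxonomy_tree`.
#' @param scope a `search_scope` from [scope_for_iteration()].
#' @return sorted integer vector of taxon ids: all descendants of the include
#'   node (itself included) minus all descendants of the exclude node.
#' @export
taxa_in_scope <- function(tree, scope) {
  stopifnot(inherits(tree, "taxonomy_tree"), inherits(scope, "search_scope"))
  inc <- descendants_of(tree, scope$include)
  if (is.null(scope$exclude)) return(inc)
  setdiff(inc, descendants_of(tree, scope$exclude))
}
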