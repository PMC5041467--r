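## Query selection for each expansion round: order-preserving redundancy
## filtering ("first five"), or optional UPGMA clustering with one
## representative per cluster.

#' Collapse near-identical members, order-preserving
#'
#' Greedy scan in member order: a sequence is kept iff its identity (SI) to
#' every previously kept sequence is at most `threshold`.  With the default
#' threshold, members with pairwise similarity greater than 95% are
#' represented by the first of them.
#'
#' @param members tibble with `id` and `seq`, in member order.
#' @param threshold identity threshold (default 0.95).
#' @return the kept subset of `members`, order preserved.
#' @export
dedupe_members <- function(members, threshold = 0.95) {
  if (nrow(members) == 0L) return(members)
  kept <- integer(0)
  for (i in seq_len(nrow(members))) {
    if (length(kept) == 0L) {
      kept <- i
      next
    }
    ident <- vapply(kept, function(k) {
      sequence_identity(members$seq[i], members$seq[k])
    }, numeric(1))
    if (all(ident <= threshold)) kept <- c(kept, i)
  }
  members[kept, , drop = FALSE]
}

#' Select query sequences for the next search round
#'
#' The first `max_queries` of the (deduplicated) members are used.
#'
#' @param kept tibble of deduplicated members.
#' @param max_queries maximum number of queries (default 5).
#' @return the first `min(nrow(kept), max_queries)` rows.
#' @export
select_queries <- function(kept, max_queries = 5L) {
  if (nrow(kept) == 0L) stop("selection error: no sequences to select queries from")
  head(kept, max_queries)
}

#' Pairwise identity distance matrix
#'
#' `d = 1 - SI` for every pair; symmetric with zero diagonal.
#'
#' @param members tibble with `id` and `seq`.
#' @return list with `labels` and the distance matrix `d`.
#' @export
si_distance_matrix <- function(members) {
  n <- nrow(members)
  d <- matrix(0, n, n, dimnames = list(members$id, members$id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- 1 - sequence_identity(members$seq[i], members$seq[j])
      }
    }
  }
  list(labels = members$id, d = d)
}

#' UPGMA clustering with an incrementally raised cutoff
#'
#' Builds the full average-linkage dendrogram, then scans cut heights upward
#' (starting at zero, so identical members always collapse) and returns the
#' first flat clustering with at most `max_clusters` clusters.  With
#' `max_clusters >= n` and all-distinct members this yields the singletons.
#'
#' @param dm distance matrix as returned by [si_distance_matrix()]: a list
#'   with `labels` and symmetric matrix `d` (zero diagonal, values in
#'   `[0, 1]`).
#' @param max_clusters maximum number of clusters (default 5).
#' @return partition of the labels: list of character vectors, ordered by
#'   each cluster's earliest label.
#' @export
upgma_clusters <- function(dm, max_clusters = 5L) {
  d <- dm$d
  labels <- dm$labels
  n <- length(labels)
  stopifnot(nrow(d) == n, ncol(d) == n)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("invariant error: distance matrix must be symmetric with zero diagonal")
  }
  as_partition <- function(assign) {
    cl <- split(seq_len(n), assign)
    cl <- cl[order(vapply(cl, min, integer(1)))]
    lapply(cl, function(ix) labels[ix])
  }
  if (n == 1L) return(as_partition(1L))
  hc <- hclust(as.dist(d), method = "average")
  heights <- sort(unique(c(0, hc$height)))
  for (h in heights) {
    assign <- cutree(hc, h = h)
    if (length(unique(assign)) <= max_clusters) return(as_partition(assign))
  }
  as_partition(rep(1L, n))
}

#' Cluster-based query selection
#'
#' Clusters the members by UPGMA on `1 - SI` distances into at most
#' `max_queries` clusters and takes from each cluster the member earliest in
#' the original member order; output follows that order.  The input sequence
#' is member 0 and therefore always among the queries while it remains a
#' member.
#'
#' @param members tibble with `id` and `seq`, in member order.
#' @param max_queries maximum number of queries (default 5).
#' @return the selected member rows.
#' @export
select_queries_clustered <- function(members, max_queries = 5L) {
  if (nrow(members) == 0L) stop("selection error: no members to cluster")
  if (nrow(members) == 1L) return(members)
  dm <- si_distance_matrix(members)
  part <- upgma_clusters(dm, max_clusters = max_queries)
  first_idx <- vapply(part, function(cl) min(match(cl, members$id)), numeric(1))
  members[sort(first_idx), , drop = FALSE]
}
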