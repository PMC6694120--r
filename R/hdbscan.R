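# Hierarchical density-based clustering (HDBSCAN*).
#
# Implemented from first principles: core distances as the minPts-th
# nearest-neighbour distance, the mutual-reachability transform, a
# single-linkage hierarchy over mutual-reachability distances (equivalent to
# the minimum spanning tree dendrogram), condensation of the hierarchy with
# minimum cluster size = minPts, cluster stability in lambda = 1/distance,
# and excess-of-mass cluster selection.  Points that fall out of the
# hierarchy before any selected cluster is born are labelled noise (0).

#' HDBSCAN* clustering
#'
#' @param x numeric matrix (rows = observations) or a `dist` object.
#' @param minPts minimum cluster size and neighbourhood size for the core
#'   distance (the point itself counts, as in the common R convention).
#' @param allow_single_cluster whether the hierarchy root may be selected.
#' @return object of class `hdbscan` with elements `labels` (integer, 0 =
#'   noise), `n_clusters`, `minPts`, `cluster_stability`.
#' @export
hdbscan <- function(x, minPts = 5L, allow_single_cluster = FALSE) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  hdbscan_dm(d, minPts, allow_single_cluster)
}

# core algorithm on a precomputed full distance matrix (reused across a
# minPts grid without recomputing distances)
hdbscan_dm <- function(d, minPts = 5L, allow_single_cluster = FALSE) {
  n <- nrow(d)
  if (n < 2) stopf("hdbscan: need at least 2 observations")
  minPts <- as.integer(minPts)
  if (minPts < 2) stopf("hdbscan: minPts must be >= 2")
  if (max(d) == 0) {
    # degenerate geometry: all points identical => one cluster
    return(structure(list(labels = rep(1L, n), n_clusters = 1L, minPts = minPts,
                          cluster_stability = Inf), class = "hdbscan"))
  }
  if (n <= minPts) {
    return(structure(list(labels = rep(0L, n), n_clusters = 0L, minPts = minPts,
                          cluster_stability = numeric()), class = "hdbscan"))
  }
  core <- apply(d, 1L, function(r) sort.int(r, partial = minPts)[minPts])
  mrd <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mrd), method = "single")
  res <- condense_tree(hc, n, minPts, allow_single_cluster)
  structure(c(res, list(minPts = minPts)), class = "hdbscan")
}

# Condense a single-linkage hierarchy and extract clusters by excess of mass.
condense_tree <- function(hc, n, minPts, allow_single_cluster) {
  merge <- hc$merge
  height <- hc$height
  m <- n - 1L
  # subtree sizes and contiguous leaf ranges in hc$order
  pos <- integer(n); pos[hc$order] <- seq_len(n)
  sz <- integer(m); lo <- integer(m); hi <- integer(m)
  child_range <- function(ch) {
    if (ch < 0) c(pos[-ch], pos[-ch], 1L) else c(lo[ch], hi[ch], sz[ch])
  }
  for (k in seq_len(m)) {
    a <- child_range(merge[k, 1]); b <- child_range(merge[k, 2])
    lo[k] <- min(a[1], b[1]); hi[k] <- max(a[2], b[2]); sz[k] <- a[3] + b[3]
  }
  subtree_points <- function(ch) {
    if (ch < 0) -ch else hc$order[lo[ch]:hi[ch]]
  }
  child_size <- function(ch) if (ch < 0) 1L else sz[ch]

  eps <- .Machine$double.xmin
  max_clusters <- 2L * m + 2L
  stability <- numeric(max_clusters)
  birth <- numeric(max_clusters)
  parent <- integer(max_clusters)
  kids <- vector("list", max_clusters)
  exit_cluster <- integer(n)
  n_cl <- 1L               # cluster 1 = root
  birth[1] <- 0
  parent[1] <- 0L

  # stack of (dendrogram node, condensed cluster id)
  stack_node <- integer(2L * m); stack_cl <- integer(2L * m)
  top <- 1L
  stack_node[1] <- m; stack_cl[1] <- 1L
  while (top > 0L) {
    node <- stack_node[top]; cl <- stack_cl[top]; top <- top - 1L
    cur <- node
    repeat {
      lam <- 1 / max(height[cur], eps)
      a <- merge[cur, 1]; b <- merge[cur, 2]
      sa <- child_size(a); sb <- child_size(b)
      if (sa >= minPts && sb >= minPts) {
        # true split: current cluster dies, two children are born
        stability[cl] <- stability[cl] + sz[cur] * (lam - birth[cl])
        for (ch in c(a, b)) {
          n_cl <- n_cl + 1L
          birth[n_cl] <- lam
          parent[n_cl] <- cl
          kids[[cl]] <- c(kids[[cl]], n_cl)
          top <- top + 1L
          stack_node[top] <- ch; stack_cl[top] <- n_cl
        }
        break
      }
      # small side(s) fall out of the current cluster as noise at lam
      cont <- NULL
      for (ch in c(a, b)) {
        s <- child_size(ch)
        if (s >= minPts) {
          cont <- ch
        } else {
          pts <- subtree_points(ch)
          stability[cl] <- stability[cl] + s * (lam - birth[cl])
          exit_cluster[pts] <- cl
        }
      }
      if (is.null(cont)) break       # cluster dwindled away entirely
      cur <- cont                    # cluster continues down the big side
    }
  }

  # excess-of-mass selection, leaves first (children always have larger ids)
  selected <- logical(n_cl)
  sel_stab <- numeric(n_cl)
  for (cl in seq.int(n_cl, 1L)) {
    ch <- kids[[cl]]
    if (is.null(ch)) {
      selected[cl] <- TRUE
      sel_stab[cl] <- stability[cl]
    } else {
      cs <- sum(sel_stab[ch])
      if (stability[cl] >= cs && (cl != 1L || allow_single_cluster)) {
        selected[cl] <- TRUE
        sel_stab[cl] <- stability[cl]
        # deselect the whole subtree below
        q <- ch
        while (length(q)) {
          selected[q] <- FALSE
          q <- unlist(kids[q])
        }
      } else {
        sel_stab[cl] <- cs
      }
    }
  }
  if (!allow_single_cluster) selected[1L] <- FALSE

  # label each point by the nearest selected ancestor of its exit cluster
  assigned <- integer(n_cl)
  for (cl in seq_len(n_cl)) {
    assigned[cl] <- if (selected[cl]) cl else if (parent[cl] > 0L) assigned[parent[cl]] else 0L
  }
  raw <- assigned[exit_cluster]
  sel_ids <- sort(unique(raw[raw > 0L]))
  labels <- match(raw, sel_ids, nomatch = 0L)
  list(labels = as.integer(labels), n_clusters = length(sel_ids),
       cluster_stability = stability[sel_ids])
}

#' @export
print.hdbscan <- function(x, ...) {
  cat(sprintf("HDBSCAN* (minPts = %d): %d cluster%s, %d noise point%s of %d\n",
              x$minPts, x$n_clusters, if (x$n_clusters == 1) "" else "s",
              sum(x$labels == 0), if (sum(x$labels == 0) == 1) "" else "s",
              length(x$labels)))
  if (x$n_clusters > 0) {
    print(table(cluster = x$labels[x$labels > 0]))
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer/character label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
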