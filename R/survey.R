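#' Euclidean distance between binary host-range profiles
#'
#' For 0/1 rows the Euclidean distance is the square root of the number of
#' host taxa in which two species groups differ.
#'
#' @param mat binary matrix, rows = species groups, columns = host taxa.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binary_euclidean_distance <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    ds_stop("survey", "need a matrix with at least 2 rows")
  if (any(is.na(mat)) || !all(mat %in% c(0, 1)))
    ds_stop("survey", "matrix entries must be 0/1")
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Complete-linkage or UPGMA (average-linkage) agglomeration over a distance
#' matrix. Ties in merge height are broken by merging the pair whose
#' (lexicographically smallest member label, then largest) is smallest, so
#' results are identical across platforms and input orderings.
#'
#' @param d symmetric distance matrix with row/column labels.
#' @param linkage "complete" (default) or "upgma".
#' @return an object of class `c("detox_hclust", "hclust")`, usable with
#'   [stats::cutree()] and [stats::as.dendrogram()].
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "upgma")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) ds_stop("cluster", "need at least 2 items")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("item", seq_len(n))
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    ds_stop("cluster", "distance matrix must be symmetric with zero diagonal")
  labels <- rownames(d)

  # active clusters: id (negative leaf index or positive merge row), members,
  # size, and the lexicographically smallest member label (the cluster label)
  act <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, size = 1L, label = labels[i]))
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  eps <- 1e-12

  for (step in seq_len(n - 1L)) {
    m <- length(act)
    # find minimum off-diagonal distance
    best <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      if (D[i, j] < best) best <- D[i, j]
    # candidate pairs within eps of the minimum; deterministic tie-break
    cand <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      if (D[i, j] <= best + eps * max(1, best)) cand <- rbind(cand, c(i, j))
    keylo <- apply(cand, 1L, function(p) min(act[[p[1]]]$label, act[[p[2]]]$label))
    keyhi <- apply(cand, 1L, function(p) max(act[[p[1]]]$label, act[[p[2]]]$label))
    pick <- order(keylo, keyhi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    ci <- act[[i]]; cj <- act[[j]]
    merge[step, ] <- sort(c(ci$id, cj$id))
    height[step] <- D[i, j]
    newc <- list(id = step, members = c(ci$members, cj$members),
                 size = ci$size + cj$size, label = min(ci$label, cj$label))
    # Lance-Williams update against every other active cluster
    others <- setdiff(seq_len(m), c(i, j))
    newd <- vapply(others, function(k) {
      if (linkage == "complete") max(D[i, k], D[j, k])
      else (ci$size * D[i, k] + cj$size * D[j, k]) / (ci$size + cj$size)
    }, numeric(1))
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    act <- c(act[others], list(newc))
  }

  order_leaves <- function(node) {
    if (node < 0L) return(-node)
    c(order_leaves(merge[node, 1L]), order_leaves(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = order_leaves(n - 1L), labels = labels,
                 method = linkage, call = match.call(),
                 dist.method = "euclidean"),
            class = c("detox_hclust", "hclust"))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges (the standard [stats::cutree()] cut).
#'
#' @param dend result of [hierarchical_cluster()].
#' @param k number of clusters, 1..n.
#' @return named integer vector of cluster memberships.
#' @export
cut_into_k <- function(dend, k) {
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n)
    ds_stop("cluster", sprintf("k must be in [1, %d]", n))
  stats::cutree(dend, k = as.integer(k))
}

#' Leaf sets of every internal node of a dendrogram
#'
#' @param dend result of [hierarchical_cluster()].
#' @return list, one character vector of leaf labels per merge row.
#' @export
dendrogram_leafsets <- function(dend) {
  n <- length(dend$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get <- function(id) if (id < 0L) dend$labels[-id] else sets[[id]]
    sets[[i]] <- sort(c(get(dend$merge[i, 1L]), get(dend$merge[i, 2L])))
  }
  sets
}

#' Host taxa shared by most species groups
#'
#' A taxon is "commonly shared" when the fraction of species groups using it
#' strictly exceeds `min_fraction`.
#'
#' @param mat binary host-range matrix (rows = species groups).
#' @param min_fraction prevalence threshold in (0, 1); default 0.5.
#' @return character vector of taxa in input column order.
#' @export
shared_taxa <- function(mat, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction >= 1)
    ds_stop("survey", "min_fraction must lie in (0, 1)")
  if (any(is.na(mat)) || !all(mat %in% c(0, 1)))
    ds_stop("survey", "matrix entries must be 0/1")
  colnames(mat)[colMeans(mat) > min_fraction]
}

#' Export a dendrogram as newick with merge heights
#'
#' Branch lengths are differences between successive merge heights, so the
#' tree is ultrametric for UPGMA and monotone for complete linkage.
#'
#' @param dend result of [hierarchical_cluster()].
#' @return single newick string.
#' @export
dendrogram_newick <- function(dend) {
  build <- function(id) {
    if (id < 0L) return(list(txt = dend$labels[-id], h = 0))
    l <- build(dend$merge[id, 1L]); r <- build(dend$merge[id, 2L])
    h <- dend$height[id]
    list(txt = sprintf("(%s:%g,%s:%g)", l$txt, h - l$h, r$txt, h - r$h), h = h)
  }
  paste0(build(nrow(dend$merge))$txt, ";")
}
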