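# Embedding-space evaluation: how well Euclidean distances between the
# unit-norm embeddings reproduce the three-level class structure, plus
# distance-based tree reconstruction (UPGMA ordering, neighbor joining).

#' Pairwise Euclidean distance matrix between embeddings
#'
#' @param embeddings Numeric matrix, one row per item; rownames become the
#'   matrix dimnames.
#' @return Symmetric n x n matrix with zero diagonal. For unit-norm rows all
#'   entries lie in `[0, 2]`.
#' @export
pairwise_distances <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("need at least 2 embeddings")
  D <- as.matrix(stats::dist(embeddings))
  dimnames(D) <- list(rownames(embeddings), rownames(embeddings))
  D
}

validate_distance_matrix <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix has non-zero diagonal")
  if (any(D < -1e-12)) stop("negative distances")
  D
}

#' Mean silhouette score per hierarchy level, against true labels
#'
#' The true class labels at each level are used as the "clustering", so the
#' score measures how consistent embedding-space distances are with the
#' known hierarchy: positive means sequences sit closer to their own class
#' than to the nearest other class.
#'
#' @param embeddings Embedding matrix.
#' @param labels Data frame with columns `family`, `subfamily`,
#'   `subsubfamily` aligned to rows.
#' @return Named numeric vector of mean silhouette widths per level, each in
#'   `[-1, 1]`.
#' @export
silhouette_by_level <- function(embeddings, labels) {
  D <- stats::dist(as.matrix(embeddings))
  out <- numeric(0)
  for (lvl in hier_levels()) {
    f <- factor(labels[[lvl]])
    if (nlevels(f) < 2L) {
      stop("silhouette undefined: only one class at level ", lvl)
    }
    sil <- cluster::silhouette(as.integer(f), D)
    # every cluster a singleton: silhouette width is 0 by convention
    out[lvl] <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  }
  out
}

#' Ward-linkage agglomerative clustering into k clusters
#'
#' Standard Ward clustering on the raw embedding coordinates
#' (`hclust(method = "ward.D2")` on Euclidean distances), cut at `k`.
#'
#' @param embeddings Embedding matrix.
#' @param k Target number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels (named by rownames).
#' @export
agglomerative_ward <- function(embeddings, k) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  hc <- stats::hclust(stats::dist(embeddings), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information adjusted for chance under the hypergeometric
#' (permutation) model, normalized by the arithmetic mean of the two
#' partition entropies: `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`.
#' Identical trivial partitions (both one cluster, or both all singletons)
#' score 1 by convention.
#'
#' @param x,y Two label vectors of equal length (any atomic type).
#' @return Scalar AMI, at most 1; near 0 for random partitions.
#' @export
adjusted_mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("partitions differ in length")
  n <- length(x)
  if (n == 0L) stop("empty label set")
  fx <- factor(x); fy <- factor(y)
  R <- nlevels(fx); C <- nlevels(fy)
  if ((R == 1L && C == 1L) || (R == n && C == n)) return(1)
  tab <- table(fx, fy)
  a <- rowSums(tab); b <- colSums(tab)

  # observed MI (natural log)
  nz <- tab > 0
  nij <- tab[nz]
  ai <- a[row(tab)[nz]]; bj <- b[col(tab)[nz]]
  mi <- sum(nij / n * (log(nij * n) - log(ai * bj)))

  # expected MI under the hypergeometric model
  emi <- 0
  lfn <- lfactorial(n)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nijs <- lo:hi
      term1 <- nijs / n * (log(nijs * n) - log(a[i] * b[j]))
      lprob <- lfactorial(a[i]) + lfactorial(b[j]) +
        lfactorial(n - a[i]) + lfactorial(n - b[j]) -
        lfn - lfactorial(nijs) - lfactorial(a[i] - nijs) -
        lfactorial(b[j] - nijs) - lfactorial(n - a[i] - b[j] + nijs)
      emi <- emi + sum(term1 * exp(lprob))
    }
  }

  hx <- -sum(a / n * log(a / n))
  hy <- -sum(b / n * log(b / n))
  denom <- (hx + hy) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

#' AMI versus number of ward clusters, per hierarchy level
#'
#' Clusters the embeddings by ward linkage at every k in the arithmetic
#' sequence `seq(k_from, k_to, step)` (defaults 2..100 step 3) and scores
#' each partition against the true labels of each level with adjusted
#' mutual information. The curve peaks near the true class count of a level
#' when the embedding geometry matches the hierarchy.
#'
#' @param embeddings Embedding matrix.
#' @param labels Data frame with the three level columns.
#' @param k_from,k_to,step Arithmetic k sequence parameters.
#' @return Data frame with columns `level`, `k`, `ami`.
#' @export
ami_curve <- function(embeddings, labels, k_from = 2L, k_to = 100L, step = 3L) {
  embeddings <- as.matrix(embeddings)
  if (is.null(labels) || nrow(labels) == 0L) stop("empty label set")
  n <- nrow(embeddings)
  ks <- seq(k_from, k_to, by = step)
  if (any(ks > n)) {
    warning("truncating k sequence at n = ", n)
    ks <- ks[ks <= n]
  }
  hc <- stats::hclust(stats::dist(embeddings), method = "ward.D2")
  cuts <- stats::cutree(hc, k = ks)   # n x length(ks)
  if (length(ks) == 1L) cuts <- matrix(cuts, ncol = 1L)
  out <- expand.grid(level = hier_levels(), k = ks, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$ami <- mapply(function(lvl, ki) {
    adjusted_mutual_information(cuts[, which(ks == ki)], labels[[lvl]])
  }, out$level, out$k)
  out[order(out$level, out$k), c("level", "k", "ami")]
}

#' Peak of an AMI curve per level
#'
#' @param curve Data frame from [ami_curve()].
#' @return Named integer vector: the k with maximal AMI at each level.
#' @export
ami_argmax <- function(curve) {
  vapply(split(curve, curve$level), function(d) d$k[which.max(d$ami)],
         numeric(1))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (Saitou-Nei). Exactly recovers the generating
#' tree (topology and branch lengths) when the input matrix is additive.
#' Negative branch-length estimates are clamped to zero; the number of
#' clamped edges is recorded in the `"clamped"` attribute.
#'
#' @param D Symmetric distance matrix with at least 3 taxa (dimnames become
#'   tip labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- validate_distance_matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- sum(neg)
  tree
}

#' UPGMA dendrogram and leaf ordering of a distance matrix
#'
#' Average-linkage hierarchical clustering; exact on ultrametric input. The
#' returned leaf order can be used to sort the rows/columns of the distance
#' matrix for display.
#'
#' @param D Symmetric distance matrix (dimnames used as labels).
#' @return List with `order` (leaf labels in dendrogram order) and `hclust`
#'   (the dendrogram).
#' @export
upgma_order <- function(D) {
  D <- validate_distance_matrix(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labs <- if (!is.null(hc$labels)) hc$labels else as.character(seq_len(nrow(D)))
  list(order = labs[hc$order], hclust = hc)
}

#' Export one FASTA file per cluster
#'
#' Writes `cluster_<label>.fasta` files (ids preserved) so external motif
#' tools (multiple aligners, logo renderers) can be run per cluster.
#'
#' @param dataset A `hier_dataset`.
#' @param clusters Vector of cluster labels aligned to the dataset order
#'   (or named by sequence id).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
export_clusters_fasta <- function(dataset, clusters, dir) {
  stopifnot(inherits(dataset, "hier_dataset"))
  ids <- names(dataset$sequences)
  if (!is.null(names(clusters))) clusters <- clusters[ids]
  if (length(clusters) != length(ids)) stop("clusters not aligned to dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in sort(unique(clusters))) {
    members <- ids[clusters == cl]
    if (length(members) == 0L) {
      warning("skipping empty cluster ", cl)
      next
    }
    path <- file.path(dir, paste0("cluster_", cl, ".fasta"))
    write_fasta(dataset$sequences[members], path)
    paths[as.character(cl)] <- path
  }
  invisible(paths)
}
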