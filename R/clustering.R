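#' Cluster observations with a standard SNN community-detection workflow
#'
#' Reproduces the conventional single-cell clustering recipe so that
#' pre/post conversion concordance can be measured on equal footing:
#'
#' 1. per-observation library-size normalization to 10,000 total counts,
#'    then `log1p`;
#' 2. selection of the `n_top_genes` most dispersed genes
#'    (variance/mean of the normalized values);
#' 3. per-gene standardization (z-score, capped at 10);
#' 4. PCA to `n_components` (capped at the data's rank budget);
#' 5. k-nearest-neighbor graph (Euclidean distance in component space);
#' 6. shared-nearest-neighbor (SNN) edge weights by Jaccard similarity of
#'    the two endpoints' neighbor sets (self included), pruned below 1/15;
#' 7. community detection by modularity optimization (multilevel/Louvain)
#'    at the given `resolution`, seeded for determinism.
#'
#' The selected genes enter PCA ordered by numeric criteria only
#' (decreasing dispersion, then decreasing total count), which makes the
#' labeling invariant to bijective renaming and reordering of features:
#' a converted matrix that merely renames genes clusters identically.
#'
#' @param x An [expression_matrix()].
#' @param n_top_genes Number of high-dispersion genes retained (default
#'   2000; all genes if fewer).
#' @param n_components Number of principal components (default 20).
#' @param k_neighbors Neighborhood size for the kNN/SNN graph (default 20).
#' @param resolution Modularity resolution (default 0.8).
#' @param seed Integer seed controlling community detection (default 0).
#' @return A [cluster_labeling()].
#' @export
cluster_observations <- function(x, n_top_genes = 2000, n_components = 20,
                                 k_neighbors = 20, resolution = 0.8,
                                 seed = 0) {
  stopifnot(inherits(x, "expression_matrix"))
  n_obs <- ncol(x$counts)
  if (n_obs < k_neighbors + 1L) {
    abort(sprintf("need at least k_neighbors + 1 = %d observations, have %d",
                  k_neighbors + 1L, n_obs))
  }

  m <- as.matrix(x$counts)
  libsize <- colSums(m)
  scale_fac <- ifelse(libsize > 0, 10000 / libsize, 0)
  norm <- log1p(sweep(m, 2L, scale_fac, `*`))

  mu <- rowMeans(norm)
  v <- apply(norm, 1L, var)
  dispersion <- ifelse(mu > 0, v / mu, 0)
  totals <- rowSums(m)
  ord <- order(-dispersion, -totals)
  keep <- ord[seq_len(min(n_top_genes, nrow(norm)))]
  sub <- norm[keep, , drop = FALSE]

  sds <- apply(sub, 1L, stats::sd)
  ctr <- sub - rowMeans(sub)
  z <- ctr / ifelse(sds > 0, sds, 1)
  z[z > 10] <- 10

  n_comp <- min(n_components, n_obs - 1L, nrow(z))
  pca <- prcomp(base::t(z), center = FALSE, scale. = FALSE, rank. = n_comp)
  scores <- pca$x

  d <- as.matrix(dist(scores))
  nb <- lapply(seq_len(n_obs), function(j) {
    ord_j <- order(d[j, ], seq_len(n_obs))
    ord_j <- ord_j[ord_j != j]
    c(j, ord_j[seq_len(min(k_neighbors, n_obs - 1L))])
  })

  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n_obs), lengths(nb)),
    j = unlist(nb), x = 1, dims = c(n_obs, n_obs))
  shared <- as.matrix(adj %*% Matrix::t(adj))
  sizes <- lengths(nb)
  union_size <- outer(sizes, sizes, `+`) - shared
  jac <- shared / union_size
  jac[jac < 1 / 15] <- 0
  diag(jac) <- 0

  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  comm <- withr::with_seed(seed, igraph::cluster_louvain(
    g, resolution = resolution))
  cluster_labeling(obs_ids(x), igraph::membership(comm))
}

#' Pre/post conversion clustering concordance
#'
#' Clusters the original and the converted matrix with identical parameters
#' and seed, and reports the Rand index and adjusted Rand index between
#' the two labelings plus the number of clusters found on each side. Both
#' the raw and the adjusted index are reported because they answer
#' slightly different questions (absolute pair agreement vs
#' chance-corrected agreement).
#'
#' @param x The input [expression_matrix()].
#' @param result A `conversion_result` from [convert_matrix()] (or any
#'   object with a `converted` expression matrix).
#' @param ... Clustering parameters passed to [cluster_observations()].
#' @return A `concordance_report`: list with `rand_index`,
#'   `adjusted_rand_index`, `n_clusters_pre`, `n_clusters_post`,
#'   `labels_pre`, `labels_post`.
#' @export
concordance_report <- function(x, result, ...) {
  stopifnot(inherits(x, "expression_matrix"))
  y <- if (inherits(result, "expression_matrix")) result else result$converted
  pre <- cluster_observations(x, ...)
  post <- cluster_observations(y, ...)
  structure(
    list(
      rand_index = rand_index(pre, post),
      adjusted_rand_index = adjusted_rand_index(pre, post),
      n_clusters_pre = dplyr::n_distinct(pre$label),
      n_clusters_post = dplyr::n_distinct(post$label),
      labels_pre = pre,
      labels_post = post
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> RI = %.4f, ARI = %.4f (%d clusters pre, %d post)\n",
    x$rand_index, x$adjusted_rand_index, x$n_clusters_pre,
    x$n_clusters_post))
  invisible(x)
}

#' @export
glance.concordance_report <- function(x, ...) {
  tibble(rand_index = x$rand_index,
         adjusted_rand_index = x$adjusted_rand_index,
         n_clusters_pre = x$n_clusters_pre,
         n_clusters_post = x$n_clusters_post)
}

#' @export
tidy.concordance_report <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(as_tibble(x$labels_pre), label_pre = "label"),
    dplyr::rename(as_tibble(x$labels_post), label_post = "label"),
    by = "obs_id"
  )
}
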