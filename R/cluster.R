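# Expression-profile clustering: replicate-averaged 8-condition profiles,
# Pearson-correlation distance, average-linkage (UPGMA) trees, and
# Figure-of-Merit selection of the number of clusters.

#' Replicate-averaged condition profiles
#'
#' For each requested gene, the mean (transformed) signal per (N, L, G)
#' design cell, columns in canonical order (see [condition_labels()]).
#'
#' @param ds An `expression_dataset`.
#' @param genes Gene ids (default: all genes).
#' @param transform `"log2"` (default) or `"identity"`.
#' @return Numeric matrix genes x 8 (class `profile_matrix`), with the
#'   per-cell standard errors over replicates in `attr(, "se")`.
#' @export
condition_profiles <- function(ds, genes = rownames(ds$signals),
                               transform = "log2") {
  missing <- setdiff(genes, rownames(ds$signals))
  if (length(missing) > 0)
    stop("unknown gene_id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  Y <- apply_transform(ds$signals[genes, , drop = FALSE], transform)
  cell <- factor(cell_label(ds$design$N, ds$design$L, ds$design$G),
                 levels = condition_labels())
  idx <- split(seq_len(ncol(Y)), cell)
  pm <- sapply(idx, function(j) rowMeans(Y[, j, drop = FALSE]))
  se <- sapply(idx, function(j) {
    apply(Y[, j, drop = FALSE], 1, stats::sd) / sqrt(length(j))
  })
  if (length(genes) == 1) {
    pm <- matrix(pm, 1, dimnames = list(genes, condition_labels()))
    se <- matrix(se, 1, dimnames = list(genes, condition_labels()))
  } else {
    rownames(pm) <- rownames(se) <- genes
  }
  structure(pm, se = se, class = c("profile_matrix", "matrix", "array"))
}

# z-score profile rows; zero-variance rows are left at 0
standardize_rows <- function(pm) {
  mu <- rowMeans(pm)
  s <- apply(pm, 1, stats::sd)
  z <- (pm - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Pearson-correlation distance between gene profiles
#'
#' `d(i, j) = 1 - cor(profile_i, profile_j)`, in \[0, 2\]. Zero-variance
#' profiles have no defined correlation; they are assigned distance 1
#' (uncorrelated) to every partner, with a message, so they remain
#' clusterable.
#'
#' @param pm A `profile_matrix` (or plain matrix), genes in rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(pm) {
  if (nrow(pm) < 2) stop("need at least 2 genes")
  s <- apply(pm, 1, stats::sd)
  if (any(s == 0))
    message(sum(s == 0), " zero-variance profile(s) assigned distance 1 to all partners")
  C <- suppressWarnings(stats::cor(t(pm)))
  C[!is.finite(C)] <- 0
  d <- 1 - C
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA tree on a precomputed distance matrix; merge heights are
#' non-decreasing for this linkage.
#'
#' @param dist Symmetric distance matrix (e.g. [correlation_distance()]).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(dist) {
  stats::hclust(stats::as.dist(dist), method = "average")
}

#' Figure of Merit for the number of clusters
#'
#' Leave-one-condition-out predictive-power criterion: for each held-out
#' condition, genes are clustered on the remaining conditions
#' (average-linkage on row-standardized profiles) and the root-mean-squared
#' deviation of the held-out condition from its cluster means is recorded;
#' the FOM at k is the average over held-out conditions, multiplied by the
#' adjustment factor `sqrt(n / (n - k))` that removes the spurious decrease
#' of the raw criterion with k.
#'
#' The number of clusters is then read off the curve's elbow. The default
#' `"segmented"` rule fits two straight lines to the curve and selects the
#' breakpoint minimizing the total squared error; it locates the knee of
#' the S-shaped curves that structured data produces, where a pointwise
#' improvement threshold stops at the first early plateau. The
#' `"threshold"` rule (smallest k whose relative improvement, as a
#' fraction of the curve's span, falls below `elbow_threshold`) is kept
#' for sensitivity analysis.
#'
#' @param pm A `profile_matrix` (rows are z-scored internally).
#' @param k_range Candidate cluster numbers (within \[1, n_genes - 1\]).
#' @param elbow_threshold Relative-improvement cutoff for the
#'   `"threshold"` rule (default 0.05).
#' @param elbow_method `"segmented"` (default) or `"threshold"`.
#' @return List of class `fom_curve`: `k`, `fom` (adjusted), `raw_fom`,
#'   `selected_k`.
#' @export
figure_of_merit <- function(pm, k_range = 2:min(40, nrow(pm) - 1),
                            elbow_threshold = 0.05,
                            elbow_method = c("segmented", "threshold")) {
  elbow_method <- match.arg(elbow_method)
  n <- nrow(pm)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range >= n))
    stop("k_range must lie within [1, n_genes - 1]")
  z <- standardize_rows(pm)
  nc <- ncol(z)
  raw <- matrix(NA_real_, length(k_range), nc)
  for (j in seq_len(nc)) {
    h <- hierarchical_cluster(correlation_distance(z[, -j, drop = FALSE]))
    cuts <- stats::cutree(h, k = k_range)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = length(k_range))
    for (i in seq_along(k_range)) {
      cl <- cuts[, i]
      pred <- stats::ave(z[, j], cl)
      raw[i, j] <- sqrt(mean((z[, j] - pred)^2))
    }
  }
  raw_fom <- rowMeans(raw)
  adj <- raw_fom * sqrt(n / (n - k_range))
  selected <- if (elbow_method == "segmented") select_k_segmented(k_range, adj)
              else select_k_threshold(k_range, adj, elbow_threshold)
  structure(list(k = k_range, fom = adj, raw_fom = raw_fom,
                 selected_k = selected, elbow_method = elbow_method,
                 elbow_threshold = elbow_threshold),
            class = "fom_curve")
}

# two-segment linear fit: the breakpoint minimizing total squared error
# over (steep decline, flat tail) is the curve's knee
select_k_segmented <- function(k, fom) {
  n <- length(k)
  if (n < 4) return(k[which.min(fom)])
  best <- k[1]; best_sse <- Inf
  for (b in 2:(n - 1)) {
    f1 <- stats::lm.fit(cbind(1, k[1:b]), fom[1:b])
    f2 <- stats::lm.fit(cbind(1, k[b:n]), fom[b:n])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best_sse) { best_sse <- sse; best <- k[b] }
  }
  best
}

# threshold rule: smallest k whose FOM improvement at the next step,
# measured against the curve's total span, drops below the threshold
select_k_threshold <- function(k, fom, threshold = 0.05) {
  if (length(k) == 1) return(k)
  span <- max(fom) - min(fom)
  if (span <= 0) return(k[1])
  impr <- -diff(fom) / span
  below <- which(impr < threshold)
  if (length(below) == 0) return(k[length(k)])
  k[below[1]]
}

#' @export
print.fom_curve <- function(x, ...) {
  cat(sprintf("FOM curve over k = %d..%d; selected k = %d\n",
              min(x$k), max(x$k), x$selected_k))
  invisible(x)
}

#' Cut a dendrogram into k gene clusters
#'
#' Partitions the genes by cutting the average-linkage tree, then computes
#' each cluster's 8-condition centroid and the per-condition standard
#' error over member genes.
#'
#' @param dendrogram An `hclust` object from [hierarchical_cluster()].
#' @param k Number of clusters (1 <= k <= n_genes).
#' @param pm The `profile_matrix` the tree was built from (used for
#'   centroids).
#' @return Object of class `gene_clusters`: list of clusters, each with
#'   `cluster_id`, `genes`, `centroid`, `se`, `size`. Cluster ids are
#'   assigned in order of first appearance in the input gene order.
#' @export
cut_clusters <- function(dendrogram, k, pm) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must lie in [1, n_genes]")
  membership <- stats::cutree(dendrogram, k = k)
  clusters <- lapply(seq_len(k), function(i) {
    genes <- names(membership)[membership == i]
    prof <- pm[genes, , drop = FALSE]
    centroid <- colMeans(prof)
    se <- if (length(genes) > 1)
      apply(prof, 2, stats::sd) / sqrt(length(genes))
    else stats::setNames(rep(NA_real_, ncol(prof)), colnames(prof))
    list(cluster_id = sprintf("cluster_%02d", i), genes = genes,
         centroid = centroid, se = se, size = length(genes))
  })
  structure(clusters, class = "gene_clusters", k = k)
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("%d gene clusters (sizes %s)\n", length(x),
              paste(vapply(x, `[[`, integer(1), "size"), collapse = ", ")))
  invisible(x)
}

#' Cluster membership as a named vector
#' @param clusters A `gene_clusters` object.
#' @return Named character vector gene_id -> cluster_id.
#' @export
cluster_membership <- function(clusters) {
  out <- unlist(lapply(clusters, function(cl)
    stats::setNames(rep(cl$cluster_id, cl$size), cl$genes)))
  out
}
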