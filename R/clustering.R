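#' Bias-corrected principal component analysis
#'
#' Scales genes to zero mean and unit variance (values clipped at +/-10),
#' computes the top principal components, and drops components whose score
#' vector has absolute Pearson correlation above `bias_r_max` with the
#' technical bias vector (log2 total counts per cell). Anti-correlated
#' components are treated as equally technical, hence the absolute value.
#'
#' @param X Normalized cells x genes matrix (sparse or dense).
#' @param totals Per-cell total raw counts (bias vector is log2 of this).
#' @param n_components Components to fit (default 100; reduced with a
#'   warning when larger than the data permits).
#' @param bias_r_max Correlation ceiling for retention (default 0.7).
#' @param clip Absolute clip applied to scaled values.
#' @return List: `embedding` (cells x retained components), `rotation`,
#'   `center`, `scale`, `retained` component ids, `bias_correlations`
#'   (all fitted components), `bias` vector.
#' @export
corrected_pca <- function(X, totals, n_components = 100, bias_r_max = 0.7,
                          clip = 10) {
  X <- as.matrix(X)
  stopifnot(length(totals) == nrow(X))
  nc_max <- min(nrow(X) - 1L, ncol(X))
  if (n_components > nc_max) {
    warning("n_components reduced to ", nc_max)
    n_components <- nc_max
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[Z > clip] <- clip
  Z[Z < -clip] <- -clip
  pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = n_components)
  scores <- pc$x
  bias <- log2(totals)
  r <- suppressWarnings(as.vector(cor(scores, bias)))
  r[is.na(r)] <- 0
  retained <- which(abs(r) <= bias_r_max)
  list(
    embedding = scores[, retained, drop = FALSE],
    rotation = pc$rotation,
    center = ctr, scale = scl, clip = clip,
    retained = retained,
    bias_correlations = r,
    bias = bias
  )
}

#' Project new cells into a reference component space
#'
#' Applies the reference gene centering/scaling (with the same clip) and
#' rotation, keeping the reference's retained components. No re-fit.
#'
#' @param pca Output of [corrected_pca()] on the reference cells.
#' @param X Normalized cells x genes matrix for the query cells (same gene
#'   order as the reference).
#' @return Query cells x retained components score matrix.
#' @export
project_cells <- function(pca, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  Z[Z > pca$clip] <- pca$clip
  Z[Z < -pca$clip] <- -pca$clip
  (Z %*% pca$rotation)[, pca$retained, drop = FALSE]
}

## shared-nearest-neighbor graph with Jaccard edge weights (exact kNN)
snn_graph <- function(E, k, prune = 1 / 15) {
  n <- nrow(E)
  nn <- RANN::nn2(E, k = k)$nn.idx  # includes self as first neighbor
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  g
}

#' Louvain clustering of the reference cells
#'
#' Builds an exact k-nearest-neighbor graph on the embedding, weights edges
#' by shared-neighbor Jaccard similarity, and runs Louvain community
#' detection with multilevel refinement. `resolution = "auto"` scans a grid
#' and keeps the partition with the highest modularity.
#'
#' @param E Reference cells x components embedding.
#' @param k Neighbors (default 50).
#' @param resolution Numeric resolution or `"auto"`.
#' @param resolution_grid Grid scanned when `resolution = "auto"`.
#' @param seed RNG seed for the community search.
#' @return List: `cluster` (per-cell labels), `modularity`, `resolution`.
#' @export
louvain_reference <- function(E, k = 50, resolution = "auto",
                              resolution_grid = seq(0.4, 2.0, by = 0.2),
                              seed = 1L) {
  if (k >= nrow(E)) stop("k must be smaller than the number of reference cells")
  g <- snn_graph(E, k)
  grid <- if (identical(resolution, "auto")) resolution_grid else as.numeric(resolution)
  best <- NULL
  for (res in grid) {
    set.seed(derive_seed(seed, paste0("louvain", res)))
    cm <- igraph::cluster_louvain(g, resolution = res)
    q <- igraph::modularity(cm)
    if (is.null(best) || q > best$modularity)
      best <- list(cluster = igraph::membership(cm), modularity = q,
                   resolution = res)
  }
  best$cluster <- setNames(as.integer(best$cluster), rownames(E))
  best
}

#' Propagate reference cluster labels to query cells
#'
#' Fits a random forest on the reference embedding and labels, then
#' predicts each query cell's cluster together with the class-vote
#' fraction. Reference cells are never relabeled.
#'
#' @param E_ref Reference embedding.
#' @param labels_ref Reference cluster labels.
#' @param E_query Query embedding in the same component space.
#' @param n_trees Trees (default 200).
#' @param seed RNG seed for forest construction.
#' @return data.frame: `cell`, `cluster`, `provenance`, `confidence`.
#' @export
propagate_labels <- function(E_ref, labels_ref, E_query, n_trees = 200,
                             seed = 1L) {
  stopifnot(nrow(E_ref) == length(labels_ref))
  if (nrow(E_query) == 0) {
    return(data.frame(cell = character(0), cluster = character(0),
                      provenance = character(0), confidence = numeric(0)))
  }
  lab <- factor(labels_ref)
  if (nlevels(lab) == 1) {
    warning("single reference class; constant prediction")
    return(data.frame(cell = rownames(E_query),
                      cluster = rep(levels(lab), nrow(E_query)),
                      provenance = "rf-predicted",
                      confidence = 1, stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(seed, "rf"))
  rf <- randomForest::randomForest(x = E_ref, y = lab, ntree = n_trees)
  votes <- predict(rf, E_query, type = "vote", norm.votes = TRUE)
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  data.frame(
    cell = rownames(E_query),
    cluster = pred,
    provenance = "rf-predicted",
    confidence = votes[cbind(seq_len(nrow(votes)),
                             max.col(votes, ties.method = "first"))],
    stringsAsFactors = FALSE
  )
}

#' Combined reference + propagated cluster assignment
#'
#' @param ref_labels Named reference labels (from [louvain_reference()]).
#' @param query_pred data.frame from [propagate_labels()].
#' @return data.frame: `cell`, `cluster`, `provenance`, `confidence`.
#' @export
cluster_assignment <- function(ref_labels, query_pred) {
  ref <- data.frame(cell = names(ref_labels),
                    cluster = as.character(ref_labels),
                    provenance = "reference-louvain",
                    confidence = 1, stringsAsFactors = FALSE)
  out <- rbind(ref, query_pred[, c("cell", "cluster", "provenance", "confidence")])
  rownames(out) <- NULL
  out
}

#' t-SNE embedding with per-cluster downsampling
#'
#' Downsamples each cluster to at most `max_per_cluster` cells without
#' replacement and computes a two-dimensional t-SNE of the retained
#' components.
#'
#' @param E Cells x components embedding.
#' @param clusters Per-cell cluster labels aligned to rows of `E`.
#' @param max_per_cluster Downsampling cap (default 1000).
#' @param seed RNG seed (downsampling and t-SNE).
#' @param perplexity t-SNE perplexity; defaults to a size-safe value.
#' @return List: `coords` (kept cells x 2), `cells` kept ids.
#' @export
embed_tsne <- function(E, clusters, max_per_cluster = 1000, seed = 1L,
                       perplexity = NULL) {
  stopifnot(nrow(E) == length(clusters))
  set.seed(derive_seed(seed, "tsne"))
  keep <- unlist(lapply(split(seq_len(nrow(E)), clusters), function(idx) {
    if (length(idx) <= max_per_cluster) idx else sample(idx, max_per_cluster)
  }), use.names = FALSE)
  keep <- sort(keep)
  n <- length(keep)
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  set.seed(derive_seed(seed, "tsne-run"))
  ts <- Rtsne::Rtsne(E[keep, , drop = FALSE], dims = 2, pca = FALSE,
                     perplexity = perplexity, check_duplicates = FALSE)
  coords <- ts$Y
  rownames(coords) <- rownames(E)[keep]
  list(coords = coords, cells = rownames(E)[keep])
}
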