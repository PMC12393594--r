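#' Differential inter-regional co-expression network for a module
#'
#' Region x region Pearson correlation over the module's gene expression,
#' computed separately under the two conditions on the inner join of
#' region labels; the edge statistic is delta = r_MOR - r_SAL, normalized
#' by the maximum |delta| (before truncation), with the top `max_edges`
#' edges by |normalized delta| retained (lexicographic tie-break).
#'
#' @param module_genes Genes defining the module.
#' @param M_sal,M_mor Region x gene matrices for the two conditions.
#' @param max_edges Edge cap (default 200).
#' @return data.frame: `region_a`, `region_b`, `r_sal`, `r_mor`, `delta`,
#'   `normalized_delta`, ordered by |normalized_delta| descending.
#' @export
differential_network <- function(module_genes, M_sal, M_mor,
                                 max_edges = 200) {
  genes <- Reduce(intersect, list(module_genes, colnames(M_sal),
                                  colnames(M_mor)))
  if (length(genes) < 2) stop("need at least 2 module genes in both matrices")
  regions <- intersect(rownames(M_sal), rownames(M_mor))
  if (length(regions) < 2) stop("need at least 2 matched regions")
  A <- M_sal[regions, genes, drop = FALSE]
  B <- M_mor[regions, genes, drop = FALSE]
  r_sal <- suppressWarnings(cor(t(A)))
  r_mor <- suppressWarnings(cor(t(B)))
  r_sal[is.na(r_sal)] <- 0
  r_mor[is.na(r_mor)] <- 0
  delta <- r_mor - r_sal
  ut <- which(upper.tri(delta), arr.ind = TRUE)
  df <- data.frame(
    region_a = regions[ut[, 1]], region_b = regions[ut[, 2]],
    r_sal = r_sal[ut], r_mor = r_mor[ut], delta = delta[ut],
    stringsAsFactors = FALSE)
  mx <- max(abs(df$delta))
  df$normalized_delta <- if (mx > 0) df$delta / mx else df$delta
  df <- df[order(-abs(df$normalized_delta), df$region_a, df$region_b), ,
           drop = FALSE]
  df <- df[seq_len(min(max_edges, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## equal-frequency discretization into ceiling(sqrt(n)) bins
discretize_ef <- function(v, n_bins) {
  r <- rank(v, ties.method = "first")
  as.integer(ceiling(r / length(v) * n_bins))
}

#' Plug-in mutual information of two vectors
#'
#' Equal-frequency discretization into ceiling(sqrt(n)) bins (unless
#' `n_bins` is given) followed by the empirical (plug-in) estimator in
#' nats.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Bin count override.
#' @return Mutual information (nats, >= 0 up to floating point).
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  bx <- discretize_ef(x, n_bins)
  by <- discretize_ef(y, n_bins)
  tab <- table(bx, by) / n
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
}

#' Mutual-information network with DPI pruning
#'
#' Pairwise plug-in mutual information over genes (equal-frequency bins),
#' an optional permutation significance threshold (raw MI networks are
#' complete graphs, so degrees are only meaningful after thresholding),
#' and data-processing-inequality pruning: in every triangle the weakest
#' edge is removed when it is weaker than both others by more than
#' `dpi_tolerance`.
#'
#' @param M Samples x genes matrix (samples are typically regions).
#' @param dpi_tolerance DPI slack (default 0 = strict weakest-edge
#'   removal).
#' @param n_perm Permutations for the edge significance threshold
#'   (0 disables thresholding).
#' @param alpha Permutation threshold level (default 0.05).
#' @param seed RNG seed for permutations.
#' @return List: `mi` raw MI matrix, `adjacency` post-threshold post-DPI
#'   weighted adjacency, `threshold`.
#' @export
aracne_network <- function(M, dpi_tolerance = 0, n_perm = 100, alpha = 0.05,
                           seed = 1L) {
  M <- as.matrix(M)
  if (nrow(M) < 4) stop("need at least 4 samples")
  if (ncol(M) < 3) stop("need at least 3 genes")
  p <- ncol(M)
  n <- nrow(M)
  n_bins <- ceiling(sqrt(n))
  B <- vapply(seq_len(p), function(j) {
    if (sd(M[, j]) == 0) rep(1L, n) else discretize_ef(M[, j], n_bins)
  }, integer(n))
  mi_pair <- function(bx, by) {
    tab <- table(bx, by) / n
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  }
  mi <- matrix(0, p, p, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    mi[i, j] <- mi[j, i] <- mi_pair(B[, i], B[, j])
  }
  const <- apply(M, 2, sd) == 0
  mi[const, ] <- 0
  mi[, const] <- 0

  threshold <- 0
  if (n_perm > 0) {
    set.seed(derive_seed(seed, "mi-perm"))
    null_mi <- replicate(n_perm, {
      i <- sample.int(p, 1); j <- sample.int(p, 1)
      mi_pair(B[sample.int(n), i], B[, j])
    })
    threshold <- unname(quantile(null_mi, 1 - alpha, type = 7))
  }
  adj <- mi
  diag(adj) <- 0
  adj[adj <= threshold] <- 0

  ## DPI on the thresholded network, evaluated on the original weights
  removed <- matrix(FALSE, p, p)
  for (k in seq_len(p)) {
    nb <- which(adj[k, ] > 0)
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      i <- nb[a]; j <- nb[b]
      if (adj[i, j] <= 0) next
      w <- c(ij = adj[i, j], ik = adj[i, k], jk = adj[j, k])
      if (w["ij"] < min(w["ik"], w["jk"]) - dpi_tolerance)
        removed[i, j] <- removed[j, i] <- TRUE
    }
  }
  adj[removed] <- 0
  list(mi = mi, adjacency = adj, threshold = threshold)
}

#' Hub-gene change between condition networks
#'
#' Degrees are counts of retained edges; delta_hub = degree_MOR -
#' degree_SAL. The top `top_k` genes by |delta_hub| (ties: higher MOR
#' degree, then lexicographic) are reported with a subnetwork of the hubs
#' and their MOR-network neighbors, truncated to `max_nodes` keeping the
#' strongest MI edges.
#'
#' @param net_sal,net_mor Weighted adjacency matrices on the same genes
#'   (post-threshold, post-DPI).
#' @param top_k Hubs reported (default 3).
#' @param max_nodes Subnetwork size cap (default 25).
#' @return List: `table` (gene, degree_sal, degree_mor, delta_hub),
#'   `top_hubs`, `subnetwork` (nodes + MOR edge list).
#' @export
delta_hub <- function(net_sal, net_mor, top_k = 3, max_nodes = 25) {
  stopifnot(identical(colnames(net_sal), colnames(net_mor)))
  genes <- colnames(net_sal)
  deg_s <- colSums(net_sal > 0)
  deg_m <- colSums(net_mor > 0)
  if (sum(deg_s) + sum(deg_m) == 0) {
    warning("both networks are empty")
    return(list(table = data.frame(gene = genes, degree_sal = 0,
                                   degree_mor = 0, delta_hub = 0),
                top_hubs = character(0),
                subnetwork = list(nodes = character(0),
                                  edges = data.frame())))
  }
  tab <- data.frame(gene = genes, degree_sal = deg_s, degree_mor = deg_m,
                    delta_hub = deg_m - deg_s, row.names = NULL,
                    stringsAsFactors = FALSE)
  ord <- order(-abs(tab$delta_hub), -tab$degree_mor, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  hubs <- head(tab$gene, top_k)
  nb <- unique(unlist(lapply(hubs, function(h)
    genes[net_mor[h, ] > 0])))
  nb <- setdiff(nb, hubs)
  if (length(hubs) + length(nb) > max_nodes) {
    strength <- vapply(nb, function(g) max(net_mor[g, hubs]), numeric(1))
    nb <- nb[order(-strength, nb)][seq_len(max_nodes - length(hubs))]
  }
  nodes <- c(hubs, nb)
  sub <- net_mor[nodes, nodes, drop = FALSE]
  ut <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
  edges <- data.frame(gene_a = nodes[ut[, 1]], gene_b = nodes[ut[, 2]],
                      mi = sub[cbind(ut[, 1], ut[, 2])],
                      stringsAsFactors = FALSE)
  list(table = tab, top_hubs = hubs,
       subnetwork = list(nodes = nodes, edges = edges))
}

#' Region-specific module flags
#'
#' z-scores each module's region-averaged eigengene across regions
#' (population sd); a module-region pair is flagged when |z| exceeds
#' `z_crit`, and the module's single-region status records whether exactly
#' one region exceeds.
#'
#' @param me_by_region Regions x modules matrix of region-averaged
#'   eigengenes.
#' @param z_crit Threshold (default 1.5, strict >).
#' @return List: `flags` (long data.frame: module, region, z,
#'   region_specific), `single_region` (named logical per module).
#' @export
region_specific_modules <- function(me_by_region, z_crit = 1.5) {
  if (nrow(me_by_region) < 3) stop("need at least 3 regions")
  z <- apply(me_by_region, 2, zscore_pop)
  z[is.na(z)] <- 0
  rownames(z) <- rownames(me_by_region)
  flags <- do.call(rbind, lapply(colnames(z), function(m) {
    data.frame(module = m, region = rownames(z), z = z[, m],
               region_specific = abs(z[, m]) > z_crit,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  single <- vapply(colnames(z), function(m) sum(abs(z[, m]) > z_crit) == 1,
                   logical(1))
  list(flags = flags, single_region = single)
}
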