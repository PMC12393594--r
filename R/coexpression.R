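#' Region-level mean expression matrix
#'
#' Optionally subsamples cells per experimental group, then averages
#' normalized expression per region (or region x group) to give the
#' sample x gene matrix used for inter-regional networks and module
#' detection. Rows with fewer than `min_cells` contributing cells are
#' excluded.
#'
#' @param normalized Normalized cells x genes matrix.
#' @param cells Cell table (`cell`, `sample`, plus region columns).
#' @param depth Region column name (default `"region_d7"`).
#' @param by_group Keep groups separate (region x group rows) or pool.
#' @param sample_n Cells sampled per group (default 50000, capped at the
#'   available cells).
#' @param min_cells Row inclusion floor (default 100).
#' @param seed RNG seed for subsampling.
#' @return List: `M` (rows = samples, cols = genes), `n_cells` per row,
#'   `region` and `group` per row.
#' @export
region_mean_matrix <- function(normalized, cells, depth = "region_d7",
                               by_group = TRUE, sample_n = 50000,
                               min_cells = 100, seed = 1L) {
  stopifnot(depth %in% names(cells),
            all(rownames(normalized) == cells$cell))
  idx <- unlist(lapply(split(seq_len(nrow(cells)), cells$sample), function(i) {
    if (length(i) <= sample_n) return(i)
    set.seed(derive_seed(seed, paste0("rmm", cells$sample[i[1]])))
    sample(i, sample_n)
  }), use.names = FALSE)
  region <- cells[[depth]][idx]
  key <- if (by_group) paste(region, cells$sample[idx], sep = "_") else region
  groups <- split(idx, key)
  n_cells <- lengths(groups)
  keep <- names(groups)[n_cells >= min_cells]
  if (length(keep) == 0) stop("no region row passes the cell-count floor")
  M <- t(vapply(keep, function(k)
    Matrix::colMeans(normalized[groups[[k]], , drop = FALSE]),
    numeric(ncol(normalized))))
  colnames(M) <- colnames(normalized)
  reg <- vapply(keep, function(k) region[match(groups[[k]][1], idx)], "")
  grp <- if (by_group)
    vapply(keep, function(k) cells$sample[groups[[k]][1]], "") else
    rep(NA_character_, length(keep))
  list(M = M, n_cells = unname(n_cells[keep]), region = unname(reg),
       group = unname(grp))
}

#' Inter-regional co-expression network
#'
#' Pearson correlation over gene vectors for every region pair; edges kept
#' where r exceeds `r_min`; degree centrality is degree normalized by the
#' number of possible connections.
#'
#' @param M Region x gene matrix (rows named by region).
#' @param r_min Correlation floor (default 0.95, strict >).
#' @return List: `edges` (`region_a`, `region_b`, `r`), `centrality`,
#'   `cor` full matrix.
#' @export
interregion_network <- function(M, r_min = 0.95) {
  if (nrow(M) < 3) stop("need at least 3 regions")
  sds <- apply(M, 1, sd)
  if (any(sds == 0)) {
    warning("constant region profile dropped: ",
            paste(rownames(M)[sds == 0], collapse = ", "))
    M <- M[sds > 0, , drop = FALSE]
  }
  R <- cor(t(M))
  n <- nrow(R)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  keep <- R[ut] > r_min
  edges <- data.frame(region_a = rownames(R)[ut[keep, 1]],
                      region_b = rownames(R)[ut[keep, 2]],
                      r = R[ut][keep], stringsAsFactors = FALSE)
  deg <- setNames(numeric(n), rownames(R))
  for (i in seq_len(nrow(edges))) {
    deg[edges$region_a[i]] <- deg[edges$region_a[i]] + 1
    deg[edges$region_b[i]] <- deg[edges$region_b[i]] + 1
  }
  list(edges = edges, centrality = deg / (n - 1), cor = R)
}

#' Biweight midcorrelation
#'
#' Outlier-robust correlation using Tukey biweights around the median
#' (tuning constant 9 MADs). Columns with zero median absolute deviation
#' fall back to Pearson centering/scaling.
#'
#' @param x Samples x variables matrix.
#' @param y Optional second matrix (defaults to `x`).
#' @return Correlation matrix.
#' @export
bicor_matrix <- function(x, y = NULL) {
  weight_transform <- function(M) {
    apply(M, 2, function(v) {
      med <- median(v)
      madv <- median(abs(v - med))
      if (madv == 0) {
        ctr <- v - mean(v)
        return(ctr / sqrt(sum(ctr^2)))
      }
      u <- (v - med) / (9 * madv)
      w <- (1 - u^2)^2
      w[abs(u) >= 1] <- 0
      t <- (v - med) * w
      t / sqrt(sum(t^2))
    })
  }
  xt <- weight_transform(as.matrix(x))
  yt <- if (is.null(y)) xt else weight_transform(as.matrix(y))
  crossprod(xt, yt)
}

#' Soft-threshold power selection by scale-free fit
#'
#' For each candidate power, forms the unsigned adjacency |bicor|^beta,
#' computes connectivities, and regresses log10 p(k) on log10 k over
#' binned k; the signed fit index is -sign(slope) * R^2 so a scale-free
#' (negative-slope) degree distribution scores positively. Returns the
#' lowest power whose fit exceeds `r2_min`, else the configured default
#' with a warning.
#'
#' @param M Samples x genes matrix.
#' @param powers Candidate powers (default 1:20).
#' @param r2_min Fit threshold (default 0.8).
#' @param default_power Fallback (default 8).
#' @param n_bins Connectivity histogram bins.
#' @return List: `power`, `fit_table` (power, signed_r2, mean_k).
#' @export
pick_soft_power <- function(M, powers = 1:20, r2_min = 0.8,
                            default_power = 8, n_bins = 10) {
  if (nrow(M) < 8) warning("fewer than 8 samples; power selection is noisy")
  sds <- apply(M, 2, sd)
  M <- M[, sds > 0, drop = FALSE]
  C <- abs(bicor_matrix(M))
  diag(C) <- 0
  fit <- lapply(powers, function(b) {
    A <- C^b
    k <- colSums(A)
    if (all(k == 0)) return(data.frame(power = b, signed_r2 = NA, mean_k = 0))
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    pk <- tapply(k, bin, length)
    km <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & km > 0
    if (sum(ok) < 3) return(data.frame(power = b, signed_r2 = NA, mean_k = mean(k)))
    lx <- log10(km[ok]); ly <- log10(pk[ok] / sum(pk[ok]))
    f <- stats::lm(ly ~ lx)
    r2 <- summary(f)$r.squared
    data.frame(power = b, signed_r2 = -sign(stats::coef(f)[2]) * r2,
               mean_k = mean(k))
  })
  fit <- do.call(rbind, fit)
  rownames(fit) <- NULL
  pass <- which(!is.na(fit$signed_r2) & fit$signed_r2 > r2_min)
  if (length(pass) == 0) {
    warning("no power reaches the scale-free fit threshold; using default ",
            default_power)
    return(list(power = default_power, fit_table = fit))
  }
  list(power = fit$power[pass[1]], fit_table = fit)
}

#' Topological overlap matrix
#'
#' Zhang-Horvath TOM of an adjacency matrix (diagonal ignored):
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj, unit diagonal.
#'
#' @param A Symmetric adjacency with entries in [0, 1].
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  diag(A) <- 0
  L <- A %*% A
  k <- colSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression
#' across samples, sign-oriented to correlate positively with the module's
#' mean expression profile and scaled to unit norm.
#'
#' @param M Samples x genes matrix.
#' @param labels Per-gene module labels (genes with label "grey" skipped).
#' @return Samples x modules matrix.
#' @export
module_eigengenes <- function(M, labels) {
  mods <- setdiff(unique(labels), "grey")
  me <- vapply(mods, function(m) {
    sub <- M[, labels == m, drop = FALSE]
    Z <- scale(sub)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    sv <- svd(Z, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (cor(e, rowMeans(sub)) < 0) e <- -e
    e / sqrt(sum(e^2))
  }, numeric(nrow(M)))
  rownames(me) <- rownames(M)
  colnames(me) <- mods
  me
}

wgcna_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow",
                  "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-expression modules
#'
#' Unsigned adjacency |bicor|^power, topological overlap, average-linkage
#' hierarchical clustering of 1 - TOM, a dynamic tree cut (static cut at a
#' deep-split-dependent fraction of the maximum merge height with a
#' minimum-size filter; unassigned genes go to "grey"), eigengene
#' computation, and iterative merging of modules whose eigengene
#' dissimilarity (1 - correlation) falls below `merge_cut`. Modules are
#' labeled by size with the conventional color sequence.
#'
#' @param M Samples x genes matrix (zero-variance genes are dropped).
#' @param power Soft-threshold power (default 8).
#' @param min_size Minimum module size (default 20).
#' @param deep_split Split aggressiveness 0-4 (default 3); higher cuts
#'   lower on the dendrogram, producing more, smaller modules.
#' @param merge_cut Eigengene-dissimilarity merge threshold (default 0.10).
#' @return List: `labels` (named per gene; "grey" = unassigned),
#'   `eigengenes`, `power`, `dendro` (hclust), `tom`, `merge_history`.
#' @export
detect_modules <- function(M, power = 8, min_size = 20, deep_split = 3,
                           merge_cut = 0.10) {
  sds <- apply(M, 2, sd)
  good <- sds > 0 & colSums(is.na(M)) == 0
  dropped <- colnames(M)[!good]
  M <- M[, good, drop = FALSE]
  if (ncol(M) < min_size) {
    warning("fewer clusterable genes than min_size; all grey")
    labels <- setNames(rep("grey", ncol(M) + length(dropped)),
                       c(colnames(M), dropped))
    return(list(labels = labels, eigengenes = NULL, power = power,
                dendro = NULL, tom = NULL, merge_history = list()))
  }
  A <- abs(bicor_matrix(M))^power
  tom <- tom_similarity(A)
  d <- stats::as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  stopifnot(deep_split %in% 0:4)
  cut_frac <- c(0.99, 0.985, 0.98, 0.975, 0.97)[deep_split + 1]
  h <- cut_frac * max(hc$height)
  raw <- cutree(hc, h = h)
  sizes <- table(raw)
  keep_ids <- names(sizes)[sizes >= min_size]
  labels <- ifelse(raw %in% as.integer(keep_ids), as.character(raw), "grey")
  names(labels) <- colnames(M)

  merge_history <- list()
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(M, labels)
    dis <- 1 - cor(me)
    diag(dis) <- Inf
    mn <- min(dis)
    if (mn >= merge_cut) break
    ij <- which(dis == mn, arr.ind = TRUE)[1, ]
    a <- colnames(dis)[ij[1]]; b <- colnames(dis)[ij[2]]
    labels[labels == b] <- a
    merge_history[[length(merge_history) + 1]] <- c(a, b, dissim = mn)
  }

  ## color labels by decreasing module size
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-vapply(mods, function(m) sum(labels == m), 1L), mods)]
  color_of <- setNames(
    rep(wgcna_colors, length.out = length(mods)), mods)
  out_labels <- ifelse(labels == "grey", "grey", color_of[labels])
  names(out_labels) <- names(labels)
  if (length(dropped))
    out_labels <- c(out_labels, setNames(rep("grey", length(dropped)), dropped))
  me <- if (length(mods)) module_eigengenes(M, out_labels[colnames(M)]) else NULL
  list(labels = out_labels, eigengenes = me, power = power, dendro = hc,
       tom = tom, merge_history = merge_history)
}

#' Module-trait correlation
#'
#' Pearson correlation between module eigengenes and (typically one-hot)
#' trait vectors, with two-sided p-values from the t approximation.
#'
#' @param eigengenes Samples x modules matrix.
#' @param traits Samples x traits numeric matrix.
#' @return List: `r` and `p` (modules x traits); constant traits give NA.
#' @export
module_trait <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == nrow(eigengenes))
  n <- nrow(traits)
  const <- apply(traits, 2, sd) == 0
  r <- suppressWarnings(cor(eigengenes, traits))
  r[, const] <- NA
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p[, const] <- NA
  list(r = r, p = p)
}

#' Paired region-wise differential expression between two conditions
#'
#' Per gene, a paired t-test across matched region rows of two
#' region-mean matrices (natural-log normalized units); log2FC is the mean
#' paired difference divided by ln 2. Genes passing FDR and fold-change
#' thresholds are returned.
#'
#' @param M_a,M_b Region x gene matrices with matching rownames.
#' @param fdr_max BH-adjusted p ceiling (default 0.05).
#' @param lfc_min Absolute log2FC floor (default 0.25).
#' @return data.frame: `gene`, `log2fc`, `p`, `fdr` (significant rows).
#' @export
paired_region_deg <- function(M_a, M_b, fdr_max = 0.05, lfc_min = 0.25) {
  common <- intersect(rownames(M_a), rownames(M_b))
  if (length(common) < 3) stop("need at least 3 matched regions")
  D <- M_a[common, , drop = FALSE] - M_b[common, , drop = FALSE]
  n <- nrow(D)
  m <- colMeans(D)
  s <- apply(D, 2, sd)
  t <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  p[s == 0] <- 1
  fdr <- p.adjust(p, "BH")
  lfc <- m / log(2)
  keep <- fdr < fdr_max & abs(lfc) > lfc_min
  data.frame(gene = colnames(D)[keep], log2fc = lfc[keep], p = p[keep],
             fdr = fdr[keep], row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher enrichment of effect gene sets in modules
#'
#' One-sided Fisher exact test of each module against each effect gene set
#' over the stated universe; -log10 p capped (default 10) and then
#' normalized to [0, 1] within each effect.
#'
#' @param labels Named per-gene module labels.
#' @param effect_sets Named list of gene sets (e.g. OUD risk genes and the
#'   four DEG contrasts).
#' @param universe Gene universe (defaults to names of `labels`).
#' @param cap -log10 p cap (default 10).
#' @return List: `capped` and `normalized` (modules x effects matrices),
#'   `p` raw p-values.
#' @export
fisher_module_enrichment <- function(labels, effect_sets,
                                     universe = names(labels), cap = 10) {
  mods <- setdiff(unique(labels), "grey")
  p <- matrix(1, length(mods), length(effect_sets),
              dimnames = list(mods, names(effect_sets)))
  for (m in mods) {
    in_mod <- universe %in% names(labels)[labels == m]
    for (e in names(effect_sets)) {
      in_set <- universe %in% effect_sets[[e]]
      if (!any(in_set)) { p[m, e] <- 1; next }
      tab <- table(factor(in_mod, c(TRUE, FALSE)),
                   factor(in_set, c(TRUE, FALSE)))
      p[m, e] <- fisher.test(tab, alternative = "greater")$p.value
    }
  }
  capped <- pmin(-log10(p), cap)
  norm <- capped
  for (e in colnames(norm)) {
    mx <- max(norm[, e])
    norm[, e] <- if (mx > 0) norm[, e] / mx else 0
  }
  list(capped = capped, normalized = norm, p = p)
}

#' Prioritize dynamic modules
#'
#' Three rankings over the capped enrichment matrix: (a) the absolute
#' difference between the AA-treatment and GG-treatment DEG enrichments,
#' (b) the per-effect maxima, and (c) the stable, deduplicated union of the
#' top `top_k` modules per metric. Ties resolve by module label order.
#'
#' @param capped Modules x effects capped enrichment matrix; must contain
#'   columns named in `aa_col` / `gg_col`.
#' @param top_k Modules per metric for the union (default 3).
#' @param aa_col,gg_col Treatment-contrast column names.
#' @return List: `delta_rank` (data.frame module, delta), `per_effect`
#'   (list of ranked module vectors), `selected` union.
#' @export
prioritize_modules <- function(capped, top_k = 3,
                               aa_col = "DEG_TREAT_AA",
                               gg_col = "DEG_TREAT_GG") {
  stopifnot(all(c(aa_col, gg_col) %in% colnames(capped)))
  delta <- abs(capped[, aa_col] - capped[, gg_col])
  ord <- order(-delta, rownames(capped))
  delta_rank <- data.frame(module = rownames(capped)[ord],
                           delta = unname(delta[ord]),
                           stringsAsFactors = FALSE)
  per_effect <- lapply(colnames(capped), function(e) {
    o <- order(-capped[, e], rownames(capped))
    rownames(capped)[o]
  })
  names(per_effect) <- colnames(capped)
  pools <- c(list(delta_rank$module),
             lapply(per_effect, function(v) v))
  selected <- unique(unlist(lapply(pools, head, top_k)))
  list(delta_rank = delta_rank, per_effect = per_effect, selected = selected)
}
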