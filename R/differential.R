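#' Wilcoxon differential expression between two cell groups
#'
#' Genes detected in at least `min_pct` of either group are tested with a
#' two-sided Wilcoxon rank-sum test on normalized expression, with
#' Benjamini-Hochberg adjustment across tested genes. The fold change is
#' log2((mean_a + eps) / (mean_b + eps)) on the normalized-count scale
#' (expm1 of the log-normalized values), with eps = 1/scale_factor.
#'
#' @param norm_a,norm_b Normalized cells x genes matrices for the two
#'   groups (same genes, same order).
#' @param min_pct Detection prefilter (default 0.25).
#' @param logfc_min Absolute log2 fold-change floor for retained rows.
#' @param upregulated_only Keep only log2FC > 0 rows.
#' @param scale_factor Normalization scale factor (sets the pseudocount).
#' @return data.frame (`gene`, `log2fc`, `p_value`, `p_adj`, `pct_in`,
#'   `pct_out`, `q_diff`) of retained rows, ordered by p-value; the number
#'   of genes entering BH is in `attr(, "n_tested")`.
#' @export
de_test <- function(norm_a, norm_b, min_pct = 0.25, logfc_min = 0.1,
                    upregulated_only = FALSE, scale_factor = 10000) {
  if (nrow(norm_a) < 3 || nrow(norm_b) < 3)
    stop("both groups need at least 3 cells")
  stopifnot(ncol(norm_a) == ncol(norm_b))
  pct_in <- Matrix::colMeans(norm_a > 0)
  pct_out <- Matrix::colMeans(norm_b > 0)
  test_idx <- which(pct_in >= min_pct | pct_out >= min_pct)
  if (length(test_idx) == 0) {
    out <- data.frame(gene = character(0), log2fc = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      q_diff = numeric(0))
    attr(out, "n_tested") <- 0L
    return(out)
  }
  A <- as.matrix(norm_a[, test_idx, drop = FALSE])
  B <- as.matrix(norm_b[, test_idx, drop = FALSE])
  eps <- 1 / scale_factor
  mean_a <- colMeans(expm1(A))
  mean_b <- colMeans(expm1(B))
  lfc <- log2((mean_a + eps) / (mean_b + eps))
  p <- vapply(seq_along(test_idx), function(j) {
    suppressWarnings(wilcox.test(A[, j], B[, j])$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(
    gene = colnames(norm_a)[test_idx],
    log2fc = lfc, p_value = p, p_adj = padj,
    pct_in = pct_in[test_idx], pct_out = pct_out[test_idx],
    q_diff = pct_in[test_idx] - pct_out[test_idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  keep <- abs(out$log2fc) >= logfc_min
  if (upregulated_only) keep <- keep & out$log2fc > 0
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  attr(out, "n_tested") <- length(test_idx)
  out
}

#' Inter-regional differential expression with subsampling
#'
#' Within each genotype and depth-5 region, subsamples up to `n_sub` cells
#' per treatment arm and tests MOR vs SAL. A gene is region-specific when
#' it passes the significance thresholds in exactly one region; multi-region
#' membership sets are also returned for Venn-style summaries.
#'
#' @param normalized Normalized cells x genes matrix.
#' @param cells Cell table with `cell`, `genotype`, `treatment`,
#'   `region_d5`.
#' @param n_sub Cells subsampled per region x treatment (default 500;
#'   regions with fewer use all cells).
#' @param p_adj_max Adjusted-P ceiling (default 0.01).
#' @param lfc_min Absolute log2FC floor (default 1.5).
#' @param seed RNG seed for subsampling.
#' @return Per-genotype list with `tables` (per-region DEG tables),
#'   `significant` (per-region significant gene sets), `region_specific`
#'   and `membership` (gene -> ';'-joined regions).
#' @export
interregional_deg <- function(normalized, cells, n_sub = 500,
                              p_adj_max = 0.01, lfc_min = 1.5, seed = 1L) {
  stopifnot(all(rownames(normalized) == cells$cell))
  out <- list()
  for (gt in sort(unique(cells$genotype))) {
    sub <- cells$genotype == gt
    regions <- sort(unique(cells$region_d5[sub]))
    tables <- list(); sig <- list()
    for (r in regions) {
      i_sal <- which(sub & cells$region_d5 == r & cells$treatment == "SAL")
      i_mor <- which(sub & cells$region_d5 == r & cells$treatment == "MOR")
      if (length(i_sal) < 3 || length(i_mor) < 3) {
        warning("region ", r, " missing a treatment arm in ", gt, "; skipped")
        next
      }
      set.seed(derive_seed(seed, paste0("ir-", gt, "-", r)))
      if (length(i_sal) > n_sub) i_sal <- sample(i_sal, n_sub)
      if (length(i_mor) > n_sub) i_mor <- sample(i_mor, n_sub)
      tab <- de_test(normalized[i_mor, , drop = FALSE],
                     normalized[i_sal, , drop = FALSE],
                     min_pct = 0.25, logfc_min = 0)
      tables[[r]] <- tab
      sig[[r]] <- tab$gene[tab$p_adj < p_adj_max & abs(tab$log2fc) > lfc_min]
    }
    all_genes <- unique(unlist(sig))
    membership <- vapply(all_genes, function(g) {
      paste(names(sig)[vapply(sig, function(s) g %in% s, logical(1))],
            collapse = ";")
    }, character(1))
    specific <- lapply(names(sig), function(r) {
      all_genes[membership == r]
    })
    names(specific) <- names(sig)
    out[[gt]] <- list(tables = tables, significant = sig,
                      region_specific = specific, membership = membership)
  }
  out
}

#' DEG-ratio z-scores across cell types
#'
#' For each condition and cell type, the DEG ratio is the number of
#' significant genes divided by the number of genes considered expressed in
#' the type (at least `min_umi` counts in at least `min_frac` of its
#' cells); ratios are then z-scored across types within each condition
#' (population sd).
#'
#' @param deg_tables Nested list: `deg_tables[[condition]][[cell_type]]`,
#'   each a DEG table from [de_test()].
#' @param counts Raw counts matrix (for the expression threshold).
#' @param clusters Per-cell type labels aligned to rows of `counts`.
#' @param min_umi,min_frac Expression threshold (defaults 1 and 0.10).
#' @return data.frame: `condition`, `cell_type`, `n_deg`, `n_expressed`,
#'   `ratio`, `z`.
#' @export
deg_ratio_z <- function(deg_tables, counts, clusters, min_umi = 1,
                        min_frac = 0.10) {
  rows <- list()
  for (cond in names(deg_tables)) {
    types <- names(deg_tables[[cond]])
    ratio <- vapply(types, function(ty) {
      expressed <- Matrix::colMeans(
        counts[clusters == ty, , drop = FALSE] >= min_umi) >= min_frac
      tab <- deg_tables[[cond]][[ty]]
      n_deg <- sum(tab$gene %in% colnames(counts)[expressed])
      if (sum(expressed) == 0) return(0)
      n_deg / sum(expressed)
    }, numeric(1))
    z <- zscore_pop(ratio)
    rows[[cond]] <- data.frame(
      condition = cond, cell_type = types,
      ratio = unname(ratio), z = unname(z), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcriptional disproportionality across cell types
#'
#' For each cell type, valid DEGs are those with nonzero expression in the
#' type; types whose valid fraction is below `min_valid_frac` are excluded.
#' The composite score is the mean (optionally |log2FC|-weighted) over
#' valid DEGs of the DEG's mean normalized expression in the type,
#' z-scored across included types (population sd). A type is flagged when
#' |z| exceeds `z_crit` and its mean |log2FC| over valid DEGs exceeds
#' `lfc_gate`.
#'
#' @param normalized Normalized cells x genes matrix.
#' @param clusters Per-cell type labels.
#' @param deg DEG table from the matching genotype's MOR-vs-SAL comparison
#'   (`gene`, `log2fc`).
#' @param z_crit Critical |z| (default 1.6449, the two-sided alpha = 0.10
#'   normal quantile).
#' @param min_valid_frac Valid-DEG fraction floor (default 0.25).
#' @param lfc_gate Mean |log2FC| gate (default 1).
#' @param weighted Weight the composite by |log2FC| (default FALSE).
#' @return data.frame per included type: `cell_type`, `composite_score`,
#'   `z`, `mean_abs_log2fc`, `valid_deg_fraction`, `flagged`.
#' @export
disproportionality <- function(normalized, clusters, deg, z_crit = 1.6449,
                               min_valid_frac = 0.25, lfc_gate = 1,
                               weighted = FALSE) {
  genes <- intersect(deg$gene, colnames(normalized))
  deg <- deg[match(genes, deg$gene), , drop = FALSE]
  if (length(genes) == 0) stop("no DEG present in the expression matrix")
  types <- sort(unique(as.character(clusters)))
  rows <- lapply(types, function(ty) {
    sub <- normalized[clusters == ty, genes, drop = FALSE]
    mean_expr <- Matrix::colMeans(sub)
    valid <- mean_expr > 0
    frac <- mean(valid)
    if (frac < min_valid_frac) return(NULL)
    w <- if (weighted) abs(deg$log2fc[valid]) else rep(1, sum(valid))
    comp <- sum(mean_expr[valid] * w) / sum(w)
    data.frame(cell_type = ty, composite_score = comp,
               mean_abs_log2fc = mean(abs(deg$log2fc[valid])),
               valid_deg_fraction = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 3)
    stop("fewer than 3 cell types pass the valid-DEG fraction; z undefined")
  out$z <- zscore_pop(out$composite_score)
  out$flagged <- abs(out$z) > z_crit & out$mean_abs_log2fc > lfc_gate
  rownames(out) <- NULL
  out[, c("cell_type", "composite_score", "z", "mean_abs_log2fc",
          "valid_deg_fraction", "flagged")]
}

#' Shannon diversity of a distribution
#'
#' H = -sum p ln p over nonzero proportions.
#'
#' @param x Nonnegative counts or proportions.
#' @return Shannon index in nats (ln K for a uniform K-category
#'   distribution, 0 for a point mass).
#' @export
shannon_index <- function(x) {
  stopifnot(all(x >= 0))
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini coefficient
#'
#' Mean absolute difference formulation: G = sum_ij |x_i - x_j| /
#' (2 n^2 mean(x)). 0 for equal shares; approaches (n-1)/n when one
#' category dominates.
#'
#' @param x Nonnegative values.
#' @return Gini coefficient in [0, 1].
#' @export
gini_coef <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) return(0)
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Cell-type composition dynamics between treatment states
#'
#' Aggregates per-genotype cell counts by depth-7 region and cell type,
#' keeping only combinations observed with at least `min_n` cells in all
#' four groups. Morphine-induced change is the percentage change relative
#' to saline; for display it is symmetric-log transformed
#' (sign(x) log1p(|x|/100)) and then scaled onto [-1, 1] by the maximum
#' absolute value (a zero-preserving min-max). Baseline circle sizes are
#' log1p saline counts clipped to the stated percentile range. Shannon
#' diversity of each type across regions is reported per state, and a Gini
#' coefficient of type proportions per region and state.
#'
#' @param cells Cell table (`genotype`, `treatment`, `region_d7`).
#' @param clusters Per-cell type labels aligned to rows of `cells`.
#' @param min_n Minimum cells per group for a (region, type) pair.
#' @param clip Percentile clip range for circle sizes (default c(5, 95)).
#' @return List: `table` (long data.frame with `genotype`, `region`,
#'   `cell_type`, `n_sal`, `n_mor`, `pct_change`, `normalized_change`,
#'   `circle_size`), `shannon` and `gini` data.frames.
#' @export
composition_dynamics <- function(cells, clusters, min_n = 50,
                                 clip = c(5, 95)) {
  df <- data.frame(genotype = cells$genotype, treatment = cells$treatment,
                   region = cells$region_d7, type = as.character(clusters),
                   stringsAsFactors = FALSE)
  cnt <- aggregate(list(n = rep(1L, nrow(df))),
                   df[, c("genotype", "treatment", "region", "type")], sum)
  ## keep (region, type) pairs meeting min_n in all four groups
  key <- paste(cnt$region, cnt$type, sep = "|")
  ok <- tapply(cnt$n >= min_n, key, function(v) sum(v) == 4)
  keep_keys <- names(ok)[ok]
  cnt <- cnt[key %in% keep_keys, , drop = FALSE]
  if (nrow(cnt) == 0) stop("no (region, cell type) pair present in all four groups at min_n")

  wide <- merge(
    cnt[cnt$treatment == "SAL", c("genotype", "region", "type", "n")],
    cnt[cnt$treatment == "MOR", c("genotype", "region", "type", "n")],
    by = c("genotype", "region", "type"), suffixes = c("_sal", "_mor"))
  zero_sal <- wide$n_sal == 0
  if (any(zero_sal)) {
    warning(sum(zero_sal), " pair(s) with zero saline count excluded")
    wide <- wide[!zero_sal, , drop = FALSE]
  }
  wide$pct_change <- 100 * (wide$n_mor - wide$n_sal) / wide$n_sal
  symlog <- sign(wide$pct_change) * log1p(abs(wide$pct_change) / 100)
  m <- max(abs(symlog))
  wide$normalized_change <- if (m > 0) symlog / m else symlog
  cs <- log1p(wide$n_sal)
  lim <- quantile(cs, clip / 100, type = 7)
  wide$circle_size <- pmin(pmax(cs, lim[1]), lim[2])
  names(wide)[names(wide) == "type"] <- "cell_type"

  shannon <- do.call(rbind, lapply(split(cnt, list(cnt$genotype, cnt$treatment, cnt$type),
                                         drop = TRUE), function(s) {
    data.frame(genotype = s$genotype[1], treatment = s$treatment[1],
               cell_type = s$type[1], shannon = shannon_index(s$n),
               stringsAsFactors = FALSE)
  }))
  gini <- do.call(rbind, lapply(split(cnt, list(cnt$genotype, cnt$treatment, cnt$region),
                                      drop = TRUE), function(s) {
    data.frame(genotype = s$genotype[1], treatment = s$treatment[1],
               region = s$region[1], gini = gini_coef(s$n / sum(s$n)),
               stringsAsFactors = FALSE)
  }))
  rownames(wide) <- rownames(shannon) <- rownames(gini) <- NULL
  list(table = wide, shannon = shannon, gini = gini)
}
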