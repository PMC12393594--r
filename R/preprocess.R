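#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly tests the most extreme value against the Grubbs critical value
#' at level `alpha`, removing it while significant. Used for negative-probe
#' screening and segmentation-area outlier removal.
#'
#' @param values Finite numeric vector.
#' @param alpha Per-step significance level (default 0.01).
#' @return Integer indices of removed values (empty if none).
#' @export
grubbs_outliers <- function(values, alpha = 0.01) {
  stopifnot(all(is.finite(values)))
  if (length(values) < 3) {
    warning("Grubbs test undefined for n < 3; no outliers flagged")
    return(integer(0))
  }
  removed <- integer(0)
  active <- seq_along(values)
  repeat {
    n <- length(active)
    if (n < 3) break
    x <- values[active]
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    g <- dev[i] / s
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g > gcrit) {
      removed <- c(removed, active[i])
      active <- active[-i]
    } else break
  }
  sort(removed)
}

neg_flags <- function(genes) {
  stopifnot(is.data.frame(genes), "is_negative_probe" %in% names(genes))
  genes$is_negative_probe
}

#' Probe-level filtering against the negative-control background
#'
#' Three rules applied to per-probe total counts: (a) negative probes flagged
#' by an iterative Grubbs test (alpha) are excluded from the background
#' model; (b) target genes whose total falls below the 50th percentile of
#' the retained-negative-probe totals are removed; (c) target genes whose
#' one-sided Poisson exceedance test against the mean retained-negative
#' total gives P > `p_max` are removed.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param genes Gene table with `gene` and `is_negative_probe`.
#' @param alpha Grubbs level for negative-probe screening.
#' @param bg_percentile Background percentile cut (default 50).
#' @param p_max Detection p-value ceiling (default 0.01).
#' @return List: `retained` (target gene names kept), `removed_background`,
#'   `removed_pvalue`, `flagged_negatives`, `background_cut`, `background_mean`.
#' @export
filter_probes <- function(counts, genes, alpha = 0.01, bg_percentile = 50,
                          p_max = 0.01) {
  neg <- neg_flags(genes)
  if (!any(neg)) stop("no negative probes present; background undefined")
  totals <- Matrix::colSums(counts)
  neg_tot <- totals[neg]
  bad_neg <- grubbs_outliers(neg_tot, alpha)
  keep_neg <- neg_tot[setdiff(seq_along(neg_tot), bad_neg)]
  bg_cut <- unname(quantile(keep_neg, bg_percentile / 100, type = 7))
  bg_mean <- mean(keep_neg)
  target <- genes$gene[!neg]
  t_tot <- totals[!neg]
  below <- t_tot < bg_cut
  ## one-sided Poisson exceedance: P(X >= observed | lambda = background mean)
  pval <- stats::ppois(t_tot - 1, lambda = bg_mean, lower.tail = FALSE)
  insig <- pval > p_max
  retained <- target[!(below | insig)]
  list(
    retained = retained,
    removed_background = target[below],
    removed_pvalue = target[insig & !below],
    flagged_negatives = genes$gene[neg][bad_neg],
    background_cut = bg_cut,
    background_mean = bg_mean
  )
}

#' Cell-level quality filtering
#'
#' Retains cells with at least `min_transcripts` total real-probe counts,
#' at most `max_neg_frac` of counts on negative probes, a total-count to
#' detected-gene ratio strictly greater than 1, and segmentation areas not
#' flagged by the Grubbs outlier screen.
#'
#' @param counts Sparse cells x genes matrix (negative probes included).
#' @param genes Gene table with negative-probe flags.
#' @param areas Per-cell segmentation areas, aligned to rows of `counts`.
#' @param min_transcripts Minimum total transcripts (default 5).
#' @param max_neg_frac Maximum fraction of counts on negative probes.
#' @param area_alpha Grubbs level for area outliers.
#' @return Character vector of retained cell ids.
#' @export
filter_cells <- function(counts, genes, areas, min_transcripts = 5,
                         max_neg_frac = 0.10, area_alpha = 0.01) {
  stopifnot(length(areas) == nrow(counts))
  neg <- neg_flags(genes)
  tot_all <- Matrix::rowSums(counts)
  tot_neg <- Matrix::rowSums(counts[, neg, drop = FALSE])
  tot_real <- tot_all - tot_neg
  detected <- Matrix::rowSums(counts[, !neg, drop = FALSE] > 0)
  neg_frac <- ifelse(tot_all > 0, tot_neg / tot_all, 0)
  ratio <- ifelse(detected > 0, tot_real / detected, 0)
  area_out <- grubbs_outliers(areas, area_alpha)
  keep <- tot_real >= min_transcripts &
    neg_frac <= max_neg_frac &
    ratio > 1 &
    !(seq_len(nrow(counts)) %in% area_out)
  rownames(counts)[keep]
}

#' Field-of-view quality filtering
#'
#' Two-stage FOV filter. Run level: mean real-probe counts per cell at
#' least `min_mean_counts`, mean negative-probe counts per cell at most
#' `max_mean_neg`, and at least `min_cells * cell_scale` detected cells.
#' Pipeline level: mean transcripts per cell at least `min_mean_transcripts`.
#' The cell minimum scale factor supports desk-scale fixtures; it is
#' reported in the result.
#'
#' @param counts Sparse cells x genes matrix.
#' @param genes Gene table with negative-probe flags.
#' @param fov Per-cell FOV ids aligned to rows of `counts`.
#' @param min_mean_counts Run-level mean counts per cell floor (default 100).
#' @param max_mean_neg Run-level mean negative counts per cell ceiling.
#' @param min_cells Run-level detected-cell floor (default 500).
#' @param cell_scale Scale factor applied to `min_cells`.
#' @param min_mean_transcripts Pipeline-level mean transcripts floor.
#' @return List: `retained` FOV ids, `stats` per-FOV data.frame,
#'   `cell_scale`.
#' @export
filter_fovs <- function(counts, genes, fov, min_mean_counts = 100,
                        max_mean_neg = 1.0, min_cells = 500, cell_scale = 1.0,
                        min_mean_transcripts = 10) {
  stopifnot(length(fov) == nrow(counts))
  if (anyNA(fov)) stop("unknown FOV id (NA) present")
  neg <- neg_flags(genes)
  tot_real <- Matrix::rowSums(counts[, !neg, drop = FALSE])
  tot_neg <- Matrix::rowSums(counts[, neg, drop = FALSE])
  ids <- sort(unique(fov))
  stats <- data.frame(
    fov = ids,
    n_cells = as.integer(table(factor(fov, levels = ids))),
    mean_counts = as.numeric(tapply(tot_real, factor(fov, levels = ids), mean)),
    mean_neg = as.numeric(tapply(tot_neg, factor(fov, levels = ids), mean))
  )
  run_ok <- stats$mean_counts >= min_mean_counts &
    stats$mean_neg <= max_mean_neg &
    stats$n_cells >= min_cells * cell_scale
  pipe_ok <- stats$mean_counts >= min_mean_transcripts
  stats$retained <- run_ok & pipe_ok
  list(retained = ids[stats$retained], stats = stats, cell_scale = cell_scale)
}

#' Library-size log-normalization
#'
#' Scales each cell to `scale_factor` total counts and applies a natural-log
#' transform: x = ln(1 + scale_factor * n / N).
#'
#' @param counts Sparse cells x genes count matrix (real probes only).
#' @param scale_factor Target total per cell (default 10,000).
#' @return Sparse cells x genes matrix of normalized values.
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    stop("zero-total cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  ## dgCMatrix is column-compressed; map each nonzero to its row's total
  x <- methods::as(counts, "CsparseMatrix")
  row_of <- x@i + 1L
  x@x <- log1p(scale_factor * x@x / totals[row_of])
  x
}

#' Secondary depth filter
#'
#' Removes cells whose total counts or detected gene counts fall strictly
#' below the `pct`-th percentile of the respective distributions
#' (linear-interpolation percentile convention). Applied after primary QC,
#' before clustering.
#'
#' @param counts Sparse cells x genes count matrix (real probes only).
#' @param pct Percentile (default 5); 0 keeps everything.
#' @return List: `retained` cell ids, `count_threshold`, `gene_threshold`.
#' @export
secondary_filter <- function(counts, pct = 5) {
  totals <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  ct <- unname(quantile(totals, pct / 100, type = 7))
  gt <- unname(quantile(detected, pct / 100, type = 7))
  keep <- totals >= ct & detected >= gt
  list(retained = rownames(counts)[keep], count_threshold = ct,
       gene_threshold = gt)
}

#' Run the full quality-control stage
#'
#' Applies probe, cell, FOV and secondary filters in sequence and assembles
#' a QC report with per-filter removal counts and the overall pass rate.
#'
#' @param dataset List with `counts`, `genes`, `cells` as produced by
#'   [generate_dataset()] or [read_fixture()].
#' @param cell_scale FOV cell-minimum scale factor for desk-scale data.
#' @param secondary_pct Secondary depth-filter percentile.
#' @param ... Passed through to the individual filters.
#' @return List: filtered `counts` (real probes only), `normalized`,
#'   `cells`, and `report`.
#' @export
run_qc <- function(dataset, cell_scale = 0.1, secondary_pct = 5, ...) {
  counts <- dataset$counts
  genes <- dataset$genes
  cells <- dataset$cells
  n_input <- nrow(counts)

  pr <- filter_probes(counts, genes, ...)
  fv <- filter_fovs(counts, genes, cells$fov, cell_scale = cell_scale)
  cl <- filter_cells(counts, genes, cells$area)

  keep_cells <- intersect(cl, cells$cell[cells$fov %in% fv$retained])
  sub <- counts[keep_cells, pr$retained, drop = FALSE]
  sec <- secondary_filter(sub, pct = secondary_pct)
  final_cells <- sec$retained
  out_counts <- counts[final_cells, pr$retained, drop = FALSE]
  report <- list(
    input_cells = n_input,
    retained_cells = length(final_cells),
    retained_genes = length(pr$retained),
    retained_fovs = fv$retained,
    removed = list(
      probes_background = length(pr$removed_background),
      probes_pvalue = length(pr$removed_pvalue),
      cells_quality = n_input - length(cl),
      cells_fov = n_input - sum(cells$fov %in% fv$retained),
      cells_secondary = nrow(sub) - length(final_cells)
    ),
    secondary_thresholds = c(counts = sec$count_threshold,
                             genes = sec$gene_threshold),
    cell_scale = cell_scale,
    percentile_convention = "type-7 linear interpolation",
    pass_rate = pass_rate(length(final_cells), n_input)
  )
  list(
    counts = out_counts,
    normalized = lognormalize(out_counts),
    cells = cells[match(final_cells, cells$cell), , drop = FALSE],
    report = report
  )
}
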