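#' Default neurotransmitter and glial classification rules
#'
#' Each identity is a list of required gene groups; a cell passes an
#' identity when every group contains at least one high-expressing gene.
#' Neurotransmitter identities use canonical transporter/biosynthesis
#' pairs; glial identities require one gene from each of two biologically
#' distinct marker modules.
#'
#' @return Named list; each element has `kind`
#'   (`"neurotransmitter"`/`"glial"`) and `groups` (list of gene vectors).
#' @export
default_rule_table <- function() {
  list(
    Glutamatergic = list(kind = "neurotransmitter",
      groups = list(c("Slc17a6", "Slc17a7", "Slc17a8"))),
    GABAergic = list(kind = "neurotransmitter",
      groups = list(c("Slc32a1", "Slc18a2"), c("Gad1", "Gad2", "Aldh1a1"))),
    Glycinergic = list(kind = "neurotransmitter",
      groups = list("Slc6a5")),
    Cholinergic = list(kind = "neurotransmitter",
      groups = list("Slc18a3", "Chat")),
    Dopaminergic = list(kind = "neurotransmitter",
      groups = list(c("Slc6a3", "Slc18a2"), "Th", "Ddc")),
    Serotonergic = list(kind = "neurotransmitter",
      groups = list(c("Slc6a4", "Slc18a2"), "Tph2", "Ddc")),
    Noradrenergic = list(kind = "neurotransmitter",
      groups = list(c("Slc6a2", "Slc18a2"), "Dbh")),
    Histaminergic = list(kind = "neurotransmitter",
      groups = list("Slc18a2", "Hdc")),
    Astrocytes = list(kind = "glial",
      groups = list(c("Gfap", "Aldoc", "S100b"), c("Slc1a3", "Aqp4", "Agt"))),
    Microglia = list(kind = "glial",
      groups = list(c("Cx3cr1", "Csf1r", "Itgam"),
                    c("Iba1", "C1qc", "Tmem119", "P2ry12"))),
    Oligodendrocytes = list(kind = "glial",
      groups = list(c("Plp1", "Mbp", "Mobp", "Mag"),
                    c("Olig1", "Olig2", "Sox10", "Nkx2-2"))),
    Ependymal = list(kind = "glial",
      groups = list("Foxj1", c("Ttr", "Aqp1"))),
    Endothelial = list(kind = "glial",
      groups = list(c("Cldn5", "Pecam1", "Vwf"), c("Flt1", "Kdr")))
  )
}

validate_rules <- function(rules) {
  stopifnot(is.list(rules), length(rules) > 0)
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!r$kind %in% c("neurotransmitter", "glial"))
      stop("identity ", nm, ": kind must be neurotransmitter or glial")
    if (length(r$groups) < 1 || any(lengths(r$groups) == 0))
      stop("identity ", nm, ": every rule needs non-empty gene groups")
  }
  invisible(rules)
}

#' log2 counts-per-million
#'
#' @param counts Sparse cells x genes raw count matrix.
#' @return Dense or sparse matrix of log2(CPM + 1) values.
#' @export
log2cpm <- function(counts) {
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  x <- methods::as(counts, "CsparseMatrix")
  row_of <- x@i + 1L
  x@x <- log2(1e6 * x@x / totals[row_of] + 1)
  x
}

#' High-expression call for one gene
#'
#' A cell is high for a gene when log2(CPM + 1) exceeds `threshold` (the
#' consensus cutoff, default 3). A two-component Gaussian mixture is also
#' fit to the gene's log2CPM values as a bimodality diagnostic; the fitted
#' component means and posterior crossover are reported but never change
#' the call.
#'
#' @param counts Sparse cells x genes raw count matrix.
#' @param gene Gene name.
#' @param threshold log2CPM cutoff (default 3).
#' @param gmm Fit the diagnostic mixture (default TRUE; skipped for
#'   degenerate distributions).
#' @return List: `high` (logical per cell), `gmm` (list with `means`,
#'   `crossover`) or NULL.
#' @export
call_high_expression <- function(counts, gene, threshold = 3, gmm = TRUE) {
  if (!gene %in% colnames(counts)) {
    warning("gene absent: ", gene)
    return(list(high = setNames(rep(FALSE, nrow(counts)), rownames(counts)),
                gmm = NULL))
  }
  v <- as.numeric(log2cpm(counts)[, gene])
  names(v) <- rownames(counts)
  high <- v > threshold
  diag <- NULL
  if (gmm && length(unique(v)) > 3) {
    fit <- tryCatch(
      Mclust(v, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        Mclust(v, G = 2, modelNames = "E", verbose = FALSE),
        error = function(e) NULL)
    if (!is.null(fit)) {
      mns <- sort(fit$parameters$mean)
      grid <- seq(mns[1], mns[2], length.out = 512)
      post <- predict(fit, grid)$z
      lowc <- which(fit$parameters$mean == min(fit$parameters$mean))[1]
      cross <- grid[which(post[, lowc] < 0.5)[1]]
      diag <- list(means = mns, crossover = unname(cross))
    }
  }
  list(high = setNames(high, rownames(counts)), gmm = diag)
}

#' Classify cells against the identity rule table
#'
#' A cell passes an identity when every required gene group has at least
#' one high-expressing gene (log2CPM above `threshold`). Cells may pass
#' multiple identities; all flags are returned.
#'
#' @param counts Sparse cells x genes raw count matrix.
#' @param rules Rule table (see [default_rule_table()]).
#' @param threshold log2CPM cutoff.
#' @return Logical cells x identities matrix.
#' @export
classify_cells <- function(counts, rules = default_rule_table(),
                           threshold = 3) {
  validate_rules(rules)
  cpm <- log2cpm(counts)
  high <- cpm > threshold
  flags <- matrix(FALSE, nrow(counts), length(rules),
                  dimnames = list(rownames(counts), names(rules)))
  for (nm in names(rules)) {
    pass <- rep(TRUE, nrow(counts))
    for (grp in rules[[nm]]$groups) {
      present <- intersect(grp, colnames(counts))
      if (length(present) == 0) { pass[] <- FALSE; break }
      hit <- Matrix::rowSums(high[, present, drop = FALSE]) > 0
      pass <- pass & hit
    }
    flags[, nm] <- pass
  }
  flags
}

#' Cluster-level identity assignment
#'
#' Computes, per cluster and identity, the fraction of cells passing the
#' rule; assigns every identity whose fraction exceeds `min_fraction`
#' (strict), with the primary identity being the one with the highest
#' fraction (lexicographic tie-break, recorded). Clusters passing nothing
#' are labeled "Other".
#'
#' @param flags Logical cells x identities matrix from [classify_cells()].
#' @param clusters Per-cell cluster labels aligned to rows of `flags`.
#' @param rules Rule table (to recover identity kinds).
#' @param min_fraction Passing-fraction cutoff (default 0.30, strict >).
#' @return data.frame per cluster: `cluster`, `primary_identity`, `kind`,
#'   `passing_fraction`, `all_identities` (';'-joined), `tie`.
#' @export
assign_cluster_identity <- function(flags, clusters,
                                    rules = default_rule_table(),
                                    min_fraction = 0.30) {
  stopifnot(nrow(flags) == length(clusters))
  ids <- sort(unique(as.character(clusters)))
  rows <- lapply(ids, function(cl) {
    sub <- flags[clusters == cl, , drop = FALSE]
    frac <- colMeans(sub)
    passing <- names(frac)[frac > min_fraction]
    if (length(passing) == 0) {
      return(data.frame(cluster = cl, primary_identity = "Other",
                        kind = "other", passing_fraction = max(frac),
                        all_identities = "", tie = FALSE,
                        stringsAsFactors = FALSE))
    }
    ord <- order(-frac[passing], passing)
    best <- passing[ord][1]
    tie <- sum(frac[passing] == frac[best]) > 1
    data.frame(cluster = cl, primary_identity = best,
               kind = rules[[best]]$kind,
               passing_fraction = unname(frac[best]),
               all_identities = paste(passing[ord], collapse = ";"),
               tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marker-based cluster quality control
#'
#' One-vs-rest Wilcoxon markers for the cluster; high-confidence markers
#' require adjusted P below `p_adj_max` and detection-fraction enrichment
#' (q_diff = fraction expressing inside minus outside) of at least
#' `q_diff_min`. The DE score is the sum of -log10 adjusted P over
#' high-confidence markers, with each gene's contribution capped to avoid
#' infinities from numerical underflow. The cluster is retained when it has
#' at least `min_markers` high-confidence markers and a DE score of at
#' least `de_score_min`.
#'
#' @param cluster Cluster id to test.
#' @param normalized Normalized cells x genes matrix.
#' @param clusters Per-cell cluster labels.
#' @param min_cells Minimum cluster size to test (default 50).
#' @param min_markers Marker-count floor (default 8).
#' @param q_diff_min q_diff floor (default 0.7).
#' @param de_score_min DE-score floor (default 150).
#' @param p_adj_max Adjusted-P ceiling (default 0.01).
#' @param cap Per-gene -log10(P_adj) cap (default 300).
#' @param min_pct Detection prefilter passed to [de_test()].
#' @param logfc_min Marker log2FC floor passed to [de_test()] (default 0.1).
#' @return List: `verdict` ("retained"/"other"/"too_small"), `n_markers`,
#'   `de_score`, `markers` (DEG table slice), `cap`.
#' @export
marker_qc <- function(cluster, normalized, clusters, min_cells = 50,
                      min_markers = 8, q_diff_min = 0.7, de_score_min = 150,
                      p_adj_max = 0.01, cap = 300, min_pct = 0.25,
                      logfc_min = 0.1) {
  in_cl <- clusters == cluster
  if (sum(in_cl) < min_cells)
    return(list(verdict = "too_small", n_markers = 0L, de_score = 0,
                markers = NULL, cap = cap))
  if (sum(Matrix::rowSums(normalized[in_cl, , drop = FALSE]) > 0) == 0)
    return(list(verdict = "other", n_markers = 0L, de_score = 0,
                markers = NULL, cap = cap))
  deg <- de_test(normalized[in_cl, , drop = FALSE],
                 normalized[!in_cl, , drop = FALSE],
                 min_pct = min_pct, logfc_min = logfc_min,
                 upregulated_only = TRUE)
  hc <- deg[deg$p_adj < p_adj_max & deg$q_diff >= q_diff_min, , drop = FALSE]
  score <- sum(pmin(-log10(hc$p_adj), cap))
  verdict <- if (nrow(hc) >= min_markers && score >= de_score_min)
    "retained" else "other"
  list(verdict = verdict, n_markers = nrow(hc), de_score = score,
       markers = hc, cap = cap)
}

#' Marker overlap score against reference gene sets
#'
#' Score for set s is |markers intersect s| / |markers|; the best match is
#' the argmax (all ties reported).
#'
#' @param markers Character vector of (pre-filtered) cluster markers.
#' @param reference_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @return List: `best_match` (possibly several), `score`, `per_set`.
#' @export
overlap_score <- function(markers, reference_sets) {
  if (length(markers) == 0)
    return(list(best_match = character(0), score = NA_real_,
                per_set = setNames(rep(NA_real_, length(reference_sets)),
                                   names(reference_sets))))
  per <- vapply(reference_sets,
                function(s) length(intersect(markers, s)) / length(markers),
                numeric(1))
  best <- names(per)[per == max(per)]
  list(best_match = best, score = unname(max(per)), per_set = per)
}

#' Four-level hierarchical cell-type labels
#'
#' Level 1: neuronal if the cluster carries any neurotransmitter identity,
#' otherwise non-neuronal. Level 2: primary identity. Level 3: identity
#' crossed with the dominant meso-structure (largest depth-3 region share).
#' Level 4: the cluster id. "Other" clusters propagate "Other" labels.
#'
#' @param records data.frame from [assign_cluster_identity()].
#' @param region_profiles Named list (per cluster) of depth-3 region count
#'   tables, or a data.frame with `cluster` and `region_d3` per cell.
#' @return data.frame: cluster plus `level1`..`level4`.
#' @export
build_hierarchy <- function(records, region_profiles) {
  if (is.data.frame(region_profiles)) {
    region_profiles <- lapply(split(region_profiles$region_d3,
                                    region_profiles$cluster), table)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$primary_identity == "Other") {
      return(data.frame(cluster = r$cluster, level1 = "non-neuronal",
                        level2 = "Other", level3 = "Other",
                        level4 = r$cluster, stringsAsFactors = FALSE))
    }
    prof <- region_profiles[[as.character(r$cluster)]]
    dom <- if (is.null(prof) || length(prof) == 0) "NA" else
      names(prof)[which.max(prof)]
    data.frame(
      cluster = r$cluster,
      level1 = if (r$kind == "neurotransmitter") "neuronal" else "non-neuronal",
      level2 = r$primary_identity,
      level3 = paste0(r$primary_identity, "-", dom),
      level4 = r$cluster, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an identity rule table from JSON
#'
#' The package ships its default neurotransmitter/glial rules as an
#' editable JSON file (`system.file("extdata", "identity_rules.json",
#' package = "stcelldyn")`); users can copy, edit, and reload it.
#'
#' @param path JSON file: an object per identity with `kind` and `groups`
#'   (array of gene arrays).
#' @return Validated rule table (same shape as [default_rule_table()]).
#' @export
read_rule_table <- function(path) {
  raw <- jsonlite::read_json(path)
  rules <- lapply(raw, function(r) {
    list(kind = r$kind,
         groups = lapply(r$groups, function(g) unlist(g)))
  })
  validate_rules(rules)
  rules
}

#' Write an identity rule table to JSON
#'
#' @param rules Rule table (see [default_rule_table()]).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_rule_table <- function(rules, path) {
  validate_rules(rules)
  jsonlite::write_json(
    lapply(rules, function(r) list(kind = jsonlite::unbox(r$kind),
                                   groups = lapply(r$groups, identity))),
    path, pretty = TRUE)
  invisible(path)
}
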