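#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-cell weighted gene set enrichment scores
#'
#' For each cell c and term T the score is a weighted mean difference:
#' sum over DEG genes in T of w_g z_cg / sum w_g, minus the mean of z_cg
#' over all DEG genes, where w_g = |log2FC| and z is the gene-standardized
#' normalized expression. Cells are then called enriched or depleted per
#' term by percentile cutoffs on the term's score distribution.
#'
#' @param normalized Normalized cells x genes matrix.
#' @param deg DEG table (`gene`, `log2fc`) defining the ranked, weighted
#'   gene universe.
#' @param sets Named list of gene sets.
#' @param upper_pct,lower_pct Percentile cutoffs for the enriched /
#'   depleted verdicts (defaults 90 / 10).
#' @return List: `scores` (cells x terms), `verdicts` (character matrix
#'   "enriched"/"depleted"/"neutral"), `cutoffs` used per term.
#' @export
percell_enrichment <- function(normalized, deg, sets, upper_pct = 90,
                               lower_pct = 10) {
  if (nrow(deg) == 0) stop("empty DEG table")
  genes <- intersect(deg$gene, colnames(normalized))
  deg <- deg[match(genes, deg$gene), , drop = FALSE]
  Z <- as.matrix(normalized[, genes, drop = FALSE])
  mu <- colMeans(Z)
  s <- apply(Z, 2, function(v) sqrt(mean((v - mean(v))^2)))
  s[s == 0] <- 1
  Z <- sweep(sweep(Z, 2, mu), 2, s, "/")
  base <- rowMeans(Z)
  w <- abs(deg$log2fc)
  keep <- vapply(sets, function(S) length(intersect(S, genes)) > 0, logical(1))
  if (any(!keep))
    warning("term(s) with no DEG overlap skipped: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  scores <- vapply(sets, function(S) {
    idx <- which(genes %in% S)
    wS <- w[idx]
    if (sum(wS) == 0) wS <- rep(1, length(idx))
    as.vector(Z[, idx, drop = FALSE] %*% wS) / sum(wS) - base
  }, numeric(nrow(Z)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = nrow(Z),
                     dimnames = list(rownames(Z), names(sets)))
  rownames(scores) <- rownames(normalized)
  cutoffs <- apply(scores, 2, quantile,
                   probs = c(lower_pct, upper_pct) / 100, type = 7)
  verdicts <- matrix("neutral", nrow(scores), ncol(scores),
                     dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    verdicts[scores[, j] > cutoffs[2, j], j] <- "enriched"
    verdicts[scores[, j] < cutoffs[1, j], j] <- "depleted"
  }
  list(scores = scores, verdicts = verdicts, cutoffs = cutoffs)
}

#' Hypergeometric over-representation of one gene set
#'
#' One-sided upper-tail test of `hits` successes among `n_deg` draws from a
#' universe with `n_set` marked genes.
#'
#' @param hits DEGs inside the set.
#' @param n_deg Total DEGs.
#' @param n_set Set size within the universe.
#' @param n_universe Universe size.
#' @return p-value P(X >= hits).
#' @export
hypergeom_test <- function(hits, n_deg, n_set, n_universe) {
  phyper(hits - 1, n_set, n_universe - n_set, n_deg, lower.tail = FALSE)
}

#' Region-level over-representation with genotype bias
#'
#' Per region and genotype, each term is tested by the one-sided
#' hypergeometric against the stated background, BH-adjusted across terms.
#' The composite metric is -log10(q) times the mean log2FC of the hit
#' genes (signed, so direction is preserved); the genotype bias is
#' composite_AA - composite_GG.
#'
#' @param deg_by_region_aa,deg_by_region_gg Named lists (per region) of
#'   DEG tables for the two genotypes.
#' @param sets Named list of gene sets.
#' @param background Character vector of all tested genes (per-region lists
#'   also accepted as a named list).
#' @param top_k Terms reported per region/genotype after ranking by
#'   |composite| (default 20).
#' @return data.frame: `region`, `term`, `composite_AA`, `composite_GG`,
#'   `bias`, plus per-genotype p/q values.
#' @export
region_enrichment <- function(deg_by_region_aa, deg_by_region_gg, sets,
                              background, top_k = 20) {
  if (length(background) == 0) stop("empty background")
  regions <- union(names(deg_by_region_aa), names(deg_by_region_gg))
  one_side <- function(deg, bg) {
    if (is.null(deg) || nrow(deg) == 0)
      return(data.frame(term = names(sets), p = NA_real_, q = NA_real_,
                        composite = 0, stringsAsFactors = FALSE))
    degs <- intersect(deg$gene, bg)
    res <- lapply(names(sets), function(nm) {
      S <- intersect(sets[[nm]], bg)
      hit_genes <- intersect(degs, S)
      p <- hypergeom_test(length(hit_genes), length(degs), length(S),
                          length(bg))
      mean_lfc <- if (length(hit_genes))
        mean(deg$log2fc[match(hit_genes, deg$gene)]) else 0
      data.frame(term = nm, p = p, hits = length(hit_genes),
                 mean_lfc = mean_lfc, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q <- p.adjust(res$p, "BH")
    res$composite <- ifelse(res$hits > 0, -log10(res$q) * res$mean_lfc, 0)
    res
  }
  rows <- lapply(regions, function(r) {
    bg <- if (is.list(background)) background[[r]] else background
    aa <- one_side(deg_by_region_aa[[r]], bg)
    gg <- one_side(deg_by_region_gg[[r]], bg)
    m <- data.frame(region = r, term = aa$term,
                    p_AA = aa$p, q_AA = aa$q, composite_AA = aa$composite,
                    p_GG = gg$p, q_GG = gg$q, composite_GG = gg$composite,
                    stringsAsFactors = FALSE)
    m$bias <- m$composite_AA - m$composite_GG
    m <- m[m$composite_AA != 0 | m$composite_GG != 0, , drop = FALSE]
    m[order(-pmax(abs(m$composite_AA), abs(m$composite_GG))), , drop = FALSE][
      seq_len(min(top_k, nrow(m))), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll enriched terms up to slim parent categories
#'
#' Ranks terms by how many region-module-group combinations they appear in
#' (primary key) and then by their minimum FDR (secondary key), keeps the
#' top `top_n`, and attaches every parent category from the flat child-to-
#' parent map (terms without a mapping get "unassigned").
#'
#' @param term_table data.frame with `term`, `fdr` and a combination
#'   identifier column `combo`.
#' @param parent_map data.frame with `child`, `parent` (multiple parents
#'   per child allowed).
#' @param top_n Terms kept (default 60).
#' @return data.frame: `term`, `frequency`, `min_fdr`, `parents`
#'   (';'-joined), ordered by rank.
#' @export
slim_rollup <- function(term_table, parent_map, top_n = 60) {
  stopifnot(all(c("term", "fdr", "combo") %in% names(term_table)))
  freq <- tapply(term_table$combo, term_table$term,
                 function(v) length(unique(v)))
  minf <- tapply(term_table$fdr, term_table$term, min)
  terms <- names(freq)
  ord <- order(-freq, minf, terms)
  keep <- terms[ord][seq_len(min(top_n, length(terms)))]
  parents <- vapply(keep, function(t) {
    p <- parent_map$parent[parent_map$child == t]
    if (length(p) == 0) "unassigned" else paste(sort(unique(p)), collapse = ";")
  }, character(1))
  data.frame(term = keep, frequency = as.integer(freq[keep]),
             min_fdr = as.numeric(minf[keep]), parents = parents,
             row.names = NULL, stringsAsFactors = FALSE)
}
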