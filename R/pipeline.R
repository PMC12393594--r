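#' Pipeline configuration
#'
#' Collects stage parameters, paths, the root seed and stage enable flags
#' into a single serializable list. Every run writes the resolved
#' configuration next to its outputs.
#'
#' @param out_dir Output directory.
#' @param seed Root seed; each stochastic stage derives its own seed from
#'   it and the stage name.
#' @param sim Simulation config (a [sim_config()]) or NULL to read a
#'   fixture from `in_dir`.
#' @param in_dir Fixture directory (used when `sim` is NULL).
#' @param stages Character vector of stages to run, in order.
#' @param reference_group Baseline group for clustering (default
#'   "AA_SAL").
#' @param cell_scale FOV cell-minimum scale factor.
#' @param k Neighbors for the reference graph.
#' @param n_components Principal components fitted before the bias filter.
#' @param n_trees Random-forest trees.
#' @param min_cells_region Region-row floor for region-mean matrices.
#' @param power,min_size,deep_split,merge_cut Module-detection parameters.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            in_dir = NULL,
                            stages = c("simulate", "qc", "cluster",
                                       "annotate", "deg", "dispro",
                                       "composition", "network", "modules",
                                       "diffnet"),
                            reference_group = "AA_SAL", cell_scale = 0.1,
                            k = 50, n_components = 30, n_trees = 200,
                            min_cells_region = 20,
                            power = 8, min_size = 20, deep_split = 3,
                            merge_cut = 0.10) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing stage outputs and a run
#' manifest (stage order, seeds, wall times, output files) to the output
#' directory. Stages communicate via the returned state list, so partial
#' runs are possible by restricting `stages`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the state list (per-stage results plus `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  manifest <- list(seed = config$seed, stages = list())
  t_stage <- function(expr) {
    t0 <- Sys.time()
    v <- expr
    list(value = v, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  for (stage in config$stages) {
    res <- switch(
      stage,
      simulate = t_stage({
        ds <- if (is.null(config$sim)) read_fixture(config$in_dir)
              else generate_dataset(config$sim)
        state$dataset <- ds
        write_fixture(ds, file.path(config$out_dir, "fixture"))
        length(ds$cells$cell)
      }),
      qc = t_stage({
        qc <- run_qc(state$dataset, cell_scale = config$cell_scale)
        state$qc <- qc
        jsonlite::write_json(qc$report,
                             file.path(config$out_dir, "qc_report.json"),
                             auto_unbox = TRUE)
        qc$report$pass_rate
      }),
      cluster = t_stage({
        qc <- state$qc
        is_ref <- qc$cells$sample == config$reference_group
        tot <- Matrix::rowSums(qc$counts)
        pca <- corrected_pca(qc$normalized[is_ref, , drop = FALSE],
                             tot[is_ref],
                             n_components = config$n_components)
        ref <- louvain_reference(pca$embedding, k = config$k,
                                 seed = derive_seed(config$seed, "louvain"))
        Eq <- project_cells(pca, qc$normalized[!is_ref, , drop = FALSE])
        pred <- propagate_labels(pca$embedding, ref$cluster, Eq,
                                 n_trees = config$n_trees,
                                 seed = derive_seed(config$seed, "rf"))
        asg <- cluster_assignment(ref$cluster, pred)
        asg <- asg[match(qc$cells$cell, asg$cell), ]
        state$assignment <- asg
        write.table(asg, file.path(config$out_dir, "assignment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        length(unique(asg$cluster))
      }),
      annotate = t_stage({
        qc <- state$qc
        flags <- classify_cells(qc$counts)
        rec <- assign_cluster_identity(flags, state$assignment$cluster)
        hier <- build_hierarchy(
          rec, data.frame(cluster = state$assignment$cluster,
                          region_d3 = qc$cells$region_d3))
        state$annotation <- merge(rec, hier, by = "cluster")
        write.table(state$annotation,
                    file.path(config$out_dir, "annotation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sum(rec$primary_identity != "Other")
      }),
      deg = t_stage({
        qc <- state$qc
        idmap <- setNames(state$annotation$primary_identity,
                          state$annotation$cluster)
        types <- idmap[as.character(state$assignment$cluster)]
        state$types <- types
        ## treatment DE within each cell type (clusters with >= 50 cells
        ## per arm), then a genotype-level union for downstream scoring
        by_type <- list(); union_tab <- list()
        for (gt in c("AA", "GG")) {
          by_type[[gt]] <- list()
          for (ty in sort(unique(types))) {
            mor <- qc$cells$genotype == gt & qc$cells$treatment == "MOR" &
              types == ty
            sal <- qc$cells$genotype == gt & qc$cells$treatment == "SAL" &
              types == ty
            if (sum(mor) < 50 || sum(sal) < 50) next
            by_type[[gt]][[ty]] <- de_test(
              qc$normalized[mor, , drop = FALSE],
              qc$normalized[sal, , drop = FALSE], logfc_min = 0.1)
          }
          hits <- do.call(rbind, lapply(names(by_type[[gt]]), function(ty) {
            tab <- by_type[[gt]][[ty]]
            tab <- tab[tab$p_adj < 0.01, , drop = FALSE]
            if (nrow(tab)) tab$cell_type <- ty
            tab
          }))
          if (!is.null(hits) && nrow(hits)) {
            ## keep, per gene, the row from its most significant comparison
            hits <- hits[order(hits$p_value), , drop = FALSE]
            union_tab[[gt]] <- hits[!duplicated(hits$gene), , drop = FALSE]
          } else union_tab[[gt]] <- NULL
        }
        state$deg_by_type <- by_type
        state$deg <- union_tab
        for (gt in names(union_tab))
          write.table(union_tab[[gt]],
                      file.path(config$out_dir, paste0("deg_", gt, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        vapply(union_tab, nrow, 1L)
      }),
      dispro = t_stage({
        qc <- state$qc
        dsp <- lapply(names(state$deg), function(gt) {
          ## noise suppression: only confident, large-effect DEGs enter
          deg <- state$deg[[gt]]
          if (is.null(deg)) return(NULL)
          deg <- deg[deg$p_adj < 0.01 & abs(deg$log2fc) > 1, , drop = FALSE]
          if (nrow(deg) == 0) return(NULL)
          in_gt <- qc$cells$genotype == gt
          d <- disproportionality(qc$normalized[in_gt, , drop = FALSE],
                                  state$types[in_gt], deg)
          d$genotype <- gt
          d
        })
        state$dispro <- do.call(rbind, dsp)
        write.table(state$dispro,
                    file.path(config$out_dir, "disproportionality.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sum(state$dispro$flagged)
      }),
      composition = t_stage({
        cd <- composition_dynamics(state$qc$cells, state$types, min_n = 5)
        state$composition <- cd
        write.table(cd$table,
                    file.path(config$out_dir, "composition.csv"),
                    sep = ",", quote = FALSE, row.names = FALSE)
        nrow(cd$table)
      }),
      network = t_stage({
        qc <- state$qc
        rmm <- region_mean_matrix(qc$normalized, qc$cells,
                                  by_group = FALSE,
                                  min_cells = config$min_cells_region,
                                  seed = derive_seed(config$seed, "rmm"))
        rownames(rmm$M) <- rmm$region
        net <- interregion_network(rmm$M)
        state$network <- net
        write.table(net$edges, file.path(config$out_dir, "network_edges.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        nrow(net$edges)
      }),
      modules = t_stage({
        qc <- state$qc
        rmm <- region_mean_matrix(qc$normalized, qc$cells,
                                  by_group = TRUE,
                                  min_cells = config$min_cells_region,
                                  seed = derive_seed(config$seed, "rmmg"))
        state$rmm <- rmm
        ms <- detect_modules(rmm$M, power = config$power,
                             min_size = config$min_size,
                             deep_split = config$deep_split,
                             merge_cut = config$merge_cut)
        state$modules <- ms
        write.table(data.frame(gene = names(ms$labels), module = ms$labels),
                    file.path(config$out_dir, "modules.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        length(setdiff(unique(ms$labels), "grey"))
      }),
      diffnet = t_stage({
        rmm <- state$rmm
        ms <- state$modules
        mods <- setdiff(unique(ms$labels), "grey")
        if (length(mods) == 0) 0L else {
          out <- list()
          for (m in mods) {
            genes <- names(ms$labels)[ms$labels == m]
            sal <- grepl("SAL", rmm$group)
            M_s <- rmm$M[sal, , drop = FALSE]
            M_m <- rmm$M[!sal, , drop = FALSE]
            rownames(M_s) <- rmm$region[sal]
            rownames(M_m) <- rmm$region[!sal]
            M_s <- M_s[!duplicated(rownames(M_s)), , drop = FALSE]
            M_m <- M_m[!duplicated(rownames(M_m)), , drop = FALSE]
            dn <- tryCatch(differential_network(genes, M_s, M_m),
                           error = function(e) NULL)
            if (!is.null(dn)) {
              dn$module <- m
              out[[m]] <- dn
            }
          }
          state$diffnet <- out
          if (length(out))
            write.table(do.call(rbind, out),
                        file.path(config$out_dir, "diffnet_edges.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
          length(out)
        }
      }),
      stop("unknown stage: ", stage)
    )
    manifest$stages[[stage]] <- list(seconds = round(res$secs, 2),
                                     summary = res$value)
  }
  cfg_out <- config
  cfg_out$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  cfg_out$sim$region_tree <- NULL
  jsonlite::write_json(list(config = cfg_out[setdiff(names(cfg_out), "stages")],
                            stages = names(manifest$stages),
                            manifest = manifest$stages),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  state$manifest <- manifest
  invisible(state)
}
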