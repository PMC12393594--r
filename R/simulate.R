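#' Default region hierarchy for simulated brain sections
#'
#' Three nested anatomical depths emulating an atlas ontology: five
#' meso-structures (depth 3), two subregions each (depth 5), and two fine
#' structures per subregion (depth 7), giving 20 depth-7 leaves.
#'
#' @return data.frame with columns `region_d3`, `region_d5`, `region_d7`,
#'   one row per depth-7 leaf.
#' @export
default_region_tree <- function() {
  d3 <- c("CTX", "CNU", "IB", "MB", "HB")
  d5 <- list(
    CTX = c("Isocortex", "OLF"),
    CNU = c("STR", "PAL"),
    IB  = c("TH", "HY"),
    MB  = c("VTA", "PAG"),
    HB  = c("P", "MY")
  )
  rows <- do.call(rbind, lapply(d3, function(m) {
    do.call(rbind, lapply(d5[[m]], function(s) {
      data.frame(
        region_d3 = m, region_d5 = s,
        region_d7 = paste0(s, ".", 1:2),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(rows) <- NULL
  rows
}

## identity rule genes planted per default cell type; required genes are
## pairwise disjoint across types so ground truth is unambiguous
default_type_table <- function(n_cell_types) {
  types <- list(
    list(name = "Glutamatergic",    kind = "neurotransmitter", genes = c("Slc17a7", "Slc17a6")),
    list(name = "GABAergic",        kind = "neurotransmitter", genes = c("Slc32a1", "Gad1", "Gad2")),
    list(name = "Dopaminergic",     kind = "neurotransmitter", genes = c("Slc6a3", "Th", "Ddc")),
    list(name = "Cholinergic",      kind = "neurotransmitter", genes = c("Slc18a3", "Chat")),
    list(name = "Glycinergic",      kind = "neurotransmitter", genes = c("Slc6a5")),
    list(name = "Astrocytes",       kind = "glial",            genes = c("Gfap", "Slc1a3")),
    list(name = "Oligodendrocytes", kind = "glial",            genes = c("Plp1", "Olig1")),
    list(name = "Microglia",        kind = "glial",            genes = c("Cx3cr1", "C1qc"))
  )
  if (n_cell_types > length(types)) {
    extra <- lapply(seq_len(n_cell_types - length(types)), function(i) {
      list(name = sprintf("Type%02d", i + length(types)), kind = "neurotransmitter",
           genes = sprintf("Nt%02da", i))
    })
    types <- c(types, extra)
  }
  types[seq_len(n_cell_types)]
}

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic imaging-based
#' spatial transcriptomics generator. Defaults define the standard test
#' fixture: 8 planted cell types at 200 cells per type in each of the four
#' genotype-by-treatment groups (AA/GG x SAL/MOR), a 300-gene panel with 20
#' negative-control probes, marker elevation of 2 on the log2 scale,
#' negative-binomial counts with dispersion 0.3 around a median library size
#' of 500, four planted 30-gene co-expression modules with region-structured
#' loadings, one treatment-responsive DEG program concentrated in
#' dopaminergic cells of the AA genotype, and one planted inter-regional
#' correlation flip in module 1.
#'
#' @param n_cells_per_group Cells per experimental group.
#' @param n_genes Real (non-control) genes on the panel.
#' @param n_negative_probes Negative-control probes.
#' @param n_cell_types Planted cell types (max 8 named defaults).
#' @param markers_per_type Total marker genes per type (identity rule genes
#'   plus filler markers).
#' @param marker_log2fc log2 elevation of filler marker genes in their type.
#' @param marker_base_weight Baseline relative weight of filler marker genes
#'   outside their type (default 0.3; smaller values give sharper on/off
#'   marker programs).
#' @param identity_log2fc log2 on/off contrast of identity rule genes in
#'   their own type (the threshold classifier keys on detection, so rule
#'   genes carry a stronger contrast than filler markers; set to 0 together
#'   with `marker_log2fc` for a no-signal dataset).
#' @param libsize_mean Median per-cell library size (counts).
#' @param libsize_sd Log-scale sd of the per-cell library size.
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param neg_rate_frac Negative-probe Poisson rate as a fraction of the
#'   mean real-probe per-gene rate.
#' @param region_tree data.frame of depth-3/5/7 region labels.
#' @param n_fovs Fields of view; each maps to one depth-7 region.
#' @param planted_deg List of DEG programs, each a list with `cell_type`,
#'   `n_genes` or `genes`, `log2fc` (treatment effect, MOR only),
#'   `type_log2fc` (baseline elevation in the target type), `genotype`,
#'   and optional `region_d5` restricting the effect to one subregion.
#' @param planted_modules List of module programs, each with `n_genes`,
#'   `region_d3` (meso-structure where the module is active) and `amp`
#'   (log2 amplitude of the region loading).
#' @param rewired_pairs List of planted rewiring events, each with
#'   `region_a`, `region_b` (depth-7 labels), `module` (index) and `sign`
#'   (-1 flips the pair's module correlation under MOR).
#' @param rewire_amp log2 amplitude of the rewiring loading.
#' @param seed RNG seed for the whole dataset.
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(n_cells_per_group = 1600,
                       n_genes = 300,
                       n_negative_probes = 20,
                       n_cell_types = 8,
                       markers_per_type = 12,
                       marker_log2fc = 2,
                       marker_base_weight = 0.3,
                       identity_log2fc = 5,
                       libsize_mean = 500,
                       libsize_sd = 0.25,
                       nb_dispersion = 0.3,
                       neg_rate_frac = 0.015,
                       region_tree = default_region_tree(),
                       n_fovs = NULL,
                       planted_deg = NULL,
                       planted_modules = NULL,
                       rewired_pairs = NULL,
                       rewire_amp = 1.5,
                       seed = 1L) {
  if (is.null(n_fovs)) n_fovs <- nrow(region_tree)
  if (is.null(planted_modules)) {
    planted_modules <- lapply(1:4, function(j) {
      list(n_genes = 30, region_d3 = default_region_tree()$region_d3[!duplicated(default_region_tree()$region_d3)][j],
           amp = 1)
    })
  }
  if (is.null(planted_deg)) {
    planted_deg <- list(list(
      cell_type = "Dopaminergic", n_genes = 20, log2fc = 2, type_log2fc = 4,
      genotype = "AA", treatment_only = TRUE, region_d5 = NULL
    ))
  }
  if (is.null(rewired_pairs)) {
    rewired_pairs <- list(list(region_a = "VTA.1", region_b = "P.1",
                               module = 1L, sign = -1))
  }
  cfg <- list(
    n_cells_per_group = as.integer(n_cells_per_group),
    n_genes = as.integer(n_genes),
    n_negative_probes = as.integer(n_negative_probes),
    n_cell_types = as.integer(n_cell_types),
    markers_per_type = as.integer(markers_per_type),
    marker_log2fc = marker_log2fc,
    marker_base_weight = marker_base_weight,
    identity_log2fc = identity_log2fc,
    libsize_mean = libsize_mean,
    libsize_sd = libsize_sd,
    nb_dispersion = nb_dispersion,
    neg_rate_frac = neg_rate_frac,
    region_tree = region_tree,
    n_fovs = as.integer(n_fovs),
    planted_deg = planted_deg,
    planted_modules = planted_modules,
    rewired_pairs = rewired_pairs,
    rewire_amp = rewire_amp,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (nrow(cfg$region_tree) == 0) stop("region tree is empty")
  counts <- c(cfg$n_cells_per_group, cfg$n_genes, cfg$n_negative_probes,
              cfg$n_cell_types, cfg$markers_per_type, cfg$n_fovs)
  if (any(counts <= 0)) stop("all size parameters must be positive")
  if (!all(c("region_d3", "region_d5", "region_d7") %in% names(cfg$region_tree)))
    stop("region tree needs region_d3/region_d5/region_d7 columns")
  types <- default_type_table(cfg$n_cell_types)
  rule_genes <- unlist(lapply(types, `[[`, "genes"))
  if (anyDuplicated(rule_genes)) stop("marker sets overlap across cell types")
  if (any(vapply(types, function(t) length(t$genes) == 0, logical(1))))
    stop("every cell type needs at least one identity rule gene")
  for (p in cfg$rewired_pairs) {
    if (!all(c(p$region_a, p$region_b) %in% cfg$region_tree$region_d7))
      stop("rewired pair references unknown depth-7 region")
    if (p$module > length(cfg$planted_modules))
      stop("rewired pair references unknown module")
  }
  invisible(cfg)
}

## lay out the gene panel: identity rule genes, filler markers per type,
## module genes, DEG genes, background fill, then negative probes
build_gene_plan <- function(cfg) {
  types <- default_type_table(cfg$n_cell_types)
  rule_genes <- lapply(types, `[[`, "genes")
  names(rule_genes) <- vapply(types, `[[`, "", "name")
  marker_fill <- lapply(seq_along(types), function(i) {
    n_fill <- max(0, cfg$markers_per_type - length(rule_genes[[i]]))
    if (n_fill == 0) return(character(0))
    sprintf("%s.mk%02d", abbreviate(types[[i]]$name, 4), seq_len(n_fill))
  })
  names(marker_fill) <- names(rule_genes)
  module_genes <- lapply(seq_along(cfg$planted_modules), function(j) {
    sprintf("Mod%d.g%02d", j, seq_len(cfg$planted_modules[[j]]$n_genes))
  })
  deg_genes <- lapply(seq_along(cfg$planted_deg), function(j) {
    pd <- cfg$planted_deg[[j]]
    if (!is.null(pd$genes)) pd$genes else sprintf("Deg%d.g%02d", j, seq_len(pd$n_genes))
  })
  named <- c(unlist(rule_genes), unlist(marker_fill), unlist(module_genes),
             unlist(deg_genes))
  if (anyDuplicated(named)) stop("planted gene sets overlap")
  n_bg <- cfg$n_genes - length(named)
  if (n_bg < 0) stop("n_genes too small for the planted gene sets")
  bg <- if (n_bg > 0) sprintf("Bkg.g%03d", seq_len(n_bg)) else character(0)
  neg <- sprintf("NegPrb%03d", seq_len(cfg$n_negative_probes))
  list(
    types = types, rule_genes = rule_genes, marker_fill = marker_fill,
    module_genes = module_genes, deg_genes = deg_genes, background = bg,
    genes = unname(c(named, bg)), negative = neg
  )
}

#' Generate a synthetic spatial transcriptomics dataset
#'
#' Draws per-cell gene counts from a gamma-Poisson (negative binomial) model
#' with log-normal library sizes, planted cell-type marker programs,
#' treatment-responsive DEG programs, region-structured co-expression
#' modules, and planted inter-regional rewiring. Negative-control probes are
#' Poisson at a small fraction of the mean real-probe rate. Cells are
#' assigned to fields of view, each mapping to one depth-7 region, across
#' the four genotype-by-treatment groups.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (sparse cells x genes, including negative
#'   probes), `genes` (data.frame: gene, is_negative_probe), `cells`
#'   (data.frame: cell, x, y, area, fov, sample, genotype, treatment,
#'   region_d3, region_d5, region_d7), and `truth` (ground-truth lists:
#'   cell types, DEG programs, module membership, rewired pairs).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  plan <- build_gene_plan(config)
  genes <- plan$genes
  n_real <- length(genes)
  groups <- c("AA_SAL", "AA_MOR", "GG_SAL", "GG_MOR")
  n_cells <- config$n_cells_per_group * 4L

  ## base gene weights (relative expression); planted categories get fixed
  ## low/moderate bases so detection behaves predictably
  w_base <- setNames(exp(rnorm(n_real, 0, 0.7)), genes)
  for (g in unlist(plan$rule_genes)) w_base[g] <- 0.12
  for (g in unlist(plan$marker_fill)) w_base[g] <- config$marker_base_weight
  for (g in unlist(plan$module_genes)) w_base[g] <- 0.8
  for (g in unlist(plan$deg_genes)) w_base[g] <- 0.1

  type_names <- vapply(plan$types, `[[`, "", "name")
  ## cells: equal type blocks within each group
  type_vec_group <- sort(rep(type_names, length.out = config$n_cells_per_group))
  cell_type <- rep(type_vec_group, 4L)
  group <- rep(groups, each = config$n_cells_per_group)
  genotype <- sub("_.*", "", group)
  treatment <- sub(".*_", "", group)
  cell_id <- sprintf("cell_%05d", seq_len(n_cells))

  ## FOV and region assignment: FOV -> one depth-7 region
  rt <- config$region_tree
  fov_region <- ((seq_len(config$n_fovs) - 1L) %% nrow(rt)) + 1L
  fov <- sample.int(config$n_fovs, n_cells, replace = TRUE)
  reg_idx <- fov_region[fov]
  region_d3 <- rt$region_d3[reg_idx]
  region_d5 <- rt$region_d5[reg_idx]
  region_d7 <- rt$region_d7[reg_idx]
  fov_col <- ((fov - 1L) %% 5L)
  fov_row <- ((fov - 1L) %/% 5L)
  x <- fov_col * 0.5 + runif(n_cells, 0, 0.5)
  y <- fov_row * 0.5 + runif(n_cells, 0, 0.5)
  area <- rlnorm(n_cells, log(120), 0.25)

  ## per-module region x group scores (shared latent driving co-expression)
  n_mod <- length(config$planted_modules)
  mod_amp <- lapply(seq_len(n_mod), function(j)
    runif(config$planted_modules[[j]]$n_genes, 0.6, 1.0))
  mod_scores <- lapply(seq_len(n_mod), function(j) {
    pm <- config$planted_modules[[j]]
    mu <- ifelse(rt$region_d3 == pm$region_d3, pm$amp, 0)
    sc <- matrix(rnorm(nrow(rt) * 4, rep(mu, 4), 0.4), nrow(rt), 4,
                 dimnames = list(rt$region_d7, groups))
    sc
  })
  ## rewiring gene loadings (signed, per module-1-style event)
  rew_load <- lapply(config$rewired_pairs, function(p)
    rnorm(config$planted_modules[[p$module]]$n_genes, 0, 1))

  libsize <- rlnorm(n_cells, log(config$libsize_mean), config$libsize_sd)

  ## build per-cell expected rates in blocks of identical profile to keep
  ## the generator fast: profile depends on (type, group, region)
  key <- paste(cell_type, group, region_d7, sep = "|")
  ukey <- unique(key)
  prof <- matrix(0, length(ukey), n_real, dimnames = list(ukey, genes))
  for (k in seq_along(ukey)) {
    parts <- strsplit(ukey[k], "|", fixed = TRUE)[[1]]
    ty <- parts[1]; gr <- parts[2]; r7 <- parts[3]
    gt <- sub("_.*", "", gr); tr <- sub(".*_", "", gr)
    w <- w_base
    ## identity rule genes on in their own type
    w[plan$rule_genes[[ty]]] <- w[plan$rule_genes[[ty]]] * 2^config$identity_log2fc
    ## filler markers elevated by marker_log2fc
    if (length(plan$marker_fill[[ty]]))
      w[plan$marker_fill[[ty]]] <- w[plan$marker_fill[[ty]]] * 2^config$marker_log2fc
    ## planted DEG programs
    for (j in seq_along(config$planted_deg)) {
      pd <- config$planted_deg[[j]]
      gset <- plan$deg_genes[[j]]
      in_region <- is.null(pd$region_d5) ||
        r7 %in% rt$region_d7[rt$region_d5 == pd$region_d5]
      if (ty == pd$cell_type && in_region) {
        w[gset] <- w[gset] * 2^(pd$type_log2fc %||% 0)
        if (gt == pd$genotype && tr == "MOR")
          w[gset] <- w[gset] * 2^pd$log2fc
      }
    }
    ## module region loadings
    for (j in seq_len(n_mod)) {
      gset <- plan$module_genes[[j]]
      w[gset] <- w[gset] * 2^(mod_amp[[j]] * mod_scores[[j]][r7, gr])
    }
    ## planted rewiring: signed gene loading in the two named regions
    for (pi in seq_along(config$rewired_pairs)) {
      p <- config$rewired_pairs[[pi]]
      gset <- plan$module_genes[[p$module]]
      dir <- 0
      if (r7 == p$region_a) dir <- 1
      if (r7 == p$region_b) dir <- if (tr == "MOR") p$sign else 1
      if (dir != 0)
        w[gset] <- w[gset] * 2^(config$rewire_amp * dir * rew_load[[pi]])
    }
    prof[k, ] <- w / sum(w)
  }

  mu <- prof[match(key, ukey), , drop = FALSE] * libsize
  n_entries <- length(mu)
  if (config$nb_dispersion > 0) {
    counts_real <- matrix(
      rnbinom(n_entries, size = 1 / config$nb_dispersion, mu = as.vector(mu)),
      n_cells, n_real)
  } else {
    counts_real <- matrix(rpois(n_entries, as.vector(mu)), n_cells, n_real)
  }
  neg_rate <- config$neg_rate_frac * config$libsize_mean / n_real
  counts_neg <- matrix(
    rpois(n_cells * config$n_negative_probes, neg_rate),
    n_cells, config$n_negative_probes)
  counts <- cbind(counts_real, counts_neg)
  dimnames(counts) <- list(cell_id, c(genes, plan$negative))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")

  gene_tab <- data.frame(
    gene = c(genes, plan$negative),
    is_negative_probe = c(rep(FALSE, n_real), rep(TRUE, config$n_negative_probes)),
    stringsAsFactors = FALSE
  )
  cell_tab <- data.frame(
    cell = cell_id, x = x, y = y, area = area, fov = fov,
    sample = group, genotype = genotype, treatment = treatment,
    region_d3 = region_d3, region_d5 = region_d5, region_d7 = region_d7,
    stringsAsFactors = FALSE
  )
  truth <- list(
    cell_type_of_cell = setNames(cell_type, cell_id),
    deg_truth = lapply(seq_along(config$planted_deg), function(j) {
      pd <- config$planted_deg[[j]]
      list(cell_type = pd$cell_type, genotype = pd$genotype,
           genes = plan$deg_genes[[j]], log2fc = pd$log2fc,
           region_d5 = pd$region_d5)
    }),
    module_truth = setNames(
      rep(seq_along(plan$module_genes),
          vapply(plan$module_genes, length, 1L)),
      unlist(plan$module_genes)),
    rewired_edges = config$rewired_pairs,
    hub_truth = if (length(config$rewired_pairs))
      lapply(config$rewired_pairs, function(p) plan$module_genes[[p$module]])
    else list(),
    seed = config$seed
  )
  list(counts = counts, genes = gene_tab, cells = cell_tab, truth = truth)
}

#' Write a dataset to a plain-text fixture directory
#'
#' Writes the count matrix as MatrixMarket coordinate format (1-based),
#' gene and cell metadata as TSV, ground truth and a manifest as JSON.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Target directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(dataset$counts, "CsparseMatrix"), mtx)
  write.table(dataset$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$cell_type_of_cell <- as.list(truth$cell_type_of_cell)
  truth$module_truth <- as.list(truth$module_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  manifest <- list(
    files = c("matrix.mtx", "genes.tsv", "cells.tsv", "truth.json"),
    n_cells = nrow(dataset$counts), n_genes = ncol(dataset$counts),
    seed = dataset$truth$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `counts`, `genes`, `cells`, `truth`.
#' @export
read_fixture <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- read.table(file.path(dir, "genes.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  cells <- read.table(file.path(dir, "cells.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  dimnames(counts) <- list(cells$cell, genes$gene)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  truth$cell_type_of_cell <- unlist(truth$cell_type_of_cell)
  truth$module_truth <- unlist(truth$module_truth)
  list(counts = counts, genes = genes, cells = cells, truth = truth)
}
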