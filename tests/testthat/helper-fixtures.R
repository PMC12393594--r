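## compact configurations used across tests; structure mirrors the default
## study fixture but scaled for unit-test runtime

## four types, small panel, one planted module; keeps generation ~1 s
tiny_config <- function(seed = 1L, markers_per_type = 8, ...) {
  sim_config(
    n_cells_per_group = 240, n_genes = 120, n_negative_probes = 10,
    n_cell_types = 4, markers_per_type = markers_per_type,
    planted_modules = list(list(n_genes = 20, region_d3 = "CTX", amp = 1)),
    planted_deg = list(list(cell_type = "Dopaminergic", n_genes = 10,
                            log2fc = 2, type_log2fc = 4, genotype = "AA",
                            treatment_only = TRUE, region_d5 = NULL)),
    seed = seed, ...
  )
}

## a no-signal configuration: flat profiles, Poisson-like noise
null_config <- function(seed = 1L, ...) {
  sim_config(
    n_cells_per_group = 240, n_genes = 120, n_negative_probes = 10,
    n_cell_types = 4, markers_per_type = 8,
    marker_log2fc = 0, identity_log2fc = 0,
    planted_modules = list(list(n_genes = 20, region_d3 = "CTX", amp = 0)),
    planted_deg = list(list(cell_type = "Dopaminergic", n_genes = 10,
                            log2fc = 0, type_log2fc = 0, genotype = "AA",
                            treatment_only = TRUE, region_d5 = NULL)),
    rewired_pairs = list(), rewire_amp = 0,
    seed = seed, ...
  )
}

## deterministic dense toy count matrix with explicit negative probes
toy_counts <- function(n_cells = 10, n_genes = 6, n_neg = 2, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * (n_genes + n_neg), lambda = 4),
              n_cells, n_genes + n_neg)
  m[, n_genes + seq_len(n_neg)] <- rpois(n_cells * n_neg, 0.2)
  dimnames(m) <- list(sprintf("c%02d", seq_len(n_cells)),
                      c(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("neg%02d", seq_len(n_neg))))
  list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
       genes = data.frame(gene = colnames(m),
                          is_negative_probe = c(rep(FALSE, n_genes),
                                                rep(TRUE, n_neg))))
}

## synthetic region x gene matrix with planted block-modular structure
block_region_matrix <- function(n_samples = 40, genes_per_module = 30,
                                n_modules = 4, noise = 0.5, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n_samples * n_modules), n_samples, n_modules)
  M <- do.call(cbind, lapply(seq_len(n_modules), function(j) {
    load <- runif(genes_per_module, 0.7, 1.3)
    scores[, j] %o% load + matrix(rnorm(n_samples * genes_per_module, 0, noise),
                                  n_samples)
  }))
  colnames(M) <- unlist(lapply(seq_len(n_modules), function(j)
    sprintf("m%d.g%02d", j, seq_len(genes_per_module))))
  rownames(M) <- sprintf("s%02d", seq_len(n_samples))
  truth <- rep(seq_len(n_modules), each = genes_per_module)
  list(M = M, truth = setNames(truth, colnames(M)))
}
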