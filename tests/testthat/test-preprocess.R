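## independent Grubbs oracle: critical value from the t-distribution
grubbs_crit <- function(n, alpha) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

test_that("Grubbs screen matches a hand-computed critical value", {
  x <- c(10, 11, 9, 10, 100)
  g <- abs(x - mean(x)) / sd(x)
  expect_gt(max(g), grubbs_crit(5, 0.01))     # 100 is significant by hand
  expect_equal(grubbs_outliers(x, 0.01), 5L)
  ## after removal the rest is clean
  expect_identical(grubbs_outliers(c(10, 11, 9, 10), 0.01), integer(0))
  ## degenerate inputs
  expect_identical(grubbs_outliers(rep(7, 6)), integer(0))
  expect_warning(out <- grubbs_outliers(c(1, 2)), "n < 3")
  expect_identical(out, integer(0))
})

test_that("Grubbs screen is iterative", {
  x <- c(rep(10, 20), 60, 200)
  out <- grubbs_outliers(x, 0.01)
  expect_true(all(c(21L, 22L) %in% out))
})

test_that("probe filter reproduces a brute-force application of its rules", {
  set.seed(1)
  n_cells <- 60
  m <- cbind(
    strong = rpois(n_cells, 5), weak = rpois(n_cells, 0.05),
    mid = rpois(n_cells, 0.6),
    neg1 = rpois(n_cells, 0.3), neg2 = rpois(n_cells, 0.35),
    neg3 = rpois(n_cells, 0.28), neg_out = rpois(n_cells, 12))
  rownames(m) <- sprintf("c%02d", 1:n_cells)
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  genes <- data.frame(gene = colnames(m),
                      is_negative_probe = startsWith(colnames(m), "neg"))
  res <- filter_probes(counts, genes)

  ## brute force: (a) Grubbs on negative totals, (b) median cut,
  ## (c) Poisson exceedance
  neg_tot <- colSums(m[, 4:7])
  drop_neg <- grubbs_outliers(neg_tot, 0.01)
  kept_neg <- neg_tot[setdiff(1:4, drop_neg)]
  cut <- quantile(kept_neg, 0.5, type = 7)
  lam <- mean(kept_neg)
  keep <- character(0)
  for (g in c("strong", "weak", "mid")) {
    tot <- sum(m[, g])
    if (tot < cut) next
    if (ppois(tot - 1, lam, lower.tail = FALSE) > 0.01) next
    keep <- c(keep, g)
  }
  expect_setequal(res$retained, keep)
  expect_true("neg_out" %in% res$flagged_negatives)
  expect_error(filter_probes(counts, data.frame(gene = genes$gene,
                                                is_negative_probe = FALSE)),
               "background")
})

test_that("cell filter enforces each stated boundary", {
  ## 4 transcripts -> removed; ratio exactly 1 -> removed; neg frac > 10%
  ## -> removed; clean cell retained
  m <- rbind(
    low = c(2, 2, 0, 0),          # 4 real transcripts
    ratio1 = c(1, 1, 1, 0),       # 3 counts over 3 genes, ratio = 1
    neg = c(20, 20, 0, 5),        # 5/45 > 10% negative
    ok = c(10, 5, 3, 0)
  )
  colnames(m) <- c("g1", "g2", "g3", "neg1")
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  genes <- data.frame(gene = colnames(m),
                      is_negative_probe = c(FALSE, FALSE, FALSE, TRUE))
  keep <- filter_cells(counts, genes, areas = rep(100, 4))
  expect_identical(keep, "ok")
})

test_that("cell filter equals an independent row-wise re-check on a 200-cell toy", {
  d <- generate_dataset(tiny_config(seed = 4))
  sub <- 1:200
  counts <- d$counts[sub, ]
  areas <- d$cells$area[sub]
  keep <- filter_cells(counts, d$genes, areas)
  ## brute force re-check, cell by cell
  neg <- d$genes$is_negative_probe
  area_out <- grubbs_outliers(areas, 0.01)
  oracle <- c()
  for (i in sub) {
    v <- as.numeric(counts[i, ])
    tot_real <- sum(v[!neg]); tot_neg <- sum(v[neg])
    det <- sum(v[!neg] > 0)
    ok <- tot_real >= 5 &&
      (tot_neg / (tot_real + tot_neg)) <= 0.10 &&
      det > 0 && tot_real / det > 1 &&
      !(i %in% area_out)
    if (ok) oracle <- c(oracle, rownames(counts)[i])
  }
  expect_setequal(keep, oracle)
})

test_that("FOV filter applies run- and pipeline-level thresholds", {
  ## six FOVs engineered around each boundary (cell_scale 0.01 -> floor 5)
  mk <- function(n, lam_real, lam_neg) {
    cbind(matrix(rpois(n * 3, lam_real / 3), n, 3), rpois(n, lam_neg))
  }
  set.seed(2)
  blocks <- list(
    good = mk(10, 150, 0.2),
    low_counts = mk(10, 50, 0.2),      # mean counts < 100
    high_neg = mk(10, 150, 3),         # mean neg > 1.0
    few_cells = mk(3, 150, 0.2),       # < 5 cells at scale 0.01
    very_low = mk(10, 6, 0.0)          # also fails the 10/cell stage
  )
  m <- do.call(rbind, blocks)
  colnames(m) <- c("g1", "g2", "g3", "neg1")
  rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  fov <- rep(seq_along(blocks), times = vapply(blocks, nrow, 1L))
  genes <- data.frame(gene = colnames(m),
                      is_negative_probe = c(FALSE, FALSE, FALSE, TRUE))
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  res <- filter_fovs(counts, genes, fov, cell_scale = 0.01)
  expect_identical(res$retained, 1L)
  ## hand-evaluate both stages from the reported stats
  st <- res$stats
  expect_equal(st$retained,
               st$mean_counts >= 100 & st$mean_neg <= 1 & st$n_cells >= 5 &
                 st$mean_counts >= 10)
  expect_error(filter_fovs(counts, genes, rep(NA_integer_, nrow(m))), "FOV")
})

test_that("log-normalization matches the closed form", {
  m <- rbind(a = c(1, 9999, 0), b = c(5, 5, 10))
  colnames(m) <- c("g1", "g2", "g3")
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  norm <- lognormalize(counts)
  expect_equal(norm["a", "g1"], log(2))    # count 1 in a 10,000-total cell
  expect_equal(norm["a", "g3"], 0)
  ## elementwise formula on a random matrix
  set.seed(3)
  r <- matrix(rpois(600, 3), 20, 30,
              dimnames = list(sprintf("c%d", 1:20), sprintf("g%d", 1:30)))
  r[1, ] <- r[1, ] + 1  # guard against zero-total rows
  rc <- methods::as(Matrix::Matrix(r, sparse = TRUE), "CsparseMatrix")
  expect_equal(as.matrix(lognormalize(rc)),
               log1p(1e4 * r / rowSums(r)), ignore_attr = TRUE)
  expect_error(lognormalize(rc * 0), "zero-total")
})

test_that("secondary filter uses the interpolated percentile and pct=0 is identity", {
  d <- generate_dataset(tiny_config(seed = 6))
  counts <- d$counts[1:100, !d$genes$is_negative_probe]
  res <- secondary_filter(counts, pct = 5)
  expect_equal(res$count_threshold,
               unname(quantile(Matrix::rowSums(counts), 0.05, type = 7)))
  expect_equal(res$gene_threshold,
               unname(quantile(Matrix::rowSums(counts > 0), 0.05, type = 7)))
  expect_setequal(secondary_filter(counts, pct = 0)$retained,
                  rownames(counts))
})

test_that("QC pass-rate arithmetic and conservation hold on the pipeline report", {
  d <- generate_dataset(tiny_config(seed = 9))
  qc <- run_qc(d, cell_scale = 0.05)
  rep <- qc$report
  expect_equal(rep$pass_rate,
               round(100 * rep$retained_cells / rep$input_cells, 1))
  expect_true(rep$retained_cells <= rep$input_cells)
  expect_equal(nrow(qc$counts), rep$retained_cells)
  expect_equal(ncol(qc$counts), rep$retained_genes)
})
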