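## build a counts matrix where named genes have the stated per-cell counts
## and each cell totals 10,000 via a filler gene (so CPM == count * 100)
rule_counts <- function(gene_counts) {
  genes <- names(gene_counts[[1]])
  m <- do.call(rbind, lapply(gene_counts, function(v) {
    c(v, filler = 10000 - sum(v))
  }))
  rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("log2CPM and the high-expression threshold behave analytically", {
  cm <- rule_counts(list(c(Th = 0), c(Th = 80)))
  expect_equal(as.numeric(log2cpm(cm)[1, "Th"]), 0)
  ## count 80 of 10,000 -> CPM 8,000 -> log2(8001) > 3
  expect_equal(as.numeric(log2cpm(cm)[2, "Th"]), log2(8001))
  hi <- call_high_expression(cm, "Th", gmm = FALSE)
  expect_identical(unname(hi$high), c(FALSE, TRUE))
  expect_warning(res <- call_high_expression(cm, "missing"), "absent")
  expect_true(all(!res$high))
})

test_that("the GMM diagnostic recovers planted bimodal modes", {
  set.seed(5)
  n <- 400
  ## bimodal log2CPM with modes near 1 and 6 (cells scaled to 1e6 total so
  ## CPM equals the raw count)
  mode_hi <- sample(c(FALSE, TRUE), n, replace = TRUE)
  cpm <- ifelse(mode_hi, 2^rnorm(n, 6, 0.3), 2^rnorm(n, 1, 0.3)) - 1
  cnt <- pmax(round(cpm), 0)
  m <- cbind(Gad1 = cnt, filler = 1e6 - cnt)
  rownames(m) <- sprintf("c%03d", seq_len(n))
  cm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  res <- call_high_expression(cm, "Gad1")
  expect_false(is.null(res$gmm))
  obs <- sort(res$gmm$means)
  planted <- sort(c(mean(log2cpm(cm)[!mode_hi, "Gad1"]),
                    mean(log2cpm(cm)[mode_hi, "Gad1"])))
  expect_lt(abs(obs[1] - planted[1]), 0.5)
  expect_lt(abs(obs[2] - planted[2]), 0.5)
})

test_that("rule classification matches the stated gene logic", {
  cm <- rule_counts(list(
    c(Slc6a5 = 50, Th = 0, Ddc = 0, Slc6a3 = 0, Slc18a2 = 0, Hdc = 0),
    c(Slc6a5 = 0, Th = 0, Ddc = 0, Slc6a3 = 0, Slc18a2 = 40, Hdc = 40),
    c(Slc6a5 = 0, Th = 50, Ddc = 50, Slc6a3 = 0, Slc18a2 = 0, Hdc = 0),
    c(Slc6a5 = 0, Th = 50, Ddc = 50, Slc6a3 = 45, Slc18a2 = 0, Hdc = 0)
  ))
  flags <- classify_cells(cm)
  ## high only for Slc6a5 -> Glycinergic only
  expect_true(flags[1, "Glycinergic"])
  expect_equal(sum(flags[1, ]), 1)
  ## Slc18a2 + Hdc -> Histaminergic
  expect_true(flags[2, "Histaminergic"])
  ## Th + Ddc without a transporter is not Dopaminergic
  expect_false(flags[3, "Dopaminergic"])
  ## adding Slc6a3 completes the rule
  expect_true(flags[4, "Dopaminergic"])
})

test_that("identity calls are monotone in the threshold", {
  d <- generate_dataset(tiny_config(seed = 12))
  sub <- d$counts[1:200, ]
  f3 <- classify_cells(sub, threshold = 3)
  f5 <- classify_cells(sub, threshold = 5)
  expect_true(all(f5 <= f3))
})

test_that("cluster identity respects the strict 30% boundary", {
  n <- 100
  counts <- rule_counts(c(
    replicate(31, c(Slc17a7 = 50), simplify = FALSE),
    replicate(69, c(Slc17a7 = 0), simplify = FALSE)
  ))
  flags <- classify_cells(counts)
  rec31 <- assign_cluster_identity(flags, rep("A", n))
  expect_equal(rec31$primary_identity, "Glutamatergic")
  ## exactly 30/100 fails the strict inequality
  counts30 <- rule_counts(c(
    replicate(30, c(Slc17a7 = 50), simplify = FALSE),
    replicate(70, c(Slc17a7 = 0), simplify = FALSE)
  ))
  rec30 <- assign_cluster_identity(classify_cells(counts30), rep("A", n))
  expect_equal(rec30$primary_identity, "Other")
})

test_that("planted clusters are classified with high passing fractions", {
  d <- generate_dataset(tiny_config(seed = 13))
  tt <- d$truth$cell_type_of_cell[d$cells$cell]
  flags <- classify_cells(d$counts)
  rec <- assign_cluster_identity(flags, tt)
  gaba <- rec[rec$cluster == "GABAergic", ]
  expect_equal(gaba$primary_identity, "GABAergic")
  expect_gte(gaba$passing_fraction, 0.9)
  ## every planted type is recovered as the primary identity
  expect_equal(sum(rec$primary_identity == rec$cluster), nrow(rec))
})

test_that("marker QC arithmetic honors the stated gates", {
  ## 8 markers at P_adj 1e-20 give a DE score of 160 >= 150
  expect_equal(sum(pmin(-log10(rep(1e-20, 8)), 300)), 160)
  ## a planted 12-marker cluster with a strong, cleanly on/off marker
  ## program on the full-size panel
  d <- generate_dataset(sim_config(n_cells_per_group = 400,
                                   n_cell_types = 4, markers_per_type = 12,
                                   marker_log2fc = 5,
                                   marker_base_weight = 0.15, seed = 14))
  tt <- d$truth$cell_type_of_cell[d$cells$cell]
  norm <- lognormalize(d$counts[, !d$genes$is_negative_probe])
  res <- marker_qc("GABAergic", norm, tt)
  expect_equal(res$verdict, "retained")
  expect_gte(res$n_markers, 8)
  expect_gte(res$de_score, 150)
  expect_true(all(res$markers$p_adj < 0.01 & res$markers$q_diff >= 0.7))
  ## small clusters are not judged
  small <- marker_qc("GABAergic", norm[c(which(tt == "GABAergic")[1:10],
                                         which(tt != "GABAergic")), ],
                     c(rep("GABAergic", 10),
                       tt[tt != "GABAergic"]))
  expect_equal(small$verdict, "too_small")
})

test_that("no cluster is retained on the no-signal fixture", {
  retained <- vapply(1:5, function(s) {
    d <- generate_dataset(null_config(seed = 100 + s))
    tt <- d$truth$cell_type_of_cell[d$cells$cell]
    norm <- lognormalize(d$counts[, !d$genes$is_negative_probe])
    any(vapply(unique(tt), function(cl)
      marker_qc(cl, norm, tt)$verdict == "retained", logical(1)))
  }, logical(1))
  expect_false(any(retained))
})

test_that("overlap scores count intersections exactly", {
  sets <- list(A = sprintf("g%d", 1:10), B = sprintf("g%d", 8:20))
  mk <- sprintf("g%d", 1:10)
  res <- overlap_score(mk, sets)
  expect_equal(res$score, 1)
  expect_equal(res$best_match, "A")
  res2 <- overlap_score(sprintf("x%d", 1:5), sets)
  expect_equal(unname(res2$per_set), c(0, 0))
  mk3 <- c("g8", "g9", "g10", "g21", "x1", "x2", "x3", "x4", "x5", "x6")
  res3 <- overlap_score(mk3, sets)
  expect_equal(unname(res3$per_set["B"]), 0.3)
  expect_true(is.na(overlap_score(character(0), sets)$score))
})

test_that("the four-level hierarchy follows identity and dominant region", {
  rec <- data.frame(cluster = c("c1", "c2"),
                    primary_identity = c("GABAergic", "Other"),
                    kind = c("neurotransmitter", "other"),
                    passing_fraction = c(0.8, 0.1),
                    all_identities = c("GABAergic", ""), tie = FALSE,
                    stringsAsFactors = FALSE)
  prof <- data.frame(cluster = c(rep("c1", 10), rep("c2", 4)),
                     region_d3 = c(rep("CNU", 7), rep("CTX", 3),
                                   rep("MB", 4)))
  h <- build_hierarchy(rec, prof)
  expect_equal(h$level1, c("neuronal", "non-neuronal"))
  expect_equal(h$level3[1], "GABAergic-CNU")
  expect_equal(h$level2[2], "Other")
})

test_that("the shipped rule JSON round-trips to the built-in table", {
  path <- system.file("extdata", "identity_rules.json", package = "stcelldyn")
  expect_true(nzchar(path))
  rules <- read_rule_table(path)
  expect_equal(rules, default_rule_table())
  ## edited copies reload through the same path
  tmp <- withr::local_tempfile(fileext = ".json")
  edited <- default_rule_table()
  edited$Glycinergic$groups <- list(c("Slc6a5", "Slc6a9"))
  write_rule_table(edited, tmp)
  expect_equal(read_rule_table(tmp), edited)
})
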