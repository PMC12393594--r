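test_that("region means equal direct arithmetic means and are reproducible", {
  d <- generate_dataset(tiny_config(seed = 40))
  norm <- lognormalize(d$counts[, !d$genes$is_negative_probe])
  r1 <- region_mean_matrix(norm, d$cells, by_group = FALSE, min_cells = 1,
                           seed = 7)
  r2 <- region_mean_matrix(norm, d$cells, by_group = FALSE, min_cells = 1,
                           seed = 7)
  expect_identical(r1$M, r2$M)
  reg <- d$cells$region_d7
  for (r in r1$region[1:3]) {
    expect_equal(r1$M[which(r1$region == r), ],
                 Matrix::colMeans(norm[reg == r, , drop = FALSE]))
  }
  ## subsampling respects the per-group cap
  r3 <- region_mean_matrix(norm, d$cells, sample_n = 100, min_cells = 1,
                           seed = 7)
  expect_lte(sum(r3$n_cells[r3$group == "AA_SAL"]), 100)
})

test_that("inter-regional network edges and centrality follow the definitions", {
  set.seed(41)
  M <- matrix(rnorm(5 * 50), 5, 50,
              dimnames = list(paste0("r", 1:5), sprintf("g%02d", 1:50)))
  M[2, ] <- M[1, ] + rnorm(50, sd = 0.01)   # near-duplicate regions
  net <- interregion_network(M, r_min = 0.95)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$region_a, net$edges$region_b), c("r1", "r2"))
  expect_equal(unname(net$centrality[c("r1", "r2")]), c(0.25, 0.25))
  ## full correlation matrix equals brute-force Pearson
  expect_equal(net$cor, cor(t(M)))
  ## independent 1,000-gene profiles yield no edges at r > 0.95
  for (s in 1:5) {
    set.seed(50 + s)
    Mi <- matrix(rnorm(6 * 1000), 6, 1000,
                 dimnames = list(paste0("r", 1:6), NULL))
    expect_equal(nrow(interregion_network(Mi)$edges), 0)
  }
  ## constant profile is dropped with a warning
  M2 <- M; M2[3, ] <- 1
  expect_warning(net2 <- interregion_network(M2), "constant")
  expect_false("r3" %in% rownames(net2$cor))
})

test_that("bicor agrees with Pearson on clean Gaussian data", {
  set.seed(42)
  X <- matrix(rnorm(200 * 6), 200, 6)
  X[, 2] <- X[, 1] * 0.8 + rnorm(200, sd = 0.5)
  b <- bicor_matrix(X)
  p <- cor(X)
  expect_lt(max(abs(b - p)), 0.05)
  expect_equal(diag(b), rep(1, 6), tolerance = 1e-12)
  ## robust to a planted outlier where Pearson is not
  X2 <- X
  X2[1, 5] <- 100
  expect_lt(abs(bicor_matrix(X2)[5, 6] - b[5, 6]), 0.05)
})

test_that("soft-power selection passes on modular data and falls back on noise", {
  ## modular data with heterogeneous module sizes plus unconnected
  ## background genes: the degree distribution approximates scale-free
  set.seed(2)
  n <- 40
  sizes <- c(50, 20, 10, 5)
  scores <- matrix(rnorm(n * 4), n, 4)
  M <- do.call(cbind, lapply(1:4, function(j) {
    load <- runif(sizes[j], 0.5, 1.5)
    scores[, j] %o% load + matrix(rnorm(n * sizes[j], 0, 0.4), n)
  }))
  M <- cbind(M, matrix(rnorm(n * 60), n, 60))
  res <- pick_soft_power(M, powers = 1:12, r2_min = 0.8)
  expect_lte(res$power, 8)
  expect_gt(res$fit_table$signed_r2[res$fit_table$power == res$power], 0.8)
  expect_true(all(res$fit_table$power == 1:12))
  ## pure noise: no power passes, default returned with warning
  set.seed(44)
  noise <- matrix(rnorm(20 * 40), 20, 40)
  expect_warning(resn <- pick_soft_power(noise, powers = 1:6, r2_min = 0.999),
                 "default")
  expect_equal(resn$power, 8)
})

test_that("TOM equals the closed-form on a 5-gene toy", {
  A <- matrix(c(
    0.0, 0.8, 0.1, 0.0, 0.3,
    0.8, 0.0, 0.2, 0.1, 0.0,
    0.1, 0.2, 0.0, 0.9, 0.4,
    0.0, 0.1, 0.9, 0.0, 0.5,
    0.3, 0.0, 0.4, 0.5, 0.0), 5, 5, byrow = TRUE)
  tom <- tom_similarity(A)
  k <- colSums(A)
  for (i in 1:4) for (j in (i + 1):5) {
    l_ij <- sum(A[i, -c(i, j)] * A[-c(i, j), j])
    expect_equal(tom[i, j], (l_ij + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j]))
  }
  expect_true(isSymmetric(tom))
  expect_equal(diag(tom), rep(1, 5))
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("module detection recovers planted modules and merge_cut=0 keeps all", {
  aris <- vapply(1:5, function(s) {
    bl <- block_region_matrix(n_samples = 40, genes_per_module = 30,
                              n_modules = 4, noise = 0.5, seed = 60 + s)
    ms <- detect_modules(bl$M, power = 8, min_size = 20, deep_split = 3,
                         merge_cut = 0.10)
    adjusted_rand(ms$labels[names(bl$truth)], bl$truth)
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 1)
  ## merge_cut = 0: no merging happens
  bl <- block_region_matrix(seed = 66)
  ms0 <- detect_modules(bl$M, merge_cut = 0)
  expect_equal(length(ms0$merge_history), 0)
  ## eigengenes are unit-norm and positively oriented to module means
  me <- ms0$eigengenes
  expect_equal(unname(apply(me, 2, function(v) sum(v^2))),
               rep(1, ncol(me)))
  for (m in colnames(me)) {
    expect_gt(cor(me[, m], rowMeans(bl$M[, ms0$labels == m, drop = FALSE])), 0)
  }
})

test_that("module-trait correlations match hand Pearson with t-based p", {
  set.seed(45)
  me <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("blue", "brown")))
  traits <- cbind(t1 = me[, 1], t2 = rnorm(6), const = rep(1, 6))
  res <- module_trait(me, traits)
  expect_equal(res$r["blue", "t1"], 1)
  expect_equal(res$p["blue", "t1"], 0)
  r_hand <- cor(me[, 2], traits[, "t2"])
  expect_equal(res$r["brown", "t2"], r_hand)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(res$p["brown", "t2"], 2 * pt(-abs(t_hand), 4))
  expect_true(all(is.na(res$r[, "const"])))
})

test_that("paired region t-tests find planted condition shifts", {
  set.seed(46)
  regions <- paste0("r", 1:10)
  genes <- sprintf("g%02d", 1:30)
  base <- matrix(rnorm(10 * 30, 5), 10, 30, dimnames = list(regions, genes))
  Mb <- base + matrix(rnorm(300, sd = 0.05), 10)
  Ma <- base + matrix(rnorm(300, sd = 0.05), 10)
  Ma[, 1:3] <- Ma[, 1:3] + 0.5          # ~0.72 log2 units
  res <- paired_region_deg(Ma, Mb)
  expect_true(all(c("g01", "g02", "g03") %in% res$gene))
  expect_equal(mean(res$log2fc[res$gene %in% c("g01", "g02", "g03")]),
               0.5 / log(2), tolerance = 0.1)
})

test_that("Fisher module enrichment equals the hypergeometric tail and caps", {
  labels <- setNames(rep(c("blue", "grey"), c(10, 30)), sprintf("g%02d", 1:40))
  eff <- list(E1 = sprintf("g%02d", 1:8), E2 = sprintf("g%02d", 30:35))
  res <- fisher_module_enrichment(labels, eff)
  ## one-sided Fisher == hypergeometric upper tail
  expect_equal(res$p["blue", "E1"],
               fisher.test(matrix(c(8, 2, 0, 30), 2, byrow = TRUE),
                           alternative = "greater")$p.value)
  expect_equal(res$p["blue", "E1"], phyper(7, 8, 32, 10, lower.tail = FALSE))
  ## cap at 10 and normalization to [0, 1]
  expect_true(all(res$capped <= 10))
  expect_true(all(res$normalized >= 0 & res$normalized <= 1))
  expect_equal(max(res$normalized[, "E1"]), 1)
})

test_that("module prioritization ranks by treatment-contrast difference", {
  capped <- matrix(c(10, 0, 5, 5, 2, 8, 1, 1, 0, 0),
                   5, 2, dimnames = list(paste0("m", 1:5),
                                         c("DEG_TREAT_AA", "DEG_TREAT_GG")))
  capped <- cbind(capped, OUD = c(0, 1, 9, 2, 3))
  res <- prioritize_modules(capped, top_k = 2)
  expect_equal(res$delta_rank$module[1], "m4")
  delta <- abs(capped[, "DEG_TREAT_AA"] - capped[, "DEG_TREAT_GG"])
  expect_equal(res$delta_rank$delta, unname(sort(delta, decreasing = TRUE)))
  ## ties resolve by module label order
  tie <- matrix(c(3, 3, 1, 1), 2, 2,
                dimnames = list(c("mB", "mA"), c("DEG_TREAT_AA", "DEG_TREAT_GG")))
  res_tie <- prioritize_modules(tie, top_k = 2)
  expect_equal(res_tie$delta_rank$module, c("mA", "mB"))
  expect_true(all(res$selected %in% rownames(capped)))
})
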