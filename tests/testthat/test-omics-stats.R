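test_that("quantile normalization equalizes sample distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical value multisets are left unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(1, 2, 3))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))

  # defining property: multisets identical across samples afterwards
  set.seed(5)
  m3 <- matrix(rnorm(200), 50, 4)
  qn3 <- quantile_normalize(m3)
  for (j in 2:4) expect_equal(unname(sort(qn3[, j])),
                              unname(sort(qn3[, 1])))

  # idempotent on fully observed matrices
  expect_equal(quantile_normalize(qn3), qn3, tolerance = 1e-12)
  # masked entries survive normalization untouched
  m3[sample(200, 20)] <- NA
  qn_na <- quantile_normalize(m3)
  expect_equal(unname(is.na(qn_na)), is.na(m3))

  m3[, 2] <- NA
  expect_error(quantile_normalize(m3), class = "baxloc_degenerate_sample")
})

test_that("presence filter keeps genes observed in >= the threshold fraction", {
  m <- matrix(rnorm(1000), 10, 100)
  rownames(m) <- paste0("g", 1:10)
  m[1, 1:21] <- NA  # 79% present: removed
  m[2, 1:20] <- NA  # 80% exactly: kept (inclusive)
  f <- presence_filter(m, 0.8)
  expect_false("g1" %in% rownames(f))
  expect_true("g2" %in% rownames(f))
  # values never altered
  expect_equal(unname(f["g3", ]), unname(m["g3", ]))

  # random mask vs direct per-gene count oracle
  set.seed(14)
  m2 <- matrix(rnorm(600), 30, 20, dimnames = list(paste0("g", 1:30), NULL))
  m2[runif(600) < 0.3] <- NA
  f2 <- presence_filter(m2, 0.8)
  oracle_keep <- rownames(m2)[rowSums(!is.na(m2)) / 20 >= 0.8]
  expect_equal(rownames(f2), oracle_keep)
})

test_that("differential genes equal an independent per-gene t-test oracle", {
  labels <- rep(c("protected", "non_protected"), each = 17)
  sim <- simulate_expression(labels, n_genes = 500, n_de = 50,
                             effect_log2 = 2, sd_log2 = 0.5,
                             missing_rate = 0.05, seed = 33L)
  de <- de_genes(sim$values, labels, alpha = 0.05)
  # oracle: stats::t.test gene by gene on observed values
  oracle_p <- apply(sim$values, 1, function(v) {
    a <- v[labels == "protected"]
    b <- v[labels == "non_protected"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (sd(c(a - mean(a), b - mean(b))) == 0) return(NA_real_)
    t.test(a, b, var.equal = TRUE)$p.value
  })
  oracle_set <- names(oracle_p)[!is.na(oracle_p) & oracle_p < 0.05]
  expect_setequal(de$gene, oracle_set)
  expect_equal(de$p, sort(oracle_p[de$gene]), ignore_attr = TRUE,
               tolerance = 1e-12)
  # most planted genes are recovered at this effect size
  expect_gt(length(intersect(de$gene, sim$de_genes)), 45)

  # zero-variance gene is skipped and logged
  m <- sim$values
  m["G00400", ] <- 5
  de2 <- de_genes(m, labels)
  expect_true("G00400" %in% attr(de2, "skipped")$gene)
  expect_false("G00400" %in% de2$gene)
  expect_error(de_genes(m, rep("x", 34)), class = "baxloc_labeling")
})

test_that("null differential expression discovers about alpha of genes", {
  labels <- rep(c("a", "b"), each = 10)
  sim <- simulate_expression(labels, n_genes = 2000, n_de = 0,
                             effect_log2 = 0, missing_rate = 0, seed = 8L)
  de <- de_genes(sim$values, labels, alpha = 0.05)
  rate <- nrow(de) / 2000
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 3.5 * se)
})

test_that("complete-linkage clustering matches brute-force agglomeration", {
  # two identical samples merge at height zero
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 4, 2))
  cl <- hierarchical_cluster(m, distance = "euclidean", k = 2)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])

  # perfectly anticorrelated samples sit at Pearson distance 2
  m2 <- cbind(u = c(1, 2, 3, 4), v = c(4, 3, 2, 1))
  d2 <- as.matrix(baxloc:::expr_distance(m2, "pearson"))
  expect_equal(d2["u", "v"], 2)

  set.seed(77)
  for (i in 1:4) {
    n_items <- sample(4:6, 1)
    m3 <- matrix(rnorm(8 * n_items), 8, n_items,
                 dimnames = list(NULL, paste0("s", seq_len(n_items))))
    for (distance in c("euclidean", "pearson")) {
      cl3 <- hierarchical_cluster(m3, distance = distance)
      dmat <- as.matrix(baxloc:::expr_distance(m3, distance))
      oracle <- brute_complete_linkage(dmat)
      expect_equal(cl3$hclust$height, oracle$heights, tolerance = 1e-12)
      for (k in seq_len(n_items - 1)) {
        labels <- cutree(cl3$hclust, k = k)
        expect_equal(cutree_partition(labels),
                     canon_partition(oracle$partitions[[n_items - k]]))
      }
    }
  }
})

test_that("pearson distances need 3 shared observations and export to Newick", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[1:3, 1] <- NA
  m[4:5, 2] <- NA  # samples 1 and 2 share no rows fully... only 0 shared
  expect_error(hierarchical_cluster(m, distance = "pearson"),
               class = "baxloc_undefined_distance")

  m2 <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("s", 1:4)))
  cl <- hierarchical_cluster(m2, distance = "pearson")
  nwk <- cluster_newick(cl)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, colnames(m2))
})

test_that("kNN imputation averages the nearest genes at the hole's sample", {
  # identical neighbour at k = 1
  m <- rbind(g1 = c(1, 2, NA, 4), g2 = c(1, 2, 3, 4), g3 = c(9, 9, 9, 9))
  imp <- knn_impute(m, k = 1)
  expect_equal(imp["g1", 3], 3)

  # constant matrix: holes filled with the constant
  mc <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  mc[2, 2] <- NA
  expect_true(all(knn_impute(mc, k = 2) == 5))

  # 6x4 toy, one hole, k = 2: mean of the two nearest rows, by hand
  m6 <- rbind(g1 = c(1, 2, 3, NA),
              g2 = c(1, 2, 3, 10),
              g3 = c(1.1, 2.1, 2.9, 20),
              g4 = c(50, 60, 70, 80),
              g5 = c(0.9, 1.9, 3.2, 30),
              g6 = c(100, 90, 80, 70))
  imp6 <- knn_impute(m6, k = 2)
  # nearest two to g1 over shared samples 1:3 are g2 and g3
  expect_equal(imp6["g1", 4], mean(c(10, 20)))

  # unimputable entries stay masked and are reported
  m7 <- rbind(g1 = c(1, NA), g2 = c(2, NA), g3 = c(1, NA))
  imp7 <- knn_impute(m7, k = 1)
  expect_true(all(is.na(imp7[, 2])))
  expect_equal(nrow(attr(imp7, "unimputed")), 3)
})

test_that("clustering the differential submatrix recovers planted groups", {
  labels <- rep(c("protected", "non_protected"), each = 17)
  agree <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_expression(labels, n_genes = 300, n_de = 40,
                               effect_log2 = 2, sd_log2 = 0.5,
                               missing_rate = 0.05, seed = 100 + i)
    de <- de_genes(presence_filter(quantile_normalize(sim$values)), labels)
    cl <- hierarchical_cluster(sim$values[de$gene, , drop = FALSE],
                               distance = "pearson", k = 2)
    tab <- table(cl$labels, labels)
    agree[i] <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / sum(tab)
  }
  expect_gte(mean(agree), 0.9)
})
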