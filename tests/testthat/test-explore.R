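# Exploratory analytics: clustering, PCA, volcano statistics and preranked
# gene-set enrichment.

test_that("hierarchical clustering matches brute-force complete linkage", {
  m <- matrix(c(0, 0, 0.1, 0.1, 5, 5, 9, 1), 4, 2, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), c("x", "y")))
  hc <- hcluster(m, metric = "euclidean")
  z <- hc$z
  dmat <- as.matrix(dist(z, method = "euclidean"))
  expect_equal(sort(hc$rows$height),
               sort(oracle_complete_linkage_heights(dmat)))
  # heights are non-decreasing along merges (ultrametric property)
  expect_true(!is.unsorted(hc$rows$height))
})

test_that("identical rows merge first at distance zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4), d = c(2, 8, 1))
  colnames(m) <- c("p1", "p2", "p3")
  hc <- hcluster(m)
  expect_equal(hc$rows$height[1], 0)
  first <- sort(-hc$rows$merge[1, ])
  expect_equal(rownames(m)[first], c("a", "b"))
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(4)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("p", 1:5)))
  hc1 <- hcluster(m)
  perm <- sample(8)
  hc2 <- hcluster(m[perm, ])
  expect_equal(hc1$rows$height, hc2$rows$height)
  d1 <- as.matrix(stats::cophenetic(hc1$rows))
  d2 <- as.matrix(stats::cophenetic(hc2$rows))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
  # zero-variance biomarker excluded with a warning
  m0 <- cbind(m, flat = 7)
  expect_warning(hcluster(m0), "zero-variance")
})

test_that("PCA explains collinear data in one component and reconstructs", {
  line <- cbind(a = 1:6, b = 2 * (1:6), c = -3 * (1:6))
  p <- pca_biomarkers(line)
  expect_equal(p$explained_variance[1], 1)
  expect_equal(sum(p$explained_variance), 1)

  set.seed(2)
  m <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  p3 <- pca_biomarkers(m)
  # reconstruction from all components equals the standardized input
  z <- scale(m)
  recon <- p3$scores %*% t(p3$loadings)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-8)
  # sign convention: the largest loading of each component is positive
  for (j in seq_len(ncol(p3$loadings)))
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  expect_warning(pca_biomarkers(cbind(m, k = 1)), "constant")

  set.seed(8)
  iso <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_lt(diff(range(pca_biomarkers(iso)$explained_variance)), 0.25)
})

test_that("volcano rows carry log2 ratios and Student t p-values", {
  set.seed(5)
  y <- rep(c(TRUE, FALSE), each = 10)
  m <- cbind(up = c(rnorm(10, 4.77 * 50, 1), rnorm(10, 50, 1)),
             flat = rnorm(20, 100, 5))
  v <- volcano(m, y)
  expect_equal(v$log2_fc[v$protein_id == "up"], log2(4.77), tolerance = 0.01)
  expect_lt(abs(v$log2_fc[v$protein_id == "flat"]), 0.2)
  # fold change is invariant to a common scale factor
  v2 <- volcano(2 * m, y)
  expect_equal(v2$log2_fc, v$log2_fc)
  expect_equal(v2$p_value, v$p_value)
  # equal means give zero log fold change
  m_eq <- cbind(same = rep(c(3, 5), 10))
  expect_equal(volcano(m_eq, y)$log2_fc, 0)
  # non-positive group mean: missing fc with a warning
  m_neg <- cbind(neg = c(rnorm(10, -5), rnorm(10, 5)), ok = rnorm(20, 10))
  expect_warning(vn <- volcano(m_neg, y), "undefined")
  expect_true(is.na(vn$log2_fc[vn$protein_id == "neg"]))
})

test_that("volcano p-values are uniform under the null", {
  set.seed(10)
  m <- matrix(rnorm(40 * 200, 100, 10), 40,
              dimnames = list(NULL, protein_ids(200)))
  y <- rep(c(TRUE, FALSE), each = 20)
  v <- volcano(m, y)
  expect_gt(stats::ks.test(v$p_value, "punif")$p.value, 0.01)
})

test_that("GSEA enrichment score equals the hand-computed running sum", {
  sc <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2, g6 = -3)
  # by hand, weight 1, set {g1, g3}: NR = |3| + |1| = 4
  # steps: +3/4 = .75, -1/4 -> .5, +1/4 -> .75, then -.25 each -> .5, .25, 0
  # extremum = 0.75
  res <- gsea_preranked(sc, list(top = c("g1", "g3")), n_perm = 200, seed = 1)
  expect_equal(res$es, 0.75)
  expect_equal(res$es, oracle_gsea_es(sc, c(1, 3)))
  expect_gt(res$nes, 1)
  expect_equal(res$leading_edge[[1]], c("g1", "g3"))
})

test_that("GSEA matches fgsea's running-sum statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  for (i in 1:10) {
    n <- 40
    sc <- setNames(sort(rnorm(n), decreasing = TRUE), paste0("g", 1:n))
    members <- sample(names(sc), 6)
    mine <- gsea_preranked(sc, list(s = members), n_perm = 50, seed = i)$es
    ref <- fgsea::calcGseaStat(sc, selectedStats = which(names(sc) %in% members),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("GSEA sign flips with a reversed ranking and skips empty sets", {
  sc <- c(a = 2, b = 1, c = 0.5, d = -0.5, e = -1, f = -2)
  res <- gsea_preranked(sc, list(s = c("a", "b")), n_perm = 100, seed = 2)
  flipped <- gsea_preranked(-sc, list(s = c("a", "b")), n_perm = 100, seed = 2)
  expect_equal(flipped$es, -res$es)
  expect_equal(sign(res$nes), sign(res$es))
  expect_warning(
    gsea_preranked(sc, list(s = c("a", "b"), ghost = c("zz")), n_perm = 50,
                   seed = 1),
    "empty")
})

test_that("random sets give approximately uniform permutation p-values", {
  set.seed(13)
  n <- 60
  sc <- setNames(rnorm(n), paste0("g", 1:n))
  sets <- lapply(1:120, function(i) sample(names(sc), 4))
  names(sets) <- paste0("rand", 1:120)
  res <- gsea_preranked(sc, sets, n_perm = 200, seed = 3)
  expect_true(mean(res$p_perm) > 0.4 && mean(res$p_perm) < 0.6)
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
})

test_that("GMT files round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4", "bad_line"),
             path)
  expect_warning(sets <- read_gmt(path), "malformed")
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4")))
})
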