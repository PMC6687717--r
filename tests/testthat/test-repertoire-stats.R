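test_that("usage vectors are count fractions per gene", {
  tab <- clonotype_table(data.frame(
    v_gene = c("TRBV12-4", "TRBV12-4"), j_gene = c("TRBJ2-2", "TRBJ1-1"),
    cdr3_aa = c("AAAA", "CCCC"), count = c(6, 4)), "s")
  u <- usage_vector(tab, "V")
  expect_equal(as.numeric(u), 1.0)
  expect_equal(names(u), "TRBV12-4")

  tab2 <- clonotype_table(data.frame(
    v_gene = c("TRBV12-4", "TRBV27"), j_gene = "TRBJ2-2",
    cdr3_aa = c("AAAA", "CCCC"), count = c(70, 30)), "s")
  expect_equal(as.numeric(usage_vector(tab2, "V")), c(0.7, 0.3))
  expect_equal(sum(usage_vector(random_table(4), "J")), 1, tolerance = 1e-9)
})

test_that("cohort normalization reduces to elementwise division", {
  tab <- random_table(8, n = 20)
  u <- usage_vector(tab, "V")
  # identical controls -> all-ones fold change
  fc <- normalize_to_cohort(u, list(u, u, u), pseudocount = 0)
  expect_equal(as.numeric(fc), rep(1, length(fc)))

  # 0.10 vs control mean 0.001 -> 100-fold
  s <- structure(c(g1 = 0.10, g2 = 0.90), axis = "V", class = "usage_vector")
  ctrl <- structure(c(g1 = 0.001, g2 = 0.999), axis = "V", class = "usage_vector")
  fc2 <- normalize_to_cohort(s, list(ctrl), pseudocount = 0)
  expect_equal(unname(fc2["g1"]), 100)

  # random case against a direct division oracle
  set.seed(2)
  ctrls <- lapply(1:4, function(i) usage_vector(random_table(100 + i), "V"))
  genes <- sort(unique(unlist(lapply(c(list(u), ctrls), names))))
  at <- function(v) {x <- setNames(numeric(length(genes)), genes); x[names(v)] <- v; x}
  cm <- rowMeans(sapply(ctrls, at))
  pc <- 1e-4
  oracle <- (at(u) + pc) / (cm + pc)
  fc3 <- normalize_to_cohort(u, ctrls, pseudocount = pc)
  expect_equal(as.numeric(fc3), unname(oracle))
  expect_equal(as.numeric(normalize_to_cohort(u, ctrls, pseudocount = pc,
                                              scale = "log10")),
               unname(log10(oracle)))

  ju <- usage_vector(tab, "J")
  expect_error(normalize_to_cohort(u, list(ju)), class = "pubtcr_validation_error")
})

test_that("V-J pairing cells group-by exactly and marginals match usage", {
  tab1 <- clonotype_table(data.frame(v_gene = "TRBV1", j_gene = "TRBJ1",
                                     cdr3_aa = "AAAA", count = 5), "s")
  expect_equal(as.numeric(vj_pairing_matrix(tab1)), 1.0)

  tab2 <- clonotype_table(data.frame(
    v_gene = c("TRBV12-4", "TRBV27"), j_gene = c("TRBJ2-2", "TRBJ2-7"),
    cdr3_aa = c("AAAA", "CCCC"), count = c(60, 40)), "s")
  M2 <- vj_pairing_matrix(tab2)
  expect_equal(M2["TRBV12-4", "TRBJ2-2"], 0.6)
  expect_equal(M2["TRBV27", "TRBJ2-7"], 0.4)

  tab <- random_table(13, n = 40)
  M <- vj_pairing_matrix(tab)
  expect_equal(sum(M), 1, tolerance = 1e-9)
  # brute-force group-by oracle
  for (v in rownames(M)) for (j in colnames(M)) {
    expect_equal(M[v, j],
                 sum(tab$count[tab$v_gene == v & tab$j_gene == j]) / total_reads(tab))
  }
  # marginal consistency with the usage vectors
  uv <- usage_vector(tab, "V"); uj <- usage_vector(tab, "J")
  expect_equal(as.numeric(rowSums(M)[names(uv)]), as.numeric(uv),
               tolerance = 1e-12)
  expect_equal(as.numeric(colSums(M)[names(uj)]), as.numeric(uj),
               tolerance = 1e-12)
})

test_that("cohort mean pairing is the union-aligned elementwise mean", {
  tabs <- lapply(1:7, function(i) random_table(200 + i, n = 25))
  mats <- lapply(tabs, vj_pairing_matrix)
  expect_equal(unclass(cohort_mean_pairing(mats[1])), unclass(mats[[1]]))
  Mm <- cohort_mean_pairing(mats)
  expect_equal(sum(Mm), 1, tolerance = 1e-9)
  vs <- rownames(Mm); js <- colnames(Mm)
  oracle <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
  for (M in mats) oracle[rownames(M), colnames(M)] <-
      oracle[rownames(M), colnames(M)] + M
  expect_equal(unclass(Mm), oracle / 7, ignore_attr = TRUE)

  A <- mats[[1]]; B <- mats[[2]]
  common_v <- intersect(rownames(A), rownames(B))
  common_j <- intersect(colnames(A), colnames(B))
  if (length(common_v) && length(common_j)) {
    v <- common_v[1]; j <- common_j[1]
    expect_equal(cohort_mean_pairing(list(A, B))[v, j], (A[v, j] + B[v, j]) / 2)
  }
  expect_error(cohort_mean_pairing(list()), class = "pubtcr_validation_error")
})

test_that("usage PCA is a faithful centered SVD", {
  # degenerate: identical samples -> zero variance, equal scores
  u <- usage_vector(random_table(31), "V")
  p0 <- usage_pca(list(a = u, b = u), k = 1)
  expect_equal(p0$explained_variance, 0)
  expect_equal(p0$scores["a", ], p0$scores["b", ])

  # variation concentrated on one gene, compensated across many others so
  # the usage stays compositional -> PC1 loading concentrated on that gene
  mk <- function(f) {
    rest <- setNames(rep((1 - f) / 100, 100), sprintf("TRBV-bg-%03d", 1:100))
    structure(c("TRBV12-4" = f, rest), axis = "V", class = "usage_vector")
  }
  us <- list(s1 = mk(0.05), s2 = mk(0.20), s3 = mk(0.45), s4 = mk(0.30))
  p1 <- usage_pca(us, k = 2)
  expect_gte(abs(p1$loadings["TRBV12-4", "PC1"]), 0.99)
  expect_true(all(diff(p1$explained_variance) <= 1e-12))

  # completeness: full-rank reconstruction
  set.seed(6)
  us2 <- lapply(1:5, function(i) usage_vector(random_table(300 + i), "V"))
  names(us2) <- paste0("s", 1:5)
  k <- 4
  p2 <- usage_pca(us2, k = k)
  X <- pubtcr:::align_union(lapply(us2, unclass))
  recon <- p2$scores %*% t(p2$loadings) + rep(1, 5) %*% t(p2$center)
  expect_equal(unname(recon), unname(X), tolerance = 1e-8)
  expect_equal(crossprod(p2$loadings), diag(k), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(usage_pca(us2, k = 10), class = "pubtcr_validation_error")

  # sample reordering leaves scores unchanged up to sign
  p3 <- usage_pca(rev(us2), k = 2)
  expect_equal(abs(p3$scores[rownames(p2$scores), ]),
               abs(p2$scores[, 1:2]), tolerance = 1e-8)
})

test_that("treemap export ranks by count and conserves total mass", {
  tab <- clonotype_table(data.frame(
    v_gene = "TRBV1", j_gene = "TRBJ1",
    cdr3_aa = c("AAAA", "CCCC", "DDDD"), count = c(5, 3, 2)), "s")
  tm <- treemap_export(tab, top_n = 2)
  expect_equal(nrow(tm), 3L)
  expect_equal(tm$cdr3_aa, c("AAAA", "CCCC", "other"))
  expect_equal(tm$area, c(0.5, 0.3, 0.2))

  tmr <- treemap_export(random_table(17, 50), top_n = 10)
  expect_equal(sum(tmr$area), 1, tolerance = 1e-9)
  expect_error(treemap_export(tab, 0), class = "pubtcr_validation_error")
})

test_that("qPCR ratios follow 2^-dCt with a 1e-4 detection floor", {
  expect_equal(qpcr_ratio(25, 25)$ratio, 1.0)
  r <- qpcr_ratio(35, 25)
  expect_equal(r$ratio, 2^-10)
  expect_false(r$floored)
  nd <- qpcr_ratio("ND", 25)
  expect_equal(nd$ratio, 1e-4)
  expect_true(nd$floored)
  expect_false(nd$detected)
  deep <- qpcr_ratio(45, 25)  # 2^-20 below the floor
  expect_equal(deep$ratio, 1e-4)
  expect_true(deep$floored)
  expect_error(qpcr_ratio(25, NA), class = "pubtcr_validation_error")
})
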