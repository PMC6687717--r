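test_that("pairwise overlap counts shared keys with richness on the diagonal", {
  a <- random_table(41, n = 5, sample_id = "a")
  b <- random_table(42, n = 6, sample_id = "b")
  M <- pairwise_overlap(list(a, b))
  expect_equal(M["a", "b"], 0L)  # independent random CDR3s never collide here
  expect_equal(M["a", "a"], 5L)

  M2 <- pairwise_overlap(list(a, a))
  expect_equal(M2[1, 2], 5L)

  # brute-force set-intersection oracle on overlapping tables
  base <- as.data.frame(random_table(43, n = 20, sample_id = "x"))
  tabs <- lapply(1:4, function(i) {
    extra <- as.data.frame(random_table(50 + i, n = 10, sample_id = "y"))
    clonotype_table(rbind(base[seq_len(5 * i), 1:4], extra[, 1:4]),
                    sample_id = paste0("s", i))
  })
  M3 <- pairwise_overlap(tabs)
  key <- function(t) unique(paste(t$v_gene, t$j_gene, t$cdr3_aa))
  for (i in 1:4) for (j in 1:4)
    expect_equal(M3[i, j],
                 if (i == j) length(key(tabs[[i]]))
                 else length(intersect(key(tabs[[i]]), key(tabs[[j]]))))
  expect_true(isSymmetric(unclass(M3)))

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  M4 <- pairwise_overlap(tabs[perm])
  expect_equal(unclass(M4), unclass(M3)[perm, perm])
  expect_error(pairwise_overlap(list(a)), class = "pubtcr_validation_error")
})

test_that("the printed-count fixture yields a public clonotype in all 7 cases", {
  cases <- assla_tables()
  controls <- lapply(1:6, function(i) filler_table(900 + i, paste0("hd", i)))
  rep <- detect_public(cases, controls)
  pub <- rep[rep$is_public, ]
  expect_equal(nrow(pub), 1L)
  expect_equal(pub$cdr3_aa, "ASSLAGELF")
  expect_equal(pub$v_gene, "TRBV12-4")
  expect_equal(pub$n_case_present, 7L)
  expect_equal(pub$control_max_frequency, 0)

  # a clonotype at 2% in a control is excluded
  leaky <- clonotype_table(data.frame(
    v_gene = c("TRBV12-4", "TRBV9"), j_gene = c("TRBJ2-2", "TRBJ1-1"),
    cdr3_aa = c("ASSLAGELF", "AAAA"), count = c(2, 98)), "leaky")
  rep2 <- detect_public(cases, c(controls, list(leaky)))
  expect_false(any(rep2$is_public))
  expect_equal(rep2$n_case_present[rep2$cdr3_aa == "ASSLAGELF"], 7L)
})

test_that("spiked synthetic cohorts flag exactly the planted clonotype", {
  pl <- paper_like_config(seed = 61, depth = 2e4, n_background = 1500,
                          design = paper_like_design(7, 0, 5, 5))
  co <- simulate_cohort(pl$config, pl$design, level = "counts")
  rep <- detect_public(co$tables[co$design$cohort == "case"],
                       co$tables[co$design$cohort != "case"])
  pub <- rep[rep$is_public, ]
  expect_equal(nrow(pub), 1L)
  expect_equal(pub$cdr3_aa, pl$public_key$cdr3_aa)
  expect_equal(pub$v_gene, pl$public_key$v_gene)
})

test_that("publicity flags are monotone in their thresholds", {
  pl <- paper_like_config(seed = 77, depth = 5000, n_background = 300,
                          design = paper_like_design(4, 0, 3, 3))
  co <- simulate_cohort(pl$config, pl$design, level = "counts")
  cases <- co$tables[co$design$cohort == "case"]
  ctrls <- co$tables[co$design$cohort != "case"]
  flags <- function(mcf, mxc) {
    r <- detect_public(cases, ctrls, min_case_fraction = 0.5,
                       min_case_freq = mcf, max_control_freq = mxc)
    sort(paste(r$v_gene, r$j_gene, r$cdr3_aa)[r$is_public])
  }
  for (mcf in c(0.001, 0.01, 0.05)) {
    # raising max_control_freq can only add public flags
    expect_true(all(flags(mcf, 1e-6) %in% flags(mcf, 1e-3)))
    expect_true(all(flags(mcf, 1e-3) %in% flags(mcf, 1e-1)))
  }
  for (mxc in c(1e-5, 1e-3)) {
    # raising min_case_freq can only remove public flags
    expect_true(all(flags(0.05, mxc) %in% flags(0.01, mxc)))
    expect_true(all(flags(0.01, mxc) %in% flags(0.001, mxc)))
  }
  expect_error(detect_public(cases, ctrls, min_case_freq = 2),
               class = "pubtcr_validation_error")
})

test_that("spike-in recovery is complete with no recurring false positives", {
  hits <- 0L
  bg_flags <- character(0)
  for (s in 1:20) {
    pl <- paper_like_config(seed = 1000 + s, depth = 5000, n_background = 250,
                            design = paper_like_design(4, 0, 3, 3))
    co <- simulate_cohort(pl$config, pl$design, level = "counts")
    rep <- detect_public(co$tables[co$design$cohort == "case"],
                         co$tables[co$design$cohort != "case"],
                         min_case_fraction = 1, min_case_freq = 0.01,
                         max_control_freq = 1e-5)
    pub <- rep[rep$is_public, ]
    if (pl$public_key$cdr3_aa %in% pub$cdr3_aa) hits <- hits + 1L
    bg_flags <- c(bg_flags, setdiff(pub$cdr3_aa, pl$public_key$cdr3_aa))
  }
  expect_equal(hits, 20L)
  expect_true(all(table(bg_flags) <= 1))
})

test_that("one-residue clusters use equal-length Hamming neighborhoods", {
  tab <- clonotype_table(data.frame(
    v_gene = "TRBV12-4", j_gene = "TRBJ2-2",
    cdr3_aa = c("ASSLAGELF", "ASSLSGELF", "ASSFAGELF", "ASSYNPGTGTEEYEQY"),
    count = c(40, 30, 20, 10)), "s")
  cl <- cdr3_cluster("ASSLAGELF", tab)
  expect_setequal(cl$members$cdr3_aa, c("ASSLAGELF", "ASSLSGELF", "ASSFAGELF"))
  expect_equal(cl$cluster_frequency, 0.9)
  expect_gte(cl$cluster_frequency,
             tab$frequency[tab$cdr3_aa == "ASSLAGELF"])

  one <- clonotype_table(data.frame(v_gene = "TRBV1", j_gene = "TRBJ1",
                                    cdr3_aa = "ASSLAGELF", count = 3), "s")
  cl1 <- cdr3_cluster("ASSLAGELF", one)
  expect_equal(nrow(cl1$members), 1L)
  expect_equal(cl1$members$distance, 0L)
})

test_that("cluster membership matches a brute-force Hamming oracle", {
  set.seed(99)
  for (rep in 1:5) {
    tab <- random_table(700 + rep, n = 60)
    seed_cdr3 <- sample(tab$cdr3_aa, 1)
    cl <- cdr3_cluster(seed_cdr3, tab)
    oracle <- tab$cdr3_aa[vapply(tab$cdr3_aa, function(x)
      pubtcr:::hamming_dist(x, seed_cdr3) <= 1, TRUE)]
    expect_setequal(cl$members$cdr3_aa, oracle)
    expect_gte(cl$cluster_frequency,
               sum(tab$frequency[tab$cdr3_aa == seed_cdr3]))
  }
})

test_that("group contrasts report means, standard errors and Welch tests", {
  mk_tab <- function(freq, id) {
    n <- 10000
    k <- round(freq * n)
    rows <- data.frame(v_gene = c("TRBV12-4", "TRBV9"),
                       j_gene = c("TRBJ2-2", "TRBJ1-1"),
                       cdr3_aa = c("ASSLAGELF", "AAAAA"),
                       count = c(k, n - k))
    clonotype_table(rows[rows$count > 0, ], id)
  }
  key <- list(v_gene = "TRBV12-4", j_gene = "TRBJ2-2", cdr3_aa = "ASSLAGELF")

  # identical constant frequencies -> t = 0, p = 1
  g1 <- lapply(1:3, function(i) mk_tab(0.05, paste0("a", i)))
  g2 <- lapply(1:3, function(i) mk_tab(0.05, paste0("b", i)))
  ct <- clonotype_group_contrast(key, list(A = g1, B = g2))
  expect_equal(ct$tests$t, 0)
  expect_equal(ct$tests$p_value, 1)

  # case PBMC at 1.31% versus tolerant controls lacking the clonotype
  case <- lapply(1:4, function(i) mk_tab(0.0131, paste0("c", i)))
  tol <- lapply(1:4, function(i) mk_tab(0, paste0("t", i)))
  ct2 <- clonotype_group_contrast(key, list(case_PBMC = case, tolerant = tol))
  expect_equal(ct2$summary$mean, c(0.0131, 0), tolerance = 1e-9)
  expect_equal(ct2$summary$n, c(4L, 4L))

  # a singleton group has no s.e. and its pair is skipped
  ct3 <- clonotype_group_contrast(key, list(A = g1, B = g2[1]))
  expect_true(is.na(ct3$summary$se[ct3$summary$group == "B"]))
  expect_true(is.na(ct3$tests$p_value))
  expect_error(clonotype_group_contrast(key, list(A = g1)),
               class = "pubtcr_validation_error")
})

test_that("the Welch test agrees with stats::t.test on regular data", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(8, 0.1, 0.03); y <- rnorm(6, 0.12, 0.05)
    ours <- pubtcr:::welch_test(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
})
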