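# brute-force segment assignment oracle: exhaustive loops, kept independent
# of the package's vectorized scorer
brute_force_assign <- function(read, germline, min_overlap = 15L) {
  rc <- strsplit(read, "")[[1]]
  L <- length(rc)
  best_v <- list(score = -1, name = NA)
  for (i in order(germline$v$name)) {
    seg <- strsplit(germline$v$nt_sequence[i], "")[[1]]
    n <- length(seg)
    for (e in min_overlap:L) {
      w <- min(e, n)
      sc <- sum(rc[(e - w + 1):e] == seg[(n - w + 1):n]) / w
      if (sc > best_v$score + 1e-12)
        best_v <- list(score = sc, name = germline$v$name[i])
    }
  }
  best_j <- list(score = -1, name = NA)
  for (i in order(germline$j$name)) {
    seg <- strsplit(germline$j$nt_sequence[i], "")[[1]]
    n <- length(seg)
    for (s in 1:(L - min_overlap + 1)) {
      w <- min(L - s + 1, n)
      sc <- sum(rc[s:(s + w - 1)] == seg[1:w]) / w
      if (sc > best_j$score + 1e-12)
        best_j <- list(score = sc, name = germline$j$name[i])
    }
  }
  list(v = best_v, j = best_j)
}

test_that("an error-free planted read recovers its segments at identity 1", {
  g <- tiny_germline()
  read <- planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF")
  asg <- assign_segments(read, g)
  expect_equal(asg$status, "ok")
  expect_equal(asg$v_name, "TRBV12-4")
  expect_equal(asg$j_name, "TRBJ2-2")
  expect_equal(asg$v_score, 1)
  expect_equal(asg$j_score, 1)
  expect_true(asg$v_end_nt <= asg$j_start_nt)
})

test_that("assignment survives substitutions and matches a brute-force argmax", {
  g <- tiny_germline()
  read <- planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF")
  set.seed(3)
  for (rep in 1:10) {
    rc <- strsplit(read, "")[[1]]
    pos <- sample(1:60, 2)  # two substitutions inside the V part
    rc[pos] <- vapply(rc[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    mutread <- paste(rc, collapse = "")
    asg <- assign_segments(mutread, g, min_identity = 0.9)
    bf <- brute_force_assign(mutread, g)
    expect_equal(asg$v_name, bf$v$name)
    expect_equal(asg$j_name, bf$j$name)
    expect_equal(asg$v_score, bf$v$score, tolerance = 1e-12)
    expect_gte(asg$v_score, 0.9)
    expect_equal(asg$status, "ok")
  }
})

test_that("random sequences are reported unassigned, not errored", {
  g <- tiny_germline()
  set.seed(9)
  for (rep in 1:5) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    asg <- assign_segments(rnd, g, min_identity = 0.9)
    bf <- brute_force_assign(rnd, g)
    expect_true(max(bf$v$score, bf$j$score) < 0.9)
    expect_equal(asg$status, "unassigned")
  }
  expect_error(assign_segments("ACGT", g), class = "pubtcr_validation_error")
})

test_that("extraction applies the anchor-exclusive junction rule", {
  g <- tiny_germline()
  read <- planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF")
  asg <- assign_segments(read, g)
  ext <- extract_cdr3(read, asg, g)
  expect_equal(ext$status, "ok")
  expect_equal(ext$cdr3_aa, "ASSLAGELF")
  expect_true(ext$productive)

  # adjacent anchors: nothing strictly between the C and the F/W
  read0 <- planted_read(g, "TRBV12-4", "TRBJ2-2", "")
  asg0 <- assign_segments(read0, g)
  ext0 <- extract_cdr3(read0, asg0, g)
  expect_equal(ext0$status, "empty_cdr3")
  expect_false(ext0$productive)
})

test_that("a stop codon in the junction makes the read nonproductive", {
  g <- tiny_germline()
  v <- g$v$nt_sequence[g$v$name == "TRBV12-4"]
  j <- g$j$nt_sequence[g$j$name == "TRBJ2-2"]
  read <- paste0(substr(v, nchar(v) - 59, nchar(v)),
                 pubtcr:::aa_to_nt("ASS"), "TAA", pubtcr:::aa_to_nt("ELF"),
                 substr(j, 1, 24))
  asg <- assign_segments(read, g)
  ext <- extract_cdr3(read, asg, g)
  expect_false(ext$productive)
})

test_that("a frame-shifted assignment cannot silently reproduce the junction", {
  g <- tiny_germline()
  read <- planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF")
  asg <- assign_segments(read, g)
  for (shift in c(1L, 2L)) {
    asg_bad <- asg
    asg_bad$v_end_nt <- asg$v_end_nt + shift
    ext <- extract_cdr3(read, asg_bad, g)
    expect_false(identical(ext$cdr3_aa, "ASSLAGELF") && ext$status == "ok")
  }
})

test_that("clonotype tables aggregate planted reads at exact fractions", {
  g <- tiny_germline()
  reads <- c(rep(planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF"), 70),
             rep(planted_read(g, "TRBV-sim-02", "TRBJ-sim-02", "ASSLSDTIY"), 20),
             rep(planted_read(g, "TRBV-sim-03", "TRBJ-sim-03", "ATSGPNQETQY"), 10))
  tab <- build_clonotype_table(reads, g)
  expect_equal(nrow(tab), 3L)
  expect_equal(total_reads(tab), 100)
  expect_equal(tab$frequency, c(0.7, 0.2, 0.1))

  tab1 <- build_clonotype_table(rep(reads[1], 10), g)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$frequency, 1.0)
})

test_that("read outcomes conserve the denominator and junk reads never count", {
  g <- tiny_germline()
  set.seed(5)
  junk <- vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = ""), "")
  reads <- c(rep(planted_read(g, "TRBV12-4", "TRBJ2-2", "ASSLAGELF"), 13), junk)
  tab <- build_clonotype_table(reads, g)
  out <- attr(tab, "read_outcomes")
  expect_equal(nrow(out), 20L)
  expect_equal(sum(out$outcome == "productive"), 13L)
  expect_equal(sum(tab$count), 13)
  expect_equal(total_reads(tab), 13)  # productive-only denominator
  expect_equal(sum(table(out$outcome)), 20)

  expect_error(build_clonotype_table(junk, g), "empty_repertoire",
               class = "pubtcr_validation_error")
})

test_that("every productive synthetic read returns its planted junction", {
  g <- simulate_germline(21, n_v = 8, n_j = 4)
  pl <- paper_like_config(seed = 21, depth = 1000, n_background = 150, n_v = 8,
                          n_j = 4)
  meta <- pl$design[pl$design$sample_id == "BC02", ]
  sim <- simulate_repertoire(pl$config, meta, g, level = "reads", seed = 33)
  tab <- build_clonotype_table(sim$reads, g, sample_meta = meta)
  truth <- sim$truth[sim$truth$count > 0, ]
  expect_equal(
    sort(paste(tab$v_gene, tab$j_gene, tab$cdr3_aa, tab$count)),
    sort(paste(truth$v_gene, truth$j_gene, truth$cdr3_aa, truth$count)))
  out <- attr(tab, "read_outcomes")
  expect_true(all(out$outcome == "productive"))
})
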