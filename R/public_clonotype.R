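# Cross-sample public-clonotype detection, pairwise overlap, one-residue
# CDR3 clustering, and group contrasts of a target clonotype's frequency.

table_keys <- function(table, key = "vj_cdr3") {
  clono_key(table$v_gene, table$j_gene, table$cdr3_aa, key)
}

# frequency of each requested key in a table (0 when absent)
key_freqs <- function(table, keys, key_mode = "vj_cdr3") {
  f <- setNames(table$frequency, table_keys(table, key_mode))
  if (key_mode == "cdr3" && anyDuplicated(names(f)))
    f <- setNames(rowsum(unname(f), names(f))[, 1], sort(unique(names(f))))
  out <- f[keys]
  out[is.na(out)] <- 0
  setNames(as.numeric(out), keys)
}

#' Pairwise clonotype overlap across samples
#'
#' Number of distinct clonotype keys shared by each pair of samples; the
#' diagonal holds each sample's richness (number of distinct keys).
#'
#' @param tables list of [clonotype_table()]s (>= 2).
#' @param key `"vj_cdr3"` (V gene + J gene + CDR3, default) or `"cdr3"`.
#' @return symmetric integer matrix of class `overlap_matrix` with sample ids
#'   as dimnames.
#' @export
pairwise_overlap <- function(tables, key = c("vj_cdr3", "cdr3")) {
  key <- match.arg(key)
  if (length(tables) < 2L) stop_validation("need at least 2 samples for overlap")
  keysets <- lapply(tables, function(t) unique(table_keys(t, key)))
  ids <- vapply(seq_along(tables), function(i) {
    s <- sample_id(tables[[i]]); if (is.na(s)) sprintf("sample%d", i) else s
  }, "")
  n <- length(tables)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    M[i, i] <- length(keysets[[i]])
    if (i < n) for (jj in seq.int(i + 1L, n)) {
      ov <- length(intersect(keysets[[i]], keysets[[jj]]))
      M[i, jj] <- ov; M[jj, i] <- ov
    }
  }
  structure(M, class = c("overlap_matrix", "matrix"))
}

#' Detect public clonotypes shared by case samples and rare in controls
#'
#' A clonotype is flagged public when it is present at frequency
#' `>= min_case_freq` in at least `min_case_fraction` of the case samples
#' *and* its maximum frequency across all control samples is strictly below
#' `max_control_freq`. The defaults mirror a stringent narrative criterion:
#' present in every case at >= 1%, and below 0.001% in every control.
#' Absence from a sample counts as frequency 0.
#'
#' The report lists every clonotype reaching `min_case_freq` in at least one
#' case sample, sorted by the number of qualifying case samples and then mean
#' case frequency, with the public flag set per the thresholds.
#'
#' @param case_tables,control_tables lists of [clonotype_table()]s.
#' @param min_case_fraction fraction of case samples that must carry the
#'   clonotype (default 1: all of them).
#' @param min_case_freq minimum within-sample frequency to count as present
#'   in a case (default 0.01).
#' @param max_control_freq strict upper bound on control frequencies
#'   (default 1e-5).
#' @param key clonotype identity: `"vj_cdr3"` (default) or `"cdr3"`.
#' @return data.frame of class `public_clonotype_report` with columns
#'   `v_gene`, `j_gene`, `cdr3_aa` (the gene columns are NA in `"cdr3"` key
#'   mode), `n_case_present`, `mean_case_freq`, `control_max_frequency`,
#'   `is_public`; attribute `"case_profile"` holds the key-by-sample case
#'   frequency matrix.
#' @export
detect_public <- function(case_tables, control_tables,
                          min_case_fraction = 1.0, min_case_freq = 0.01,
                          max_control_freq = 1e-5,
                          key = c("vj_cdr3", "cdr3")) {
  key <- match.arg(key)
  if (length(case_tables) == 0L || length(control_tables) == 0L)
    stop_validation("case and control collections must both be non-empty")
  for (th in c(min_case_fraction, min_case_freq, max_control_freq))
    if (is.na(th) || th < 0 || th > 1)
      stop_validation("thresholds must lie in [0, 1]")

  n_case <- length(case_tables)
  all_keys <- sort(unique(unlist(lapply(case_tables, table_keys, key))))
  prof <- vapply(case_tables, key_freqs, numeric(length(all_keys)),
                 keys = all_keys, key_mode = key)
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = length(all_keys))
  rownames(prof) <- all_keys
  colnames(prof) <- vapply(seq_along(case_tables), function(i) {
    s <- sample_id(case_tables[[i]]); if (is.na(s)) sprintf("case%d", i) else s
  }, "")

  n_present <- rowSums(prof >= min_case_freq)
  cand <- all_keys[n_present >= 1L]
  if (length(cand) == 0L) {
    rep0 <- data.frame(v_gene = character(), j_gene = character(),
                       cdr3_aa = character(), n_case_present = integer(),
                       mean_case_freq = numeric(),
                       control_max_frequency = numeric(),
                       is_public = logical(), stringsAsFactors = FALSE)
    attr(rep0, "case_profile") <- prof
    class(rep0) <- c("public_clonotype_report", "data.frame")
    return(rep0)
  }

  ctrl_max <- setNames(numeric(length(cand)), cand)
  for (ct in control_tables)
    ctrl_max <- pmax(ctrl_max, key_freqs(ct, cand, key))

  need_n <- min_case_fraction * n_case - 1e-9
  fields <- if (key == "vj_cdr3") {
    do.call(rbind, strsplit(cand, "|", fixed = TRUE))
  } else {
    cbind(NA_character_, NA_character_, cand)
  }
  rep <- data.frame(v_gene = fields[, 1], j_gene = fields[, 2],
                    cdr3_aa = fields[, 3],
                    n_case_present = as.integer(n_present[cand]),
                    mean_case_freq = rowMeans(prof[cand, , drop = FALSE]),
                    control_max_frequency = unname(ctrl_max),
                    stringsAsFactors = FALSE)
  rep$is_public <- rep$n_case_present >= need_n &
    rep$control_max_frequency < max_control_freq
  rep <- rep[order(-rep$n_case_present, -rep$mean_case_freq), ]
  rownames(rep) <- NULL
  attr(rep, "case_profile") <- prof
  class(rep) <- c("public_clonotype_report", "data.frame")
  rep
}

#' One-residue CDR3 cluster around a seed sequence
#'
#' Members are the table's clonotypes whose CDR3 has the same length as the
#' seed and Hamming distance at most 1 from it (substitutions only, no
#' indels). The seed itself is included when present; the cluster frequency
#' is the sum of member frequencies within the sample.
#'
#' @param seed CDR3 amino-acid string.
#' @param table a [clonotype_table()].
#' @return list of class `cdr3_cluster` with `seed`, `members` (data.frame
#'   `v_gene`, `j_gene`, `cdr3_aa`, `count`, `frequency`, `distance`) and
#'   `cluster_frequency`. An empty cluster is allowed.
#' @export
cdr3_cluster <- function(seed, table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (!nzchar(seed)) stop_validation("cluster seed must be non-empty")
  len <- nchar(seed)
  cand <- as.data.frame(table)[nchar(table$cdr3_aa) == len, , drop = FALSE]
  if (nrow(cand)) {
    sc <- strsplit(seed, "")[[1]]
    d <- vapply(strsplit(cand$cdr3_aa, ""), function(ch) sum(ch != sc), 0)
    cand$distance <- as.integer(d)
    cand <- cand[d <= 1, , drop = FALSE]
  } else {
    cand$distance <- integer(0)
  }
  cand <- cand[order(cand$distance, -cand$count, cand$cdr3_aa), ]
  rownames(cand) <- NULL
  structure(list(seed = seed, members = cand,
                 cluster_frequency = sum(cand$frequency)),
            class = "cdr3_cluster")
}

# Welch two-sample t-test tolerant of degenerate inputs. stats::t.test is the
# workhorse; zero-variance data (which it refuses) fall back to the limiting
# values: equal means -> t = 0, p = 1; unequal -> t = +/-Inf, p = 0.
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_))
  if (stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Group contrast of a target clonotype's frequency
#'
#' Computes per-group sample frequencies of a single clonotype (0 when the
#' clonotype is absent from a sample), group means and standard errors, and
#' Welch unpaired two-sided t-tests for every group pair. Groups of size 1
#' have no standard error and their pairwise tests are reported as missing.
#'
#' @param target list with `v_gene`, `j_gene`, `cdr3_aa` (gene entries may be
#'   NA in `"cdr3"` key mode) or a plain CDR3 string.
#' @param tables_by_group named list of lists of [clonotype_table()]s
#'   (>= 2 groups, each non-empty).
#' @param key clonotype identity: `"vj_cdr3"` (default) or `"cdr3"`.
#' @return list of class `group_contrast` with `summary` (data.frame `group`,
#'   `n`, `mean`, `se`), `tests` (data.frame `group1`, `group2`, `t`, `df`,
#'   `p_value`) and `frequencies` (named list of per-sample frequency
#'   vectors).
#' @export
clonotype_group_contrast <- function(target, tables_by_group,
                                     key = c("vj_cdr3", "cdr3")) {
  key <- match.arg(key)
  if (length(tables_by_group) < 2L)
    stop_validation("need at least 2 groups")
  if (any(vapply(tables_by_group, length, 0L) == 0L))
    stop_validation("every group must contain at least one sample")
  if (is.character(target)) target <- list(v_gene = NA, j_gene = NA, cdr3_aa = target)
  k <- if (key == "cdr3") target$cdr3_aa else
    clono_key(normalize_gene_name(target$v_gene),
              normalize_gene_name(target$j_gene), target$cdr3_aa)

  freqs <- lapply(tables_by_group, function(tabs)
    vapply(tabs, function(t) key_freqs(t, k, key), 0))
  summ <- data.frame(
    group = names(tables_by_group),
    n = vapply(freqs, length, 0L),
    mean = vapply(freqs, mean, 0),
    se = vapply(freqs, function(f)
      if (length(f) >= 2L) stats::sd(f) / sqrt(length(f)) else NA_real_, 0),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL

  pairs <- utils::combn(names(tables_by_group), 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    wt <- welch_test(freqs[[g1]], freqs[[g2]])
    data.frame(group1 = g1, group2 = g2, t = wt$t, df = wt$df,
               p_value = wt$p_value, stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, tests = tests, frequencies = freqs),
            class = "group_contrast")
}
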