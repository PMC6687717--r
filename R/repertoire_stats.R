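# Usage, normalization, pairing, ordination and qPCR statistics.

#' V or J gene usage of a sample
#'
#' Frequency of each gene: summed clonotype counts carrying that gene divided
#' by the sample's total reads. Entries sum to one.
#'
#' @param table a [clonotype_table()].
#' @param axis `"V"` or `"J"`.
#' @return named numeric vector of class `usage_vector` (attributes `axis`,
#'   `sample_id`, `total_reads`), sorted by gene name.
#' @export
usage_vector <- function(table, axis = c("V", "J")) {
  stopifnot(inherits(table, "clonotype_table"))
  axis <- match.arg(axis)
  gene <- if (axis == "V") table$v_gene else table$j_gene
  u <- rowsum(table$count, gene)[, 1] / total_reads(table)
  u <- u[order(names(u))]
  structure(u, axis = axis, sample_id = sample_id(table),
            total_reads = total_reads(table), class = "usage_vector")
}

#' @export
print.usage_vector <- function(x, ...) {
  cat(sprintf("<usage_vector> axis=%s sample=%s\n", attr(x, "axis"),
              attr(x, "sample_id")))
  print(round(unclass(x), 4))
  invisible(x)
}

# align a list of named vectors onto the union of names, zero-filled
align_union <- function(vecs) {
  genes <- sort(unique(unlist(lapply(vecs, names))))
  t(vapply(vecs, function(v) {
    out <- setNames(numeric(length(genes)), genes)
    out[names(v)] <- as.numeric(v)
    out
  }, numeric(length(genes))))
}

#' Fold change of gene usage relative to a control cohort
#'
#' Per-gene fold change of a sample's usage over the mean usage of a control
#' cohort (e.g., each gene normalized to the mean value of the corresponding
#' gene in healthy-donor PBMC). A pseudocount keeps fold changes finite for
#' genes unseen in controls; its default, half a read at the deepest involved
#' sample (`1 / (2 * max total_reads)`), stays below one-read resolution.
#'
#' @param sample_usage a [usage_vector()].
#' @param control_usages list of [usage_vector()]s on the same axis.
#' @param pseudocount added to numerator and denominator; `NULL` (default)
#'   uses `1/(2*max total_reads)` across the involved samples when totals are
#'   known, else 0.
#' @param scale `"linear"` or `"log10"`.
#' @return named numeric vector of class `fold_change_vector` (attributes
#'   `scale`, `pseudocount`).
#' @export
normalize_to_cohort <- function(sample_usage, control_usages,
                                pseudocount = NULL,
                                scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (length(control_usages) == 0L)
    stop_validation("control usage collection is empty")
  axes <- vapply(control_usages, attr, "", "axis")
  if (any(axes != attr(sample_usage, "axis")))
    stop_validation("axis mismatch: sample is %s, controls include %s",
                    attr(sample_usage, "axis"),
                    paste(setdiff(axes, attr(sample_usage, "axis")), collapse = ","))
  if (is.null(pseudocount)) {
    totals <- c(attr(sample_usage, "total_reads"),
                unlist(lapply(control_usages, attr, "total_reads")))
    totals <- totals[!is.na(totals)]
    pseudocount <- if (length(totals)) 1 / (2 * max(totals)) else 0
  }
  M <- align_union(c(list(unclass(sample_usage)), lapply(control_usages, unclass)))
  s <- M[1, ]
  cm <- colMeans(M[-1, , drop = FALSE])
  denom <- cm + pseudocount
  if (any(denom == 0))
    stop_validation("zero control mean for gene '%s' with pseudocount 0; supply a pseudocount",
                    names(denom)[denom == 0][1])
  fc <- (s + pseudocount) / denom
  if (scale == "log10") fc <- log10(fc)
  structure(fc, scale = scale, pseudocount = pseudocount,
            class = "fold_change_vector")
}

#' V-J pairing matrix of a sample
#'
#' Joint frequency of each (V gene, J gene) pair: summed counts of clonotypes
#' with that pair over total reads. Cells sum to one; row sums equal the V
#' usage vector and column sums the J usage vector.
#'
#' @param table a [clonotype_table()].
#' @return numeric matrix (V genes x J genes) of class `vj_pairing_matrix`.
#' @export
vj_pairing_matrix <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  vs <- sort(unique(table$v_gene)); js <- sort(unique(table$j_gene))
  M <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
  agg <- rowsum(table$count, paste(table$v_gene, table$j_gene, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  for (i in seq_along(parts))
    M[parts[[i]][1], parts[[i]][2]] <- agg[i, 1]
  structure(M / total_reads(table), class = c("vj_pairing_matrix", "matrix"))
}

#' Elementwise mean of V-J pairing matrices across a cohort
#'
#' Matrices are aligned on the union of their V and J gene axes (absent genes
#' filled with zero) before averaging; the mean still sums to one.
#'
#' @param matrices list of [vj_pairing_matrix()] results.
#' @return a `vj_pairing_matrix` of cohort mean pairing frequencies.
#' @export
cohort_mean_pairing <- function(matrices) {
  if (length(matrices) == 0L) stop_validation("empty matrix collection")
  vs <- sort(unique(unlist(lapply(matrices, rownames))))
  js <- sort(unique(unlist(lapply(matrices, colnames))))
  acc <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
  for (M in matrices) {
    A <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
    A[rownames(M), colnames(M)] <- M
    acc <- acc + A
  }
  structure(acc / length(matrices), class = c("vj_pairing_matrix", "matrix"))
}

#' PCA of gene usage across samples
#'
#' Samples-by-genes usage matrix (union of genes, zero-filled), column
#' centered and decomposed by singular value decomposition. Usage vectors are
#' compositional fractions, so no unit-variance scaling is applied.
#'
#' @param cohort_usages named list of [usage_vector()]s (names = sample ids).
#' @param k number of components to return.
#' @return list of class `pca_result` with `scores` (samples x k),
#'   `explained_variance` (length k, non-increasing), `loadings`
#'   (genes x k, orthonormal columns) and `center` (gene means).
#' @export
usage_pca <- function(cohort_usages, k = 2L) {
  if (length(cohort_usages) < 2L)
    stop_validation("usage PCA needs at least 2 samples")
  X <- align_union(lapply(cohort_usages, unclass))
  rownames(X) <- names(cohort_usages)
  kmax <- min(ncol(X), nrow(X) - 1L)
  if (k > kmax)
    stop_validation("k = %d exceeds min(genes, samples - 1) = %d", k, kmax)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  s <- svd(Xc)
  tot <- sum(s$d^2)
  ev <- if (tot > 0) s$d^2 / tot else rep(0, length(s$d))
  scores <- s$u %*% diag(s$d, nrow = length(s$d))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_along(s$d)))
  loadings <- s$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(s$d)))
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 loadings = loadings[, seq_len(k), drop = FALSE],
                 center = ctr),
            class = "pca_result")
}

#' Ranked clonotype export for treemap display
#'
#' Clonotypes sorted by descending count; area weight equals frequency. The
#' residual mass beyond `top_n` is aggregated as a single `"other"` row, so
#' that weights always sum to one.
#'
#' @param table a [clonotype_table()].
#' @param top_n number of individual clonotypes to report (>= 1).
#' @return data.frame with columns `rank`, `v_gene`, `j_gene`, `cdr3_aa`,
#'   `frequency`, `area` (`other` row has NA genes and rank NA).
#' @export
treemap_export <- function(table, top_n) {
  stopifnot(inherits(table, "clonotype_table"))
  if (top_n < 1L) stop_validation("top_n must be >= 1")
  df <- as.data.frame(table)
  df <- df[order(-df$count, df$cdr3_aa, df$v_gene, df$j_gene), ]
  top <- utils::head(df, top_n)
  out <- data.frame(rank = seq_len(nrow(top)),
                    v_gene = top$v_gene, j_gene = top$j_gene,
                    cdr3_aa = top$cdr3_aa,
                    frequency = top$frequency, area = top$frequency,
                    stringsAsFactors = FALSE)
  resid <- 1 - sum(top$frequency)
  if (nrow(df) > top_n)
    out <- rbind(out, data.frame(rank = NA_integer_, v_gene = NA_character_,
                                 j_gene = NA_character_, cdr3_aa = "other",
                                 frequency = resid, area = resid))
  rownames(out) <- NULL
  out
}

#' Clonotype/CD3 expression ratio from qPCR cycle thresholds
#'
#' Ratio model `2^(Ct_reference - Ct_target)` (the 2^-dCt rule without
#' efficiency correction), floored at the assay's detection limit of 1e-4.
#' A non-detected target (NA or the `"ND"` sentinel) maps to the floor.
#'
#' @param ct_target cycle threshold of the clonotype assay; `NA` or `"ND"`
#'   for not detected.
#' @param ct_reference cycle threshold of the CD3 reference (required).
#' @param floor detection limit of the ratio (default 1e-4).
#' @return list with `ct_target`, `ct_reference`, `ratio`, `floored`,
#'   `detected`.
#' @export
qpcr_ratio <- function(ct_target, ct_reference, floor = 1e-4) {
  if (missing(ct_reference) || is.null(ct_reference) || is.na(ct_reference))
    stop_validation("reference (CD3) Ct is required")
  nd <- is.null(ct_target) || (is.character(ct_target) && ct_target == "ND") ||
    is.na(suppressWarnings(as.numeric(ct_target)))
  if (nd) {
    return(list(ct_target = NA_real_, ct_reference = ct_reference,
                ratio = floor, floored = TRUE, detected = FALSE))
  }
  ct_target <- as.numeric(ct_target)
  ratio <- 2^(ct_reference - ct_target)
  floored <- ratio < floor
  list(ct_target = ct_target, ct_reference = ct_reference,
       ratio = max(ratio, floor), floored = floored, detected = TRUE)
}
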