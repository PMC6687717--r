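# Single-cell alpha/beta chain pairing summaries and the panel-gene
# expression matrix.

#' Default 18-gene phenotyping panel
#'
#' Genes covering cytotoxic effectors, inflammatory cytokines and T-cell
#' differentiation markers used to characterize single-cell clones.
#'
#' @return character vector of 18 gene symbols.
#' @export
default_sc_panel <- function() {
  c("GNLY", "GZMB", "PRF1", "IFNG", "TNF", "IL17A", "IL12A", "IL10",
    "RORC", "FOXP3", "TBX21", "GATA3", "CCR7", "SELL", "CD28", "PDCD1",
    "LAG3", "CTLA4")
}

#' Read a per-cell chain-call table
#'
#' Tab-separated input with columns `cell_id`, `beta_cdr3`, `alpha_cdr3`
#' (empty string or NA for a missing chain) and one numeric column per panel
#' gene. Cells lacking both chains are rejected. A rare secondary alpha chain
#' may be supplied in an `alpha2_cdr3` column; it is retained but excluded
#' from pairing percentages.
#'
#' @param path path to the TSV file.
#' @param panel optional character vector naming the panel genes; defaults
#'   to all columns beyond the chain calls.
#' @return data.frame of class `single_cell_clones` with attribute `panel`.
#' @export
read_single_cell_tsv <- function(path, panel = NULL) {
  if (!file.exists(path)) stop_format("single-cell TSV not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          encoding = "UTF-8")
  single_cell_clones(df, panel = panel)
}

#' Construct a single-cell clone table
#'
#' @param cells data.frame with `cell_id`, `beta_cdr3`, `alpha_cdr3`,
#'   optional `alpha2_cdr3`, plus numeric gene columns.
#' @param panel optional panel gene names (default: all remaining columns).
#' @return data.frame of class `single_cell_clones` with attribute `panel`.
#' @export
single_cell_clones <- function(cells, panel = NULL) {
  df <- as.data.frame(cells, stringsAsFactors = FALSE)
  need <- c("cell_id", "beta_cdr3", "alpha_cdr3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("single-cell table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop_validation("duplicated cell_id(s): %s",
                    paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  for (col in c("beta_cdr3", "alpha_cdr3"))
    df[[col]][!is.na(df[[col]]) & !nzchar(df[[col]])] <- NA_character_
  no_chain <- is.na(df$beta_cdr3) & is.na(df$alpha_cdr3)
  if (any(no_chain))
    stop_validation("cell '%s' has neither an alpha nor a beta chain call",
                    df$cell_id[no_chain][1])
  if (is.null(panel))
    panel <- setdiff(names(df), c(need, "alpha2_cdr3",
                                  grep("_call$", names(df), value = TRUE)))
  extra <- setdiff(panel, names(df))
  for (g in extra) df[[g]] <- 0   # absent genes fill 0
  if (any(vapply(df[panel], function(x) any(!is.na(x) & x < 0), TRUE)))
    stop_validation("negative expression values in the gene panel")
  structure(df, panel = panel, class = c("single_cell_clones", "data.frame"))
}

#' Summarize alpha/beta chain pairing across single cells
#'
#' Cells are grouped by beta-chain CDR3 and, within each beta clonotype, by
#' alpha-chain CDR3. Percentages are rounded half-up to two decimals. The
#' beta-level percentage is over all cells; alpha-level percentages are over
#' the cells carrying that beta clonotype (cells with a missing alpha call
#' form the per-beta remainder, so alpha percentages plus the missing
#' fraction sum to 100 within rounding).
#'
#' @param cells a [single_cell_clones()] data.frame.
#' @return list of class `pairing_summary` with `n_total`,
#'   `n_missing_alpha`, `beta_summary` (data.frame `beta_cdr3`, `n_cells`,
#'   `percent`) and `pairs` (data.frame `beta_cdr3`, `alpha_cdr3`,
#'   `n_cells`, `percent`).
#' @export
summarize_pairing <- function(cells) {
  stopifnot(inherits(cells, "single_cell_clones"))
  if (nrow(cells) == 0L) stop_validation("empty cell collection")
  n_total <- nrow(cells)
  beta <- ifelse(is.na(cells$beta_cdr3), "<missing>", cells$beta_cdr3)
  bt <- sort(table(beta), decreasing = TRUE)
  beta_summary <- data.frame(beta_cdr3 = names(bt),
                             n_cells = as.integer(bt),
                             percent = round_half_up(100 * as.integer(bt) / n_total, 2),
                             stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(names(bt), function(b) {
    sub <- cells[beta == b, ]
    n_beta <- nrow(sub)
    alpha <- sub$alpha_cdr3[!is.na(sub$alpha_cdr3)]
    if (length(alpha) == 0L) return(NULL)
    at <- sort(table(alpha), decreasing = TRUE)
    data.frame(beta_cdr3 = b, alpha_cdr3 = names(at),
               n_cells = as.integer(at),
               percent = round_half_up(100 * as.integer(at) / n_beta, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(list(n_total = n_total,
                 n_missing_alpha = sum(is.na(cells$alpha_cdr3)),
                 beta_summary = beta_summary, pairs = pairs),
            class = "pairing_summary")
}

#' @export
print.pairing_summary <- function(x, ...) {
  cat(sprintf("<pairing_summary> %d cells (%d missing alpha)\n",
              x$n_total, x$n_missing_alpha))
  print(x$pairs)
  invisible(x)
}

#' Per-cell expression matrix over a gene panel
#'
#' Cells-by-genes matrix ordered by (beta CDR3, alpha CDR3, cell id) so the
#' output is stable under permutation of the input cells. Genes absent from
#' the input are filled with zero; `log1p` transformation is optional.
#'
#' @param cells a [single_cell_clones()] data.frame.
#' @param panel ordered character vector of gene names (default: the table's
#'   panel attribute).
#' @param transform `"none"` or `"log1p"`.
#' @return numeric matrix (cells x genes) with `cell_id` rownames; attribute
#'   `"annotation"` is a data.frame (`cell_id`, `beta_cdr3`, `alpha_cdr3`)
#'   in matrix row order.
#' @export
expression_matrix <- function(cells, panel = NULL,
                              transform = c("none", "log1p")) {
  stopifnot(inherits(cells, "single_cell_clones"))
  if (is.character(transform) && !all(transform %in% c("none", "log1p")))
    stop_validation("unknown transform '%s'; use 'none' or 'log1p'", transform[1])
  transform <- match.arg(transform)
  if (is.null(panel)) panel <- attr(cells, "panel")
  if (length(panel) == 0L) stop_validation("gene panel must be non-empty")
  df <- as.data.frame(cells)
  for (g in setdiff(panel, names(df))) df[[g]] <- 0
  ord <- order(df$beta_cdr3, df$alpha_cdr3, df$cell_id, na.last = TRUE)
  df <- df[ord, ]
  M <- as.matrix(df[, panel, drop = FALSE])
  M[is.na(M)] <- 0
  rownames(M) <- df$cell_id
  if (transform == "log1p") M <- log1p(M)
  ann <- data.frame(cell_id = df$cell_id, beta_cdr3 = df$beta_cdr3,
                    alpha_cdr3 = df$alpha_cdr3, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  attr(M, "annotation") <- ann
  M
}
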