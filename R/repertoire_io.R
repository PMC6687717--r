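# Readers/writers for the formats the pipeline touches: germline FASTA,
# AIRR-style rearrangement TSV, sample sheets. All validation funnels into
# classed conditions (pubtcr_format_error / pubtcr_validation_error).

.COHORTS <- c("case", "tolerant", "healthy")
.TISSUES <- c("blister", "PBMC", "other")

## ---- germline sets ---------------------------------------------------------

#' Construct a germline segment set
#'
#' A `germline_set` holds the V and J segment references used for read
#' assignment and junction extraction. Each segment carries its nucleotide
#' sequence and the reading-frame offset (0-2) at which translation of the
#' segment yields its conserved anchor motif in frame.
#'
#' @param v,j data.frames with columns `name`, `nt_sequence`, `frame`
#'   (integer 0-2).
#' @return an object of class `germline_set`, a list with elements `v` and `j`
#'   (each a data.frame with columns `name`, `segment_class`, `nt_sequence`,
#'   `frame`).
#' @export
germline_set <- function(v, j) {
  check_seg <- function(df, cls) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    need <- c("name", "nt_sequence")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_format("germline %s table missing column(s): %s", cls,
                  paste(miss, collapse = ", "))
    if (nrow(df) < 1L)
      stop_validation("germline set needs at least one %s segment", cls)
    if (is.null(df$frame)) df$frame <- 0L
    df$frame <- as.integer(df$frame)
    if (any(is.na(df$frame)) || any(df$frame < 0L | df$frame > 2L))
      stop_validation("reading-frame offsets must be integers in 0..2")
    if (any(!nzchar(df$nt_sequence)))
      stop_validation("empty nucleotide sequence for segment '%s'",
                      df$name[!nzchar(df$nt_sequence)][1])
    bad <- !grepl("^[ACGTN]+$", df$nt_sequence)
    if (any(bad))
      stop_validation("segment '%s' has characters outside {A,C,G,T,N}",
                      df$name[bad][1])
    df$segment_class <- cls
    df <- df[, c("name", "segment_class", "nt_sequence", "frame")]
    rownames(df) <- NULL
    df
  }
  v <- check_seg(v, "V")
  j <- check_seg(j, "J")
  dup <- c(v$name, j$name)[duplicated(c(v$name, j$name))]
  if (length(dup))
    stop_validation("duplicate germline segment name(s): %s",
                    paste(unique(dup), collapse = ", "))
  structure(list(v = v, j = j), class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("<germline_set> %d V, %d J segments\n", nrow(x$v), nrow(x$j)))
  invisible(x)
}

# infer V/J class from an IMGT-style name, honoring an explicit class= tag
infer_segment_class <- function(name, explicit = NA_character_) {
  if (!is.na(explicit)) {
    if (!explicit %in% c("V", "J"))
      stop_format("segment class must be V or J, got '%s' for '%s'", explicit, name)
    return(explicit)
  }
  if (grepl("^TR[ABGD]V", name)) return("V")
  if (grepl("^TR[ABGD]J", name)) return("J")
  stop_format("cannot infer segment class from name '%s'; add a class=V|J header tag",
              name)
}

#' Read a germline segment FASTA
#'
#' Headers carry the IMGT-style segment name as first token, optionally
#' followed by `key=value` tags: `frame=<0-2>` for the reading-frame offset
#' (default 0) and `class=V|J` when the name prefix (TRBV/TRBJ/TRAV/TRAJ)
#' does not determine the class.
#'
#' @param path path to a FASTA file.
#' @return a [germline_set()].
#' @export
read_germline_fasta <- function(path) {
  if (!file.exists(path)) stop_format("germline FASTA not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop_format("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)))
  if (length(seqs) == 0L) stop_format("no records in germline FASTA '%s'", path)
  headers <- names(seqs)
  parse_one <- function(h) {
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    kv <- grep("=", toks[-1], value = TRUE)
    tags <- if (length(kv)) {
      sp <- strsplit(kv, "=", fixed = TRUE)
      setNames(vapply(sp, `[`, "", 2), vapply(sp, `[`, "", 1))
    } else c()
    name <- normalize_gene_name(toks[1])
    frame <- if ("frame" %in% names(tags)) suppressWarnings(as.integer(tags[["frame"]])) else 0L
    if (is.na(frame)) stop_format("record '%s': frame tag is not an integer", name)
    cls <- infer_segment_class(name, if ("class" %in% names(tags)) tags[["class"]] else NA_character_)
    list(name = name, frame = frame, class = cls)
  }
  meta <- lapply(headers, parse_one)
  df <- data.frame(name = vapply(meta, `[[`, "", "name"),
                   segment_class = vapply(meta, `[[`, "", "class"),
                   nt_sequence = toupper(as.character(seqs)),
                   frame = vapply(meta, `[[`, 0L, "frame"),
                   stringsAsFactors = FALSE)
  germline_set(df[df$segment_class == "V", ], df[df$segment_class == "J", ])
}

#' Write a germline set as FASTA
#'
#' @param gs a [germline_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(gs, path) {
  stopifnot(inherits(gs, "germline_set"))
  df <- rbind(gs$v, gs$j)
  lines <- as.vector(rbind(
    sprintf(">%s frame=%d class=%s", df$name, df$frame, df$segment_class),
    df$nt_sequence))
  writeLines(lines, path)
  invisible(path)
}

## ---- clonotype tables ------------------------------------------------------

#' Construct a clonotype table
#'
#' The central per-sample container: one row per unique
#' (V gene, J gene, CDR3 amino-acid) clonotype with read count and frequency.
#' Frequencies are counts over `total_reads`, which equals the column sum of
#' counts, so they always sum to one.
#'
#' @param clonotypes data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`,
#'   `count`. Rows sharing a clonotype key are merged by summing counts.
#' @param sample_id sample identifier.
#' @param sample_meta optional one-row data.frame of sample metadata
#'   (see [read_sample_sheet()]).
#' @return a data.frame of class `clonotype_table` with columns `v_gene`,
#'   `j_gene`, `cdr3_aa`, `count`, `frequency`, plus attributes `sample_id`,
#'   `total_reads` and (optionally) `sample_meta`.
#' @export
clonotype_table <- function(clonotypes, sample_id = NA_character_,
                            sample_meta = NULL) {
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  need <- c("v_gene", "j_gene", "cdr3_aa", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("clonotype table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_validation("empty_repertoire: no clonotypes")
  if (any(is.na(df$count)) || any(df$count < 0) || any(df$count != floor(df$count)))
    stop_validation("clonotype counts must be non-negative integers")
  df$v_gene <- normalize_gene_name(df$v_gene)
  df$j_gene <- normalize_gene_name(df$j_gene)
  key <- clono_key(df$v_gene, df$j_gene, df$cdr3_aa)
  if (anyDuplicated(key)) {
    agg <- rowsum(df$count, key)
    first <- !duplicated(key)
    df <- df[first, need]
    df$count <- as.numeric(agg[clono_key(df$v_gene, df$j_gene, df$cdr3_aa), 1])
  } else {
    df <- df[, need]
  }
  df <- df[df$count > 0, , drop = FALSE]
  if (nrow(df) == 0L) stop_validation("empty_repertoire: all counts are zero")
  df <- df[order(-df$count, df$v_gene, df$j_gene, df$cdr3_aa), ]
  total <- sum(df$count)
  df$frequency <- df$count / total
  rownames(df) <- NULL
  structure(df,
            class = c("clonotype_table", "data.frame"),
            sample_id = sample_id, total_reads = total,
            sample_meta = sample_meta)
}

#' Total read count of a clonotype table
#' @param table a [clonotype_table()].
#' @return integer scalar.
#' @export
total_reads <- function(table) attr(table, "total_reads")

#' Sample identifier of a clonotype table
#' @param table a [clonotype_table()].
#' @return character scalar.
#' @export
sample_id <- function(table) attr(table, "sample_id")

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> sample=%s  %d clonotypes, %s reads\n",
              sample_id(x), nrow(x), format(total_reads(x), big.mark = ",")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read an AIRR-style rearrangement TSV into a clonotype table
#'
#' Required columns: `sample_id`, `v_call`, `j_call`, `duplicate_count`, and
#' one of `cdr3_aa` (anchorless CDR3) or `junction_aa` (IMGT junction with the
#' flanking conserved C and F/W). When only `junction_aa` is present the CDR3
#' is derived by stripping the first and last residue, matching the anchorless
#' convention used throughout the package. Gene calls are normalized to gene
#' level (allele suffixes removed). Rows with identical
#' (V, J, CDR3) keys are merged by summing counts. Lines starting `#` are
#' treated as comments.
#'
#' @param path path to a tab-separated file.
#' @param sample_meta optional one-row metadata data.frame attached to the
#'   result.
#' @return a [clonotype_table()].
#' @export
read_rearrangement_tsv <- function(path, sample_meta = NULL) {
  if (!file.exists(path)) stop_format("rearrangement TSV not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", encoding = "UTF-8")
  need <- c("sample_id", "v_call", "j_call", "duplicate_count")
  miss <- setdiff(need, names(df))
  has_cdr3 <- "cdr3_aa" %in% names(df)
  has_junc <- "junction_aa" %in% names(df)
  if (!has_cdr3 && !has_junc) miss <- c(miss, "cdr3_aa|junction_aa")
  if (length(miss))
    stop_format("rearrangement TSV '%s' missing column(s): %s", path,
                paste(miss, collapse = ", "))
  if (any(is.na(df$duplicate_count)) || any(df$duplicate_count < 0))
    stop_validation("duplicate_count must be non-negative")
  cdr3 <- if (has_cdr3) df$cdr3_aa else
    substr(df$junction_aa, 2L, nchar(df$junction_aa) - 1L)
  sid <- unique(df$sample_id)
  if (length(sid) > 1L)
    stop_validation("rearrangement TSV '%s' mixes sample_ids: %s", path,
                    paste(sid, collapse = ", "))
  clonotype_table(data.frame(v_gene = df$v_call, j_gene = df$j_call,
                             cdr3_aa = cdr3, count = df$duplicate_count,
                             stringsAsFactors = FALSE),
                  sample_id = sid, sample_meta = sample_meta)
}

#' Write a clonotype table as an AIRR-style rearrangement TSV
#'
#' Emits columns `sample_id`, `v_call`, `j_call`, `cdr3_aa`,
#' `duplicate_count`, `frequency`. An optional provenance line (starting `#`)
#' can be placed before the header.
#'
#' @param table a [clonotype_table()].
#' @param path output path.
#' @param provenance optional character scalar written as a `#` comment line.
#' @return `path`, invisibly.
#' @export
write_rearrangement_tsv <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "clonotype_table"))
  out <- data.frame(sample_id = sample_id(table),
                    v_call = table$v_gene, j_call = table$j_gene,
                    cdr3_aa = table$cdr3_aa,
                    duplicate_count = table$count,
                    frequency = table$frequency,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- sample sheets ---------------------------------------------------------

#' Construct a cohort design
#'
#' @param samples data.frame with columns `sample_id`, `cohort`
#'   (case/tolerant/healthy), `phenotype`, `drug`, `tissue`
#'   (blister/PBMC/other) and optional logical `hla_flag`.
#' @return data.frame of class `cohort_design` with an added `group` column
#'   (`case_blister`, `case_PBMC`, `tolerant`, `healthy`).
#' @export
cohort_design <- function(samples) {
  df <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "phenotype", "drug", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop_validation("duplicated sample_id(s): %s", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$cohort), .COHORTS)
  if (length(bad))
    stop_validation("unknown cohort '%s'; allowed: %s", bad[1],
                    paste(.COHORTS, collapse = ", "))
  bad <- setdiff(unique(df$tissue), .TISSUES)
  if (length(bad))
    stop_validation("unknown tissue '%s'; allowed: %s", bad[1],
                    paste(.TISSUES, collapse = ", "))
  if (is.null(df$hla_flag)) df$hla_flag <- NA
  df$hla_flag <- as.logical(df$hla_flag)
  df$group <- ifelse(df$cohort == "case", paste0("case_", df$tissue), df$cohort)
  rownames(df) <- NULL
  structure(df, class = c("cohort_design", "data.frame"))
}

#' Read a tab-separated sample sheet into a cohort design
#'
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `cohort`, `phenotype`, `drug`, `tissue` and optional `hla_flag`.
#' @return a [cohort_design()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_format("sample sheet not found: %s", path)
  cohort_design(utils::read.delim(path, stringsAsFactors = FALSE,
                                  comment.char = "#", encoding = "UTF-8"))
}

#' Write a cohort design as a tab-separated sample sheet
#'
#' @param design a [cohort_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(design, path) {
  stopifnot(inherits(design, "cohort_design"))
  cols <- c("sample_id", "cohort", "phenotype", "drug", "tissue", "hla_flag")
  utils::write.table(as.data.frame(design)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
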