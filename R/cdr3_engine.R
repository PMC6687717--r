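# V/J segment assignment and CDR3 junction extraction.
#
# A TCR beta amplicon read is modelled as [3' end of a V segment][junction
# nucleotides][5' start of a J segment]. Assignment scores each germline V by
# identity of its 3'-terminal overlap with the read (anchored at a candidate
# V end position) and each J by identity of its 5'-prefix overlap (anchored at
# a candidate J start). The junction is then extracted from the V-frame
# translation: all residues strictly between the conserved C of the rightmost
# Y[YFLI]C at the V 3' end and the F/W of the leftmost [FW]GXGT in the J.

# Alignments are scored on integer-encoded sequences (utf8ToInt) with all
# candidate anchor positions evaluated at once via an index-matrix compare.

# best anchored-suffix alignment of segment 3' end against the read:
# returns c(score, end) where `end` is the 1-based read position of the last
# aligned segment base. For each candidate end e the aligned overlap is the
# read prefix window (e - w, e] against the segment's 3'-terminal w bases,
# w = min(e, segment length).
best_suffix_alignment <- function(read_int, seg_int, min_overlap) {
  L <- length(read_int); n <- length(seg_int)
  if (L < min_overlap) return(c(score = -1, end = 0))
  ends <- seq.int(min_overlap, L)
  # read position aligned to segment base i at candidate end e: e - n + i
  pos <- outer(seq_len(n), ends, function(i, e) e - n + i)
  valid <- pos >= 1L
  pos[!valid] <- 1L
  hits <- (matrix(read_int[pos], nrow = n) == seg_int) & valid
  score <- colSums(hits) / pmin(ends, n)
  best <- max(score)
  e <- max(ends[score >= best - 1e-12])  # prefer the longest V extension
  c(score = best, end = e)
}

# best anchored-prefix alignment of segment 5' start against the read:
# returns c(score, start) with `start` the 1-based read position where the
# segment begins; overlap is the read suffix [s, s + w) against the segment's
# first w bases, w = min(L - s + 1, segment length).
best_prefix_alignment <- function(read_int, seg_int, min_overlap) {
  L <- length(read_int); n <- length(seg_int)
  last_start <- L - min_overlap + 1L
  if (last_start < 1L) return(c(score = -1, start = 0))
  starts <- seq_len(last_start)
  pos <- outer(seq_len(n), starts, function(i, s) s + i - 1L)
  valid <- pos <= L
  pos[!valid] <- 1L
  hits <- (matrix(read_int[pos], nrow = n) == seg_int) & valid
  score <- colSums(hits) / pmin(L - starts + 1L, n)
  best <- max(score)
  s <- min(starts[score >= best - 1e-12])  # prefer the longest J extension
  c(score = best, start = s)
}

#' Assign germline V and J segments to a read
#'
#' The best V is chosen by anchored terminal-suffix alignment of each V
#' segment's 3' end against the read; the best J by anchored prefix alignment
#' of each J segment's 5' start. Scores are identity fractions of the aligned
#' overlap. Ties between segments are broken by lexicographically smallest
#' gene name. Reads whose best V or J score falls below `min_identity` yield
#' an `"unassigned"` outcome; a V end beyond the J start yields
#' `"incoherent"`. Neither is an error condition.
#'
#' @param read nucleotide string (or a list with `nt_sequence`).
#' @param germline a [germline_set()].
#' @param min_identity minimum identity fraction for both segment calls
#'   (default 0.9).
#' @param min_overlap minimum aligned overlap in nucleotides (default 15).
#' @return list with `v_name`, `j_name`, `v_score`, `j_score`, `v_end_nt`,
#'   `j_start_nt` (0-based half-open read coordinates: the read interval
#'   `[0, v_end_nt)` is V, `[j_start_nt, length)` is J) and
#'   `status` in `"ok"`, `"unassigned"`, `"incoherent"`.
#' @export
assign_segments <- function(read, germline, min_identity = 0.9,
                            min_overlap = 15L) {
  stopifnot(inherits(germline, "germline_set"))
  seq <- if (is.list(read)) read$nt_sequence else read
  if (nchar(seq) < 30L)
    stop_validation("read shorter than 30 nt (%d)", nchar(seq))
  rc <- utf8ToInt(toupper(seq))

  pick_best <- function(segments, aligner) {
    # segments visited in name order => first max is the lexicographic tie-break
    ord <- order(segments$name)
    best <- NULL
    for (i in ord) {
      sc <- aligner(rc, utf8ToInt(segments$nt_sequence[i]), min_overlap)
      if (is.null(best) || sc[1] > best$score + 1e-12) {
        best <- list(name = segments$name[i], score = unname(sc[1]),
                     pos = unname(sc[2]))
      }
    }
    best
  }
  v <- pick_best(germline$v, best_suffix_alignment)
  j <- pick_best(germline$j, best_prefix_alignment)

  out <- list(v_name = v$name, j_name = j$name,
              v_score = v$score, j_score = j$score,
              v_end_nt = as.integer(v$pos),          # 0-based half-open end
              j_start_nt = as.integer(j$pos) - 1L,   # 0-based start
              status = "ok")
  if (v$score < min_identity || j$score < min_identity) {
    out$status <- "unassigned"
  } else if (out$v_end_nt > out$j_start_nt) {
    out$status <- "incoherent"
  }
  out
}

#' Extract the CDR3 junction from an assigned read
#'
#' The read is translated in the frame propagated from the assigned V
#' segment's reading-frame offset. The junction comprises all amino acids
#' strictly between the conserved C of the *rightmost* `Y[YFLI]C` within the
#' translated V region (plus `slack` residues of tolerance) and the F/W of
#' the *leftmost* `[FW]GXGT` at or after that anchor — both anchor residues
#' excluded, so the reported CDR3 lacks the canonical leading cysteine.
#'
#' A junction is productive when the translated span through the J motif
#' contains no stop codon and the extracted CDR3 is non-empty and composed of
#' standard amino acids.
#'
#' @param read nucleotide string (or list with `nt_sequence`).
#' @param assignment result of [assign_segments()] with status `"ok"`.
#' @param germline the [germline_set()] used for assignment.
#' @param slack residues of tolerance past the estimated V region when
#'   searching for the V anchor (default 2).
#' @return list with `cdr3_aa`, `productive`, `frame_offset` (0-2 offset into
#'   the read at which translation started) and `status` in `"ok"`,
#'   `"no_v_motif"`, `"no_j_motif"`, `"empty_cdr3"`.
#' @export
extract_cdr3 <- function(read, assignment, germline, slack = 2L) {
  stopifnot(inherits(germline, "germline_set"))
  if (!identical(assignment$status, "ok"))
    stop_validation("cannot extract CDR3 from a read with assignment status '%s'",
                    assignment$status)
  seq <- toupper(if (is.list(read)) read$nt_sequence else read)
  vrow <- germline$v[germline$v$name == assignment$v_name, ]
  if (nrow(vrow) != 1L)
    stop_validation("assigned V segment '%s' not in germline set", assignment$v_name)
  nv <- nchar(vrow$nt_sequence)
  f <- vrow$frame
  e <- assignment$v_end_nt  # read prefix of length e is V-derived

  # codon starts of the V segment sit at segment offsets f, f+3, ...;
  # read position p (1-based) maps to segment offset p - 1 + (nv - e).
  p0 <- ((f + e - nv) %% 3L) + 1L
  aa <- translate_nt(substr(seq, p0, nchar(seq)))
  if (!nzchar(aa))
    return(list(cdr3_aa = NA_character_, productive = FALSE,
                frame_offset = p0 - 1L, status = "no_v_motif"))

  # residues whose codon starts within the V span, plus slack
  v_aa_end <- max(0L, (e - p0) %/% 3L + 1L)
  window_end <- min(nchar(aa), v_aa_end + slack)
  if (window_end < 3L)
    return(list(cdr3_aa = NA_character_, productive = FALSE,
                frame_offset = p0 - 1L, status = "no_v_motif"))
  vm <- gregexpr(.V_MOTIF, substr(aa, 1L, window_end))[[1]]
  if (vm[1] == -1L)
    return(list(cdr3_aa = NA_character_, productive = FALSE,
                frame_offset = p0 - 1L, status = "no_v_motif"))
  anchor_c <- vm[length(vm)] + 2L  # position of the conserved C

  jm <- regexpr(.J_MOTIF, substr(aa, anchor_c + 1L, nchar(aa)))
  if (jm[1] == -1L)
    return(list(cdr3_aa = NA_character_, productive = FALSE,
                frame_offset = p0 - 1L, status = "no_j_motif"))
  j_anchor <- anchor_c + jm[1]  # position of the F/W

  cdr3 <- substr(aa, anchor_c + 1L, j_anchor - 1L)
  if (!nzchar(cdr3))
    return(list(cdr3_aa = "", productive = FALSE,
                frame_offset = p0 - 1L, status = "empty_cdr3"))
  span <- substr(aa, 1L, min(nchar(aa), j_anchor + 4L))
  productive <- !grepl("*", span, fixed = TRUE) &&
    grepl(sprintf("^[%s]+$", paste(.AA20, collapse = "")), cdr3)
  list(cdr3_aa = cdr3, productive = productive,
       frame_offset = p0 - 1L, status = "ok")
}

#' Build a clonotype table from reads
#'
#' Runs [assign_segments()] and [extract_cdr3()] on every read, aggregates
#' productive junctions by (V gene, J gene, CDR3), and computes frequencies
#' over the productive assigned reads (the denominator convention: frequencies
#' are fractions of reported TCR reads, not of raw input reads). Identical
#' read sequences are processed once. Per-read outcomes are preserved in the
#' `"read_outcomes"` attribute, so that
#' productive + nonproductive + unassigned/incoherent/motif failures equals
#' the number of input reads.
#'
#' @param reads a named character vector, `Biostrings::DNAStringSet`, or
#'   data.frame with columns `read_id`, `nt_sequence`.
#' @param germline a [germline_set()].
#' @param sample_meta optional one-row metadata data.frame; its `sample_id`
#'   is used when present.
#' @param min_identity minimum identity for segment assignment (default 0.9).
#' @return a [clonotype_table()]; attribute `"read_outcomes"` holds a
#'   data.frame (`read_id`, `outcome`, `v_gene`, `j_gene`, `cdr3_aa`).
#' @export
build_clonotype_table <- function(reads, germline, sample_meta = NULL,
                                  min_identity = 0.9) {
  if (inherits(reads, "XStringSet")) {
    ids <- names(reads); seqs <- as.character(reads)
  } else if (is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- reads$nt_sequence
  } else {
    ids <- names(reads); seqs <- unname(unlist(reads))
  }
  if (length(seqs) == 0L) stop_validation("empty read collection")
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))

  uniq <- unique(seqs)
  res <- lapply(uniq, function(s) {
    asg <- assign_segments(s, germline, min_identity = min_identity)
    if (asg$status != "ok")
      return(list(outcome = asg$status, v = NA_character_, j = NA_character_,
                  cdr3 = NA_character_))
    ext <- extract_cdr3(s, asg, germline)
    if (ext$status != "ok")
      return(list(outcome = ext$status, v = asg$v_name, j = asg$j_name,
                  cdr3 = NA_character_))
    list(outcome = if (ext$productive) "productive" else "nonproductive",
         v = asg$v_name, j = asg$j_name, cdr3 = ext$cdr3_aa)
  })
  idx <- match(seqs, uniq)
  outcomes <- data.frame(
    read_id = ids,
    outcome = vapply(res, `[[`, "", "outcome")[idx],
    v_gene = vapply(res, `[[`, "", "v")[idx],
    j_gene = vapply(res, `[[`, "", "j")[idx],
    cdr3_aa = vapply(res, `[[`, "", "cdr3")[idx],
    stringsAsFactors = FALSE)

  prod <- outcomes[outcomes$outcome == "productive", ]
  if (nrow(prod) == 0L) stop_validation("empty_repertoire: no productive reads")
  key <- clono_key(prod$v_gene, prod$j_gene, prod$cdr3_aa)
  agg <- rowsum(rep(1L, nrow(prod)), key)
  first <- prod[!duplicated(key), ]
  tab <- clonotype_table(
    data.frame(v_gene = first$v_gene, j_gene = first$j_gene,
               cdr3_aa = first$cdr3_aa,
               count = as.integer(agg[clono_key(first$v_gene, first$j_gene,
                                                first$cdr3_aa), 1]),
               stringsAsFactors = FALSE),
    sample_id = if (!is.null(sample_meta)) sample_meta$sample_id else NA_character_,
    sample_meta = sample_meta)
  attr(tab, "read_outcomes") <- outcomes
  tab
}
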