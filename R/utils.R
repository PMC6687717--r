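# Shared internal helpers: condition constructors, rounding, gene-name
# normalization, amino-acid alphabet, deterministic codon choices.

# the 20 standard amino acids
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# conserved junction anchors (amino-acid regular expressions)
.V_MOTIF <- "Y[YFLI]C"
.J_MOTIF <- "[FW]G.GT"

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pubtcr_validation_error", "pubtcr_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pubtcr_format_error", "pubtcr_error", "error")))
}

#' Round half up
#'
#' Deterministic half-up rounding (`round()` in R rounds half to even);
#' used wherever printed-precision percentages are reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(3.995, 2.5, 83.333), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against values like 4284.99999999 from fp division
  floor(x * m + 0.5 + 1e-9) / m
}

#' Normalize gene names to IMGT gene level
#'
#' Strips allele suffixes (`*01`), converts en/em dashes to ASCII hyphens and
#' trims whitespace, so that usage statistics aggregate at gene level
#' (`TRBV12-4`, not `TRBV12-4*01`).
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @examples
#' normalize_gene_name(c("TRBV12-4*01", "TRBJ2–2"))
#' @export
normalize_gene_name <- function(x) {
  x <- gsub("–|—", "-", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

# Hamming distance between two equal-length strings; Inf when lengths differ.
hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Deterministic reverse codon table: for every amino acid the alphabetically
# first codon of the standard genetic code. Memoised at first use.
.codon_env <- new.env(parent = emptyenv())

first_codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- sort(names(gc))
    .codon_env$tab <- vapply(split(codons, unname(gc[codons])), `[`, "", 1)
  }
  .codon_env$tab
}

# Encode an amino-acid string as nucleotides using the fixed codon table.
aa_to_nt <- function(aa) {
  if (!nzchar(aa)) return("")
  tab <- first_codon_table()
  chars <- strsplit(aa, "")[[1]]
  bad <- setdiff(chars, names(tab))
  if (length(bad))
    stop_validation("cannot encode amino acid(s): %s", paste(unique(bad), collapse = ", "))
  paste(tab[chars], collapse = "")
}

# Translate a nucleotide string (length need not be a multiple of 3; trailing
# partial codon is dropped). Ambiguous codons become "X". Plain lookup into
# the standard genetic code: called once per read, so kept free of S4
# dispatch overhead.
translate_nt <- function(nt) {
  n <- 3L * (nchar(nt) %/% 3L)
  if (n == 0L) return("")
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[substring(nt, seq.int(1L, n, 3L), seq.int(3L, n, 3L))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# key <-> fields for clonotype identity
clono_key <- function(v, j, cdr3, mode = c("vj_cdr3", "cdr3")) {
  mode <- match.arg(mode)
  if (mode == "cdr3") cdr3 else paste(v, j, cdr3, sep = "|")
}
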