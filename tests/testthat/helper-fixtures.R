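# Fixtures are built in code. The printed-count fixture reproduces the seven
# case samples' ASSLAGELF read counts and library totals; filler clonotypes
# absorb the remaining reads.

assla_counts <- function() {
  data.frame(
    case = paste0("case", 1:7),
    count = c(27829, 153620, 5411, 31148, 143248, 13273, 31881),
    total = c(746406, 792164, 81449, 72692, 822649, 1229012, 798017),
    printed_pct = c(3.73, 19.39, 6.64, 42.85, 17.41, 1.08, 4.00))
}

# AIRR-style rearrangement data.frame for one printed case: the public
# clonotype plus two case-private filler clonotypes summing to the library
# total (private fillers keep the shared clonotype unique to the fixture).
assla_rearrangement_df <- function(case_row) {
  rest <- case_row$total - case_row$count
  tag <- sub("case", "", case_row$case)
  data.frame(
    sample_id = case_row$case,
    v_call = c("TRBV12-4", "TRBV27", "TRBV6-1"),
    j_call = c("TRBJ2-2", "TRBJ2-7", "TRBJ1-3"),
    cdr3_aa = c("ASSLAGELF",
                paste0("ASSLSQYEQYAA", strrep("A", as.integer(tag))),
                paste0("ASSLSDTIYAA", strrep("C", as.integer(tag)))),
    duplicate_count = c(case_row$count, floor(rest / 2), rest - floor(rest / 2)),
    stringsAsFactors = FALSE)
}

assla_tables <- function() {
  rows <- assla_counts()
  lapply(seq_len(nrow(rows)), function(i) {
    df <- assla_rearrangement_df(rows[i, ])
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    on.exit(unlink(path))
    read_rearrangement_tsv(path)
  })
}

tiny_germline <- function(seed = 42) simulate_germline(seed, n_v = 5, n_j = 3)

# read with a planted junction: V 3' suffix + CDR3 codons + J 5' prefix
planted_read <- function(germline, v_name, j_name, cdr3,
                         v_suffix = 60L, j_prefix = 24L) {
  v <- germline$v$nt_sequence[germline$v$name == v_name]
  j <- germline$j$nt_sequence[germline$j$name == j_name]
  paste0(substr(v, max(1L, nchar(v) - v_suffix + 1L), nchar(v)),
         pubtcr:::aa_to_nt(cdr3), substr(j, 1L, j_prefix))
}

# random clonotype table for oracle tests
random_table <- function(seed, n = 30, sample_id = "S") {
  set.seed(seed)
  cdr3 <- pubtcr:::sample_background_cdr3s(n)
  clonotype_table(data.frame(
    v_gene = sample(paste0("TRBV", 1:6), n, replace = TRUE),
    j_gene = sample(paste0("TRBJ", 1:3), n, replace = TRUE),
    cdr3_aa = cdr3,
    count = sample(1:50, n, replace = TRUE)), sample_id = sample_id)
}

# small control table lacking a given clonotype
filler_table <- function(seed, sample_id = "ctrl", n = 20) {
  random_table(seed, n = n, sample_id = sample_id)
}
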