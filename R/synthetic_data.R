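# Seedable synthetic cohorts: germline segments whose anchors are guaranteed
# by construction, repertoires with planted spike-in clonotypes over a
# heavy-tailed background, sample sheets, and single-cell fixtures. Every
# generated object carries its exact ground truth.

#' Simulation configuration
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param n_background number of background clonotypes per sample.
#' @param abundance background abundance model: `list(model = "lognormal",
#'   meanlog =, sdlog =)` or `list(model = "power_law", alpha =)`.
#' @param depth reads per sample (>= 100).
#' @param spikes data.frame of planted clonotypes with columns `group`,
#'   `v_gene`, `j_gene`, `cdr3_aa`, `freq`, and optional `sample_id` for
#'   per-sample frequencies (overrides the group row for that sample).
#' @param usage_skew named list: group label -> named numeric vector of
#'   per-gene sampling-weight multipliers applied to the uniform gene
#'   weights when assigning V/J genes to background clonotypes.
#' @param error_rate per-base substitution probability for read-level output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_background = 20000L,
                       abundance = list(model = "lognormal", meanlog = 0, sdlog = 1),
                       depth = 1e5, spikes = NULL, usage_skew = NULL,
                       error_rate = 0) {
  if (depth < 100) stop_validation("depth must be >= 100")
  if (!abundance$model %in% c("lognormal", "power_law"))
    stop_validation("unknown abundance model '%s'", abundance$model)
  if (error_rate < 0 || error_rate > 1)
    stop_validation("error_rate must lie in [0, 1]")
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
    need <- c("group", "v_gene", "j_gene", "cdr3_aa", "freq")
    miss <- setdiff(need, names(spikes))
    if (length(miss))
      stop_format("spikes missing column(s): %s", paste(miss, collapse = ", "))
    if (is.null(spikes$sample_id)) spikes$sample_id <- NA_character_
    tot <- tapply(spikes$freq,
                  ifelse(is.na(spikes$sample_id), spikes$group, spikes$sample_id),
                  sum)
    if (any(tot >= 1))
      stop_validation("spike frequencies for '%s' sum to >= 1",
                      names(tot)[tot >= 1][1])
  }
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 abundance = abundance, depth = depth, spikes = spikes,
                 usage_skew = usage_skew, error_rate = error_rate),
            class = "sim_config")
}

#' Simulate a germline segment set
#'
#' V segments end, in frame 0, with a `Y[YFLI]C`-encoding suffix; J segments
#' begin with a `[FW]GXGT`-encoding prefix, so junction extraction on any
#' planted read can never fail for motif reasons. The first V/J pair can be
#' given the real gene names TRBV12-4 / TRBJ2-2 as aliases; remaining
#' segments are named `TRBV-sim-i` / `TRBJ-sim-j`.
#'
#' @param seed integer seed.
#' @param n_v,n_j numbers of V and J segments (>= 1).
#' @param include_aliases name the first V/J pair TRBV12-4/TRBJ2-2
#'   (default TRUE).
#' @return a [germline_set()].
#' @export
simulate_germline <- function(seed = 1L, n_v = 12L, n_j = 6L,
                              include_aliases = TRUE) {
  if (n_v < 1L || n_j < 1L) stop_validation("n_v and n_j must be >= 1")
  set.seed(seed)
  rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")
  v_seqs <- vapply(seq_len(n_v), function(i) {
    core <- rand_aa(20L)
    aa_to_nt(paste0(core, "Y", sample(c("Y", "F", "L", "I"), 1L), "C"))
  }, "")
  j_seqs <- vapply(seq_len(n_j), function(i) {
    x <- sample(setdiff(.AA20, c("T")), 1L)  # X of the motif; avoid FG(T)GT repeats
    aa_to_nt(paste0(sample(c("F", "W"), 1L), "G", x, "GT", rand_aa(8L)))
  }, "")
  v_names <- sprintf("TRBV-sim-%02d", seq_len(n_v))
  j_names <- sprintf("TRBJ-sim-%02d", seq_len(n_j))
  if (include_aliases) { v_names[1] <- "TRBV12-4"; j_names[1] <- "TRBJ2-2" }
  germline_set(data.frame(name = v_names, nt_sequence = v_seqs, frame = 0L,
                          stringsAsFactors = FALSE),
               data.frame(name = j_names, nt_sequence = j_seqs, frame = 0L,
                          stringsAsFactors = FALSE))
}

# Batch sampler of background CDR3 peptides (lengths 8-17). Rejects
# sequences that could interfere with anchored extraction or clustering:
# anything containing an F/W followed by G (spurious J anchor risk), a
# Y[YFLI]C match (spurious V anchor), or lying within Hamming distance 1 of
# an excluded (spiked) sequence of equal length.
sample_background_cdr3s <- function(n, exclude = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    guard <- guard + 1L
    m <- ceiling((n - length(out)) * 1.4) + 10L
    lens <- sample(8:17, m, replace = TRUE)
    # batch generation: one letter matrix per candidate length
    cand <- unlist(lapply(unique(lens), function(L) {
      k <- sum(lens == L)
      do.call(paste0, as.data.frame(matrix(sample(.AA20, k * L, replace = TRUE),
                                           k, L), stringsAsFactors = FALSE))
    }), use.names = FALSE)
    ok <- !grepl("[FW]G", cand) & !grepl(.V_MOTIF, cand)
    cand <- cand[ok]
    for (e in unique(exclude)) {  # drop near-spike candidates, vectorized per length
      idx <- which(nchar(cand) == nchar(e))
      if (!length(idx)) next
      ech <- strsplit(e, "")[[1]]
      mm <- colSums(matrix(unlist(strsplit(cand[idx], ""), use.names = FALSE),
                           nrow = nchar(e)) != ech)
      if (any(mm <= 1)) cand <- cand[-idx[mm <= 1]]
    }
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# gene sampling probabilities: uniform weights times per-gene multipliers
skewed_gene_probs <- function(genes, skew) {
  w <- setNames(rep(1, length(genes)), genes)
  if (!is.null(skew)) {
    hit <- intersect(names(skew), genes)
    w[hit] <- w[hit] * skew[hit]
  }
  w / sum(w)
}

#' Skew multiplier reaching a target background gene share
#'
#' With `n_genes` genes at uniform weight 1 and one gene at multiplier `m`,
#' that gene's sampling probability is `m / (m + n_genes - 1)`; this inverts
#' the relation to reach a target probability `q`.
#'
#' @param q target background share of the gene, in (0, 1).
#' @param n_genes number of genes on the axis.
#' @return the multiplier `m`.
#' @export
skew_multiplier <- function(q, n_genes) {
  if (q <= 0 || q >= 1) stop_validation("target share must lie in (0, 1)")
  (n_genes - 1) * q / (1 - q)
}

#' Simulate one sample's repertoire
#'
#' Spike-in clonotypes receive fixed counts `round_half_up(freq * depth)`;
#' the remaining depth is drawn multinomially over the background clonotypes
#' with abundance-model weights. At `level = "reads"` each clonotype is
#' materialized as reads of the form V 3' suffix + junction nucleotides
#' (fixed codon encoding of the CDR3) + J 5' prefix, with independent
#' per-base substitution errors at `error_rate`.
#'
#' @param config a [sim_config()].
#' @param sample_meta one-row data.frame (a [cohort_design()] row).
#' @param germline a [germline_set()] from [simulate_germline()].
#' @param level `"counts"` (clonotype table only, default) or `"reads"`.
#' @param seed sample-level seed (default: the config seed).
#' @param v_suffix_nt,j_prefix_nt lengths of the V/J read windows.
#' @return list with `table` (a [clonotype_table()]), `truth` (data.frame
#'   `v_gene`, `j_gene`, `cdr3_aa`, `count`, `origin` = spike/background;
#'   counts sum to `depth`), `sample_meta`, and `reads`
#'   (`Biostrings::DNAStringSet`, reads level only).
#' @export
simulate_repertoire <- function(config, sample_meta, germline,
                                level = c("counts", "reads"),
                                seed = config$seed,
                                v_suffix_nt = 60L, j_prefix_nt = 24L) {
  stopifnot(inherits(config, "sim_config"), inherits(germline, "germline_set"))
  level <- match.arg(level)
  set.seed(seed)
  sm <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  grp <- if (!is.null(sm$group)) sm$group else
    ifelse(sm$cohort == "case", paste0("case_", sm$tissue), sm$cohort)

  sp <- config$spikes
  if (!is.null(sp)) {
    sp <- sp[(!is.na(sp$sample_id) & sp$sample_id == sm$sample_id) |
               (is.na(sp$sample_id) & sp$group == grp), , drop = FALSE]
  }
  if (is.null(sp)) sp <- data.frame()
  spike_counts <- if (nrow(sp)) round_half_up(sp$freq * config$depth) else numeric(0)

  n_bg <- config$n_background
  bg_cdr3 <- sample_background_cdr3s(n_bg, exclude = if (nrow(sp)) sp$cdr3_aa else character())
  skew <- if (!is.null(config$usage_skew)) config$usage_skew[[grp]] else NULL
  bg_v <- sample(germline$v$name, n_bg, replace = TRUE,
                 prob = skewed_gene_probs(germline$v$name, skew))
  bg_j <- sample(germline$j$name, n_bg, replace = TRUE,
                 prob = skewed_gene_probs(germline$j$name, skew))
  w <- switch(config$abundance$model,
              lognormal = stats::rlnorm(n_bg, config$abundance$meanlog,
                                        config$abundance$sdlog),
              power_law = sample(seq_len(n_bg))^(-config$abundance$alpha))
  n_bg_reads <- config$depth - sum(spike_counts)
  if (n_bg_reads < 0) stop_validation("spike counts exceed depth")
  bg_counts <- as.numeric(stats::rmultinom(1L, n_bg_reads, w))

  truth <- rbind(
    if (nrow(sp)) data.frame(v_gene = sp$v_gene, j_gene = sp$j_gene,
                             cdr3_aa = sp$cdr3_aa, count = spike_counts,
                             origin = "spike", stringsAsFactors = FALSE),
    data.frame(v_gene = bg_v, j_gene = bg_j, cdr3_aa = bg_cdr3,
               count = bg_counts, origin = "background",
               stringsAsFactors = FALSE))
  tab <- clonotype_table(truth[truth$count > 0, c("v_gene", "j_gene", "cdr3_aa", "count")],
                         sample_id = sm$sample_id, sample_meta = sm)
  out <- list(table = tab, truth = truth, sample_meta = sm)

  if (level == "reads") {
    obs <- truth[truth$count > 0, ]
    vseq <- setNames(germline$v$nt_sequence, germline$v$name)
    jseq <- setNames(germline$j$nt_sequence, germline$j$name)
    proto <- vapply(seq_len(nrow(obs)), function(i) {
      v <- vseq[[obs$v_gene[i]]]
      paste0(substr(v, max(1L, nchar(v) - v_suffix_nt + 1L), nchar(v)),
             aa_to_nt(obs$cdr3_aa[i]),
             substr(jseq[[obs$j_gene[i]]], 1L, j_prefix_nt))
    }, "")
    seqs <- rep(proto, obs$count)
    if (config$error_rate > 0) {
      chars <- strsplit(seqs, "")
      seqs <- vapply(chars, function(ch) {
        hit <- which(stats::runif(length(ch)) < config$error_rate)
        if (length(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
      }, "")
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("%s_r%06d", sm$sample_id, seq_along(seqs))
    out$reads <- reads
  }
  out
}

#' Simulate a full cohort
#'
#' Runs [simulate_repertoire()] for every sample of a design with
#' group-specific usage skew and spike frequencies, deriving one
#' deterministic sub-seed per sample from the config seed. When `dir` is
#' given, writes per-sample FASTA (reads level) or rearrangement TSVs
#' (counts level), the sample sheet, the germline FASTA and a truth TSV.
#'
#' @param config a [sim_config()].
#' @param design a [cohort_design()].
#' @param germline a [germline_set()]; default [simulate_germline()] from
#'   the config seed.
#' @param level `"counts"` (default) or `"reads"`.
#' @param dir optional output directory.
#' @return list of class `sim_cohort` with `tables` (named list of
#'   [clonotype_table()]s), `truths` (named list), `reads` (named list,
#'   reads level only), `germline`, `design`, `config`.
#' @export
simulate_cohort <- function(config, design, germline = NULL,
                            level = c("counts", "reads"), dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "cohort_design"))
  level <- match.arg(level)
  if (is.null(germline)) germline <- simulate_germline(config$seed)
  sims <- lapply(seq_len(nrow(design)), function(i)
    simulate_repertoire(config, design[i, ], germline, level = level,
                        seed = (config$seed + 7919L * i) %% 2147483647L))
  ids <- design$sample_id
  out <- structure(list(
    tables = setNames(lapply(sims, `[[`, "table"), ids),
    truths = setNames(lapply(sims, `[[`, "truth"), ids),
    reads = if (level == "reads") setNames(lapply(sims, `[[`, "reads"), ids),
    germline = germline, design = design, config = config),
    class = "sim_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_germline_fasta(germline, file.path(dir, "germline.fasta"))
    write_sample_sheet(design, file.path(dir, "samples.tsv"))
    truth_all <- do.call(rbind, lapply(ids, function(s)
      cbind(sample_id = s, out$truths[[s]])))
    utils::write.table(truth_all, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (s in ids) {
      if (level == "reads") {
        Biostrings::writeXStringSet(out$reads[[s]],
                                    file.path(dir, paste0(s, ".fasta")))
      } else {
        write_rearrangement_tsv(out$tables[[s]],
                                file.path(dir, paste0(s, ".tsv")))
      }
    }
  }
  out
}

#' Study-like cohort design
#'
#' The default design mirrors the reference study layout: 7 blister-cell
#' case samples, 11 case PBMC samples, 12 drug-tolerant PBMC controls and
#' 44 healthy-donor PBMC samples. HLA carrier flags are set for all cases,
#' half the tolerant controls, and 4/44 healthy donors (a ~9% phenotype
#' frequency).
#'
#' @param n_blister,n_case_pbmc,n_tolerant,n_healthy group sizes.
#' @return a [cohort_design()].
#' @export
paper_like_design <- function(n_blister = 7L, n_case_pbmc = 11L,
                              n_tolerant = 12L, n_healthy = 44L) {
  mk <- function(prefix, n, cohort, phenotype, drug, tissue, hla) {
    if (n == 0L) return(NULL)
    data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
               cohort = cohort, phenotype = phenotype, drug = drug,
               tissue = tissue, hla_flag = hla, stringsAsFactors = FALSE)
  }
  cohort_design(rbind(
    mk("BC", n_blister, "case", "SJS/TEN", "CBZ", "blister", TRUE),
    mk("PB", n_case_pbmc, "case", "SJS/TEN", "CBZ", "PBMC", TRUE),
    mk("TC", n_tolerant, "tolerant", "tolerant", "CBZ", "PBMC",
       rep(c(TRUE, FALSE), length.out = n_tolerant)),
    mk("HD", n_healthy, "healthy", "healthy", "none", "PBMC",
       rep(c(TRUE, FALSE), length.out = n_healthy) &
         seq_len(n_healthy) <= 8L)))
}

#' Study-like simulation preset
#'
#' Plants the public clonotype ASSLAGELF (TRBV12-4/TRBJ2-2) at the seven
#' per-case blister frequencies 3.73, 19.39, 6.64, 42.85, 17.41, 1.08 and
#' 4.00 percent, and at 1.31 percent in case PBMC; controls carry no spike.
#' Background V/J gene skews are derived from cohort-mean usage targets
#' (blister TRBV12-4 31.62 percent and TRBJ2-2 22.15 percent, case PBMC
#' TRBV12-4 4.95 percent, tolerant 0.69 percent) after subtracting the spike
#' contribution, via [skew_multiplier()].
#'
#' @param seed integer master seed.
#' @param depth reads per sample.
#' @param n_background background clonotypes per sample.
#' @param error_rate per-base substitution probability.
#' @param n_v,n_j germline sizes (the first V/J are TRBV12-4/TRBJ2-2).
#' @param design a [cohort_design()]; default [paper_like_design()].
#' @return list with `config` (a [sim_config()]), `design`, and the spike
#'   key as `public_key` (list `v_gene`, `j_gene`, `cdr3_aa`).
#' @export
paper_like_config <- function(seed = 1L, depth = 1e5, n_background = 20000L,
                              error_rate = 0, n_v = 12L, n_j = 6L,
                              design = paper_like_design()) {
  blister_ids <- design$sample_id[design$group == "case_blister"]
  blister_freq <- c(0.0373, 0.1939, 0.0664, 0.4285, 0.1741, 0.0108, 0.0400)
  if (length(blister_ids) > length(blister_freq))
    blister_freq <- rep_len(blister_freq, length(blister_ids))
  blister_freq <- blister_freq[seq_along(blister_ids)]
  spikes <- rbind(
    data.frame(group = "case_blister", sample_id = blister_ids,
               v_gene = "TRBV12-4", j_gene = "TRBJ2-2",
               cdr3_aa = "ASSLAGELF", freq = blister_freq,
               stringsAsFactors = FALSE),
    if (any(design$group == "case_PBMC"))
      data.frame(group = "case_PBMC", sample_id = NA_character_,
                 v_gene = "TRBV12-4", j_gene = "TRBJ2-2",
                 cdr3_aa = "ASSLAGELF", freq = 0.0131,
                 stringsAsFactors = FALSE))

  # background gene shares q solve: target = mean(spike) + (1 - mean(spike)) q
  mean_bl <- mean(blister_freq)
  q_bl_v <- (0.3162 - mean_bl) / (1 - mean_bl)
  q_bl_j <- (0.2215 - mean_bl) / (1 - mean_bl)
  q_pb_v <- (0.0495 - 0.0131) / (1 - 0.0131)
  q_tc_v <- 0.0069
  usage_skew <- list(
    case_blister = c("TRBV12-4" = skew_multiplier(q_bl_v, n_v),
                     "TRBJ2-2" = skew_multiplier(q_bl_j, n_j)),
    case_PBMC = c("TRBV12-4" = skew_multiplier(q_pb_v, n_v)),
    tolerant = c("TRBV12-4" = skew_multiplier(q_tc_v, n_v)))

  list(config = sim_config(seed = seed, n_background = n_background,
                           depth = depth, spikes = spikes,
                           usage_skew = usage_skew, error_rate = error_rate),
       design = design,
       public_key = list(v_gene = "TRBV12-4", j_gene = "TRBJ2-2",
                         cdr3_aa = "ASSLAGELF"))
}

#' Simulate single-cell clones with a fixed pairing profile
#'
#' Every cell carries the given beta CDR3; alpha CDR3s follow the pairing
#' profile exactly (the default mirrors a 25/4/1 split over 30 cells).
#' Panel-gene expression is drawn per gene from a negative binomial, with a
#' planted elevation for the cytotoxic effectors GNLY and GZMB.
#'
#' @param seed integer seed.
#' @param n_cells number of cells.
#' @param beta_cdr3 the shared beta-chain CDR3.
#' @param pairing_profile named integer vector alpha CDR3 -> cell count;
#'   must sum to at most `n_cells` (any remainder becomes cells with a
#'   missing alpha call).
#' @param panel gene panel (default [default_sc_panel()]).
#' @param elevated genes with elevated expression.
#' @param mu_base,mu_elevated,nb_size negative-binomial parameters.
#' @return a [single_cell_clones()] data.frame; attribute `"truth"` records
#'   the profile and elevated genes.
#' @export
simulate_single_cells <- function(seed = 1L, n_cells = 30L,
                                  beta_cdr3 = "ASSLAGELF",
                                  pairing_profile = c(VFDNTDKLI = 25L,
                                                      AASPPDGNQFY = 4L,
                                                      ALDIPNFGNEKLT = 1L),
                                  panel = default_sc_panel(),
                                  elevated = c("GNLY", "GZMB"),
                                  mu_base = 5, mu_elevated = 50,
                                  nb_size = 2) {
  if (sum(pairing_profile) > n_cells)
    stop_validation("pairing profile counts (%d) exceed n_cells (%d)",
                    sum(pairing_profile), n_cells)
  set.seed(seed)
  alpha <- c(rep(names(pairing_profile), pairing_profile),
             rep(NA_character_, n_cells - sum(pairing_profile)))
  df <- data.frame(cell_id = sprintf("cell%02d", seq_len(n_cells)),
                   beta_cdr3 = beta_cdr3, alpha_cdr3 = alpha,
                   stringsAsFactors = FALSE)
  for (g in panel) {
    mu <- if (g %in% elevated) mu_elevated else mu_base
    df[[g]] <- stats::rnbinom(n_cells, size = nb_size, mu = mu)
  }
  out <- single_cell_clones(df, panel = panel)
  attr(out, "truth") <- list(beta_cdr3 = beta_cdr3,
                             pairing_profile = pairing_profile,
                             elevated = elevated)
  out
}
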