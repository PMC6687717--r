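# One-shot orchestration: ingest germline + sample sheet + per-sample reads,
# extract clonotypes, compute usage/pairing/PCA statistics, detect public
# clonotypes and the one-residue cluster around the top hit. Every output TSV
# carries a provenance comment line (config hash + seed).

#' Assemble or load a pipeline configuration
#'
#' Either pass a list of settings, or a path to a flat `key=value` text file
#' (one pair per line, `#` comments allowed); explicit arguments in `...`
#' override file values. Required keys: `germline`, `reads_dir` (directory
#' containing one `<sample_id>.fasta` per sample), `sample_sheet`,
#' `out_dir`. Optional keys with defaults: `min_identity` 0.9,
#' `min_case_fraction` 1, `min_case_freq` 0.01, `max_control_freq` 1e-5,
#' `pca_k` 2, `seed` 1, `cluster_seed` (CDR3 string; default: top public
#' clonotype).
#'
#' @param x list of settings or path to a key=value file.
#' @param ... overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list(), ...) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop_format("config file not found: %s", x)
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
    setNames(vals, trimws(vapply(kv, `[`, "", 1)))
  } else as.list(x)
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(min_identity = 0.9, min_case_fraction = 1,
                   min_case_freq = 0.01, max_control_freq = 1e-5,
                   pca_k = 2, seed = 1, cluster_seed = NA_character_)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("min_identity", "min_case_fraction", "min_case_freq",
              "max_control_freq", "pca_k", "seed"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  need <- c("germline", "reads_dir", "sample_sheet", "out_dir")
  miss <- need[!vapply(need, function(k) !is.null(cfg[[k]]), TRUE)]
  if (length(miss))
    stop_validation("pipeline config missing: %s", paste(miss, collapse = ", "))
  if (cfg$min_identity < 0 || cfg$min_identity > 1 ||
      cfg$min_case_freq < 0 || cfg$min_case_freq > 1 ||
      cfg$max_control_freq < 0 || cfg$max_control_freq > 1)
    stop_validation("pipeline thresholds must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

# md5 of the canonicalized config, for provenance headers
config_hash <- function(cfg) {
  flat <- vapply(cfg[order(names(cfg))], function(v) paste(v, collapse = ","), "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat), flat, sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) ingest germline, sample sheet and per-sample read
#' FASTAs; (2) extract per-sample clonotype tables; (3) usage vectors, V-J
#' pairing (per sample and cohort mean over case samples), usage PCA;
#' (4) public-clonotype detection (cases vs all non-case samples) and the
#' one-residue CDR3 cluster around the top public clonotype (or
#' `cluster_seed`). Input validation happens before any stage runs. All
#' outputs are TSVs in `out_dir`, each with a `#` provenance line carrying
#' the config hash and seed; a plain-text `run.log` records stage timings.
#'
#' @param config a [pipeline_config()], settings list, or config file path.
#' @return list of class `pipeline_result` with `tables`, `usage`, `pairing`,
#'   `pca`, `public`, `cluster`, `files` (named vector of output paths) and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  # fail-fast validation before any stage output
  for (p in c(config$germline, config$sample_sheet, config$reads_dir))
    if (!file.exists(p)) stop_validation("input path does not exist: %s", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("pubtcr config_hash=%s seed=%s", config_hash(config),
                  format(config$seed))
  logf <- file.path(config$out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("[%s] FAILED: %s", name, conditionMessage(e)), logcon)
      stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("pubtcr_pipeline_error", "pubtcr_error", "error")))
    })
    writeLines(sprintf("[%s] ok (%.2fs)", name,
                       proc.time()[["elapsed"]] - t0), logcon)
    res
  }
  write_tsv <- function(df, path) {
    con <- file(path, "w")
    writeLines(paste0("# ", prov), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  writeLines(paste0("# ", prov), logcon)
  files <- c()

  ing <- stage("ingest", {
    germline <- read_germline_fasta(config$germline)
    design <- read_sample_sheet(config$sample_sheet)
    fas <- file.path(config$reads_dir, paste0(design$sample_id, ".fasta"))
    missing <- fas[!file.exists(fas)]
    if (length(missing))
      stop_format("missing read FASTA(s): %s", paste(missing, collapse = ", "))
    list(germline = germline, design = design, fastas = fas)
  })

  tables <- stage("extract", {
    tabs <- lapply(seq_len(nrow(ing$design)), function(i) {
      reads <- Biostrings::readDNAStringSet(ing$fastas[i])
      build_clonotype_table(reads, ing$germline,
                            sample_meta = ing$design[i, ],
                            min_identity = config$min_identity)
    })
    names(tabs) <- ing$design$sample_id
    for (s in names(tabs))
      files[paste0("table_", s)] <- write_rearrangement_tsv(
        tabs[[s]], file.path(config$out_dir, paste0(s, ".clonotypes.tsv")),
        provenance = prov)
    tabs
  })

  stats_out <- stage("stats", {
    vu <- lapply(tables, usage_vector, axis = "V")
    ju <- lapply(tables, usage_vector, axis = "J")
    usage_df <- do.call(rbind, lapply(names(vu), function(s)
      rbind(data.frame(sample_id = s, axis = "V", gene = names(vu[[s]]),
                       frequency = as.numeric(vu[[s]])),
            data.frame(sample_id = s, axis = "J", gene = names(ju[[s]]),
                       frequency = as.numeric(ju[[s]])))))
    files <- c(files, usage = write_tsv(usage_df,
                                        file.path(config$out_dir, "usage.tsv")))
    mats <- lapply(tables, vj_pairing_matrix)
    case_ids <- ing$design$sample_id[ing$design$cohort == "case"]
    mean_mat <- cohort_mean_pairing(mats[intersect(names(mats), case_ids)])
    link <- data.frame(source = rep(rownames(mean_mat), ncol(mean_mat)),
                       target = rep(colnames(mean_mat), each = nrow(mean_mat)),
                       value = as.numeric(mean_mat))
    link <- link[link$value > 0, ]
    files <- c(files, pairing = write_tsv(link,
                                          file.path(config$out_dir, "pairing.tsv")))
    pca <- NULL
    kmax <- min(length(vu) - 1L,
                length(unique(unlist(lapply(vu, names)))))
    if (length(vu) >= 2L && kmax >= 1L) {
      pca <- usage_pca(vu, k = min(config$pca_k, kmax))
      sc <- data.frame(sample_id = rownames(pca$scores), pca$scores)
      files <- c(files, pca = write_tsv(sc, file.path(config$out_dir,
                                                      "pca_scores.tsv")))
    }
    list(usage_v = vu, usage_j = ju, pairing = mats, mean_pairing = mean_mat,
         pca = pca, files = files)
  })
  files <- stats_out$files

  pub_out <- stage("public", {
    is_case <- ing$design$cohort == "case"
    if (!any(is_case) || all(is_case))
      stop_validation("public detection needs both case and non-case samples")
    rep <- detect_public(tables[is_case], tables[!is_case],
                         min_case_fraction = config$min_case_fraction,
                         min_case_freq = config$min_case_freq,
                         max_control_freq = config$max_control_freq)
    files <- c(files, public = write_tsv(as.data.frame(rep),
                                         file.path(config$out_dir, "public.tsv")))
    seed_cdr3 <- config$cluster_seed
    if (is.na(seed_cdr3) && any(rep$is_public))
      seed_cdr3 <- rep$cdr3_aa[rep$is_public][1]
    cluster <- NULL
    if (!is.na(seed_cdr3)) {
      clusters <- do.call(rbind, lapply(names(tables), function(s) {
        cl <- cdr3_cluster(seed_cdr3, tables[[s]])
        if (nrow(cl$members) == 0L) return(NULL)
        cbind(sample_id = s, cl$members, cluster_frequency = cl$cluster_frequency)
      }))
      if (!is.null(clusters))
        files <- c(files, cluster = write_tsv(clusters,
                                              file.path(config$out_dir,
                                                        "cluster.tsv")))
      cluster <- clusters
    }
    list(report = rep, cluster = cluster, files = files)
  })
  files <- pub_out$files

  structure(list(tables = tables, usage = stats_out$usage_v,
                 usage_j = stats_out$usage_j,
                 pairing = stats_out$mean_pairing, pca = stats_out$pca,
                 public = pub_out$report, cluster = pub_out$cluster,
                 files = files, config = config, log = logf),
            class = "pipeline_result")
}
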