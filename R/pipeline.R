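#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the canonical
#' defaults: homology E-value cutoff 1e-10, tandem distance < 100 kb with
#' coverage and identity > 70%, the shipped epitope set, and the default
#' expression-pattern thresholds.  All values can be overridden per call.
#'
#' @param genome Named character vector of chromosome sequences (or FASTA
#'   path).
#' @param models Gene-model table (or GFF3 path); optional when only
#'   scanning.
#' @param queries Named character vector of query CDS nucleotides for
#'   homology scanning.
#' @param genome_label Genome label used in summaries.
#' @param scan [scan_params()].
#' @param tandem List with `max_dist`, `min_coverage`, `min_identity`.
#' @param epitope_defs Epitope definition table.
#' @param rules Subfamily rule set.
#' @param counts,metadata,lengths Expression inputs (optional).
#' @param out_dir Output directory for the TSV/JSON bundle (optional).
#' @return A `run_config` list.
#' @export
run_config <- function(genome = NULL, models = NULL, queries = NULL,
                       genome_label = "E",
                       scan = scan_params(),
                       tandem = list(max_dist = 1e5, min_coverage = 70,
                                     min_identity = 70),
                       epitope_defs = default_epitopes(),
                       rules = subfamily_rules(),
                       counts = NULL, metadata = NULL, lengths = NULL,
                       out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(models) && length(models) == 1L && file.exists(models)) {
    models <- read_gff3(models)
  }
  structure(list(genome = genome, models = models, queries = queries,
                 genome_label = genome_label, scan = scan, tandem = tandem,
                 epitope_defs = epitope_defs, rules = rules,
                 counts = counts, metadata = metadata, lengths = lengths,
                 out_dir = out_dir),
            class = "run_config")
}

#' Discover and annotate prolamin loci
#'
#' Chains the homology scan over all queries, merges hits into candidate
#' loci, and -- when gene models are supplied -- extracts, translates and
#' classifies every modelled gene, calling functional status.  Writes
#' `loci.tsv` and `calls.tsv` plus a per-subfamily count table when an
#' output directory is configured.
#'
#' @param config A [run_config()].
#' @return List with `loci`, `calls` (data.frame), `subfamily_counts`.
#' @export
run_identify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$genome)) stop("run_identify requires a genome")
  loci <- NULL
  if (!is.null(config$queries)) {
    if (length(config$queries) == 0L) stop("empty query set")
    index <- build_kmer_index(config$genome, config$scan$k)
    hits <- do.call(rbind, lapply(names(config$queries), function(q) {
      scan_homology(config$queries[[q]], index, config$genome,
                    config$scan, query_id = q)
    }))
    loci <- merge_to_loci(hits, config$genome)
  }
  calls <- NULL
  counts <- NULL
  if (!is.null(config$models)) {
    ann <- annotate_models(config$models, config$genome, config$rules)
    calls <- ann$calls
    counts <- table(calls$subfamily)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(loci)) write_tsv(loci, file.path(config$out_dir, "loci.tsv"))
    if (!is.null(calls)) write_tsv(calls, file.path(config$out_dir, "calls.tsv"))
  }
  list(loci = loci, calls = calls, subfamily_counts = counts)
}

# extract + translate + classify + call every modelled gene; pseudogenes
# whose broken translation defeats the rule-based classifier inherit the
# subfamily of their closest classified relative (nucleotide identity > 50%),
# mirroring homology-based family assignment
annotate_models <- function(models, genome, rules = subfamily_rules()) {
  cds_list <- lapply(seq_len(nrow(models)), function(i) {
    extract_cds(models[i, ], genome)
  })
  proteins <- lapply(cds_list, translate_cds)
  names(proteins) <- models$gene_id
  calls <- lapply(seq_len(nrow(models)), function(i) {
    cl <- classify_subfamily(proteins[[i]], rules)
    call_status(cds_list[[i]], proteins[[i]], cl$subfamily, rules)
  })
  labelled <- which(vapply(calls, `[[`, "", "subfamily") != "unclassified")
  for (i in which(vapply(calls, `[[`, "", "subfamily") == "unclassified")) {
    if (length(calls[[i]]$defects) == 0L || length(labelled) == 0L) next
    # rank references by alignment score (identity alone can be 100% on a
    # short spurious overlap); require half-length coverage and identity,
    # and stop early at a near-sibling match
    lens <- vapply(labelled, function(j) nchar(cds_list[[j]]$nucleotides), 0L)
    ord <- labelled[order(abs(lens - nchar(cds_list[[i]]$nucleotides)))]
    best <- NULL; best_j <- NA_integer_
    for (j in ord) {
      st <- pair_stats(cds_list[[i]]$nucleotides, cds_list[[j]]$nucleotides)
      if (st$coverage_pct > 50 && st$identity_pct > 50 &&
          (is.null(best) || st$score > best$score)) {
        best <- st; best_j <- j
      }
      if (!is.null(best) && best$identity_pct > 85 && best$coverage_pct > 80) break
    }
    if (!is.null(best)) calls[[i]]$subfamily <- calls[[best_j]]$subfamily
  }
  df <- data.frame(
    gene_id = models$gene_id,
    chrom = models$chrom,
    subfamily = vapply(calls, `[[`, "", "subfamily"),
    status = vapply(calls, `[[`, "", "status"),
    defects = vapply(calls, function(x) paste(x$defects, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  cds_seqs <- stats::setNames(
    vapply(cds_list, `[[`, "", "nucleotides"), models$gene_id)
  list(calls = df, calls_raw = calls, proteins = proteins, cds = cds_seqs)
}

#' Run the full annotation and profiling pipeline
#'
#' Annotates every gene model (subfamily, status, defects, MW/pI for
#' functional proteins), clusters tandem duplications per subfamily,
#' profiles CD epitopes over functional alpha-gliadins, computes TPM stage
#' profiles when counts are supplied, and assembles a report with explicit
#' numerators and denominators for every percentage.  The thresholds in
#' force are recorded in the report's `parameters` block; when `out_dir` is
#' set, per-gene TSVs and a JSON report are written.
#'
#' @param config A [run_config()] with `genome` and `models`.
#' @return List with `calls`, `physchem`, `pseudogene_rates`, `clusters`,
#'   `tandem_proportions`, `epitope_summary`, `expression`, `parameters`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$genome) || is.null(config$models)) {
    stop("run_full requires a genome and gene models")
  }
  ann <- annotate_models(config$models, config$genome, config$rules)
  calls_df <- ann$calls

  pc <- physchem_table(ann$calls_raw, ann$proteins)

  rates <- lapply(split(calls_df$status, calls_df$subfamily), pseudogene_rate)

  clusters <- list()
  props <- list()
  for (sf in unique(calls_df$subfamily)) {
    ids <- calls_df$gene_id[calls_df$subfamily == sf]
    sub_models <- config$models[config$models$gene_id %in% ids, , drop = FALSE]
    cl <- cluster_tandem(sub_models, ann$cds,
                         max_dist = config$tandem$max_dist,
                         min_coverage = config$tandem$min_coverage,
                         min_identity = config$tandem$min_identity)
    clusters[[sf]] <- cl
    props[[sf]] <- tandem_proportion(cl, ids)
  }

  alpha_fun <- calls_df$gene_id[calls_df$subfamily == "alpha" &
                                  calls_df$status == "functional"]
  epi <- NULL
  if (length(alpha_fun)) {
    profiles <- lapply(alpha_fun, function(g) {
      scan_epitopes(ann$proteins[[g]], config$epitope_defs)
    })
    epi <- summarize_genome(profiles, config$genome_label)
  }

  expr <- NULL
  if (!is.null(config$counts)) {
    lens <- config$lengths
    if (is.null(lens)) {
      lens <- vapply(ann$cds[rownames(config$counts)], nchar, 0L)
    }
    tpm <- compute_tpm(config$counts, lens)
    expr <- list(tpm = tpm,
                 profiles = profile_stages(tpm, config$metadata))
  }

  params <- list(
    evalue_cutoff = config$scan$evalue_cutoff,
    seed_k = config$scan$k,
    tandem_max_dist_bp = config$tandem$max_dist,
    tandem_min_coverage_pct = config$tandem$min_coverage,
    tandem_min_identity_pct = config$tandem$min_identity,
    epitope_set = config$epitope_defs$name)

  report <- list(calls = calls_df, physchem = pc,
                 pseudogene_rates = rates, clusters = clusters,
                 tandem_proportions = props, epitope_summary = epi,
                 expression = expr, parameters = params)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(calls_df, file.path(config$out_dir, "calls.tsv"))
    write_tsv(pc, file.path(config$out_dir, "physchem.tsv"))
    if (!is.null(expr)) {
      write_tsv(expr$profiles, file.path(config$out_dir, "stage_profiles.tsv"))
    }
    json <- report[c("pseudogene_rates", "tandem_proportions",
                     "epitope_summary", "parameters")]
    json$subfamily_counts <- as.list(table(calls_df$subfamily))
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_lines <- c(
      sprintf("e-value cutoff: %g", config$scan$evalue_cutoff),
      sprintf("tandem distance threshold: %g bp", config$tandem$max_dist),
      sprintf("tandem coverage threshold: %g %%", config$tandem$min_coverage),
      sprintf("tandem identity threshold: %g %%", config$tandem$min_identity))
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  report
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
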