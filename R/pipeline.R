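# End-to-end orchestration: merge -> trim -> competitive map -> deduplicate
# -> consensus -> local database search -> tree placement -> authentication
# -> reports.  One master seed drives every stochastic stage through named
# substreams; a fixed config + seed reproduces every artifact byte for byte.

#' Pipeline run configuration
#'
#' @param panel_fasta,panel_metadata reference panel paths.
#' @param out_dir output directory (one directory per sample, fixed file
#'   names).
#' @param sample_id sample label used in reports and the consensus FASTA id.
#' @param sampling_method `"brushing"`, `"rubbing"`, `"cutting"`, or
#'   `"unknown"` (annotation only; presets live in [simulation_config()]).
#' @param fastq1,fastq2 paired FASTQ inputs (ignored when `simulation` is
#'   given).
#' @param simulation optional [simulation_config()]; when set, reads are
#'   simulated into `out_dir/sim/` and used as input.
#' @param thresholds an [auth_thresholds()] list.
#' @param merge_min_overlap,merge_max_mismatch_rate read-pair merge
#'   parameters.
#' @param trim_quality_limit,trim_min_length modified-Mott trim parameters.
#' @param map a [mapping_params()].
#' @param bootstrap_replicates bootstrap replicates for the placement tree.
#' @param seed master integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(panel_fasta, panel_metadata, out_dir,
                       sample_id = "sample", sampling_method = "unknown",
                       fastq1 = NULL, fastq2 = NULL, simulation = NULL,
                       thresholds = auth_thresholds(),
                       merge_min_overlap = 15L, merge_max_mismatch_rate = 0.2,
                       trim_quality_limit = 0.05, trim_min_length = 30L,
                       map = mapping_params(), bootstrap_replicates = 100L,
                       seed = 1L) {
  if (is.null(simulation) && (is.null(fastq1) || is.null(fastq2)))
    stop("either paired FASTQ inputs or a simulation config is required")
  structure(list(
    panel_fasta = panel_fasta, panel_metadata = panel_metadata,
    out_dir = out_dir, sample_id = sample_id,
    sampling_method = sampling_method, fastq1 = fastq1, fastq2 = fastq2,
    simulation = simulation, thresholds = thresholds,
    merge_min_overlap = as.integer(merge_min_overlap),
    merge_max_mismatch_rate = merge_max_mismatch_rate,
    trim_quality_limit = trim_quality_limit,
    trim_min_length = as.integer(trim_min_length), map = map,
    bootstrap_replicates = as.integer(bootstrap_replicates),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from a flat YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; optional `simulation`
#' and `mapping` blocks mirror [simulation_config()] / [mapping_params()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  map <- if (!is.null(y$mapping)) do.call(mapping_params, y$mapping)
         else mapping_params()
  thr <- if (!is.null(y$thresholds)) do.call(auth_thresholds, y$thresholds)
         else auth_thresholds()
  args <- y[setdiff(names(y), c("simulation", "mapping", "thresholds"))]
  do.call(run_config, c(args, list(simulation = sim, map = map,
                                   thresholds = thr)))
}

not_evaluated_report <- function(species = NA_character_) {
  structure(list(
    status = setNames(rep("not_evaluated", 4L),
                      c("mean_coverage", "breadth", "db_match", "tree_placement")),
    assigned_species = NA_character_,
    metrics = list(mean_coverage = NA_real_, breadth_pct = NA_real_,
                   e_value = NA_real_, percent_identity = NA_real_,
                   query_coverage = NA_real_, placement_ok = NA)
  ), class = "auth_report")
}

write_run_log <- function(config, path, extra = character(0)) {
  thr <- config$thresholds
  mp <- config$map
  lines <- c(
    "# pipeline run log (audit of parameters actually used)",
    paste0("sample_id: ", config$sample_id),
    paste0("sampling_method: ", config$sampling_method),
    paste0("seed: ", config$seed),
    paste0("merge_min_overlap: ", config$merge_min_overlap),
    paste0("merge_max_mismatch_rate: ", config$merge_max_mismatch_rate),
    paste0("trim_quality_limit: ", config$trim_quality_limit),
    paste0("trim_min_length: ", config$trim_min_length),
    paste0("map_match: ", mp$match), paste0("map_mismatch: ", mp$mismatch),
    paste0("map_gap_open: ", mp$gap_open),
    paste0("map_gap_extend: ", mp$gap_extend), paste0("map_k: ", mp$k),
    paste0("map_min_score_frac: ", mp$min_score_frac),
    paste0("bootstrap_replicates: ", config$bootstrap_replicates),
    paste0("threshold_mean_coverage_gt: ", thr$min_mean_coverage),
    paste0("threshold_breadth_pct_gt: ", thr$min_breadth_pct),
    paste0("threshold_evalue_lt: ", thr$max_evalue),
    paste0("threshold_identity_pct_gt: ", thr$min_identity_pct),
    paste0("threshold_query_cov_pct_gt: ", thr$min_query_cov_pct),
    extra
  )
  writeLines(lines, path)
}

#' Run the whole identification pipeline for one sample
#'
#' Executes merge -> trim -> competitive mapping -> deduplication ->
#' consensus -> local database search -> bootstrap tree -> sequential
#' authentication -> reports.  Stages after a failed authentication
#' criterion are skipped (their artifacts are simply absent).  All artifacts
#' are deterministic for a fixed config + seed.
#'
#' Artifacts in `out_dir`: `merged.fastq`, `trimmed.fastq`, `counts.tsv`,
#' `assigned.sam`, `consensus.fasta`, `query_for_external_search.fasta`,
#' `tree.nwk`, `auth_report.json` / `auth_report.tsv`,
#' `sample_report.tsv`, `contamination.json`, `run_log.txt` (plus `sim/`
#' when simulating).
#'
#' @param config a [run_config()].
#' @return invisible list: `panel`, `merged`, `trimmed`, `mapping`,
#'   `top_reference`, `consensus`, `db_matches`, `tree`, `support`,
#'   `placement_ok`, `auth`, `report` (a `sample_report`), `contamination`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  panel <- load_panel(config$panel_fasta, config$panel_metadata)

  if (!is.null(config$simulation)) {
    sim <- simulate_sample(config$simulation, panel, file.path(out, "sim"))
    f1 <- sim$fastq1; f2 <- sim$fastq2
  } else {
    f1 <- config$fastq1; f2 <- config$fastq2
  }
  r1 <- read_fastq(f1)
  r2 <- read_fastq(f2)
  if (nrow(r1) != nrow(r2) || (nrow(r1) && any(r1$id != r2$id)))
    stop("read merging stage: FASTQ mates out of sync between files")
  pairs <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                      seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)

  merged <- merge_pairs(pairs, config$merge_min_overlap,
                        config$merge_max_mismatch_rate)
  write_fastq(merged, file.path(out, "merged.fastq"))
  trimmed <- trim_reads(merged, config$trim_quality_limit,
                        config$trim_min_length)
  write_fastq(trimmed, file.path(out, "trimmed.fastq"))

  mapping <- competitive_assign(trimmed, panel, config$map)
  write_tsv(data.frame(reference_id = names(mapping$per_reference_counts),
                       assigned_reads = as.integer(mapping$per_reference_counts)),
            file.path(out, "counts.tsv"))
  write_sam(mapping, panel, file.path(out, "assigned.sam"))

  top <- top_nonhuman_reference(mapping$per_reference_counts, panel)
  consensus <- NULL; db <- NULL; tree <- NULL; support <- NULL
  placement_ok <- NA
  if (is.na(top)) {
    auth <- not_evaluated_report()
  } else {
    ref <- panel_get(panel, top)
    consensus <- build_consensus(
      mapping$hits[mapping$hits$reference_id == top, , drop = FALSE], ref)
    cons_id <- paste0(config$sample_id, "_", top)
    cs <- Biostrings::DNAStringSet(consensus$sequence)
    names(cs) <- cons_id
    Biostrings::writeXStringSet(cs, file.path(out, "consensus.fasta"))

    thr <- config$thresholds
    c1 <- consensus$mean_coverage > thr$min_mean_coverage
    c2 <- consensus$breadth_pct > thr$min_breadth_pct
    if (c1 && c2) {
      db <- local_db_search(consensus, panel,
                            match = config$map$match,
                            mismatch = config$map$mismatch,
                            gap_open = config$map$gap_open,
                            gap_extend = config$map$gap_extend,
                            hook_fasta = file.path(out, "query_for_external_search.fasta"))
      c3 <- db$e_value[1] < thr$max_evalue &&
        db$percent_identity[1] > thr$min_identity_pct &&
        db$query_coverage[1] > thr$min_query_cov_pct
      if (c3) {
        leaf <- paste0(config$sample_id, "_consensus")
        seqs <- c(setNames(consensus$sequence, leaf),
                  setNames(panel$genomes$sequence, panel$genomes$id))
        msa <- build_msa(seqs)
        bs <- bootstrap_support(msa, config$bootstrap_replicates,
                                seed = derive_seed(config$seed, "bootstrap"))
        tree <- bs$tree; support <- bs$support
        write_newick(tree, file.path(out, "tree.nwk"))
        placement_ok <- placement_check(tree, leaf,
                                        db$species_scientific[1], panel)
      }
    }
    auth <- evaluate_authentication(consensus,
                                    if (!is.null(db)) db[1, , drop = FALSE],
                                    placement_ok, config$thresholds)
  }

  write_auth_report(auth, json_path = file.path(out, "auth_report.json"),
                    tsv_path = file.path(out, "auth_report.tsv"),
                    sample_id = config$sample_id)
  report <- sample_report(config$sample_id, config$sampling_method, mapping,
                          consensus, auth, panel)
  write_sample_report(report, file.path(out, "sample_report.tsv"))

  contamination <- NULL
  human_ids <- panel$genomes$id[panel$genomes$is_human]
  hl <- mapping$hits$read_length[mapping$hits$reference_id %in% human_ids]
  el <- if (!is.na(top))
    mapping$hits$read_length[mapping$hits$reference_id == top] else numeric(0)
  if (length(hl) >= 1L && length(el) >= 1L)
    contamination <- length_contrast(el, hl)
  jsonlite::write_json(list(
    sample_id = config$sample_id,
    human_read_pct = human_fraction(mapping, panel),
    length_contrast = contamination
  ), file.path(out, "contamination.json"), auto_unbox = TRUE, digits = NA,
  na = "null", null = "null", pretty = TRUE)

  write_run_log(config, file.path(out, "run_log.txt"),
                extra = paste0("top_reference: ",
                               if (is.na(top)) "no assignable species" else top))

  invisible(list(panel = panel, merged = merged, trimmed = trimmed,
                 mapping = mapping, top_reference = top,
                 consensus = consensus, db_matches = db, tree = tree,
                 support = support, placement_ok = placement_ok, auth = auth,
                 report = report, contamination = contamination,
                 out_dir = out))
}
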