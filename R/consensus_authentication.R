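# Consensus mitogenome on the top non-human reference, depth/breadth
# statistics, a local-database replacement for the online nucleotide search,
# and the four-criterion sequential authentication gate.

#' Build a reference-frame consensus from deduplicated hits
#'
#' Per reference position: depth below `min_depth` gives N; otherwise the
#' strict-majority base; an exact tie gives the IUPAC ambiguity code of the
#' tied bases.  Insertions relative to the reference are not emitted (the
#' consensus stays in the reference coordinate frame); positions where a
#' majority of covering reads show a deletion are annotated in `deletions`
#' but remain reference-length.
#'
#' @param hits post-deduplication hits on one reference (`mapping_result$hits`
#'   subset), carrying gapped alignment strings.
#' @param ref one-row panel genome data frame.
#' @param min_depth minimum covering reads for a non-N call (default 1).
#' @return object of class `consensus_genome`: `reference_id`, `sequence`,
#'   `per_position_depth`, `mean_coverage`, `breadth_pct`, `n_reads`,
#'   `mean_read_length`, `deletions` (0-based positions).
#' @export
build_consensus <- function(hits, ref, min_depth = 1L) {
  L <- nchar(ref$sequence)
  depth <- integer(L)
  base_counts <- matrix(0L, nrow = 5L, ncol = L,
                        dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  if (nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      a <- strsplit(hits$aln_read[i], "", fixed = TRUE)[[1]]
      b <- strsplit(hits$aln_ref[i], "", fixed = TRUE)[[1]]
      ref_col <- b != "-"
      pos <- (hits$ref_start[i] + cumsum(ref_col) - 1L) %% L + 1L  # 1-based
      pos <- pos[ref_col]
      obs <- a[ref_col]                    # base or '-' (deletion in read)
      depth[pos] <- depth[pos] + 1L
      keep <- obs %in% c("A", "C", "G", "T", "-")
      # positions are unique within one hit, so vectorized increment is safe
      idx <- cbind(match(obs[keep], rownames(base_counts)), pos[keep])
      base_counts[idx] <- base_counts[idx] + 1L
    }
  }
  cons <- rep("N", L)
  deletions <- integer(0)
  called <- which(depth >= min_depth)
  for (p in called) {
    bc <- base_counts[1:4, p]
    gap <- base_counts[5L, p]
    if (gap > sum(bc)) deletions <- c(deletions, p - 1L)
    if (sum(bc) == 0L) next                       # only gaps observed
    mx <- max(bc)
    winners <- names(bc)[bc == mx]
    cons[p] <- if (length(winners) == 1L) winners else iupac_code(winners)
  }
  sequence <- paste(cons, collapse = "")
  structure(list(
    reference_id = ref$id,
    sequence = sequence,
    per_position_depth = depth,
    mean_coverage = sum(depth) / L,
    breadth_pct = 100 * sum(cons != "N") / L,
    n_reads = nrow(hits),
    mean_read_length = if (nrow(hits)) mean(hits$read_length) else NA_real_,
    deletions = deletions
  ), class = "consensus_genome")
}

#' @export
print.consensus_genome <- function(x, ...) {
  cat(sprintf("Consensus on %s: %d bp, %d reads, mean coverage %.1fX, breadth %.1f%%\n",
              x$reference_id, nchar(x$sequence), x$n_reads,
              x$mean_coverage, x$breadth_pct))
  invisible(x)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw alignment score `S`, query
#' length `m`, and database (subject) length `n`.  Defaults are the ungapped
#' constants for +1/-2 nucleotide scoring.
#'
#' @param S raw alignment score.
#' @param m,n query / subject lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @export
evalue <- function(S, m, n, lambda = 1.33, K = 0.621) {
  K * m * n * exp(-lambda * S)
}

#' Search a consensus against the local reference panel
#'
#' Deterministic, offline replacement for the online nucleotide search of
#' authentication criterion 3: the consensus is globally aligned (query
#' global, subject local) against every non-human panel reference under the
#' search scoring scheme; matches are ranked by Karlin-Altschul E-value,
#' then by percent identity.  Percent identity excludes alignment columns
#' where the query is N; query coverage is the percentage of non-N query
#' positions that are aligned to a subject base.
#'
#' A hook for an external online search is provided by `hook_fasta`: when
#' set, the consensus is additionally written there as FASTA (nothing is
#' ever fetched).
#'
#' @param consensus a `consensus_genome`.
#' @param panel a `ref_panel`.
#' @param lambda,K Karlin-Altschul parameters for [evalue()].
#' @param match,mismatch,gap_open,gap_extend search scoring scheme.
#' @param hook_fasta optional path; writes the query FASTA for an external
#'   search.
#' @return data frame of matches sorted best-first (best match = row 1) with
#'   columns `subject_id`, `species_scientific`, `percent_identity`,
#'   `query_coverage`, `bit_score`, `e_value`, `m`, `n`.
#' @export
local_db_search <- function(consensus, panel, lambda = 1.33, K = 0.621,
                            match = 1L, mismatch = -2L, gap_open = 3L,
                            gap_extend = 1L, hook_fasta = NULL) {
  stopifnot(inherits(consensus, "consensus_genome"), inherits(panel, "ref_panel"))
  q <- consensus$sequence
  n_informative <- nchar(gsub("N", "", q))
  if (n_informative == 0L) stop("nothing to search: consensus is all N")
  if (!is.null(hook_fasta)) {
    s <- Biostrings::DNAStringSet(q)
    names(s) <- paste0("consensus_", consensus$reference_id)
    Biostrings::writeXStringSet(s, hook_fasta)
  }
  subjects <- panel$genomes[!panel$genomes$is_human, , drop = FALSE]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    subj <- subjects$sequence[i]
    pa <- Biostrings::pairwiseAlignment(
      pattern = q, subject = subj, type = "global-local",
      substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    informative <- ap != "N" & ap != "-" & as != "-"
    ident <- if (any(informative))
      100 * sum(ap[informative] == as[informative]) / sum(informative)
    else 0
    qcov <- 100 * sum(informative) / n_informative
    S <- Biostrings::score(pa)
    data.frame(subject_id = subjects$id[i],
               species_scientific = subjects$species_scientific[i],
               percent_identity = ident, query_coverage = qcov,
               bit_score = S,
               e_value = evalue(S, m = nchar(q), n = nchar(subj),
                                lambda = lambda, K = K),
               m = nchar(q), n = nchar(subj), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$e_value, -out$percent_identity, out$subject_id), ]
  rownames(out) <- NULL
  out
}

#' Authentication thresholds
#'
#' The gate's boundaries are strict inequalities exactly as stated: mean
#' coverage > 10X, breadth > 90%, E-value < 0.001 with identity > 99% and
#' query coverage > 95%.
#'
#' @param min_mean_coverage,min_breadth_pct,max_evalue,min_identity_pct,min_query_cov_pct
#'   criterion boundaries.
#' @export
auth_thresholds <- function(min_mean_coverage = 10, min_breadth_pct = 90,
                            max_evalue = 0.001, min_identity_pct = 99,
                            min_query_cov_pct = 95) {
  stopifnot(min_mean_coverage > 0, min_breadth_pct > 0, max_evalue > 0,
            min_identity_pct > 0, min_query_cov_pct > 0)
  list(min_mean_coverage = min_mean_coverage,
       min_breadth_pct = min_breadth_pct, max_evalue = max_evalue,
       min_identity_pct = min_identity_pct,
       min_query_cov_pct = min_query_cov_pct)
}

#' Sequential four-criterion authentication
#'
#' Criteria are evaluated strictly in order — 1) mean mapping coverage,
#' 2) percentage of the reference covered, 3) database top match (E-value,
#' identity, query coverage), 4) phylogenetic tree placement.  The first
#' failure short-circuits: later criteria are recorded `not_evaluated`, and
#' a species is assigned only when all four pass.
#'
#' @param consensus a `consensus_genome`.
#' @param match best database match (row 1 of [local_db_search()]), or
#'   `NULL` if unavailable.
#' @param placement_ok logical result of [placement_check()], or `NA` if not
#'   computed.
#' @param thresholds an [auth_thresholds()] list.
#' @param species candidate species name (assigned on full pass); defaults
#'   to the database match species.
#' @return object of class `auth_report`: per-criterion status
#'   (`pass`/`fail`/`not_evaluated`), `assigned_species` (or `NA`), and a
#'   `metrics` snapshot.
#' @export
evaluate_authentication <- function(consensus, match, placement_ok,
                                    thresholds = auth_thresholds(),
                                    species = NULL) {
  status <- rep("not_evaluated", 4L)
  names(status) <- c("mean_coverage", "breadth", "db_match", "tree_placement")
  checks <- list(
    function() consensus$mean_coverage > thresholds$min_mean_coverage,
    function() consensus$breadth_pct > thresholds$min_breadth_pct,
    function() {
      if (is.null(match) || nrow(match) == 0L) return(FALSE)
      match$e_value[1] < thresholds$max_evalue &&
        match$percent_identity[1] > thresholds$min_identity_pct &&
        match$query_coverage[1] > thresholds$min_query_cov_pct
    },
    function() isTRUE(placement_ok)
  )
  for (i in 1:4) {
    ok <- checks[[i]]()
    status[i] <- if (isTRUE(ok)) "pass" else "fail"
    if (status[i] == "fail") break
  }
  passed_all <- all(status == "pass")
  if (is.null(species) && !is.null(match) && nrow(match) > 0L)
    species <- match$species_scientific[1]
  structure(list(
    status = status,
    assigned_species = if (passed_all) species else NA_character_,
    metrics = list(
      mean_coverage = consensus$mean_coverage,
      breadth_pct = consensus$breadth_pct,
      e_value = if (!is.null(match) && nrow(match)) match$e_value[1] else NA_real_,
      percent_identity = if (!is.null(match) && nrow(match)) match$percent_identity[1] else NA_real_,
      query_coverage = if (!is.null(match) && nrow(match)) match$query_coverage[1] else NA_real_,
      placement_ok = placement_ok
    )
  ), class = "auth_report")
}

#' @export
print.auth_report <- function(x, ...) {
  cat("Authentication report\n")
  for (i in seq_along(x$status))
    cat(sprintf("  %d. %-15s %s\n", i, names(x$status)[i], x$status[i]))
  cat("  assigned species:",
      if (is.na(x$assigned_species)) "none" else x$assigned_species, "\n")
  invisible(x)
}

#' Write an authentication report as JSON and TSV
#'
#' @param report an `auth_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @param sample_id sample label recorded in the outputs.
#' @export
write_auth_report <- function(report, json_path = NULL, tsv_path = NULL,
                              sample_id = "sample") {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      sample_id = sample_id,
      criteria = as.list(report$status),
      assigned_species = report$assigned_species,
      metrics = report$metrics
    ), json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      sample_id = sample_id,
      criterion = names(report$status),
      status = unname(report$status),
      stringsAsFactors = FALSE
    )
    df$value <- c(sprintf("%.4f", report$metrics$mean_coverage),
                  sprintf("%.4f", report$metrics$breadth_pct),
                  sprintf("%g|%.4f|%.4f", report$metrics$e_value,
                          report$metrics$percent_identity,
                          report$metrics$query_coverage),
                  as.character(report$metrics$placement_ok))
    write_tsv(df, tsv_path)
  }
  invisible(report)
}
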