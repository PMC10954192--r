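# Contamination profiling: how much of a sample's sequencing effort maps to
# the human mitogenome (touch DNA from handling), and whether contaminant
# reads are distinguishably longer than the degraded endogenous fraction.

#' Percentage of reads mapping to the human reference
#'
#' Denominator is every read that entered mapping (assigned anywhere + ties
#' + unmapped), not just assigned reads.
#'
#' @param mapping a `mapping_result`.
#' @param panel the `ref_panel` mapped against.
#' @return percentage in `[0, 100]`, or `NA` when no reads entered mapping.
#' @export
human_fraction <- function(mapping, panel) {
  stopifnot(inherits(mapping, "mapping_result"), inherits(panel, "ref_panel"))
  if (mapping$n_input == 0L) return(NA_real_)
  human_ids <- panel$genomes$id[panel$genomes$is_human]
  100 * sum(mapping$per_reference_counts[human_ids]) / mapping$n_input
}

#' Two-sample Student's t test (pooled variance)
#'
#' Pooled-variance two-sided t test, as used for the per-method comparisons
#' of library yield, mapped reads, and read length.  Degenerate inputs are
#' handled explicitly: zero pooled variance with equal means gives `t = 0,
#' p = 1`; zero pooled variance with unequal means is flagged as infinite t
#' with `p = 0`.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param welch use the Welch (unpooled) variant instead.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
students_t <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  ma <- mean(group_a); mb <- mean(group_b)
  pooled_var <- (sum((group_a - ma)^2) + sum((group_b - mb)^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (!welch && pooled_var == 0) {
    df <- length(group_a) + length(group_b) - 2L
    if (ma == mb) return(list(t = 0, df = df, p = 1, mean_a = ma, mean_b = mb))
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0, mean_a = ma, mean_b = mb))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = ma, mean_b = mb)
}

#' One-way ANOVA across groups
#'
#' Standard between/within decomposition via [stats::oneway.test()] with
#' equal variances assumed; all-identical values give `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each length >= 2).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df_between <- length(groups) - 1L
  df_within <- length(values) - length(groups)
  if (all(values == values[1]))
    return(list(F = 0, df_between = df_between, df_within = df_within, p = 1))
  ht <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]), p = ht$p.value)
}

#' Length contrast between endogenous and human-contaminant reads
#'
#' Degraded endogenous parchment DNA is short; human touch DNA is closer to
#' library length.  Reports means and SDs and, when both groups have at
#' least 2 reads, the pooled-variance t test of the difference.
#'
#' @param endogenous_lengths,human_lengths mapped-read lengths (bp).
#' @return list with `endogenous_mean_len`, `endogenous_sd_len`,
#'   `human_mean_len`, `human_sd_len`, `n_endogenous`, `n_human`,
#'   `t_statistic`, `df`, `p_value` (test fields `NA` for degenerate input).
#' @export
length_contrast <- function(endogenous_lengths, human_lengths) {
  stopifnot(length(endogenous_lengths) >= 1L, length(human_lengths) >= 1L)
  out <- list(
    endogenous_mean_len = mean(endogenous_lengths),
    endogenous_sd_len = stats::sd(endogenous_lengths),
    human_mean_len = mean(human_lengths),
    human_sd_len = stats::sd(human_lengths),
    n_endogenous = length(endogenous_lengths),
    n_human = length(human_lengths),
    t_statistic = NA_real_, df = NA_real_, p_value = NA_real_
  )
  if (length(endogenous_lengths) >= 2L && length(human_lengths) >= 2L) {
    tt <- students_t(human_lengths, endogenous_lengths)
    out$t_statistic <- tt$t
    out$df <- tt$df
    out$p_value <- tt$p
  }
  out
}

#' Per-sample summary report
#'
#' Mirrors the per-sample summary table of the workflow: mapped reads, mean
#' coverage, percentage of reference covered, mean mapped read length, and
#' the assigned source species, plus the human-contamination percentage and
#' the authentication gate outcome.
#'
#' @param sample_id sample label.
#' @param sampling_method `"brushing"`, `"rubbing"`, `"cutting"`, or
#'   `"unknown"`.
#' @param mapping a `mapping_result`.
#' @param consensus a `consensus_genome` (or `NULL`).
#' @param auth an `auth_report` (or `NULL`).
#' @param panel the `ref_panel`.
#' @return one-row data frame of class `sample_report`.
#' @export
sample_report <- function(sample_id, sampling_method, mapping, consensus,
                          auth, panel) {
  df <- data.frame(
    sample_id = sample_id,
    sampling_method = sampling_method,
    reads_in = mapping$n_input,
    mapped_reads = if (!is.null(consensus)) consensus$n_reads else 0L,
    mean_coverage = if (!is.null(consensus)) consensus$mean_coverage else NA_real_,
    reference_covered_pct = if (!is.null(consensus)) consensus$breadth_pct else NA_real_,
    mean_read_length = if (!is.null(consensus)) consensus$mean_read_length else NA_real_,
    human_read_pct = human_fraction(mapping, panel),
    ties_ignored = mapping$n_ties_ignored,
    unmapped = mapping$n_unmapped,
    duplicate_rate = mapping$duplicate_rate,
    source_species = if (!is.null(auth)) auth$assigned_species else NA_character_,
    stringsAsFactors = FALSE
  )
  class(df) <- c("sample_report", class(df))
  df
}

#' Write / read a sample report TSV (exact round-trip)
#'
#' @param report a `sample_report`.
#' @param path TSV path.
#' @export
write_sample_report <- function(report, path) {
  out <- as.data.frame(report)
  # full-precision numeric serialization so parsing reproduces fields exactly
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sample_report
#' @export
read_sample_report <- function(path) {
  df <- read_tsv(path)
  num_cols <- c("reads_in", "mapped_reads", "mean_coverage",
                "reference_covered_pct", "mean_read_length", "human_read_pct",
                "ties_ignored", "unmapped", "duplicate_rate")
  for (col in intersect(num_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  int_cols <- c("reads_in", "mapped_reads", "ties_ignored", "unmapped")
  for (col in intersect(int_cols, names(df))) df[[col]] <- as.integer(df[[col]])
  df$sample_id <- as.character(df$sample_id)
  df$source_species <- as.character(df$source_species)
  class(df) <- c("sample_report", class(df))
  df
}
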