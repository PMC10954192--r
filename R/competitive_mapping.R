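# Competitive mapping: each merged read is aligned against every panel
# reference (k-mer seeded local alignment with affine gaps, both strands,
# circular references unwrapped by extension).  A read is assigned only to a
# unique best-scoring reference; reads scoring equally against two or more
# references are ignored rather than placed arbitrarily.  PCR duplicates are
# then removed by identical mapping coordinates and read length.

#' Alignment scoring and seeding parameters
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores; a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param k seed k-mer length; reads shorter than `k` are unalignable.
#' @param min_score_frac minimum alignment score as a fraction of
#'   `read length * match`.
#' @param margin seed-window margin (bp) around clustered seed diagonals.
#' @return list of class `map_params`.
#' @export
mapping_params <- function(match = 1L, mismatch = -2L, gap_open = 3L,
                           gap_extend = 1L, k = 13L, min_score_frac = 0.8,
                           margin = 16L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), k = as.integer(k),
                 min_score_frac = min_score_frac, margin = as.integer(margin)),
            class = "map_params")
}

# extend a circular reference so reads spanning the origin align contiguously
extend_reference <- function(sequence, circular, max_read_len, margin) {
  if (!circular) return(sequence)
  ext <- min(nchar(sequence), max_read_len + margin)
  paste0(sequence, substr(sequence, 1L, ext))
}

# batch-align reads against one reference; coordinates reported modulo the
# original reference length (0-based half-open; ref_end may exceed the
# length, meaning the hit wraps across the circular origin)
align_batch <- function(seqs, ref_row, params) {
  L <- nchar(ref_row$sequence)
  ref_ext <- extend_reference(ref_row$sequence, ref_row$circular,
                              max(nchar(seqs), 0L), params$margin)
  min_score <- ceiling(params$min_score_frac * nchar(seqs) * params$match)
  r <- cpp_align_batch(seqs, ref_ext, params$k, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       as.numeric(min_score), params$margin)
  ref_len_aln <- ifelse(is.na(r$aln_ref), NA_integer_,
                        nchar(gsub("-", "", r$aln_ref)))
  start0 <- ifelse(is.na(r$ref_start), NA_integer_, r$ref_start %% L)
  data.frame(score = r$score, ref_start = start0,
             ref_end = start0 + ref_len_aln, strand = r$strand,
             edit_distance = r$edit_distance, aln_read = r$aln_read,
             aln_ref = r$aln_ref, stringsAsFactors = FALSE)
}

#' Align one read against one reference
#'
#' Best local alignment of the read and its reverse complement, found by
#' k-mer seeding and affine-gap dynamic programming on the seeded windows.
#' Circular references are extended by one read length so hits spanning the
#' origin are contiguous; coordinates are reported modulo reference length.
#'
#' @param seq merged read sequence.
#' @param ref one-row data frame (a `ref_panel` genome row) with `id`,
#'   `sequence`, `circular`.
#' @param params a [mapping_params()].
#' @return list (`reference_id`, `score`, `ref_start`, `ref_end` 0-based
#'   half-open, `strand`, `edit_distance`, `aln_read`, `aln_ref`,
#'   `read_length`), or `NULL` when unaligned.
#' @export
align_read <- function(seq, ref, params = mapping_params()) {
  h <- align_batch(seq, ref, params)
  if (is.na(h$score[1])) return(NULL)
  c(list(reference_id = ref$id), as.list(h[1, ]), list(read_length = nchar(seq)))
}

#' Left-normalize the gaps of an alignment
#'
#' Shifts every gap run to its leftmost score-equivalent position so that
#' indels inside homopolymers are placed consistently across reads (local
#' realignment).  Alignment score and edit distance are unchanged.
#'
#' @param hit list with gapped strings `aln_read` and `aln_ref` (other
#'   fields are passed through).
#' @return `hit` with normalized `aln_read`/`aln_ref`.
#' @export
normalize_indels <- function(hit) {
  a <- strsplit(hit$aln_read, "", fixed = TRUE)[[1]]
  b <- strsplit(hit$aln_ref, "", fixed = TRUE)[[1]]
  shift_gaps <- function(x, y) {
    # shift gap blocks in x left while the score is unchanged
    i <- 1L
    n <- length(x)
    while (i <= n) {
      if (x[i] != "-") { i <- i + 1L; next }
      j <- i
      while (j < n && x[j + 1L] == "-") j <- j + 1L
      a0 <- i
      while (a0 > 1L && x[a0 - 1L] != "-" && y[a0 - 1L] != "-" &&
             (x[a0 - 1L] == y[a0 - 1L]) == (x[a0 - 1L] == y[j])) {
        # move the char before the block to the block's right edge
        x[j] <- x[a0 - 1L]
        x[a0 - 1L] <- "-"
        j <- j - 1L
        a0 <- a0 - 1L
      }
      i <- max(j + 1L, i + 1L)
    }
    x
  }
  a <- shift_gaps(a, b)
  b <- shift_gaps(b, a)
  hit$aln_read <- paste(a, collapse = "")
  hit$aln_ref <- paste(b, collapse = "")
  hit
}

#' Remove PCR duplicates from the hits of one (or more) references
#'
#' Hits are grouped by (reference, start, stop, read length); one
#' representative per group is kept — highest mean base quality, then
#' lexicographically smallest read id.
#'
#' @param hits data frame with columns `reference_id`, `ref_start`,
#'   `ref_end`, `read_length`, `mean_qual`, `read_id`.
#' @return list with `hits` (retained rows), `n_removed`, and
#'   `duplicate_rate` (= removed / input).
#' @export
deduplicate <- function(hits) {
  if (nrow(hits) == 0L)
    return(list(hits = hits, n_removed = 0L, duplicate_rate = NA_real_))
  key <- paste(hits$reference_id, hits$ref_start, hits$ref_end,
               hits$read_length, sep = "\r")
  ord <- order(key, -hits$mean_qual, hits$read_id, method = "radix")
  keep_idx <- ord[!duplicated(key[ord])]
  keep_idx <- sort(keep_idx)
  list(hits = hits[keep_idx, , drop = FALSE],
       n_removed = nrow(hits) - length(keep_idx),
       duplicate_rate = (nrow(hits) - length(keep_idx)) / nrow(hits))
}

#' Competitively assign merged reads across a reference panel
#'
#' Every read is aligned to every panel reference; a read is assigned to the
#' reference with the strictly highest alignment score.  Reads whose maximal
#' score is achieved by two or more references are counted in
#' `n_ties_ignored` and assigned nowhere; reads aligning nowhere are counted
#' unmapped.  Assigned hits are indel-left-normalized, then deduplicated per
#' reference by mapping coordinates.
#'
#' @param reads data frame of merged reads (`id`, `seq`, `qual`).
#' @param panel a `ref_panel`.
#' @param params a [mapping_params()].
#' @return object of class `mapping_result`: list with `hits`
#'   (post-deduplication assigned hits), `per_reference_counts` (named,
#'   pre-deduplication assigned counts in panel order), `n_ties_ignored`,
#'   `n_unmapped`, `n_input`, `n_duplicates_removed`, `duplicate_rate`.
#' @export
competitive_assign <- function(reads, panel, params = mapping_params()) {
  stopifnot(inherits(panel, "ref_panel"))
  ids <- panel_ids(panel)
  n <- nrow(reads)
  empty_hits <- data.frame(
    read_id = character(0), reference_id = character(0), score = numeric(0),
    ref_start = integer(0), ref_end = integer(0), strand = character(0),
    edit_distance = integer(0), read_length = integer(0),
    mean_qual = numeric(0), aln_read = character(0), aln_ref = character(0),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(structure(list(
      hits = empty_hits,
      per_reference_counts = setNames(integer(length(ids)), ids),
      n_ties_ignored = 0L, n_unmapped = 0L, n_input = 0L,
      n_duplicates_removed = 0L, duplicate_rate = NA_real_
    ), class = "mapping_result"))
  }

  per_ref <- lapply(seq_len(nrow(panel$genomes)), function(i)
    align_batch(reads$seq, panel$genomes[i, ], params))
  scores <- vapply(per_ref, function(h) h$score, numeric(n))
  scores <- matrix(scores, nrow = n)

  best <- apply(scores, 1L, function(s) if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
  n_best <- vapply(seq_len(n), function(i) {
    if (is.na(best[i])) 0L else sum(scores[i, ] == best[i], na.rm = TRUE)
  }, integer(1))

  unmapped <- is.na(best)
  tied <- !unmapped & n_best >= 2L
  assigned <- !unmapped & n_best == 1L
  which_ref <- rep(NA_integer_, n)
  which_ref[assigned] <- vapply(which(assigned), function(i)
    which(scores[i, ] == best[i])[1], integer(1))

  rows <- lapply(which(assigned), function(i) {
    ri <- which_ref[i]
    h <- per_ref[[ri]][i, ]
    h <- normalize_indels(h)
    data.frame(read_id = reads$id[i], reference_id = ids[ri], score = h$score,
               ref_start = h$ref_start, ref_end = h$ref_end, strand = h$strand,
               edit_distance = h$edit_distance,
               read_length = nchar(reads$seq[i]),
               mean_qual = mean_qual(reads$qual[i]),
               aln_read = h$aln_read, aln_ref = h$aln_ref,
               stringsAsFactors = FALSE)
  })
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits
  rownames(hits) <- NULL

  counts <- setNames(integer(length(ids)), ids)
  if (nrow(hits)) {
    tab <- table(hits$reference_id)
    counts[names(tab)] <- as.integer(tab)
  }

  dd <- deduplicate(hits)
  structure(list(
    hits = dd$hits, per_reference_counts = counts,
    n_ties_ignored = sum(tied), n_unmapped = sum(unmapped), n_input = n,
    n_duplicates_removed = dd$n_removed, duplicate_rate = dd$duplicate_rate
  ), class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("Competitive mapping of", x$n_input, "reads\n")
  cat("  assigned:", sum(x$per_reference_counts),
      "| ties ignored:", x$n_ties_ignored, "| unmapped:", x$n_unmapped, "\n")
  cat("  duplicates removed:", x$n_duplicates_removed,
      sprintf("(rate %.3f)\n", x$duplicate_rate))
  for (id in names(x$per_reference_counts))
    cat(sprintf("  %-12s %6d\n", id, x$per_reference_counts[[id]]))
  invisible(x)
}

# CIGAR string from gapped alignment strings (M/I/D; read-frame)
cigar_from_alignment <- function(aln_read, aln_ref) {
  a <- strsplit(aln_read, "", fixed = TRUE)[[1]]
  b <- strsplit(aln_ref, "", fixed = TRUE)[[1]]
  op <- ifelse(a == "-", "D", ifelse(b == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Export assigned hits as SAM
#'
#' Minimal valid SAM: header with panel reference lengths, one record per
#' retained hit (SEQ is the aligned portion of the read; hits wrapping the
#' circular origin keep their unwrapped start coordinate).
#'
#' @param mapping a `mapping_result`.
#' @param panel the `ref_panel` mapped against.
#' @param path output path.
#' @export
write_sam <- function(mapping, panel, path) {
  g <- panel$genomes
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", g$id, nchar(g$sequence)))
  h <- mapping$hits
  rec <- character(0)
  if (nrow(h)) {
    seq <- gsub("-", "", h$aln_read)
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                   h$read_id, ifelse(h$strand == "-", 16L, 0L), h$reference_id,
                   h$ref_start + 1L,
                   vapply(seq_len(nrow(h)), function(i)
                     cigar_from_alignment(h$aln_read[i], h$aln_ref[i]),
                     character(1)),
                   seq, h$edit_distance)
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}
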