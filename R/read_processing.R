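# Read processing: merge inward-facing read pairs on their overlap and
# quality-trim the merged fragments.  Only merged reads are carried forward;
# unmerged pairs are dropped from the pipeline (degraded inserts are short
# enough that genuine endogenous fragments overlap).

#' Merge one read pair on its best overlap
#'
#' Read 2 is reverse-complemented, then every overlap length from
#' `min_overlap` up to the shorter mate is scored as matches minus
#' mismatches (N counts as a mismatch).  The best-scoring overlap with a
#' mismatch rate at most `max_mismatch_rate` is accepted (ties prefer the
#' longer overlap).  Inside the overlap each output base comes from the
#' higher-quality mate and the output quality is the larger of the two.
#'
#' @param pair list or one-row data frame with `seq1`, `qual1`, `seq2`,
#'   `qual2` (read 2 as sequenced, i.e. reverse strand).
#' @param min_overlap minimum acceptable overlap (bp).
#' @param max_mismatch_rate maximum mismatch proportion inside the overlap.
#' @return list with `seq`, `qual`, `overlap_len`, or `NULL` when no
#'   acceptable overlap exists (the pair stays unmerged and is dropped).
#' @export
merge_pair <- function(pair, min_overlap = 15L, max_mismatch_rate = 0.2) {
  df <- data.frame(id = "read", seq1 = pair$seq1, qual1 = pair$qual1,
                   seq2 = pair$seq2, qual2 = pair$qual2,
                   stringsAsFactors = FALSE)
  m <- merge_pairs(df, min_overlap, max_mismatch_rate)
  if (nrow(m) == 0L) return(NULL)
  list(seq = m$seq[1], qual = m$qual[1], overlap_len = m$overlap_len[1])
}

#' Merge a set of read pairs
#'
#' Vectorized form of [merge_pair()].  Pairs without an acceptable overlap
#' are dropped (merged-only policy).
#'
#' @param pairs data frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @inheritParams merge_pair
#' @return data frame of merged reads (`id`, `seq`, `qual`, `overlap_len`)
#'   with attribute `n_unmerged`.
#' @export
merge_pairs <- function(pairs, min_overlap = 15L, max_mismatch_rate = 0.2) {
  stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    out <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), overlap_len = integer(0))
    attr(out, "n_unmerged") <- 0L
    return(out)
  }
  if (any(nchar(pairs$seq1) == 0L | nchar(pairs$seq2) == 0L))
    stop("empty sequence in read pair")
  s2rc <- revcomp(pairs$seq2)
  q2rev <- vapply(pairs$qual2, function(q)
    paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  res <- cpp_merge_pairs(pairs$seq1, pairs$qual1, s2rc, q2rev,
                         as.integer(min_overlap), max_mismatch_rate)
  ok <- !is.na(res$overlap)
  out <- data.frame(id = pairs$id[ok], seq = res$seq[ok], qual = res$qual[ok],
                    overlap_len = res$overlap[ok], stringsAsFactors = FALSE)
  attr(out, "n_unmerged") <- sum(!ok)
  out
}

#' Modified-Mott quality trimming
#'
#' Each base is scored `limit - 10^(-Q/10)` (error probability relative to
#' the error-probability limit); the retained segment is the contiguous run
#' maximizing the running score sum.  Among equal-scoring segments the
#' leftmost (smallest start, then smallest end) is kept.  Segments shorter
#' than `min_length` are discarded.  N bases are treated as quality 0.
#'
#' @param seq DNA string.
#' @param qual Phred+33 quality string (same length).
#' @param quality_limit error-probability limit (default 0.05).
#' @param min_length minimum retained length (default 30).
#' @return list with `seq`, `qual`, `start`, `end` (1-based, inclusive), or
#'   `NULL` when the whole read is discarded.
#' @export
mott_trim <- function(seq, qual, quality_limit = 0.05, min_length = 30L) {
  stopifnot(quality_limit > 0, quality_limit < 1, nchar(seq) == nchar(qual))
  q <- qual_to_int(qual)
  q[strsplit(seq, "", fixed = TRUE)[[1]] == "N"] <- 0L
  sc <- quality_limit - 10^(-q / 10)
  seg <- best_segment(sc)
  if (is.null(seg) || (seg[2] - seg[1] + 1L) < min_length) return(NULL)
  list(seq = substr(seq, seg[1], seg[2]), qual = substr(qual, seg[1], seg[2]),
       start = seg[1], end = seg[2])
}

# maximum-sum contiguous segment; ties -> smallest start, then smallest end.
# Returns c(start, end) 1-based or NULL when every prefix sum move is negative.
best_segment <- function(sc, tol = 1e-12) {
  n <- length(sc)
  if (n == 0L) return(NULL)
  cs <- cumsum(sc)
  pre <- cummin(c(0, cs[-n]))          # best (lowest) prefix sum before j
  val <- cs - pre
  best <- max(val)
  if (best <= tol) return(NULL)
  js <- which(val >= best - tol)
  # candidate start for each j: earliest prefix achieving pre[j]
  starts <- vapply(js, function(j) {
    p <- c(0, cs)[seq_len(j)]          # prefix sums 0..j-1
    which(p <= pre[j] + tol)[1]        # earliest minimal prefix (start index)
  }, integer(1))
  i <- min(starts)
  j <- min(js[starts == i])
  c(i, j)
}

#' Trim a set of merged reads
#'
#' @param reads data frame with `id`, `seq`, `qual` (e.g. [merge_pairs()]
#'   output).
#' @inheritParams mott_trim
#' @return data frame of retained reads with attribute `n_discarded`.
#' @export
trim_reads <- function(reads, quality_limit = 0.05, min_length = 30L) {
  keep <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    t <- mott_trim(reads$seq[i], reads$qual[i], quality_limit, min_length)
    if (!is.null(t))
      keep[[i]] <- data.frame(id = reads$id[i], seq = t$seq, qual = t$qual,
                              stringsAsFactors = FALSE)
  }
  kept <- keep[!vapply(keep, is.null, logical(1))]
  out <- if (length(kept)) do.call(rbind, kept)
         else data.frame(id = character(0), seq = character(0), qual = character(0))
  rownames(out) <- NULL
  attr(out, "n_discarded") <- nrow(reads) - nrow(out)
  out
}
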