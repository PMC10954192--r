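# Internal helpers: deterministic seed substreams, sequence/quality utilities,
# plain-text FASTQ writing (byte-stable across platforms).

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws from its own substream, keyed
#' by a label, so that one master seed reproduces a whole run byte-for-byte
#' while stages stay independent.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 69069 + h * 1013904223) %% (2^31 - 1))
}

# evaluate expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# circular substring: 0-based start, length len, wrapping around the origin
circular_substr <- function(seq, start0, len) {
  L <- nchar(seq)
  stopifnot(len <= L)
  start0 <- start0 %% L
  if (start0 + len <= L) {
    substr(seq, start0 + 1L, start0 + len)
  } else {
    paste0(substr(seq, start0 + 1L, L), substr(seq, 1L, start0 + len - L))
  }
}

# Phred+33 <-> integer scores
qual_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_qual <- function(q) intToUtf8(pmax(0L, pmin(93L, as.integer(q))) + 33L)

mean_qual <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}

# IUPAC code for a set of observed bases (sorted, unique, subset of ACGT)
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_CODES[key]
  if (is.na(code)) "N" else unname(code)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  empty <- data.frame(id = character(0), seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE)
  if (!file.exists(path) || isTRUE(file.size(path) == 0)) return(empty)
  # suppressWarnings: Biostrings notes dropped metadata columns on subsetting
  qs <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  if (length(qs) == 0L) return(empty)
  suppressWarnings(data.frame(
    id = sub("\\s.*$", "", names(qs)),
    seq = as.character(qs),
    qual = as.character(Biostrings::quality(qs)),
    row.names = NULL, stringsAsFactors = FALSE
  ))
}

#' Write reads to a FASTQ file
#'
#' Plain 4-line records, Phred+33; output is byte-stable for fixed input.
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rec <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(rec, path)
  invisible(path)
}

# stable TSV writers (no quoting surprises, deterministic bytes)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
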