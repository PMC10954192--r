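# Reference panel: the candidate mitochondrial genomes a sample's reads are
# competitively mapped against, plus species metadata.  The panel always
# carries at least one human reference so touch-DNA contamination can be
# quantified alongside the candidate parchment species.

PANEL_META_COLS <- c("id", "species_scientific", "species_common",
                     "is_human", "is_bait_species", "circular")

#' Construct a reference panel from a metadata data frame with sequences
#'
#' @param genomes data frame with columns `id`, `species_scientific`,
#'   `species_common`, `is_human`, `is_bait_species`, `circular` (logical),
#'   and `sequence` (uppercase DNA over A/C/G/T/N).
#' @param min_len,max_len allowed sequence length range; defaults bracket
#'   mitogenome-scale inputs (1 kb - 20 kb).
#' @return an object of class `ref_panel`.
#' @export
reference_panel <- function(genomes, min_len = 1000L, max_len = 20000L) {
  req <- c(PANEL_META_COLS, "sequence")
  miss <- setdiff(req, names(genomes))
  if (length(miss))
    stop("panel metadata is missing column(s): ", paste(miss, collapse = ", "))
  genomes$sequence <- toupper(genomes$sequence)
  if (anyDuplicated(genomes$id))
    stop("duplicate reference id(s): ",
         paste(unique(genomes$id[duplicated(genomes$id)]), collapse = ", "))
  if (nrow(genomes) < 2L)
    stop("a reference panel needs at least 2 genomes")
  for (i in seq_len(nrow(genomes))) {
    s <- genomes$sequence[i]
    if (nchar(s) == 0L)
      stop("reference '", genomes$id[i], "' has an empty sequence")
    bad <- gsub("[ACGTN]", "", s)
    if (nchar(bad) > 0L)
      stop("reference '", genomes$id[i], "' contains illegal character(s): ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
    if (nchar(s) < min_len || nchar(s) > max_len)
      stop("reference '", genomes$id[i], "' length ", nchar(s),
           " outside the allowed mtGenome-like range [", min_len, ", ", max_len, "]")
  }
  genomes$is_human <- as.logical(genomes$is_human)
  genomes$is_bait_species <- as.logical(genomes$is_bait_species)
  genomes$circular <- as.logical(genomes$circular)
  if (!any(genomes$is_human))
    stop("panel must contain at least one human reference (contamination accounting)")
  structure(
    list(genomes = genomes, exactly_one_human = sum(genomes$is_human) == 1L),
    class = "ref_panel"
  )
}

#' Load a reference panel from FASTA plus a metadata TSV
#'
#' The metadata table (tab-separated, with header) has columns `id`,
#' `species_scientific`, `species_common`, `is_human`, `is_bait_species`,
#' `circular`; panel order follows the metadata file.  FASTA records and
#' metadata rows must match one-to-one by id.  Lowercase FASTA letters are
#' uppercased; characters outside A/C/G/T/N are rejected.
#'
#' @param fasta_path multi-record FASTA of reference sequences.
#' @param metadata_path metadata TSV.
#' @return a `ref_panel`.
#' @export
load_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- read_tsv(metadata_path)
  miss <- setdiff(PANEL_META_COLS, names(meta))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  orphan_fa <- setdiff(names(seqs), meta$id)
  if (length(orphan_fa))
    stop("FASTA record(s) absent from metadata: ", paste(orphan_fa, collapse = ", "))
  orphan_meta <- setdiff(meta$id, names(seqs))
  if (length(orphan_meta))
    stop("metadata row(s) without a FASTA record: ", paste(orphan_meta, collapse = ", "))
  meta$sequence <- as.character(seqs[meta$id])
  reference_panel(meta)
}

#' Write a reference panel back to FASTA + metadata TSV
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p))` round-trips ids,
#' metadata, and sequences exactly.
#'
#' @param panel a `ref_panel`.
#' @param fasta_path,metadata_path output paths.
#' @export
write_panel <- function(panel, fasta_path, metadata_path) {
  stopifnot(inherits(panel, "ref_panel"))
  seqs <- Biostrings::DNAStringSet(panel$genomes$sequence)
  names(seqs) <- panel$genomes$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(panel$genomes[, PANEL_META_COLS], metadata_path)
  invisible(list(fasta = fasta_path, metadata = metadata_path))
}

#' @export
print.ref_panel <- function(x, ...) {
  g <- x$genomes
  cat("Reference panel:", nrow(g), "mtGenomes (",
      sum(g$is_human), "human )\n")
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s %-22s %5d bp%s%s\n", g$id[i], g$species_scientific[i],
                nchar(g$sequence[i]),
                if (g$is_human[i]) "  [human]" else "",
                if (g$is_bait_species[i]) "  [bait]" else ""))
  invisible(x)
}

panel_ids <- function(panel) panel$genomes$id

panel_get <- function(panel, id) {
  i <- match(id, panel$genomes$id)
  if (is.na(i)) stop("reference '", id, "' not in panel")
  panel$genomes[i, ]
}

#' Top non-human reference by assigned-read count
#'
#' Reference mappings are ranked by the number of reads assigned; the human
#' reference is excluded regardless of its count (it tracks contamination,
#' never the parchment source).  Ties break by panel order.
#'
#' @param counts named numeric vector, assigned-read count per reference id;
#'   must cover every panel id (zeros allowed).
#' @param panel a `ref_panel`.
#' @return the winning non-human reference id, or `NA_character_` when every
#'   non-human count is zero (no assignable species).
#' @export
top_nonhuman_reference <- function(counts, panel) {
  stopifnot(inherits(panel, "ref_panel"))
  ids <- panel_ids(panel)
  miss <- setdiff(ids, names(counts))
  if (length(miss))
    stop("counts missing panel id(s): ", paste(miss, collapse = ", "))
  nh <- ids[!panel$genomes$is_human]
  cnh <- counts[nh]                      # panel order preserved -> tie-break
  if (all(cnh == 0)) return(NA_character_)
  nh[which.max(cnh)]
}
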