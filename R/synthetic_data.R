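# Synthetic parchment libraries.  Emulates the read characteristics of
# capture-enriched, degraded skin DNA: short endogenous fragments from a
# slightly diverged historical haplotype, longer human touch-DNA fragments,
# PCR duplicates re-emitted at identical coordinates, and 2 x 151 bp paired
# reads with per-base substitution errors.  Every emitted pair is recorded in
# a ground-truth manifest so downstream stages can be scored exactly.

#' Simulation configuration for a synthetic parchment sample
#'
#' Defaults are the study conditions this generator emulates: endogenous
#' fragments 119 +/- 21 bp, human contaminant fragments 149 +/- 18 bp, PCR
#' duplicate fraction 0.34, 2 x 151 bp reads, and per-sampling-method human
#' read fractions (brushing 0.241, rubbing 0.119, cutting 0.002).
#'
#' @param source_reference_id panel id of the parchment source species.
#' @param n_fragments total read pairs to emit (uniques + duplicates).
#' @param divergence per-site substitution probability separating the
#'   historical haplotype from its modern reference (default 0.002).
#' @param sampling_method one of `"brushing"`, `"rubbing"`, `"cutting"`; sets
#'   `human_read_fraction` to the matching preset unless that is given
#'   explicitly.
#' @param human_read_fraction proportion of unique fragments of human origin.
#' @param endogenous_fragment_mean,endogenous_fragment_sd fragment-length
#'   normal parameters (bp) for endogenous DNA, truncated at 30 bp and at the
#'   reference length.
#' @param contaminant_fragment_mean,contaminant_fragment_sd same for human
#'   contaminant fragments.
#' @param duplicate_fraction proportion of emitted pairs that are PCR
#'   re-emissions of an already-drawn fragment.
#' @param read_length sequencing read length (bp, >= 30).
#' @param per_base_error per-base substitution error probability applied to
#'   each written read, independent of the written quality string.
#' @param quality_dropoff number of bases at each read's 3' end written at Q2
#'   instead of the Q30 baseline (exercises quality trimming; default 0).
#' @param dropout_region optional 0-based half-open interval `c(start, end)`
#'   on the source reference with reduced fragment sampling (models coverage
#'   gaps over the hypervariable control region).
#' @param dropout_factor acceptance probability for fragments overlapping
#'   `dropout_region` (0 = complete dropout).
#' @param seed master integer seed for the sample.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(source_reference_id,
                              n_fragments,
                              divergence = 0.002,
                              sampling_method = NULL,
                              human_read_fraction = NULL,
                              endogenous_fragment_mean = 119,
                              endogenous_fragment_sd = 21,
                              contaminant_fragment_mean = 149,
                              contaminant_fragment_sd = 18,
                              duplicate_fraction = 0.34,
                              read_length = 151L,
                              per_base_error = 0.001,
                              quality_dropoff = 0L,
                              dropout_region = NULL,
                              dropout_factor = 0,
                              seed = 1L) {
  presets <- c(brushing = 0.241, rubbing = 0.119, cutting = 0.002)
  if (is.null(human_read_fraction)) {
    if (is.null(sampling_method)) {
      human_read_fraction <- 0
      sampling_method <- "unknown"
    } else {
      sampling_method <- match.arg(sampling_method, names(presets))
      human_read_fraction <- unname(presets[sampling_method])
    }
  } else if (is.null(sampling_method)) {
    sampling_method <- "unknown"
  }
  stopifnot(
    endogenous_fragment_mean > 0, contaminant_fragment_mean > 0,
    endogenous_fragment_sd >= 0, contaminant_fragment_sd >= 0,
    human_read_fraction >= 0, human_read_fraction <= 1,
    duplicate_fraction >= 0, duplicate_fraction <= 1,
    per_base_error >= 0, per_base_error <= 1,
    read_length >= 30, n_fragments >= 0,
    dropout_factor >= 0, dropout_factor <= 1
  )
  if (!is.null(dropout_region)) {
    stopifnot(length(dropout_region) == 2L, dropout_region[1] < dropout_region[2])
  }
  structure(list(
    source_reference_id = source_reference_id,
    n_fragments = as.integer(n_fragments),
    divergence = divergence,
    sampling_method = sampling_method,
    human_read_fraction = human_read_fraction,
    endogenous_fragment_mean = endogenous_fragment_mean,
    endogenous_fragment_sd = endogenous_fragment_sd,
    contaminant_fragment_mean = contaminant_fragment_mean,
    contaminant_fragment_sd = contaminant_fragment_sd,
    duplicate_fraction = duplicate_fraction,
    read_length = as.integer(read_length),
    per_base_error = per_base_error,
    quality_dropoff = as.integer(quality_dropoff),
    dropout_region = dropout_region,
    dropout_factor = dropout_factor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Mutate a reference into a historical haplotype
#'
#' Applies independent per-site substitutions at the given rate with a 2:1
#' transition:transversion bias (mammalian mtDNA-like).  N sites are left
#' untouched.
#'
#' @param sequence reference DNA string (A/C/G/T/N).
#' @param divergence substitution probability per site, in `[0, 0.2]`
#'   (capture baits tolerate roughly 20% mismatch, so larger values are
#'   outside the regime this models).
#' @param seed integer seed.
#' @return the mutated sequence (same length).
#' @export
mutate_reference <- function(sequence, divergence, seed) {
  if (divergence < 0 || divergence > 0.2)
    stop("divergence must be in [0, 0.2], got ", divergence)
  if (divergence == 0) return(sequence)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  with_seed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < divergence & chars %in% DNA_BASES
    idx <- which(hit)
    if (length(idx)) {
      is_ts <- runif(length(idx)) < 2 / 3
      new <- character(length(idx))
      new[is_ts] <- transitions[chars[idx[is_ts]]]
      for (j in which(!is_ts)) {
        b <- chars[idx[j]]
        tv <- setdiff(DNA_BASES, c(b, transitions[b]))
        new[j] <- tv[sample.int(2L, 1L)]
      }
      chars[idx] <- new
    }
    paste(chars, collapse = "")
  })
}

# truncated-normal fragment lengths on [lo, hi], rejection sampling
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- which(out < lo | out > hi)
    guard <- guard + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], lo), hi)
  as.integer(out)
}

# draw fragment coordinates on a (circular) reference, honoring dropout
draw_fragments <- function(n, ref_len, circular, mean, sd, dropout = NULL,
                           dropout_factor = 0) {
  if (n == 0L)
    return(data.frame(start = integer(0), len = integer(0)))
  len <- rtrunc_norm_int(n, mean, sd, 30L, ref_len)
  start <- if (circular) {
    sample.int(ref_len, n, replace = TRUE) - 1L
  } else {
    # linear reference: fragment must fit
    floor(runif(n) * (ref_len - len + 1L))
  }
  if (!is.null(dropout)) {
    overlaps <- function(s, l) {
      e <- s + l
      # circular overlap test against [dropout[1], dropout[2])
      hit <- (s < dropout[2] & e > dropout[1])
      wrap <- e > ref_len
      hit | (wrap & (e - ref_len) > dropout[1])
    }
    bad <- which(overlaps(start, len) & runif(n) >= dropout_factor)
    guard <- 0L
    while (length(bad) > 0L && guard < 2000L) {
      len[bad] <- rtrunc_norm_int(length(bad), mean, sd, 30L, ref_len)
      start[bad] <- if (circular) sample.int(ref_len, length(bad), replace = TRUE) - 1L
                    else floor(runif(length(bad)) * (ref_len - len[bad] + 1L))
      bad <- bad[overlaps(start[bad], len[bad]) & runif(length(bad)) >= dropout_factor]
      guard <- guard + 1L
    }
  }
  data.frame(start = as.integer(start), len = as.integer(len))
}

# apply per-base substitution errors to a vector of sequences
apply_seq_errors <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate & ch %in% DNA_BASES)
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a capture-enriched parchment sample
#'
#' Draws unique endogenous fragments from a mutated historical haplotype of
#' the source reference and human contaminant fragments from the panel's
#' human reference, re-emits a configured fraction as PCR duplicates at
#' identical coordinates, and writes inward-facing paired reads (read 1 =
#' fragment 5' end, read 2 = reverse complement of the fragment 3' end) so
#' that fragments shorter than twice the read length produce overlapping,
#' mergeable pairs.
#'
#' @param config a [simulation_config()].
#' @param panel a `ref_panel` containing `config$source_reference_id` and a
#'   human reference.
#' @param out_dir directory for `reads_R1.fastq`, `reads_R2.fastq`, and
#'   `truth_manifest.tsv` (created if needed).
#' @return invisible list with `fastq1`, `fastq2`, `manifest` (data frame:
#'   `read_id`, `origin`, `ref_id`, `start`, `end`, `frag_len`,
#'   `is_duplicate`), and `haplotype` (the mutated source sequence).
#' @export
simulate_sample <- function(config, panel, out_dir) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "ref_panel"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  src <- panel_get(panel, config$source_reference_id)
  human <- panel$genomes[panel$genomes$is_human, ][1, ]
  f1 <- file.path(out_dir, "reads_R1.fastq")
  f2 <- file.path(out_dir, "reads_R2.fastq")
  mf <- file.path(out_dir, "truth_manifest.tsv")

  haplotype <- mutate_reference(src$sequence, config$divergence,
                                derive_seed(config$seed, "haplotype"))

  n <- config$n_fragments
  n_dup <- as.integer(round(config$duplicate_fraction * n))
  n_unique <- n - n_dup
  n_human <- as.integer(round(config$human_read_fraction * n_unique))
  n_endo <- n_unique - n_human

  empty_manifest <- data.frame(
    read_id = character(0), origin = character(0), ref_id = character(0),
    start = integer(0), end = integer(0), frag_len = integer(0),
    is_duplicate = logical(0), stringsAsFactors = FALSE
  )
  if (n == 0L) {
    write_fastq(data.frame(id = character(0), seq = character(0), qual = character(0)), f1)
    write_fastq(data.frame(id = character(0), seq = character(0), qual = character(0)), f2)
    write_tsv(empty_manifest, mf)
    return(invisible(list(fastq1 = f1, fastq2 = f2, manifest = empty_manifest,
                          haplotype = haplotype, config = config)))
  }

  frags <- with_seed(derive_seed(config$seed, "fragments"), {
    fe <- draw_fragments(n_endo, nchar(haplotype), src$circular,
                         config$endogenous_fragment_mean,
                         config$endogenous_fragment_sd,
                         config$dropout_region, config$dropout_factor)
    fh <- draw_fragments(n_human, nchar(human$sequence), human$circular,
                         config$contaminant_fragment_mean,
                         config$contaminant_fragment_sd)
    uni <- rbind(
      if (n_endo) data.frame(origin = "endogenous", ref_id = src$id, fe),
      if (n_human) data.frame(origin = "human", ref_id = human$id, fh)
    )
    if (is.null(uni)) uni <- cbind(data.frame(origin = character(0),
                                              ref_id = character(0)),
                                   fe[0, , drop = FALSE])
    uni$is_duplicate <- FALSE
    dup <- if (n_dup > 0L && nrow(uni) > 0L) {
      d <- uni[sample.int(nrow(uni), n_dup, replace = TRUE), , drop = FALSE]
      d$is_duplicate <- TRUE
      d
    }
    all <- rbind(uni, dup)
    all <- all[sample.int(nrow(all)), , drop = FALSE]   # shuffle emission order
    rownames(all) <- NULL
    all
  })
  frags$read_id <- sprintf("frag%06d", seq_len(nrow(frags)))
  frags$end <- frags$start + frags$len

  frag_seq <- character(nrow(frags))
  endo_rows <- frags$origin == "endogenous"
  frag_seq[endo_rows] <- mapply(circular_substr, start0 = frags$start[endo_rows],
                                len = frags$len[endo_rows],
                                MoreArgs = list(seq = haplotype))
  frag_seq[!endo_rows] <- mapply(circular_substr, start0 = frags$start[!endo_rows],
                                 len = frags$len[!endo_rows],
                                 MoreArgs = list(seq = human$sequence))

  rl <- config$read_length
  r1_len <- pmin(rl, frags$len)
  read1 <- substr(frag_seq, 1L, r1_len)
  read2 <- revcomp(substr(frag_seq, frags$len - r1_len + 1L, frags$len))

  with_seed(derive_seed(config$seed, "errors"), {
    read1 <- apply_seq_errors(read1, config$per_base_error)
    read2 <- apply_seq_errors(read2, config$per_base_error)
  })

  qual_for <- function(len) {
    vapply(len, function(L) {
      drop <- min(config$quality_dropoff, L)
      paste0(strrep(int_to_qual(30L), L - drop), strrep(int_to_qual(2L), drop))
    }, character(1))
  }
  write_fastq(data.frame(id = frags$read_id, seq = read1, qual = qual_for(r1_len)), f1)
  write_fastq(data.frame(id = frags$read_id, seq = read2, qual = qual_for(r1_len)), f2)

  manifest <- frags[, c("read_id", "origin", "ref_id", "start", "end",
                        "frag_len" = "len", "is_duplicate")]
  names(manifest)[names(manifest) == "len"] <- "frag_len"
  write_tsv(manifest, mf)
  invisible(list(fastq1 = f1, fastq2 = f2, manifest = manifest,
                 haplotype = haplotype, config = config))
}
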