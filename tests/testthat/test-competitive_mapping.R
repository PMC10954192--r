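test_that("an exact substring aligns with full score, zero edits, exact coordinates", {
  p <- tiny_panel(seed = 61)
  ref <- p$genomes[1, ]
  read <- substr(ref$sequence, 201, 320)  # 120 bp, 0-based start 200
  h <- align_read(read, ref)
  expect_equal(h$score, 120)
  expect_equal(h$edit_distance, 0)
  expect_equal(h$ref_start, 200)
  expect_equal(h$ref_end, 320)
  expect_identical(h$strand, "+")

  # reverse-complemented read: same score and span, minus strand
  h2 <- align_read(parchmentid:::revcomp(read), ref)
  expect_equal(h2$score, 120)
  expect_equal(h2$ref_start, 200)
  expect_identical(h2$strand, "-")

  # read shorter than the seed k-mer is unalignable
  expect_null(align_read(substr(read, 1, 10), ref))
})

test_that("alignment scores agree with the Biostrings dynamic-programming oracle", {
  p <- tiny_panel(seed = 62)
  ref <- p$genomes[1, ]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  set.seed(63)
  for (i in 1:25) {
    start <- sample(1:1200, 1)
    len <- sample(60:150, 1)
    read <- substr(ref$sequence, start, start + len - 1)
    read <- mutate_reference(read, 0.03, 7000 + i)   # a few substitutions
    h <- align_read(read, ref, mapping_params(min_score_frac = 0.5))
    pa <- Biostrings::pairwiseAlignment(read, ref$sequence, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 3, gapExtension = 1)
    expect_equal(h$score, Biostrings::score(pa))
  }
})

test_that("a read spanning the circular origin gets one contiguous wrapped hit", {
  p <- tiny_panel(seed = 64)
  ref <- p$genomes[1, ]
  L <- nchar(ref$sequence)
  read <- paste0(substr(ref$sequence, L - 59, L), substr(ref$sequence, 1, 60))
  h <- align_read(read, ref)
  expect_equal(h$score, 120)
  expect_equal(h$ref_start, L - 60)
  expect_equal(h$ref_end, L + 60)    # half-open, wraps past the origin
  expect_equal(h$edit_distance, 0)
})

test_that("competitive assignment places reads with a unique best reference only", {
  # panel: A, B = copy of A with a fully distinct second half, plus human
  a <- rand_seq(2000, 65)
  half2 <- chartr("ACGT", "CATG", substr(a, 1001, 2000))  # differs everywhere
  b <- paste0(substr(a, 1, 1000), half2)
  hum <- mutate_reference(a, 0.2, 66)
  panel <- reference_panel(data.frame(
    id = c("refA", "refB", "human_ref"),
    species_scientific = c("Aa aa", "Bb bb", "Homo sapiens"),
    species_common = c("a", "b", "human"),
    is_human = c(FALSE, FALSE, TRUE), is_bait_species = TRUE, circular = TRUE,
    sequence = c(a, b, hum), stringsAsFactors = FALSE))

  # read wholly inside the shared half ties and is ignored
  shared <- substr(a, 301, 420)
  # read wholly inside the distinct half is uniquely A's
  own <- substr(a, 1301, 1420)
  reads <- data.frame(id = c("tie1", "uniq1"), seq = c(shared, own),
                      qual = c(q30(120), q30(120)))
  mp <- competitive_assign(reads, panel)
  expect_equal(mp$n_ties_ignored, 1L)
  expect_equal(unname(mp$per_reference_counts["refA"]), 1L)
  expect_equal(unname(mp$per_reference_counts["refB"]), 0L)
  expect_equal(mp$hits$read_id, "uniq1")
  expect_equal(mp$n_unmapped, 0L)

  # read matching A exactly but with 3 mismatches to every other reference
  # region is assigned to A (unique best)
  expect_identical(mp$hits$reference_id, "refA")
})

test_that("assignment is permutation-invariant and exact for a clean single-source sample", {
  p <- tiny_panel(seed = 67)
  cfg <- simulation_config("cow_ref", 150, divergence = 0, per_base_error = 0,
                           human_read_fraction = 0, duplicate_fraction = 0,
                           seed = 68)
  sim <- simulate_sample(cfg, p, tempfile("sim"))
  r1 <- read_fastq(sim$fastq1); r2 <- read_fastq(sim$fastq2)
  pairs <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                      seq2 = r2$seq, qual2 = r2$qual)
  reads <- merge_pairs(pairs)
  mp <- competitive_assign(reads, p)
  expect_equal(mp$n_unmapped, 0L)
  expect_equal(mp$n_ties_ignored, 0L)
  expect_equal(unname(mp$per_reference_counts["cow_ref"]), nrow(reads))

  set.seed(69)
  shuf <- reads[sample.int(nrow(reads)), ]
  mp2 <- competitive_assign(shuf, p)
  expect_identical(mp2$per_reference_counts, mp$per_reference_counts)
  h1 <- mp$hits[order(mp$hits$read_id), c("read_id", "reference_id", "ref_start", "ref_end")]
  h2 <- mp2$hits[order(mp2$hits$read_id), c("read_id", "reference_id", "ref_start", "ref_end")]
  rownames(h1) <- rownames(h2) <- NULL
  expect_identical(h1, h2)

  # accounting invariant
  expect_equal(sum(mp$per_reference_counts) + mp$n_ties_ignored + mp$n_unmapped,
               mp$n_input)
})

test_that("indel left-normalization shifts homopolymer gaps leftmost, score-equivalently", {
  # deletion placed at the right edge of an AAAA homopolymer
  h <- list(aln_read = "GC-AAAT", aln_ref = "GCAAAAT")
  # equivalent alignment with the gap at the left edge
  h_left <- list(aln_read = "G-CAAAT", aln_ref = "GCAAAAT")
  n1 <- normalize_indels(list(aln_read = "GCAAA-T", aln_ref = "GCAAAAT"))
  expect_identical(n1$aln_read, "GC-AAAT")
  expect_identical(n1$aln_ref, "GCAAAAT")
  # fixed point: a gap with no equivalent shift is unchanged
  n2 <- normalize_indels(list(aln_read = "GC-TTAT", aln_ref = "GCATTAT"))
  expect_identical(n2$aln_read, "GC-TTAT")
  # insertions normalize the same way
  n3 <- normalize_indels(list(aln_read = "GCAAAAT", aln_ref = "GCAAA-T"))
  expect_identical(n3$aln_ref, "GC-AAAT")
})

test_that("equivalent gap placements all normalize to the same form", {
  set.seed(70)
  for (i in 1:50) {
    base <- strsplit(rand_seq(30, 700 + i), "")[[1]]
    ref <- paste(base, collapse = "")
    # delete one base from inside a read copy, at an arbitrary position
    pos <- sample(5:25, 1)
    read_chars <- base[-pos]
    # all alignment paths placing the single gap at positions with identical
    # score must normalize identically
    forms <- list()
    for (gp in 5:25) {
      ar <- append(read_chars, "-", after = gp - 1)
      cand <- list(aln_read = paste(ar, collapse = ""), aln_ref = ref)
      # score-equivalent only if the non-gap columns match those of pos
      mism <- sum(ar != base & ar != "-")
      if (mism == 0) forms[[length(forms) + 1]] <- cand
    }
    norm <- lapply(forms, normalize_indels)
    reads_norm <- unique(vapply(norm, function(x) x$aln_read, character(1)))
    expect_length(reads_norm, 1L)
  }
})

test_that("deduplication keeps one representative per coordinate group", {
  h <- rbind(
    fake_hit("r1", "cow_ref", 100, strrep("A", 50), qual = 35),
    fake_hit("r2", "cow_ref", 100, strrep("A", 50), qual = 30),
    fake_hit("r3", "cow_ref", 100, strrep("A", 60), qual = 20)   # same start, different end
  )
  d <- deduplicate(h)
  expect_equal(d$n_removed, 1L)
  expect_equal(d$duplicate_rate, 1 / 3)
  expect_setequal(d$hits$read_id, c("r1", "r3"))   # r1 beats r2 on quality

  # quality tie -> lexicographically smallest read id survives
  h2 <- rbind(fake_hit("zz", "cow_ref", 5, strrep("C", 40), qual = 30),
              fake_hit("aa", "cow_ref", 5, strrep("C", 40), qual = 30))
  expect_identical(deduplicate(h2)$hits$read_id, "aa")
})

test_that("deduplication agrees exactly with the brute-force grouping oracle", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(1:25, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(j) {
      fake_hit(sprintf("r%02d", j),
               sample(c("x", "y"), 1),
               sample(1:5, 1) * 10,
               strrep("A", sample(c(40, 50), 1)),
               qual = sample(20:40, 1))
    }))
    d <- deduplicate(h)
    expect_identical(sort(d$hits$read_id), sort(h$read_id[dedup_oracle(h)]))
    expect_equal(d$n_removed, nrow(h) - length(dedup_oracle(h)))
  }
})

test_that("recovered duplicate rate reflects the configured fraction", {
  p <- tiny_panel(seed = 72)
  cfg <- simulation_config("cow_ref", 1500, divergence = 0.002,
                           duplicate_fraction = 0.34, seed = 73)
  sim <- simulate_sample(cfg, p, tempfile("sim"))
  r1 <- read_fastq(sim$fastq1); r2 <- read_fastq(sim$fastq2)
  pairs <- data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                      seq2 = r2$seq, qual2 = r2$qual)
  reads <- trim_reads(merge_pairs(pairs))
  mp <- competitive_assign(reads, p)
  expect_lt(abs(mp$duplicate_rate - 0.34), 0.05)
})

test_that("SAM export is structurally valid and complete", {
  p <- tiny_panel(seed = 74)
  cfg <- simulation_config("cow_ref", 80, human_read_fraction = 0, seed = 75)
  sim <- simulate_sample(cfg, p, tempfile("sim"))
  r1 <- read_fastq(sim$fastq1); r2 <- read_fastq(sim$fastq2)
  reads <- merge_pairs(data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
                                  seq2 = r2$seq, qual2 = r2$qual))
  mp <- competitive_assign(reads, p)
  sam <- tempfile(fileext = ".sam")
  write_sam(mp, p, sam)
  lines <- readLines(sam)
  expect_equal(sum(startsWith(lines, "@SQ")), 2)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), nrow(mp$hits))
  fields <- strsplit(body, "\t")
  expect_true(all(vapply(fields, length, integer(1)) == 12))
  # CIGAR-consumed read length equals SEQ length
  for (f in fields[1:min(20, length(fields))]) {
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MID]", cig))[[1]]
    consumed <- sum(as.integer(sub("[MID]", "", ops[grepl("[MI]", ops)])))
    expect_equal(consumed, nchar(f[10]))
  }
})
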