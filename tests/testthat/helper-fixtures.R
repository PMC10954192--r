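# Shared test helpers: tiny panels, random sequences, and independent
# brute-force oracles for trimming, deduplication, UPGMA, and patristic
# distances.  Oracles are deliberately naive re-derivations, kept separate
# from the implementation code paths they check.

rand_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# two-reference panel (one human) with given divergence between them
tiny_panel <- function(seed = 1, len = 1500, divergence = 0.15) {
  a <- rand_seq(len, seed)
  h <- mutate_reference(a, divergence, seed + 1000)
  reference_panel(data.frame(
    id = c("cow_ref", "human_ref"),
    species_scientific = c("Bos taurus", "Homo sapiens"),
    species_common = c("cow", "human"),
    is_human = c(FALSE, TRUE),
    is_bait_species = c(TRUE, FALSE),
    circular = TRUE,
    sequence = c(a, h),
    stringsAsFactors = FALSE
  ))
}

q30 <- function(n) strrep("?", n)  # Phred+33 Q30

# exhaustive modified-Mott oracle: best contiguous substring by total score,
# ties -> smallest start then smallest end
mott_oracle <- function(qual_ints, limit, tol = 1e-12) {
  sc <- limit - 10^(-qual_ints / 10)
  n <- length(sc)
  best <- 0; bi <- NA_integer_; bj <- NA_integer_
  for (i in seq_len(n)) {
    run <- 0
    for (j in i:n) {
      run <- run + sc[j]
      if (run > best + tol) { best <- run; bi <- i; bj <- j }
    }
  }
  if (is.na(bi)) NULL else c(bi, bj)
}

# brute-force duplicate grouping oracle
dedup_oracle <- function(hits) {
  key <- paste(hits$reference_id, hits$ref_start, hits$ref_end,
               hits$read_length)
  keep <- logical(nrow(hits))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-hits$mean_qual[idx], hits$read_id[idx])]
    keep[idx[1]] <- TRUE
  }
  which(keep)
}

# definitional UPGMA oracle: cluster distance recomputed each step as the
# plain average of all between-cluster entries of the ORIGINAL matrix
upgma_oracle_heights <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    bd <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights[[length(heights) + 1L]] <-
      list(tips = merged, height = bd / 2)
    clusters <- c(clusters[-c(bi, bj)], list(merged))
  }
  heights
}

# clade tip sets with their heights from an ultrametric ape tree
tree_clade_heights <- function(tree) {
  pd <- ape::cophenetic.phylo(tree)
  pp <- ape::prop.part(tree)
  lab <- attr(pp, "labels")
  lapply(pp, function(idx) {
    tips <- sort(match(sort(lab[idx]), rownames(pd)))
    h <- if (length(idx) > 1) max(pd[lab[idx], lab[idx]]) / 2 else 0
    list(tips = sort(lab[idx]), height = h)
  })
}

# path-length (patristic) oracle: walk node-to-root paths
patristic_oracle <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  plen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(x) {
    p <- x
    while (parent[p] != 0) { p <- parent[p]; x <- c(x, p) }
    x
  }
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- path_to_root(ia); pb <- path_to_root(ib)
  mrca <- intersect(pa, pb)[1]
  sum(plen[pa[seq_len(which(pa == mrca) - 1L)]]) +
    sum(plen[pb[seq_len(which(pb == mrca) - 1L)]])
}

# build a hits data frame row for consensus tests (ungapped alignment)
fake_hit <- function(read_id, reference_id, start0, seq, qual = NULL,
                     ref_seq_at = seq) {
  data.frame(read_id = read_id, reference_id = reference_id,
             score = nchar(seq), ref_start = start0,
             ref_end = start0 + nchar(seq), strand = "+",
             edit_distance = sum(strsplit(seq, "")[[1]] != strsplit(ref_seq_at, "")[[1]]),
             read_length = nchar(seq),
             mean_qual = if (is.null(qual)) 30 else qual,
             aln_read = seq, aln_ref = ref_seq_at,
             stringsAsFactors = FALSE)
}
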